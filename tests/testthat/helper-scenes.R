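# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk.

# A short clean beat plus the default rig; memoized because several files
# need the same scene.
tiny_scene <- local({
  cache <- NULL
  function(n_frames = 200, noise_sigma_3d = 0) {
    key <- paste(n_frames, noise_sigma_3d)
    if (!is.null(cache) && cache$key == key) return(cache$value)
    tpl <- build_default_template()
    cfg <- motion_config(n_frames = n_frames, noise_sigma_3d = noise_sigma_3d)
    traj <- set_marker_shapes(simulate_beat(tpl, cfg), tpl)
    value <- list(template = tpl, cfg = cfg, traj = traj,
                  rig = default_camera_rig())
    cache <<- list(key = key, value = value)
    value
  }
})

# Random planar convex decagon embedded at a random 3D orientation;
# returns the 10 x 3 vertices plus its exact shoelace area (computed in
# the 2D plane before embedding - the independent oracle). Convexity by
# construction: the polygon is the convex hull of a uniform point cloud,
# redrawn until the hull has exactly 10 vertices.
random_convex_decagon <- function() {
  repeat {
    cloud <- matrix(stats::runif(120, -10, 10), ncol = 2)
    hull <- grDevices::chull(cloud)
    if (length(hull) == 10) break
  }
  pts2 <- cloud[hull, , drop = FALSE]
  x <- pts2[, 1]; y <- pts2[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  R <- cardiomark:::random_rotation()
  t3 <- stats::rnorm(3, sd = 20)
  pts3 <- cbind(pts2, 0) %*% t(R) + matrix(t3, 10, 3, byrow = TRUE)
  list(points = pts3, area = area)
}

# Exhaustive enumeration of all source -> sink paths of an observation
# graph (independent oracle for the shortest-path extraction); returns the
# minimum total cost and one minimizing node sequence.
enumerate_best_path <- function(frame, node_cost, edges, entry, exit) {
  n <- length(frame)
  out_adj <- split(seq_len(nrow(edges)), edges$from)
  best <- list(cost = Inf, path = integer())
  recurse <- function(v, path, cost) {
    total <- cost + exit
    if (total < best$cost) best <<- list(cost = total, path = path)
    oe <- out_adj[[as.character(v)]]
    for (k in oe) {
      w <- edges$to[k]
      recurse(w, c(path, w), cost + edges$cost[k] + node_cost[w])
    }
  }
  for (v in seq_len(n)) recurse(v, v, entry + node_cost[v])
  best
}

# Fabricated hypothesis table from explicit per-frame positions (one row
# per marker per frame), with unique detection ids and zero residuals.
fake_hypotheses <- function(pos_list) {
  rows <- list()
  det <- 0L
  for (f in seq_along(pos_list)) {
    P <- pos_list[[f]]
    if (is.null(P) || !nrow(P)) next
    for (i in seq_len(nrow(P))) {
      det <- det + 2L
      rows[[length(rows) + 1]] <- data.frame(
        frame = f - 1L, x = P[i, 1], y = P[i, 2], z = P[i, 3],
        det_a = det - 1L, det_b = det, reproj_px = 0, epi_px = 0,
        shared = FALSE)
    }
  }
  h <- do.call(rbind, rows)
  h <- h[order(h$frame), ]
  h$hyp <- seq_len(nrow(h))
  rownames(h) <- NULL
  h[, c("hyp", "frame", "x", "y", "z", "det_a", "det_b", "reproj_px",
        "epi_px", "shared")]
}

# All permutations of 1..n (tiny n only) - brute-force matching oracle.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (k in 1:n) out <- rbind(out, cbind(k, sub + (sub >= k)))
  out
}

# Apply one similarity transform to every frame of a trajectory set.
transform_trajectories <- function(traj, R = diag(3), t = c(0, 0, 0), s = 1) {
  P <- traj$positions
  for (f in seq_len(dim(P)[1]))
    P[f, , ] <- cardiomark:::apply_similarity(P[f, , , drop = TRUE], R, t, s)
  out <- trajectory_set(P, traj$frame_rate, traj$marker_id)
  attr(out, "shapes") <- attr(traj, "shapes")
  out
}
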