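#' Tracking parameters
#'
#' Gates, graph-cost coefficients and stop rules for the two-stage
#' graph-based 3D tracker. Edge cost between hypotheses at frames t and t'
#' (dt = t' - t) is `alpha * ||dx|| / dt + beta * (dt - 1) + gamma * mean
#' reprojection error`; every hypothesis node additionally contributes
#' `-node_reward` so that long, physically plausible chains have low
#' (negative) total cost, and virtual source/sink arcs cost
#' `entry_cost`/`exit_cost`. Tracklet extraction stops when the best
#' remaining source-to-sink path costs more than `stop_cost`, is shorter
#' than `min_tracklet_length` frames, or has mean per-edge cost above
#' `max_mean_edge_cost`.
#'
#' @param epipolar_gate_px admit a cross-view detection pair only if its
#'   symmetric epipolar distance is below this (px).
#' @param reproj_gate_px admit a triangulated hypothesis only if its mean
#'   reprojection error is below this (px).
#' @param max_gap maximum frame gap bridged inside a tracklet.
#' @param max_speed mm/frame speed gate for tracklet edges; see
#'   [derive_max_speed()] for the recommended data-driven default.
#' @param alpha,beta,gamma edge-cost coefficients (per mm, per frame,
#'   per px).
#' @param node_reward reward per hypothesis on a path.
#' @param entry_cost,exit_cost source/sink arc costs.
#' @param stop_cost,min_tracklet_length,max_mean_edge_cost stop rules.
#' @param max_link_gap maximum frame gap bridged when linking tracklets
#'   (25 frames = 50 ms at 500 Hz).
#' @param link_w_gap,link_w_dist,link_w_vel tracklet-link edge-cost weights
#'   for the temporal gap, end-to-start distance, and constant-velocity
#'   extrapolation mismatch.
#' @param link_slack_mm additive slack on the link distance gate.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(epipolar_gate_px = 2, reproj_gate_px = 1.5,
                            max_gap = 3, max_speed = 1,
                            alpha = 1, beta = 0.5, gamma = 0.1,
                            node_reward = 1, entry_cost = 0.5,
                            exit_cost = 0.5, stop_cost = -2,
                            min_tracklet_length = 5,
                            max_mean_edge_cost = 1,
                            max_link_gap = 25, link_w_gap = 0.05,
                            link_w_dist = 1, link_w_vel = 0.5,
                            link_slack_mm = 2) {
  p <- as.list(environment())
  stopifnot(p$max_gap >= 1, p$max_speed > 0, p$max_link_gap >= 1)
  class(p) <- "tracking_params"
  p
}

#' Data-driven speed gate
#'
#' The recommended `max_speed` gate: 1.5 times the peak frame-to-frame
#' marker speed observed in a noise-free simulation of the configured beat,
#' plus an allowance for the apparent jitter that pixel-localization noise
#' induces in the triangulated positions (`5 * noise_px * mm_per_px`, with
#' the mm-per-px scale taken at the scene centroid of the first camera).
#'
#' @param template,cfg the synthetic template and motion configuration.
#' @param cameras the camera pair (for the pixel scale).
#' @param noise_px expected detection noise, px.
#' @return mm/frame.
#' @export
derive_max_speed <- function(template, cfg, cameras, noise_px = 0.3) {
  cfg0 <- cfg
  cfg0$noise_sigma_3d <- 0
  cfg0$n_frames <- min(cfg$n_frames,
                       as.integer(ceiling(beat_period_frames(cfg))) + 1L)
  traj <- simulate_beat(template, cfg0)
  P <- traj$positions
  d <- P[-1, , , drop = FALSE] - P[-dim(P)[1], , , drop = FALSE]
  peak <- sqrt(max(apply(d^2, c(1, 2), sum)))
  cam <- cameras[[1]]
  ctr <- colMeans(template_positions(template))
  depth <- point_depths(cam, ctr)
  f_px <- vnorm(cam$projection[1, 1:3])
  mm_per_px <- depth / f_px
  1.5 * peak + 5 * noise_px * mm_per_px + 3 * cfg$noise_sigma_3d
}

#' Triangulate gated cross-view detection pairs into 3D hypotheses
#'
#' For every frame, all pairs of view-A and view-B detections whose
#' symmetric epipolar distance passes `epipolar_gate_px` are triangulated;
#' hypotheses whose mean reprojection error passes `reproj_gate_px` are
#' kept. A detection may participate in several hypotheses; the ambiguity is
#' resolved later by the observation graph.
#'
#' @param detections a `detection_set` (both views).
#' @param cameras list of the two [camera_model()]s, names matching the
#'   `view` column.
#' @param epipolar_gate_px,reproj_gate_px gates, px.
#' @return data frame with columns `hyp`, `frame`, `x`, `y`, `z`,
#'   `det_a`, `det_b`, `reproj_px`, `epi_px`, `shared` (TRUE when either
#'   source detection is an occlusion merge).
#' @export
build_hypotheses <- function(detections, cameras, epipolar_gate_px = 2,
                             reproj_gate_px = 1.5) {
  views <- vapply(cameras, function(c) c$view_id, "")
  da <- detections[detections$view == views[1], , drop = FALSE]
  db <- detections[detections$view == views[2], , drop = FALSE]
  F <- fundamental_from_cameras(cameras[[1]], cameras[[2]])
  fa <- split(seq_len(nrow(da)), da$frame)
  fb <- split(seq_len(nrow(db)), db$frame)
  common <- intersect(names(fa), names(fb))
  res <- vector("list", length(common))
  has_merge <- "merged_with" %in% names(detections)
  for (k in seq_along(common)) {
    ia <- fa[[common[k]]]; ib <- fb[[common[k]]]
    Ua <- cbind(da$u_px[ia], da$v_px[ia])
    Ub <- cbind(db$u_px[ib], db$v_px[ib])
    E <- epipolar_distance(Ua, Ub, F)
    pass <- which(E <= epipolar_gate_px, arr.ind = TRUE)
    if (!nrow(pass)) next
    tri <- triangulate_pairs(Ua[pass[, 1], , drop = FALSE],
                             Ub[pass[, 2], , drop = FALSE],
                             cameras[[1]], cameras[[2]])
    keep <- tri$reprojection_error <= reproj_gate_px
    if (!any(keep)) next
    sa <- ia[pass[keep, 1]]; sb <- ib[pass[keep, 2]]
    shared <- if (has_merge)
      !is.na(da$merged_with[sa]) | !is.na(db$merged_with[sb]) else
      rep(FALSE, length(sa))
    res[[k]] <- data.frame(
      frame = as.integer(common[k]),
      x = tri$points[keep, 1], y = tri$points[keep, 2],
      z = tri$points[keep, 3],
      det_a = da$det_id[sa], det_b = db$det_id[sb],
      reproj_px = tri$reprojection_error[keep],
      epi_px = E[pass[keep, , drop = FALSE]],
      shared = shared
    )
  }
  hyp <- do.call(rbind, res)
  if (is.null(hyp)) hyp <- data.frame(
    frame = integer(), x = numeric(), y = numeric(), z = numeric(),
    det_a = integer(), det_b = integer(), reproj_px = numeric(),
    epi_px = numeric(), shared = logical())
  hyp <- hyp[order(hyp$frame), , drop = FALSE]
  hyp$hyp <- seq_len(nrow(hyp))
  rownames(hyp) <- NULL
  hyp[, c("hyp", "frame", "x", "y", "z", "det_a", "det_b", "reproj_px",
          "epi_px", "shared")]
}

#' Build the weighted directed acyclic observation graph
#'
#' Nodes are 3D hypotheses (plus implicit source/sink); a directed edge runs
#' from a hypothesis at frame t to one at frame t' iff `1 <= t' - t <=
#' max_gap` and the implied speed `||dx|| / (t' - t)` is at most
#' `max_speed`. Edges carry the cost described in [tracking_params()];
#' acyclicity holds by construction because all edges increase the frame.
#'
#' @param hypotheses output of [build_hypotheses()] (sorted by frame).
#' @param params a [tracking_params()].
#' @return list of class `observation_graph` with `nodes`, `edges`
#'   (`from`, `to`, `cost`), and `params`.
#' @export
build_observation_graph <- function(hypotheses, params = tracking_params()) {
  h <- hypotheses
  stopifnot(!is.unsorted(h$frame))
  by_frame <- split(seq_len(nrow(h)), h$frame)
  frames <- as.integer(names(by_frame))
  P <- as.matrix(h[, c("x", "y", "z")])
  ef <- list(); k <- 0L
  for (i in seq_along(frames)) {
    for (dt in seq_len(params$max_gap)) {
      j <- match(frames[i] + dt, frames)
      if (is.na(j)) next
      a <- by_frame[[i]]; b <- by_frame[[j]]
      D <- cross_dist(P[a, , drop = FALSE], P[b, , drop = FALSE])
      ok <- which(D / dt <= params$max_speed, arr.ind = TRUE)
      if (!nrow(ok)) next
      from <- a[ok[, 1]]; to <- b[ok[, 2]]
      cost <- params$alpha * D[ok] / dt + params$beta * (dt - 1) +
        params$gamma * (h$reproj_px[from] + h$reproj_px[to]) / 2
      k <- k + 1L
      ef[[k]] <- data.frame(from = from, to = to, cost = cost)
    }
  }
  edges <- if (k) do.call(rbind, ef) else
    data.frame(from = integer(), to = integer(), cost = numeric())
  edges <- edges[order(edges$to, edges$from), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = h, edges = edges, params = params),
            class = "observation_graph")
}

# Deterministic successive shortest source->sink paths in a frame-ordered
# DAG. Nodes are processed in index order (already sorted by frame then id),
# ties resolved by keeping the first minimizing predecessor. Returns a list
# of integer node-index paths together with their total costs.
#
# remove_fn(path, active) -> updated active mask; defaults to removing only
# the path's own nodes.
dag_successive_paths <- function(frame, node_cost, edges,
                                 entry_cost, exit_cost,
                                 stop_cost, min_length,
                                 max_mean_edge_cost = Inf,
                                 remove_fn = NULL) {
  n <- length(frame)
  if (n == 0) return(list())
  stopifnot(!is.unsorted(frame))
  in_adj <- vector("list", n)
  if (nrow(edges)) {
    sp <- split(seq_len(nrow(edges)), edges$to)
    in_adj[as.integer(names(sp))] <- sp
  }
  e_from <- edges$from; e_cost <- edges$cost
  active <- rep(TRUE, n)
  paths <- list()
  repeat {
    best <- rep(Inf, n); parent <- integer(n); steps <- integer(n)
    for (v in seq_len(n)) {
      if (!active[v]) next
      b <- entry_cost; p <- 0L; st <- 1L
      ie <- in_adj[[v]]
      if (!is.null(ie)) {
        fr <- e_from[ie]
        cand <- best[fr] + e_cost[ie]
        m <- which.min(cand)
        if (length(m) && cand[m] < b) {
          b <- cand[m]; p <- fr[m]; st <- steps[p] + 1L
        }
      }
      best[v] <- b + node_cost[v]
      parent[v] <- p
      steps[v] <- st
    }
    total <- best + exit_cost
    total[!active] <- Inf
    v <- which.min(total)
    if (!length(v) || !is.finite(total[v]) || total[v] >= stop_cost) break
    path <- integer(steps[v])
    node <- v
    for (s in steps[v]:1) { path[s] <- node; node <- parent[node] }
    if (length(path) < min_length) break
    edge_costs <- best[path[length(path)]] - entry_cost -
      sum(node_cost[path])
    if (length(path) > 1 &&
        edge_costs / (length(path) - 1) > max_mean_edge_cost) break
    paths[[length(paths) + 1L]] <- list(path = path, cost = total[v])
    active <- if (is.null(remove_fn)) {
      a <- active; a[path] <- FALSE; a
    } else remove_fn(path, active)
    if (!any(active)) break
  }
  paths
}

#' Extract tracklets by successive shortest paths
#'
#' Repeatedly finds the minimum-cost source-to-sink path in the observation
#' graph (topological-order dynamic programming), emits it as a tracklet,
#' and removes its hypotheses together with every other hypothesis that
#' shares a 2D detection with them - except detections flagged as occlusion
#' merges, which legitimately serve two markers. Extraction stops according
#' to the rules in [tracking_params()]. Deterministic given the input.
#'
#' @param graph an [build_observation_graph()] result.
#' @return list of tracklets; each is a data frame of hypothesis rows in
#'   frame order with attribute `cost`.
#' @export
extract_tracklets <- function(graph) {
  h <- graph$nodes; p <- graph$params
  if (!nrow(h)) return(list())
  # map detection id -> hypothesis indices, for conflict removal
  det_map <- split(rep(seq_len(nrow(h)), 2), c(h$det_a, h$det_b))
  remove_fn <- function(path, active) {
    active[path] <- FALSE
    for (v in path) {
      if (h$shared[v]) next   # merged detection: exempt from exclusivity
      conflicts <- c(det_map[[as.character(h$det_a[v])]],
                     det_map[[as.character(h$det_b[v])]])
      active[conflicts] <- FALSE
    }
    active
  }
  res <- dag_successive_paths(
    frame = h$frame, node_cost = rep(-p$node_reward, nrow(h)),
    edges = graph$edges,
    entry_cost = p$entry_cost, exit_cost = p$exit_cost,
    stop_cost = p$stop_cost, min_length = p$min_tracklet_length,
    max_mean_edge_cost = p$max_mean_edge_cost,
    remove_fn = remove_fn
  )
  lapply(res, function(r) {
    tk <- h[r$path, , drop = FALSE]
    rownames(tk) <- NULL
    attr(tk, "cost") <- r$cost
    tk
  })
}

#' Link tracklets into full tracks
#'
#' A second DAG whose nodes are tracklets: an edge from tracklet u to
#' tracklet v exists when v starts 1 to `max_link_gap` frames after u ends
#' and the end-to-start distance is within the speed gate (plus slack); its
#' cost combines the temporal gap, the end-to-start distance, and the
#' mismatch between v's first position and a constant-velocity extrapolation
#' of u's tail. Successive shortest-path extraction yields disjoint tracklet
#' chains; every tracklet ends up in exactly one track. Frame gaps inside a
#' track are filled by linear interpolation and flagged.
#'
#' @param tracklets list from [extract_tracklets()].
#' @param params a [tracking_params()].
#' @return list of tracks; each a data frame `frame`, `x`, `y`, `z`,
#'   `det_a`, `det_b`, `interpolated` with attribute `tracklet_ids`.
#' @export
link_tracklets <- function(tracklets, params = tracking_params()) {
  nt <- length(tracklets)
  if (nt == 0) return(list())
  start_f <- vapply(tracklets, function(t) t$frame[1], 0L)
  end_f <- vapply(tracklets, function(t) t$frame[nrow(t)], 0L)
  head_p <- t(vapply(tracklets, function(t)
    as.numeric(t[1, c("x", "y", "z")]), numeric(3)))
  tail_p <- t(vapply(tracklets, function(t)
    as.numeric(t[nrow(t), c("x", "y", "z")]), numeric(3)))
  tail_v <- t(vapply(tracklets, function(t) {
    k <- min(nrow(t), 6)
    if (k < 2) return(c(0, 0, 0))
    tt <- t[(nrow(t) - k + 1):nrow(t), ]
    as.numeric((as.numeric(tt[k, c("x", "y", "z")]) -
                as.numeric(tt[1, c("x", "y", "z")])) /
               (tt$frame[k] - tt$frame[1]))
  }, numeric(3)))

  ord <- order(start_f, end_f)
  tl <- tracklets[ord]
  start_f <- start_f[ord]; end_f <- end_f[ord]
  head_p <- head_p[ord, , drop = FALSE]; tail_p <- tail_p[ord, , drop = FALSE]
  tail_v <- tail_v[ord, , drop = FALSE]

  ef <- list(); k <- 0L
  for (u in seq_len(nt)) {
    gap <- start_f - end_f[u]
    cand <- which(gap >= 1 & gap <= params$max_link_gap)
    if (!length(cand)) next
    d <- row_dist(head_p[cand, , drop = FALSE],
                  matrix(tail_p[u, ], length(cand), 3, byrow = TRUE))
    ok <- d <= params$max_speed * gap[cand] + params$link_slack_mm
    cand <- cand[ok]; d <- d[ok]
    if (!length(cand)) next
    extrap <- matrix(tail_p[u, ], length(cand), 3, byrow = TRUE) +
      outer(gap[cand], tail_v[u, ])
    mis <- row_dist(head_p[cand, , drop = FALSE], extrap)
    k <- k + 1L
    ef[[k]] <- data.frame(
      from = u, to = cand,
      cost = params$link_w_gap * gap[cand] + params$link_w_dist * d +
        params$link_w_vel * mis
    )
  }
  edges <- if (k) do.call(rbind, ef) else
    data.frame(from = integer(), to = integer(), cost = numeric())
  edges <- edges[order(edges$to, edges$from), , drop = FALSE]

  chains <- dag_successive_paths(
    frame = start_f, node_cost = rep(-1, nt), edges = edges,
    entry_cost = 0, exit_cost = 0, stop_cost = -0.5, min_length = 1
  )
  lapply(chains, function(ch) {
    parts <- lapply(tl[ch$path], function(t)
      t[, c("frame", "x", "y", "z", "det_a", "det_b")])
    obs <- do.call(rbind, parts)
    obs$interpolated <- FALSE
    obs <- obs[order(obs$frame), , drop = FALSE]
    filled <- fill_track_gaps(obs)
    rownames(filled) <- NULL
    attr(filled, "tracklet_ids") <- ch$path
    filled
  })
}

# Linear interpolation across interior frame gaps of a track.
fill_track_gaps <- function(obs) {
  gaps <- which(diff(obs$frame) > 1)
  if (!length(gaps)) return(obs)
  add <- list()
  for (g in gaps) {
    f0 <- obs$frame[g]; f1 <- obs$frame[g + 1]
    p0 <- as.numeric(obs[g, c("x", "y", "z")])
    p1 <- as.numeric(obs[g + 1, c("x", "y", "z")])
    fr <- (f0 + 1):(f1 - 1)
    w <- (fr - f0) / (f1 - f0)
    add[[length(add) + 1]] <- data.frame(
      frame = fr,
      x = p0[1] + w * (p1[1] - p0[1]),
      y = p0[2] + w * (p1[2] - p0[2]),
      z = p0[3] + w * (p1[3] - p0[3]),
      det_a = NA_integer_, det_b = NA_integer_, interpolated = TRUE
    )
  }
  out <- rbind(obs, do.call(rbind, add))
  out[order(out$frame), , drop = FALSE]
}

#' End-to-end multi-marker 3D tracking
#'
#' Composes the four tracking stages: hypothesis generation by gated
#' epipolar triangulation, observation-graph construction, tracklet
#' extraction by successive shortest paths, and tracklet linking.
#' Deterministic given inputs and parameters.
#'
#' @param detections a `detection_set` covering both views.
#' @param cameras the calibrated camera pair.
#' @param params a [tracking_params()].
#' @return list of class `track_set`: `trajectories` (a `trajectory_set`
#'   with anonymous labels `T1`, `T2`, ...), `tracks` (the per-track data
#'   frames), and `hypotheses`.
#' @export
track_markers <- function(detections, cameras, params = tracking_params()) {
  hyp <- build_hypotheses(detections, cameras,
                          epipolar_gate_px = params$epipolar_gate_px,
                          reproj_gate_px = params$reproj_gate_px)
  graph <- build_observation_graph(hyp, params)
  tracklets <- extract_tracklets(graph)
  tracks <- link_tracklets(tracklets, params)
  nf <- max(c(detections$frame, 0L)) + 1L
  nt <- length(tracks)
  pos <- array(NA_real_, dim = c(nf, max(nt, 1), 3))
  interp <- matrix(FALSE, nf, max(nt, 1))
  for (i in seq_len(nt)) {
    tr <- tracks[[i]]
    pos[tr$frame + 1L, i, ] <- as.matrix(tr[, c("x", "y", "z")])
    interp[tr$frame + 1L, i] <- tr$interpolated
  }
  labels <- if (nt) paste0("T", seq_len(nt)) else character()
  traj <- trajectory_set(pos[, seq_len(nt), , drop = FALSE],
                         frame_rate = attr(detections, "frame_rate") %||% NA,
                         marker_id = labels)
  attr(traj, "interpolated") <- interp[, seq_len(nt), drop = FALSE]
  structure(list(trajectories = traj, tracks = tracks, hypotheses = hyp,
                 params = params),
            class = "track_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.track_set <- function(x, ...) {
  cat("Track set:", length(x$tracks), "tracks from",
      nrow(x$hypotheses), "hypotheses\n")
  invisible(x)
}
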