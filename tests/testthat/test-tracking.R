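test_that("gated hypothesis generation recovers exactly the true markers", {
  sc <- tiny_scene(n_frames = 10)
  det <- project_and_corrupt(sc$traj, sc$rig, noise_px = 0, p_missing = 0,
                             fp_per_frame = 0, occlusion_radius_px = 0,
                             seed = 1)
  hyp <- build_hypotheses(det, sc$rig, epipolar_gate_px = 1e-6,
                          reproj_gate_px = 1e-6)
  expect_true(all(table(hyp$frame) == 35))
  # positions match the generator truth
  for (f in c(0, 5, 9)) {
    hf <- hyp[hyp$frame == f, ]
    D <- cardiomark:::cross_dist(as.matrix(hf[, c("x", "y", "z")]),
                                 sc$traj$positions[f + 1, , ])
    expect_lt(max(apply(D, 2, min)), 1e-6)
  }
  # zero-width gates reject noisy input almost entirely
  detn <- project_and_corrupt(sc$traj, sc$rig, noise_px = 0.5,
                              p_missing = 0, fp_per_frame = 0,
                              occlusion_radius_px = 0, seed = 1)
  hyp0 <- build_hypotheses(detn, sc$rig, epipolar_gate_px = 1e-9,
                           reproj_gate_px = 1e-9)
  expect_equal(nrow(hyp0), 0)
})

test_that("co-epipolar markers yield multiple hypotheses per detection", {
  # two world points on the same epipolar plane of the rig
  rig <- default_camera_rig()
  F <- fundamental_from_cameras(rig$A, rig$B)
  p1 <- c(0, -35, 0)
  # find a second point projecting onto p1's epipolar line in view B:
  # move along the view-A ray of p1 (same image point in A, so exactly
  # co-epipolar by construction)
  C <- cardiomark:::camera_center(rig$A)
  p2 <- C + 1.1 * (p1 - C)
  pos <- array(NA_real_, c(2, 2, 3))
  pos[1, 1, ] <- p1; pos[1, 2, ] <- p2
  pos[2, 1, ] <- p1; pos[2, 2, ] <- p2
  traj <- trajectory_set(pos, 500, c("1", "2"))
  det <- project_and_corrupt(traj, rig, noise_px = 0, p_missing = 0,
                             fp_per_frame = 0, occlusion_radius_px = 0,
                             seed = 1)
  hyp <- build_hypotheses(det, rig, epipolar_gate_px = 1,
                          reproj_gate_px = Inf)
  # 2 true + 2 ghost pairings, all emitted for the graph to resolve
  expect_equal(sum(hyp$frame == 0), 4)
})

test_that("observation graph edges obey the gates and are acyclic", {
  p <- tracking_params(max_gap = 2, max_speed = 0.5)
  # 3-frame toy set: brute-force enumeration of gated pairs
  pos <- list(rbind(c(0, 0, 0), c(5, 0, 0)),
              rbind(c(0.2, 0, 0), c(5.2, 0, 0)),
              rbind(c(0.4, 0, 0), c(5.4, 0, 0)))
  h <- fake_hypotheses(pos)
  g <- build_observation_graph(h, p)
  manual <- 0
  for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
    dt <- h$frame[j] - h$frame[i]
    d <- sqrt(sum((h[j, c("x", "y", "z")] - h[i, c("x", "y", "z")])^2))
    if (dt >= 1 && dt <= 2 && d / dt <= 0.5) manual <- manual + 1
  }
  expect_equal(nrow(g$edges), manual)
  expect_true(all(h$frame[g$edges$to] > h$frame[g$edges$from]))
  # two hypotheses farther apart than the speed gate get no edge
  far <- fake_hypotheses(list(rbind(c(0, 0, 0)), rbind(c(3, 0, 0))))
  expect_equal(nrow(build_observation_graph(far, p)$edges), 0)
})

test_that("a static chain is extracted whole with zero distance cost", {
  pos <- lapply(1:10, function(f) rbind(c(1, 2, 3)))
  h <- fake_hypotheses(pos)
  p <- tracking_params(max_speed = 0.5)
  g <- build_observation_graph(h, p)
  tks <- extract_tracklets(g)
  expect_length(tks, 1)
  expect_equal(nrow(tks[[1]]), 10)
  # cost: entry + exit - 10 rewards + 9 zero-distance edges
  expect_equal(attr(tks[[1]], "cost"),
               p$entry_cost + p$exit_cost - 10 * p$node_reward,
               tolerance = 1e-12)
})

test_that("crossing constant-velocity markers separate into pure tracklets", {
  # marker A moves +x, marker B passes it 0.3 mm away
  pos <- lapply(0:19, function(f)
    rbind(c(0.2 * f, 0, 0), c(4 - 0.2 * f, 0.3, 0)))
  h <- fake_hypotheses(pos)
  p <- tracking_params(max_speed = 1)
  tks <- extract_tracklets(build_observation_graph(h, p))
  expect_length(tks, 2)
  for (tk in tks) {
    # pure: y-coordinate constant within each tracklet
    expect_lt(diff(range(tk$y)), 1e-9)
    expect_equal(nrow(tk), 20)
  }
})

test_that("shortest-path extraction matches exhaustive enumeration", {
  # many random small instances: <= 6 frames x <= 4 markers
  set.seed(404)
  for (rep in 1:25) {
    nf <- sample(3:6, 1); nm <- sample(2:4, 1)
    pos <- lapply(seq_len(nf), function(f)
      matrix(stats::runif(nm * 3, 0, 2), nm, 3))
    h <- fake_hypotheses(pos)
    p <- tracking_params(max_gap = 2, max_speed = 4,
                         min_tracklet_length = 2, stop_cost = 0,
                         max_mean_edge_cost = Inf)
    g <- build_observation_graph(h, p)
    if (!nrow(g$edges)) next
    tks <- extract_tracklets(g)
    oracle <- enumerate_best_path(h$frame, rep(-p$node_reward, nrow(h)),
                                  g$edges, p$entry_cost, p$exit_cost)
    expect_equal(attr(tks[[1]], "cost"), oracle$cost, tolerance = 1e-9)
    expect_equal(tks[[1]]$hyp, oracle$path)
  }
})

test_that("extraction agrees with an independent graph-library oracle", {
  # fold node costs onto incoming arcs and compare the first path's cost
  # with igraph's Bellman-Ford distance on the same DAG
  set.seed(77)
  pos <- lapply(1:8, function(f) matrix(stats::runif(9, 0, 1.5), 3, 3))
  h <- fake_hypotheses(pos)
  p <- tracking_params(max_gap = 3, max_speed = 3,
                       min_tracklet_length = 2, stop_cost = 0)
  g <- build_observation_graph(h, p)
  tks <- extract_tracklets(g)

  n <- nrow(h)
  src <- n + 1L; snk <- n + 2L
  el <- rbind(
    cbind(g$edges$from, g$edges$to,
          g$edges$cost - p$node_reward),
    cbind(rep(src, n), seq_len(n), p$entry_cost - p$node_reward),
    cbind(seq_len(n), rep(snk, n), p$exit_cost)
  )
  ig <- igraph::graph_from_edgelist(el[, 1:2], directed = TRUE)
  d <- igraph::distances(ig, v = src, to = snk, mode = "out",
                         weights = el[, 3], algorithm = "bellman-ford")
  expect_equal(attr(tks[[1]], "cost"), as.numeric(d), tolerance = 1e-9)
})

test_that("a split tracklet is relinked and interpolated across the gap", {
  # constant-velocity marker, frames 0..29, observations missing 12..16
  pos <- lapply(0:29, function(f) {
    if (f >= 12 && f <= 16) return(NULL)
    rbind(c(0.1 * f, -0.05 * f, 0))
  })
  h <- fake_hypotheses(pos)
  p <- tracking_params(max_gap = 3, max_speed = 1, max_link_gap = 10)
  tks <- extract_tracklets(build_observation_graph(h, p))
  expect_length(tks, 2)
  trks <- link_tracklets(tks, p)
  expect_length(trks, 1)
  tr <- trks[[1]]
  expect_equal(nrow(tr), 30)
  expect_equal(sum(tr$interpolated), 5)
  truth <- t(vapply(0:29, function(f) c(0.1 * f, -0.05 * f, 0), numeric(3)))
  expect_lt(max(cardiomark:::row_dist(as.matrix(tr[, c("x", "y", "z")]),
                                      truth)), 1e-9)
})

test_that("distant tracklets are never linked; singletons pass through", {
  pos1 <- lapply(0:9, function(f) rbind(c(0.05 * f, 0, 0)))
  pos2 <- lapply(0:9, function(f)
    if (f < 3) NULL else rbind(c(50, 50, 50 + 0.05 * f)))
  h <- fake_hypotheses(mapply(rbind, pos1, pos2, SIMPLIFY = FALSE))
  p <- tracking_params(max_speed = 1, min_tracklet_length = 3)
  tks <- extract_tracklets(build_observation_graph(h, p))
  expect_length(tks, 2)
  trks <- link_tracklets(tks, p)
  expect_length(trks, 2)
  single <- link_tracklets(tks[1], p)
  expect_length(single, 1)
  expect_equal(nrow(single[[1]]), 10)
})

test_that("corruption-free input is recovered exactly", {
  sc <- tiny_scene(n_frames = 120)
  det <- project_and_corrupt(sc$traj, sc$rig, noise_px = 0, p_missing = 0,
                             fp_per_frame = 0, occlusion_radius_px = 0,
                             seed = 1)
  params <- tracking_params(
    max_speed = derive_max_speed(sc$template, sc$cfg, sc$rig, 0))
  ts <- track_markers(det, sc$rig, params)
  expect_length(ts$tracks, 35)
  ev <- evaluate_tracking(ts, sc$traj)
  expect_lt(ev$mean_rmse_mm, 1e-3)
  expect_equal(ev$min_completeness, 1)
  expect_equal(ev$min_purity, 1)
  expect_equal(ev$false_tracks, 0)
  # determinism: a second run is identical
  ts2 <- track_markers(det, sc$rig, params)
  expect_identical(ts$trajectories$positions, ts2$trajectories$positions)
})

test_that("zero detections produce zero tracks", {
  sc <- tiny_scene(n_frames = 5)
  det <- project_and_corrupt(sc$traj, sc$rig, p_missing = 1,
                             fp_per_frame = 0, seed = 1)
  ts <- track_markers(det, sc$rig, tracking_params())
  expect_length(ts$tracks, 0)
  ev <- evaluate_tracking(ts, sc$traj)
  expect_equal(ev$min_completeness, 0)
})

test_that("no 2D detection feeds two tracks at the same frame", {
  sc <- tiny_scene(n_frames = 60)
  det <- project_and_corrupt(sc$traj, sc$rig, noise_px = 0.3,
                             p_missing = 0.02, fp_per_frame = 2,
                             occlusion_radius_px = 0, seed = 3)
  params <- tracking_params(
    max_speed = derive_max_speed(sc$template, sc$cfg, sc$rig, 0.3))
  ts <- track_markers(det, sc$rig, params)
  used <- unlist(lapply(ts$tracks, function(t)
    c(t$det_a[!t$interpolated], t$det_b[!t$interpolated])))
  merged_ids <- det$det_id[!is.na(det$merged_with)]
  plain <- used[!used %in% merged_ids]
  expect_false(any(duplicated(plain)))
})

test_that("completeness does not improve when more detections go missing", {
  # 5-marker subscene over 20 seed pairs; mean completeness at high
  # p_missing must not exceed the low-p_missing mean (sampling slack)
  sc <- tiny_scene(n_frames = 80)
  keep <- c("1", "5", "13", "22", "33")
  sub <- trajectory_set(sc$traj$positions[, keep, , drop = FALSE], 500, keep)
  params <- tracking_params(
    max_speed = derive_max_speed(sc$template, sc$cfg, sc$rig, 0.3))
  mean_completeness <- function(p_miss, seeds) {
    mean(vapply(seeds, function(s) {
      det <- project_and_corrupt(sub, sc$rig, noise_px = 0.3,
                                 p_missing = p_miss, fp_per_frame = 0,
                                 occlusion_radius_px = 0, seed = s)
      ts <- track_markers(det, sc$rig, params)
      evaluate_tracking(ts, sub)$mean_completeness
    }, 0))
  }
  seeds <- 1:20
  lo <- mean_completeness(0.02, seeds)
  hi <- mean_completeness(0.40, seeds)
  expect_gte(lo, hi - 0.02)
})

test_that("evaluation metrics behave on constructed fixtures", {
  sc <- tiny_scene(n_frames = 50)
  # truth against itself
  ev <- evaluate_tracking(sc$traj, sc$traj)
  expect_equal(ev$mean_rmse_mm, 0)
  expect_equal(ev$min_completeness, 1)
  expect_equal(ev$min_purity, 1)
  expect_equal(ev$id_switches, 0)
  # swap the second halves of two distant markers: 2 identity switches
  P <- sc$traj$positions[, c("1", "33"), , drop = FALSE]
  swapped <- P
  swapped[26:50, 1, ] <- P[26:50, 2, ]
  swapped[26:50, 2, ] <- P[26:50, 1, ]
  two_truth <- trajectory_set(P, 500, c("1", "33"))
  two_tracks <- trajectory_set(swapped, 500, c("a", "b"))
  ev2 <- evaluate_tracking(two_tracks, two_truth)
  expect_equal(ev2$id_switches, 2)
  expect_lt(ev2$min_purity, 1)
})
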