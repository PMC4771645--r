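test_that("calibration pattern has the 18-hole 5/7/6 planar layout", {
  p <- generate_pattern()
  expect_equal(nrow(p), 18)
  expect_equal(as.integer(table(p$row)), c(5L, 7L, 6L))
  expect_true(all(p$z == p$z[1]))
  expect_equal(attr(p, "hole_diameter"), 5)
})

test_that("pattern holes are identified under random projective views", {
  set.seed(101)
  pat <- generate_pattern()
  n_ok <- 0
  for (i in 1:15) {
    R <- cardiomark:::rot_axis_angle(c(stats::runif(2, -1, 1), 1),
                                     stats::runif(1, 0, 0.5))
    t <- c(stats::runif(2, -20, 20), 0)
    W <- cardiomark:::pattern_points_world(pat, R, t)
    cam <- default_camera_rig(angle_deg = stats::runif(1, -50, 50),
                              distance = stats::runif(1, 600, 1000),
                              target = colMeans(W))[[1]]
    C <- cardiomark:::camera_center(cam)
    side <- as.numeric(t(R) %*% (C - t))[3] > 0
    perm <- sample(18)
    res <- identify_pattern_holes(project_points(cam, W)[perm, ],
                                  flip = side)
    expect_true(all(perm[res$obs] == res$hole))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 15)
})

test_that("pattern identification survives a 180-degree image rotation", {
  pat <- generate_pattern()
  cam <- default_camera_rig()[[1]]
  W <- cardiomark:::pattern_points_world(pat, diag(3), c(-30, -45, 0))
  uv <- project_points(cam, W)
  r1 <- identify_pattern_holes(uv, flip = TRUE)
  uv180 <- -uv + matrix(rep(2 * colMeans(uv), each = 18), ncol = 2)
  r2 <- identify_pattern_holes(uv180, flip = TRUE)
  expect_true(all(r1$obs == r1$hole))
  expect_true(all(r2$obs == r2$hole))
})

test_that("pattern identification fails explicitly on degenerate input", {
  pat <- generate_pattern()
  cam <- default_camera_rig()[[1]]
  uv <- project_points(cam, cardiomark:::pattern_points_world(
    pat, diag(3), c(-30, -45, 0)))
  expect_error(identify_pattern_holes(uv[1:17, ]), "at least 18")
})

test_that("DLT recovers a known camera exactly from noise-free views", {
  rig <- default_camera_rig()
  v <- simulate_calibration_views(rig$A)
  est <- calibrate_camera(v$world, v$image, view_id = "A")
  expect_lt(back_projection_error(est, v$world, v$image), 1e-6)
  # equal to truth up to scale (both stored with unit last-row norm)
  Pr <- est$projection / rig$A$projection
  expect_lt(diff(range(Pr[abs(rig$A$projection) > 1e-6])), 1e-6)
})

test_that("calibration under 0.5 px noise stays below 1 px back-projection", {
  # bound established beforehand by Monte-Carlo over repeated noisy draws
  # of the two-pose 36-point rig (mean error ~0.6 px)
  set.seed(2024)
  rig <- default_camera_rig()
  for (i in 1:5) {
    v <- simulate_calibration_views(rig$A, noise_px = 0.5)
    est <- calibrate_camera(v$world, v$image)
    expect_lt(back_projection_error(est, v$world, v$image), 1.0)
  }
})

test_that("degenerate calibration input raises explicit errors", {
  rig <- default_camera_rig()
  pat <- generate_pattern()
  W <- cardiomark:::pattern_points_world(pat)     # one pose: coplanar
  uv <- project_points(rig$A, W)
  expect_error(calibrate_camera(W, uv), "coplanar")
  v <- simulate_calibration_views(rig$A)
  expect_error(calibrate_camera(v$world[1:5, ], v$image[1:5, ]),
               "at least 6")
  expect_error(back_projection_error(rig$A, v$world[0, ], v$image[0, ]),
               "empty")
})

test_that("back-projection error matches direct projection arithmetic", {
  rig <- default_camera_rig()
  X <- matrix(stats::runif(60, -40, 40), ncol = 3)
  uv <- project_points(rig$A, X)
  expect_equal(back_projection_error(rig$A, X, uv), 0, tolerance = 1e-9)
  # shifting the principal point by one pixel shifts every projection by
  # exactly one pixel along u
  shifted <- rig$A
  shifted$projection[1, ] <- shifted$projection[1, ] +
    shifted$projection[3, ]
  expect_equal(back_projection_error(shifted, X, uv), 1, tolerance = 1e-9)
})

test_that("fundamental matrix satisfies the epipolar identity", {
  rig <- default_camera_rig()
  F <- fundamental_from_cameras(rig$A, rig$B)
  set.seed(5)
  X <- matrix(stats::runif(300, -40, 40), ncol = 3)
  ha <- cbind(project_points(rig$A, X), 1)
  hb <- cbind(project_points(rig$B, X), 1)
  expect_lt(max(abs(rowSums((hb %*% F) * ha))), 1e-9)
  expect_equal(sum(svd(F)$d > 1e-10 * svd(F)$d[1]), 2)   # rank 2
  Fba <- fundamental_from_cameras(rig$B, rig$A)
  expect_lt(min(max(abs(Fba - t(F))), max(abs(Fba + t(F)))), 1e-9)
  expect_error(fundamental_from_cameras(rig$A, rig$A), "centre")
})

test_that("epipolar distance measures perpendicular displacement", {
  rig <- default_camera_rig()
  F <- fundamental_from_cameras(rig$A, rig$B)
  X <- c(5, -20, 10)
  xa <- project_points(rig$A, X)[1, ]
  xb <- project_points(rig$B, X)[1, ]
  expect_lt(epipolar_distance(xa, xb, F)[1, 1], 1e-6)
  # displace xb perpendicular to its epipolar line by d px
  l <- as.numeric(F %*% c(xa, 1))
  nvec <- l[1:2] / sqrt(sum(l[1:2]^2))
  for (d in c(0.5, 2, 7)) {
    got <- epipolar_distance(xa, xb + d * nvec, F)[1, 1]
    # symmetric distance averages the two views' point-line distances,
    # each close to d for a near-orthonormal F pair
    expect_equal(got, d, tolerance = 0.15 * d)
  }
})

test_that("triangulation round trip is exact and degeneracies error", {
  rig <- default_camera_rig()
  X <- c(10, -50, 5)
  tri <- triangulate(project_points(rig$A, X)[1, ],
                     project_points(rig$B, X)[1, ], rig$A, rig$B)
  expect_lt(sqrt(sum((tri$point - X)^2)), 1e-6)
  expect_lt(tri$reprojection_error, 1e-6)
  expect_error(triangulate(c(512, 512), c(512, 512), rig$A, rig$A),
               "parallel")
})

test_that("symmetric pixel perturbations show up as reprojection error", {
  rig <- default_camera_rig()
  F <- fundamental_from_cameras(rig$A, rig$B)
  X <- c(0, -35, 0)
  xa <- project_points(rig$A, X)[1, ]
  xb <- project_points(rig$B, X)[1, ]
  # push the two detections 1 px in opposite directions along their
  # epipolar normal: the optimal 3D point splits the difference, leaving
  # about 1 px mean reprojection error
  l <- as.numeric(F %*% c(xa, 1))
  nvec <- l[1:2] / sqrt(sum(l[1:2]^2))
  tri <- triangulate(xa, xb + 2 * nvec, rig$A, rig$B)
  expect_equal(tri$reprojection_error, 1, tolerance = 0.15)
})

test_that("calibration/triangulation commute with uniform world scaling", {
  rig <- default_camera_rig()
  set.seed(8)
  X <- matrix(stats::runif(90, -40, 40), ncol = 3)
  ua <- project_points(rig$A, X); ub <- project_points(rig$B, X)
  s <- 2
  # cameras recalibrated against the scaled world see the same images
  va <- simulate_calibration_views(rig$A)
  vb <- simulate_calibration_views(rig$B)
  cam_a2 <- calibrate_camera(va$world * s, va$image, view_id = "A")
  cam_b2 <- calibrate_camera(vb$world * s, vb$image, view_id = "B")
  tri <- cardiomark:::triangulate_pairs(ua, ub, cam_a2, cam_b2)
  expect_lt(max(cardiomark:::row_dist(tri$points, s * X)), 1e-5)
})

test_that("camera JSON round trip preserves the projection", {
  rig <- default_camera_rig()
  path <- withr::local_tempfile(fileext = ".json")
  write_cameras_json(rig, path)
  back <- read_cameras_json(path)
  expect_equal(back$A$projection, rig$A$projection, tolerance = 1e-12)
  expect_equal(back$B$image_size, rig$B$image_size)
})
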