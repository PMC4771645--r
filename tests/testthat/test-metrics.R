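test_that("alpha11 matches hand trigonometry and handles degeneracies", {
  expect_equal(alpha11(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0)), 0)
  expect_equal(alpha11(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)), 90)
  expect_equal(alpha11(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 45)
  expect_equal(alpha11(c(1, 1, 1), c(2, 1, 1), c(0, 1, 1)), 180)
  expect_error(alpha11(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)), "coincident")
})

test_that("fan area of a regular decagon matches the analytic value", {
  th <- 2 * pi * (0:9) / 10
  deca <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_equal(annular_area(deca), 5 * 100 * sin(36 * pi / 180),
               tolerance = 1e-9)
  expect_equal(annular_area(matrix(1, 10, 3)), 0)
  expect_error(annular_area(deca[1:9, ]), "10")
})

test_that("fan area equals shoelace area for random planar convex 10-gons", {
  set.seed(31)
  for (i in 1:200) {
    d <- random_convex_decagon()
    expect_equal(annular_area(d$points), d$area, tolerance = 1e-9)
  }
})

test_that("least-squares plane recovers constructed geometries", {
  set.seed(4)
  # coplanar points: all orthogonal distances zero
  pts <- cbind(stats::runif(10, -5, 5), stats::runif(10, -5, 5), 2)
  pl <- least_squares_plane(pts)
  expect_lt(max(abs(sweep(pts, 2, pl$point) %*% pl$normal)), 1e-9)
  # symmetric saddle +-h about z = 0
  th <- 2 * pi * (0:9) / 10
  h <- 1.5
  saddle <- cbind(8 * cos(th), 8 * sin(th), h * cos(2 * th) * c(1, -1))
  saddle[, 3] <- h * rep(c(1, -1), 5)
  pl2 <- least_squares_plane(saddle)
  expect_equal(abs(pl2$normal[3]), 1, tolerance = 1e-9)
  d <- as.numeric(sweep(saddle, 2, pl2$point) %*% pl2$normal)
  expect_equal(abs(d), rep(h, 10), tolerance = 1e-9)
  # permutation invariance
  pl3 <- least_squares_plane(saddle[sample(10), ])
  expect_equal(abs(sum(pl3$normal * pl2$normal)), 1, tolerance = 1e-9)
  # collinear set errors
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(least_squares_plane(line), "collinear")
})

test_that("signed annular heights sum to zero and alternate on a saddle", {
  th <- 2 * pi * (0:9) / 10
  saddle <- cbind(8 * cos(th), 1.5 * rep(c(1, -1), 5), 8 * sin(th))
  h <- annular_heights(saddle, apex = c(0, -50, 0))
  expect_equal(sum(h), 0, tolerance = 1e-9)
  expect_equal(sign(h), rep(c(1, -1), 5))
  # translation invariance
  h2 <- annular_heights(sweep(saddle, 2, c(10, -3, 7), "+"),
                        apex = c(10, -53, 7))
  expect_equal(h, h2, tolerance = 1e-9)
  # coplanar ring: all zero
  flat <- cbind(8 * cos(th), 0, 8 * sin(th))
  expect_equal(annular_heights(flat, apex = c(0, -50, 0)), rep(0, 10),
               tolerance = 1e-9)
})

test_that("annular coordinate frame satisfies its defining constraints", {
  sc <- tiny_scene(n_frames = 30)
  for (f in c(1, 15, 30)) {
    ann <- sc$traj$positions[f, 1:10, ]
    apex <- sc$traj$positions[f, "33", ]
    fr <- annular_coordinate_system(ann, apex)
    A <- fr$axes
    expect_equal(A %*% t(A), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(det(A), 1, tolerance = 1e-9)
    expect_lt(abs(fr$to_frame(rbind(ann[3, ]))[1, 3]), 1e-9)  # z3 = 0
    apex_local <- fr$to_frame(rbind(apex))[1, ]
    expect_lt(abs(apex_local[1]), 1e-9)
    expect_lt(abs(apex_local[3]), 1e-9)
    expect_lt(apex_local[2], 0)                  # apex on negative y
    # z points anteriorly
    ant <- colMeans(ann[6:8, ]) - colMeans(ann)
    expect_gt(sum(A["z", ] * ant), 0)
  }
})

test_that("annular frame construction commutes with rigid motion", {
  sc <- tiny_scene(n_frames = 5)
  ann <- sc$traj$positions[1, 1:10, ]
  apex <- sc$traj$positions[1, "33", ]
  fr <- annular_coordinate_system(ann, apex)
  local0 <- fr$to_frame(ann)
  set.seed(17)
  for (i in 1:50) {
    R <- cardiomark:::random_rotation()
    t <- stats::rnorm(3, sd = 40)
    ann2 <- cardiomark:::apply_similarity(ann, R, t)
    apex2 <- as.numeric(R %*% apex + t)
    fr2 <- annular_coordinate_system(ann2, apex2)
    expect_equal(fr2$to_frame(ann2), local0, tolerance = 1e-8)
  }
  expect_error(annular_coordinate_system(ann, colMeans(ann)), "apex")
})

test_that("septal-lateral and apex distances are plain Euclidean metrics", {
  expect_equal(sl_diameter(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sl_diameter(c(0, 0, 0), c(3, 4, 0)), 5)
  th <- 2 * pi * (0:9) / 10
  ring <- cbind(cos(th), 0, sin(th))
  expect_equal(apex_annulus_distances(c(0, 0, 0), ring), rep(1, 10))
  d <- apex_annulus_distances(c(1, -7, 2), ring)
  expect_equal(d, apply(ring, 1, function(p) sl_diameter(p, c(1, -7, 2))))
  # monotone under pure apex-away translation
  d2 <- apex_annulus_distances(c(1, -17, 2), ring)
  expect_true(all(d2 > d))
})

test_that("RV strip triangulation matches a planar shoelace oracle", {
  # planar trapezoidal strips: 4/3/2 chains in the z = 0 plane
  basal <- cbind(c(0, 2, 4, 6), 0, 0)
  equat <- cbind(c(0.5, 3, 5.5), 2, 0)
  apic <- cbind(c(1.5, 4.5), 4, 0)
  rv <- rv_regional_areas(basal, equat, apic)
  expect_length(rv$triangle_areas, 8)
  shoelace <- function(xy) abs(sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) -
                                   c(xy[-1, 1], xy[1, 1]) * xy[, 2])) / 2
  poly1 <- rbind(basal[, 1:2], equat[3:1, 1:2])      # basal-equatorial strip
  poly2 <- rbind(equat[, 1:2], apic[2:1, 1:2])       # equatorial-apical strip
  expect_equal(rv$total, shoelace(poly1) + shoelace(poly2),
               tolerance = 1e-9)
  # similarity: doubling scales all areas by 4
  rv2 <- rv_regional_areas(2 * basal, 2 * equat, 2 * apic)
  expect_equal(rv2$triangle_areas, 4 * rv$triangle_areas, tolerance = 1e-9)
  # degenerate collinear level zeroes the affected triangles only
  rv3 <- rv_regional_areas(basal, cbind(c(0.5, 3, 5.5), 0, 0), apic)
  expect_equal(rv3$triangle_areas[1], 0)
  expect_error(rv_regional_areas(basal[1:3, ], equat, apic), "4")
})

test_that("LV surface area uses 16 triangles and needs the apex", {
  sc <- tiny_scene(n_frames = 2)
  P <- sc$traj$positions[1, , ]
  lv <- lv_surface_area(P[21:24, ], P[25:28, ], P[29:32, ], P[33, ])
  expect_length(lv$triangle_areas, 16)
  expect_gt(lv$total, 0)
  lv2 <- lv_surface_area(3 * P[21:24, ], 3 * P[25:28, ], 3 * P[29:32, ],
                         3 * P[33, ])
  expect_equal(lv2$total, 9 * lv$total, tolerance = 1e-9)
  expect_error(lv_surface_area(P[21:24, ], P[25:28, ], P[29:32, ], NULL),
               "apex")
})

test_that("annular-area extrema are located to within a frame", {
  f <- 0:499
  area <- 300 + 40 * cos(2 * pi * (f - 137) / 500)
  lm <- find_min_max_taa(area, f)
  expect_lte(abs(lm$max_taa_frame - 137), 1)
  expect_lte(abs(lm$min_taa_frame - 387), 1)
  # constant series: tie goes to the earliest frame
  lmc <- find_min_max_taa(rep(5, 100))
  expect_equal(lmc$min_taa_frame, 0)
  expect_equal(lmc$max_taa_frame, 0)
  # window 1 is the raw argmin/argmax
  noisy <- c(5, 1, 5, 5, 0.5, 5)
  expect_equal(find_min_max_taa(noisy, smooth_window = 1)$min_taa_frame, 4)
})

test_that("beat analysis reproduces the generator's analytic series", {
  sc <- tiny_scene(n_frames = 500)
  ba <- analyze_beat(sc$traj, template = sc$template)
  expect_equal(nrow(ba$metrics), 500)
  taa <- ba$metrics$taa_mm2
  expect_equal((max(taa) - min(taa)) / max(taa),
               sc$cfg$annular_area_amplitude, tolerance = 0.05)
  expect_equal(range(ba$metrics$alpha11_deg), sc$cfg$leaflet_angle_range,
               tolerance = 1e-6)
  expect_equal(ba$metrics$rv_total_mm2,
               rowSums(ba$metrics[, paste0("rv_tri_", 1:8, "_mm2")]),
               tolerance = 1e-9)
  # signed heights sum to zero every frame
  expect_lt(max(abs(rowSums(ba$metrics[, paste0("h", 1:10, "_mm")]))),
            1e-6)
  # landmark invariant: TAA at MinTAA below TAA at MaxTAA
  expect_lt(taa[ba$landmarks$min_taa_frame + 1],
            taa[ba$landmarks$max_taa_frame + 1])
})

test_that("a static heart yields constant metrics with MinTAA = MaxTAA", {
  tpl <- build_default_template()
  cfg <- motion_config(n_frames = 30, annular_area_amplitude = 0,
                       annular_height_amplitude = 0,
                       ventricular_contraction_fraction = 0,
                       leaflet_angle_range = c(40, 40), tapse_mm = 0,
                       noise_sigma_3d = 0)
  ba <- analyze_beat(simulate_beat(tpl, cfg), template = tpl)
  expect_lt(diff(range(ba$metrics$taa_mm2)), 1e-9)
  expect_equal(ba$metrics$taa_mm2[ba$landmarks$min_taa_frame + 1],
               ba$metrics$taa_mm2[ba$landmarks$max_taa_frame + 1])
})

test_that("missing required slots are reported by name", {
  sc <- tiny_scene(n_frames = 5)
  keep <- setdiff(sc$traj$marker_id, c("11", "33"))
  sub <- trajectory_set(sc$traj$positions[, keep, , drop = FALSE], 500,
                        keep)
  expect_error(analyze_beat(sub, template = sc$template),
               "leaflet.*apex|apex.*leaflet")
})

test_that("metrics are rigid-invariant; areas scale quadratically", {
  sc <- tiny_scene(n_frames = 40)
  ba <- analyze_beat(sc$traj, template = sc$template)
  set.seed(9)
  R <- cardiomark:::random_rotation()
  moved <- transform_trajectories(sc$traj, R, c(30, -10, 55), 1)
  ba2 <- analyze_beat(moved, template = sc$template)
  for (col in c("taa_mm2", "alpha11_deg", "ta_sl_mm", "rv_total_mm2",
                "lv_total_mm2"))
    expect_equal(ba2$metrics[[col]], ba$metrics[[col]], tolerance = 1e-6)
  scaled <- transform_trajectories(sc$traj, diag(3), c(0, 0, 0), 2)
  ba3 <- analyze_beat(scaled, template = sc$template)
  expect_equal(ba3$metrics$taa_mm2, 4 * ba$metrics$taa_mm2,
               tolerance = 1e-6)
  expect_equal(ba3$metrics$ta_sl_mm, 2 * ba$metrics$ta_sl_mm,
               tolerance = 1e-6)
})
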