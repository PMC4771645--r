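#' The 18-hole planar calibration pattern
#'
#' Generates the radiopaque plate used for camera calibration: 18 circular
#' holes of 5 mm diameter on a regular grid in the z = 0 plane, arranged in
#' three rows of 5, 7 and 6 holes. The asymmetric 5/7/6 row signature makes
#' the hole identities recoverable from an unordered projective view of the
#' plate (see [identify_pattern_holes()]).
#'
#' @param spacing hole-centre spacing, mm.
#' @return data frame of class `calibration_pattern` with columns `hole`
#'   (1-18), `row`, `col`, `x`, `y`, `z` (mm); attribute `hole_diameter`.
#' @examples
#' p <- generate_pattern()
#' table(p$row)   # 5 7 6
#' @export
generate_pattern <- function(spacing = 10) {
  counts <- c(5L, 7L, 6L)
  rows <- rep(1:3, counts)
  cols <- unlist(lapply(counts, seq_len))
  out <- data.frame(
    hole = seq_len(18L), row = rows, col = cols,
    x = (cols - 1) * spacing, y = (rows - 1) * spacing, z = 0
  )
  attr(out, "hole_diameter") <- 5
  class(out) <- c("calibration_pattern", "data.frame")
  out
}

# Pattern hole centres in world coordinates after a rigid pose (R, t).
pattern_points_world <- function(pattern, R = diag(3), t = c(0, 0, 0)) {
  apply_similarity(as.matrix(pattern[, c("x", "y", "z")]), R, t)
}

#' Identify the holes of the calibration pattern in an unordered 2D view
#'
#' Given unordered 2D centres from a (possibly projectively distorted) image
#' of the 18-hole plate, recovers the bijection between observations and
#' pattern hole indices. Rows are found as maximal collinear groups and the
#' 5/7/6 row-count signature resolves which row is which - including under a
#' 180 degree rotation of the image. What no single view of a planar target
#' can resolve is its mirror image (both interpretations are exact
#' homographies), which physically corresponds to imaging the plate from
#' its front or its back: the along-row order is therefore fixed by an
#' orientation convention. With `flip = FALSE` the local orientation of the
#' (row direction, row-1-to-row-3) axes in the image is taken to match the
#' pattern's (x, y) axes - the view from the plate's negative-z side; set
#' `flip = TRUE` when the plate is imaged from the other side.
#'
#' @param points n x 2 matrix of observed centres (px), n >= 18; extra
#'   spurious points are tolerated provided they are not collinear with a
#'   row.
#' @param collinear_tol tolerance for row membership, as a fraction of the
#'   median nearest-neighbour spacing.
#' @param flip mirrored (back-side) interpretation?
#' @return data frame with columns `obs` (row index into `points`) and
#'   `hole` (pattern hole 1-18); 18 rows.
#' @export
identify_pattern_holes <- function(points, collinear_tol = 0.15,
                                   flip = FALSE) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 18) stop("need at least 18 observed centres, got ", n)

  # scale for the collinearity tolerance: median nearest-neighbour distance
  D <- cross_dist(pts, pts); diag(D) <- Inf
  tol <- collinear_tol * stats::median(apply(D, 1, min))

  # find supported lines by exhaustive pair enumeration
  line_inliers <- function(i, j) {
    d <- unitv(pts[j, ] - pts[i, ])
    nvec <- c(-d[2], d[1])
    off <- abs(as.numeric((sweep(pts, 2, pts[i, ])) %*% nvec))
    which(off < tol)
  }
  best <- list()
  used <- rep(FALSE, n)
  cand <- utils::combn(n, 2)
  # greedy: repeatedly take the largest-support line among unused points
  for (rep_i in 1:3) {
    sup <- list(); size <- integer(0)
    for (k in seq_len(ncol(cand))) {
      i <- cand[1, k]; j <- cand[2, k]
      if (used[i] || used[j]) next
      inl <- line_inliers(i, j)
      inl <- inl[!used[inl]]
      sup[[length(sup) + 1]] <- inl
      size <- c(size, length(inl))
    }
    if (!length(size)) stop("pattern identification failed: no rows found")
    take <- sup[[which.max(size)]]
    best[[rep_i]] <- take
    used[take] <- TRUE
  }
  counts <- lengths(best)
  if (!setequal(counts, c(5L, 6L, 7L)))
    stop("pattern identification failed: row sizes ", paste(sort(counts),
         collapse = "/"), " do not match the 5/7/6 signature")

  r1 <- best[[which(counts == 5)]]
  r2 <- best[[which(counts == 7)]]
  r3 <- best[[which(counts == 6)]]

  # order each row along the direction of the 7-hole (middle) row
  d2 <- unitv(pts[r2[which.max(cross_dist(pts[r2, , drop = FALSE],
                                          pts[r2[1], , drop = FALSE]))], ] -
              pts[r2[1], ])
  ord_along <- function(idx) idx[order(as.numeric(pts[idx, , drop = FALSE] %*% d2))]
  r1 <- ord_along(r1); r2 <- ord_along(r2); r3 <- ord_along(r3)

  # the 5-row and 6-row must flank the 7-row; orientation convention:
  # (row direction) x (row1 -> row3 direction) must have the pattern's sign
  c1 <- colMeans(pts[r1, , drop = FALSE])
  c2 <- colMeans(pts[r2, , drop = FALSE])
  c3 <- colMeans(pts[r3, , drop = FALSE])
  if (sum((c1 - c2) * (c3 - c2)) > 0)
    stop("pattern identification failed: 7-hole row is not between the others")
  crossz <- d2[1] * (c3 - c1)[2] - d2[2] * (c3 - c1)[1]
  # pattern: rows ordered +y, columns ordered +x => cross (+x) x (+y) = +1
  if ((crossz < 0) != flip) { r1 <- rev(r1); r2 <- rev(r2); r3 <- rev(r3) }

  data.frame(obs = c(r1, r2, r3), hole = 1:18)
}

#' Calibrate a camera by the direct linear transform
#'
#' Estimates the 3x4 projection matrix from >= 6 world/image correspondences
#' using the DLT with Hartley normalization (centroid shift and isotropic
#' scaling of both point sets) for numerical conditioning. A single planar
#' target cannot determine a full projective camera, so the world points must
#' not be coplanar: image the plate at two or more poses, or add out-of-plane
#' control points.
#'
#' @param world n x 3 matrix, mm.
#' @param image n x 2 matrix, px.
#' @param image_size (width, height) px recorded in the model.
#' @param view_id identifier.
#' @return a [camera_model()].
#' @export
calibrate_camera <- function(world, image, image_size = c(1024L, 1024L),
                             view_id = "A") {
  world <- as.matrix(world); image <- as.matrix(image)
  if (nrow(world) != nrow(image)) stop("world/image point counts differ")
  if (nrow(world) < 6) stop("need at least 6 correspondences, got ", nrow(world))
  sv <- svd(scale(world, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1])
    stop("degenerate configuration: world points are (near-)coplanar; ",
         "image the plate at a second pose or add out-of-plane points")

  nw <- hartley_normalization(world)
  ni <- hartley_normalization(image)
  Xn <- nw$normalized; xn <- ni$normalized
  n <- nrow(world)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- c(Xn[i, ], 1)
    A[2 * i - 1, ] <- c(X, rep(0, 4), -xn[i, 1] * X)
    A[2 * i, ] <- c(rep(0, 4), X, -xn[i, 2] * X)
  }
  p <- svd(A)$v[, 12]
  Pn <- matrix(p, 3, 4, byrow = TRUE)
  P <- solve(ni$T) %*% Pn %*% nw$T
  # orient so depths are positive for the calibration points
  cm <- camera_model(P, image_size = image_size, view_id = view_id)
  if (mean(point_depths(cm, world) < 0) > 0.5)
    cm$projection <- -cm$projection
  cm
}

# Hartley conditioning: shift to centroid, scale so mean radius = sqrt(d).
hartley_normalization <- function(pts) {
  pts <- as.matrix(pts)
  d <- ncol(pts)
  ctr <- colMeans(pts)
  r <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  s <- if (r > 0) sqrt(d) / r else 1
  T <- diag(c(rep(s, d), 1))
  T[seq_len(d), d + 1] <- -s * ctr
  hom <- cbind(pts, 1) %*% t(T)
  list(T = T, normalized = hom[, seq_len(d), drop = FALSE] /
         hom[, d + 1])
}

#' Mean back-projection error of a calibrated camera
#'
#' Mean Euclidean pixel distance between the projections of known world
#' points and their observed image positions; the standard calibration
#' quality metric for this kind of rig.
#'
#' @param camera a [camera_model()].
#' @param world n x 3 mm.
#' @param image n x 2 px.
#' @return mean error, px.
#' @export
back_projection_error <- function(camera, world, image) {
  world <- as.matrix(world); image <- as.matrix(image)
  if (nrow(world) == 0) stop("empty correspondence set")
  mean(row_dist(project_points(camera, world), image))
}

#' Fundamental matrix of a calibrated camera pair
#'
#' Computes F such that for corresponding homogeneous image points
#' `x_b' F x_a = 0`. Built from the cameras as `[e_b]_x P_b P_a^+` where
#' `e_b` is the epipole (projection of camera A's centre in view B).
#'
#' @param cam_a,cam_b two distinct [camera_model()]s.
#' @return 3x3 matrix of rank 2, scaled to unit Frobenius norm.
#' @export
fundamental_from_cameras <- function(cam_a, cam_b) {
  Ca <- camera_center(cam_a)
  Cb <- camera_center(cam_b)
  if (vnorm(Ca - Cb) < 1e-9)
    stop("degenerate pair: the two cameras share a centre")
  e_b <- as.numeric(cam_b$projection %*% c(Ca, 1))
  Ex <- matrix(c(0, e_b[3], -e_b[2],
                 -e_b[3], 0, e_b[1],
                 e_b[2], -e_b[1], 0), 3, 3)
  Pa_pinv <- t(cam_a$projection) %*%
    solve(cam_a$projection %*% t(cam_a$projection))
  F <- Ex %*% cam_b$projection %*% Pa_pinv
  F / sqrt(sum(F^2))
}

#' Symmetric epipolar distance
#'
#' Mean of the two point-to-epipolar-line pixel distances for a candidate
#' correspondence: the distance of `xb` to the line `F xa` plus the distance
#' of `xa` to `t(F) xb`, divided by two. Vectorized: `xa` (n x 2) against
#' `xb` (m x 2) gives an n x m matrix.
#'
#' @param xa,xb 2D points (px) in views A and B; vectors or matrices.
#' @param F fundamental matrix from [fundamental_from_cameras()] (view A to
#'   view B convention).
#' @return matrix of symmetric epipolar distances, px.
#' @export
epipolar_distance <- function(xa, xb, F) {
  xa <- matrix(as.numeric(xa), ncol = 2)
  xb <- matrix(as.numeric(xb), ncol = 2)
  ha <- cbind(xa, 1); hb <- cbind(xb, 1)
  la <- ha %*% t(F)              # n x 3: epipolar lines in view B
  lb <- hb %*% F                 # m x 3: epipolar lines in view A
  num <- abs(tcrossprod(la, hb)) # n x m: |l_a . x_b|
  da <- num / sqrt(la[, 1]^2 + la[, 2]^2)
  db <- t(abs(tcrossprod(lb, ha))) / rep(sqrt(lb[, 1]^2 + lb[, 2]^2),
                                         each = nrow(xa))
  (da + db) / 2
}

#' Triangulate a stereo correspondence
#'
#' Homogeneous DLT triangulation (SVD, smallest singular vector) of one 2D
#' correspondence into a 3D point, with the mean two-view reprojection error.
#'
#' @param xa,xb length-2 pixel positions in views A and B.
#' @param cam_a,cam_b the calibrated pair.
#' @return list with `point` (3-vector, mm) and `reprojection_error` (px).
#' @export
triangulate <- function(xa, xb, cam_a, cam_b) {
  Pa <- cam_a$projection; Pb <- cam_b$projection
  A <- rbind(
    xa[1] * Pa[3, ] - Pa[1, ],
    xa[2] * Pa[3, ] - Pa[2, ],
    xb[1] * Pb[3, ] - Pb[1, ],
    xb[2] * Pb[3, ] - Pb[2, ]
  )
  s <- svd(A)
  X <- s$v[, 4]
  if (s$d[3] < 1e-9 * s$d[1] || abs(X[4]) < 1e-12 * vnorm(X[1:3]))
    stop("degenerate triangulation: rays are (near-)parallel")
  pt <- X[1:3] / X[4]
  err <- (vnorm(project_points(cam_a, pt) - xa) +
          vnorm(project_points(cam_b, pt) - xb)) / 2
  list(point = pt, reprojection_error = err)
}

# Batch triangulation of paired pixel rows (n x 2 each); returns list of
# n x 3 points and n reprojection errors. Loop over small SVDs is fast
# enough at the problem sizes used here.
triangulate_pairs <- function(Ua, Ub, cam_a, cam_b) {
  n <- nrow(Ua)
  pts <- matrix(NA_real_, n, 3)
  Pa <- cam_a$projection; Pb <- cam_b$projection
  for (i in seq_len(n)) {
    A <- rbind(
      Ua[i, 1] * Pa[3, ] - Pa[1, ],
      Ua[i, 2] * Pa[3, ] - Pa[2, ],
      Ub[i, 1] * Pb[3, ] - Pb[1, ],
      Ub[i, 2] * Pb[3, ] - Pb[2, ]
    )
    X <- svd(A, nu = 0)$v[, 4]
    pts[i, ] <- X[1:3] / X[4]
  }
  ra <- row_dist(project_points(cam_a, pts), Ua)
  rb <- row_dist(project_points(cam_b, pts), Ub)
  list(points = pts, reprojection_error = (ra + rb) / 2)
}

#' Simulate calibration correspondences from a known rig
#'
#' Images the 18-hole plate at several rigid poses through a ground-truth
#' camera, optionally corrupting the detected hole centres with Gaussian
#' pixel noise. Two default poses (one tilted out of plane) provide the
#' non-coplanar world set the DLT needs.
#'
#' @param camera ground-truth [camera_model()].
#' @param pattern a [generate_pattern()].
#' @param poses list of `list(R, t)` rigid poses for the plate.
#' @param noise_px Gaussian noise sd added to image points.
#' @return list with `world` (n x 3) and `image` (n x 2).
#' @export
simulate_calibration_views <- function(camera, pattern = generate_pattern(),
                                       poses = default_plate_poses(),
                                       noise_px = 0) {
  world <- do.call(rbind, lapply(poses, function(p)
    pattern_points_world(pattern, p$R, p$t)))
  image <- project_points(camera, world)
  if (noise_px > 0)
    image <- image + stats::rnorm(length(image), sd = noise_px)
  list(world = world, image = image)
}

#' @rdname simulate_calibration_views
#' @export
default_plate_poses <- function() {
  list(
    list(R = diag(3), t = c(-30, -60, -20)),
    list(R = rot_axis_angle(c(1, 0, 0), 35 * pi / 180) %*%
           rot_axis_angle(c(0, 1, 0), 20 * pi / 180),
         t = c(-30, -20, 30))
  )
}
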