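#' Projective camera model
#'
#' A finite projective camera mapping homogeneous world coordinates (mm) to
#' homogeneous image coordinates (px) through a 3x4 matrix. The matrix is
#' stored normalized so that its last-row rotation part (first three entries
#' of row 3) has unit norm; this makes the third homogeneous coordinate equal
#' to the signed depth along the principal axis.
#'
#' @param projection 3x4 numeric matrix; the left 3x3 block must have full
#'   rank.
#' @param image_size length-2 integer (width, height) in px.
#' @param view_id identifier string.
#' @return list of class `camera_model`.
#' @export
camera_model <- function(projection, image_size = c(1024L, 1024L),
                         view_id = "A") {
  P <- matrix(as.numeric(projection), 3, 4)
  if (abs(det(P[, 1:3])) < 1e-12) stop("left 3x3 block of projection is singular")
  n3 <- vnorm(P[3, 1:3])
  P <- P / n3
  structure(list(projection = P, image_size = as.integer(image_size),
                 view_id = view_id),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Camera", x$view_id, "-", x$image_size[1], "x", x$image_size[2], "px\n")
  print(round(x$projection, 4))
  invisible(x)
}

#' Project world points into a camera
#'
#' @param camera a [camera_model()].
#' @param points n x 3 matrix (mm), or length-3 vector.
#' @return n x 2 matrix of (u, v) pixel coordinates.
#' @export
project_points <- function(camera, points) {
  X <- rbind(t(matrix(as.numeric(points), ncol = 3)), 1)
  x <- camera$projection %*% X
  t(x[1:2, , drop = FALSE] / rep(x[3, ], each = 2))
}

# Signed depths of world points (positive = in front for a proper camera).
point_depths <- function(camera, points) {
  X <- rbind(t(matrix(as.numeric(points), ncol = 3)), 1)
  as.numeric(camera$projection[3, ] %*% X)
}

# Camera centre (world mm): -M^-1 p4 for a finite camera P = [M | p4].
camera_center <- function(camera) {
  P <- camera$projection
  as.numeric(-solve(P[, 1:3], P[, 4]))
}

#' Default synthetic biplane rig
#'
#' Two calibrated cameras emulating a biplane X-ray acquisition: both look at
#' the heart centre from `distance` mm, separated by `angle_deg` about the
#' long (y) axis, with focal length `focal` px. The default focal length
#' frames the ~100 mm marker array across most of the 1024 px detector
#' (about 0.13 mm per px at the isocentre), as a clinical acquisition
#' would. Useful as ground truth for simulation and as the reference rig
#' the synthetic calibration recovers.
#'
#' The two views also differ in elevation (cranio-caudal angulation), as
#' clinical biplane projections do; without it the epipolar planes would all
#' contain the horizontal baseline, and marker pairs lying at equal heights
#' would stay co-epipolar for whole beats, creating persistent triangulation
#' ghosts no tracker could disambiguate.
#'
#' @param angle_deg angular separation of the two views, degrees.
#' @param distance source-to-isocentre distance, mm.
#' @param focal focal length, px.
#' @param image_size (width, height) px.
#' @param target world point both cameras look at (mm).
#' @param elevation_deg length-2 elevations of the two views, degrees.
#' @return list of two [camera_model()]s named `A` and `B`.
#' @export
default_camera_rig <- function(angle_deg = 60, distance = 800, focal = 6000,
                               image_size = c(1024L, 1024L),
                               target = c(0, -35, 0),
                               elevation_deg = c(-10, 25)) {
  K <- matrix(c(focal, 0, 0,
                0, focal, 0,
                image_size[1] / 2, image_size[2] / 2, 1), 3, 3)
  one <- function(az_deg, el_deg, id) {
    az <- az_deg * pi / 180
    el <- el_deg * pi / 180
    centre <- target + distance * c(sin(az) * cos(el), sin(el),
                                    cos(az) * cos(el))
    z_axis <- unitv(target - centre)             # optical axis toward target
    x_axis <- unitv(cross3(c(0, 1, 0), z_axis))
    y_axis <- cross3(z_axis, x_axis)
    R <- rbind(x_axis, y_axis, z_axis)
    P <- K %*% cbind(R, -R %*% centre)
    camera_model(P, image_size = image_size, view_id = id)
  }
  list(A = one(-angle_deg / 2, elevation_deg[1], "A"),
       B = one(angle_deg / 2, elevation_deg[2], "B"))
}

#' Write / read cameras as JSON
#'
#' The JSON layout is a list of objects `{view_id, projection (12 numbers,
#' row-major), image_size}`.
#'
#' @param cameras list of [camera_model()]s.
#' @param path file path.
#' @return `read_cameras_json` returns a named list of cameras.
#' @export
write_cameras_json <- function(cameras, path) {
  obj <- lapply(cameras, function(cm) list(
    view_id = cm$view_id,
    projection = as.numeric(t(cm$projection)),
    image_size = cm$image_size
  ))
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cameras_json
#' @export
read_cameras_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cams <- lapply(seq_len(nrow(obj)), function(i) {
    camera_model(matrix(unlist(obj$projection[i]), 3, 4, byrow = TRUE),
                 image_size = unlist(obj$image_size[i]),
                 view_id = obj$view_id[i])
  })
  names(cams) <- vapply(cams, function(c) c$view_id, "")
  cams
}
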