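#' Project trajectories into both views and corrupt the detections
#'
#' Emulates the imperfections of real fluoroscopic marker detection: each
#' true marker position is projected into each calibrated view, then
#' (in this order) detections are dropped independently with probability
#' `p_missing`, true projections closer than `occlusion_radius_px` within a
#' view are merged into a single detection at their midpoint (a 2D occlusion
#' event), Gaussian localization noise of sd `noise_px` is added, and
#' `Poisson(fp_per_frame)` false positives are drawn uniformly over the
#' image. Every detection carries a hidden ground-truth annotation (the
#' marker id, a possible merge partner, and the marker shape) intended only
#' for evaluation; [write_detection_csv()] with `blinded = TRUE` drops it.
#'
#' @param traj a `trajectory_set` of true marker positions (mm).
#' @param cameras list of two [camera_model()]s (views A and B).
#' @param noise_px localization noise sd, px.
#' @param p_missing per-detection drop probability in `[0, 1]`.
#' @param fp_per_frame expected false positives per frame per view.
#' @param occlusion_radius_px merge radius for projective occlusions, px.
#' @param seed integer RNG seed.
#' @return data frame of class `detection_set` with columns `view`, `frame`
#'   (0-based), `u_px`, `v_px`, `det_id` (unique per view), `truth_id` (-1
#'   for false positives), `merged_with` (second marker id of an occlusion
#'   merge, else NA), `shape`; attribute `image_size`.
#' @export
project_and_corrupt <- function(traj, cameras, noise_px = 0.3,
                                p_missing = 0.02, fp_per_frame = 2,
                                occlusion_radius_px = 2, seed = 1L) {
  stopifnot(inherits(traj, "trajectory_set"), length(cameras) == 2)
  if (p_missing < 0 || p_missing > 1) stop("p_missing must be in [0, 1]")
  if (noise_px < 0 || fp_per_frame < 0 || occlusion_radius_px < 0)
    stop("noise_px, fp_per_frame and occlusion_radius_px must be >= 0")
  set.seed(seed)
  nf <- n_frames(traj)
  ids <- suppressWarnings(as.integer(traj$marker_id))
  shapes <- attr(traj, "shapes")
  out <- vector("list", 2L)
  for (vi in 1:2) {
    cam <- cameras[[vi]]
    view <- cam$view_id
    W <- cam$image_size[1]; H <- cam$image_size[2]
    per_frame <- vector("list", nf)
    for (f in seq_len(nf)) {
      P <- traj$positions[f, , , drop = TRUE]
      ok <- which(!is.na(P[, 1]))
      uv <- if (length(ok)) project_points(cam, P[ok, , drop = FALSE]) else
        matrix(0, 0, 2)
      tid <- ids[ok]
      shp <- if (is.null(shapes)) rep(NA_character_, length(ok)) else shapes[ok]
      keep <- stats::runif(length(ok)) >= p_missing
      uv <- uv[keep, , drop = FALSE]; tid <- tid[keep]; shp <- shp[keep]
      merged <- rep(NA_integer_, nrow(uv))
      if (occlusion_radius_px > 0 && nrow(uv) > 1) {
        cl <- merge_close_points(uv, occlusion_radius_px)
        if (any(duplicated(cl))) {
          uv2 <- rowsum(uv, cl) / as.vector(table(cl))
          first <- tapply(tid, cl, function(v) v[1])
          second <- tapply(tid, cl, function(v) if (length(v) > 1) v[2] else
            NA_integer_)
          shp2 <- tapply(shp, cl, function(v) v[1])
          uv <- uv2; tid <- as.integer(first)
          merged <- as.integer(second); shp <- as.character(shp2)
        }
      }
      if (noise_px > 0 && nrow(uv) > 0)
        uv <- uv + stats::rnorm(length(uv), sd = noise_px)
      n_fp <- stats::rpois(1, fp_per_frame)
      if (n_fp > 0) {
        uv <- rbind(uv, cbind(stats::runif(n_fp, 0, W),
                              stats::runif(n_fp, 0, H)))
        tid <- c(tid, rep(-1L, n_fp))
        merged <- c(merged, rep(NA_integer_, n_fp))
        shp <- c(shp, rep(NA_character_, n_fp))
      }
      per_frame[[f]] <- if (nrow(uv)) data.frame(
        view = view, frame = f - 1L, u_px = uv[, 1], v_px = uv[, 2],
        truth_id = tid, merged_with = merged, shape = shp
      ) else NULL
    }
    out[[vi]] <- do.call(rbind, per_frame)
  }
  det <- do.call(rbind, out)
  if (is.null(det)) det <- data.frame(
    view = character(), frame = integer(), u_px = numeric(), v_px = numeric(),
    truth_id = integer(), merged_with = integer(), shape = character())
  det$det_id <- seq_len(nrow(det))
  det <- det[, c("view", "frame", "u_px", "v_px", "det_id", "truth_id",
                 "merged_with", "shape")]
  rownames(det) <- NULL
  attr(det, "image_size") <- cameras[[1]]$image_size
  attr(det, "frame_rate") <- traj$frame_rate
  class(det) <- c("detection_set", "data.frame")
  det
}

# Single-linkage grouping of 2D points with link distance <= radius;
# returns a cluster label per point.
merge_close_points <- function(uv, radius) {
  n <- nrow(uv)
  lab <- seq_len(n)
  D <- cross_dist(uv, uv)
  close <- which(D <= radius & upper.tri(D), arr.ind = TRUE)
  if (nrow(close)) {
    for (k in seq_len(nrow(close))) {
      a <- lab[close[k, 1]]; b <- lab[close[k, 2]]
      if (a != b) lab[lab == b] <- a
    }
  }
  match(lab, unique(lab))
}

#' Attach marker shapes to a trajectory set
#'
#' Records each marker's shape (from the template) on a trajectory set so
#' that [project_and_corrupt()] can tag detections the way a human reader
#' of the X-ray would (ball vs cylinder).
#'
#' @param traj a `trajectory_set` whose marker ids match the template.
#' @param template a [build_default_template()].
#' @return `traj` with a `shapes` attribute.
#' @export
set_marker_shapes <- function(traj, template) {
  idx <- match(traj$marker_id, as.character(template$marker_id))
  attr(traj, "shapes") <- template$shape[idx]
  traj
}

#' Render detections of one frame as a raster image
#'
#' Convenience renderer for exercising the 2D detector: isotropic Gaussian
#' spots of sd `spot_sigma_px` and peak `amplitude` are drawn additively on a
#' zero background, using the `[x, y]` (column-major width x height) matrix
#' convention of EBImage. Pixel centres are at integer coordinates starting
#' at (1, 1), so a detection at (u, v) peaks at pixel (round(u), round(v)).
#'
#' @param detections data frame with `u_px`, `v_px` (one frame, one view).
#' @param image_size (width, height) px.
#' @param spot_sigma_px Gaussian spot sd, px.
#' @param amplitude peak intensity per spot.
#' @return `width x height` numeric matrix.
#' @export
render_frame <- function(detections, image_size = c(256L, 256L),
                         spot_sigma_px = 1.5, amplitude = 1) {
  W <- image_size[1]; H <- image_size[2]
  img <- matrix(0, W, H)
  if (is.null(detections) || nrow(detections) == 0) return(img)
  half <- ceiling(4 * spot_sigma_px)
  for (i in seq_len(nrow(detections))) {
    u <- detections$u_px[i]; v <- detections$v_px[i]
    xs <- max(1, floor(u - half)):min(W, ceiling(u + half))
    ys <- max(1, floor(v - half)):min(H, ceiling(v + half))
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - u)^2 / (2 * spot_sigma_px^2))
    gy <- exp(-(ys - v)^2 / (2 * spot_sigma_px^2))
    img[xs, ys] <- img[xs, ys] + amplitude * outer(gx, gy)
  }
  img
}

#' Detect marker spots in a grayscale frame
#'
#' A deliberately simple spot detector whose failure modes (merged blobs,
#' missed faint spots, threshold false negatives) the downstream tracker must
#' tolerate: difference-of-Gaussians band-pass filtering
#' (via [EBImage::gblur()]), 8-neighbourhood local maxima above an intensity
#' threshold, and sub-pixel refinement by a separable quadratic fit through
#' each maximum.
#'
#' @param img `width x height` matrix (as from [render_frame()]).
#' @param sigma_small,sigma_large band-pass scales, px.
#' @param threshold absolute response threshold for a maximum.
#' @return data frame with columns `u_px`, `v_px`, `response`.
#' @export
detect_markers_2d <- function(img, sigma_small = 1, sigma_large = 3,
                              threshold = 0.05) {
  stopifnot(is.matrix(img))
  band <- EBImage::gblur(img, sigma = sigma_small) -
    EBImage::gblur(img, sigma = sigma_large)
  W <- nrow(band); H <- ncol(band)
  if (W < 3 || H < 3) return(data.frame(u_px = numeric(), v_px = numeric(),
                                        response = numeric()))
  core <- band[2:(W - 1), 2:(H - 1)]
  is_max <- core >= threshold
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- band[2:(W - 1) + dx, 2:(H - 1) + dy]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(u_px = numeric(), v_px = numeric(),
                                    response = numeric()))
  x <- idx[, 1] + 1L; y <- idx[, 2] + 1L
  # sub-pixel: vertex of the parabola through the 3 samples on each axis
  sub <- function(l, c, r) {
    den <- l - 2 * c + r
    ifelse(abs(den) > 1e-12, 0.5 * (l - r) / den, 0)
  }
  du <- sub(band[cbind(x - 1L, y)], band[cbind(x, y)], band[cbind(x + 1L, y)])
  dv <- sub(band[cbind(x, y - 1L)], band[cbind(x, y)], band[cbind(x, y + 1L)])
  data.frame(u_px = x + pmax(pmin(du, 0.5), -0.5),
             v_px = y + pmax(pmin(dv, 0.5), -0.5),
             response = band[cbind(x, y)])
}
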