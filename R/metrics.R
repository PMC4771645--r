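#' Leaflet opening angle
#'
#' The angle (degrees) at annular marker #10 between the trans-annular chord
#' to marker #5 and the segment to the leaflet marker #11 - the proxy for
#' leaflet opening. Computed as the arccosine of the normalized dot product
#' of (p5 - p10) and (p11 - p10), clamped to `[-1, 1]`.
#'
#' @param p10,p5,p11 length-3 positions, mm.
#' @return degrees in `[0, 180]`.
#' @examples
#' alpha11(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # 45
#' @export
alpha11 <- function(p10, p5, p11) {
  u <- p5 - p10; v <- p11 - p10
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12)
    stop("alpha11 undefined: coincident points at the vertex")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Tricuspid annular area (fan triangulation)
#'
#' The annular area in 3D space: the sum of the areas of the 10 triangles
#' formed by consecutive annular marker pairs (wrapping #10 -> #1) and the
#' annular centroid (the arithmetic mean of markers #1-10). Each triangle
#' area is half the cross-product magnitude.
#'
#' @param annulus 10 x 3 matrix of annular marker positions, mm, in ring
#'   order.
#' @return area, mm^2.
#' @export
annular_area <- function(annulus) {
  annulus <- as.matrix(annulus)
  if (nrow(annulus) != 10) stop("need exactly 10 annular positions, got ",
                                nrow(annulus))
  ctr <- colMeans(annulus)
  nxt <- c(2:10, 1)
  total <- 0
  for (i in 1:10) {
    a <- annulus[i, ] - ctr
    b <- annulus[nxt[i], ] - ctr
    total <- total + vnorm(cross3(a, b)) / 2
  }
  total
}

#' Total least-squares plane through a point set
#'
#' The plane through the centroid whose normal is the smallest principal
#' direction of the centered scatter (total least squares, minimizing the
#' summed squared orthogonal distances).
#'
#' @param points n x 3 matrix, n >= 3, not all collinear.
#' @return list with `point` (the centroid) and `normal` (unit 3-vector).
#' @export
least_squares_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate plane fit: points are (near-)collinear")
  list(point = ctr, normal = sv$v[, 3])
}

#' Signed orthogonal distances of annular markers to their plane
#'
#' Distances of each annular marker to the least-squares annular plane,
#' signed positive toward the atrial side (away from the ventricular apex)
#' when `apex` is supplied. Because the plane passes through the centroid,
#' the signed heights sum to zero.
#'
#' @param annulus 10 x 3 matrix, ring order.
#' @param apex optional apex position fixing the sign convention.
#' @return numeric length-10, mm.
#' @export
annular_heights <- function(annulus, apex = NULL) {
  pl <- least_squares_plane(annulus)
  n <- pl$normal
  if (!is.null(apex) && sum((pl$point - apex) * n) < 0) n <- -n
  as.numeric(sweep(as.matrix(annulus), 2, pl$point) %*% n)
}

#' Annular cartesian coordinate system
#'
#' The right-handed coordinate frame used to plot annular geometry: origin
#' at the annular centroid; y-axis through the LV apex marker (pointing from
#' the apex toward the annulus, i.e. the apex has negative y); x-axis
#' orthogonal to y in the plane containing the mid-septal annular marker
#' (#3), so that #3 has zero z; z-axis orthogonal to x-y, its positive
#' sense chosen to point anteriorly (toward the mean of annular markers
#' #6-#8 by default).
#'
#' @param annulus 10 x 3 matrix, ring order (#1..#10).
#' @param apex LV apex position, mm.
#' @param marker3 optional explicit #3 position (defaults to row 3).
#' @param anterior_ref optional direction fixing the z sign (defaults to the
#'   mean of rows 6-8 minus the centroid).
#' @return list of class `annular_frame`: `origin`, `axes` (3x3 with rows
#'   x, y, z; orthonormal, det +1) and `to_frame(points)` mapping world
#'   points into annular coordinates.
#' @export
annular_coordinate_system <- function(annulus, apex, marker3 = NULL,
                                      anterior_ref = NULL) {
  annulus <- as.matrix(annulus)
  origin <- colMeans(annulus)
  if (is.null(marker3)) marker3 <- annulus[3, ]
  if (is.null(anterior_ref))
    anterior_ref <- colMeans(annulus[6:8, , drop = FALSE]) - origin
  ya <- origin - apex
  if (vnorm(ya) < 1e-9) stop("degenerate frame: apex coincides with centroid")
  y <- unitv(ya)
  m3 <- marker3 - origin
  x_raw <- m3 - sum(m3 * y) * y
  if (vnorm(x_raw) < 1e-9)
    stop("degenerate frame: marker #3 lies on the y-axis")
  x <- unitv(x_raw)
  z <- cross3(x, y)
  if (sum(z * anterior_ref) < 0) { x <- -x; z <- -z }
  axes <- rbind(x = x, y = y, z = z)
  structure(list(
    origin = origin, axes = axes,
    to_frame = function(points)
      sweep(as.matrix(points), 2, origin) %*% t(axes)
  ), class = "annular_frame")
}

#' Septal-lateral diameter
#'
#' Euclidean distance between a marker pair: the tricuspid annular
#' septal-lateral diameter uses markers #3 and #8; the right-ventricular
#' variant uses the basal mid-free-wall RV marker and its septal partner.
#'
#' @param pa,pb length-3 positions, mm.
#' @return mm.
#' @export
sl_diameter <- function(pa, pb) vnorm(pa - pb)

#' Apex-to-annulus distance panel
#'
#' Distances between the LV apex marker and each of the ten annular markers;
#' their systolic change generalizes the tricuspid annular plane systolic
#' excursion (TAPSE) to all ten annular segments.
#'
#' @param apex length-3 position, mm.
#' @param annulus 10 x 3 matrix, ring order.
#' @return numeric length-10, mm.
#' @export
apex_annulus_distances <- function(apex, annulus) {
  annulus <- as.matrix(annulus)
  row_dist(annulus, matrix(apex, nrow(annulus), 3, byrow = TRUE))
}

# Zigzag strip triangulation between two ordered chains with m and n
# points; returns a list of index triples into c(upper, lower) and yields
# m + n - 2 triangles.
strip_triangles <- function(m, n) {
  i <- 1L; j <- 1L
  tris <- list()
  while (i < m || j < n) {
    adv_upper <- if (i >= m) FALSE else if (j >= n) TRUE else
      (i - 1) / (m - 1) <= (j - 1) / (n - 1)
    if (adv_upper) {
      tris[[length(tris) + 1]] <- c(i, i + 1L, m + j)
      i <- i + 1L
    } else {
      tris[[length(tris) + 1]] <- c(i, m + j, m + j + 1L)
      j <- j + 1L
    }
  }
  tris
}

triangle_area3 <- function(a, b, c) vnorm(cross3(b - a, c - a)) / 2

#' Regional and total right-ventricular surface area
#'
#' The 9 RV epicardial markers (4 basal, 3 equatorial, 2 apical) are
#' triangulated as two zigzag strips between adjacent levels: basal-to-
#' equatorial yields triangles 1-5, equatorial-to-apical triangles 6-8
#' (eight in total; the strip triangulation of 4/3/2 chains yields
#' (4+3-2) + (3+2-2) = 8). The triangle vertex table is fixed:
#' 1 (b1,b2,e1), 2 (b2,e1,e2), 3 (b2,b3,e2), 4 (b3,e2,e3), 5 (b3,b4,e3),
#' 6 (e1,e2,a1), 7 (e2,a1,a2), 8 (e2,e3,a2). Total RV surface area is the
#' sum of all eight triangle areas.
#'
#' @param basal 4 x 3, `equatorial` 3 x 3, `apical` 2 x 3 matrices (mm) in
#'   chain order.
#' @param equatorial,apical see `basal`.
#' @return list `triangle_areas` (length 8, mm^2) and `total` (mm^2).
#' @export
rv_regional_areas <- function(basal, equatorial, apical) {
  basal <- as.matrix(basal); equatorial <- as.matrix(equatorial)
  apical <- as.matrix(apical)
  if (nrow(basal) != 4 || nrow(equatorial) != 3 || nrow(apical) != 2)
    stop("RV level counts must be 4 (basal), 3 (equatorial), 2 (apical)")
  areas <- c(
    strip_areas(basal, equatorial),
    strip_areas(equatorial, apical)
  )
  list(triangle_areas = areas, total = sum(areas))
}

strip_areas <- function(upper, lower) {
  pts <- rbind(upper, lower)
  vapply(strip_triangles(nrow(upper), nrow(lower)), function(t)
    triangle_area3(pts[t[1], ], pts[t[2], ], pts[t[3], ]), 0)
}

#' Total left-ventricular surface area
#'
#' The 13 LV markers (4 basal, 4 equatorial, 4 apical-ring, 1 apex) are
#' triangulated as zigzag strips basal-to-equatorial (6 triangles) and
#' equatorial-to-apical (6 triangles) plus a closed fan from the apical ring
#' to the apex marker (4 triangles): 16 triangles in total, whose summed
#' area estimates the LV epicardial surface.
#'
#' @param basal,equatorial,apical 4 x 3 matrices (mm) in chain order.
#' @param apex length-3 apex marker position (mm).
#' @return list `triangle_areas` (length 16, mm^2) and `total` (mm^2).
#' @export
lv_surface_area <- function(basal, equatorial, apical, apex) {
  basal <- as.matrix(basal); equatorial <- as.matrix(equatorial)
  apical <- as.matrix(apical)
  if (nrow(basal) != 4 || nrow(equatorial) != 4 || nrow(apical) != 4)
    stop("LV level counts must be 4/4/4")
  if (length(apex) != 3) stop("missing or malformed LV apex position")
  fan <- vapply(1:4, function(i)
    triangle_area3(apical[i, ], apical[i %% 4 + 1, ], apex), 0)
  areas <- c(strip_areas(basal, equatorial), strip_areas(equatorial, apical),
             fan)
  list(triangle_areas = areas, total = sum(areas))
}

#' Locate the annular-area extrema of a beat
#'
#' The frames at which the tricuspid annular area reaches its minimum
#' (MinTAA) and maximum (MaxTAA) within the analyzed beat, after optional
#' smoothing with a centered moving average (default window 11 frames =
#' 22 ms at 500 Hz, shrinking symmetrically at the series ends); ties go to
#' the earliest frame.
#'
#' @param area numeric series of annular areas, one per frame.
#' @param frames 0-based frame indices of the series (default
#'   `0:(length(area)-1)`).
#' @param smooth_window odd window length; 1 = no smoothing.
#' @return list `min_taa_frame`, `max_taa_frame`.
#' @export
find_min_max_taa <- function(area, frames = seq_along(area) - 1L,
                             smooth_window = 11) {
  if (!length(area)) stop("empty area series")
  s <- moving_average(area, smooth_window)
  list(min_taa_frame = frames[which.min(s)],
       max_taa_frame = frames[which.max(s)])
}

# Centered moving average with symmetric shrink at the ends.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  h <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(x[(i - k):(i + k)])
  }, 0)
}

#' Full per-frame quantitative analysis of one beat
#'
#' Computes every per-frame metric of the analysis suite over the given
#' frame range: the annular fan area, the leaflet angle alpha11, the annular
#' (#3-#8) and RV septal-lateral diameters, the ten signed annular heights,
#' the ten apex-to-annulus distances, the eight regional RV triangle areas
#' with RV and LV surface-area totals - plus the MinTAA/MaxTAA phase
#' landmarks. Trajectories must carry anatomical marker ids, either directly
#' as labels or through an assignment table.
#'
#' @param traj a `trajectory_set`.
#' @param assignment optional `anatomical_assignment` mapping track labels
#'   to marker ids (omit when `traj` is already labeled by marker id).
#' @param beat length-2 frame range (0-based, half-open `[start, end)`);
#'   defaults to the full series.
#' @param template template used for role/level lookup.
#' @param rv_sl_pair length-2 marker ids for the RV septal-lateral diameter
#'   (defaults to the basal mid-free-wall RV marker #13 and the basal septal
#'   LV marker #21).
#' @param smooth_window extremum-detection smoothing window, frames.
#' @return list of class `beat_analysis`: `metrics` (one row per frame,
#'   columns `frame`, `time_ms`, `taa_mm2`, `alpha11_deg`, `ta_sl_mm`,
#'   `rv_sl_mm`, `h1..h10_mm`, `d_apex_1..10_mm`, `rv_tri_1..8_mm2`,
#'   `rv_total_mm2`, `lv_total_mm2`), `landmarks`
#'   (`min_taa_frame`, `max_taa_frame`, `beat_start`, `beat_end`), and
#'   `provenance` (missing optional roles).
#' @export
analyze_beat <- function(traj, assignment = NULL, beat = NULL,
                         template = build_default_template(),
                         rv_sl_pair = c(13L, 21L), smooth_window = 11) {
  pos <- traj$positions
  labels <- traj$marker_id
  if (!is.null(assignment)) {
    idx <- match(assignment$track, labels)
    pos <- pos[, idx, , drop = FALSE]
    labels <- as.character(assignment$marker_id)
  }
  have <- function(ids) all(as.character(ids) %in% labels)
  required <- list(annulus = 1:10, leaflet = 11, apex = 33)
  absent <- names(required)[!vapply(required, have, TRUE)]
  if (length(absent))
    stop("missing required marker slots: ", paste(absent, collapse = ", "))

  nf <- dim(pos)[1]
  if (is.null(beat)) beat <- c(0L, nf)
  if (beat[1] < 0 || beat[2] > nf || beat[2] <= beat[1])
    stop("invalid beat bounds [", beat[1], ", ", beat[2], ")")
  frames <- beat[1]:(beat[2] - 1)
  rows <- frames + 1L

  gi <- function(ids) match(as.character(ids), labels)
  i_ann <- gi(1:10); i_lf <- gi(11); i_apex <- gi(33)
  i_rvb <- gi(12:15); i_rve <- gi(16:18); i_rva <- gi(19:20)
  i_lvb <- gi(21:24); i_lve <- gi(25:28); i_lva <- gi(29:32)
  i_sl <- gi(rv_sl_pair)

  has_rv <- !anyNA(c(i_rvb, i_rve, i_rva))
  has_lv <- !anyNA(c(i_lvb, i_lve, i_lva, i_apex))
  has_rvsl <- !anyNA(i_sl)
  provenance <- list(missing_optional = c(
    if (!has_rv) "rv_epicardial", if (!has_lv) "lv_wall",
    if (!has_rvsl) "rv_sl_pair"))

  n <- length(frames)
  taa <- a11 <- tasl <- rvsl <- rvtot <- lvtot <- rep(NA_real_, n)
  H <- Dap <- matrix(NA_real_, n, 10)
  RvT <- matrix(NA_real_, n, 8)
  for (k in seq_len(n)) {
    r <- rows[k]
    ann <- pos[r, i_ann, , drop = TRUE]
    if (anyNA(ann)) next
    apex <- pos[r, i_apex, ]
    taa[k] <- annular_area(ann)
    leaf <- pos[r, i_lf, ]
    if (!anyNA(leaf)) a11[k] <- alpha11(ann[10, ], ann[5, ], leaf)
    tasl[k] <- sl_diameter(ann[3, ], ann[8, ])
    H[k, ] <- annular_heights(ann, apex = if (!anyNA(apex)) apex else NULL)
    if (!anyNA(apex)) Dap[k, ] <- apex_annulus_distances(apex, ann)
    if (has_rvsl)
      rvsl[k] <- sl_diameter(pos[r, i_sl[1], ], pos[r, i_sl[2], ])
    if (has_rv) {
      rv <- rv_regional_areas(pos[r, i_rvb, , drop = TRUE],
                              pos[r, i_rve, , drop = TRUE],
                              pos[r, i_rva, , drop = TRUE])
      RvT[k, ] <- rv$triangle_areas
      rvtot[k] <- rv$total
    }
    if (has_lv)
      lvtot[k] <- lv_surface_area(pos[r, i_lvb, , drop = TRUE],
                                  pos[r, i_lve, , drop = TRUE],
                                  pos[r, i_lva, , drop = TRUE],
                                  pos[r, i_apex, ])$total
  }

  metrics <- data.frame(frame = frames,
                        time_ms = frames / traj$frame_rate * 1000,
                        taa_mm2 = taa, alpha11_deg = a11,
                        ta_sl_mm = tasl, rv_sl_mm = rvsl)
  colnames(H) <- paste0("h", 1:10, "_mm")
  colnames(Dap) <- paste0("d_apex_", 1:10, "_mm")
  colnames(RvT) <- paste0("rv_tri_", 1:8, "_mm2")
  metrics <- cbind(metrics, H, Dap, RvT,
                   data.frame(rv_total_mm2 = rvtot, lv_total_mm2 = lvtot))

  ok <- !is.na(taa)
  lm <- find_min_max_taa(taa[ok], frames[ok], smooth_window = smooth_window)
  structure(list(
    metrics = metrics,
    landmarks = list(min_taa_frame = lm$min_taa_frame,
                     max_taa_frame = lm$max_taa_frame,
                     beat_start = beat[1], beat_end = beat[2]),
    provenance = provenance
  ), class = "beat_analysis")
}

#' @export
print.beat_analysis <- function(x, ...) {
  lmk <- x$landmarks
  cat("Beat analysis over frames [", lmk$beat_start, ",", lmk$beat_end,
      "): MinTAA at", lmk$min_taa_frame, ", MaxTAA at", lmk$max_taa_frame,
      "\n")
  cat("TAA range:", signif(min(x$metrics$taa_mm2, na.rm = TRUE), 5), "-",
      signif(max(x$metrics$taa_mm2, na.rm = TRUE), 5), "mm^2\n")
  invisible(x)
}
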