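#' Per-track summary features for identification
#'
#' Time-averaged position, motion amplitude (largest excursion from the
#' per-frame right-heart centroid after removing the common translation; see
#' [find_leaflet_track()]), and the majority shape tag carried from the
#' detections.
#'
#' @param traj a `trajectory_set` of tracks.
#' @param shapes optional named character vector (track label -> `"sphere"`,
#'   `"cylinder"` or `NA`).
#' @return data frame `track`, `x`, `y`, `z` (mean mm), `amplitude_mm`,
#'   `shape`.
#' @export
track_features <- function(traj, shapes = NULL) {
  labs <- traj$marker_id
  mp <- t(vapply(seq_along(labs), function(i)
    colMeans(traj$positions[, i, , drop = TRUE], na.rm = TRUE), numeric(3)))
  amp <- vapply(seq_along(labs), function(i) {
    P <- traj$positions[, i, , drop = TRUE]
    ok <- !is.na(P[, 1])
    if (sum(ok) < 2) return(0)
    ctr <- colMeans(P[ok, , drop = FALSE])
    max(row_dist(P[ok, , drop = FALSE], matrix(ctr, sum(ok), 3, byrow = TRUE)))
  }, 0)
  sh <- if (is.null(shapes)) rep(NA_character_, length(labs)) else
    as.character(shapes[labs])
  data.frame(track = labs, x = mp[, 1], y = mp[, 2], z = mp[, 3],
             amplitude_mm = amp, shape = sh)
}

#' Majority shape tag per track
#'
#' Propagates the per-detection shape tags to tracks: each track is tagged
#' with the majority shape among the detections its hypotheses used.
#'
#' @param track_set a [track_markers()] result.
#' @param detections the `detection_set` the tracks were built from.
#' @return named character vector (track label -> shape or NA).
#' @export
track_shapes <- function(track_set, detections) {
  shp <- stats::setNames(detections$shape, detections$det_id)
  vapply(seq_along(track_set$tracks), function(i) {
    tr <- track_set$tracks[[i]]
    s <- shp[as.character(c(tr$det_a, tr$det_b))]
    s <- s[!is.na(s)]
    if (!length(s)) return(NA_character_)
    names(sort(table(s), decreasing = TRUE))[1]
  }, "") |> stats::setNames(track_set$trajectories$marker_id)
}

#' Separate right-heart from left-heart candidates by marker shape
#'
#' Spherical markers were sutured to the right heart (annulus, leaflet, RV
#' epicardium, plus the guide ball) and cylindrical markers to the left
#' ventricle (plus the guide cylinder), so the shape tag splits the track
#' pool into right/left candidate sets; untagged tracks are deferred to
#' template matching.
#'
#' @param shapes named character vector of shape tags per track.
#' @return list with `right` (sphere tracks), `left` (cylinder tracks) and
#'   `deferred` (unknown) track labels. Warns when the counts are
#'   incompatible with the 21/14 template split.
#' @export
split_by_shape <- function(shapes) {
  labs <- names(shapes)
  right <- labs[!is.na(shapes) & shapes == "sphere"]
  left <- labs[!is.na(shapes) & shapes == "cylinder"]
  deferred <- setdiff(labs, c(right, left))
  if (length(right) > 21 || length(left) > 14)
    warning("shape-tag counts exceed the template's 21 sphere / 14 cylinder ",
            "slots; extras will be resolved by template matching")
  list(right = right, left = left, deferred = deferred)
}

#' Find the leaflet track among right-heart candidates
#'
#' The leaflet marker is by far the fastest-moving right-heart marker; the
#' automated analogue of spotting it in a video loop is to remove the common
#' rigid translation (per-frame centroid of the candidates) and pick the
#' track with the largest residual motion amplitude. The winning margin over
#' the runner-up is reported, and the result is flagged ambiguous when the
#' margin is below `margin_threshold` or all amplitudes are negligible.
#'
#' @param traj `trajectory_set` of tracks.
#' @param candidates labels of the right-heart candidate tracks (>= 2).
#' @param margin_threshold minimum relative margin (best - second) / second.
#' @param min_amplitude_mm amplitudes below this are treated as static.
#' @return list `track` (label or NA), `margin`, `ambiguous`, `amplitudes`.
#' @export
find_leaflet_track <- function(traj, candidates, margin_threshold = 0.5,
                               min_amplitude_mm = 0.5) {
  stopifnot(length(candidates) >= 2)
  idx <- match(candidates, traj$marker_id)
  P <- traj$positions[, idx, , drop = FALSE]
  ctr <- apply(P, c(1, 3), mean, na.rm = TRUE)     # per-frame centroid
  amp <- vapply(seq_along(idx), function(i) {
    R <- P[, i, ] - ctr
    ok <- !is.na(R[, 1])
    if (sum(ok) < 2) return(0)
    mu <- colMeans(R[ok, , drop = FALSE])
    max(row_dist(R[ok, , drop = FALSE], matrix(mu, sum(ok), 3, byrow = TRUE)))
  }, 0)
  names(amp) <- candidates
  o <- order(amp, decreasing = TRUE)
  best <- amp[o[1]]; second <- amp[o[2]]
  margin <- if (second > 0) (best - second) / second else Inf
  ambiguous <- best < min_amplitude_mm || margin < margin_threshold
  list(track = if (ambiguous) NA_character_ else candidates[o[1]],
       margin = margin, ambiguous = ambiguous, amplitudes = amp)
}

# Mutual-nearest-neighbour pairs closer than `threshold` among rows of a
# point matrix; returns a 2-column index matrix.
find_doublets <- function(pts, threshold) {
  D <- cross_dist(pts, pts); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  out <- list()
  for (i in seq_len(nrow(pts))) {
    j <- nn[i]
    if (j > i && nn[j] == i && D[i, j] <= threshold)
      out[[length(out) + 1]] <- c(i, j)
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(), 0, 2)
}

#' Assign anonymous tracks to template marker slots
#'
#' Automates the manual 3D-model identification procedure: the two guide
#' doublets (the ball pair beside annulus #7 and the cylinder pair beside
#' #3) are detected in both the tracked scene and the template as
#' mutual-nearest-neighbour pairs closer than `doublet_threshold`; their
#' midpoints plus the overall centroid seed a similarity transform
#' (rotation + translation + optional isotropic scale), which is refined by
#' alternating globally optimal one-to-one matching
#' (Hungarian assignment via [clue::solve_LSAP()], with shape-incompatible
#' pairings penalized) and re-fitting the transform on the matched pairs.
#' When no doublet is found, a coarse search over rotations initializes the
#' alignment instead.
#'
#' @param traj `trajectory_set` of tracks (count within +/- 3 of 35).
#' @param template a [build_default_template()].
#' @param shapes optional named shape tags per track.
#' @param allow_scale allow isotropic scale in the alignment (the template
#'   is schematic, not animal-specific).
#' @param doublet_threshold mm; guide pairs are closer than this.
#' @param residual_ceiling mm; mean post-alignment distance above this is an
#'   explicit failure.
#' @return data frame of class `anatomical_assignment` with columns `track`,
#'   `marker_id`, `role`, `residual_mm`; attributes `residual` (mean mm),
#'   `transform` (list R, t, s), `method`.
#' @export
assign_to_template <- function(traj, template, shapes = NULL,
                               allow_scale = TRUE, doublet_threshold = 4,
                               residual_ceiling = 10) {
  feats <- track_features(traj, shapes)
  n <- nrow(feats)
  if (abs(n - nrow(template)) > 3)
    stop("track count ", n, " is too far from the ", nrow(template),
         "-marker template")
  X <- as.matrix(feats[, c("x", "y", "z")])          # track means
  Y <- template_positions(template)                  # template rest

  # template guide doublets are known from their roles
  anchor_of <- function(role) {
    g <- which(template$role == role)
    c(g, which(template$marker_id == template$anchor_id[g]))
  }
  midY_ball <- colMeans(Y[anchor_of("guide_ball"), , drop = FALSE])
  midY_cyl <- colMeans(Y[anchor_of("guide_cylinder"), , drop = FALSE])

  # scene doublet candidates, filtered by shape composition when tagged:
  # the ball doublet is sphere+sphere, the cylinder doublet has a cylinder
  dX <- find_doublets(X, doublet_threshold * max(1, scene_scale(X, Y)))
  shX <- feats$shape
  n_cyl <- if (nrow(dX)) apply(dX, 1, function(p)
    sum(!is.na(shX[p]) & shX[p] == "cylinder")) else integer()
  tagged <- if (nrow(dX)) apply(dX, 1, function(p) !anyNA(shX[p])) else
    logical()
  ball_cand <- which(!tagged | n_cyl == 0)
  cyl_cand <- which(!tagged | n_cyl == 1)

  method <- "guide_doublets"
  inits <- list()
  if (nrow(dX) >= 2) {
    midX <- t(apply(dX, 1, function(p) colMeans(X[p, , drop = FALSE])))
    for (i in ball_cand) for (j in cyl_cand) {
      if (i == j) next
      A <- rbind(midX[i, ], midX[j, ], colMeans(X))
      B <- rbind(midY_ball, midY_cyl, colMeans(Y))
      inits[[length(inits) + 1]] <- fit_similarity(A, B, scale = allow_scale)
    }
  }
  if (!length(inits)) {
    method <- "coarse_rotation_search"
    inits <- coarse_rotation_inits(X, Y, allow_scale)
  }

  best <- NULL
  for (ini in inits) {
    sol <- refine_assignment(X, Y, ini, feats$shape, template$shape,
                             allow_scale)
    if (is.null(best) || sol$residual < best$residual) best <- sol
  }
  if (is.null(best)) stop("assignment failed: no usable initialization")
  if (best$residual > residual_ceiling)
    stop("assignment residual ", signif(best$residual, 4),
         " mm exceeds ceiling ", residual_ceiling, " mm")

  out <- data.frame(
    track = feats$track[best$rows],
    marker_id = template$marker_id[best$cols],
    role = template$role[best$cols],
    residual_mm = best$dists
  )
  out <- out[order(out$marker_id), ]
  rownames(out) <- NULL
  attr(out, "residual") <- best$residual
  attr(out, "transform") <- best$transform
  attr(out, "method") <- method
  missing <- setdiff(template$marker_id, out$marker_id)
  attr(out, "missing_slots") <- missing
  class(out) <- c("anatomical_assignment", "data.frame")
  out
}

# Approximate scene/template scale ratio from RMS radius about the centroid.
scene_scale <- function(X, Y) {
  rx <- sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  ry <- sqrt(mean(rowSums(sweep(Y, 2, colMeans(Y))^2)))
  if (ry > 0) rx / ry else 1
}

# Fallback initializations: centroid/scale alignment composed with a fixed
# set of coarse rotations (the 24 rotational symmetries of the cube).
coarse_rotation_inits <- function(X, Y, allow_scale) {
  s <- if (allow_scale) 1 / scene_scale(X, Y) else 1
  cX <- colMeans(X); cY <- colMeans(Y)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rots <- list(diag(3))
  for (a in axes) for (ang in c(90, 180, 270) * pi / 180)
    rots[[length(rots) + 1]] <- rot_axis_angle(a, ang)
  for (a in list(c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1), c(1, 1, -1)))
    for (ang in c(120, 240) * pi / 180)
      rots[[length(rots) + 1]] <- rot_axis_angle(a, ang)
  for (a in list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, -1, 0),
                 c(1, 0, -1), c(0, 1, -1)))
    rots[[length(rots) + 1]] <- rot_axis_angle(a, pi)
  lapply(rots, function(R) list(R = R, t = cY - s * as.vector(R %*% cX),
                                s = s))
}

# Alternate optimal matching and similarity refitting (2 rounds).
refine_assignment <- function(X, Y, init, shapeX, shapeY, allow_scale) {
  tr <- init
  sol <- NULL
  for (it in 1:3) {
    Xt <- apply_similarity(X, tr$R, tr$t, tr$s)
    D <- cross_dist(Xt, Y)
    if (!is.null(shapeX)) {
      bad <- outer(shapeX, shapeY, function(a, b)
        !is.na(a) & a != b)
      D <- D + bad * 1e4
    }
    m <- optimal_matching(D)
    tr2 <- fit_similarity(X[m$rows, , drop = FALSE],
                          Y[m$cols, , drop = FALSE], scale = allow_scale)
    tr <- tr2
    Xt <- apply_similarity(X, tr$R, tr$t, tr$s)
    dists <- row_dist(Xt[m$rows, , drop = FALSE], Y[m$cols, , drop = FALSE])
    sol <- list(rows = m$rows, cols = m$cols, dists = dists,
                residual = mean(dists), transform = tr)
  }
  sol
}

# Globally optimal one-to-one matching minimizing summed distance; handles
# rectangular cost matrices (the smaller side is fully matched).
optimal_matching <- function(D) {
  transposed <- nrow(D) > ncol(D)
  C <- if (transposed) t(D) else D
  s <- clue::solve_LSAP(C)
  rows <- seq_len(nrow(C)); cols <- as.integer(s)
  if (transposed) list(rows = cols, cols = rows) else
    list(rows = rows, cols = cols)
}

#' Apply a manual override file to an assignment
#'
#' The automated identification mirrors a procedure that was originally
#' manual; a track -> marker CSV (columns `track`, `marker_id`) read with
#' [utils::read.csv()] takes precedence over the automatic assignment for
#' the listed tracks.
#'
#' @param assignment an `anatomical_assignment`.
#' @param override data frame with columns `track`, `marker_id`.
#' @param template the template (for role lookup).
#' @return updated assignment.
#' @export
apply_override <- function(assignment, override, template) {
  for (k in seq_len(nrow(override))) {
    tr <- override$track[k]; mid <- override$marker_id[k]
    assignment <- assignment[!(assignment$marker_id == mid &
                               assignment$track != tr), ]
    i <- which(assignment$track == tr)
    role <- template$role[template$marker_id == mid]
    if (length(i)) {
      assignment$marker_id[i] <- mid
      assignment$role[i] <- role
      assignment$residual_mm[i] <- NA_real_
    } else {
      assignment <- rbind(assignment, data.frame(
        track = tr, marker_id = mid, role = role, residual_mm = NA_real_))
    }
  }
  assignment[order(assignment$marker_id), ]
}

#' Wireframe connectivity of the marker array
#'
#' The virtual lines connecting markers of each anatomical entity: the
#' closed annulus ring (1-2, ..., 9-10, 10-1), the RV level chains plus the
#' inter-level struts of the 4/3/2 strip triangulation, and the LV level
#' chains, struts, and apex fan. Each undirected edge appears once, in a
#' deterministic order; edges touching unassigned markers are omitted.
#'
#' @param assignment optional `anatomical_assignment`; when given, only
#'   edges between assigned marker slots are returned.
#' @param template a [build_default_template()].
#' @return data frame `from`, `to` (marker ids, from < to), `group`
#'   (`tricuspid_annulus`, `right_ventricle`, `left_ventricle`).
#' @export
build_wireframe <- function(assignment = NULL,
                            template = build_default_template()) {
  chain <- function(ids, closed = FALSE) {
    e <- cbind(ids[-length(ids)], ids[-1])
    if (closed) e <- rbind(e, c(ids[length(ids)], ids[1]))
    e
  }
  ann <- chain(1:10, closed = TRUE)
  rv <- rbind(chain(12:15), chain(16:18), chain(19:20),
              tri_strip_edges(12:15, 16:18), tri_strip_edges(16:18, 19:20))
  lv <- rbind(chain(21:24), chain(25:28), chain(29:32),
              tri_strip_edges(21:24, 25:28), tri_strip_edges(25:28, 29:32),
              cbind(29:32, 33))
  e <- rbind(
    data.frame(from = ann[, 1], to = ann[, 2], group = "tricuspid_annulus"),
    data.frame(from = rv[, 1], to = rv[, 2], group = "right_ventricle"),
    data.frame(from = lv[, 1], to = lv[, 2], group = "left_ventricle")
  )
  sw <- e$from > e$to
  tmp <- e$from[sw]; e$from[sw] <- e$to[sw]; e$to[sw] <- tmp
  e <- e[!duplicated(e[, c("from", "to")]), ]
  if (!is.null(assignment)) {
    have <- assignment$marker_id
    e <- e[e$from %in% have & e$to %in% have, ]
  }
  rownames(e) <- NULL
  e
}

# Unique undirected edges of the zigzag strip triangulation between two
# ordered level chains (see rv_regional_areas for the triangle table).
tri_strip_edges <- function(upper, lower) {
  tris <- strip_triangles(length(upper), length(lower))
  ids <- c(upper, lower)
  do.call(rbind, lapply(tris, function(t)
    cbind(ids[t][c(1, 2, 1)], ids[t][c(2, 3, 3)])))
}
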