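#' Evaluate tracker output against ground truth
#'
#' Assigns tracks to ground-truth markers greedily one-to-one by increasing
#' median distance over their common frames, then computes standard
#' multi-object tracking metrics. Definitions:
#' \describe{
#'   \item{rmse_mm}{per track, the root-mean-square distance to the assigned
#'     truth marker over all frames where both have positions.}
#'   \item{completeness}{per truth marker, the fraction of its frames at
#'     which the assigned track has a position within `match_radius` mm
#'     (interpolated positions count).}
#'   \item{purity}{per track, the fraction of its non-interpolated positions
#'     whose nearest truth marker (over all markers, that frame) is the
#'     assigned one.}
#'   \item{id_switches}{total count, over tracks, of transitions between
#'     distinct nearest-truth-marker identities along the track (non-
#'     interpolated positions within `match_radius` only).}
#'   \item{false_tracks}{tracks with no assigned truth marker or with median
#'     distance above `match_radius`.}
#' }
#'
#' @param tracks a `track_set` or a `trajectory_set` of anonymous tracks.
#' @param truth the ground-truth `trajectory_set`.
#' @param match_radius mm radius for frame-level matching.
#' @return list of class `tracking_evaluation`: `per_track` and `per_marker`
#'   data frames plus scalar summaries `mean_rmse_mm`, `min_completeness`,
#'   `mean_completeness`, `min_purity`, `id_switches`, `false_tracks`.
#' @export
evaluate_tracking <- function(tracks, truth, match_radius = 2) {
  traj <- if (inherits(tracks, "track_set")) tracks$trajectories else tracks
  interp <- attr(traj, "interpolated")
  nf <- min(n_frames(traj), n_frames(truth))
  Tn <- length(traj$marker_id)
  Mn <- length(truth$marker_id)
  if (Tn == 0) {
    per_marker <- data.frame(marker = truth$marker_id, track = NA,
                             completeness = 0)
    return(structure(list(
      per_track = data.frame(), per_marker = per_marker,
      mean_rmse_mm = NA_real_, min_completeness = 0, mean_completeness = 0,
      min_purity = NA_real_, id_switches = 0L,
      false_tracks = 0L), class = "tracking_evaluation"))
  }

  # median distance matrix between tracks and truth markers
  med <- matrix(Inf, Tn, Mn)
  for (i in seq_len(Tn)) {
    ti <- traj$positions[seq_len(nf), i, , drop = TRUE]
    ok_t <- which(!is.na(ti[, 1]))
    if (!length(ok_t)) next
    for (j in seq_len(Mn)) {
      mj <- truth$positions[seq_len(nf), j, , drop = TRUE]
      common <- ok_t[!is.na(mj[ok_t, 1])]
      if (length(common) < 2) next
      med[i, j] <- stats::median(row_dist(ti[common, , drop = FALSE],
                                          mj[common, , drop = FALSE]))
    }
  }
  # greedy one-to-one assignment by increasing median distance
  assign_track <- rep(NA_integer_, Tn)
  assign_marker <- rep(NA_integer_, Mn)
  M <- med
  repeat {
    k <- which.min(M)
    if (!length(k) || !is.finite(M[k])) break
    i <- (k - 1) %% Tn + 1; j <- (k - 1) %/% Tn + 1
    assign_track[i] <- j; assign_marker[j] <- i
    M[i, ] <- Inf; M[, j] <- Inf
  }

  per_track <- data.frame(track = traj$marker_id,
                          marker = NA_character_, rmse_mm = NA_real_,
                          purity = NA_real_, n_obs = 0L, switches = 0L,
                          false_track = FALSE)
  for (i in seq_len(Tn)) {
    ti <- traj$positions[seq_len(nf), i, , drop = TRUE]
    ok <- which(!is.na(ti[, 1]))
    per_track$n_obs[i] <- length(ok)
    j <- assign_track[i]
    assigned <- !is.na(j) && med[i, j] <= match_radius
    if (!assigned) per_track$false_track[i] <- TRUE else {
      per_track$marker[i] <- truth$marker_id[j]
      mj <- truth$positions[seq_len(nf), j, , drop = TRUE]
      common <- ok[!is.na(mj[ok, 1])]
      per_track$rmse_mm[i] <-
        sqrt(mean(row_dist(ti[common, , drop = FALSE],
                           mj[common, , drop = FALSE])^2))
    }
    # purity / switches: nearest truth marker per non-interpolated
    # position; the reference id is the assigned marker, or the majority
    # nearest id for unassigned tracks
    obs <- ok
    if (!is.null(interp)) obs <- obs[!interp[obs, i]]
    if (length(obs)) {
      nearest <- integer(length(obs))
      for (s in seq_along(obs)) {
        f <- obs[s]
        d <- row_dist(matrix(truth$positions[f, , , drop = TRUE],
                             ncol = 3),
                      matrix(ti[f, ], Mn, 3, byrow = TRUE))
        nearest[s] <- which.min(d)
        if (!length(nearest[s]) || is.na(d[nearest[s]]) ||
            d[nearest[s]] > match_radius) nearest[s] <- NA_integer_
      }
      seen <- nearest[!is.na(nearest)]
      if (length(seen)) {
        ref <- if (assigned) j else
          as.integer(names(sort(table(seen), decreasing = TRUE))[1])
        per_track$purity[i] <- mean(seen == ref)
        runs <- rle(seen)$values
        per_track$switches[i] <- max(0L, length(runs) - 1L)
      }
    }
  }

  per_marker <- data.frame(marker = truth$marker_id,
                           track = NA_character_, completeness = 0)
  for (j in seq_len(Mn)) {
    i <- assign_marker[j]
    mj <- truth$positions[seq_len(nf), j, , drop = TRUE]
    frames_j <- which(!is.na(mj[, 1]))
    if (is.na(i) || med[i, j] > match_radius || !length(frames_j)) next
    per_marker$track[j] <- traj$marker_id[i]
    ti <- traj$positions[seq_len(nf), i, , drop = TRUE]
    d <- row_dist(ti[frames_j, , drop = FALSE], mj[frames_j, , drop = FALSE])
    per_marker$completeness[j] <- mean(!is.na(d) & d <= match_radius)
  }

  structure(list(
    per_track = per_track, per_marker = per_marker,
    mean_rmse_mm = mean(per_track$rmse_mm, na.rm = TRUE),
    min_completeness = min(per_marker$completeness),
    mean_completeness = mean(per_marker$completeness),
    min_purity = if (all(is.na(per_track$purity))) NA_real_ else
      min(per_track$purity, na.rm = TRUE),
    id_switches = sum(per_track$switches),
    false_tracks = sum(per_track$false_track)
  ), class = "tracking_evaluation")
}

#' @export
print.tracking_evaluation <- function(x, ...) {
  cat("Tracking evaluation:\n",
      " mean RMSE:", signif(x$mean_rmse_mm, 4), "mm\n",
      " completeness (min/mean):", signif(x$min_completeness, 4), "/",
      signif(x$mean_completeness, 4), "\n",
      " min purity:", signif(x$min_purity, 4), "\n",
      " id switches:", x$id_switches, "; false tracks:", x$false_tracks, "\n")
  invisible(x)
}
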