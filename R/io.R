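# Interchange formats. All writers produce plain headers + full-precision
# numerics (round trip is lossless well beyond the stated 1e-6 mm / 1e-4 px
# tolerances); frames are 0-based everywhere on disk.

#' Trajectory CSV
#'
#' Columns `frame`, `marker_id`, `x_mm`, `y_mm`, `z_mm`; a gap is an absent
#' row.
#'
#' @param traj a `trajectory_set`.
#' @param path file path.
#' @param frame_rate frame rate recorded when reading (Hz).
#' @return the reader returns a `trajectory_set`.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- dim(traj$positions)
  rows <- do.call(rbind, lapply(seq_len(d[2]), function(i) {
    P <- traj$positions[, i, , drop = TRUE]
    ok <- which(!is.na(P[, 1]))
    if (!length(ok)) return(NULL)
    data.frame(frame = ok - 1L, marker_id = traj$marker_id[i],
               x_mm = P[ok, 1], y_mm = P[ok, 2], z_mm = P[ok, 3])
  }))
  rows <- rows[order(rows$frame, rows$marker_id), ]
  utils::write.csv(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, frame_rate = 500) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker_id", "x_mm", "y_mm", "z_mm")
  check_columns(d, need, path)
  ids <- sort(unique(as.character(d$marker_id)))
  nf <- max(d$frame) + 1L
  pos <- array(NA_real_, dim = c(nf, length(ids), 3))
  mi <- match(as.character(d$marker_id), ids)
  pos[cbind(d$frame + 1L, mi, 1L)] <- d$x_mm
  pos[cbind(d$frame + 1L, mi, 2L)] <- d$y_mm
  pos[cbind(d$frame + 1L, mi, 3L)] <- d$z_mm
  trajectory_set(pos, frame_rate = frame_rate, marker_id = ids)
}

#' Detection CSV
#'
#' Columns `view`, `frame`, `u_px`, `v_px` plus, unless blinded, the hidden
#' evaluation annotations `truth_id` (-1 = false positive), `merged_with`
#' and `shape`. `blinded = TRUE` exports only what a real acquisition would
#' provide (with the shape tag, which a human reader annotates on real
#' data).
#'
#' @param det a `detection_set`.
#' @param path file path.
#' @param blinded drop ground-truth provenance columns?
#' @export
write_detection_csv <- function(det, path, blinded = FALSE) {
  d <- as.data.frame(det)
  if (blinded) d <- d[, c("view", "frame", "u_px", "v_px", "shape")]
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) format(x, digits = 15, trim = TRUE,
                                              scientific = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detection_csv
#' @export
read_detection_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  check_columns(d, c("view", "frame", "u_px", "v_px"), path)
  if (!"det_id" %in% names(d)) d$det_id <- seq_len(nrow(d))
  if (!"truth_id" %in% names(d)) d$truth_id <- NA_integer_
  if (!"merged_with" %in% names(d)) d$merged_with <- NA_integer_
  if (!"shape" %in% names(d)) d$shape <- NA_character_
  class(d) <- c("detection_set", "data.frame")
  d
}

#' Assignment CSV
#'
#' Columns `track`, `marker_id`, `role`, `residual_mm`. The same schema is
#' used for manual override files (only `track` and `marker_id` required).
#'
#' @param assignment an `anatomical_assignment`.
#' @param path file path.
#' @export
write_assignment_csv <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_assignment_csv
#' @export
read_assignment_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("track", "marker_id"), path)
  d
}

#' Per-frame metrics CSV and landmark JSON
#'
#' The metrics table is written one row per frame with the exact column
#' names of [analyze_beat()]; landmarks go to JSON as
#' `{min_taa_frame, max_taa_frame, beat_start, beat_end}`.
#'
#' @param analysis a `beat_analysis`.
#' @param csv_path,json_path output paths.
#' @export
write_beat_analysis <- function(analysis, csv_path, json_path = NULL) {
  utils::write.csv(analysis$metrics, csv_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(analysis$landmarks, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}

#' Evaluation report JSON
#'
#' @param evaluation a `tracking_evaluation`.
#' @param path output path.
#' @export
write_evaluation_json <- function(evaluation, path) {
  obj <- list(
    summary = evaluation[c("mean_rmse_mm", "min_completeness",
                           "mean_completeness", "min_purity", "id_switches",
                           "false_tracks")],
    per_track = evaluation$per_track,
    per_marker = evaluation$per_marker
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

check_columns <- function(d, need, path) {
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in intersect(c("frame", "u_px", "v_px", "x_mm", "y_mm", "z_mm"),
                        need)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[col]]))))
    if (length(bad))
      stop("schema violation in ", path, ": non-numeric value in column '",
           col, "', row ", bad[1])
  }
  invisible(TRUE)
}

#' Run configuration
#'
#' The full parameter set of a pipeline run as a nested list, readable and
#' writable as YAML. Every stochastic stage derives its seed from the global
#' `seed` plus the stage name, so a run is reproducible from the file alone.
#'
#' @param seed global integer seed.
#' @param motion list of [motion_config()] arguments.
#' @param corruption list of [project_and_corrupt()] arguments
#'   (`noise_px`, `p_missing`, `fp_per_frame`, `occlusion_radius_px`).
#' @param rig list of [default_camera_rig()] arguments.
#' @param tracking list of [tracking_params()] overrides.
#' @param identification list: `doublet_threshold`, `residual_ceiling`.
#' @param metrics list: `smooth_window`, `rv_sl_pair`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, motion = list(), corruption = list(),
                       rig = list(), tracking = list(),
                       identification = list(), metrics = list()) {
  structure(list(seed = as.integer(seed), motion = motion,
                 corruption = corruption, rig = rig, tracking = tracking,
                 identification = identification, metrics = metrics),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj[intersect(names(obj), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
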