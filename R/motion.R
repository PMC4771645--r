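#' Motion configuration for the synthetic beating heart
#'
#' Collects the parameters that drive the periodic marker motion. Each
#' structure follows a raised-cosine contraction gain
#' \eqn{s(t) = (1 + cos(2\pi(f t - \phi)))/2} with beat frequency
#' \eqn{f = heart\_rate/60} Hz and per-structure phase \eqn{\phi} (fraction of
#' the cycle at which contraction peaks). The gains are analytic, so every
#' derived metric has a closed-form ground truth.
#'
#' Defaults emulate the acquisition and physiology the package targets: a
#' 500 Hz biplane acquisition of one ~1 s sinus beat at 60 beats/min, a 25 %
#' tricuspid-annular-area excursion, a saddle that flattens by 2 mm at peak
#' annular contraction, a 12 % radial ventricular contraction, a leaflet
#' opening angle swinging between 20 and 60 degrees, a 6 mm systolic descent
#' of the annulus toward the apex (TAPSE-like), and annular contraction
#' lagging ventricular contraction by 0.17 of the cycle (170 ms at 60
#' beats/min, matching the ~250 ms vs ~420 ms ordering seen in vivo).
#'
#' @param heart_rate beats per minute (> 0).
#' @param frame_rate acquisition rate, Hz (> 0).
#' @param n_frames number of frames to generate (>= 2).
#' @param annular_area_amplitude fractional peak reduction of annular area.
#' @param annular_height_amplitude mm of saddle flattening at peak annular
#'   contraction.
#' @param ventricular_contraction_fraction fractional peak reduction of the
#'   ventricular ring radii.
#' @param leaflet_angle_range length-2 degrees, open/closed leaflet angle.
#' @param tapse_mm peak systolic displacement of the annulus toward the apex.
#' @param phase_offsets named fractions of the cycle (in `[0, 1)`) at which
#'   each structure's contraction peaks; names `ventricle`, `annulus`,
#'   `leaflet`.
#' @param noise_sigma_3d mm standard deviation of iid Gaussian jitter added
#'   per marker per frame (0 = deterministic output).
#' @param rng_seed integer seed for the jitter.
#' @return list of class `motion_config`.
#' @export
motion_config <- function(heart_rate = 60, frame_rate = 500, n_frames = 1000,
                          annular_area_amplitude = 0.25,
                          annular_height_amplitude = 2,
                          ventricular_contraction_fraction = 0.12,
                          leaflet_angle_range = c(20, 60),
                          tapse_mm = 6,
                          phase_offsets = c(ventricle = 0.35, annulus = 0.52,
                                            leaflet = 0.35),
                          noise_sigma_3d = 0.02,
                          rng_seed = 1L) {
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (annular_area_amplitude < 0 || annular_area_amplitude >= 1)
    stop("annular_area_amplitude must be in [0, 1)")
  if (annular_height_amplitude < 0) stop("annular_height_amplitude must be >= 0")
  if (ventricular_contraction_fraction < 0 || ventricular_contraction_fraction >= 1)
    stop("ventricular_contraction_fraction must be in [0, 1)")
  stopifnot(length(leaflet_angle_range) == 2)
  po <- phase_offsets
  if (is.null(names(po)) ||
      !all(c("ventricle", "annulus", "leaflet") %in% names(po)))
    stop("phase_offsets must be named: ventricle, annulus, leaflet")
  if (any(po < 0) || any(po >= 1)) stop("phase offsets must be in [0, 1)")
  if (noise_sigma_3d < 0) stop("noise_sigma_3d must be >= 0")
  structure(list(
    heart_rate = heart_rate, frame_rate = frame_rate,
    n_frames = as.integer(n_frames),
    annular_area_amplitude = annular_area_amplitude,
    annular_height_amplitude = annular_height_amplitude,
    ventricular_contraction_fraction = ventricular_contraction_fraction,
    leaflet_angle_range = sort(as.numeric(leaflet_angle_range)),
    tapse_mm = tapse_mm,
    phase_offsets = po,
    noise_sigma_3d = noise_sigma_3d,
    rng_seed = as.integer(rng_seed)
  ), class = "motion_config")
}

#' Analytic contraction gain of one structure
#'
#' The raised-cosine gain driving a structure's motion, evaluated at the given
#' frames; 1 at peak contraction (cycle phase equal to the structure's phase
#' offset), 0 half a cycle away. This is the generator's own ground truth and
#' serves as the oracle for phase and amplitude recovery tests.
#'
#' @param cfg a [motion_config()].
#' @param frames 0-based frame indices.
#' @param structure `"ventricle"`, `"annulus"` or `"leaflet"`.
#' @return numeric vector of gains in `[0, 1]`.
#' @export
beat_gain <- function(cfg, frames, structure = c("ventricle", "annulus", "leaflet")) {
  structure <- match.arg(structure)
  f <- cfg$heart_rate / 60
  t <- frames / cfg$frame_rate
  0.5 * (1 + cos(2 * pi * (f * t - cfg$phase_offsets[[structure]])))
}

# Frames per beat (may be fractional).
beat_period_frames <- function(cfg) cfg$frame_rate * 60 / cfg$heart_rate

#' Simulate one or more beats of the 35-marker array
#'
#' Generates periodic 3D trajectories for every template marker. The annulus
#' scales in-plane by `sqrt(1 - annular_area_amplitude * s_a(t))` (so the fan
#' area oscillates with exactly the configured fractional amplitude), its
#' saddle height is `h0 - annular_height_amplitude * s_a(t)` (flattening at
#' peak annular contraction), and the whole annulus (with leaflet and guides)
#' translates toward the apex by `tapse_mm * s_v(t)`. Ventricular wall markers
#' contract radially toward the long axis by the configured fraction; the LV
#' apex marker is the fixed reference. The leaflet marker is placed so that
#' the opening angle at annulus marker #10 (between the chords to #5 and to
#' #11) equals the configured analytic angle exactly. With
#' `noise_sigma_3d = 0` the output is a deterministic function of the
#' configuration and is periodic to machine precision.
#'
#' @param template a [build_default_template()] layout.
#' @param cfg a [motion_config()].
#' @return A `trajectory_set`: list with `frame_rate`, `marker_id`, and
#'   `positions`, an `n_frames x n_markers x 3` array (mm) with dimnames
#'   `frame` (0-based), `marker`, `coord`.
#' @export
simulate_beat <- function(template, cfg) {
  stopifnot(inherits(template, "marker_template"), inherits(cfg, "motion_config"))
  n <- cfg$n_frames
  frames <- 0:(n - 1)
  s_v <- beat_gain(cfg, frames, "ventricle")
  s_a <- beat_gain(cfg, frames, "annulus")
  s_l <- beat_gain(cfg, frames, "leaflet")

  ids <- template$marker_id
  pos <- array(NA_real_, dim = c(n, length(ids), 3),
               dimnames = list(frame = frames, marker = ids,
                               coord = c("x", "y", "z")))

  rest <- template_positions(template)
  dy_tapse <- -cfg$tapse_mm * s_v                             # toward apex
  # saddle scale relative to the template rest height h0 = 3 mm
  h0 <- 3
  h_t <- pmax(h0 - cfg$annular_height_amplitude * s_a, 0) / h0
  # In-plane annular scale: solved per frame so that the 3D fan area of the
  # (saddle-shaped) ring equals exactly A0 * (1 - amplitude * s_a(t)); a
  # closed-form sqrt scale would be off by the out-of-plane term.
  rho_ann <- annular_inplane_scale(cfg$annular_area_amplitude * s_a, h_t * h0)

  ann_like <- which(template$role %in%
                    c("tricuspid_annulus", "guide_ball", "guide_cylinder"))
  for (k in ann_like) {
    p <- rest[k, ]
    pos[, k, 1] <- p[1] * rho_ann
    pos[, k, 3] <- p[3] * rho_ann
    pos[, k, 2] <- p[2] * h_t + dy_tapse
  }

  vent <- which(template$role %in% c("rv_epicardial", "lv_wall"))
  rho_v <- 1 - cfg$ventricular_contraction_fraction * s_v
  for (k in vent) {
    p <- rest[k, ]
    pos[, k, 1] <- p[1] * rho_v
    pos[, k, 3] <- p[3] * rho_v
    pos[, k, 2] <- p[2]
  }

  apex_k <- which(template$role == "lv_apex")
  pos[, apex_k, ] <- matrix(rest[apex_k, ], n, 3, byrow = TRUE)

  # leaflet: angle alpha(t) at vertex #10, exact by construction
  i10 <- which(template$marker_id == 10)
  i5 <- which(template$marker_id == 5)
  i11 <- which(template$marker_id == 11)
  rng <- cfg$leaflet_angle_range
  alpha_t <- rng[2] - (rng[2] - rng[1]) * s_l     # closes at peak contraction
  for (f in seq_len(n)) {
    pos[f, i11, ] <- leaflet_position(pos[f, i10, ], pos[f, i5, ],
                                      alpha_deg = alpha_t[f])
  }

  if (cfg$noise_sigma_3d > 0) {
    set.seed(cfg$rng_seed)
    pos <- pos + stats::rnorm(length(pos), sd = cfg$noise_sigma_3d)
  }

  trajectory_set(pos, frame_rate = cfg$frame_rate)
}

# Fan area of the canonical annulus ring at in-plane scale rho and saddle
# height h (template semi-axes 16 x 14 mm).
annulus_fan_area <- function(rho, h, a = 16, b = 14) {
  th <- 2 * pi * ((1:10) - 3) / 10
  annular_area(cbind(a * cos(th) * rho, h * cos(2 * th), b * sin(th) * rho))
}

# Solve rho(t) so that fan_area(rho, h_t) = A0 * (1 - frac_t), where A0 is
# the rest-state fan area; monotone in rho, solved by uniroot per distinct
# (frac, h) value.
annular_inplane_scale <- function(frac, h) {
  A0 <- annulus_fan_area(1, 3)
  key <- paste(signif(frac, 12), signif(h, 12))
  uk <- !duplicated(key)
  sol <- vapply(which(uk), function(i) {
    if (frac[i] == 0 && h[i] == 3) return(1)
    target <- A0 * (1 - frac[i])
    stats::uniroot(function(r) annulus_fan_area(r, h[i]) - target,
                   interval = c(0.3, 1.5), tol = 1e-12)$root
  }, 0)
  as.numeric(sol[match(key, key[uk])])
}

#' Analytic leaflet opening angle series
#'
#' The configured opening angle alpha(t) in degrees, per frame; ground truth
#' for the leaflet angle recovered by the metrics module.
#'
#' @inheritParams beat_gain
#' @return numeric vector, degrees.
#' @export
leaflet_angle_series <- function(cfg, frames) {
  rng <- cfg$leaflet_angle_range
  rng[2] - (rng[2] - rng[1]) * beat_gain(cfg, frames, "leaflet")
}

#' Analytic septal-lateral amplitude implied by a motion configuration
#'
#' The annular septal-lateral (#3-#8) diameter in the generator equals
#' `2 * 16 mm * rho(t)` with `rho(t)` the solved in-plane scale, so its
#' fractional peak-to-peak amplitude is `1 - rho_min`. Ground truth for
#' end-to-end parameter-recovery tests.
#'
#' @param cfg a [motion_config()].
#' @return fractional amplitude (max - min) / max of the TA S-L series.
#' @export
expected_sl_amplitude <- function(cfg) {
  h_min <- max(3 - cfg$annular_height_amplitude, 0)
  rho_min <- annular_inplane_scale(cfg$annular_area_amplitude, h_min)
  1 - rho_min
}

#' Construct a trajectory set
#'
#' @param positions `n_frames x n_markers x 3` array of positions in mm; `NA`
#'   marks a gap.
#' @param frame_rate Hz.
#' @param marker_id optional marker labels (defaults to the array dimnames).
#' @return list of class `trajectory_set`.
#' @export
trajectory_set <- function(positions, frame_rate, marker_id = NULL) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3)
  if (is.null(marker_id)) marker_id <- dimnames(positions)[[2]]
  if (is.null(marker_id)) marker_id <- as.character(seq_len(dim(positions)[2]))
  dimnames(positions) <- list(frame = 0:(dim(positions)[1] - 1),
                              marker = marker_id, coord = c("x", "y", "z"))
  structure(list(frame_rate = frame_rate, marker_id = marker_id,
                 positions = positions),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat("Trajectory set:", d[2], "markers x", d[1], "frames @",
      x$frame_rate, "Hz;",
      sum(is.na(x$positions[, , 1])), "gap positions\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1]

# n x 3 position matrix of one marker (by label).
marker_track <- function(traj, marker) traj$positions[, as.character(marker), ]
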