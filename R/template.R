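#' The canonical 35-marker beating-heart array
#'
#' Builds the default anatomical marker template used throughout the package:
#' 10 spherical markers on the tricuspid annulus (#1-10, ordered consecutively
#' around the ring), one spherical marker on the tricuspid leaflet edge (#11;
#' the source protocol labels this leaflet both "posterior" and "anterior" in
#' different places, so the role here is simply `leaflet`), 9 spherical
#' markers on the right-ventricular epicardium (4 basal, 3 equatorial,
#' 2 apical), 12 cylindrical markers in the left-ventricular wall (4 per
#' level) plus one cylindrical marker at the LV apex, and two guide markers:
#' a ball sutured next to annulus marker #7 and a cylinder next to annulus
#' marker #3, used to anchor anatomical orientation during identification.
#'
#' Rest geometry (the protocol gives none, so this layout is schematic but
#' respects the ring ordering and basal/equatorial/apical level structure):
#' the annulus is an ellipse of semi-axes 16 x 14 mm in the x-z plane with a
#' sinusoidal out-of-plane saddle term (two high points, at the septal #3 and
#' anterior #8 regions); ventricular markers sit on nested rings around the
#' long axis (the y-axis) which passes through the LV apex marker at
#' (0, -70, 0) mm.
#'
#' @return A data frame of class `marker_template` with one row per marker and
#'   columns `marker_id`, `label`, `role` (one of `tricuspid_annulus`,
#'   `leaflet`, `rv_epicardial`, `lv_wall`, `lv_apex`, `guide_ball`,
#'   `guide_cylinder`), `shape` (`sphere`/`cylinder`), `side`
#'   (`right`/`left`), `level` (`basal`/`equatorial`/`apical`/`annulus`/
#'   `apex`), `level_index`, `septal` (logical; the designated septal slots),
#'   `anchor_id` (annulus anchor for guide markers, else NA), and rest
#'   coordinates `x`, `y`, `z` in mm.
#' @examples
#' tpl <- build_default_template()
#' nrow(tpl)                       # 35
#' table(tpl$shape)                # 21 spheres, 14 cylinders
#' @export
build_default_template <- function() {
  # --- tricuspid annulus ring, #3 septal at theta = 0, #8 lateral/anterior ---
  i <- 1:10
  theta <- 2 * pi * (i - 3) / 10
  a <- 16; b <- 14; h0 <- 3
  ann <- data.frame(
    marker_id = i,
    label = paste0("ta", i),
    role = "tricuspid_annulus", shape = "sphere", side = "right",
    level = "annulus", level_index = i, septal = i == 3, anchor_id = NA_integer_,
    x = a * cos(theta), y = h0 * cos(2 * theta), z = b * sin(theta)
  )

  # --- leaflet marker #11: rest position at mid-range opening angle ---
  p10 <- as.numeric(ann[10, c("x", "y", "z")])
  p5 <- as.numeric(ann[5, c("x", "y", "z")])
  lf <- leaflet_position(p10, p5, alpha_deg = 40, length_mm = 12)
  leaflet <- data.frame(
    marker_id = 11, label = "leaflet11",
    role = "leaflet", shape = "sphere", side = "right",
    level = "annulus", level_index = NA_integer_, septal = FALSE,
    anchor_id = NA_integer_, x = lf[1], y = lf[2], z = lf[3]
  )

  ring <- function(ids, prefix, role, shape, side, level, y, r, psi_deg,
                   septal = rep(FALSE, length(ids))) {
    psi <- psi_deg * pi / 180
    data.frame(
      marker_id = ids, label = paste0(prefix, seq_along(ids)),
      role = role, shape = shape, side = side, level = level,
      level_index = seq_along(ids), septal = septal,
      anchor_id = NA_integer_,
      x = r * cos(psi), y = y, z = r * sin(psi)
    )
  }

  # --- RV epicardial free wall: 4/3/2 markers on a truncated cone ---
  rv <- rbind(
    ring(12:15, "rvb", "rv_epicardial", "sphere", "right", "basal",
         y = -12, r = 30, psi_deg = c(-60, 0, 60, 120)),
    ring(16:18, "rve", "rv_epicardial", "sphere", "right", "equatorial",
         y = -34, r = 25, psi_deg = c(-40, 30, 100)),
    ring(19:20, "rva", "rv_epicardial", "sphere", "right", "apical",
         y = -52, r = 18, psi_deg = c(-10, 70))
  )

  # --- LV wall: 4/4/4 rings + apex; first marker of each ring is septal ---
  lv <- rbind(
    ring(21:24, "lvb", "lv_wall", "cylinder", "left", "basal",
         y = -15, r = 27, psi_deg = c(210, 300, 30, 120) + 15,
         septal = c(TRUE, FALSE, FALSE, FALSE)),
    ring(25:28, "lve", "lv_wall", "cylinder", "left", "equatorial",
         y = -35, r = 24, psi_deg = c(210, 300, 30, 120) + 30,
         septal = c(TRUE, FALSE, FALSE, FALSE)),
    ring(29:32, "lva", "lv_wall", "cylinder", "left", "apical",
         y = -55, r = 16, psi_deg = c(210, 300, 30, 120) + 45,
         septal = c(TRUE, FALSE, FALSE, FALSE))
  )
  apex <- data.frame(
    marker_id = 33, label = "lvapex", role = "lv_apex", shape = "cylinder",
    side = "left", level = "apex", level_index = 1L, septal = FALSE,
    anchor_id = NA_integer_, x = 0, y = -70, z = 0
  )

  # --- guide markers: 2.5 mm radially outward from their annulus anchors ---
  guide <- function(id, label, role, shape, anchor) {
    p <- as.numeric(ann[anchor, c("x", "y", "z")])
    dir <- unitv(c(p[1], 0, p[3]))
    q <- p + 2.5 * dir
    data.frame(
      marker_id = id, label = label, role = role, shape = shape,
      side = "right", level = "annulus", level_index = NA_integer_,
      septal = FALSE, anchor_id = anchor, x = q[1], y = q[2], z = q[3]
    )
  }
  guides <- rbind(
    guide(34, "guide_ball7", "guide_ball", "sphere", 7L),
    guide(35, "guide_cyl3", "guide_cylinder", "cylinder", 3L)
  )

  tpl <- rbind(ann, leaflet, rv, lv, apex, guides)
  rownames(tpl) <- NULL
  class(tpl) <- c("marker_template", "data.frame")
  tpl
}

# Place the leaflet marker: at `length_mm` from p10, rotated `alpha_deg` away
# from the annular chord p10 -> p5 about an axis perpendicular to the chord
# (so the angle at vertex p10 equals alpha exactly, by construction).
leaflet_position <- function(p10, p5, alpha_deg, length_mm = 12) {
  u <- unitv(p5 - p10)
  axis <- unitv(cross3(u, c(0, 1, 0)))
  w <- cross3(axis, u)              # unit, perpendicular to u
  al <- alpha_deg * pi / 180
  p10 + length_mm * (cos(al) * u + sin(al) * w)
}

#' @export
print.marker_template <- function(x, ...) {
  cat("Marker template:", nrow(x), "markers\n")
  print(table(role = x$role, shape = x$shape))
  invisible(x)
}

# n x 3 matrix of rest positions, rows named by marker id.
template_positions <- function(template) {
  m <- as.matrix(template[, c("x", "y", "z")])
  rownames(m) <- template$marker_id
  m
}
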