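#' Machine projection geometry
#'
#' Bundles the distances and detector constants shared by the simulator and
#' every image analysis. Distances are in cm, detector quantities in mm.
#' The magnification from the isocentre plane to the imager panel is
#' `M = sid / sad`.
#'
#' The default source-axis distance is 143.5 cm, the value for a ring-gantry
#' MR-linac whose isocentre sits 143.5 cm from the source. The
#' source-to-imager distance and the panel pixel pitch are machine constants
#' that must be configured; the defaults (215.25 cm, i.e. M = 1.5, and
#' 0.25 mm/px) are plausible placeholders, not vendor values.
#'
#' @param sad_cm Source-axis distance, cm. Default 143.5.
#' @param sid_cm Source-to-imager distance, cm. Must exceed `sad_cm`.
#' @param pixel_pitch_mm Detector pixel pitch at the panel, mm/pixel.
#' @param panel_extent_cm Maximum imaged field at the isocentre plane,
#'   c(width_x, length_y) in cm. Default `c(22, 9.5)`.
#' @param central_pixel Optional c(u, v) 0-based pixel coordinates of the beam
#'   axis on the panel at gantry 0. `NULL` means "centre of whatever image is
#'   analysed".
#' @return An object of class `machine_geometry`.
#' @export
machine_geometry <- function(sad_cm = 143.5, sid_cm = 215.25,
                             pixel_pitch_mm = 0.25,
                             panel_extent_cm = c(22.0, 9.5),
                             central_pixel = NULL) {
  stopifnot(is.numeric(sad_cm), length(sad_cm) == 1L,
            is.numeric(sid_cm), length(sid_cm) == 1L,
            is.numeric(pixel_pitch_mm), length(pixel_pitch_mm) == 1L,
            is.numeric(panel_extent_cm), length(panel_extent_cm) == 2L)
  if (sad_cm <= 0) stop("`sad_cm` must be positive", call. = FALSE)
  if (sid_cm <= sad_cm) {
    stop("`sid_cm` must exceed `sad_cm` (imager beyond the isocentre)",
         call. = FALSE)
  }
  if (pixel_pitch_mm <= 0) stop("`pixel_pitch_mm` must be positive", call. = FALSE)
  if (any(panel_extent_cm <= 0)) {
    stop("`panel_extent_cm` components must be positive", call. = FALSE)
  }
  structure(
    list(sad_cm = sad_cm, sid_cm = sid_cm,
         pixel_pitch_mm = pixel_pitch_mm,
         panel_extent_cm = panel_extent_cm,
         central_pixel = central_pixel),
    class = "machine_geometry"
  )
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat("<machine_geometry>\n")
  cat(sprintf("  SAD %.1f cm, SID %.2f cm (M = %.4f)\n",
              x$sad_cm, x$sid_cm, magnification(x)))
  cat(sprintf("  pixel pitch %.3f mm, panel extent %.1f x %.1f cm at isocentre\n",
              x$pixel_pitch_mm, x$panel_extent_cm[1], x$panel_extent_cm[2]))
  invisible(x)
}

#' Panel magnification
#' @param geom A [machine_geometry()].
#' @return `sid / sad`, dimensionless, > 1.
#' @export
magnification <- function(geom) geom$sid_cm / geom$sad_cm

#' Normalize a gantry angle to [0, 360)
#'
#' Angles follow the IEC61217 sense: the beam points straight down (-Z) at 0
#' degrees and the rotation axis is Y.
#'
#' @param angle_deg Numeric vector of angles in degrees.
#' @return Angles wrapped into `[0, 360)`.
#' @export
normalize_gantry_angle <- function(angle_deg) {
  stopifnot(is.numeric(angle_deg))
  a <- angle_deg %% 360
  a[a == 360] <- 0
  a
}

#' Project a length between planes of a diverging beam
#'
#' Full similar-triangle scaling of a transverse length from the isocentre
#' plane to another plane at `distance_cm` from the source (no parallel-ray
#' approximation). `inverse_project_length()` goes the other way: given the
#' length measured at `distance_cm`, it returns the equivalent length at the
#' isocentre. For instance a 10.0 cm field defined at a source-chamber
#' distance of 147.5 cm corresponds to a 9.7 cm field at a 143.5 cm SAD
#' isocentre.
#'
#' @param length_at_iso Transverse length in the isocentre plane, cm (or any
#'   unit; scaling is linear).
#' @param distance_cm Distance from the source to the target plane, cm; > 0.
#' @param geom A [machine_geometry()].
#' @return Scaled length, same unit as the input.
#' @export
project_length <- function(length_at_iso, distance_cm, geom = machine_geometry()) {
  if (any(!is.finite(length_at_iso)) || any(length_at_iso <= 0)) {
    stop("`length_at_iso` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("`distance_cm` must be positive and finite", call. = FALSE)
  }
  length_at_iso * distance_cm / geom$sad_cm
}

#' @rdname project_length
#' @param length_at_distance Length measured in the plane at `distance_cm`.
#' @export
inverse_project_length <- function(length_at_distance, distance_cm,
                                   geom = machine_geometry()) {
  if (any(!is.finite(length_at_distance)) || any(length_at_distance <= 0)) {
    stop("`length_at_distance` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("`distance_cm` must be positive and finite", call. = FALSE)
  }
  length_at_distance * geom$sad_cm / distance_cm
}

#' Beam direction in the transverse (X-Z) plane
#'
#' Unit vector along which the beam travels for a given gantry angle, IEC61217:
#' at 0 degrees the source is above the isocentre and the beam travels -Z; at
#' 90 degrees it travels -X.
#'
#' @param angle_deg Gantry angle in degrees (any real value; normalized).
#' @return Length-2 numeric c(dx, dz), unit norm.
#' @export
beam_direction <- function(angle_deg) {
  stopifnot(is.numeric(angle_deg), length(angle_deg) == 1L)
  th <- normalize_gantry_angle(angle_deg) * pi / 180
  c(-sin(th), -cos(th))
}

# Unit vector of the panel u axis in the X-Z plane: u increases with +X at
# gantry 0 and rotates with the gantry (perpendicular to the beam).
panel_u_axis <- function(angle_deg) {
  th <- normalize_gantry_angle(angle_deg) * pi / 180
  c(cos(th), -sin(th))
}

#' Panel coordinate of a ballbearing offset from the isocentre
#'
#' Projects a transverse offset in the isocentre plane onto the imager panel
#' for a given gantry angle, using full similar-triangle magnification from
#' the point's actual distance from the source (offsets with a component along
#' the beam are magnified slightly more or less than `M`). A zero offset maps
#' to the central pixel (u = 0) at every angle; a pure perpendicular offset of
#' 1 mm maps to exactly `M` mm.
#'
#' @param offset_mm c(x, z) offset from the isocentre, mm, IEC61217 X-Z plane.
#' @param angle_deg Gantry angle, degrees.
#' @param geom A [machine_geometry()].
#' @return Signed panel displacement u from the central pixel, mm. The u axis
#'   increases with +X at gantry 0.
#' @export
bb_panel_coordinate <- function(offset_mm, angle_deg, geom = machine_geometry()) {
  stopifnot(is.numeric(offset_mm), length(offset_mm) == 2L)
  d <- beam_direction(angle_deg)
  e_u <- panel_u_axis(angle_deg)
  perp <- sum(offset_mm * e_u)
  along_cm <- sum(offset_mm * d) / 10  # mm -> cm along the beam
  t_cm <- geom$sad_cm + along_cm       # distance source -> point, along axis
  perp * geom$sid_cm / t_cm
}

# Project a 3-D point (x, y, z) in isocentre-frame mm onto the panel for a
# beam whose axis passes through `axis_offset_mm` (x, z at the isocentre
# plane) at gantry `angle_deg`. Returns c(u, v) panel mm relative to the
# central pixel (which tracks the beam axis: the gantry, source and panel move
# as one rigid ring). v increases with -Y (toward the feet for head-first
# supine at gantry 0).
project_point_panel <- function(p_mm, angle_deg, geom,
                                axis_offset_mm = c(0, 0)) {
  d <- beam_direction(angle_deg)
  e_u <- panel_u_axis(angle_deg)
  rel <- c(p_mm[1] - axis_offset_mm[1], p_mm[3] - axis_offset_mm[2])
  t_cm <- geom$sad_cm + sum(rel * d) / 10
  u <- sum(rel * e_u) * geom$sid_cm / t_cm
  v <- -p_mm[2] * geom$sid_cm / t_cm
  c(u = u, v = v, mag = geom$sid_cm / t_cm)
}
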