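# Landmark geometry: the simplified occlusal plane, perpendicular CEJ
# distances, the eruption quotient, tooth angulation and eligibility.
#
# Quotient measurement resolves the apical direction anatomically (the M2
# CEJ side of the occlusal line), so it is invariant under arbitrary
# rotations of the image, not just upright ones.
#
# Coordinate convention throughout: raster image coordinates, origin at the
# top-left, x rightward, y downward. For mandibular teeth "apical" therefore
# means increasing y, and perpendicular distances from the occlusal line are
# signed positive on the apical side.

#' Construct the simplified occlusal line
#'
#' The simplified occlusal plane of a lower molar region is the straight line
#' through the radiologically highest mesial cusp point of the first molar and
#' the highest distal cusp point of the second molar. It is treated as an
#' infinite line: perpendicular feet may fall outside the anchor segment,
#' which is the usual situation for an unerupted third molar.
#'
#' @param m1_mesial_cusp,m2_distal_cusp Numeric length-2 vectors `c(x, y)` in
#'   pixel coordinates (raster convention, y down).
#' @return An object of class `occlusal_line` with elements `p1`, `p2` and the
#'   unit direction `u` (oriented so that `u[1] >= 0`, i.e. left-to-right).
#' @export
#' @examples
#' occlusal_line(c(0, 0), c(10, 0))
occlusal_line <- function(m1_mesial_cusp, m2_distal_cusp) {
  p1 <- as.numeric(m1_mesial_cusp)
  p2 <- as.numeric(m2_distal_cusp)
  if (length(p1) != 2L || length(p2) != 2L || !all(is.finite(c(p1, p2)))) {
    abort("Occlusal line anchors must be finite length-2 coordinates.",
          class = "eruptq_error_geometry")
  }
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len <= 1e-9) {
    abort("Occlusal plane undefined: anchor points coincide.",
          class = "eruptq_error_occlusal_plane_undefined")
  }
  u <- d / len
  # orient left-to-right so the apical (y-down) side has positive sign
  # regardless of which anchor is mesial in the image
  if (u[1] < 0) u <- -u
  structure(list(p1 = p1, p2 = p2, u = u), class = "occlusal_line")
}

#' Signed perpendicular distance from the occlusal line to a point
#'
#' Distance magnitude is `|cross(p2 - p1, p - p1)| / |p2 - p1|`; the sign is
#' positive when the point lies on the apical side of the line (larger y for a
#' horizontal line under the raster convention) and negative on the coronal
#' side.
#'
#' @param line An [occlusal_line()].
#' @param p A length-2 point, or an n x 2 matrix of points.
#' @return Signed distance(s) in the same units as the coordinates (pixels).
#' @export
#' @examples
#' l <- occlusal_line(c(0, 0), c(10, 0))
#' perpendicular_distance(l, c(3, 4)) # +4, apical side
perpendicular_distance <- function(line, p) {
  stopifnot(inherits(line, "occlusal_line"))
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 2L)
  # z-component of cross(u, p - p1); u oriented left-to-right so apical
  # (y-down) is positive
  line$u[1] * (p[, 2] - line$p1[2]) - line$u[2] * (p[, 1] - line$p1[1])
}

#' Measure the eruption quotient of one annotation record
#'
#' Two perpendiculars are dropped from the simplified occlusal line to the
#' mesial cementoenamel junction (CEJ) of the second and of the third molar;
#' the eruption quotient is the ratio of the two lengths. Because both lengths
#' share the radiograph's local magnification, the quotient is dimensionless
#' and invariant to uniform projection scaling, which is the reason a ratio is
#' used on panoramic radiographs at all.
#'
#' When `round_lengths = TRUE` and a `mm_per_px` calibration is available, the
#' lengths are converted to millimetres and rounded half-up to one decimal
#' place before division, mirroring a measurement protocol that records
#' lengths to 0.1 mm; the unrounded lengths are always returned alongside.
#'
#' @param record A single annotation record: a list or one-row tibble with a
#'   `landmarks` tibble (`label`, `x`, `y`) and optionally `mm_per_px`.
#' @param direction `"m2_over_m3"` (default; quotient rises towards 1 as the
#'   third molar erupts) or `"m3_over_m2"`.
#' @param round_lengths Round lengths to 0.1 mm before forming the quotient?
#'   Requires calibration; an error is raised if requested without
#'   `mm_per_px`.
#' @return A one-row tibble with pixel distances `d_m2`, `d_m3`, millimetre
#'   lengths `d_m2_mm`, `d_m3_mm` (NA without calibration), the quotient `q`,
#'   `direction` and `rounded`.
#' @export
measure_quotient <- function(record,
                             direction = c("m2_over_m3", "m3_over_m2"),
                             round_lengths = TRUE) {
  direction <- match.arg(direction)
  lm <- record_landmarks(record)
  need <- measurement_labels()
  missing <- setdiff(need, lm$label)
  if (length(missing) > 0L) {
    abort(paste0("Record not measurable; missing landmark(s): ",
                 paste(missing, collapse = ", ")),
          class = "eruptq_error_missing_landmark")
  }
  pt <- function(label) unlist(lm[lm$label == label, c("x", "y")], use.names = FALSE)
  line <- occlusal_line(pt("M1_MESIAL_CUSP"), pt("M2_DISTAL_CUSP"))
  d2 <- perpendicular_distance(line, pt("M2_MESIAL_CEJ"))
  d3 <- perpendicular_distance(line, pt("M3_MESIAL_CEJ"))
  # The anatomy, not the image frame, defines "apical": the anchor tooth's
  # CEJ always lies apical to the occlusal line, so a frame-negative d_m2
  # means the image is rotated upside-down relative to the raster convention
  # and both signs flip. A sign mismatch between the CEJs remains invalid.
  if (d2 < 0) {
    d2 <- -d2
    d3 <- -d3
  }
  if (d2 <= 0 || d3 <= 0) {
    abort("Non-positive perpendicular distance: CEJ not apical to the occlusal plane.",
          class = "eruptq_error_nonpositive_distance")
  }
  mm_per_px <- record_mm_per_px(record)
  d2_mm <- if (is.na(mm_per_px)) NA_real_ else d2 * mm_per_px
  d3_mm <- if (is.na(mm_per_px)) NA_real_ else d3 * mm_per_px
  if (round_lengths) {
    if (is.na(mm_per_px)) {
      abort("round_lengths = TRUE requires a mm_per_px calibration (rounding pixels would be scale-dependent).",
            class = "eruptq_error_config")
    }
    num <- round_half_up(if (direction == "m2_over_m3") d2_mm else d3_mm, 1L)
    den <- round_half_up(if (direction == "m2_over_m3") d3_mm else d2_mm, 1L)
  } else {
    num <- if (direction == "m2_over_m3") d2 else d3
    den <- if (direction == "m2_over_m3") d3 else d2
  }
  if (den <= 0) {
    abort("Quotient denominator rounded to zero.",
          class = "eruptq_error_nonpositive_distance")
  }
  tibble(
    d_m2 = d2, d_m3 = d3,
    d_m2_mm = d2_mm, d_m3_mm = d3_mm,
    q = num / den,
    direction = direction,
    rounded = round_lengths
  )
}

# round half away from zero at `digits` decimals (commercial rounding, the
# convention for clinical length recording); base round() is half-to-even
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Signed mesio-distal angulation of the third molar
#'
#' The angulation is the angle between the long axis of the third molar and
#' the long axis of the second molar (a Winter-style axis comparison). The
#' sign encodes the tilt direction of the third molar's coronal end: positive
#' mesial, negative distal. Under standard panoramic orientation (patient's
#' left on the viewer's right), "mesial" is decreasing image x for tooth 38
#' and increasing x for tooth 48; `orientation = "flipped"` reverses this.
#'
#' @param m3_axis,m2_axis Lists or length-4 numeric vectors giving the coronal
#'   point then the apical point of each axis: `c(x_cor, y_cor, x_ap, y_ap)`,
#'   or `list(coronal = c(x, y), apical = c(x, y))`.
#' @param side 38 or 48 (FDI tooth number of the third molar).
#' @param orientation `"standard"` or `"flipped"` image orientation.
#' @return Signed angle in degrees; magnitude is the angle between the axes.
#' @export
tooth_angulation <- function(m3_axis, m2_axis, side,
                             orientation = c("standard", "flipped")) {
  orientation <- match.arg(orientation)
  side <- as.integer(side)
  if (!side %in% c(38L, 48L)) {
    abort("side must be 38 or 48 (FDI).", class = "eruptq_error_geometry")
  }
  ax <- function(a) {
    if (is.list(a)) a <- c(a$coronal, a$apical)
    a <- as.numeric(a)
    v <- a[1:2] - a[3:4]               # apical -> coronal direction
    len <- sqrt(sum(v^2))
    if (!all(is.finite(v)) || len <= 1e-9) {
      abort("Degenerate (zero-length) tooth axis.", class = "eruptq_error_geometry")
    }
    v / len
  }
  u3 <- ax(m3_axis)
  u2 <- ax(m2_axis)
  phi <- atan2(u2[1] * u3[2] - u2[2] * u3[1], sum(u2 * u3)) * 180 / pi
  # In raster coordinates a positive phi rotates the coronal tip towards +x.
  # +x is mesial for 48 and distal for 38 under standard orientation.
  mesial <- if (side == 48L) phi else -phi
  if (orientation == "flipped") mesial <- -mesial
  mesial
}

#' Eligibility configuration
#'
#' @param mesial_angle_limit Exclusion threshold in degrees for mesial
#'   angulation; a tooth is excluded when its mesial angle strictly exceeds
#'   `mesial_angle_limit + angle_tolerance`.
#' @param distal_angle_limit Allowed distal angulation in degrees (default 0:
#'   any distal tilt beyond the tolerance excludes).
#' @param angle_tolerance Measurement slack in degrees applied to both limits.
#' @return A list of class `eligibility_config`.
#' @export
eligibility_config <- function(mesial_angle_limit = 30,
                               distal_angle_limit = 0,
                               angle_tolerance = 0) {
  stopifnot(mesial_angle_limit >= 0, distal_angle_limit >= 0,
            angle_tolerance >= 0)
  structure(list(mesial_angle_limit = mesial_angle_limit,
                 distal_angle_limit = distal_angle_limit,
                 angle_tolerance = angle_tolerance),
            class = "eligibility_config")
}

#' Assess study eligibility of one annotation record
#'
#' Applies the inclusion rules: the four measurement landmarks must be
#' present, the occlusal plane must be definable, both CEJs must lie apical
#' to it, mesial angulation must not exceed the limit (strictly: an angle of
#' exactly the limit is included) and any distal angulation beyond the
#' tolerance excludes. Reasons are accumulated, not short-circuited. Records
#' without axis landmarks are eligible by default, with angulation flagged as
#' not assessed.
#'
#' @param record A single annotation record (see [measure_quotient()]), with
#'   a `side` field used for the angulation sign.
#' @param config An [eligibility_config()].
#' @param orientation Image orientation passed to [tooth_angulation()].
#' @return A list of class `eligibility_result`: `included` (logical),
#'   `reasons` (character vector, empty iff included), `angle` (degrees or
#'   NA) and `angle_assessed` (logical).
#' @export
assess_eligibility <- function(record, config = eligibility_config(),
                               orientation = "standard") {
  stopifnot(inherits(config, "eligibility_config"))
  lm <- record_landmarks(record)
  reasons <- character()

  missing <- setdiff(measurement_labels(), lm$label)
  if (length(missing) > 0L) reasons <- c(reasons, "MISSING_LANDMARK")

  d_ok <- TRUE
  if (all(c("M1_MESIAL_CUSP", "M2_DISTAL_CUSP") %in% lm$label)) {
    pt <- function(label) unlist(lm[lm$label == label, c("x", "y")], use.names = FALSE)
    line <- tryCatch(occlusal_line(pt("M1_MESIAL_CUSP"), pt("M2_DISTAL_CUSP")),
                     eruptq_error_occlusal_plane_undefined = function(e) NULL)
    if (is.null(line)) {
      reasons <- c(reasons, "OCCLUSAL_PLANE_UNDEFINED")
    } else if (length(missing) == 0L) {
      d2 <- perpendicular_distance(line, pt("M2_MESIAL_CEJ"))
      d3 <- perpendicular_distance(line, pt("M3_MESIAL_CEJ"))
      if (d2 < 0) { # inverted frame; see measure_quotient()
        d2 <- -d2
        d3 <- -d3
      }
      d_ok <- d2 > 0 && d3 > 0
      if (!d_ok) reasons <- c(reasons, "NONPOSITIVE_DISTANCE")
    }
  }

  axis_labels <- c("M3_AXIS_CORONAL", "M3_AXIS_APICAL",
                   "M2_AXIS_CORONAL", "M2_AXIS_APICAL")
  angle <- NA_real_
  angle_assessed <- all(axis_labels %in% lm$label)
  if (angle_assessed) {
    pt <- function(label) unlist(lm[lm$label == label, c("x", "y")], use.names = FALSE)
    angle <- tooth_angulation(
      m3_axis = c(pt("M3_AXIS_CORONAL"), pt("M3_AXIS_APICAL")),
      m2_axis = c(pt("M2_AXIS_CORONAL"), pt("M2_AXIS_APICAL")),
      side = record_field(record, "side"),
      orientation = orientation
    )
    tol <- config$angle_tolerance
    if (angle > config$mesial_angle_limit + tol) {
      reasons <- c(reasons, "MESIAL_ANGULATION_GT_30")
    }
    if (angle < -(config$distal_angle_limit + tol)) {
      reasons <- c(reasons, "DISTAL_ANGULATION")
    }
  }

  structure(list(included = length(reasons) == 0L,
                 reasons = reasons,
                 angle = angle,
                 angle_assessed = angle_assessed),
            class = "eligibility_result")
}

# --- small record accessors shared with landmark_io -------------------------

record_landmarks <- function(record) {
  if (is_tibble(record) && "landmarks" %in% names(record)) {
    stopifnot(nrow(record) == 1L)
    return(record$landmarks[[1L]])
  }
  if (is.list(record) && !is.null(record$landmarks)) {
    lm <- record$landmarks
    if (is.data.frame(lm)) return(as_tibble(lm))
  }
  abort("Record must carry a `landmarks` data frame (label, x, y).",
        class = "eruptq_error_schema")
}

record_field <- function(record, field) {
  v <- record[[field]]
  if (is.null(v)) abort(paste0("Record is missing field `", field, "`."),
                        class = "eruptq_error_schema")
  if (is_tibble(record)) v <- v[[1L]]
  v
}

record_mm_per_px <- function(record) {
  v <- tryCatch(record_field(record, "mm_per_px"), error = function(e) NA_real_)
  if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
}
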