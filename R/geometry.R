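# Radiographic geometry: the raw measurements that feed the score.

#' Magnification-corrected tip-apex distance
#'
#' Combines the apparent tip-to-apex lengths measured on the AP and lateral
#' films into Baumgaertner's tip-apex distance (TAD). Each film's
#' magnification is corrected by the ratio of the true (manufactured)
#' lag-screw diameter to its apparent diameter on that film, so
#' `TAD = x_ap * d_true/d_ap + x_lat * d_true/d_lat`.
#'
#' The result is invariant to uniform magnification of either film: scaling
#' `x_ap` and `d_ap` by a common factor leaves the AP term unchanged.
#'
#' @param x_ap,x_lat Apparent tip-to-apex length on the AP / lateral film
#'   (mm, non-negative).
#' @param d_ap,d_lat Apparent lag-screw diameter on the AP / lateral film
#'   (mm, strictly positive).
#' @param d_true True lag-screw diameter (mm, strictly positive). Values
#'   outside a plausible implant range (6--16 mm) trigger a warning, not an
#'   error.
#' @return Numeric vector of tip-apex distances in mm.
#' @examples
#' tip_apex_distance(x_ap = 12, x_lat = 10, d_ap = 12, d_lat = 8, d_true = 10.5)
#' @export
tip_apex_distance <- function(x_ap, x_lat, d_ap, d_lat, d_true) {
  check_nonneg(x_ap, "x_ap")
  check_nonneg(x_lat, "x_lat")
  check_pos(d_ap, "d_ap")
  check_pos(d_lat, "d_lat")
  check_pos(d_true, "d_true")
  if (any(d_true < 6 | d_true > 16, na.rm = TRUE)) {
    warning("d_true outside the plausible implant range (6-16 mm)")
  }
  x_ap * (d_true / d_ap) + x_lat * (d_true / d_lat)
}

#' Planar projection of the femoral head and lag screw
#'
#' Describes one radiographic plane (AP or lateral) by the femoral head
#' circle, the neck axis direction, and the position of the lag-screw
#' centre where it sits in the head. Coordinates are abstract planar units;
#' only ratios enter downstream formulas, so pixel spacing is irrelevant.
#'
#' @param head_centre Numeric length-2 centre of the femoral head circle.
#' @param head_radius Positive head radius, same units.
#' @param neck_axis Numeric length-2 direction of the femoral neck axis;
#'   normalised internally (must be non-zero).
#' @param screw_centre Numeric length-2 position of the lag-screw centre at
#'   the level of the head.
#' @return An object of class `head_projection`.
#' @seealso [assign_band()], [quadrant_from_projections()]
#' @export
head_projection <- function(head_centre, head_radius, neck_axis, screw_centre) {
  stopifnot(length(head_centre) == 2L, length(neck_axis) == 2L,
            length(screw_centre) == 2L, is.numeric(head_radius),
            length(head_radius) == 1L)
  if (!is.finite(head_radius) || head_radius <= 0) {
    stop("head_radius must be a positive number")
  }
  nrm <- sqrt(sum(neck_axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("neck_axis must be a non-zero vector")
  structure(
    list(head_centre = as.numeric(head_centre),
         head_radius = as.numeric(head_radius),
         neck_axis = as.numeric(neck_axis) / nrm,
         screw_centre = as.numeric(screw_centre)),
    class = "head_projection")
}

# Normalised transverse position of the screw centre within the head:
# project onto the axis perpendicular to the neck axis (90 degrees
# counter-clockwise rotation) and map the head diameter to [0, 1].
# 0 corresponds to the superior (AP) / anterior (lateral) edge under the
# usual image orientation.
band_position <- function(p, tolerance = 0.05) {
  stopifnot(inherits(p, "head_projection"))
  rel <- p$screw_centre - p$head_centre
  dist <- sqrt(sum(rel^2))
  if (dist > p$head_radius * (1 + tolerance)) {
    stop("screw centre lies outside the femoral head circle")
  }
  perp <- c(-p$neck_axis[2], p$neck_axis[1])
  s <- (sum(rel * perp) + p$head_radius) / (2 * p$head_radius)
  min(max(s, 0), 1)
}

#' Assign a head third (band) to a screw position
#'
#' The femoral head is divided into three equal parts perpendicular to the
#' neck axis in each plane. The screw centre's normalised transverse
#' position `s` in `[0, 1]` maps to the first band when `s < 1/3`, the last
#' band when `s > 2/3`, and the middle band otherwise; the boundary points
#' `1/3` and `2/3` go to the centre band so ties favour the clinically
#' modal category.
#'
#' @param p A [head_projection()] object, or directly a numeric position
#'   `s` in `[0, 1]`.
#' @param labels Ordered band names for the plane, first label at `s = 0`:
#'   `c("superior", "centre", "inferior")` for AP films,
#'   `c("anterior", "centre", "posterior")` for lateral films.
#' @param tolerance Fraction of the head radius by which the screw centre
#'   may fall outside the head circle before an error is raised.
#' @return One of `labels`.
#' @export
assign_band <- function(p, labels = c("superior", "centre", "inferior"),
                        tolerance = 0.05) {
  stopifnot(length(labels) == 3L, is.character(labels))
  s <- if (inherits(p, "head_projection")) band_position(p, tolerance) else p
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0, s <= 1)
  if (s < 1 / 3) labels[1L] else if (s > 2 / 3) labels[3L] else labels[2L]
}

#' Cleveland-Bosworth quadrant from AP and lateral projections
#'
#' Composes [assign_band()] on the two planes into the 3x3 quadrant
#' locating the lag screw in the femoral head (superior/centre/inferior on
#' AP, anterior/centre/posterior on lateral).
#'
#' @param ap,lat [head_projection()] objects for the AP and lateral films.
#' @param tolerance Passed to [assign_band()].
#' @return Named character vector `c(ap_band = ..., lat_band = ...)`.
#' @export
quadrant_from_projections <- function(ap, lat, tolerance = 0.05) {
  c(ap_band = assign_band(ap, c("superior", "centre", "inferior"), tolerance),
    lat_band = assign_band(lat, c("anterior", "centre", "posterior"), tolerance))
}

#' Collo-diaphyseal angle difference (fractured minus intact)
#'
#' Negative differences indicate varus alignment of the operated hip
#' relative to the contralateral side; positive differences indicate
#' valgus.
#'
#' @param cda_fractured,cda_intact Neck-shaft angles in degrees, each in
#'   `[90, 180]`.
#' @return Signed difference in degrees.
#' @export
cda_difference <- function(cda_fractured, cda_intact) {
  for (nm in c("cda_fractured", "cda_intact")) {
    v <- get(nm)
    if (any(v < 90 | v > 180, na.rm = TRUE)) {
      stop(sprintf("%s must lie in [90, 180] degrees", nm))
    }
  }
  cda_fractured - cda_intact
}

#' Classify medial / anterior cortical support from a cortical offset
#'
#' The offset is the signed distance of the head-neck fragment cortex
#' relative to the shaft cortex (positive when the fragment cortex rests on
#' or medial/anterior to the shaft cortex). Offsets within `tolerance` of
#' zero are graded neutral. The published grading was visual; this helper
#' exists for coordinate-level inputs and the category can equally be
#' supplied directly.
#'
#' @param offset Signed cortical offset in mm (vectorised).
#' @param tolerance Non-negative neutrality half-width in mm (default 1).
#' @return Character vector in `c("negative", "neutral", "positive")`.
#' @export
classify_cortical_support <- function(offset, tolerance = 1) {
  stopifnot(is.numeric(offset), is.numeric(tolerance), length(tolerance) == 1L,
            tolerance >= 0)
  out <- ifelse(offset > tolerance, "positive",
                ifelse(offset < -tolerance, "negative", "neutral"))
  out[is.na(offset)] <- NA_character_
  out
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", name))
  if (any(x < 0, na.rm = TRUE)) stop(sprintf("%s must be non-negative", name))
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", name))
  if (any(x <= 0, na.rm = TRUE)) {
    stop(sprintf("invalid measurement: %s must be strictly positive", name))
  }
  invisible(x)
}
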