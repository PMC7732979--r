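# Heat-loss index, thermal-image ROI temperatures, and indirect-calorimetry
# derived measures.

#' Heat loss index
#'
#' `HLI = (Tskin - Tambient) / (Tcore - Tambient)`: a normalized measure of
#' heat dissipation through the skin, near 0 with full vasoconstriction and
#' near 1 when the skin approaches core temperature. Undefined (returned as
#' `NA`) when core and ambient temperatures are within `epsilon` of each
#' other. Values above 1 (skin warmer than core) are reported as-is, not
#' clamped, with a warning.
#'
#' @param t_skin,t_core,t_ambient temperatures in deg C (vectorized).
#' @param epsilon minimum |t_core - t_ambient| (deg C) for a defined index
#'   (default 0.1).
#' @return Dimensionless HLI, `NA` where undefined.
#' @examples
#' heat_loss_index(28, 34, 22)  # 0.5
#' @export
heat_loss_index <- function(t_skin, t_core, t_ambient, epsilon = 0.1) {
  stopifnot(all(is.finite(t_skin)), all(is.finite(t_core)),
            all(is.finite(t_ambient)), epsilon > 0)
  denom <- t_core - t_ambient
  hli <- (t_skin - t_ambient) / denom
  hli[abs(denom) < epsilon] <- NA_real_
  if (any(hli > 1, na.rm = TRUE))
    warning("HLI > 1: skin warmer than core (reported unclamped)")
  hli
}

#' Thermal image container
#'
#' @param temps numeric matrix of per-pixel temperatures, deg C.
#' @param pixel_pitch physical size of a pixel, mm/pixel.
#' @return Object of class `thermal_image`.
#' @export
thermal_image <- function(temps, pixel_pitch = 1) {
  stopifnot(is.matrix(temps), all(is.finite(temps)), pixel_pitch > 0)
  structure(list(temps = temps, pixel_pitch = pixel_pitch),
            class = "thermal_image")
}

#' Circular region of interest
#'
#' @param center `c(x, y)` in pixel units (pixel centers at integer
#'   coordinates, column = x, row = y).
#' @param radius radius in pixels.
#' @return ROI descriptor for [roi_mean_temperature()].
#' @export
roi_circle <- function(center, radius) {
  stopifnot(length(center) == 2L, radius > 0)
  structure(list(center = center, radius = radius), class = "roi_circle")
}

#' Line-segment region of interest
#'
#' Emulates a line ROI along the tail: pixels within `width/2` of the
#' segment (in pixels), rasterized at pixel resolution.
#'
#' @param p1,p2 segment endpoints, `c(x, y)` in pixel units.
#' @param width band width in pixels (default 1).
#' @return ROI descriptor for [roi_mean_temperature()].
#' @export
roi_segment <- function(p1, p2, width = 1) {
  stopifnot(length(p1) == 2L, length(p2) == 2L, width > 0)
  if (all(p1 == p2)) stop("segment endpoints coincide")
  structure(list(p1 = p1, p2 = p2, width = width), class = "roi_segment")
}

#' Mean temperature over a region of interest
#'
#' Averages the pixels whose centers fall inside the ROI — a circle (as used
#' for the interscapular BAT region) or a line segment of given width (as
#' used for the tail).
#'
#' @param image a [thermal_image()].
#' @param roi a [roi_circle()] or [roi_segment()].
#' @return Mean temperature, deg C.
#' @export
roi_mean_temperature <- function(image, roi) {
  stopifnot(inherits(image, "thermal_image"))
  nr <- nrow(image$temps); nc <- ncol(image$temps)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # column = x
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)          # row = y
  inside <- if (inherits(roi, "roi_circle")) {
    (xs - roi$center[1])^2 + (ys - roi$center[2])^2 <= roi$radius^2
  } else if (inherits(roi, "roi_segment")) {
    vx <- roi$p2[1] - roi$p1[1]; vy <- roi$p2[2] - roi$p1[2]
    len2 <- vx^2 + vy^2
    t <- pmin(pmax(((xs - roi$p1[1]) * vx + (ys - roi$p1[2]) * vy) / len2, 0), 1)
    dx <- xs - (roi$p1[1] + t * vx); dy <- ys - (roi$p1[2] + t * vy)
    sqrt(dx^2 + dy^2) <= roi$width / 2
  } else stop("roi must be a roi_circle or roi_segment")
  if (!any(inside)) stop("ROI does not intersect the image")
  mean(image$temps[inside])
}

#' Respiratory exchange ratio
#'
#' `RER = VCO2 / VO2`, a measure of metabolic fuel preference
#' (~0.7 for pure fat oxidation, 1.0 for pure carbohydrate).
#'
#' @param vco2,vo2 gas exchange rates, ml/h (vectorized; `vo2` must be > 0).
#' @return Dimensionless RER.
#' @export
respiratory_exchange_ratio <- function(vco2, vo2) {
  if (any(vo2 <= 0, na.rm = TRUE)) stop("vo2 must be positive")
  vco2 / vo2
}

#' Normalize a calorimetry series by lean body mass
#'
#' Elementwise division of VO2 (ml/h) or heat (kcal/h) by the animal's lean
#' mass in grams, giving ml/h/g or kcal/h/g.
#'
#' @param series numeric series.
#' @param lean_mass lean body mass, g (> 0).
#' @return Per-gram series.
#' @export
normalize_by_lean_mass <- function(series, lean_mass) {
  stopifnot(length(lean_mass) == 1L)
  if (!is.finite(lean_mass) || lean_mass <= 0)
    stop("lean_mass must be a positive number")
  series / lean_mass
}

#' Heat production from the Lusk equation (helper)
#'
#' `heat (kcal/h) = (3.815 + 1.232 * RER) * VO2 (l/h)`. This classical
#' calorific-equivalent formula is provided as a convenience for calorimetry
#' exports that lack a heat column; the study's calorimetry software computed
#' heat internally and this equation is not taken from it.
#'
#' @param vo2 oxygen consumption, ml/h.
#' @param rer respiratory exchange ratio.
#' @return Heat production, kcal/h.
#' @export
lusk_heat <- function(vo2, rer) (3.815 + 1.232 * rer) * vo2 / 1000
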