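# PGV -> macroseismic intensity conversion and intensity-class binning.

#' Log-linear PGV-to-intensity law
#'
#' `I = clamp(c0 + c1 * log10(PGV), 1, 12)` with PGV in m/s.  The shipped
#' defaults (`c0 = 9.77`, `c1 = 3.00`) approximate the instrumental
#' PGV-intensity relationship of the current Chinese seismic intensity
#' standard; both coefficients are meant to be set from the standard in use
#' and are validated here only for monotonicity (`c1 > 0`).
#'
#' @param c0 intercept.
#' @param c1 slope per decade of PGV (> 0).
#' @param clamp two-element intensity clamp (default `c(1, 12)`).
#' @return object of class `intensity_law`.
#' @export
intensity_law <- function(c0 = 9.77, c1 = 3.00, clamp = c(1, 12)) {
  stopifnot(is.finite(c0), is.finite(c1), length(clamp) == 2,
            clamp[1] < clamp[2])
  if (c1 <= 0) stop("c1 must be > 0 (intensity increases with PGV)",
                    call. = FALSE)
  structure(list(c0 = c0, c1 = c1, clamp = clamp, pgv_units = "m/s"),
            class = "intensity_law")
}

#' Convert peak ground velocity to intensity
#'
#' Applies an [intensity_law()] cellwise.  `PGV = 0` maps to the lower
#' clamp; the conversion is monotone non-decreasing in PGV.
#'
#' @param pgv a [geo_grid()] of PGV in m/s, or a plain numeric
#'   vector/matrix.
#' @param law an [intensity_law()].
#' @return object of the same shape: a `geo_grid` of continuous intensity,
#'   or numeric.
#' @examples
#' pgv_to_intensity(0.1, intensity_law(9.77, 3))  # 6.77
#' @export
pgv_to_intensity <- function(pgv, law = intensity_law()) {
  stopifnot(inherits(law, "intensity_law"))
  vals <- if (inherits(pgv, "geo_grid")) pgv$values else pgv
  if (any(vals[is.finite(vals)] < 0)) stop("PGV must be non-negative",
                                           call. = FALSE)
  I <- law$c0 + law$c1 * log10(vals)
  I[vals == 0] <- law$clamp[1]
  I <- pmin(pmax(I, law$clamp[1]), law$clamp[2])
  if (inherits(pgv, "geo_grid")) return(geo_grid(pgv$spec, I, pgv$nodata))
  I
}

#' Bin continuous intensity into damaging classes
#'
#' Rounds half-up to the nearest integer class.  Values binning below V are
#' below the damaging range and return `NA`; values binning above XI are
#' clamped to XI with a warning.
#'
#' @param x numeric vector of continuous intensity (finite).
#' @return integer vector of classes in 5..11, `NA` below the damaging
#'   range.
#' @examples
#' bin_intensity(c(7.5, 4.49, 11.6))
#' @export
bin_intensity <- function(x) {
  if (any(!is.finite(x))) stop("intensity must be finite", call. = FALSE)
  cls <- round_half_up(x)
  cls[cls < 5] <- NA
  if (any(cls > 11, na.rm = TRUE)) {
    warning(sum(cls > 11, na.rm = TRUE),
            " cell(s) above class XI clamped to XI", call. = FALSE)
    cls[cls > 11] <- 11
  }
  as.integer(cls)
}
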