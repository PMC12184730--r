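#' Delta notation for stable isotope ratios
#'
#' Converts a raw heavy/light isotope abundance ratio to delta notation relative
#' to an international standard (atmospheric N2 for nitrogen, Vienna Peedee
#' Belemnite for carbon):
#' \deqn{\delta X = (R_{sample}/R_{standard} - 1) \times 1000}
#' in units of per mil.
#'
#' @param r_sample Heavy/light isotope ratio of the sample; strictly positive.
#' @param r_standard Heavy/light isotope ratio of the standard; strictly
#'   positive. Vectors are recycled in the usual way.
#' @return Delta value(s) in per mil.
#' @seealso [delta_to_ratio()] for the inverse map.
#' @examples
#' compute_delta(0.0112372, 0.0112372)  # sample identical to standard -> 0
#' @export
compute_delta <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    stop("isotope ratios must be numeric", call. = FALSE)
  }
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be finite and strictly positive", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Invert delta notation back to a raw ratio
#'
#' @param delta Delta value(s), per mil.
#' @param r_standard Ratio of the standard; strictly positive.
#' @return The sample ratio implied by `delta`.
#' @export
delta_to_ratio <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("r_standard must be finite and strictly positive", call. = FALSE)
  }
  (delta / 1000 + 1) * r_standard
}

#' Two-point calibration of measured delta values
#'
#' Instrumental delta values are placed on the international scale with an
#' affine map fitted through two reference standards (e.g., USGS-40 and
#' USGS-41A): the line sending each standard's measured value to its accepted
#' value is applied to the raw measurement.
#'
#' @param raw Measured delta value(s), per mil.
#' @param measured_1,measured_2 Measured delta values of the two standards;
#'   must differ.
#' @param true_1,true_2 Accepted delta values of the two standards.
#' @return Calibrated delta value(s), per mil.
#' @examples
#' two_point_calibration(5, measured_1 = 0, true_1 = 1,
#'                       measured_2 = 10, true_2 = 21)  # slope 2, offset 1 -> 11
#' @export
two_point_calibration <- function(raw, measured_1, true_1, measured_2, true_2) {
  vals <- c(measured_1, true_1, measured_2, true_2)
  if (length(vals) != 4 || any(!is.finite(vals))) {
    stop("calibration anchors must be four finite scalars", call. = FALSE)
  }
  if (measured_1 == measured_2) {
    stop("degenerate calibration: measured anchor values coincide",
         call. = FALSE)
  }
  slope <- (true_2 - true_1) / (measured_2 - measured_1)
  true_1 + slope * (raw - measured_1)
}
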