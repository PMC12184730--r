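#' Quality-control configuration for whisker segments
#'
#' Keratin segments with atomic C:N ratios outside a narrow band indicate
#' contaminated or degraded tissue. The conventional acceptance band for
#' unaltered whisker keratin is 3.0 to 4.0 (inclusive); a slightly wider lower
#' bound of 2.9 is sometimes used in practice and can be configured here.
#'
#' @param cn_min,cn_max Inclusive bounds on the acceptable atomic C:N ratio.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(cn_min = 3.0, cn_max = 4.0) {
  stopifnot(is.numeric(cn_min), is.numeric(cn_max), length(cn_min) == 1,
            length(cn_max) == 1, is.finite(cn_min), is.finite(cn_max))
  if (cn_min >= cn_max) stop("cn_min must be < cn_max", call. = FALSE)
  structure(list(cn_min = cn_min, cn_max = cn_max), class = "qc_config")
}

#' Filter whisker segments on atomic C:N ratio
#'
#' Partitions a segment table into segments with acceptable C:N ratios
#' (`cn_min <= cn_ratio <= cn_max`, bounds inclusive) and the excluded
#' complement, preserving input order.
#'
#' @param segments A data frame with (at least) a numeric `cn_ratio` column,
#'   one row per segment.
#' @param cfg A [qc_config()].
#' @return A list with elements `kept` and `excluded` (both data frames with
#'   the input columns) and `cfg`.
#' @export
qc_filter_cn <- function(segments, cfg = qc_config()) {
  stopifnot(is.data.frame(segments), inherits(cfg, "qc_config"))
  if (!"cn_ratio" %in% names(segments)) {
    stop("segments must have a 'cn_ratio' column", call. = FALSE)
  }
  bad <- which(!is.finite(segments$cn_ratio))
  if (length(bad)) {
    stop("missing or non-finite cn_ratio on segment row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ok <- segments$cn_ratio >= cfg$cn_min & segments$cn_ratio <= cfg$cn_max
  list(kept = segments[ok, , drop = FALSE],
       excluded = segments[!ok, , drop = FALSE],
       cfg = cfg)
}
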