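#' Von Bertalanffy growth parameters for a whisker
#'
#' Whisker growth is modelled by the saturating Von Bertalanffy curve
#' \eqn{L(t) = L_\infty (1 - e^{-kt})}. Published leopard seal growth
#' parameters are not bundled with this package; the defaults used by the
#' simulator are documented assumptions (see the package vignette), and real
#' analyses should pass study-specific values.
#'
#' @param l_inf Asymptotic whisker length, mm; > 0.
#' @param k_rate Growth-rate constant, per day; > 0.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(l_inf, k_rate) {
  stopifnot(is.numeric(l_inf), is.numeric(k_rate), length(l_inf) == 1,
            length(k_rate) == 1)
  if (!is.finite(l_inf) || l_inf <= 0 || !is.finite(k_rate) || k_rate <= 0) {
    stop("l_inf and k_rate must be finite and > 0", call. = FALSE)
  }
  structure(list(l_inf = l_inf, k_rate = k_rate), class = "growth_params")
}

#' Whisker length at a given age
#'
#' Evaluates \eqn{L(t) = L_\infty (1 - e^{-kt})}; the value lies in
#' `[0, l_inf)` for finite non-negative ages.
#'
#' @param age_days Age(s) since growth started, days; >= 0.
#' @param params A [growth_params()].
#' @return Length(s), mm.
#' @export
vb_length <- function(age_days, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(age_days)) || any(age_days < 0)) {
    stop("age_days must be finite and >= 0", call. = FALSE)
  }
  params$l_inf * (1 - exp(-params$k_rate * age_days))
}

#' Age at which a whisker reaches a given length
#'
#' Exact inverse of [vb_length()]:
#' \eqn{t(L) = -\log(1 - L/L_\infty)/k}.
#'
#' @param length_mm Length(s), mm, in `[0, l_inf)`.
#' @param params A [growth_params()].
#' @return Age(s), days.
#' @export
vb_age_at_length <- function(length_mm, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(length_mm)) || any(length_mm < 0)) {
    stop("length_mm must be finite and >= 0", call. = FALSE)
  }
  if (any(length_mm >= params$l_inf)) {
    stop("length ", max(length_mm), " mm is at or beyond the asymptote l_inf = ",
         params$l_inf, " mm; the growth curve never reaches it", call. = FALSE)
  }
  -log(1 - length_mm / params$l_inf) / params$k_rate
}

#' Assign calendar dates to whisker segments
#'
#' Inverts the Von Bertalanffy growth curve anchored at the collection date.
#' With total whisker length `L` and whisker age `T = vb_age_at_length(L)`,
#' material whose segment midpoint lies at distance `d` from the root (the
#' follicle, newest growth) was laid down when the whisker had cumulative
#' length `s = L - d`, i.e. at growth age `vb_age_at_length(s)`; its date is
#' `collection_date - (T - vb_age_at_length(s))`. Dates therefore equal the
#' collection date at the root and strictly decrease toward the tip. Fractional
#' days are kept internally; `mid_date` is rounded to whole days.
#'
#' @param whisker Segment data frame for a single whisker (rows sharing one
#'   `whisker_id`, schema of [read_segments_csv()]).
#' @param params A [growth_params()] with `l_inf` exceeding the whisker length.
#' @return The input rows with added columns `age_days_at_collection` (age of
#'   the segment material, days before collection, fractional), `mid_date`
#'   (`Date`), and `mid_date_frac` (fractional days since collection date,
#'   non-positive).
#' @export
timestamp_whisker <- function(whisker, params) {
  stopifnot(is.data.frame(whisker), inherits(params, "growth_params"))
  if (length(unique(whisker$whisker_id)) != 1) {
    stop("timestamp_whisker expects segments of a single whisker", call. = FALSE)
  }
  whisker <- whisker[order(whisker$segment_index), , drop = FALSE]
  L <- max(whisker$end_mm)
  if (L >= params$l_inf) {
    stop("whisker length ", L, " mm >= l_inf = ", params$l_inf,
         " mm; growth parameters cannot time-stamp this whisker", call. = FALSE)
  }
  collection <- as.Date(whisker$collection_date[1])
  T_age <- vb_age_at_length(L, params)
  d_mid <- (whisker$start_mm + whisker$end_mm) / 2
  s <- L - d_mid
  age_at_formation <- vb_age_at_length(s, params)
  back_days <- T_age - age_at_formation      # days before collection
  whisker$age_days_at_collection <- back_days
  whisker$mid_date_frac <- -back_days
  whisker$mid_date <- collection - round(back_days)
  whisker
}

#' Time span covered by a time-stamped whisker
#'
#' @param timestamped Output of [timestamp_whisker()] for one whisker.
#' @return Difference between the newest and oldest segment midpoint dates in
#'   fractional days (>= 0). A single-segment whisker yields 0 with a warning.
#' @export
whisker_span_days <- function(timestamped) {
  stopifnot(is.data.frame(timestamped),
            "age_days_at_collection" %in% names(timestamped))
  if (nrow(timestamped) < 2) {
    warning("whisker has a single segment; span is 0")
    return(0)
  }
  diff(range(timestamped$age_days_at_collection))
}
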