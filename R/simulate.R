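#' Configuration for the synthetic whisker-population generator
#'
#' Defaults mirror the shape of the Cape Shirreff study: 34 individuals and 46
#' whiskers (12 extra whiskers from resampled individuals), segments of 0.5-3
#' mm, whisker time spans of roughly 20-290 days, population means near
#' (-21.9, 11.5) per mil and between-individual variance set so the
#' between-individual share of total variance is roughly 50-60%. Within-whisker
#' covariances are parameterized per specialization class through a target
#' specialization index: for class SI target `s`, the within variance is
#' `s/(1-s)` times the between-individual variance, per isotope.
#'
#' @param n_individuals Number of individuals.
#' @param n_whiskers Total whiskers (>= n_individuals); extras are assigned to
#'   randomly chosen individuals as repeat samples in later years.
#' @param class_mix Named fractions over Specialist/Intermediate/Generalist
#'   summing to 1; each whisker's class is drawn from this mix.
#' @param si_by_class Named target SI per class, used to derive the
#'   within-whisker covariance from `sigma_between`.
#' @param mu_population Population mean (delta13C, delta15N), per mil.
#' @param sigma_between 2x2 covariance of individual niche centers.
#' @param sex_effect Additive delta15N shift applied to males, per mil.
#' @param prop_male Fraction of male individuals.
#' @param trend Piecewise-linear year effect on delta15N: a list with `knots`
#'   (fractional years) and `values` (per mil at the knots), or `NULL` for no
#'   trend.
#' @param month_amplitude Amplitude of a sinusoidal month effect on delta15N.
#' @param growth A [growth_params()].
#' @param segment_length_range Segment lengths, mm (uniform).
#' @param span_range_days Whisker growth spans sampled uniformly in this range.
#' @param years Candidate sampling years.
#' @param cn_outlier_rate Fraction of segments given out-of-range C:N ratios.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 34, n_whiskers = 46,
                       class_mix = c(Specialist = 0.59, Intermediate = 0.28,
                                     Generalist = 0.13),
                       si_by_class = c(Specialist = 0.15, Intermediate = 0.40,
                                       Generalist = 0.70),
                       mu_population = c(-21.93, 11.46),
                       sigma_between = diag(c(0.34, 1.36)),
                       sex_effect = -1.2, prop_male = 6 / 34,
                       trend = NULL, month_amplitude = 0,
                       growth = growth_params(l_inf = 120, k_rate = 0.0054),
                       segment_length_range = c(0.5, 3),
                       span_range_days = c(20, 290),
                       years = 2013:2023,
                       cn_outlier_rate = 0.005, seed = 1L) {
  stopifnot(n_whiskers >= n_individuals, n_individuals >= 2)
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1", call. = FALSE)
  }
  ev <- eigen(sigma_between, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("sigma_between must be PSD", call. = FALSE)
  if (segment_length_range[1] <= 0 ||
      segment_length_range[1] >= segment_length_range[2]) {
    stop("invalid segment_length_range", call. = FALSE)
  }
  max_len <- vb_length(max(span_range_days), growth)
  if (max_len >= growth$l_inf) stop("infeasible growth geometry", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Section a whisker into random segment increments
#'
#' Partitions `[0, total_length)` into contiguous pieces with lengths drawn
#' uniformly from `segment_length_range`; a final remainder shorter than the
#' minimum is merged into its neighbor.
#'
#' @param total_length_mm Whisker length, mm; must exceed the minimum segment
#'   length.
#' @param segment_length_range Length bounds, mm.
#' @return A data frame with `start_mm`, `end_mm` tiling `[0, total_length)`.
#' @export
section_whisker <- function(total_length_mm, segment_length_range = c(0.5, 3)) {
  lo <- segment_length_range[1]; hi <- segment_length_range[2]
  stopifnot(total_length_mm > lo)
  cuts <- 0
  while (cuts[length(cuts)] < total_length_mm) {
    cuts <- c(cuts, cuts[length(cuts)] + stats::runif(1, lo, hi))
  }
  cuts[length(cuts)] <- total_length_mm
  # merge a too-short final remainder into its neighbor
  n <- length(cuts)
  if (n > 2 && (cuts[n] - cuts[n - 1]) < lo) {
    cuts <- cuts[-(n - 1)]
  }
  data.frame(start_mm = cuts[-length(cuts)], end_mm = cuts[-1])
}

#' Piecewise-linear temporal trend
#'
#' Evaluates a continuous piecewise-linear function through `(knots, values)`
#' at fractional-year dates; outside the knot support the offset is 0 (the
#' spec'd trend has compact support, so the end values should be 0 for
#' continuity).
#'
#' @param dates Fractional years.
#' @param trend_spec `NULL`, or a list with ordered `knots` and `values` of
#'   equal length.
#' @return Per-mil offsets, one per date.
#' @export
inject_trend <- function(dates, trend_spec) {
  if (is.null(trend_spec)) return(rep(0, length(dates)))
  k <- trend_spec$knots; v <- trend_spec$values
  if (is.unsorted(k, strictly = TRUE)) {
    stop("trend knots must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(k) == length(v), length(k) >= 2)
  out <- rep(0, length(dates))
  inside <- dates >= k[1] & dates <= k[length(k)]
  out[inside] <- stats::approx(k, v, xout = dates[inside])$y
  out
}

# draw from a bivariate normal via Cholesky (PSD-safe)
rmvnorm2 <- function(n, mu, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  matrix(stats::rnorm(2 * n), n, 2) %*% root + matrix(mu, n, 2, byrow = TRUE)
}

#' Simulate a whisker isotope population with known ground truth
#'
#' Generates a full synthetic dataset under the statistical model the analysis
#' modules assume: individual niche centers are bivariate normal around the
#' population mean; each whisker grows along a Von Bertalanffy curve over a
#' sampled time window and is sectioned into random 0.5-3 mm segments; each
#' segment's (delta13C, delta15N) is bivariate normal around the individual
#' center plus (delta15N only) a sex effect, an injected piecewise-linear year
#' trend, and a sinusoidal month effect, with a class-specific within-whisker
#' covariance; C:N ratios are uniform inside the QC band except a configured
#' outlier fraction placed outside it.
#'
#' @param cfg A [sim_config()].
#' @return A list with `segments` (validated segment data frame) and `truth`
#'   (list: `centers` per individual, `whiskers` data frame with true class,
#'   true SI, collection info, and per-segment formation dates inside
#'   `segments` as `true_date_frac`).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_ind <- cfg$n_individuals
  centers <- rmvnorm2(n_ind, cfg$mu_population, cfg$sigma_between)
  sex <- ifelse(stats::runif(n_ind) < cfg$prop_male, "M", "F")
  animal_ids <- sprintf("A%02d", seq_len(n_ind))

  owner <- c(seq_len(n_ind),
             sample(seq_len(n_ind), cfg$n_whiskers - n_ind, replace = TRUE))
  classes <- sample(names(cfg$class_mix), cfg$n_whiskers, replace = TRUE,
                    prob = cfg$class_mix)
  # class-specific within-whisker covariance from the target SI:
  # si = w / (w + b)  =>  w = b * si / (1 - si), per isotope (diagonal).
  b_diag <- diag(cfg$sigma_between)
  sigma_within <- lapply(cfg$si_by_class, function(s) {
    diag(pmax(b_diag, 1e-6) * s / (1 - s), 2)
  })

  seg_list <- list()
  wh_rows <- list()
  for (w in seq_len(cfg$n_whiskers)) {
    ind <- owner[w]
    year <- sample(cfg$years, 1)
    # sampling season: day-of-year within Jan-May
    doy <- sample(15:150, 1)
    collection <- as.Date(sprintf("%d-01-01", year)) + (doy - 1)
    span <- stats::runif(1, cfg$span_range_days[1], cfg$span_range_days[2])
    L <- vb_length(span, cfg$growth)
    secs <- section_whisker(L, cfg$segment_length_range)
    n_seg <- nrow(secs)
    # true formation date of each segment midpoint (fractional days before
    # collection), by the same root-anchored growth inversion used downstream
    d_mid <- (secs$start_mm + secs$end_mm) / 2
    T_age <- vb_age_at_length(L, cfg$growth)
    back <- T_age - vb_age_at_length(L - d_mid, cfg$growth)
    frac_year <- as.numeric(format(collection, "%Y")) +
      (as.numeric(format(collection, "%j")) - 1 - back) / 365.25
    month_frac <- (frac_year %% 1) * 12
    mu_seg <- matrix(centers[ind, ], n_seg, 2, byrow = TRUE)
    mu_seg[, 2] <- mu_seg[, 2] +
      (if (sex[ind] == "M") cfg$sex_effect else 0) +
      inject_trend(frac_year, cfg$trend) +
      cfg$month_amplitude * sin(2 * pi * month_frac / 12)
    iso <- rmvnorm2(n_seg, c(0, 0), sigma_within[[classes[w]]]) + mu_seg
    cn <- stats::runif(n_seg, 3.0, 4.0)
    out_cn <- stats::runif(n_seg) < cfg$cn_outlier_rate
    if (any(out_cn)) {
      lowside <- stats::runif(sum(out_cn)) < 0.5
      cn[out_cn] <- ifelse(lowside, stats::runif(sum(out_cn), 2.5, 2.99),
                           stats::runif(sum(out_cn), 4.01, 4.5))
    }
    wid <- sprintf("W%03d", w)
    seg_list[[w]] <- data.frame(
      whisker_id = wid, animal_id = animal_ids[ind], sex = sex[ind],
      sampling_year = year, collection_date = collection,
      segment_index = seq_len(n_seg) - 1L,
      start_mm = secs$start_mm, end_mm = secs$end_mm,
      d13C = iso[, 1], d15N = iso[, 2], cn_ratio = cn,
      true_date_frac = frac_year, stringsAsFactors = FALSE)
    wh_rows[[w]] <- data.frame(
      whisker_id = wid, animal_id = animal_ids[ind], sex = sex[ind],
      sampling_year = year, true_class = classes[w],
      true_si = cfg$si_by_class[[classes[w]]],
      span_days = span, length_mm = L, n_segments = n_seg,
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_list)
  segments <- validate_segments(segments)
  list(segments = segments,
       truth = list(centers = data.frame(animal_id = animal_ids, sex = sex,
                                         d13C = centers[, 1],
                                         d15N = centers[, 2]),
                    whiskers = do.call(rbind, wh_rows),
                    trend = cfg$trend, config = cfg))
}
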