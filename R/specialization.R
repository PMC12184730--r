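#' One-way variance components for unbalanced groups
#'
#' Method-of-moments decomposition of isotope variance into between-group
#' (between-individual) and within-group (along-whisker) components for
#' unbalanced one-way layouts: with `g` groups of sizes `n_i` and total `N`,
#' `MSW` is the pooled within-group mean square, `MSB` the between-group mean
#' square, and `n0 = (N - sum(n_i^2)/N) / (g - 1)` the effective group size;
#' then `sigma2_within = MSW` and
#' `sigma2_between = max(0, (MSB - MSW)/n0)` (negative estimates are truncated
#' at zero with a warning).
#'
#' @param values Numeric vector of observations (e.g., segment delta15N).
#' @param groups Grouping vector of the same length (e.g., whisker id).
#' @return A list of class `variance_components`: `sigma2_within`,
#'   `sigma2_between`, `share_within`, `share_between`, `n_groups`, `n_total`.
#' @export
variance_components <- function(values, groups) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  g <- length(sizes)
  if (g < 2) stop("between-group variance undefined with a single group",
                  call. = FALSE)
  if (!any(sizes >= 2)) {
    stop("need at least one group with >= 2 values", call. = FALSE)
  }
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssw <- sum((values - means[groups])^2)
  msw <- ssw / (N - g)
  ssb <- sum(sizes * (means[names(sizes)] - grand)^2)
  msb <- ssb / (g - 1)
  n0 <- (N - sum(sizes^2) / N) / (g - 1)
  s2b <- (msb - msw) / n0
  if (s2b < 0) {
    warning("negative between-group variance estimate truncated at 0")
    s2b <- 0
  }
  tot <- msw + s2b
  structure(list(sigma2_within = msw, sigma2_between = s2b,
                 share_within = msw / tot, share_between = s2b / tot,
                 n_groups = g, n_total = N),
            class = "variance_components")
}

#' Individual niche width of a whisker
#'
#' The within-whisker (individual) niche width: the sample variance (n-1
#' denominator) of one whisker's segment values for a given isotope.
#'
#' @param whisker Segment data frame for one whisker.
#' @param isotope `"d15N"` or `"d13C"`.
#' @return Variance, per mil squared.
#' @export
individual_niche_width <- function(whisker, isotope = c("d15N", "d13C")) {
  isotope <- match.arg(isotope)
  v <- whisker[[isotope]]
  if (length(v) < 2) {
    stop("need >= 2 segments to estimate individual niche width", call. = FALSE)
  }
  stats::var(v)
}

#' Specialization index
#'
#' `SI = INW / (INW + BINW)`, the fraction of the total niche width
#' (`TNW = INW + BINW`) occupied by one individual: small values mean the
#' individual uses a narrow slice of the population niche.
#'
#' @param inw Individual (within-whisker) niche width, >= 0.
#' @param binw Between-individual niche width, >= 0; `inw + binw > 0`.
#' @return SI in `[0, 1]`.
#' @export
specialization_index <- function(inw, binw) {
  stopifnot(is.numeric(inw), is.numeric(binw))
  if (any(inw < 0) || any(binw < 0)) {
    stop("niche widths must be non-negative", call. = FALSE)
  }
  if (any(inw + binw == 0)) {
    stop("SI undefined when both niche widths are zero", call. = FALSE)
  }
  inw / (inw + binw)
}

#' Classify a specialization index
#'
#' Specialist for `SI < 0.3`, Generalist for `SI > 0.5`, Intermediate for
#' `0.3 <= SI <= 0.5` (boundary values are Intermediate).
#'
#' @param si SI value(s) in `[0, 1]`.
#' @return Factor with levels Specialist, Intermediate, Generalist.
#' @export
classify_si <- function(si) {
  if (any(!is.finite(si)) || any(si < 0) || any(si > 1)) {
    stop("si must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(si < 0.3, "Specialist", ifelse(si > 0.5, "Generalist",
                                               "Intermediate"))
  factor(out, levels = c("Specialist", "Intermediate", "Generalist"))
}

#' Per-whisker specialization table
#'
#' Computes INW, BINW, SI and the category for every whisker in a segment
#' table. For each isotope, BINW is the sample variance of the whisker mean
#' values across all whiskers (the focal whisker included); INW is each
#' whisker's within-segment variance.
#'
#' @param segments A validated segment data frame.
#' @param isotope `"d15N"` or `"d13C"`.
#' @return A data frame with one row per whisker: `whisker_id`, `animal_id`,
#'   `isotope`, `n_segments`, `mean`, `inw`, `binw`, `si`, `category`.
#' @export
specialization_table <- function(segments, isotope = c("d15N", "d13C")) {
  isotope <- match.arg(isotope)
  parts <- split(segments, segments$whisker_id)
  means <- vapply(parts, function(w) mean(w[[isotope]]), numeric(1))
  if (length(parts) < 2) stop("need >= 2 whiskers", call. = FALSE)
  binw <- stats::var(means)
  inw <- vapply(parts, individual_niche_width, numeric(1), isotope = isotope)
  si <- specialization_index(inw, rep(binw, length(inw)))
  data.frame(whisker_id = names(parts),
             animal_id = vapply(parts, function(w) as.character(w$animal_id[1]),
                                character(1)),
             isotope = isotope,
             n_segments = vapply(parts, nrow, integer(1)),
             mean = means, inw = inw, binw = binw, si = si,
             category = classify_si(si),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dunn cluster-validity index
#'
#' Ratio of the minimum between-cluster pairwise distance to the maximum
#' within-cluster diameter (Euclidean); large values indicate compact,
#' well-separated clusters. If every cluster has zero diameter the index is
#' `Inf` (flagged via attribute `degenerate`).
#'
#' @param values Numeric vector or matrix (rows = items).
#' @param labels Cluster labels, >= 2 non-empty clusters.
#' @return The Dunn index (scalar).
#' @export
dunn_index <- function(values, labels) {
  x <- as.matrix(values)
  labels <- as.vector(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("need at least 2 clusters", call. = FALSE)
  }
  d <- as.matrix(stats::dist(x))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  between <- d[!same & !is.na(same)]
  within <- d[same & !is.na(same)]
  max_diam <- if (length(within)) max(within) else 0
  min_between <- min(between)
  if (max_diam == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  min_between / max_diam
}

#' Cluster specialist whiskers into trophic groups
#'
#' Agglomerative hierarchical clustering (average linkage / UPGMA, Euclidean
#' distance) of specialist whisker values (typically mean delta15N), cut at
#' each `k` in `[2, k_max]`; the `k` maximizing the Dunn index is selected
#' (ties broken toward the smallest `k`). Cluster 1 is relabelled to be the
#' group with the higher mean value (the "H", high trophic-level group).
#'
#' @param values Numeric vector of per-whisker values (>= 3 items).
#' @param k_max Largest number of clusters tried (default 6).
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @return A list of class `cluster_result`: `labels` (1 = higher-mean
#'   cluster), `k`, `dunn_by_k` (named vector), `hclust` (the tree).
#' @export
cluster_specialists <- function(values, k_max = 6, linkage = "average") {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 3) stop("need >= 3 items to cluster", call. = FALSE)
  if (k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  k_max <- min(k_max, n - 1)
  hc <- stats::hclust(stats::dist(values), method = linkage)
  ks <- 2:k_max
  dunn <- vapply(ks, function(k) {
    as.numeric(dunn_index(values, stats::cutree(hc, k)))
  }, numeric(1))
  names(dunn) <- ks
  k_best <- ks[which.max(dunn)]          # which.max takes the first maximum
  labels <- stats::cutree(hc, k_best)
  means <- tapply(values, labels, mean)
  relabel <- order(means, decreasing = TRUE)   # 1 = highest-mean cluster
  labels <- match(labels, relabel)
  structure(list(labels = labels, k = k_best, dunn_by_k = dunn, hclust = hc),
            class = "cluster_result")
}
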