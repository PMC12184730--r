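#' Fit a quadratic discriminant model to isotope data
#'
#' Gaussian classifier with class-specific means and covariances, appropriate
#' for isotope data sampled unevenly across years with unequal variances.
#' Priors are proportional to class counts. If a class covariance is
#' near-singular (condition number > 1e12), a ridge `eps * I` with
#' `eps = 1e-8 * trace(sigma)/2` is added (and recorded).
#'
#' @param points Two-column matrix or data frame of (delta13C, delta15N).
#' @param labels Class labels (e.g., sampling years), one per row; every class
#'   needs >= 3 points.
#' @return A list of class `qda_model`: `classes`, `mu` (list of 2-vectors),
#'   `sigma` (list of 2x2), `prior`, `ridged` (logical per class).
#' @export
fit_qda <- function(points, labels) {
  x <- as.matrix(points)
  stopifnot(ncol(x) == 2, nrow(x) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 3)) {
    stop("class '", names(counts)[which(counts < 3)[1]],
         "' has fewer than 3 points", call. = FALSE)
  }
  mu <- sigma <- vector("list", length(classes))
  ridged <- logical(length(classes))
  names(mu) <- names(sigma) <- names(ridged) <- classes
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    mu[[cl]] <- colMeans(xi)
    s <- stats::cov(xi)
    if (kappa(s, exact = TRUE) > 1e12) {
      s <- s + diag(2) * (1e-8 * sum(diag(s)) / 2)
      ridged[cl] <- TRUE
    }
    sigma[[cl]] <- s
  }
  structure(list(classes = classes, mu = mu, sigma = sigma,
                 prior = as.numeric(counts[classes]) / nrow(x),
                 ridged = ridged),
            class = "qda_model")
}

#' Predict classes and posteriors from a fitted QDA model
#'
#' Assigns each point to the class maximizing the quadratic discriminant score
#' `-0.5 log det(sigma_k) - 0.5 (x - mu_k)' sigma_k^{-1} (x - mu_k) +
#' log prior_k`; posteriors are the normalized class likelihoods.
#'
#' @param model A [fit_qda()] result.
#' @param points Two-column matrix or data frame.
#' @return A list: `labels` (character), `posterior` (matrix, one column per
#'   class), `scores` (discriminant scores).
#' @export
predict_qda <- function(model, points) {
  stopifnot(inherits(model, "qda_model"))
  x <- as.matrix(points)
  stopifnot(ncol(x) == 2)
  k <- length(model$classes)
  scores <- matrix(NA_real_, nrow(x), k, dimnames = list(NULL, model$classes))
  for (i in seq_len(k)) {
    s <- model$sigma[[i]]
    si <- solve(s)
    cent <- sweep(x, 2, model$mu[[i]])
    maha <- rowSums((cent %*% si) * cent)
    scores[, i] <- -0.5 * log(det(s)) - 0.5 * maha + log(model$prior[i])
  }
  # softmax with max subtraction for stability
  m <- apply(scores, 1, max)
  post <- exp(scores - m)
  post <- post / rowSums(post)
  list(labels = model$classes[max.col(scores, ties.method = "first")],
       posterior = post, scores = scores)
}

#' Resubstitution (or leave-one-out) year-assignment accuracy
#'
#' Fits a QDA to labelled isotope points and evaluates assignment accuracy.
#' Under the study's rule, assignment is "successful" only if the percent
#' correct strictly exceeds 70; at or below 70% the years are considered too
#' isotopically similar to distinguish.
#'
#' @param points Two-column matrix of (delta13C, delta15N).
#' @param labels Year labels.
#' @param loocv If `TRUE`, use leave-one-out cross-validation instead of
#'   resubstitution (the default).
#' @return A list of class `assignment_result`: `confusion` (true x predicted
#'   counts), `percent_correct`, `per_class_percent`, `successful`.
#' @export
assign_years <- function(points, labels, loocv = FALSE) {
  x <- as.matrix(points)
  labels <- as.character(labels)
  if (loocv) {
    pred <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
      m <- fit_qda(x[-i, , drop = FALSE], labels[-i])
      pred[i] <- predict_qda(m, x[i, , drop = FALSE])$labels
    }
  } else {
    model <- fit_qda(x, labels)
    pred <- predict_qda(model, x)$labels
  }
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, classes), factor(pred, classes))
  pc <- 100 * sum(diag(confusion)) / sum(confusion)
  per_class <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, percent_correct = pc,
                 per_class_percent = per_class,
                 successful = assignment_success(pc)),
            class = "assignment_result")
}

#' The <=70 percent success rule
#'
#' @param percent_correct Overall percent of points assigned to the correct
#'   year.
#' @return `TRUE` only if strictly greater than 70 (exactly 70% is
#'   unsuccessful).
#' @export
assignment_success <- function(percent_correct) {
  stopifnot(is.numeric(percent_correct), length(percent_correct) == 1,
            is.finite(percent_correct))
  percent_correct > 70
}

#' Between-year niche overlap for a resampled individual
#'
#' Fits a niche ellipse per sampling year for one animal's segments and
#' computes all pairwise SEAc-scale overlaps. Years with fewer than 3 segments
#' are dropped with a warning.
#'
#' @param segments Segment data frame for one animal across years.
#' @param m Vertices for the overlap polygons.
#' @return A list of class `between_year_overlap`: `years`, `overlap` (matrix
#'   of pairwise `prop_union`), `mean_overlap`, `range_overlap`, `ellipses`.
#' @export
between_year_overlap <- function(segments, m = 1024) {
  parts <- split(segments, segments$sampling_year)
  small <- names(parts)[vapply(parts, nrow, integer(1)) < 3]
  if (length(small)) {
    warning("dropping year(s) with < 3 segments: ",
            paste(small, collapse = ", "))
    parts <- parts[!names(parts) %in% small]
  }
  if (length(parts) < 2) stop("need >= 2 usable years", call. = FALSE)
  ell <- lapply(parts, function(p) fit_standard_ellipse(p[, c("d13C", "d15N")]))
  years <- names(parts)
  ov <- matrix(1, length(years), length(years), dimnames = list(years, years))
  pair <- utils::combn(length(years), 2)
  vals <- numeric(ncol(pair))
  for (j in seq_len(ncol(pair))) {
    i1 <- pair[1, j]; i2 <- pair[2, j]
    vals[j] <- ellipse_overlap(ell[[i1]], ell[[i2]], m = m)$prop_union
    ov[i1, i2] <- ov[i2, i1] <- vals[j]
  }
  structure(list(years = years, overlap = ov, mean_overlap = mean(vals),
                 range_overlap = range(vals), ellipses = ell),
            class = "between_year_overlap")
}
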