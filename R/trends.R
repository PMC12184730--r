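# Penalized additive model of d15N over time: cyclic month smooth + year
# smooth + per-individual ridge-penalized intercepts, with GCV-selected
# smoothing parameters. The spline machinery below is the value-at-knot
# parameterization of cubic regression splines: a spline is parameterized by
# its values at the knots, second derivatives at the knots follow from the
# banded system B m = D beta, and the curvature penalty is D' B^{-1} D.

#' Cyclic cubic regression spline basis
#'
#' Builds a `k`-dimensional cyclic cubic regression spline basis on
#' `[0, period)` with evenly spaced knots, parameterized by the spline's values
#' at the knots (the value at `period` wraps to the value at 0, with matching
#' first and second derivatives). The returned penalty matrix penalizes
#' integrated squared second derivative; constants lie in its null space.
#'
#' @param x Covariate values; values outside `[0, period)` are wrapped with a
#'   warning.
#' @param k Basis dimension, >= 4.
#' @param period Length of the cycle (12 for calendar months).
#' @return A list of class `spline_basis`: `X` (design matrix, n x k), `S`
#'   (k x k penalty), `knots`, `type = "cyclic"`, and internals used by
#'   [basis_eval()].
#' @export
build_month_basis <- function(x, k = 10, period = 12) {
  if (k < 4) stop("k must be >= 4", call. = FALSE)
  if (any(x < 0 | x >= period)) {
    warning("month values outside [0, ", period, ") wrapped into range")
    x <- x %% period
  }
  knots <- seq(0, period, length.out = k + 1)   # knot k+1 wraps to knot 1
  h <- diff(knots)                              # k interval widths
  idx <- function(i) ((i - 1) %% k) + 1         # cyclic index
  B <- D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    hm <- h[idx(i - 1)]; hp <- h[i]
    D[i, idx(i - 1)] <- D[i, idx(i - 1)] + 1 / hm
    D[i, i] <- D[i, i] - (1 / hm + 1 / hp)
    D[i, idx(i + 1)] <- D[i, idx(i + 1)] + 1 / hp
    B[i, idx(i - 1)] <- B[i, idx(i - 1)] + hm / 6
    B[i, i] <- B[i, i] + (hm + hp) / 3
    B[i, idx(i + 1)] <- B[i, idx(i + 1)] + hp / 6
  }
  Binv <- solve(B)
  F_mat <- Binv %*% D                           # second derivatives = F beta
  S <- t(D) %*% Binv %*% D
  S <- (S + t(S)) / 2
  basis <- structure(list(knots = knots, h = h, F_mat = F_mat, S = S, k = k,
                          type = "cyclic", period = period),
                     class = "spline_basis")
  basis$X <- basis_eval(basis, x)
  basis
}

#' Cubic regression spline basis with curvature penalty
#'
#' Builds a `k`-dimensional natural cubic regression spline basis with evenly
#' spaced knots over the observed range, parameterized by values at the knots.
#' Linear functions lie in the penalty null space. If the data have fewer than
#' `k` distinct values, `k` is reduced accordingly.
#'
#' @param x Covariate values (e.g., fractional years); >= 3 distinct values.
#' @param k Basis dimension, >= 3.
#' @param range Optional knot range (default `range(x)`).
#' @return A `spline_basis` list as in [build_month_basis()], with
#'   `type = "natural"`.
#' @export
build_year_basis <- function(x, k = 10, range = NULL) {
  ux <- sort(unique(x))
  if (length(ux) < 3) stop("need >= 3 distinct values", call. = FALSE)
  k <- max(3, min(k, length(ux)))
  if (is.null(range)) range <- range(x)
  if (diff(range) <= 0) stop("degenerate (constant) covariate", call. = FALSE)
  knots <- seq(range[1], range[2], length.out = k)
  h <- diff(knots)                              # k - 1 widths
  B <- matrix(0, k - 2, k - 2)
  D <- matrix(0, k - 2, k)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -(1 / h[i] + 1 / h[i + 1])
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i > 1) B[i, i - 1] <- h[i] / 6
    if (i < k - 2) B[i, i + 1] <- h[i + 1] / 6
  }
  Binv <- solve(B)
  F_mat <- rbind(0, Binv %*% D, 0)              # natural ends: m_1 = m_k = 0
  S <- t(D) %*% Binv %*% D
  S <- (S + t(S)) / 2
  basis <- structure(list(knots = knots, h = h, F_mat = F_mat, S = S, k = k,
                          type = "natural"),
                     class = "spline_basis")
  basis$X <- basis_eval(basis, x)
  basis
}

#' Evaluate a spline basis at new covariate values
#'
#' @param basis A `spline_basis` from [build_month_basis()] or
#'   [build_year_basis()].
#' @param x New covariate values. Cyclic bases wrap; natural bases extrapolate
#'   linearly beyond the boundary knots.
#' @return Design matrix (length(x) x k) in the value-at-knot
#'   parameterization.
#' @export
basis_eval <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  knots <- basis$knots
  k <- basis$k
  n_int <- length(knots) - 1
  if (basis$type == "cyclic") x <- x %% basis$period
  X <- matrix(0, length(x), k)
  # map wrapped column index (cyclic: knot k+1 is knot 1)
  col_of <- function(j) if (basis$type == "cyclic") ((j - 1) %% k) + 1 else j
  j_int <- pmin(pmax(findInterval(x, knots, rightmost.closed = TRUE), 1), n_int)
  for (r in seq_along(x)) {
    j <- j_int[r]
    hj <- knots[j + 1] - knots[j]
    xr <- x[r]
    if (basis$type == "natural" && (xr < knots[1] || xr > knots[k])) {
      # linear extrapolation: value + slope continuation from boundary knot
      if (xr < knots[1]) { j <- 1; xb <- knots[1] } else { j <- n_int; xb <- knots[k] }
      hj <- knots[j + 1] - knots[j]
      # derivative at boundary of the cubic on interval j
      arow <- numeric(k); crow <- numeric(k)
      if (xb == knots[1]) {
        arow[col_of(j)] <- -1 / hj; arow[col_of(j + 1)] <- 1 / hj
        crow[col_of(j)] <- -hj / 3; crow[col_of(j + 1)] <- -hj / 6
      } else {
        arow[col_of(j)] <- -1 / hj; arow[col_of(j + 1)] <- 1 / hj
        crow[col_of(j)] <- hj / 6; crow[col_of(j + 1)] <- hj / 3
      }
      drow <- arow + as.numeric(crow %*% basis$F_mat)       # f'(boundary)
      vrow <- numeric(k); vrow[col_of(if (xb == knots[1]) 1 else k)] <- 1
      X[r, ] <- vrow + (xr - xb) * drow
      next
    }
    am <- (knots[j + 1] - xr) / hj
    ap <- (xr - knots[j]) / hj
    cm <- ((knots[j + 1] - xr)^3 / hj - hj * (knots[j + 1] - xr)) / 6
    cp <- ((xr - knots[j])^3 / hj - hj * (xr - knots[j])) / 6
    arow <- numeric(k); crow <- numeric(k)
    arow[col_of(j)] <- arow[col_of(j)] + am
    arow[col_of(j + 1)] <- arow[col_of(j + 1)] + ap
    crow[col_of(j)] <- crow[col_of(j)] + cm
    crow[col_of(j + 1)] <- crow[col_of(j + 1)] + cp
    X[r, ] <- arow + as.numeric(crow %*% basis$F_mat)
  }
  X
}

# sum-to-zero constraint: reparameterize X -> X Z with colSums(X Z) = 0
constraint_null <- function(X) {
  C <- matrix(colSums(X), nrow = 1)
  qr_c <- qr(t(C))
  qr.Q(qr_c, complete = TRUE)[, -1, drop = FALSE]
}

#' Fit the penalized additive isotope-trend model
#'
#' Fits `y ~ intercept + f_month(month) + f_year(year) + b[individual]` by
#' penalized least squares: the month term is a cyclic cubic regression spline
#' (default `k = 10`), the year term a cubic regression spline (default
#' `k = 10`), and the individual term a ridge-penalized set of indicator
#' columns (the random-intercept equivalent). Each smooth carries a
#' sum-to-zero constraint. Smoothing parameters are chosen by generalized
#' cross-validation on a log-spaced grid, coordinate-wise with two passes.
#' The coefficient covariance is the frequentist sandwich
#' `sigma^2 (X'X + S)^{-1} X'X (X'X + S)^{-1}`.
#'
#' @param data Data frame with numeric `month` (in `[0, 12)`), `year`
#'   (fractional years), a response column, and `animal_id`.
#' @param response Name of the response column (default `"d15N"`).
#' @param month_k,year_k Basis dimensions.
#' @param lambda_grid Candidate smoothing parameters (default
#'   `10^seq(-5, 9, length.out = 21)`).
#' @param n_passes Coordinate-descent passes over the three penalties.
#' @return An object of class `additive_fit` with coefficients, covariance,
#'   per-term effective degrees of freedom (`edf`), selected `lambda`s,
#'   `fitted`, `rss`, `sigma2`, `gcv`, and the basis/constraint objects needed
#'   for prediction.
#' @export
fit_additive_model <- function(data, response = "d15N", month_k = 10,
                               year_k = 10,
                               lambda_grid = 10^seq(-5, 9, length.out = 21),
                               n_passes = 2) {
  stopifnot(is.data.frame(data),
            all(c("month", "year", response, "animal_id") %in% names(data)))
  y <- data[[response]]
  n <- length(y)
  ids <- factor(data$animal_id)
  if (nlevels(ids) < 2) stop("need >= 2 individuals", call. = FALSE)

  mb <- build_month_basis(data$month, k = month_k)
  yb <- build_year_basis(data$year, k = year_k)
  Zm <- constraint_null(mb$X)
  Zy <- constraint_null(yb$X)
  Xm <- mb$X %*% Zm; Sm <- t(Zm) %*% mb$S %*% Zm
  Xy <- yb$X %*% Zy; Sy <- t(Zy) %*% yb$S %*% Zy
  Xid <- stats::model.matrix(~ ids - 1)
  X <- cbind(1, Xm, Xy, Xid)
  p <- ncol(X)
  blocks <- list(month = 1 + seq_len(ncol(Xm)),
                 year = 1 + ncol(Xm) + seq_len(ncol(Xy)),
                 individual = 1 + ncol(Xm) + ncol(Xy) + seq_len(ncol(Xid)))
  S_list <- list(month = Sm, year = Sy, individual = diag(ncol(Xid)))
  embed <- function(S_small, cols) {
    S <- matrix(0, p, p); S[cols, cols] <- S_small; S
  }
  S_full <- Map(embed, S_list, blocks)
  # scale-normalize penalties so one lambda grid serves all terms
  xtx <- crossprod(X)
  for (nm in names(S_full)) {
    sc <- sum(diag(xtx[blocks[[nm]], blocks[[nm]], drop = FALSE])) /
      sum(diag(S_full[[nm]])[blocks[[nm]]])
    S_full[[nm]] <- S_full[[nm]][, , drop = FALSE] * sc
  }
  xty <- crossprod(X, y)
  yty <- sum(y^2)

  # an exactly constant response carries no information for any term: GCV
  # differences are pure floating-point noise, so return the intercept-only
  # fit directly
  if (all(y == y[1])) {
    beta <- c(y[1], rep(0, p - 1))
    zero <- matrix(0, p, p)
    return(structure(list(coefficients = beta, coef_covariance = zero,
                          coef_covariance_bayes = zero,
                          lambda = stats::setNames(rep(max(lambda_grid), 3),
                                                   names(blocks)),
                          edf = stats::setNames(rep(0, 3), names(blocks)),
                          edf_total = 1,
                          fitted = rep(y[1], n), rss = 0, sigma2 = 0, gcv = 0,
                          month_basis = mb, year_basis = yb, Zm = Zm, Zy = Zy,
                          blocks = blocks, id_levels = levels(ids),
                          response = response, n = n,
                          year_range = range(data$year)),
                     class = "additive_fit"))
  }

  gcv_of <- function(lams) {
    A <- xtx + lams[1] * S_full[[1]] + lams[2] * S_full[[2]] +
      lams[3] * S_full[[3]]
    Ainv_xtx <- tryCatch(solve(A, xtx), error = function(e) NULL)
    if (is.null(Ainv_xtx)) return(list(gcv = Inf))
    beta <- solve(A, xty)
    edf <- sum(diag(Ainv_xtx))
    rss <- yty - 2 * sum(beta * xty) + sum(beta * (xtx %*% beta))
    rss <- max(rss, 0)
    denom <- max(n - edf, 1e-8)
    list(gcv = n * rss / denom^2, beta = beta, edf = edf, rss = rss, A = A,
         Ainv_xtx = Ainv_xtx)
  }

  lams <- rep(1, 3)
  for (pass in seq_len(n_passes)) {
    for (j in 1:3) {
      scores <- vapply(lambda_grid, function(l) {
        lt <- lams; lt[j] <- l; gcv_of(lt)$gcv
      }, numeric(1))
      lams[j] <- lambda_grid[which.min(scores)]
    }
  }
  best <- gcv_of(lams)
  beta <- drop(best$beta)
  Ainv <- solve(best$A)
  sigma2 <- best$rss / max(n - best$edf, 1e-8)
  V <- sigma2 * Ainv %*% xtx %*% Ainv     # frequentist sandwich
  Vb <- sigma2 * Ainv                     # smoothing-bias-aware (for intervals)
  edf_term <- vapply(blocks, function(cols) {
    sum(diag(best$Ainv_xtx)[cols])
  }, numeric(1))
  fitted <- unname(drop(X %*% beta))

  structure(list(coefficients = beta, coef_covariance = V,
                 coef_covariance_bayes = Vb,
                 lambda = stats::setNames(lams, names(blocks)),
                 edf = edf_term, edf_total = best$edf,
                 fitted = fitted, rss = best$rss, sigma2 = sigma2,
                 gcv = best$gcv,
                 month_basis = mb, year_basis = yb, Zm = Zm, Zy = Zy,
                 blocks = blocks, id_levels = levels(ids),
                 response = response, n = n,
                 year_range = range(data$year)),
            class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("Penalized additive fit:", x$n, "observations,",
      length(x$id_levels), "individuals\n")
  cat(sprintf("  edf: month %.2f, year %.2f, individuals %.2f (total %.2f)\n",
              x$edf["month"], x$edf["year"], x$edf["individual"], x$edf_total))
  cat(sprintf("  rss %.4f, sigma2 %.4f, GCV %.4f\n", x$rss, x$sigma2, x$gcv))
  invisible(x)
}

# design rows for new (month, year) with individual effects at their zero mean
design_rows <- function(fit, month, year, terms = c("intercept", "month", "year")) {
  n <- max(length(month), length(year))
  month <- rep_len(month, n); year <- rep_len(year, n)
  p <- length(fit$coefficients)
  X <- matrix(0, n, p)
  if ("intercept" %in% terms) X[, 1] <- 1
  if ("month" %in% terms) {
    X[, fit$blocks$month] <- basis_eval(fit$month_basis, month) %*% fit$Zm
  }
  if ("year" %in% terms) {
    X[, fit$blocks$year] <- basis_eval(fit$year_basis, year) %*% fit$Zy
  }
  X
}

#' Predict on a homogeneous month-by-year grid
#'
#' Conditional expectations of the response on a regular lattice, averaging
#' over individuals (the ridge-penalized individual effects are set to their
#' zero mean), with pointwise standard errors propagated from the coefficient
#' covariance.
#'
#' @param fit An [fit_additive_model()] result.
#' @param grid Optional data frame with `month` and `year` columns; by default
#'   a monthly-resolution lattice spanning the observed year range.
#' @return `grid` with added `fit` and `se` columns.
#' @export
predict_grid <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "additive_fit"))
  if (is.null(grid)) {
    yr <- seq(fit$year_range[1], fit$year_range[2], by = 1 / 12)
    grid <- data.frame(year = yr, month = (yr %% 1) * 12)
  }
  if (any(grid$year < fit$year_range[1] - 1e-9 |
          grid$year > fit$year_range[2] + 1e-9)) {
    warning("grid extends beyond the observed year range; extrapolating")
  }
  X <- design_rows(fit, grid$month, grid$year)
  grid$fit <- drop(X %*% fit$coefficients)
  grid$se <- sqrt(pmax(rowSums((X %*% fit$coef_covariance_bayes) * X), 0))
  grid
}

#' First-derivative significance windows of the year trend
#'
#' Central finite differences of the fitted year-trend component on an ordered
#' grid give the instantaneous slope (per mil per year); confidence intervals
#' are propagated through the (linear) difference operator. Windows are the
#' maximal runs of grid points whose interval excludes zero, each with its
#' direction and mean slope (and a CI on that mean slope). With
#' `interval = "pointwise"` (the default) each grid point carries an
#' unadjusted interval; `interval = "simultaneous"` replaces the normal
#' quantile with a max-statistic critical value estimated by parametric
#' simulation from the coefficient posterior, controlling family-wise error
#' across the whole grid (windows then tend to be fewer and concentrated in
#' the steepest region).
#'
#' @param fit An [fit_additive_model()] result.
#' @param grid Optional data frame with `year` (and `month`, ignored for the
#'   year-trend derivative); default monthly lattice over the observed span.
#' @param level Confidence level (default 0.95).
#' @param interval `"pointwise"` (default) or `"simultaneous"`.
#' @param n_draws Coefficient draws used for the simultaneous critical value.
#' @return A list of class `derivative_windows`: `grid` (year, derivative,
#'   ci_low, ci_high, significant) and `windows` (data frame with start, end,
#'   direction, mean_slope, slope_ci_low, slope_ci_high).
#' @export
derivative_windows <- function(fit, grid = NULL, level = 0.95,
                               interval = c("pointwise", "simultaneous"),
                               n_draws = 2000) {
  stopifnot(inherits(fit, "additive_fit"))
  interval <- match.arg(interval)
  if (is.null(grid)) {
    yr <- seq(fit$year_range[1], fit$year_range[2], by = 1 / 12)
    grid <- data.frame(year = yr)
  }
  yr <- sort(grid$year)
  if (length(yr) < 3) stop("need >= 3 grid points", call. = FALSE)
  X <- design_rows(fit, month = 0, year = yr, terms = "year")
  m <- length(yr)
  i <- 2:(m - 1)
  hstep <- yr[i + 1] - yr[i - 1]
  L <- (X[i + 1, , drop = FALSE] - X[i - 1, , drop = FALSE]) / hstep
  deriv <- drop(L %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((L %*% fit$coef_covariance_bayes) * L), 0))
  z <- if (interval == "simultaneous") {
    # critical value of max_g |t_g| over the grid, by simulating coefficient
    # deviations from N(0, Vb) restricted to the year block
    cols <- fit$blocks$year
    Vy <- fit$coef_covariance_bayes[cols, cols, drop = FALSE]
    ev <- eigen(Vy, symmetric = TRUE)
    root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    draws <- matrix(stats::rnorm(n_draws * length(cols)), n_draws) %*% root
    tmat <- abs(draws %*% t(L[, cols, drop = FALSE])) /
      matrix(pmax(se, 1e-12), n_draws, length(se), byrow = TRUE)
    crit <- stats::quantile(apply(tmat, 1, max), probs = level, names = FALSE)
    # the max statistic dominates any single coordinate, so the simultaneous
    # critical value can never fall below the pointwise one; clamp away
    # Monte-Carlo undershoot
    max(crit, stats::qnorm(1 - (1 - level) / 2))
  } else stats::qnorm(1 - (1 - level) / 2)
  lo <- deriv - z * se; hi <- deriv + z * se
  sig <- lo > 0 | hi < 0
  g <- data.frame(year = yr[i], derivative = deriv, ci_low = lo, ci_high = hi,
                  significant = sig)
  windows <- data.frame(start = numeric(0), end = numeric(0),
                        direction = character(0), mean_slope = numeric(0),
                        slope_ci_low = numeric(0), slope_ci_high = numeric(0))
  r <- rle(ifelse(sig, sign(deriv), 0))
  pos <- cumsum(r$lengths)
  start_i <- c(1, utils::head(pos, -1) + 1)
  for (j in seq_along(r$values)) {
    if (r$values[j] == 0) next
    idx <- start_i[j]:pos[j]
    Lw <- colMeans(L[idx, , drop = FALSE])      # mean slope is linear in beta
    se_w <- sqrt(max(drop(t(Lw) %*% fit$coef_covariance_bayes %*% Lw), 0))
    ms <- mean(g$derivative[idx])
    windows <- rbind(windows, data.frame(
      start = g$year[idx[1]], end = g$year[idx[length(idx)]],
      direction = if (r$values[j] > 0) "increase" else "decrease",
      mean_slope = ms, slope_ci_low = ms - z * se_w,
      slope_ci_high = ms + z * se_w))
  }
  structure(list(grid = g, windows = windows, level = level),
            class = "derivative_windows")
}
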