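# shared small simulated dataset builders
sim_trend_data <- function(seed, f_year = function(yr) 0,
                           f_month = function(m) 0,
                           n_id = 6, sd_id = 0.4, sd_eps = 0.3,
                           years = 2013:2022) {
  set.seed(seed)
  yr <- rep(seq(min(years), max(years) + 11 / 12, by = 1 / 12), times = n_id)
  id <- rep(sprintf("I%02d", seq_len(n_id)), each = length(yr) / n_id)
  b <- rep(rnorm(n_id, 0, sd_id), each = length(yr) / n_id)
  m <- (yr %% 1) * 12
  data.frame(d15N = 11 + b + f_year(yr) + f_month(m) + rnorm(length(yr), 0, sd_eps),
             year = yr, month = m, animal_id = id)
}

test_that("the cyclic month basis is periodic in value and derivatives", {
  mb <- build_month_basis(seq(0, 11.9, by = 0.1), k = 10)
  set.seed(1)
  beta <- rnorm(10)
  f <- function(x) drop(basis_eval(mb, x) %*% beta)
  eps <- 1e-4
  # value, first and second derivative continuity across the period boundary
  expect_equal(f(0), f(12 - 1e-12), tolerance = 1e-6)
  d_left <- (f(12 - eps) - f(12 - 2 * eps)) / eps
  d_right <- (f(2 * eps) - f(eps)) / eps
  expect_equal(d_left, d_right, tolerance = 1e-2)
  dd_left <- (f(12 - eps) - 2 * f(12 - 2 * eps) + f(12 - 3 * eps)) / eps^2
  dd_right <- (f(3 * eps) - 2 * f(2 * eps) + f(eps)) / eps^2
  expect_equal(dd_left, dd_right, tolerance = 1e-1)
})

test_that("penalty null spaces hold constants (cyclic) and linears (natural)", {
  mb <- build_month_basis(seq(0, 11.5, by = 0.5), k = 8)
  expect_equal(max(abs(mb$S %*% rep(1, 8))), 0, tolerance = 1e-10)

  yb <- build_year_basis(seq(2013, 2022, by = 0.25), k = 8)
  expect_equal(max(abs(yb$S %*% rep(1, 8))), 0, tolerance = 1e-10)
  expect_equal(max(abs(yb$S %*% yb$knots)), 0, tolerance = 1e-8)
  # a quadratic is penalized
  expect_gt(max(abs(yb$S %*% yb$knots^2)), 1e-6)
})

test_that("spline bases interpolate their own knot values", {
  yb <- build_year_basis(seq(2013, 2022, length.out = 40), k = 7)
  X_at_knots <- basis_eval(yb, yb$knots)
  expect_equal(X_at_knots, diag(7), tolerance = 1e-10, ignore_attr = TRUE)
  mb <- build_month_basis(seq(0, 11, by = 1), k = 6)
  X_mk <- basis_eval(mb, mb$knots[1:6])
  expect_equal(X_mk, diag(6), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("basis construction rejects degenerate inputs", {
  expect_error(build_month_basis(1:5, k = 3), ">= 4")
  expect_warning(build_month_basis(c(3, 13), k = 4), "wrapped")
  expect_error(build_year_basis(c(1, 1, 1), k = 5), "distinct")
})

test_that("a constant response yields an intercept-only fit with no windows", {
  dat <- sim_trend_data(3, sd_id = 0, sd_eps = 0)
  dat$d15N <- 11.46
  fit <- fit_additive_model(dat)
  expect_equal(unname(fit$edf["month"]), 0, tolerance = 1e-4)
  expect_equal(unname(fit$edf["year"]), 0, tolerance = 1e-4)
  expect_equal(fit$fitted, rep(11.46, nrow(dat)), tolerance = 1e-8)
  dw <- derivative_windows(fit)
  expect_equal(max(abs(dw$grid$derivative)), 0, tolerance = 1e-8)
  expect_equal(nrow(dw$windows), 0)
})

test_that("a linear year trend is recovered with a flat derivative near the true slope", {
  dat <- sim_trend_data(4, f_year = function(yr) 0.5 * (yr - 2013),
                        sd_eps = 0.1)
  fit <- fit_additive_model(dat)
  dw <- derivative_windows(fit)
  expect_true(all(abs(dw$grid$derivative - 0.5) < 0.05))
  # the derivative is constant across the grid to a tight relative band
  expect_lt(diff(range(dw$grid$derivative)) / mean(dw$grid$derivative), 0.05)
  # detected as increase over (essentially) the whole span
  inc <- dw$windows[dw$windows$direction == "increase", ]
  expect_gte(nrow(inc), 1)
  expect_gt(sum(inc$end - inc$start), 0.8 * diff(fit$year_range))
})

test_that("month and year signals separate into their own smooth terms", {
  dat <- sim_trend_data(5, f_month = function(m) sin(2 * pi * m / 12),
                        sd_eps = 0.1)
  fit <- fit_additive_model(dat)
  X_month <- whiskerniche:::design_rows(fit, month = dat$month, year = 0,
                                        terms = "month")
  month_part <- drop(X_month %*% fit$coefficients)
  truth <- sin(2 * pi * dat$month / 12)
  r2 <- 1 - sum((month_part - truth)^2) / sum((truth - mean(truth))^2)
  expect_gt(r2, 0.9)
  dw <- derivative_windows(fit)
  expect_true(all(abs(dw$grid$derivative) < 0.05))
})

test_that("month-term predictions are periodic at fixed year", {
  dat <- sim_trend_data(6, f_month = function(m) cos(2 * pi * m / 12))
  fit <- fit_additive_model(dat)
  g0 <- predict_grid(fit, data.frame(year = 2015.5, month = 0))
  g12 <- predict_grid(fit, data.frame(year = 2015.5, month = 12 - 1e-9))
  expect_equal(g0$fit, g12$fit, tolerance = 1e-6)
})

test_that("the penalized fit interpolates harder as lambda shrinks and flattens as it grows", {
  dat <- sim_trend_data(7, f_year = function(yr) sin(yr - 2013), sd_eps = 0.3)
  fit_small <- fit_additive_model(dat, lambda_grid = 1e-8)
  fit_large <- fit_additive_model(dat, lambda_grid = 1e8)
  expect_lt(fit_small$rss, fit_large$rss)
  # at huge smoothing the cyclic term dies and the year term keeps only
  # its linear null space
  expect_lt(unname(fit_large$edf["month"]), 0.05)
  expect_lt(unname(fit_large$edf["year"]), 1.05)
  expect_lt(unname(fit_large$edf["individual"]), 0.5)
  # at tiny smoothing the terms use most of their basis dimensions
  expect_gt(fit_small$edf_total, fit_large$edf_total)
})

test_that("individual effects shrink monotonically with the shared penalty", {
  dat <- sim_trend_data(8, sd_id = 1)
  spread <- sapply(c(1e-4, 1, 1e4), function(l) {
    fit <- fit_additive_model(dat, lambda_grid = l)
    var(fit$coefficients[fit$blocks$individual])
  })
  expect_true(all(diff(spread) < 0))
})

test_that("the coefficient covariances are symmetric positive semi-definite", {
  dat <- sim_trend_data(9, f_year = function(yr) 0.2 * (yr - 2013))
  fit <- fit_additive_model(dat)
  for (V in list(fit$coef_covariance, fit$coef_covariance_bayes)) {
    expect_equal(V, t(V), tolerance = 1e-8)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  expect_true(all(fit$edf >= 0))
  expect_lte(unname(fit$edf["month"]), 10)
  expect_lte(unname(fit$edf["year"]), 10)
})

test_that("the fit agrees with an established GAM implementation", {
  dat <- sim_trend_data(10, f_year = function(yr) sin((yr - 2013) / 2),
                        f_month = function(m) 0.5 * sin(2 * pi * m / 12),
                        sd_eps = 0.3)
  fit <- fit_additive_model(dat)
  ref <- mgcv::gam(d15N ~ s(month, bs = "cc", k = 10) + s(year, k = 10) +
                     s(animal_id, bs = "re"),
                   data = transform(dat, animal_id = factor(animal_id)),
                   knots = list(month = seq(0, 12, length.out = 10)))
  expect_lt(sqrt(mean((fit$fitted - fitted(ref))^2)), 0.1)
  expect_gt(cor(fit$fitted, fitted(ref)), 0.99)
})

test_that("prediction grids carry standard errors and flag extrapolation", {
  dat <- sim_trend_data(11)
  fit <- fit_additive_model(dat)
  g <- predict_grid(fit)
  expect_true(all(c("year", "month", "fit", "se") %in% names(g)))
  expect_true(all(g$se > 0))
  expect_warning(predict_grid(fit, data.frame(year = 2030, month = 3)),
                 "extrapolating")
})

test_that("derivative windows validate their grid and respect interval widening", {
  dat <- sim_trend_data(12, f_year = function(yr) 0.5 * (yr - 2013),
                        sd_eps = 0.1)
  fit <- fit_additive_model(dat)
  expect_error(derivative_windows(fit, grid = data.frame(year = c(2014, 2015))),
               ">= 3 grid points")
  dw_p <- derivative_windows(fit)
  dw_s <- derivative_windows(fit, interval = "simultaneous")
  # simultaneous bands are at least as wide as pointwise bands
  expect_true(all(dw_s$grid$ci_high - dw_s$grid$ci_low >=
                    dw_p$grid$ci_high - dw_p$grid$ci_low - 1e-12))
  expect_equal(dw_s$grid$derivative, dw_p$grid$derivative)
  # window directions match derivative signs
  for (dw in list(dw_p, dw_s)) {
    if (nrow(dw$windows)) {
      for (j in seq_len(nrow(dw$windows))) {
        sel <- dw$grid$year >= dw$windows$start[j] &
          dw$grid$year <= dw$windows$end[j]
        expect_true(all(sign(dw$grid$derivative[sel]) ==
                          ifelse(dw$windows$direction[j] == "increase", 1, -1)))
      }
    }
  }
})
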