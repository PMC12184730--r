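test_that("the generator is deterministic given its seed", {
  a <- simulate_population(sim_config(seed = 99))
  b <- simulate_population(sim_config(seed = 99))
  c <- simulate_population(sim_config(seed = 100))
  expect_identical(a$segments, b$segments)
  expect_identical(a$truth$whiskers, b$truth$whiskers)
  expect_false(identical(a$segments$d15N, c$segments$d15N))
})

test_that("generated segment tables satisfy every schema invariant", {
  pop <- simulate_population(sim_config(seed = 2))
  seg <- pop$segments
  expect_silent(validate_segments(seg))
  expect_equal(length(unique(seg$whisker_id)), 46)
  expect_equal(length(unique(seg$animal_id)), 34)
  lens <- seg$end_mm - seg$start_mm
  # lengths are in the configured band except a merged final remainder,
  # which is bounded by min + max segment length
  expect_true(all(lens >= 0.5 - 1e-9))
  expect_true(all(lens <= 3.5 + 1e-9))
  expect_true(all(seg$sex %in% c("F", "M")))
  expect_true(all(seg$sampling_year %in% 2013:2023))
})

test_that("whisker sectioning tiles the whisker exactly", {
  set.seed(20)
  for (L in c(5, 23.7, 80)) {
    secs <- section_whisker(L)
    expect_equal(secs$start_mm[1], 0)
    expect_equal(secs$end_mm[nrow(secs)], L)
    expect_equal(secs$start_mm[-1], secs$end_mm[-nrow(secs)])
    expect_true(all(secs$end_mm > secs$start_mm))
  }
  expect_error(section_whisker(0.3), "total_length_mm > lo")
})

test_that("the piecewise-linear trend is exact at knots and zero outside support", {
  tr <- list(knots = c(2015, 2017.5), values = c(0, -2))
  expect_equal(inject_trend(c(2015, 2017.5), tr), c(0, -2))
  expect_equal(inject_trend(2016.25, tr), -1)
  expect_equal(inject_trend(c(2013, 2020), tr), c(0, 0))
  expect_equal(inject_trend(2016, NULL), 0)
  expect_error(inject_trend(2016, list(knots = c(2017, 2015), values = c(0, 1))),
               "strictly increasing")
})

test_that("whisker lengths and spans follow the configured growth curve", {
  cfg <- sim_config(seed = 3)
  pop <- simulate_population(cfg)
  wh <- pop$truth$whiskers
  expect_equal(wh$length_mm, vb_length(wh$span_days, cfg$growth))
  expect_true(all(wh$span_days >= 20 & wh$span_days <= 290))
  counts <- table(pop$segments$whisker_id)
  expect_equal(as.integer(counts[wh$whisker_id]), wh$n_segments)
})

test_that("segment formation dates precede collection and respect ordering", {
  pop <- simulate_population(sim_config(seed = 4))
  seg <- pop$segments
  for (w in split(seg, seg$whisker_id)) {
    yr_col <- as.numeric(format(w$collection_date[1], "%Y")) +
      (as.numeric(format(w$collection_date[1], "%j")) - 1) / 365.25
    expect_true(all(w$true_date_frac <= yr_col + 1e-9))
    expect_true(all(diff(w$true_date_frac) < 0))  # older toward the tip
  }
})

test_that("class labels map to their configured specialization targets", {
  cfg <- sim_config(seed = 5)
  pop <- simulate_population(cfg)
  wh <- pop$truth$whiskers
  expect_true(all(wh$true_class %in% names(cfg$class_mix)))
  expect_equal(wh$true_si, unname(cfg$si_by_class[wh$true_class]))
})

test_that("the class mix is respected at large whisker counts", {
  cfg <- sim_config(n_individuals = 300, n_whiskers = 600, seed = 6)
  pop <- simulate_population(cfg)
  freq <- table(pop$truth$whiskers$true_class) / 600
  expect_equal(unname(freq["Specialist"]), 0.59, tolerance = 0.12)
  expect_equal(unname(freq["Intermediate"]), 0.28, tolerance = 0.25)
  expect_equal(unname(freq["Generalist"]), 0.13, tolerance = 0.4)
})

test_that("the sex effect shifts male delta15N by the configured amount", {
  cfg <- sim_config(n_individuals = 400, n_whiskers = 400, prop_male = 0.5,
                    sigma_between = diag(c(0.1, 0.1)), seed = 7)
  pop <- simulate_population(cfg)
  seg <- pop$segments
  gap <- mean(seg$d15N[seg$sex == "M"]) - mean(seg$d15N[seg$sex == "F"])
  expect_equal(gap, cfg$sex_effect, tolerance = 0.15)
})

test_that("C:N outliers appear at the configured rate and vanish at rate zero", {
  cfg <- sim_config(n_individuals = 100, n_whiskers = 150,
                    cn_outlier_rate = 0.2, seed = 8)
  seg <- simulate_population(cfg)$segments
  out_frac <- mean(seg$cn_ratio < 3 | seg$cn_ratio > 4)
  expect_equal(out_frac, 0.2, tolerance = 0.15)

  clean <- simulate_population(sim_config(cn_outlier_rate = 0, seed = 9))$segments
  expect_true(all(clean$cn_ratio >= 3 & clean$cn_ratio <= 4))
})

test_that("an injected temporal trend is visible in the raw segment values", {
  tr <- list(knots = c(2015, 2018, 2024), values = c(0, -3, -3))
  cfg <- sim_config(n_individuals = 150, n_whiskers = 300, trend = tr,
                    sigma_between = diag(c(0.05, 0.05)), seed = 10)
  seg <- simulate_population(cfg)$segments
  early <- seg$d15N[seg$true_date_frac < 2015]
  late <- seg$d15N[seg$true_date_frac > 2018 & seg$true_date_frac < 2020]
  expect_lt(mean(late) - mean(early), -2)
})

test_that("configuration errors are caught up front", {
  expect_error(sim_config(class_mix = c(Specialist = 0.5, Intermediate = 0.2,
                                        Generalist = 0.2)), "sum to 1")
  expect_error(sim_config(n_individuals = 10, n_whiskers = 5))
  expect_error(sim_config(sigma_between = matrix(c(1, 2, 2, 1), 2)), "PSD")
  expect_error(sim_config(segment_length_range = c(3, 0.5)),
               "segment_length_range")
  expect_error(sim_config(growth = growth_params(l_inf = 10, k_rate = 0.5),
                          span_range_days = c(20, 5000)), "infeasible")
})
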