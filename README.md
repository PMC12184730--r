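# whiskerniche

Quantitative machinery for studying **individual trophic specialization from
whisker stable-isotope chronologies**, modelled on a leopard seal
(*Hydrurga leptonyx*) population study at Cape Shirreff, Antarctica.

Pinniped whiskers are accretionary keratin: tissue laid down at the follicle
records the animal's diet at the time of growth, so a whisker sectioned into
0.5–3 mm segments and analysed for δ13C and δ15N yields a months-long
isotopic time series per individual. This package implements the full
analysis chain for such data:

1. **Data model, QC, and calibration** — segment-level schema with validated
   geometry, inclusive C:N 3.0–4.0 keratin quality filter, delta-notation
   arithmetic, and two-point (e.g., USGS-40/USGS-41A) affine calibration.
2. **Time-stamping** — each segment midpoint is dated by inverting a Von
   Bertalanffy growth curve anchored at the collection date
   (`L(t) = L∞(1 − e^(−kt))`, newest material at the root).
3. **Isotopic niche geometry** — maximum-likelihood standard ellipse areas
   (SEA, and the small-sample corrected SEAc = SEA·(n−1)/(n−2)), convex-hull
   total area (TA), and exact convex-polygon ellipse overlap with
   union/pairwise overlap proportions.
4. **Individual specialization** — one-way variance components split total
   niche width into within-whisker (INW) and between-individual (BINW)
   parts; the specialization index SI = INW/(INW + BINW) classifies whiskers
   as Specialist (SI < 0.3), Intermediate, or Generalist (SI > 0.5), and
   specialists are split into trophic clusters by UPGMA clustering with
   Dunn-index model selection.
5. **Between-year assignment** — quadratic discriminant analysis assigns a
   resampled individual's segments to sampling years; assignment is deemed
   successful only above 70% accuracy, and per-year niche overlap quantifies
   between-year consistency.
6. **Temporal trends** — a hand-rolled penalized additive model of δ15N with
   a cyclic cubic spline for month, a cubic regression spline for year, and
   ridge-penalized individual intercepts; GCV smoothing selection; prediction
   grids with standard errors; and first-derivative significance windows that
   localize significant increases or declines in time.
7. **Synthetic populations** — a fully deterministic (seeded) generator of
   whisker populations with known ground truth: bivariate-normal individual
   niches, class-specific within-whisker covariance derived from a target SI,
   Von Bertalanffy growth and random sectioning, sex effects, seasonal and
   multi-year injected trends, and C:N outliers. Every stochastic guarantee in
   the test suite is a parameter-recovery experiment against this generator.

The package ships a verbatim transcription of the study's whisker-level
summary table (46 whiskers, 34 seals, 2,199 segments) as
`inst/extdata/table1_whisker_summaries.csv`, so the published population
statistics can be reproduced without any download.

## Worked example

Reproduce the published population summaries from the packaged table:

```r
library(whiskerniche)

t1 <- load_table1()
summarize_weighted(t1, "population", "d15N")
#>        group n_whiskers n_segments weighted_mean  min   max
#> 1 population         46       2199      11.46071 6.49 15.21

summarize_unweighted_by_category(t1, "d15N")
#>        category n_whiskers n_segments     mean        sd   min   max
#> 1  H-Specialist         13        619 12.87154 0.4372041 10.26 15.21
#> 2 ML-Specialist         14        604 11.19143 0.5647444  8.39 13.41
#> 3  Intermediate         13        759 10.95308 1.1067775  6.95 15.17
#> 4    Generalist          6        217 10.74333 1.1499855  6.49 14.38
```

Simulate a synthetic population with an injected δ15N decline of
−0.8 ‰ yr⁻¹ over 2015–2017.5 (recovering by 2020) and push it through the
whole pipeline:

```r
cfg <- sim_config(trend = list(knots = c(2015, 2017.5, 2020),
                               values = c(0, -2, 0)),
                  seed = 7)
pop <- simulate_population(cfg)
report <- run_pipeline(pop$segments, cfg$growth)
report
#> Whisker isotope pipeline report
#>   segments: 1766 in, 1759 kept, 7 excluded by C:N QC
#>   whiskers: 46; population SEAc 3.34, TA 46.14
#>   specialization categories:
#>
#>   Specialist Intermediate   Generalist
#>           24           14            8

head(report$specialization[, c("whisker_id", "n_segments", "inw", "si",
                               "category", "cluster")])
#>   whisker_id n_segments       inw        si     category cluster
#> 1       W001         16 0.6541759 0.3842062 Intermediate      NA
#> 2       W002         28 0.8456632 0.4464591 Intermediate      NA
#> 3       W003         17 0.3273545 0.2379294   Specialist       3
#> 4       W004         17 0.2707487 0.2052306   Specialist       5
#> 5       W005         27 0.1860933 0.1507333   Specialist       6
#> 6       W006         34 2.8365791 0.7301227   Generalist      NA
```

The temporal model localizes the injected decline. Simultaneous bands
(critical value from parametric draws of the coefficients) control the
family-wise error of scanning the whole monthly grid for significant slopes:

```r
dw <- derivative_windows(report$trend$fit, interval = "simultaneous")
subset(dw$windows, direction == "decrease")
#>      start      end direction mean_slope slope_ci_low slope_ci_high
#> 1 2015.395 2016.645  decrease -0.6235205   -0.9535593    -0.2934816
```

The detected window lies inside the injected 2015–2017.5 decline and its
slope interval covers the true −0.8 ‰ yr⁻¹.

## Reproduction

Published desk-scale statistics are reproduced exactly from the packaged
table by the acceptance script:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes, per target, the computed value and the size of the sample it
is computed over — among them the mean segments per whisker (47.8), the
unweighted ML-Specialist/Intermediate/Generalist δ15N means (11.19 / 10.95 /
10.74 ‰), segment-weighted male/female/population δ15N means (9.92 / 11.71 /
11.46 ‰), the population δ13C mean (−21.93 ‰), the specialist whisker count
(27), and the maximum δ15N (15.21 ‰).

The full test suite:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "whiskerniche",
                               load_package = "installed")'
```

includes, beyond unit and property tests, stochastic acceptance experiments:
SEAc/hull/overlap checks against analytic values and rejection-sampling
oracles (within 1%), variance-component and SI recovery on simulated
populations, QDA equivalence with a Gaussian-density oracle, and recovery of
an injected −0.8 ‰ yr⁻¹ decline as a single significant window in ≥90 of 100
seeded replicates.

## Notes and caveats

- Statistical machinery (spline bases, GCV, QDA, variance components,
  ellipse geometry) is implemented from first principles in base R;
  `MASS::qda` and `mgcv::gam` appear only in the test suite as independent
  reference implementations.
- Von Bertalanffy growth parameters are study-specific inputs; the
  simulator's defaults are documented assumptions, not published estimates.
- The between-individual niche width is the variance of whisker means with
  the focal whisker included, and SI is computed per whisker (an individual
  resampled in different years can change category).
- See the vignette (`vignettes/whisker-specialization.Rmd`) for the model
  equations, numerical choices, and the generator's realism limits.
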