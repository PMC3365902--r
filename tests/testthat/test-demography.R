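test_that("ageing a survey floors continuous ages and flags censored lengths", {
  gp <- general_growth_params()
  rec <- data.frame(length_mm = c(12.8, 0.5, 15.4, 16.0, 3.0))
  aged <- assign_ages(rec, gp)
  expect_equal(aged$age_class[1:2], c(28L, 0L))
  expect_true(all(aged$censored[3:4]))
  expect_false(any(aged$censored[c(1, 2, 5)]))
  # censored individuals join the oldest finite class (floor age of 0.99 L_inf)
  expect_equal(aged$age_class[3],
               floor(vbgf_age_at_length(gp, 0.99 * 15.4)))
})

test_that("age structures count correctly and keep interior zero classes", {
  s <- structure_from_counts(c(2L, 1L, 0L, 1L))
  expect_equal(s$age, 0:3)
  expect_equal(s$observed, c(2L, 1L, 0L, 1L))
  expect_equal(sum(s$observed), s$n)
  expect_error(build_age_structure(data.frame(age_class = integer())),
               class = "pd_insufficient_data_error")
})

test_that("semi-log mortality fit is exact on exponential structures", {
  st <- exact_exponential_structure(100, 0.427, 10)
  fit <- fit_mortality(st)
  expect_equal(fit$Z, 0.427, tolerance = 1e-12)
  expect_equal(fit$N0, 100, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # flat structure convention
  flat <- structure_from_counts(c(8L, 8L, 8L, 8L))
  ffit <- fit_mortality(flat)
  expect_equal(ffit$Z, 0)
  expect_equal(ffit$r2, 0)
  expect_equal(ffit$N0, 8, tolerance = 1e-12)
  expect_error(fit_mortality(structure_from_counts(c(5L, 3L))),
               class = "pd_insufficient_data_error")
})

test_that("zero classes are excluded, not log-transformed", {
  counts <- round(100 * exp(-0.427 * (0:10)))
  counts[5] <- 0L
  st <- structure_from_counts(counts)
  fit <- fit_mortality(st)
  expect_equal(fit$n_classes, 10L)
  expect_equal(fit$Z, 0.427, tolerance = 0.05)
})

test_that("median recovered Z is within 15% under Poisson noise", {
  # catch-curve oracle: Poisson counts about 200 exp(-0.25 t), t = 0..12
  # (120 replicates keep the default run fast; the
  # median is stable well before that)
  zs <- vapply(1:120, function(s) {
    set.seed(s)
    counts <- rpois(13, 200 * exp(-0.25 * (0:12)))
    fit_mortality(structure(list(site = "x", age = 0:12, observed = counts,
                                 theoretical = NULL, n = sum(counts)),
                            class = "age_structure"))$Z
  }, numeric(1))
  expect_lt(abs(median(zs) - 0.25) / 0.25, 0.15)
})

test_that("survivorship and theoretical structure follow N0 exp(-Z t)", {
  st <- exact_exponential_structure(100, 0.427, 10)
  fit <- fit_mortality(st)
  expect_equal(survivorship(fit, 0), 100, tolerance = 1e-9)
  expect_equal(survivorship(fit, 3), 27.77594, tolerance = 1e-5)
  theo <- theoretical_structure(fit, 10)
  expect_equal(sum(theo), 285.1147, tolerance = 1e-4)  # geometric series
  ratios <- theo[-1] / theo[-length(theo)]
  expect_equal(ratios, rep(exp(-0.427), 10), tolerance = 1e-9)
  expect_equal(theoretical_structure(fit, 0), 100, tolerance = 1e-9)
  # no mortality: constant
  flat <- fit_mortality(structure_from_counts(c(8L, 8L, 8L, 8L)))
  expect_equal(survivorship(flat, c(0, 5, 50)), rep(8, 3), tolerance = 1e-12)
  expect_error(survivorship(fit, -1), class = "pd_domain_error")
})

test_that("demographic summary: maturity class, mean ages, biomass ages", {
  gp <- growth_params(8.6, 0.185)
  mm <- length_mass_model(0.0016, 2.7)
  aged <- data.frame(age_class = c(1L, 2L, 3L), mass_g = c(1, 1, 1),
                     censored = FALSE)
  st <- build_age_structure(aged, "toy")
  fit <- fit_mortality(structure_from_counts(c(4L, 2L, 1L)))  # any valid fit
  sm <- summarize_demography(st, fit, gp, mm, aged)
  # maturity at 3 mm -> continuous age 2.32 -> first mature class 3
  expect_equal(sm$maturity_class, 3L)
  expect_equal(sm$observed_mean_age, 2)
  expect_equal(sm$observed_mean_age_biomass, 2)
  # equal masses, classes 1..3: observed % immature counts classes < 3
  expect_equal(sm$observed_pct_immature, 100 * 2 / 3, tolerance = 1e-9)

  # all individuals mature
  aged2 <- data.frame(age_class = c(5L, 6L, 7L), mass_g = c(1, 2, 3),
                      censored = FALSE)
  st2 <- build_age_structure(aged2, "toy2")
  sm2 <- summarize_demography(st2, fit, gp, mm, aged2)
  expect_equal(sm2$observed_pct_immature, 0)

  # theoretical mean age of the truncated geometric with Z = 0.427 on 0..10
  st3 <- exact_exponential_structure(100, 0.427, 10)
  fit3 <- fit_mortality(st3)
  aged3 <- data.frame(age_class = rep(0:10, round(100 * exp(-0.427 * 0:10)) + 1L),
                      mass_g = 1, censored = FALSE)
  st3o <- build_age_structure(aged3, "geo")
  sm3 <- summarize_demography(st3o, fit3, general_growth_params(), mm, aged3)
  expect_equal(sm3$theoretical_mean_age, 1.776124, tolerance = 1e-4)

  # missing masses are an explicit error
  aged_na <- data.frame(age_class = c(1L, 2L), mass_g = c(1, NA), censored = FALSE)
  expect_error(
    summarize_demography(build_age_structure(aged_na, "z"), fit, gp, mm, aged_na),
    class = "pd_missing_mass_error")
})

test_that("% immature from the structure equals the individual-level value", {
  cfg <- small_config()
  pop <- simulate_population(cfg, 1L)
  aged <- assign_ages(pop$records, general_growth_params())
  st <- build_age_structure(aged, "s")
  fit <- fit_mortality(st)
  sm <- summarize_demography(st, fit, general_growth_params(),
                             length_mass_model(0.0016, 2.7), aged)
  direct <- 100 * mean(aged$age_class < sm$maturity_class)
  expect_equal(sm$observed_pct_immature, direct, tolerance = 1e-12)
})

test_that("theoretical biomass vector is unimodal on synthetic populations", {
  # mass grows allometrically while numbers decay exponentially, so the
  # theoretical biomass-at-age curve rises then falls (single interior peak)
  cfg <- simulation_config(seed = 5L)
  for (i in c(1L, 2L, 5L)) {
    pop <- simulate_population(cfg, i)
    aged <- assign_ages(pop$records, general_growth_params())
    st <- build_age_structure(aged, "s")
    fit <- fit_mortality(st)
    sm <- summarize_demography(st, fit, general_growth_params(),
                               length_mass_model(0.0016, 2.7), aged)
    b <- sm$theoretical_biomass
    peak <- which.max(b)
    expect_true(all(diff(b[seq_len(peak)]) >= 0))
    expect_true(all(diff(b[peak:length(b)]) <= 0))
    expect_gte(sm$theoretical_age_max_biomass, 1)
  }
})

test_that("stability r2 decreases as structures get noisier", {
  # noise ladder: multiplicative lognormal disturbance of an exponential
  # structure; median r2 must fall strictly along the ladder
  # (60 replicates per rung suffice for a stable median)
  rung_r2 <- vapply(c(0.1, 0.5, 1.1), function(sdl) {
    median(vapply(1:60, function(s) {
      set.seed(s)
      counts <- pmax(1, round(150 * exp(-0.3 * (0:10)) * exp(rnorm(11, 0, sdl))))
      fit_mortality(structure_from_counts(as.integer(counts)))$r2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rung_r2) < 0))
})
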