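test_that("site-level SST correlations reproduce the published coefficients", {
  ref <- reference_sites()
  cz <- pearson_with_bootstrap(ref$sst_mean_c, ref$Z,
                               n_resamples = 20000L, seed = 1L)
  expect_equal(cz$r, -0.627, tolerance = 0.002)
  expect_equal(cz$r2, 0.393, tolerance = 0.005)
  cb <- pearson_with_bootstrap(ref$sst_mean_c, ref$observed_age_max_biomass,
                               n_resamples = 20000L, seed = 2L)
  expect_equal(cb$r, 0.701, tolerance = 0.002)
  expect_equal(cb$r2, 0.492, tolerance = 0.005)
  # bootstrap estimate attenuates toward zero but keeps the sign
  expect_lt(abs(cz$r_BS), abs(cz$r))
  expect_lt(cz$r_BS, 0)
  expect_gt(cb$r_BS, 0)
})

test_that("bootstrap correlation is exact on perfect lines and reproducible", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- pearson_with_bootstrap(x, 2 * x + 1, n_resamples = 5000L, seed = 9L)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$r_BS, 1, tolerance = 1e-9)
  res2 <- pearson_with_bootstrap(x, 2 * x + 1, n_resamples = 5000L, seed = 9L)
  expect_identical(res$r_BS, res2$r_BS)
  expect_identical(res$n_degenerate_resamples, res2$n_degenerate_resamples)
  # degenerate resamples are counted, retained coefficients stay in [-1, 1]
  set.seed(4)
  y <- rnorm(6)
  r <- pearson_with_bootstrap(x, y, n_resamples = 20000L, seed = 4L)
  expect_true(abs(r$r_BS) <= 1)
  expect_lt(r$n_degenerate_resamples, r$n_resamples)
  expect_error(pearson_with_bootstrap(x, rep(1, 6)),
               class = "pd_undefined_correlation_error")
  expect_error(pearson_with_bootstrap(1:2, 1:2), class = "pd_domain_error")
})

test_that("ANCOVA gate: identical sites homogeneous, offset lines differ in intercept", {
  pairs <- data.frame(L_t = c(1, 2, 3, 4), L_t1 = c(1.9, 2.7, 3.4, 4.0))
  same <- ancova_walford(list(pairs, pairs))
  expect_equal(same$decision, "homogeneous")
  expect_equal(same$p_slopes, 1, tolerance = 1e-6)
  offset <- pairs
  offset$L_t1 <- offset$L_t1 + 1
  par <- ancova_walford(list(pairs, offset))
  expect_equal(par$decision, "intercepts_differ")
  expect_equal(par$p_slopes, 1, tolerance = 1e-6)
  expect_lt(par$p_intercepts, 1e-4)
  # relabeling sites does not change the decision
  par2 <- ancova_walford(list(offset, pairs))
  expect_equal(par2$decision, par$decision)
  expect_equal(par2$p_slopes, par$p_slopes)
  # singular design
  const <- data.frame(L_t = c(2, 2, 2), L_t1 = c(1, 2, 3))
  expect_error(ancova_walford(list(pairs, const)), class = "pd_design_error")
})

test_that("ANCOVA type-I rate under a shared truth is near alpha", {
  # both sites drawn from the same VBGF world; a full calibration would use
  # hundreds of replicates with band [0.02, 0.09]; 100 keep the run fast,
  # band widened by its own binomial SE accordingly
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    mk <- function() {
      ages <- 1:10
      L <- 15.4 * (1 - exp(-0.062 * ages)) * (1 + rnorm(10, 0, 0.03))
      pairs <- data.frame(L_t = L[-10], L_t1 = L[-1])
      pairs
    }
    ancova_walford(list(mk(), mk()))$p_slopes < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)
})

test_that("Kruskal-Wallis matches the hand-ranked statistic and edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1)
  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # invariance under strictly monotone transforms
  g <- list(rnorm(8), rnorm(8) + 1, rnorm(8) - 0.5)
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(v) exp(3 * v)))$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), class = "pd_domain_error")
})

test_that("simulated site temperatures with distinct means separate clearly", {
  cfg <- simulation_config(seed = 3L)
  temps <- lapply(seq_len(cfg$n_sites), function(i)
    simulate_temperature_series(cfg$sst_means[i], amplitude = 4,
                                n_days = 365L, noise_sd = 0.5,
                                seed = 30L + i)$surface$temp_c)
  expect_lt(kruskal_wallis(temps)$p, 0.001)
})

test_that("KS comparison of age structures: identity, power, scale invariance", {
  a <- structure_from_counts(c(30L, 20L, 12L, 7L, 4L))
  self <- ks_compare_structures(list(a, a))
  expect_equal(self$D[1, 2], 0)
  expect_equal(self$p[1, 2], 1)
  # strongly different mortalities are detected (Z = 0.1 vs 0.5, n = 150);
  # expect p < 0.001 in the overwhelming majority of replicates; 25 here
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    draw <- function(z) {
      p <- exp(-z * 0:12)
      table(factor(sample(0:12, 150, TRUE, prob = p / sum(p)), levels = 0:12))
    }
    s1 <- structure_from_counts(as.integer(draw(0.1)))
    s2 <- structure_from_counts(as.integer(draw(0.5)))
    ks_compare_structures(list(s1, s2))$p[1, 2] < 0.001
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  # D depends only on the count-weighted CDF, so x10 counts leave it unchanged
  b <- structure_from_counts(c(10L, 5L, 2L, 1L, 1L))
  d1 <- ks_compare_structures(list(a, b))$D[1, 2]
  a10 <- structure_from_counts(c(30L, 20L, 12L, 7L, 4L) * 10L)
  b10 <- structure_from_counts(c(10L, 5L, 2L, 1L, 1L) * 10L)
  d2 <- ks_compare_structures(list(a10, b10))$D[1, 2]
  expect_equal(d1, d2, tolerance = 1e-12)
  # bonferroni never lowers a p-value
  three <- list(a, b, structure_from_counts(c(5L, 5L, 5L, 5L, 5L)))
  p_raw <- ks_compare_structures(three, "none")$p
  p_bon <- ks_compare_structures(three, "bonferroni")$p
  expect_true(all(p_bon >= p_raw - 1e-15))
  tiny <- structure_from_counts(c(2L, 1L))
  expect_error(ks_compare_structures(list(a, tiny)),
               class = "pd_insufficient_data_error")
})

test_that("KS p-values under the null are not anti-conservative", {
  # same generating structure for both sites: empirical rejection at 0.05
  # should be at most ~0.08 (100 replicates)
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    draw <- function() {
      p <- exp(-0.3 * 0:10)
      table(factor(sample(0:10, 120, TRUE, prob = p / sum(p)), levels = 0:10))
    }
    s1 <- structure_from_counts(as.integer(draw()))
    s2 <- structure_from_counts(as.integer(draw()))
    ks_compare_structures(list(s1, s2))$p[1, 2] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.08)
})

test_that("surface/depth agreement: identity, fixed offset, uncorrelated noise", {
  ts <- simulate_temperature_series(19, amplitude = 4, depth_offset = 0,
                                    n_days = 365L, noise_sd = 0, seed = 1L)
  same <- sst_depth_agreement(ts$surface, ts$depth)
  expect_equal(same$r2, 1, tolerance = 1e-12)
  expect_equal(same$mean_diff, 0, tolerance = 1e-12)
  ts2 <- simulate_temperature_series(19, amplitude = 4, depth_offset = 2.18,
                                     n_days = 365L, noise_sd = 0, seed = 1L)
  off <- sst_depth_agreement(ts2$surface, ts2$depth)
  expect_equal(off$mean_diff, 2.18, tolerance = 1e-12)
  expect_equal(off$sd_diff, 0, tolerance = 1e-12)
  # pure white noise shares no seasonal signal: r2 stays near zero
  r2s <- vapply(1:20, function(s) {
    ns <- simulate_temperature_series(19, amplitude = 0, depth_offset = 0,
                                      n_days = 365L, noise_sd = 1,
                                      seed = 100L + s)
    # break the pairing so the two series are independent noise
    sh <- ns$depth
    sh$temp_c <- rev(sh$temp_c)
    sst_depth_agreement(ns$surface, sh)$r2
  }, numeric(1))
  expect_gt(mean(r2s < 0.05), 0.9)
  short <- lapply(simulate_temperature_series(19, n_days = 10L, seed = 1L),
                  identity)
  expect_error(sst_depth_agreement(short$surface, short$depth),
               class = "pd_insufficient_overlap_error")
})
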