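#' Configuration of the coral population simulator
#'
#' The simulator emulates the statistical world the analysis assumes: at
#' each site, recruitment is open and mortality is constant, so the number
#' of individuals in integer age class `t` is Poisson with mean
#' `N0 * exp(-Z * t)` for `t = 0..max_age`; corallite lengths follow the
#' von Bertalanffy curve evaluated at the class midpoint `t + 0.5` with
#' multiplicative Gaussian noise; dry skeletal mass follows an allometric
#' power law of length with lognormal noise.
#'
#' Defaults describe the six-site reference survey ([reference_sites()]):
#' six populations spanning ~2 degrees C of mean annual SST, 76-210 polyps
#' per site in 3-4 patches, site-specific mortality `Z` in 0.07-0.43, and a
#' growth curve homogeneous across sites (the pooled
#' [general_growth_params()] truth).  Per-site recruitment `N0` is derived
#' so that the expected population size matches the reference sample count.
#' The allometric coefficients are synthetic placeholders (no published
#' values are shipped) and only matter for biomass summaries.
#'
#' @param n_sites number of sites.
#' @param site_labels site names, recycled defaults from the reference
#'   survey.
#' @param L_inf,K per-site true growth parameters (recycled to `n_sites`).
#' @param Z per-site true instantaneous mortality, 1/year, >= 0.
#' @param N0 per-site recruits per year; default derived from
#'   `expected_n` and `Z`.
#' @param expected_n per-site expected population size used to derive `N0`
#'   when `N0` is `NULL`.
#' @param max_age oldest age class simulated, years, >= 3.
#' @param length_cv relative SD of length about its VBGF mean, in [0, 0.5).
#' @param a_m,b_m allometric mass coefficients (`mass = a_m * L^b_m`).
#' @param mass_sdlog lognormal noise SD of mass on the log scale.
#' @param n_patches per-site number of collection patches.
#' @param ct_subsample_size band-dated skeletons per site (or in total,
#'   see [simulate_ct_subsample()] callers).
#' @param sst_means per-site mean annual SST, degrees C.
#' @param sst_amplitude seasonal (annual sinusoid) amplitude, degrees C,
#'   >= 0.
#' @param depth_offset mean excess of SST over temperature at sampling
#'   depth, degrees C.
#' @param seed integer seed making every simulation from this config
#'   reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 6L,
                              site_labels = NULL,
                              L_inf = 15.4, K = 0.062,
                              Z = NULL, N0 = NULL, expected_n = NULL,
                              max_age = 28L, length_cv = 0.05,
                              a_m = 0.0016, b_m = 2.7, mass_sdlog = 0.1,
                              n_patches = NULL, ct_subsample_size = 30L,
                              sst_means = NULL, sst_amplitude = 4,
                              depth_offset = 2.18, seed = 1L) {
  ref <- reference_sites()
  take <- function(x, default) rep_len(x %||% default, n_sites)
  site_labels <- site_labels %||%
    if (n_sites <= nrow(ref)) ref$site[seq_len(n_sites)] else
      paste0("site", seq_len(n_sites))
  cfg <- list(
    n_sites = as.integer(n_sites),
    site_labels = rep_len(site_labels, n_sites),
    L_inf = take(L_inf, 15.4), K = take(K, 0.062),
    Z = take(Z, ref$Z[seq_len(min(n_sites, nrow(ref)))]),
    max_age = as.integer(max_age), length_cv = length_cv,
    a_m = a_m, b_m = b_m, mass_sdlog = mass_sdlog,
    n_patches = take(n_patches, ref$n_patches[seq_len(min(n_sites, nrow(ref)))]),
    ct_subsample_size = as.integer(ct_subsample_size),
    sst_means = take(sst_means, ref$sst_mean_c[seq_len(min(n_sites, nrow(ref)))]),
    sst_amplitude = sst_amplitude, depth_offset = depth_offset,
    seed = as.integer(seed)
  )
  expected_n <- take(expected_n, ref$n_samples[seq_len(min(n_sites, nrow(ref)))])
  if (is.null(N0)) {
    # N0 such that N0 * sum_t exp(-Z t) over 0..max_age = expected_n
    s <- vapply(cfg$Z, function(z) sum(exp(-z * 0:cfg$max_age)), numeric(1))
    cfg$N0 <- expected_n / s
  } else {
    cfg$N0 <- take(N0, N0)
  }
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg) if (!all(ok)) stop_config(msg)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  for (f in c("L_inf", "K", "Z", "N0", "length_cv", "a_m", "b_m",
              "mass_sdlog", "sst_means", "sst_amplitude", "depth_offset"))
    chk(num_ok(cfg[[f]]), sprintf("config field `%s` must be finite numeric", f))
  chk(cfg$L_inf > 0, "L_inf must be > 0")
  chk(cfg$K > 0, "K must be > 0")
  chk(cfg$Z >= 0, "Z must be >= 0")
  chk(cfg$N0 > 0, "N0 must be > 0")
  chk(cfg$length_cv >= 0 & cfg$length_cv < 0.5, "length_cv must be in [0, 0.5)")
  chk(cfg$max_age >= 3, "max_age must be >= 3")
  chk(cfg$sst_amplitude >= 0, "sst_amplitude must be >= 0")
  chk(cfg$n_patches >= 1, "n_patches must be >= 1")
  invisible(cfg)
}

#' Simulate one site's coral population
#'
#' Draws a full census of one site under the model described in
#' [simulation_config()]: independent Poisson counts per age class about
#' `N0 * exp(-Z * t)` (so the total is Poisson about
#' `N0 * sum_t exp(-Z t)` and the age marginal is the truncated geometric
#' `P(t) proportional to exp(-Z t)`), VBGF lengths at class midpoints with
#' multiplicative Gaussian noise truncated at 0.1 mm, allometric masses
#' with lognormal noise, and uniform patch membership.  Byte-identical
#' across calls with the same config and site index.
#'
#' @param config a [simulation_config] object.
#' @param site_index which site (1-based) to simulate.
#' @return An object of class `simulated_population`: `records` (data frame
#'   with columns `site`, `patch`, `length_mm`, `mass_g`, `band_age_years`
#'   all `NA`, plus the hidden `true_age`), `site_label` and `true_params`.
#' @export
simulate_population <- function(config, site_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  i <- as.integer(site_index)
  if (i < 1L || i > config$n_sites) stop_request("site_index out of range")
  with_seed(config$seed + 7919L * i, {
    ages_support <- 0:config$max_age
    counts <- stats::rpois(length(ages_support),
                           config$N0[i] * exp(-config$Z[i] * ages_support))
    true_age <- rep(ages_support, counts)
    n <- length(true_age)
    mean_len <- config$L_inf[i] * (1 - exp(-config$K[i] * (true_age + 0.5)))
    length_mm <- pmax(0.1, mean_len * (1 + stats::rnorm(n, 0, config$length_cv)))
    mass_g <- config$a_m * length_mm^config$b_m *
      exp(stats::rnorm(n, 0, config$mass_sdlog))
    patch <- paste0("P", sample.int(config$n_patches[i], n, replace = TRUE))
    structure(
      list(records = data.frame(
             site = config$site_labels[i], patch = patch,
             length_mm = length_mm, mass_g = mass_g,
             band_age_years = NA_integer_, true_age = true_age),
           site_label = config$site_labels[i],
           true_params = list(L_inf = config$L_inf[i], K = config$K[i],
                              Z = config$Z[i], N0 = config$N0[i])),
      class = "simulated_population"
    )
  })
}

#' Draw a band-dated (CT) subsample from a simulated population
#'
#' Uniform random subsample without replacement, emulating the random
#' selection of ~30 skeletons per site for computerized-tomography growth
#' band counting.  Only individuals that have laid down at least one annual
#' band (hidden age >= 1) are eligible: younger recruits cannot be dated by
#' band counting.  The band-count age is the hidden true age plus rounded
#' Gaussian reading error, clipped below at 1 year.  The default reading
#' error is zero: band ages are treated as exact.
#'
#' @param pop a [simulate_population()] result.
#' @param n subsample size, `<=` the number of eligible (age >= 1)
#'   individuals.
#' @param age_error_sd SD of the Gaussian band-reading error, years.
#' @param seed optional integer seed.
#' @return Data frame of `n` records with `band_age_years` set.
#' @export
simulate_ct_subsample <- function(pop, n, age_error_sd = 0, seed = NULL) {
  stopifnot(inherits(pop, "simulated_population"))
  eligible <- which(pop$records$true_age >= 1L)
  if (n > length(eligible))
    stop_request(sprintf("subsample of %d exceeds the %d datable (age >= 1) individuals",
                         n, length(eligible)))
  with_seed(seed, {
    rows <- eligible[sample.int(length(eligible), n, replace = FALSE)]
    out <- pop$records[rows, , drop = FALSE]
    err <- if (age_error_sd > 0) round(stats::rnorm(n, 0, age_error_sd)) else 0
    out$band_age_years <- as.integer(pmax(1, out$true_age + err))
    rownames(out) <- NULL
    attr(out, "rows") <- rows
    out
  })
}

#' Simulate paired surface / at-depth temperature series
#'
#' Daily temperatures over `n_days` starting at `start_date`: the surface
#' series is an annual sinusoid about `mean_sst` (peaking in early August,
#' as Mediterranean coastal SST does) plus white noise; the at-depth series
#' is the surface series shifted down by `depth_offset` plus independent
#' white noise.  Both share the same dates.
#'
#' @param mean_sst annual mean of the surface series, degrees C.
#' @param amplitude sinusoid amplitude, degrees C, >= 0.
#' @param depth_offset mean surface-minus-depth difference, degrees C.
#' @param n_days number of daily observations, >= 2.
#' @param noise_sd SD of the white noise on each series, degrees C.
#' @param seed optional integer seed.
#' @param start_date first day (ISO-8601 string or Date).
#' @return List with `surface` and `depth`, each a data frame with columns
#'   `timestamp` (Date), `temp_c` and `series`.
#' @export
simulate_temperature_series <- function(mean_sst, amplitude = 4,
                                        depth_offset = 2.18, n_days = 365L,
                                        noise_sd = 0.5, seed = NULL,
                                        start_date = "2003-01-01") {
  if (!is.finite(amplitude) || amplitude < 0)
    stop_config("`amplitude` must be >= 0")
  if (n_days < 2L) stop_config("`n_days` must be >= 2")
  with_seed(seed, {
    dates <- as.Date(start_date) + seq_len(n_days) - 1L
    doy <- as.numeric(format(dates, "%j"))
    seasonal <- amplitude * cos(2 * pi * (doy - 220) / 365.25)
    surface <- mean_sst + seasonal + stats::rnorm(n_days, 0, noise_sd)
    depth <- surface - depth_offset + stats::rnorm(n_days, 0, noise_sd)
    list(
      surface = data.frame(timestamp = dates, temp_c = surface,
                           series = "surface"),
      depth = data.frame(timestamp = dates, temp_c = depth,
                         series = "depth")
    )
  })
}

#' Simulate a whole multi-site survey
#'
#' Convenience wrapper: simulates every site of a config, draws the
#' band-dated subsample at each site, and stacks everything into one survey
#' data frame, with band ages set on the subsampled rows and `NA`
#' elsewhere.
#'
#' @param config a [simulation_config] object.
#' @param ct_mode `"per_site"` dates `ct_subsample_size` skeletons at each
#'   site; `"total"` spreads `ct_subsample_size` dated skeletons across
#'   sites proportionally to site size.
#' @return List: `survey` (records of all sites, hidden `true_age` column
#'   retained), `populations` (per-site [simulate_population()] results)
#'   and `temperature` (per-site series from
#'   [simulate_temperature_series()]).
#' @export
simulate_survey <- function(config, ct_mode = c("per_site", "total")) {
  ct_mode <- match.arg(ct_mode)
  stopifnot(inherits(config, "simulation_config"))
  pops <- lapply(seq_len(config$n_sites), function(i)
    simulate_population(config, i))
  sizes <- vapply(pops, function(p) sum(p$records$true_age >= 1L), 0L)
  n_ct <- if (ct_mode == "per_site") {
    pmin(rep(config$ct_subsample_size, config$n_sites), sizes)
  } else {
    pmin(pmax(1L, round(config$ct_subsample_size * sizes / sum(sizes))), sizes)
  }
  survey <- do.call(rbind, lapply(seq_along(pops), function(i) {
    rec <- pops[[i]]$records
    sub <- simulate_ct_subsample(pops[[i]], n_ct[i],
                                 seed = config$seed + 104729L * i)
    rec$band_age_years[attr(sub, "rows")] <- sub$band_age_years
    rec
  }))
  rownames(survey) <- NULL
  temperature <- lapply(seq_len(config$n_sites), function(i)
    simulate_temperature_series(config$sst_means[i],
                                amplitude = config$sst_amplitude,
                                depth_offset = config$depth_offset,
                                n_days = 365L,
                                seed = config$seed + 15485863L * i))
  names(temperature) <- config$site_labels
  list(survey = survey, populations = pops, temperature = temperature)
}
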