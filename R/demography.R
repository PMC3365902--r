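#' Assign integer age classes to survey records from a growth curve
#'
#' Ages every measured polyp by inverting the growth curve at its length,
#' using the completed-years (floor) convention.  Individuals at least as
#' long as `L_inf` cannot be aged by inversion; they are flagged censored and
#' assigned the completed-years age of `0.99 * L_inf` (they are real, old
#' animals — dropping them would bias the proportion of immature individuals
#' upward).
#'
#' @param records data frame with a `length_mm` column.
#' @param params a [growth_params] object.
#' @return `records` with integer `age_class` and logical `censored` columns
#'   appended.
#' @export
assign_ages <- function(records, params) {
  stopifnot(inherits(params, "growth_params"))
  L <- records$length_mm
  if (any(!is.finite(L)) || any(L < 0)) stop_domain("lengths must be finite and >= 0")
  censored <- L >= params$L_inf
  age <- integer(length(L))
  if (any(!censored))
    age[!censored] <- vbgf_age_at_length(params, L[!censored], "completed_years")
  if (any(censored))
    age[censored] <- vbgf_age_at_length(params, 0.99 * params$L_inf, "completed_years")
  records$age_class <- as.integer(age)
  records$censored <- censored
  records
}

#' Build the observed age structure of one site
#'
#' Tabulates aged individuals into integer age classes 0..max observed class,
#' keeping interior empty classes with count zero.
#'
#' @param aged data frame with an integer `age_class` column
#'   (from [assign_ages()]).
#' @param site site label stored with the structure.
#' @return An object of class `age_structure`: fields `site`, `age`
#'   (0..max class), `observed` (integer counts), `n` and optionally
#'   `theoretical` (see [theoretical_structure()]).
#' @export
build_age_structure <- function(aged, site = "site") {
  if (is.null(aged$age_class) || nrow(aged) == 0L)
    stop_insufficient("no aged records supplied")
  ages <- as.integer(aged$age_class)
  if (any(ages < 0)) stop_domain("age classes must be >= 0")
  support <- 0:max(ages)
  counts <- tabulate(ages + 1L, nbins = max(ages) + 1L)
  structure(
    list(site = site, age = support, observed = as.integer(counts),
         theoretical = NULL, n = length(ages)),
    class = "age_structure"
  )
}

#' @export
print.age_structure <- function(x, ...) {
  cat(sprintf("Age structure for %s: n = %d over classes 0..%d\n",
              x$site, x$n, max(x$age)))
  df <- data.frame(age = x$age, observed = x$observed)
  if (!is.null(x$theoretical)) df$theoretical <- round(x$theoretical, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Estimate instantaneous mortality from an age structure
#'
#' Semi-log catch-curve regression: ordinary least squares of
#' `ln(N_t)` on `t` over age classes with at least one individual (classes
#' with zero count are excluded because `ln 0` is undefined).  The slope with
#' sign changed is the instantaneous rate of mortality `Z` (1/year), the
#' exponentiated intercept is `N_0`, the number of individuals at age zero,
#' and the regression r-squared measures population-structure stability: it
#' is exactly 1 for a steady-state (exactly exponential) structure and
#' decreases toward 0 as the structure departs from steady state.
#'
#' A perfectly flat structure (all counts equal) is reported with the
#' convention `Z = 0`, `r2 = 0` rather than as an error.
#'
#' @param structure an [age_structure][build_age_structure] object.
#' @return An object of class `mortality_fit`: `Z`, `ln_N0`, `N0`, `r2`
#'   (stability) and `n_classes` used in the regression.
#' @export
fit_mortality <- function(structure) {
  stopifnot(inherits(structure, "age_structure"))
  keep <- structure$observed >= 1L
  if (sum(keep) < 3L)
    stop_insufficient("semi-log regression needs >= 3 age classes with counts >= 1")
  t <- structure$age[keep]
  ln_n <- log(structure$observed[keep])
  fit <- stats::lm(ln_n ~ t)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact fits warn "essentially perfect"
  if (stats::var(ln_n) == 0) {  # flat structure convention
    slope <- 0
    r2 <- 0
  }
  base::structure(  # arg `structure` shadows base::structure here
    list(Z = -slope, ln_N0 = intercept, N0 = exp(intercept),
         r2 = if (is.finite(r2)) r2 else 0, n_classes = sum(keep)),
    class = "mortality_fit"
  )
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("Mortality fit: Z = %.4g 1/yr, N0 = %.4g, stability r2 = %.3f (%d classes)\n",
              x$Z, x$N0, x$r2, x$n_classes))
  invisible(x)
}

#' Survivorship curve
#'
#' Expected number of individuals surviving to age `t` under constant
#' mortality: `N_t = N_0 * exp(-Z * t)`.
#'
#' @param fit a [mortality_fit][fit_mortality] object.
#' @param t age in years, vectorised, >= 0.
#' @return Expected counts.
#' @export
survivorship <- function(fit, t) {
  stopifnot(inherits(fit, "mortality_fit"))
  if (any(!is.finite(t)) || any(t < 0)) stop_domain("age `t` must be finite and >= 0")
  fit$N0 * exp(-fit$Z * t)
}

#' Theoretical (steady-state) age structure
#'
#' Evaluates the survivorship curve at every integer age class on the
#' observed support, giving the age structure the population would have at
#' steady state with the fitted mortality.
#'
#' @param fit a [mortality_fit][fit_mortality] object.
#' @param max_age oldest class of the support (classes run 0..`max_age`).
#' @return Numeric vector of expected counts, one per class.
#' @export
theoretical_structure <- function(fit, max_age) {
  if (!is.finite(max_age) || max_age < 0) stop_domain("`max_age` must be >= 0")
  survivorship(fit, 0:max_age)
}

#' Attach the theoretical counts to an observed age structure
#'
#' @param structure an [age_structure][build_age_structure] object.
#' @param fit a [mortality_fit][fit_mortality] object for the same site.
#' @return The structure with its `theoretical` field filled on the observed
#'   support.
#' @export
add_theoretical <- function(structure, fit) {
  stopifnot(inherits(structure, "age_structure"))
  structure$theoretical <- theoretical_structure(fit, max(structure$age))
  structure
}

#' Allometric length-mass model
#'
#' Dry skeletal mass as a power law of corallite length,
#' `mass = a_m * L^b_m` (g, mm).  The coefficients are species- and
#' study-specific and must be supplied by the user (or taken from the
#' simulator's synthetic defaults); none are asserted against published
#' values.
#'
#' @param a_m coefficient, g * mm^(-b_m), > 0.
#' @param b_m exponent, dimensionless, > 0.
#' @return An object of class `length_mass_model`.
#' @export
length_mass_model <- function(a_m, b_m) {
  if (!is.finite(a_m) || a_m <= 0) stop_domain("`a_m` must be > 0")
  if (!is.finite(b_m) || b_m <= 0) stop_domain("`b_m` must be > 0")
  structure(list(a_m = a_m, b_m = b_m), class = "length_mass_model")
}

predict_mass <- function(model, length_mm) {
  stopifnot(inherits(model, "length_mass_model"))
  model$a_m * length_mm^model$b_m
}

#' Demographic summary of one site
#'
#' Computes the eight observed/theoretical demographic parameters of a site
#' from its age structure, mortality fit, growth curve and length-mass
#' model:
#'
#' * percentage of immature individuals — individuals in age classes below
#'   the first mature class.  The maturity class is derived from the
#'   maturity length (default 3 mm) through the same ageing curve used for
#'   the population: `T_m = floor(age at maturity length) + 1`.
#' * mean age — mean of individual age classes (observed) or the
#'   count-weighted mean of the theoretical structure.
#' * age at maximum percentage biomass — modal class of the biomass-by-age
#'   distribution (ties break to the youngest class).
#' * mean age of biomass — biomass-weighted mean age.
#'
#' Observed biomass per class sums the measured corallite masses in the
#' class; theoretical biomass multiplies the theoretical count by the
#' allometric mass at the VBGF length for that age.  Theoretical summaries
#' use the observed support (0..max observed class), matching how
#' steady-state curves are conventionally drawn over the observed range.
#'
#' @param structure an [age_structure][build_age_structure] object.
#' @param fit the site's [mortality_fit][fit_mortality].
#' @param params the [growth_params] used to age the site.
#' @param massmodel a [length_mass_model].
#' @param aged the aged records of the site (columns `age_class`, `mass_g`).
#' @param maturity_length length at sexual maturity, mm (default 3).
#' @return An object of class `demography_summary` with the eight parameters
#'   plus `Z`, `stability_r2`, `maturity_class`, `n` and `n_censored`.
#' @export
summarize_demography <- function(structure, fit, params, massmodel, aged,
                                 maturity_length = 3) {
  stopifnot(inherits(structure, "age_structure"),
            inherits(fit, "mortality_fit"),
            inherits(params, "growth_params"),
            inherits(massmodel, "length_mass_model"))
  if (maturity_length >= params$L_inf)
    stop_domain("maturity length must be below L_inf")
  support <- structure$age
  obs <- structure$observed
  theo <- structure$theoretical %||% theoretical_structure(fit, max(support))

  t_mat <- vbgf_age_at_length(params, maturity_length, "completed_years") + 1L
  obs_pct_imm <- 100 * sum(obs[support < t_mat]) / sum(obs)
  theo_pct_imm <- 100 * sum(theo[support < t_mat]) / sum(theo)

  obs_mean_age <- mean(aged$age_class)
  theo_mean_age <- sum(support * theo) / sum(theo)

  if (any(is.na(aged$mass_g)))
    stop_missing_mass(sprintf("%d records lack mass; observed biomass undefined",
                              sum(is.na(aged$mass_g))))
  obs_biomass <- vapply(support, function(a)
    sum(aged$mass_g[aged$age_class == a]), numeric(1))
  theo_biomass <- theo * predict_mass(massmodel, vbgf_length_at_age(params, support))
  if (sum(obs_biomass) <= 0 || sum(theo_biomass) <= 0)
    stop_undefined("total biomass is zero; biomass summaries undefined")

  base::structure(
    list(site = structure$site,
         observed_pct_immature = obs_pct_imm,
         theoretical_pct_immature = theo_pct_imm,
         observed_mean_age = obs_mean_age,
         theoretical_mean_age = theo_mean_age,
         observed_age_max_biomass = support[which.max(obs_biomass)],
         theoretical_age_max_biomass = support[which.max(theo_biomass)],
         observed_mean_age_biomass = sum(support * obs_biomass) / sum(obs_biomass),
         theoretical_mean_age_biomass = sum(support * theo_biomass) / sum(theo_biomass),
         Z = fit$Z, stability_r2 = fit$r2,
         maturity_class = t_mat, n = structure$n,
         n_censored = sum(aged$censored %||% FALSE),
         observed_biomass = obs_biomass, theoretical_biomass = theo_biomass),
    class = "demography_summary"
  )
}

#' @export
print.demography_summary <- function(x, ...) {
  cat(sprintf("Demographic summary for %s (n = %d, Z = %.3f, stability r2 = %.3f)\n",
              x$site, x$n, x$Z, x$stability_r2))
  f <- function(lab, o, t, d = 1)
    cat(sprintf("  %-28s observed %6.*f | theoretical %6.*f\n", lab, d, o, d, t))
  f("% immature", x$observed_pct_immature, x$theoretical_pct_immature)
  f("mean age (yr)", x$observed_mean_age, x$theoretical_mean_age)
  f("age at max % biomass (yr)", x$observed_age_max_biomass,
    x$theoretical_age_max_biomass, 0)
  f("mean age of biomass (yr)", x$observed_mean_age_biomass,
    x$theoretical_mean_age_biomass)
  invisible(x)
}
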