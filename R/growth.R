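#' Von Bertalanffy growth parameters
#'
#' Container for the two parameters of the von Bertalanffy growth function
#' (VBGF), `L_t = L_inf * (1 - exp(-K * t))`, together with the Ford-Walford
#' regression diagnostics they were estimated from.  `L_inf` is the asymptotic
#' (maximum expected) corallite length in mm and `K` (1/year) controls how
#' fast that asymptote is approached.  The Walford slope and intercept obey
#' the identities `slope = exp(-K)` and `intercept = L_inf * (1 - slope)`.
#'
#' @param L_inf asymptotic length, mm; must be positive.
#' @param K growth constant, 1/year; must be positive.
#' @param walford_slope,walford_intercept Ford-Walford regression
#'   coefficients.  Defaults are derived from `L_inf` and `K` via the
#'   identities above, for parameter sets not produced by a regression.
#' @param n_age_classes number of age-class means behind the fit.
#' @param r2 coefficient of determination of the Walford regression.
#' @return An object of class `growth_params`.
#' @seealso [ford_walford_fit()], [vbgf_length_at_age()]
#' @export
#' @examples
#' gp <- growth_params(L_inf = 15.4, K = 0.062)
#' vbgf_length_at_age(gp, 28)
growth_params <- function(L_inf, K,
                          walford_slope = exp(-K),
                          walford_intercept = L_inf * (1 - walford_slope),
                          n_age_classes = NA_integer_, r2 = NA_real_) {
  if (!is.finite(L_inf) || L_inf <= 0) stop_domain("`L_inf` must be a positive number")
  if (!is.finite(K) || K <= 0) stop_domain("`K` must be a positive number")
  structure(
    list(L_inf = L_inf, K = K,
         walford_slope = walford_slope, walford_intercept = walford_intercept,
         n_age_classes = n_age_classes, r2 = r2),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Von Bertalanffy growth parameters\n")
  cat(sprintf("  L_inf = %.4g mm, K = %.4g 1/yr\n", x$L_inf, x$K))
  cat(sprintf("  Walford slope = %.4f, intercept = %.4f mm",
              x$walford_slope, x$walford_intercept))
  if (is.finite(x$r2))
    cat(sprintf("  (n classes = %d, r2 = %.3f)", x$n_age_classes, x$r2))
  cat("\n")
  invisible(x)
}

#' Evaluate the von Bertalanffy growth curve
#'
#' Expected corallite length at age `t`: `L_inf * (1 - exp(-K * t))`.
#'
#' @param params a [growth_params] object.
#' @param t age in years, vectorised; must be non-negative.
#' @return Length(s) in mm, strictly increasing in `t`, bounded by `L_inf`.
#' @export
vbgf_length_at_age <- function(params, t) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop_domain("age `t` must be finite and >= 0")
  params$L_inf * (1 - exp(-params$K * t))
}

#' Invert the von Bertalanffy growth curve
#'
#' Age at which the growth curve reaches length `L`:
#' `t = -ln(1 - L / L_inf) / K`.  In `"completed_years"` mode the continuous
#' age is floored to an integer age class, the convention used to age whole
#' survey populations from their length measurements.
#'
#' Lengths at or above `L_inf` cannot be aged (the curve never reaches them);
#' they raise a condition of class `pd_censored_length`, which
#' [assign_ages()] catches to flag such individuals rather than drop them.
#'
#' @param params a [growth_params] object.
#' @param L corallite length, mm, vectorised; `0 <= L < L_inf`.
#' @param mode `"continuous"` (default) or `"completed_years"`.
#' @return Age(s) in years.
#' @export
#' @examples
#' gp <- growth_params(15.4, 0.062)
#' vbgf_age_at_length(gp, 12.8, mode = "completed_years")  # 28
vbgf_age_at_length <- function(params, L, mode = c("continuous", "completed_years")) {
  stopifnot(inherits(params, "growth_params"))
  mode <- match.arg(mode)
  if (any(!is.finite(L)) || any(L < 0)) stop_domain("length `L` must be finite and >= 0")
  if (any(L >= params$L_inf))
    stop_censored(sprintf(
      "length >= L_inf (%.4g mm): age is right-censored under this growth curve",
      params$L_inf))
  t <- -log(1 - L / params$L_inf) / params$K
  if (mode == "completed_years") floor(t) else t
}

# mean length per integer band age; returns data.frame(age, mean_length, n)
walford_class_means <- function(records) {
  dated <- records[!is.na(records$band_age_years), , drop = FALSE]
  if (any(dated$band_age_years < 1))
    stop_domain("band-dated records must have band_age_years >= 1")
  m <- stats::aggregate(length_mm ~ band_age_years, data = dated, FUN = mean)
  n <- stats::aggregate(length_mm ~ band_age_years, data = dated, FUN = length)
  out <- data.frame(age = m$band_age_years, mean_length = m$length_mm, n = n$length_mm)
  out[order(out$age), , drop = FALSE]
}

# consecutive-age pairs (t, t+1) of class mean lengths
walford_pairs <- function(records) {
  cm <- walford_class_means(records)
  idx <- match(cm$age + 1L, cm$age)
  keep <- !is.na(idx)
  data.frame(age = cm$age[keep], L_t = cm$mean_length[keep],
             L_t1 = cm$mean_length[idx[keep]])
}

#' Estimate growth parameters by the Ford-Walford plot method
#'
#' Computes the mean corallite length in each integer band-age class, then
#' regresses mean length at age `t + 1` on mean length at age `t` over
#' consecutive class pairs.  The VBGF is recovered from the fitted line:
#' `L_inf = intercept / (1 - slope)` and `K = -ln(slope)`.  On class means
#' that lie exactly on a VBGF the Walford plot is exactly linear and the
#' recovery is exact.
#'
#' Missing intermediate age classes break the consecutive-pair chain (pairs
#' spanning a gap are not formed and classes are never interpolated).  A
#' fitted slope outside (0, 1) means the sample does not display asymptotic
#' growth and is reported as a non-convergent-growth error rather than as
#' nonsensical parameters.
#'
#' @param records data frame of band-dated corals with columns `length_mm`
#'   and `band_age_years` (integer, >= 1); undated rows (`NA` band age) are
#'   ignored.
#' @return A [growth_params] object; the Walford pairs used are attached as
#'   attribute `"pairs"` for downstream ANCOVA comparison.
#' @export
ford_walford_fit <- function(records) {
  pairs <- walford_pairs(records)
  if (nrow(pairs) < 3L)
    stop_insufficient(sprintf(
      "Ford-Walford needs >= 3 consecutive age-class pairs, got %d", nrow(pairs)))
  fit <- stats::lm(L_t1 ~ L_t, data = pairs)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 1 - 1e-9 || slope <= 0)
    stop_nonconvergent(sprintf(
      "Walford slope %.4f outside (0, 1): no asymptotic growth in this sample", slope))
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact fits warn "essentially perfect"
  out <- growth_params(L_inf = intercept / (1 - slope), K = -log(slope),
                       walford_slope = slope, walford_intercept = intercept,
                       n_age_classes = nrow(pairs) + 1L,
                       r2 = if (is.finite(r2)) r2 else NA_real_)
  attr(out, "pairs") <- pairs
  out
}

#' Fit the exponential decay of mean growth rate with age
#'
#' The premise of the von Bertalanffy model is that growth slows with age.
#' For each band-dated individual the mean lifetime growth rate is
#' `length / age` (mm/year); the model `rate(t) = A * exp(-B * t)` is fitted
#' by ordinary least squares on the log scale,
#' `ln(rate) = ln(A) - B * age`, and its r-squared reports how much of the
#' rate variance age explains.  A clearly positive `B` justifies asymptotic
#' growth modelling for the population.
#'
#' @param records band-dated data frame (columns `length_mm`,
#'   `band_age_years`).  Needs >= 4 dated records spanning >= 3 distinct ages.
#' @return An object of class `growth_rate_decay` with fields `A` (mm/year),
#'   `B` (1/year), `r2` and `n`.
#' @export
fit_growth_rate_decay <- function(records) {
  dated <- records[!is.na(records$band_age_years), , drop = FALSE]
  if (nrow(dated) < 4L || length(unique(dated$band_age_years)) < 3L)
    stop_insufficient("need >= 4 dated records spanning >= 3 distinct ages")
  if (any(dated$band_age_years < 1))
    stop_domain("band-dated records must have band_age_years >= 1")
  rate <- dated$length_mm / dated$band_age_years
  fit <- stats::lm(log(rate) ~ dated$band_age_years)
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact fits warn "essentially perfect"
  structure(
    list(A = exp(unname(stats::coef(fit)[1L])),
         B = -unname(stats::coef(fit)[2L]),
         r2 = if (is.finite(r2)) r2 else 0,
         n = nrow(dated)),
    class = "growth_rate_decay"
  )
}

#' Pool growth curves across sites after an ANCOVA homogeneity gate
#'
#' Sites can share one general growth curve only if their Ford-Walford
#' regressions are statistically indistinguishable.  The gate tests slope
#' homogeneity first, then intercept homogeneity under a common slope
#' (see [ancova_walford()]); if neither rejects at level `alpha`, the
#' band-dated records of all sites are merged, class means recomputed on the
#' merged data, and a single general Ford-Walford regression refitted.
#' Otherwise pooling is refused and the refusal names the test that rejected.
#'
#' @param per_site_records named list of band-dated record data frames, one
#'   per site.
#' @param alpha significance level of the gate (default 0.05).
#' @param per_site_fits optional pre-computed list of [growth_params] fits
#'   (with Walford pairs attached); computed from the records if omitted.
#' @return An object of class `pooling_result`: fields `pooled` (logical),
#'   `params` (the general [growth_params] if pooled, else `NULL`),
#'   `per_site` (list of site fits), `ancova` (the gate result, `NULL` for a
#'   single site) and `reason`.
#' @export
pool_growth_curves <- function(per_site_records, alpha = 0.05,
                               per_site_fits = NULL) {
  if (length(per_site_records) < 1L) stop_insufficient("no sites supplied")
  if (is.null(per_site_fits))
    per_site_fits <- lapply(per_site_records, ford_walford_fit)
  if (length(per_site_records) == 1L) {
    return(structure(
      list(pooled = TRUE, params = per_site_fits[[1L]],
           per_site = per_site_fits, ancova = NULL,
           reason = "single site: nothing to pool"),
      class = "pooling_result"))
  }
  pair_list <- lapply(per_site_fits, attr, "pairs")
  gate <- ancova_walford(pair_list, alpha = alpha)
  if (gate$decision != "homogeneous") {
    return(structure(
      list(pooled = FALSE, params = NULL, per_site = per_site_fits,
           ancova = gate,
           reason = sprintf("pooling refused: %s at alpha = %g (p = %.4g)",
                            gate$decision, alpha,
                            if (gate$decision == "slopes_differ") gate$p_slopes
                            else gate$p_intercepts)),
      class = "pooling_result"))
  }
  merged <- do.call(rbind, lapply(per_site_records, function(r)
    r[, c("length_mm", "band_age_years")]))
  structure(
    list(pooled = TRUE, params = ford_walford_fit(merged),
         per_site = per_site_fits, ancova = gate,
         reason = "Walford regressions homogeneous across sites"),
    class = "pooling_result"
  )
}

#' @export
print.pooling_result <- function(x, ...) {
  cat("Growth-curve pooling:", if (x$pooled) "POOLED" else "REFUSED", "\n")
  cat(" ", x$reason, "\n")
  if (x$pooled) print(x$params)
  invisible(x)
}
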