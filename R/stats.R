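#' Pearson correlation with bootstrap resampling
#'
#' Site-level demographic parameters are correlated with site temperature
#' on very few points (typically six sites), where the usual Pearson
#' assumptions are shaky.  Alongside the plain sample coefficient this
#' routine reports a bootstrap estimate: `n` index pairs are drawn with
#' replacement `n_resamples` times, the coefficient recomputed on each
#' resample, and `r_BS` taken as the mean over retained resamples.
#' Resamples in which either coordinate is constant (so the coefficient is
#' undefined) are discarded and counted, not redrawn.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite, neither
#'   constant.
#' @param n_resamples number of bootstrap resamples (default 100000).
#' @param seed optional integer for a reproducible resampling stream.
#' @return An object of class `correlation_result`: `n`, `r`, `r2`, `r_BS`,
#'   `r2_BS`, `ci` (2.5/97.5 percentile interval of the resample
#'   coefficients), `n_resamples`, `n_degenerate_resamples`.
#' @export
#' @examples
#' pearson_with_bootstrap(1:6, c(2, 1, 4, 3, 6, 5), n_resamples = 1000, seed = 1)
pearson_with_bootstrap <- function(x, y, n_resamples = 100000L, seed = NULL) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop_domain("`x` and `y` must share length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_domain("values must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_correlation("a constant variable has no defined Pearson correlation")
  r <- stats::cor(x, y)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
    xs <- matrix(x[idx], nrow = n)
    ys <- matrix(y[idx], nrow = n)
    sxx <- colSums(xs^2) - colSums(xs)^2 / n
    syy <- colSums(ys^2) - colSums(ys)^2 / n
    sxy <- colSums(xs * ys) - colSums(xs) * colSums(ys) / n
    scale <- max(sxx, syy)
    degen <- sxx <= 1e-12 * scale | syy <= 1e-12 * scale
    r_b <- sxy[!degen] / sqrt(sxx[!degen] * syy[!degen])
    structure(
      list(n = n, r = r, r2 = r^2,
           r_BS = mean(r_b), r2_BS = mean(r_b)^2,
           ci = stats::quantile(r_b, c(0.025, 0.975), names = FALSE),
           n_resamples = n_resamples,
           n_degenerate_resamples = sum(degen)),
      class = "correlation_result"
    )
  })
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (r2 = %.3f), n = %d\n", x$r, x$r2, x$n))
  cat(sprintf("  bootstrap r_BS = %.3f (r2_BS = %.3f) over %d resamples (%d degenerate)\n",
              x$r_BS, x$r2_BS, x$n_resamples, x$n_degenerate_resamples))
  invisible(x)
}

# p-value of an extra-sum-of-squares F test between nested lm fits, robust
# to exactly-fitting models (RSS = 0), where the standard F is 0/0 or Inf.
nested_f_p <- function(reduced, full) {
  rss_r <- sum(stats::residuals(reduced)^2)
  rss_f <- sum(stats::residuals(full)^2)
  tss <- sum((stats::model.response(stats::model.frame(reduced)) -
                mean(stats::model.response(stats::model.frame(reduced))))^2)
  tol <- 1e-10 * max(tss, 1)
  extra <- rss_r - rss_f
  if (rss_f <= tol) {            # full model exact
    return(if (extra <= tol) 1 else 0)
  }
  a <- stats::anova(reduced, full)
  p <- a[["Pr(>F)"]][2L]
  if (!is.finite(p)) p <- 1
  p
}

#' ANCOVA comparison of Ford-Walford regressions across sites
#'
#' Tests whether per-site Walford regressions (mean length at age `t + 1` on
#' mean length at age `t`) can be treated as one line.  Slope homogeneity is
#' tested first via the interaction F-test between the full-interaction and
#' common-slope linear models; if slopes are homogeneous at level `alpha`,
#' intercept homogeneity is tested via the site F-test in the common-slope
#' model.  The decision is `"homogeneous"`, `"slopes_differ"` or
#' `"intercepts_differ"` and is invariant to site relabeling.
#'
#' @param pairs_by_site list (one element per site, >= 2 sites) of data
#'   frames with columns `L_t` and `L_t1`, each with >= 3 rows, as attached
#'   to [ford_walford_fit()] results.
#' @param alpha significance level (default 0.05).
#' @return An object of class `ancova_result` with `p_slopes`,
#'   `p_intercepts` (`NA` when slopes already differ) and `decision`.
#' @export
ancova_walford <- function(pairs_by_site, alpha = 0.05) {
  if (length(pairs_by_site) < 2L) stop_insufficient("ANCOVA needs >= 2 sites")
  if (any(vapply(pairs_by_site, nrow, 0L) < 3L))
    stop_insufficient("every site needs >= 3 Walford pairs")
  if (any(vapply(pairs_by_site, function(p) stats::var(p$L_t) == 0, TRUE)))
    stop_design("a site has a constant predictor; ANCOVA design is singular")
  dat <- do.call(rbind, Map(function(p, s)
    data.frame(L_t = p$L_t, L_t1 = p$L_t1, site = s),
    pairs_by_site,
    as.character(seq_along(pairs_by_site))))
  dat$site <- factor(dat$site)
  full <- stats::lm(L_t1 ~ L_t * site, data = dat)
  common <- stats::lm(L_t1 ~ L_t + site, data = dat)
  single <- stats::lm(L_t1 ~ L_t, data = dat)
  p_slopes <- nested_f_p(common, full)
  if (p_slopes < alpha) {
    decision <- "slopes_differ"
    p_int <- NA_real_
  } else {
    p_int <- nested_f_p(single, common)
    decision <- if (p_int < alpha) "intercepts_differ" else "homogeneous"
  }
  structure(list(p_slopes = p_slopes, p_intercepts = p_int,
                 decision = decision, alpha = alpha),
            class = "ancova_result")
}

#' Kruskal-Wallis comparison of groups
#'
#' Rank-based comparison of two or more groups (used for mean SST among
#' sites, where the data are heteroskedastic).  Thin wrapper around
#' [stats::kruskal.test()] with input validation; `H` uses the tie
#' correction and `p` comes from the chi-square approximation with
#' `groups - 1` degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors, none empty, total n >= 5.
#' @return List with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_domain("`groups` must be a list of >= 2 numeric vectors")
  if (any(vapply(groups, length, 0L) == 0L)) stop_domain("empty group supplied")
  if (sum(vapply(groups, length, 0L)) < 5L)
    stop_insufficient("Kruskal-Wallis needs total n >= 5")
  kt <- stats::kruskal.test(groups)
  H <- unname(kt$statistic)
  if (!is.finite(H)) H <- 0  # every observation tied: no rank variance
  list(H = H, df = unname(kt$parameter),
       p = if (is.finite(kt$p.value)) kt$p.value else 1)
}

#' Pairwise Kolmogorov-Smirnov comparison of age structures
#'
#' Expands each site's class counts into an individual-age sample and runs
#' the two-sample KS test on every site pair, optionally
#' Bonferroni-correcting the p-values over the number of pairs.
#'
#' @param structures list of >= 2 [age_structure][build_age_structure]
#'   objects, each with >= 5 individuals.
#' @param correction `"none"` or `"bonferroni"`.
#' @return List with matrices `D` and `p` (sites x sites), the correction
#'   used, and `max_p`, the largest corrected pairwise p-value (all pairwise
#'   differences are significant at `alpha` iff `max_p < alpha`).
#' @export
ks_compare_structures <- function(structures, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(structures) < 2L) stop_insufficient("need >= 2 structures")
  samples <- lapply(structures, function(s) {
    stopifnot(inherits(s, "age_structure"))
    if (s$n < 5L)
      stop_insufficient(sprintf("site %s has < 5 individuals", s$site))
    rep(s$age, s$observed)
  })
  labels <- vapply(structures, function(s) s$site, "")
  k <- length(samples)
  D <- p <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(D) <- 0; diag(p) <- 1
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ks <- suppressWarnings(stats::ks.test(samples[[i]], samples[[j]]))
    pv <- ks$p.value
    if (correction == "bonferroni") pv <- min(1, pv * n_pairs)
    D[i, j] <- D[j, i] <- unname(ks$statistic)
    p[i, j] <- p[j, i] <- pv
  }
  off <- p[upper.tri(p)]
  list(D = D, p = p, correction = correction, max_p = max(off))
}

#' Agreement between surface and at-depth temperature series
#'
#' Checks whether sea surface temperature tracks the temperature at coral
#' sampling depth: both series are averaged to daily means, aligned on
#' common dates, and summarised by the Pearson r-squared and the paired
#' difference statistics (mean, SD, SE = SD / sqrt(days)) of
#' surface - depth.
#'
#' @param surface,depth temperature data frames with columns `timestamp`
#'   (Date or POSIXct) and `temp_c`.
#' @return List with `r2`, `mean_diff`, `sd_diff`, `se_diff` and `n_days`.
#' @export
sst_depth_agreement <- function(surface, depth) {
  ds <- daily_means(surface)
  dd <- daily_means(depth)
  common <- merge(ds, dd, by = "date", suffixes = c("_surface", "_depth"))
  if (nrow(common) < 30L)
    stop_overlap(sprintf("only %d common days; need >= 30", nrow(common)))
  d <- common$temp_c_surface - common$temp_c_depth
  r2 <- if (stats::var(common$temp_c_surface) == 0 ||
            stats::var(common$temp_c_depth) == 0) {
    if (stats::var(d) == 0) 1 else 0  # identical-constant degenerate case
  } else {
    stats::cor(common$temp_c_surface, common$temp_c_depth)^2
  }
  list(r2 = r2,
       mean_diff = mean(d), sd_diff = stats::sd(d),
       se_diff = stats::sd(d) / sqrt(nrow(common)),
       n_days = nrow(common))
}

daily_means <- function(series) {
  if (is.null(series$timestamp) || is.null(series$temp_c))
    stop_schema("temperature series needs `timestamp` and `temp_c` columns")
  day <- as.Date(series$timestamp)
  agg <- stats::aggregate(series$temp_c, by = list(date = day), FUN = mean)
  names(agg)[2L] <- "temp_c"
  agg[order(agg$date), , drop = FALSE]
}
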