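#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference between the two empirical CDFs.
#' The p-value is exact when `n_a * n_b <= 1e4` (the regime of typical
#' per-animal group sizes), asymptotic otherwise; the mode used is
#' reported.
#'
#' @param a,b Numeric samples, each with >= 2 finite values.
#' @return List with `D`, `p`, `mode` (`"exact"` or `"asymptotic"`).
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("insufficient sample")
  exact <- length(a) * length(b) <= 1e4
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value,
       mode = if (exact) "exact" else "asymptotic")
}

#' Shapiro-Wilk normality test p-value
#'
#' Used as a reported gate on each group before the Kolmogorov-Smirnov
#' comparison (the workflow proceeds to KS regardless; the gate is never
#' used to switch tests silently). A zero-variance sample is degenerate:
#' `NA` is returned with a warning.
#'
#' @param x Numeric sample, 3 <= n <= 5000 finite values.
#' @return P-value (scalar), or `NA` for a degenerate sample.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("sample size must be between 3 and 5000")
  if (stats::var(x) == 0) {
    warning("degenerate sample: zero variance, normality p undefined")
    return(NA_real_)
  }
  stats::shapiro.test(x)$p.value
}

#' Normalize values to the wild-type mean
#'
#' Divides every value by the mean of the wild-type group, so the
#' wild-type group has mean exactly 1 (the convention used for intensity
#' bar graphs).
#'
#' @param values Values to normalize.
#' @param wt_values Wild-type reference values (mean must be nonzero).
#' @return Normalized values.
#' @export
normalize_to_wt <- function(values, wt_values) {
  m <- mean(wt_values, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("zero or undefined wild-type mean")
  values / m
}

#' Percent change of a mutant mean relative to wild type
#' @param wt_mean,mut_mean Group means.
#' @return `100 * (mut_mean - wt_mean) / wt_mean`.
#' @export
percent_change <- function(wt_mean, mut_mean) {
  100 * (mut_mean - wt_mean) / wt_mean
}

#' Compare two genotype groups on one per-animal metric
#'
#' Extracts the per-animal metric by genotype, reports Shapiro-Wilk
#' normality p for each group, runs the two-sample Kolmogorov-Smirnov
#' test across groups, and computes the mutant-vs-wild-type percent
#' change of means. Missing values are dropped with a message.
#'
#' @param animals Per-animal tibble (from [analyze_study()] or
#'   [aggregate_animal()]) with a `genotype` column and the metric column.
#' @param metric One of `"mean_peak_to_bead"`, `"mean_fwhm_um"`,
#'   `"density_per_10um"` (or any numeric per-animal column).
#' @param wt_genotype,mut_genotype Genotype labels.
#' @return One-row tibble: metric, group sizes, means, percent_change,
#'   shapiro p per group, ks_D, ks_p, ks_mode.
#' @export
compare_groups <- function(animals, metric, wt_genotype, mut_genotype) {
  if (!metric %in% names(animals))
    stop("metric column missing: ", metric)
  for (g in c(wt_genotype, mut_genotype))
    if (!any(animals$genotype == g)) stop("genotype absent: ", g)
  pull <- function(g) {
    v <- animals[[metric]][animals$genotype == g]
    drop <- sum(!is.finite(v))
    if (drop > 0)
      message(drop, " missing ", metric, " value(s) dropped for ", g)
    v[is.finite(v)]
  }
  wt <- pull(wt_genotype); mut <- pull(mut_genotype)
  if (length(wt) < 2L || length(mut) < 2L)
    stop("need >= 2 animals per genotype with defined ", metric)
  ks <- ks_two_sample(wt, mut)
  sw <- function(v) if (length(v) >= 3L)
    suppressWarnings(shapiro_wilk(v)) else NA_real_
  tibble::tibble(
    metric = metric,
    n_wt = length(wt), n_mut = length(mut),
    wt_mean = mean(wt), mut_mean = mean(mut),
    percent_change = percent_change(mean(wt), mean(mut)),
    shapiro_p_wt = sw(wt), shapiro_p_mut = sw(mut),
    ks_D = ks$D, ks_p = ks$p, ks_mode = ks$mode
  )
}

#' Compare groups on the three standard per-animal metrics
#'
#' Runs [compare_groups()] for peak-to-bead intensity, FWHM width and
#' density per 10 um. No multiple-testing correction is applied to the
#' calls; a Bonferroni-adjusted column is emitted for transparency only.
#'
#' @inheritParams compare_groups
#' @param metrics Character vector of metric columns.
#' @return Tibble, one row per metric, with a `ks_p_bonferroni` column.
#' @export
compare_all_metrics <- function(animals, wt_genotype, mut_genotype,
                                metrics = c("mean_peak_to_bead",
                                            "mean_fwhm_um",
                                            "density_per_10um")) {
  out <- do.call(rbind, lapply(metrics, function(m)
    compare_groups(animals, m, wt_genotype, mut_genotype)))
  out$ks_p_bonferroni <- pmin(out$ks_p * length(metrics), 1)
  out
}

#' Empirical type-I error of the KS comparison under the null
#'
#' Draws both groups from the same distribution and reports the fraction
#' of replicates with `ks_p < alpha` — a calibration check that the exact
#' small-sample p-values hold their nominal size at the study's group
#' sizes.
#'
#' @param n_wt,n_mut Group sizes per replicate.
#' @param n_reps Number of replicates.
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @param rdist Sampling function taking `n`.
#' @return List with `rejection_rate`, `n_reps`, `alpha`.
#' @export
calibrate_null <- function(n_wt = 13L, n_mut = 28L, n_reps = 2000L,
                           alpha = 0.05, seed = 1L, rdist = stats::rnorm) {
  set.seed(seed)
  rej <- 0L
  for (i in seq_len(n_reps)) {
    if (ks_two_sample(rdist(n_wt), rdist(n_mut))$p < alpha) rej <- rej + 1L
  }
  list(rejection_rate = rej / n_reps, n_reps = n_reps, alpha = alpha)
}
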