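# Regional summaries and comparisons.
#
# The unit of analysis is one (MD, FA) value per tissue per subject per
# region — the mean over that subject's retained cluster voxels — because
# voxels within a subject are not independent observations. Group sizes
# can differ between comparisons when a tissue cluster is missing in some
# subject, hence the unequal-sample-size, unequal-variance (Welch) test.

#' Per-subject tissue centroids
#'
#' Mean MD and FA over the retained voxels of each tissue cluster for one
#' subject — the subject-level observation used by regional statistics.
#'
#' @param model A labeled, restricted `cluster_model`.
#' @return Data frame with columns tissue, md, fa, n_voxels.
#' @export
subject_centroids <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (anyNA(model$tissue)) stopf("assign tissues first")
  rows <- lapply(seq_len(model$k), function(i) {
    sel <- model$membership == i & model$retained
    if (!any(sel)) return(NULL)
    data.frame(tissue = model$tissue[i],
               md = mean(model$values$md[sel]),
               fa = mean(model$values$fa[sel]),
               n_voxels = sum(sel))
  })
  out <- do.call(rbind, rows)
  out[order(match(out$tissue, c("WM", "GM", "CSF"))), , drop = FALSE]
}

#' Summarize a region across subjects
#'
#' Per-tissue mean and standard deviation of the subject-level MD and FA
#' centroids, for one cord region.
#'
#' @param centroids List of per-subject [subject_centroids()] data frames.
#' @param region Region name attached to the output.
#' @return Object of class `region_summary`: data frame with columns
#'   region, tissue, md_mean, md_sd, fa_mean, fa_sd, n_subjects,
#'   n_voxels (total retained).
#' @export
summarize_region <- function(centroids, region = "region") {
  stopifnot(length(centroids) >= 1L)
  all <- do.call(rbind, Map(function(d, i) cbind(d, subject = i),
                            centroids, seq_along(centroids)))
  rows <- lapply(c("WM", "GM", "CSF"), function(tis) {
    d <- all[all$tissue == tis, ]
    if (nrow(d) == 0L) {
      warnf("region %s: no subjects with a %s cluster; tissue omitted",
            region, tis)
      return(NULL)
    }
    data.frame(region = region, tissue = tis,
               md_mean = mean(d$md), md_sd = stats::sd(d$md),
               fa_mean = mean(d$fa), fa_sd = stats::sd(d$fa),
               n_subjects = nrow(d), n_voxels = sum(d$n_voxels))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Welch's two-sample t-test
#'
#' Two-tailed t-test for unequal sample sizes and unequal variances:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite (possibly fractional) degrees of freedom.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(1, 2, 3, 4, 5, 6))
#' @export
welch_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stopf("each sample needs >= 2 finite values")
  if (stats::var(a) + stats::var(b) == 0)
    stopf("zero variance in both samples")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Bonferroni correction
#'
#' @param pvals Numeric vector of raw p-values in [0, 1].
#' @param m Number of tests in the family (>= `length(pvals)`).
#' @return Corrected p-values, `min(1, m * p)`.
#' @examples
#' bonferroni_correct(c(0.01, 0.5), m = 5)
#' @export
bonferroni_correct <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  if (m < length(pvals)) stopf("m must be >= number of p-values")
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}

#' Pairwise regional comparisons of tissue DTI indices
#'
#' Welch t-tests of each tissue's subject-level MD and FA centroids between
#' every pair of regions, with Bonferroni correction over the whole family
#' (default family size: all region pairs x tissues x metrics actually
#' tested, or `m` if given). Subjects missing a tissue cluster simply drop
#' out of that tissue's comparisons.
#'
#' @param centroids_by_region Named list (one element per region) of lists
#'   of per-subject [subject_centroids()] data frames.
#' @param m Bonferroni family size; defaults to the number of comparisons
#'   performed.
#' @param alpha_raw,alpha_corrected Significance levels reported (defaults
#'   0.001 raw — the uncorrected threshold used alongside the corrected one
#'   — and 0.05 after correction).
#' @return Data frame of class `comparison_results`: tissue, metric,
#'   region_a, region_b, t, df, p, p_bonferroni, n_a, n_b,
#'   sig_raw_05, sig_raw (at `alpha_raw`), sig_corrected.
#' @export
compare_regions <- function(centroids_by_region, m = NULL,
                            alpha_raw = 0.001, alpha_corrected = 0.05) {
  stopifnot(is.list(centroids_by_region), length(centroids_by_region) >= 2L,
            !is.null(names(centroids_by_region)))
  regions <- names(centroids_by_region)
  pull <- function(region, tissue, metric) {
    vapply(centroids_by_region[[region]], function(d) {
      v <- d[[metric]][d$tissue == tissue]
      if (length(v) == 1L) v else NA_real_
    }, numeric(1))
  }
  rows <- list()
  for (tis in c("WM", "GM", "CSF")) for (metric in c("md", "fa")) {
    for (i in seq_along(regions)[-length(regions)])
      for (j in (i + 1L):length(regions)) {
        a <- pull(regions[i], tis, metric)
        b <- pull(regions[j], tis, metric)
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2L || length(b) < 2L) next
        ht <- welch_t_test(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          tissue = tis, metric = toupper(metric),
          region_a = regions[i], region_b = regions[j],
          t = ht$t, df = ht$df, p = ht$p, n_a = ht$n_a, n_b = ht$n_b)
      }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no testable comparisons")
  if (is.null(m)) m <- nrow(out)
  out$p_bonferroni <- bonferroni_correct(out$p, m)
  out$sig_raw_05 <- out$p < 0.05
  out$sig_raw <- out$p < alpha_raw
  out$sig_corrected <- out$p_bonferroni < alpha_corrected
  class(out) <- c("comparison_results", "data.frame")
  out
}

#' Regress white-matter FA on grey-matter area percentage
#'
#' Ordinary least squares of regional WM anisotropy on the grey-matter
#' share of the cord cross-section — the structural explanation for the
#' rostro-caudal FA profile: regions with more grey matter show lower
#' cord-average WM FA.
#'
#' @param fa Regional WM FA values (length >= 2).
#' @param gm_percent Grey-matter area percentages, same length.
#' @return List with `slope` (FA per percentage point), `intercept`,
#'   `r_squared`, `n`, and the underlying `stats::lm` fit.
#' @examples
#' nv <- cord_normative_values()
#' wm <- nv[nv$tissue == "WM", ]
#' regress_fa_on_gm(wm$fa, wm$gm_area_percent)$r_squared
#' @export
regress_fa_on_gm <- function(fa, gm_percent) {
  if (length(fa) != length(gm_percent)) stopf("input lengths differ")
  if (length(fa) < 2L) stopf("need at least two points")
  if (stats::var(gm_percent) == 0) stopf("constant predictor")
  fit <- stats::lm(fa ~ gm_percent)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(fa), fit = fit)
}
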