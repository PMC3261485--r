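# End-to-end driver: simulate -> fit -> cluster -> report, per region and
# subject, with every intermediate artifact written to disk.

#' Pipeline configuration
#'
#' Collects the knobs of the full simulation-and-analysis pipeline with
#' the package defaults: three cord regions with grey-matter area
#' fractions 18 / 13.2 / 36.3%, a 20-direction b = 700 s/mm^2 scheme plus
#' one b = 0 volume, SNR 20, and the 0.2 partial-volume restriction.
#'
#' @param regions Character vector of regions to simulate.
#' @param n_subjects Subjects per region.
#' @param shape Grid dimensions per region.
#' @param n_directions,b Gradient scheme parameters.
#' @param snr Simulated signal-to-noise ratio.
#' @param threshold_frac Cluster restriction fraction.
#' @param m_tests Bonferroni family size (NULL: number of comparisons
#'   actually made).
#' @param seed Base seed; per-subject seeds are derived from it.
#' @param out Output directory.
#' @return A `pipeline_config` list, including its own `hash`.
#' @export
pipeline_config <- function(regions = c("cervical", "thoracic", "lumbar"),
                            n_subjects = 9L, shape = c(64L, 64L, 28L),
                            n_directions = 20L, b = 700, snr = 20,
                            threshold_frac = 0.2, m_tests = 18L,
                            seed = 1L, out = tempfile("cordti_")) {
  cfg <- list(regions = regions, n_subjects = as.integer(n_subjects),
              shape = as.integer(shape), n_directions = as.integer(n_directions),
              b = b, snr = snr, threshold_frac = threshold_frac,
              m_tests = m_tests, seed = as.integer(seed), out = out)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "out")])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Analyze one simulated subject
#'
#' Convenience wrapper over the single-subject analysis chain: simulate
#' (or reuse a precomputed noise-free signal), fit tensors over the ROI,
#' build scalar maps, cluster, restrict, assign tissues. This is the unit
#' of work that [run_pipeline()] and [null_study()] repeat.
#'
#' @param phantom A [build_phantom()] object.
#' @param scheme A gradient scheme.
#' @param snr Signal-to-noise ratio.
#' @param seed Noise and clustering seed for this subject.
#' @param threshold_frac Restriction fraction.
#' @param s0 Unweighted signal level.
#' @param clean Optional precomputed [noise_free_signal()] array (avoids
#'   recomputing it when many subjects share one phantom).
#' @return List with `model` (labeled `cluster_model`), `maps`, and
#'   `centroids` ([subject_centroids()] table).
#' @export
analyze_subject <- function(phantom, scheme, snr = 20, seed = 1L,
                            threshold_frac = 0.2, s0 = 1000, clean = NULL) {
  if (is.null(clean)) clean <- noise_free_signal(phantom, scheme, s0)
  signal <- if (is.finite(snr))
    add_rician_noise(clean, s0 / snr, derive_seed(seed, 1L)) else clean
  dwi <- new_dwi_volume(signal, scheme, phantom$voxel, s0 = s0, snr = snr,
                        seed = seed, phantom = phantom)
  field <- fit_tensor_field(dwi, phantom$roi)
  maps <- make_scalar_maps(field)
  model <- kmeans_partition(maps, k = 3L, seed = derive_seed(seed, 2L))
  model <- restrict_clusters(model, threshold_frac)
  model <- suppressWarnings(assign_tissues(model))
  list(model = model, maps = maps, centroids = subject_centroids(model))
}

#' Run the full pipeline
#'
#' For every region and subject: build the phantom, simulate the
#' acquisition, fit the tensor field, cluster, restrict and label, then
#' aggregate per-region summaries, pairwise Welch comparisons with
#' Bonferroni correction, and the WM-FA-versus-grey-matter regression.
#' All intermediate artifacts (NIfTI volumes, gradient tables, CSV tables,
#' JSON sidecars) are written under `config$out`, and the run is
#' deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param write Write artifacts to disk (default TRUE); FALSE keeps
#'   everything in memory, for simulation studies.
#' @return List with `summaries` (rbind of [summarize_region()] rows),
#'   `comparisons` ([compare_regions()] table), `regression`
#'   ([regress_fa_on_gm()] on regional WM FA means, when >= 2 regions),
#'   `retention` (per region x subject x tissue retained fraction),
#'   `centroids` (nested per region), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  scheme <- make_gradient_scheme(config$n_directions, config$b)
  centroids_by_region <- list()
  summaries <- list()
  retention <- list()
  for (ri in seq_along(config$regions)) {
    region <- config$regions[ri]
    rseed <- derive_seed(config$seed, 1000L * ri)
    phantom <- build_phantom(region, shape = config$shape, seed = rseed)
    clean <- noise_free_signal(phantom, scheme)
    subj_centroids <- vector("list", config$n_subjects)
    for (si in seq_len(config$n_subjects)) {
      sseed <- derive_seed(rseed, si)
      res <- analyze_subject(phantom, scheme, snr = config$snr,
                             seed = sseed,
                             threshold_frac = config$threshold_frac,
                             clean = clean)
      subj_centroids[[si]] <- res$centroids
      ret <- res$model$retained_counts / pmax(res$model$counts, 1L)
      retention[[length(retention) + 1L]] <- data.frame(
        region = region, subject = si,
        tissue = res$model$tissue, retained_fraction = ret)
      if (write) {
        sdir <- file.path(config$out, region, sprintf("subject%02d", si))
        write_subject_outputs(sdir, phantom, scheme, res, config, sseed)
      }
    }
    centroids_by_region[[region]] <- subj_centroids
    summaries[[region]] <- summarize_region(subj_centroids, region)
    message(sprintf("[%s] %d subjects analyzed; mean WM retention %.0f%%",
                    region, config$n_subjects,
                    100 * mean(unlist(lapply(retention, function(d)
                      d$retained_fraction[d$tissue == "WM"])))))
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  comparisons <- if (length(config$regions) >= 2L)
    compare_regions(centroids_by_region, m = config$m_tests) else NULL
  regression <- if (length(config$regions) >= 2L) {
    wm <- summaries[summaries$tissue == "WM", ]
    regress_fa_on_gm(wm$fa_mean,
                     vapply(wm$region, gm_area_percent, numeric(1)))
  } else NULL
  retention <- do.call(rbind, retention)
  result <- list(summaries = summaries, comparisons = comparisons,
                 regression = regression, retention = retention,
                 centroids = centroids_by_region, config = config)
  if (write) write_report(result, config$out)
  result
}

write_subject_outputs <- function(dir, phantom, scheme, res, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scalar_maps(res$maps, dir)
  write_cluster(res$model, res$maps, dir)
  jsonlite::write_json(
    list(seed = seed, config_hash = config$hash,
         region = phantom$region, snr = config$snr,
         centroids = res$centroids),
    file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_summary_table(result$summaries),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(result$comparisons))
    utils::write.csv(result$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  utils::write.csv(result$retention, file.path(dir, "retention.csv"),
                   row.names = FALSE)
  meta <- list(config_hash = result$config$hash, seed = result$config$seed,
               package_version = as.character(utils::packageVersion("cordti")))
  if (!is.null(result$regression))
    meta$regression <- result$regression[c("slope", "intercept",
                                           "r_squared", "n")]
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Wide mean +/- SD table, one row per region, tissue x metric columns.
format_summary_table <- function(summaries) {
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  regions <- unique(summaries$region)
  rows <- lapply(regions, function(r) {
    d <- summaries[summaries$region == r, ]
    out <- data.frame(region = r)
    for (tis in c("WM", "GM", "CSF")) {
      dd <- d[d$tissue == tis, ]
      out[[paste0(tis, "_MD")]] <- if (nrow(dd)) fmt(dd$md_mean, dd$md_sd)
        else NA_character_
      out[[paste0(tis, "_FA")]] <- if (nrow(dd)) fmt(dd$fa_mean, dd$fa_sd)
        else NA_character_
    }
    out
  })
  do.call(rbind, rows)
}

#' Type-I error calibration under the null
#'
#' Simulates pairs of regions with *identical* phantom parameters and
#' counts how often the pairwise Welch tests reject at the raw alpha
#' level. Under the null every rejection is a false positive, so across
#' replicates the rejection rate should sit near alpha; the binomial 95%
#' interval around alpha is returned for reference. One phantom geometry
#' is shared by all replicates (only the noise differs), which is what
#' "identically distributed" means here.
#'
#' @param n_replicates Number of replicate studies.
#' @param n_subjects Subjects per group (default 9).
#' @param region Phantom parameter set used for both groups.
#' @param shape Grid size (default reduced 32 x 32 x 8 for simulation
#'   studies).
#' @param snr Signal-to-noise ratio.
#' @param alpha Nominal level (default 0.05).
#' @param seed Base seed.
#' @return List with `rejection_rate`, `n_tests`, `n_rejections`,
#'   `binomial_ci` (95% bounds for the rate under the null), `alpha`, and
#'   `p_values`.
#' @export
null_study <- function(n_replicates = 200L, n_subjects = 9L,
                       region = "cervical", shape = c(32L, 32L, 8L),
                       snr = 20, alpha = 0.05, seed = 1L) {
  scheme <- make_gradient_scheme()
  phantom <- build_phantom(region, shape = shape,
                           seed = derive_seed(seed, 7L))
  clean <- noise_free_signal(phantom, scheme)
  pvals <- numeric(0)
  for (rep in seq_len(n_replicates)) {
    groups <- lapply(1:2, function(g) {
      lapply(seq_len(n_subjects), function(si) {
        sseed <- derive_seed(seed, rep * 10000L + g * 100L + si)
        analyze_subject(phantom, scheme, snr = snr, seed = sseed,
                        clean = clean)$centroids
      })
    })
    names(groups) <- c("group_a", "group_b")
    cmp <- compare_regions(groups)
    pvals <- c(pvals, cmp$p)
  }
  n_rej <- sum(pvals < alpha)
  n <- length(pvals)
  ci <- alpha + c(-1, 1) * stats::qnorm(0.975) * sqrt(alpha * (1 - alpha) / n)
  list(rejection_rate = n_rej / n, n_tests = n, n_rejections = n_rej,
       binomial_ci = ci, alpha = alpha, p_values = pvals)
}
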