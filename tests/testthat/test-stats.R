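test_that("subject centroids and regional summaries aggregate correctly", {
  nf <- fx_noisefree()
  model <- suppressWarnings(assign_tissues(restrict_clusters(
    kmeans_partition(nf$maps, seed = 1), 0.2)))
  cc <- subject_centroids(model)
  expect_setequal(cc$tissue, c("WM", "GM", "CSF"))
  # mean over retained WM voxels, recomputed directly
  wm_idx <- which(model$tissue == "WM")
  sel <- model$membership == wm_idx & model$retained
  expect_equal(cc$fa[cc$tissue == "WM"], mean(model$values$fa[sel]))
  expect_equal(cc$n_voxels[cc$tissue == "WM"], sum(sel))

  # constant input: SD 0; two subjects with FA 0.6 / 0.8 average to 0.7
  s1 <- data.frame(tissue = "WM", md = 1, fa = 0.6, n_voxels = 10)
  s2 <- data.frame(tissue = "WM", md = 1, fa = 0.8, n_voxels = 12)
  summ <- suppressWarnings(summarize_region(list(s1, s2), "cervical"))
  wm <- summ[summ$tissue == "WM", ]
  expect_equal(wm$fa_mean, 0.7)
  expect_equal(wm$md_sd, 0)
  expect_equal(wm$n_subjects, 2L)
  one <- suppressWarnings(summarize_region(list(s1), "x"))
  expect_equal(one$fa_sd[one$tissue == "WM"], NA_real_)

  # permutation invariance over subjects
  s3 <- data.frame(tissue = "WM", md = 1.2, fa = 0.7, n_voxels = 8)
  a <- suppressWarnings(summarize_region(list(s1, s2, s3), "r"))
  b <- suppressWarnings(summarize_region(list(s3, s1, s2), "r"))
  expect_equal(a, b)
})

test_that("Welch test matches an independent formula evaluation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  got <- welch_t_test(a, b)
  ref <- welch_by_hand(a, b)
  expect_equal(got$t, ref$t, tolerance = 1e-10)
  expect_equal(got$df, ref$df, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)

  set.seed(12)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), rnorm(1), runif(1, 0.5, 2))
    y <- rnorm(sample(3:20, 1), rnorm(1), runif(1, 0.5, 2))
    got <- welch_t_test(x, y)
    ref <- welch_by_hand(x, y)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("Welch test symmetry and degenerate inputs", {
  a <- c(1, 2, 3); b <- c(2, 4, 5, 7)
  ab <- welch_t_test(a, b); ba <- welch_t_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(0.01, m = 5), 0.05)
  expect_equal(bonferroni_correct(0.5, m = 10), 1.0)
  expect_equal(bonferroni_correct(0, m = 1000), 0)
  expect_equal(bonferroni_correct(c(0.001, 0.02), m = 18),
               c(0.018, 0.36))
  expect_error(bonferroni_correct(1.2, m = 2), "\\[0, 1\\]")
  expect_error(bonferroni_correct(c(0.1, 0.2), m = 1), "m must be")
})

test_that("WM FA regressed on GM area percentage explains the profile", {
  nv <- cord_normative_values()
  wm <- nv[nv$tissue == "WM", ]
  reg <- regress_fa_on_gm(wm$fa, wm$gm_area_percent)
  expect_equal(round(reg$r_squared, 3), 0.998)
  expect_lt(reg$slope, 0)    # more grey matter, lower cord-average WM FA

  # collinear points and two points give a perfect fit
  expect_equal(suppressWarnings(
    regress_fa_on_gm(c(1, 2, 3), c(10, 20, 30))$r_squared), 1)
  expect_equal(suppressWarnings(
    regress_fa_on_gm(c(0.7, 0.6), c(10, 30))$r_squared), 1)
  expect_error(regress_fa_on_gm(c(1, 2), c(5, 5)), "constant")
  expect_error(regress_fa_on_gm(c(1, 2), c(5, 5, 6)), "lengths")
})

test_that("pairwise regional comparisons assemble the full family", {
  set.seed(3)
  mk <- function(fa_shift = 0) lapply(1:5, function(i)
    data.frame(tissue = c("WM", "GM", "CSF"),
               md = c(0.97, 1.8, 3.0) + rnorm(3, 0, 0.02),
               fa = c(0.70 + fa_shift, 0.45, 0.10) + rnorm(3, 0, 0.01),
               n_voxels = 50L))
  byreg <- list(cervical = mk(), thoracic = mk(), lumbar = mk(-0.05))
  cmp <- compare_regions(byreg, m = 18)
  expect_equal(nrow(cmp), 18L)
  expect_equal(cmp$p_bonferroni, pmin(1, 18 * cmp$p))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))

  # the injected lumbar WM FA deficit is detected with the correct sign:
  # cervical minus lumbar positive
  row <- cmp[cmp$tissue == "WM" & cmp$metric == "FA" &
             cmp$region_a == "cervical" & cmp$region_b == "lumbar", ]
  expect_gt(row$t, 0)
  expect_lt(row$p, 0.05)

  # subjects missing a tissue drop out of that comparison only
  byreg2 <- byreg
  byreg2$cervical[[1]] <- byreg2$cervical[[1]][
    byreg2$cervical[[1]]$tissue != "CSF", ]
  cmp2 <- compare_regions(byreg2, m = 18)
  csf_row <- cmp2[cmp2$tissue == "CSF" & cmp2$region_a == "cervical" &
                  cmp2$region_b == "thoracic" & cmp2$metric == "MD", ]
  expect_equal(csf_row$n_a, 4L)
})

test_that("an injected regional WM FA deficit survives the full pipeline", {
  # two simulated groups, one with WM FA lowered by 0.05: the comparison
  # must come out with the correct sign
  sch <- fx_scheme()
  ph_a <- fx_phantom("cervical", shape = c(24L, 24L, 4L), seed = 3L)
  low <- default_tissue_models("cervical")
  low$WM <- tissue_model("WM", md = low$WM$md, fa = low$WM$fa - 0.05)
  ph_b <- build_phantom("cervical", shape = c(24, 24, 4), seed = 3,
                        tissues = low)
  groups <- list(
    normal = lapply(1:6, function(i)
      analyze_subject(ph_a, sch, snr = 20, seed = 100 + i)$centroids),
    lowered = lapply(1:6, function(i)
      analyze_subject(ph_b, sch, snr = 20, seed = 200 + i)$centroids))
  cmp <- compare_regions(groups)
  row <- cmp[cmp$tissue == "WM" & cmp$metric == "FA", ]
  expect_gt(row$t, 0)   # normal minus lowered
})
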