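test_that("noise-free fits invert the forward model exactly", {
  nf <- fx_noisefree()
  ph <- nf$phantom
  field <- nf$field
  expect_equal(sum(field$flag), 0L)

  fr <- matrix(ph$fractions, ncol = 3)
  roi_lin <- which(ph$roi)
  fit_lin <- (field$voxels$x - 1) + ph$shape[1] * (field$voxels$y - 1) +
    prod(ph$shape[1:2]) * (field$voxels$slice - 1) + 1

  for (t in 1:3) {
    tm <- ph$tissues[[t]]
    pure <- which(fr[, t] == 1)
    rows <- match(pure, fit_lin)
    rows <- rows[!is.na(rows)]
    expect_gt(length(rows), 0)
    D_true <- tm$tensor
    truth <- c(D_true[1, 1], D_true[2, 2], D_true[3, 3],
               D_true[1, 2], D_true[1, 3], D_true[2, 3])
    err <- abs(sweep(field$tensors[rows, , drop = FALSE], 2, truth))
    expect_lt(max(err) / max(abs(truth)), 1e-8)
    expect_equal(field$s0[rows], rep(1000, length(rows)), tolerance = 1e-8)
  }
})

test_that("constant signal fits to the zero tensor", {
  sch <- fx_scheme()
  sig <- array(500, dim = c(3, 3, 1, length(sch$bvals)))
  dwi <- cordti:::new_dwi_volume(sig, sch, c(1.2, 1.2, 3))
  field <- fit_tensor_field(dwi, array(TRUE, dim = c(3, 3, 1)))
  expect_equal(max(abs(field$tensors)), 0, tolerance = 1e-10)
  expect_equal(field$s0, rep(500, 9), tolerance = 1e-10)
})

test_that("nonpositive signals are clamped and flagged, not dropped", {
  sch <- fx_scheme()
  sig <- array(500, dim = c(2, 1, 1, length(sch$bvals)))
  sig[1, 1, 1, 3] <- 0
  dwi <- cordti:::new_dwi_volume(sig, sch, c(1.2, 1.2, 3))
  field <- fit_tensor_field(dwi, array(TRUE, dim = c(2, 1, 1)))
  expect_identical(field$flag, c(TRUE, FALSE))
  expect_true(all(is.finite(field$tensors)))
})

test_that("closed-form eigenvalues match the eigen() oracle", {
  # diagonal and rotated similarity cases
  ev <- eigendecompose(matrix(c(1.7, 0.5, 0.5, 0, 0, 0), nrow = 1))
  expect_equal(drop(ev), c(1.7, 0.5, 0.5), ignore_attr = TRUE)

  R <- qr.Q(qr(matrix(c(2, -1, 0.5, 1, 3, -2, 0, 1, 1), 3, 3)))
  D <- R %*% diag(c(1.7, 0.5, 0.5)) %*% t(R)
  ev2 <- eigendecompose(matrix(c(D[1, 1], D[2, 2], D[3, 3],
                                 D[1, 2], D[1, 3], D[2, 3]), nrow = 1))
  expect_equal(drop(ev2), c(1.7, 0.5, 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 100 random symmetric tensors against base eigen(), plus trace identity
  set.seed(5)
  M <- matrix(rnorm(600), 100, 6)
  got <- eigendecompose(M)
  for (i in 1:100) {
    D <- matrix(c(M[i, 1], M[i, 4], M[i, 5],
                  M[i, 4], M[i, 2], M[i, 6],
                  M[i, 5], M[i, 6], M[i, 3]), 3, 3)
    expect_equal(unname(got[i, ]), eigen(D, symmetric = TRUE,
                                         only.values = TRUE)$values,
                 tolerance = 1e-9)
    expect_equal(sum(got[i, ]), sum(diag(D)), tolerance = 1e-9)
  }
  expect_true(all(got[, 1] >= got[, 2] & got[, 2] >= got[, 3]))
})

test_that("non-finite tensors yield NA spectra", {
  ev <- eigendecompose(matrix(c(NA, 1, 1, 0, 0, 0), nrow = 1))
  expect_true(all(is.na(ev)))
})

test_that("MD is the eigenvalue mean and scales linearly", {
  expect_equal(compute_md(c(1, 1, 1)), 1)
  expect_equal(compute_md(c(1.7, 0.5, 0.5)), 0.9)
  expect_equal(compute_md(c(3, 3, 3)), 3)
  ev <- c(1.9, 0.6, 0.2)
  for (c0 in c(0.1, 10))
    expect_equal(compute_md(c0 * ev), c0 * compute_md(ev))
})

test_that("FA hits its closed-form limits and is scale-invariant", {
  expect_identical(compute_fa(c(1, 1, 1)), 0)
  expect_identical(compute_fa(c(1, 0, 0)), 1)
  # independent direct evaluation of the FA formula for (1.7, 0.5, 0.5):
  # mean 0.9; deviations (0.8, -0.4, -0.4); sum sq 0.96; norm sq 3.39
  expect_equal(compute_fa(c(1.7, 0.5, 0.5)), sqrt(1.5 * 0.96 / 3.39),
               tolerance = 1e-12)
  expect_equal(compute_fa(c(1.7, 0.5, 0.5)), 0.6518, tolerance = 1e-4)
  ev <- c(1.9, 0.6, 0.2)
  for (c0 in c(0.1, 10))
    expect_equal(compute_fa(c0 * ev), compute_fa(ev), tolerance = 1e-12)
  expect_true(is.na(compute_fa(c(0, 0, 0))))
})

test_that("scalar maps conserve the masked voxel set and pure-tissue values", {
  nf <- fx_noisefree()
  maps <- nf$maps
  expect_s3_class(maps, "scalar_maps")
  expect_identical(nrow(maps$values), sum(nf$phantom$roi))

  fr <- matrix(nf$phantom$fractions, ncol = 3)
  lin <- (maps$values$x - 1) + nf$phantom$shape[1] * (maps$values$y - 1) +
    prod(nf$phantom$shape[1:2]) * (maps$values$slice - 1) + 1
  for (t in 1:3) {
    tm <- nf$phantom$tissues[[t]]
    rows <- which(fr[lin, t] == 1)
    expect_gt(length(rows), 0)
    expect_lt(max(abs(maps$values$fa[rows] - tm$fa)), 1e-6)
    expect_lt(max(abs(maps$values$md[rows] - tm$md)), 1e-6)
    # identical tensors give identical indices
    expect_lt(diff(range(maps$values$fa[rows])), 1e-8)
  }
})

test_that("median pure-WM FA at SNR 20 stays near the generator value", {
  ph <- fx_phantom("cervical", shape = c(32L, 32L, 8L), seed = 1L)
  sch <- fx_scheme()
  fr <- matrix(ph$fractions, ncol = 3)
  med <- vapply(1:3, function(s) {
    dwi <- simulate_dwi(ph, sch, snr = 20, seed = s)
    maps <- make_scalar_maps(fit_tensor_field(dwi))
    lin <- (maps$values$x - 1) + ph$shape[1] * (maps$values$y - 1) +
      prod(ph$shape[1:2]) * (maps$values$slice - 1) + 1
    stats::median(maps$values$fa[fr[lin, 1] == 1])
  }, numeric(1))
  expect_lt(abs(mean(med) - ph$tissues$WM$fa), 0.05)
})

test_that("weighted refit recovers a single-tensor signal exactly", {
  # pure monoexponential data: OLS and WLS must agree with the truth,
  # since the fit is exact regardless of weighting
  sch <- fx_scheme()
  wm <- tissue_model("WM", md = 0.97, fa = 0.70)
  atten <- vapply(seq_along(sch$bvals), function(i) {
    g <- sch$bvecs[, i]
    exp(-(sch$bvals[i] / 1000) * drop(t(g) %*% wm$tensor %*% g))
  }, numeric(1))
  sig <- array(rep(800 * atten, each = 4), dim = c(2, 2, 1, length(atten)))
  dwi <- cordti:::new_dwi_volume(sig, sch, c(1.2, 1.2, 3))
  truth <- c(wm$tensor[1, 1], wm$tensor[2, 2], wm$tensor[3, 3],
             wm$tensor[1, 2], wm$tensor[1, 3], wm$tensor[2, 3])
  for (w in c(FALSE, TRUE)) {
    f <- fit_tensor_field(dwi, array(TRUE, dim = c(2, 2, 1)), weighted = w)
    expect_lt(max(abs(sweep(f$tensors, 2, truth))), 1e-8)
    expect_equal(f$s0, rep(800, 4), tolerance = 1e-8)
  }
})
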