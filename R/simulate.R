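# Forward simulation: monoexponential tensor signal with signal-fraction
# partial-volume mixing, plus Rician (magnitude) noise.

#' Noise-free diffusion-weighted signal for a phantom
#'
#' For volume i with b-value b_i and direction g_i, the voxel signal is
#' `S0 * sum_t f_t * exp(-b_i g_i' D_t g_i)` over the tissue compartments t
#' (signals mix, not tensors: each compartment decays with its own tensor,
#' which is what produces the continuum of intermediate FA/MD values at
#' tissue interfaces). Voxels partially outside the canal lose the
#' background share of their signal.
#'
#' @param phantom A [build_phantom()] object.
#' @param scheme A [make_gradient_scheme()] scheme.
#' @param s0 Unweighted (b = 0) signal of a pure voxel, arbitrary units.
#' @return 4-D array (x, y, slice, volume) of noise-free signals.
#' @export
noise_free_signal <- function(phantom, scheme, s0 = 1000) {
  stopifnot(inherits(phantom, "cord_phantom"),
            inherits(scheme, "gradient_scheme"))
  atten <- tissue_attenuation(phantom$tissues, scheme)   # 3 x nvol
  d <- dim(phantom$fractions)
  nvol <- length(scheme$bvals)
  flat <- matrix(phantom$fractions, ncol = 3L)           # nvox x 3
  sig <- s0 * (flat %*% atten)                           # nvox x nvol
  array(sig, dim = c(d[1:3], nvol))
}

# Per-tissue attenuation exp(-b g' D g) for every volume; b in s/mm^2 and
# D in 1e-3 mm^2/s, so the exponent uses b/1000.
tissue_attenuation <- function(tissues, scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals / 1000
  t(vapply(tissues, function(tm) {
    quad <- colSums(g * (tm$tensor %*% g))
    exp(-b * quad)
  }, numeric(length(b))))
}

#' Add Rician noise to a signal array
#'
#' MRI magnitude noise: the modulus of the complex signal after independent
#' Gaussian perturbation of both quadrature channels,
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, sigma^2)`.
#'
#' @param signal Numeric array of noise-free magnitudes.
#' @param sigma Gaussian channel noise standard deviation (> 0).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return Array of the same shape, all values >= 0.
#' @export
add_rician_noise <- function(signal, sigma, seed) {
  if (sigma <= 0) stopf("sigma must be positive")
  n <- length(signal)
  with_seed(seed, {
    e1 <- stats::rnorm(n, 0, sigma)
    e2 <- stats::rnorm(n, 0, sigma)
    array(sqrt((signal + e1)^2 + e2^2), dim = dim(signal))
  })
}

#' Simulate a diffusion-weighted acquisition of a cord phantom
#'
#' Evaluates the noise-free partial-volume tensor signal
#' ([noise_free_signal()]) and corrupts it with Rician noise. SNR is
#' defined as the b = 0 signal of a pure white-matter voxel (`s0`) divided
#' by the Gaussian channel noise sigma; `snr = Inf` yields noise-free data.
#'
#' @param phantom A [build_phantom()] object.
#' @param scheme A [make_gradient_scheme()] scheme.
#' @param snr Signal-to-noise ratio (> 0, possibly `Inf`). Default 20, a
#'   plausible figure for gated single-shot spinal EPI.
#' @param seed Integer seed for the noise draw.
#' @param s0 b = 0 signal of a pure voxel, arbitrary units.
#' @return Object of class `dwi_volume`: `signal` (4-D array, x, y, slice,
#'   volume), `scheme`, `voxel`, `s0`, `snr`, `seed`, and `phantom` (the
#'   ground-truth reference).
#' @examples
#' ph <- build_phantom("cervical", shape = c(16, 16, 2), seed = 1)
#' dwi <- simulate_dwi(ph, make_gradient_scheme(20, 700), snr = 20, seed = 1)
#' dim(dwi$signal)
#' @export
simulate_dwi <- function(phantom, scheme, snr = 20, seed = 1L, s0 = 1000) {
  if (snr <= 0) stopf("snr must be positive")
  clean <- noise_free_signal(phantom, scheme, s0)
  signal <- if (is.finite(snr))
    add_rician_noise(clean, s0 / snr, seed) else clean
  new_dwi_volume(signal, scheme, phantom$voxel, s0 = s0, snr = snr,
                 seed = seed, phantom = phantom)
}

new_dwi_volume <- function(signal, scheme, voxel, s0 = NA_real_,
                           snr = NA_real_, seed = NA_integer_,
                           phantom = NULL) {
  stopifnot(length(dim(signal)) == 4L,
            dim(signal)[4] == length(scheme$bvals))
  if (any(signal < 0)) stopf("negative signal values")
  structure(list(signal = signal, scheme = scheme,
                 voxel = as.numeric(voxel), s0 = s0, snr = snr,
                 seed = seed, phantom = phantom),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("dwi_volume: %d x %d x %d grid, %d volumes, SNR %s\n",
              d[1], d[2], d[3], d[4],
              if (is.finite(x$snr)) format(x$snr) else "Inf (noise-free)"))
  invisible(x)
}
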