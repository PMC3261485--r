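# Shared fixtures, memoized so expensive phantoms are built once per run.

.fx <- new.env(parent = emptyenv())

fx_scheme <- function() {
  if (is.null(.fx$scheme)) .fx$scheme <- make_gradient_scheme(20, 700)
  .fx$scheme
}

fx_phantom <- function(region = "cervical", shape = c(24L, 24L, 4L),
                       seed = 1L, ...) {
  key <- paste(region, paste(shape, collapse = "x"), seed,
               paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fx[[key]]))
    .fx[[key]] <- build_phantom(region, shape = shape, seed = seed, ...)
  .fx[[key]]
}

# Noise-free analysis of the default-geometry (cervical) phantom.
fx_noisefree <- function() {
  if (is.null(.fx$noisefree)) {
    ph <- fx_phantom("cervical", shape = c(32L, 32L, 8L), seed = 1L)
    dwi <- simulate_dwi(ph, fx_scheme(), snr = Inf, seed = 1L)
    field <- fit_tensor_field(dwi)
    maps <- make_scalar_maps(field)
    .fx$noisefree <- list(phantom = ph, dwi = dwi, field = field,
                          maps = maps)
  }
  .fx$noisefree
}

# Wrap bare (md, fa) points in a scalar_maps object so feature-space
# operations can be tested on synthetic point sets.
as_maps <- function(md, fa) {
  n <- length(md)
  structure(list(
    values = data.frame(x = seq_len(n), y = 1L, slice = 1L,
                        md = md, fa = fa, flag = FALSE),
    shape = c(n, 1L, 1L), voxel = c(1, 1, 1)
  ), class = "scalar_maps")
}

# Three well-separated Gaussian blobs in (md, fa); returns maps + truth.
blob_maps <- function(n_per = 100L, sd = 0.05, seed = 42L,
                      centers = rbind(c(0.97, 0.70), c(1.8, 0.45),
                                      c(3.0, 0.1))) {
  set.seed(seed)
  md <- fa <- numeric(0)
  truth <- integer(0)
  for (i in seq_len(nrow(centers))) {
    md <- c(md, rnorm(n_per, centers[i, 1], sd))
    fa <- c(fa, rnorm(n_per, centers[i, 2], sd))
    truth <- c(truth, rep(i, n_per))
  }
  list(maps = as_maps(md, fa), truth = truth, centers = centers)
}

# Exhaustive k-means oracle: global minimum within-cluster sum of squares
# over all assignments of n points to k non-empty clusters (n small).
exact_kmeans_ss <- function(X, k = 3L) {
  n <- nrow(X)
  stopifnot(n <= 12L)
  best <- Inf
  for (code in 0:(k^n - 1L)) {
    lab <- integer(n)
    c0 <- code
    for (i in seq_len(n)) { lab[i] <- c0 %% k; c0 <- c0 %/% k }
    if (lab[1] != 0L) next              # fix first point's label (symmetry)
    if (length(unique(lab)) < k) next
    ss <- 0
    for (j in 0:(k - 1L)) {
      P <- X[lab == j, , drop = FALSE]
      ss <- ss + sum(sweep(P, 2, colMeans(P))^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# Textbook Welch statistic, computed independently of the package path.
welch_by_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
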