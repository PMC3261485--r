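# Gradient schemes: diffusion directions and b-values for one acquisition.

#' Construct a diffusion gradient scheme
#'
#' Builds a `gradient_scheme`: `n_directions` diffusion-sensitizing unit
#' vectors at b-value `b` plus one unweighted (b = 0) measurement, the
#' sampling used for single-shell spinal DTI. Directions come from a fixed
#' point set spread approximately uniformly over the hemisphere (a
#' spherical Fibonacci lattice polished by electrostatic repulsion), so the
#' scheme is fully deterministic; the 20-direction set ships with the
#' package as a versioned fixture.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6; six
#'   noncollinear directions are the minimum that determines the tensor).
#' @param b Diffusion weighting in s/mm^2 (> 0). The default 700 s/mm^2 is
#'   typical for cord imaging, where SNR is lower than in the brain.
#' @return An object of class `gradient_scheme` with elements `bvals`
#'   (length `n_directions + 1`, first entry 0) and `bvecs`
#'   (3 x (`n_directions + 1`) matrix of unit columns; zero column for
#'   b = 0).
#' @examples
#' sch <- make_gradient_scheme(20, 700)
#' colSums(sch$bvecs^2)
#' @seealso [read_gradients()], [write_gradients()]
#' @export
make_gradient_scheme <- function(n_directions = 20L, b = 700) {
  if (n_directions < 6L) stopf("tensor underdetermined: need >= 6 directions, got %d",
                               n_directions)
  if (b <= 0) stopf("b must be positive")
  dirs <- if (n_directions == 20L) shipped_directions20()
          else hemisphere_points(n_directions)
  bvecs <- cbind(0, t(dirs))
  bvals <- c(0, rep(b, n_directions))
  new_gradient_scheme(bvals, bvecs)
}

new_gradient_scheme <- function(bvals, bvecs) {
  stopifnot(is.matrix(bvecs), nrow(bvecs) == 3L, length(bvals) == ncol(bvecs))
  if (any(bvals < 0)) stopf("negative b-value")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-8
  if (any(bad)) stopf("non-unit direction at volume %d", which(bad)[1])
  if (any(bvals == 0 & nrm > 1e-8)) stopf("nonzero direction with b = 0")
  structure(list(bvals = as.numeric(bvals), bvecs = unname(bvecs)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient_scheme: %d volumes (%d at b = 0, %d weighted, b = %s s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = "/")))
  invisible(x)
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

# Deterministic, approximately uniform unit vectors on the upper hemisphere:
# spherical Fibonacci lattice start, then a few hundred steps of projected
# gradient descent on the (antipodally symmetrized) Coulomb energy, which is
# the classic electrostatic-repulsion construction for DTI schemes.
hemisphere_points <- function(n, iters = 300L, step = 0.05) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n                      # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  for (it in seq_len(iters)) {
    force <- matrix(0, n, 3)
    for (j in seq_len(n)) {
      d1 <- sweep(p[-j, , drop = FALSE], 2, p[j, ], "-")   # to p_j
      d2 <- sweep(-p[-j, , drop = FALSE], 2, p[j, ], "-")  # to antipodes
      w1 <- pmax(rowSums(d1^2), 1e-6)
      w2 <- pmax(rowSums(d2^2), 1e-6)
      force[j, ] <- -colSums(d1 / w1^1.5) - colSums(d2 / w2^1.5)
    }
    p <- p + step * force / n
    p <- p / sqrt(rowSums(p^2))
  }
  p[p[, 3] < 0, ] <- -p[p[, 3] < 0, , drop = FALSE]  # canonical hemisphere
  p
}

shipped_directions20 <- function() {
  path <- system.file("extdata", "directions20.txt", package = "cordti",
                      mustWork = TRUE)
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  m / sqrt(rowSums(m^2))
}

#' Tensor-fit design matrix for a gradient scheme
#'
#' Rows are `(1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz,
#' -2b gy gz)` with b rescaled to units of 10^3 s/mm^2 so that the fitted
#' tensor comes out in 10^-3 mm^2/s; the leading 1 absorbs log(S0).
#'
#' @param scheme A `gradient_scheme`.
#' @return A numeric matrix with one row per volume and 7 columns.
#' @export
design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$bvals / 1000   # pairs with diffusivities in 1e-3 mm^2/s
  g <- scheme$bvecs
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Read an FSL-dialect gradient table
#'
#' `bvals` holds one whitespace-separated row of b-values; `bvecs` holds
#' three rows (x, y, z components), one column per volume. Near-unit
#' vectors are renormalized; deviations beyond 1% are rejected.
#'
#' @param bvals_path,bvecs_path Paths to the two text files.
#' @return A `gradient_scheme`.
#' @export
read_gradients <- function(bvals_path, bvecs_path) {
  bvals <- scan_numeric_table(bvals_path, 1L)
  bvecs <- scan_numeric_table(bvecs_path, 3L)
  if (length(bvals) != ncol(bvecs))
    stopf("gradient table mismatch: %d b-values but %d directions",
          length(bvals), ncol(bvecs))
  nrm <- sqrt(colSums(bvecs^2))
  weighted <- bvals > 0
  if (any(weighted & nrm < 1e-8))
    stopf("zero direction with nonzero b at volume %d",
          which(weighted & nrm < 1e-8)[1])
  if (any(weighted & abs(nrm - 1) > 1e-2))
    stopf("direction norm deviates more than 1%% from unit at volume %d",
          which(weighted & abs(nrm - 1) > 1e-2)[1])
  bvecs[, weighted] <- sweep(bvecs[, weighted, drop = FALSE], 2,
                             nrm[weighted], "/")
  bvecs[, !weighted] <- 0
  new_gradient_scheme(as.numeric(bvals), bvecs)
}

scan_numeric_table <- function(path, expect_rows) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != expect_rows)
    stopf("%s: expected %d nonempty lines, found %d", path, expect_rows,
          length(lines))
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v)) stopf("%s: non-numeric entry on line %d", path, i)
    v
  })
  if (length(unique(lengths(rows))) != 1L)
    stopf("%s: ragged rows", path)
  m <- do.call(rbind, rows)
  if (expect_rows == 1L) as.numeric(m) else m
}

#' Write an FSL-dialect gradient table
#'
#' @param scheme A `gradient_scheme`.
#' @param bvals_path,bvecs_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradients <- function(scheme, bvals_path, bvecs_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}
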