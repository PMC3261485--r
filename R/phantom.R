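# Synthetic cord phantom: an elliptical cord (WM annulus around a GM
# "butterfly") inside a CSF-filled canal, voxelized with sub-voxel
# supersampling so tissue interfaces carry partial-volume fractions.

#' Build a synthetic spinal cord phantom
#'
#' Constructs a voxelized cross-sectional model of one cord region: a
#' central grey-matter butterfly (two lateral wing lobes joined by a
#' commissural bridge, echoing the dorsal/ventral horn shape) inside an
#' elliptical white-matter cord, surrounded by a CSF rim, all inside an
#' otherwise signal-free background. The butterfly is scaled by bisection
#' until grey matter occupies `gm_fraction` percent of the cord
#' cross-section (the fraction differs by region: cervical 18%, thoracic
#' 13.2%, lumbar 36.3%). Per-voxel tissue fractions are computed by 5 x 5
#' in-plane supersampling, so voxels straddling an interface carry mixed
#' fractions. A small deterministic sinusoidal center wobble (phase from
#' `seed`) displaces the cord from slice to slice so boundary voxels differ
#' between slices.
#'
#' @param region `"cervical"`, `"thoracic"` or `"lumbar"`; selects the
#'   default tissue tensors and (if `gm_fraction` is missing) the
#'   grey-matter area percentage.
#' @param shape Grid dimensions `c(nx, ny, nslices)`.
#' @param gm_fraction Target grey-matter share of the cord cross-section,
#'   in percent (0, 100).
#' @param seed Integer seed (wobble phase; the geometry is otherwise
#'   deterministic).
#' @param voxel Voxel size in mm, `c(dx, dy, dz)`.
#' @param cord_radii Cord ellipse semi-axes (left-right,
#'   anterior-posterior) in mm.
#' @param csf_rim CSF rim thickness around the cord in mm.
#' @param tissues Named list of three [tissue_model()] objects; defaults to
#'   [default_tissue_models()] for the region.
#' @param supersample In-plane subdivisions per voxel axis for fraction
#'   estimation.
#' @return Object of class `cord_phantom`: `fractions` (4-D array
#'   x,y,slice,tissue with tissue order WM/GM/CSF; sums to 1 inside the
#'   canal, < 1 on canal-edge voxels, 0 outside), `labels` (integer array,
#'   0 background, 1 WM, 2 GM, 3 CSF by dominant fraction), `roi` (logical
#'   array: voxel center inside the canal — the analysis mask, as a drawn
#'   cord ROI would include the cord edge), `canal` (logical array: voxels
#'   fully inside the canal), `tissues`, `region`, `shape`, `voxel`,
#'   `gm_fraction` (requested, %), `realized_gm_fraction` (%), `seed`.
#' @examples
#' ph <- build_phantom("cervical", shape = c(24, 24, 2), seed = 1)
#' ph$realized_gm_fraction
#' @export
build_phantom <- function(region = c("cervical", "thoracic", "lumbar"),
                          shape = c(64L, 64L, 28L), gm_fraction = NULL,
                          seed = 1L, voxel = c(1.2, 1.2, 3.0),
                          cord_radii = NULL, csf_rim = 1.8,
                          tissues = NULL, supersample = 5L) {
  region <- match.arg(region)
  stopifnot(length(shape) == 3L, all(shape[1:2] >= 8L), shape[3] >= 1L,
            length(voxel) == 3L,
            all(voxel > 0), supersample >= 1L)
  if (is.null(gm_fraction)) gm_fraction <- gm_area_percent(region)
  if (gm_fraction <= 0 || gm_fraction >= 100)
    stopf("gm_fraction must lie in (0, 100) percent")
  if (is.null(cord_radii))
    cord_radii <- switch(region,
                         cervical = c(6.5, 4.2),
                         thoracic = c(5.0, 4.0),
                         lumbar   = c(5.2, 4.4))
  if (is.null(tissues)) tissues <- default_tissue_models(region)
  stopifnot(setequal(names(tissues), c("WM", "GM", "CSF")))
  if (2 * cord_radii[1] / voxel[1] < 8)
    warnf("cord diameter below 8 voxels; partial-volume dominated phantom")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  fov <- c(nx * voxel[1], ny * voxel[2])
  canal_radii <- cord_radii + csf_rim
  if (any(2 * canal_radii >= fov))
    stopf("cord (canal %.1f x %.1f mm) does not fit in the %g x %g mm grid",
          2 * canal_radii[1], 2 * canal_radii[2], fov[1], fov[2])

  # butterfly scale calibrated on a centered cross-section; the wobble only
  # translates the shapes so the realized fraction is unchanged up to
  # voxelization
  scale <- calibrate_gm_scale(gm_fraction / 100, cord_radii, voxel[1:2],
                              c(nx, ny), supersample)

  # slice-to-slice center wobble: deterministic sinusoid, phase from seed,
  # amplitude a fraction of a voxel (the cord is never straight in the canal)
  phase <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  sl <- seq_len(nz)
  wobble <- cbind(0.3 * voxel[1] * sin(2 * pi * sl / max(nz, 8) + phase[1]),
                  0.3 * voxel[2] * sin(2 * pi * sl / max(nz, 11) + phase[2]))

  fractions <- array(0, dim = c(nx, ny, nz, 3L))
  canal <- array(FALSE, dim = c(nx, ny, nz))
  roi <- array(FALSE, dim = c(nx, ny, nz))
  for (z in sl) {
    fr <- slice_fractions(cord_radii, csf_rim, scale, voxel[1:2],
                          c(nx, ny), supersample, center = wobble[z, ])
    fractions[, , z, ] <- fr$fractions
    canal[, , z] <- fr$canal
    roi[, , z] <- fr$roi
  }

  cord <- fractions[, , , 1] + fractions[, , , 2]
  realized <- 100 * sum(fractions[, , , 2]) / sum(cord)
  labels <- apply_labels(fractions)

  structure(list(
    fractions = fractions, labels = labels, roi = roi, canal = canal,
    tissues = tissues[c("WM", "GM", "CSF")], region = region,
    shape = as.integer(shape), voxel = as.numeric(voxel),
    cord_radii = cord_radii, csf_rim = csf_rim, gm_scale = scale,
    gm_fraction = gm_fraction, realized_gm_fraction = realized,
    seed = as.integer(seed)
  ), class = "cord_phantom")
}

#' @export
print.cord_phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "cord_phantom: %s region, %d x %d x %d grid (%.1f x %.1f x %.1f mm voxels)\n",
    "  GM fraction %.1f%% requested, %.1f%% realized; %d ROI voxels\n"),
    x$region, x$shape[1], x$shape[2], x$shape[3],
    x$voxel[1], x$voxel[2], x$voxel[3],
    x$gm_fraction, x$realized_gm_fraction, sum(x$roi)))
  invisible(x)
}

# Dominant-fraction labels: 0 background, 1 WM, 2 GM, 3 CSF.
apply_labels <- function(fractions) {
  d <- dim(fractions)
  flat <- matrix(fractions, ncol = 3L)
  lab <- max.col(flat, ties.method = "first")
  lab[rowSums(flat) == 0] <- 0L
  array(as.integer(lab), dim = d[1:3])
}

# Sub-voxel sample offsets (voxel units, centered on 0) for one axis.
subgrid_offsets <- function(supersample) {
  (seq_len(supersample) - (supersample + 1) / 2) / supersample
}

# Fraction maps for one slice: classify supersampled in-plane points
# against the analytic shapes and average within each voxel.
slice_fractions <- function(cord_radii, csf_rim, gm_scale, voxel, n,
                            supersample, center = c(0, 0)) {
  off <- subgrid_offsets(supersample)
  # voxel centers in mm, grid centered on the field of view
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * voxel[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * voxel[2]
  sx <- rep(cx, each = supersample) + rep(off * voxel[1], times = n[1])
  sy <- rep(cy, each = supersample) + rep(off * voxel[2], times = n[2])
  X <- matrix(rep(sx, times = length(sy)), nrow = length(sx)) - center[1]
  Y <- matrix(rep(sy, each = length(sx)), nrow = length(sx)) - center[2]

  cls <- classify_points(X, Y, cord_radii, csf_rim, gm_scale)
  # reduce supersample x supersample blocks to per-voxel fractions
  frac <- vapply(1:3, function(t) {
    m <- matrix(as.numeric(cls == t), nrow = nrow(cls))
    block_mean(m, supersample)
  }, matrix(0, n[1], n[2]))
  canal_cov <- block_mean(matrix(as.numeric(cls > 0), nrow = nrow(cls)),
                          supersample)

  # center-in-canal test for the ROI (what a rater outlining the cord edge
  # on a b0 image would include)
  ctrX <- outer(cx, rep(1, n[2])) - center[1]
  ctrY <- outer(rep(1, n[1]), cy) - center[2]
  roi <- in_ellipse(ctrX, ctrY, cord_radii + csf_rim)

  list(fractions = array(c(frac), dim = c(n[1], n[2], 3L)),
       canal = canal_cov >= 1 - 1e-12,
       roi = roi)
}

block_mean <- function(m, s) {
  # m is (nx*s) x (ny*s); average disjoint s x s blocks
  nx <- nrow(m) / s; ny <- ncol(m) / s
  m1 <- rowsum(m, rep(seq_len(nx), each = s), reorder = FALSE)
  t(rowsum(t(m1), rep(seq_len(ny), each = s), reorder = FALSE)) / s^2
}

in_ellipse <- function(x, y, radii, center = c(0, 0)) {
  ((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 <= 1
}

# Point classification: 0 background, 1 WM, 2 GM, 3 CSF. The GM butterfly
# is two dorsoventrally elongated wing ellipses at +/- 0.40 a_x plus a
# central bridge ellipse, all scaled by `s` and clipped to the cord.
classify_points <- function(x, y, cord_radii, csf_rim, s) {
  ax <- cord_radii[1]; ay <- cord_radii[2]
  gm <- in_ellipse(x, y, c(0.25 * ax * s, 0.60 * ay * s),
                   center = c(-0.40 * ax * s, 0)) |
        in_ellipse(x, y, c(0.25 * ax * s, 0.60 * ay * s),
                   center = c(0.40 * ax * s, 0)) |
        in_ellipse(x, y, c(0.45 * ax * s, 0.18 * ay * s))
  cord <- in_ellipse(x, y, cord_radii)
  canal <- in_ellipse(x, y, cord_radii + csf_rim)
  out <- array(0L, dim = dim(x))
  out[canal] <- 3L
  out[cord] <- 1L
  out[cord & gm] <- 2L
  out
}

# Bisection on the butterfly scale so GM / (GM + WM) area hits the target.
calibrate_gm_scale <- function(target, cord_radii, voxel, n, supersample) {
  frac_at <- function(s) {
    fr <- slice_fractions(cord_radii, 0.0, s, voxel, n, supersample)$fractions
    sum(fr[, , 2]) / sum(fr[, , 1] + fr[, , 2])
  }
  lo <- 0.05; hi <- 2.2
  f_hi <- frac_at(hi)
  if (f_hi < target)
    stopf("target GM fraction %.1f%% exceeds the butterfly's maximum (%.1f%%)",
          100 * target, 100 * f_hi)
  for (i in 1:36) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
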