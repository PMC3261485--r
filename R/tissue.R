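# Per-tissue diffusion models: one cigar- or sphere-shaped tensor per
# compartment, parameterized by its target MD/FA rather than by raw
# eigenvalues so phantom defaults can be read straight off normative
# centroid tables.

#' Axially symmetric eigenvalues with prescribed MD and FA
#'
#' For a prolate tensor with eigenvalues (m + 2d, m - d, m - d), mean
#' diffusivity is m and FA = 3d / sqrt(3 m^2 + 6 d^2), which inverts to
#' d = FA m / sqrt(3 - 2 FA^2). Used to construct tissue tensors whose
#' scalar indices hit requested targets exactly.
#'
#' @param md Target mean diffusivity (10^-3 mm^2/s, > 0).
#' @param fa Target fractional anisotropy in [0, 1).
#' @return Descending eigenvalue triple (10^-3 mm^2/s).
#' @examples
#' axial_eigenvalues(0.97, 0.70)
#' @export
axial_eigenvalues <- function(md, fa) {
  if (md <= 0) stopf("md must be positive")
  if (fa < 0 || fa >= 1) stopf("fa must lie in [0, 1)")
  d <- fa * md / sqrt(3 - 2 * fa^2)
  ev <- c(md + 2 * d, md - d, md - d)
  if (any(ev <= 0)) stopf("md/fa combination gives nonpositive eigenvalues")
  ev
}

#' Single-tissue diffusion tensor model
#'
#' An axially symmetric diffusion tensor for one tissue compartment. White
#' and grey matter default to anisotropic tensors whose principal axis runs
#' along the cord (the slice-select z axis); CSF is near-isotropic and
#' fast-diffusing.
#'
#' @param name Tissue name: `"WM"`, `"GM"` or `"CSF"`.
#' @param md,fa Target mean diffusivity (10^-3 mm^2/s) and fractional
#'   anisotropy of the tensor.
#' @param axis Principal diffusion axis (3-vector, need not be unit).
#' @return Object of class `tissue_model`: `name`, `eigenvalues`
#'   (descending), `axis` (unit), `tensor` (3 x 3, 10^-3 mm^2/s), `md`,
#'   `fa`.
#' @examples
#' wm <- tissue_model("WM", md = 0.97, fa = 0.70)
#' mean(wm$eigenvalues)   # = md
#' @export
tissue_model <- function(name = c("WM", "GM", "CSF"), md, fa,
                         axis = c(0, 0, 1)) {
  name <- match.arg(name)
  if (missing(md) || missing(fa)) {
    def <- default_tissue_params("cervical")[[name]]
    if (missing(md)) md <- def$md
    if (missing(fa)) fa <- def$fa
  }
  stopifnot(length(axis) == 3L, any(axis != 0))
  axis <- axis / sqrt(sum(axis^2))
  ev <- axial_eigenvalues(md, fa)
  R <- rotation_to(axis)
  # principal eigenvalue on the frame's third column, which is the axis
  D <- R %*% diag(ev[c(2, 3, 1)]) %*% t(R)
  structure(list(name = name, eigenvalues = ev, axis = axis,
                 tensor = (D + t(D)) / 2, md = md, fa = fa),
            class = "tissue_model")
}

# Rotation taking the z axis onto `axis` (any completion of the frame works:
# only the image of z matters for an axially symmetric tensor).
rotation_to <- function(axis) {
  z <- axis / sqrt(sum(axis^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

# Default per-region tissue parameters. WM and GM take the region's
# normative centroids; the CSF compartment is modelled as near-isotropic
# free water (MD 3.0, FA 0.05) - the higher FA of *measured* CSF clusters
# arises from noise and partial volume, which the simulation adds on top.
default_tissue_params <- function(region) {
  nv <- cord_normative_values()
  nv <- nv[nv$region == region, ]
  list(
    WM  = list(md = nv$md[nv$tissue == "WM"], fa = nv$fa[nv$tissue == "WM"]),
    GM  = list(md = nv$md[nv$tissue == "GM"], fa = nv$fa[nv$tissue == "GM"]),
    CSF = list(md = 3.0, fa = 0.05)
  )
}

#' Default tissue models for a cord region
#'
#' @param region One of `"cervical"`, `"thoracic"`, `"lumbar"`.
#' @return Named list of three [tissue_model()] objects (WM, GM, CSF).
#' @export
default_tissue_models <- function(region = c("cervical", "thoracic", "lumbar")) {
  region <- match.arg(region)
  p <- default_tissue_params(region)
  list(WM  = tissue_model("WM",  md = p$WM$md,  fa = p$WM$fa),
       GM  = tissue_model("GM",  md = p$GM$md,  fa = p$GM$fa),
       CSF = tissue_model("CSF", md = p$CSF$md, fa = p$CSF$fa))
}
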