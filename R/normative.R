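#' Normative spinal cord DTI values by region and tissue
#'
#' Representative in vivo centroid values of mean diffusivity (MD) and
#' fractional anisotropy (FA) for white matter (WM), grey matter (GM) and
#' CSF in the cervical, thoracic and lumbar cord of healthy young adults,
#' together with the grey-matter share of the cord cross-sectional area in
#' each region. These values parameterize the default synthetic phantoms
#' (see [tissue_model()] and [build_phantom()]) and the worked regression
#' of WM anisotropy on grey-matter content ([regress_fa_on_gm()]).
#'
#' MD is in 10^-3 mm^2/s throughout. The CSF rows describe the *measured*
#' CSF-and-noise cluster (partial volume and noise inflate its FA); the
#' phantom's underlying CSF compartment is near-isotropic (see
#' [tissue_model()]).
#'
#' @return A data frame with columns `region`, `tissue`, `md`, `md_sd`,
#'   `fa`, `fa_sd` and (per region, repeated) `gm_area_percent`.
#' @examples
#' cord_normative_values()
#' @export
cord_normative_values <- function() {
  out <- data.frame(
    region = rep(c("cervical", "thoracic", "lumbar"), each = 3L),
    tissue = rep(c("WM", "GM", "CSF"), times = 3L),
    md    = c(0.97, 1.8, 3.06,   0.96, 1.9, 3.12,   0.87, 1.7, 2.72),
    md_sd = c(0.32, 0.61, 1.02,  0.32, 0.34, 0.61,  0.32, 0.34, 0.33),
    fa    = c(0.70, 0.45, 0.28,  0.71, 0.44, 0.27,  0.65, 0.44, 0.30),
    fa_sd = c(0.08, 0.07, 0.08,  0.08, 0.08, 0.07,  0.08, 0.08, 0.07),
    stringsAsFactors = FALSE
  )
  gm <- c(cervical = 18, thoracic = 13.2, lumbar = 36.3)
  out$gm_area_percent <- gm[out$region]
  rownames(out) <- NULL
  out
}

#' Grey-matter cross-sectional area percentage for a cord region
#'
#' @param region One of `"cervical"`, `"thoracic"`, `"lumbar"`.
#' @return Percentage of the cord cross-section occupied by grey matter.
#' @examples
#' gm_area_percent("lumbar")
#' @export
gm_area_percent <- function(region) {
  region <- match.arg(region, c("cervical", "thoracic", "lumbar"))
  unname(c(cervical = 18, thoracic = 13.2, lumbar = 36.3)[region])
}
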