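# Interleaved multi-series slice geometry.
#
# Spinal DTI with cardiac gating can only image a few slices per series, so
# a region is covered by several series of widely gapped slices, each series
# shifted along the cord; the union of slice centers tiles the region
# contiguously.

#' Plan an interleaved multi-series slice acquisition
#'
#' Each of `series` acquisitions images `per_series` slices of thickness
#' `thickness` mm whose centers are `thickness + gap` mm apart; successive
#' series are shifted by `shift` mm. The default plan (7 series of 4 slices,
#' 3 mm thick, 18 mm gap, one-thickness shift) yields 28 contiguous slices.
#'
#' @param series Number of imaging series (> 0).
#' @param per_series Slices per series (> 0).
#' @param thickness Slice thickness in mm (> 0).
#' @param gap Gap between slices within one series in mm (> 0).
#' @param shift Per-series positional shift in mm (> 0).
#' @return An object of class `slice_plan`: a list with `positions`
#'   (sorted slice-center positions in mm, 0 = first slice of series 1),
#'   `series` (series index of each position), `n_slices` (distinct slice
#'   count), `contiguous` (TRUE if adjacent centers are exactly one
#'   thickness apart), `span_mm` (tissue covered, `n_slices * thickness`
#'   when contiguous), and the input parameters.
#' @examples
#' plan_slices(7, 4, 3, 18, 3)$n_slices
#' @export
plan_slices <- function(series = 7L, per_series = 4L, thickness = 3,
                        gap = 18, shift = 3) {
  if (any(c(series, per_series, thickness, gap, shift) <= 0))
    stopf("all slice-plan parameters must be positive")
  pitch <- thickness + gap               # center-to-center within a series
  pos <- as.vector(outer((seq_len(per_series) - 1) * pitch,
                         (seq_len(series) - 1) * shift, "+"))
  ser <- rep(seq_len(series), each = per_series)
  o <- order(pos)
  pos <- pos[o]; ser <- ser[o]
  keep <- !duplicated(round(pos / thickness * 2))   # half-thickness tolerance
  pos <- pos[keep]; ser <- ser[keep]
  gaps <- diff(pos)
  contiguous <- length(pos) > 1L && all(abs(gaps - thickness) < 1e-9)
  structure(list(
    positions = pos, series = ser, n_slices = length(pos),
    contiguous = contiguous,
    span_mm = if (contiguous || length(pos) == 1L)
      length(pos) * thickness else NA_real_,
    params = list(series = series, per_series = per_series,
                  thickness = thickness, gap = gap, shift = shift)
  ), class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf("slice_plan: %d series x %d slices -> %d distinct slices, %s\n",
              x$params$series, x$params$per_series, x$n_slices,
              if (x$contiguous) sprintf("contiguous (%g mm span)", x$span_mm)
              else "non-contiguous"))
  invisible(x)
}
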