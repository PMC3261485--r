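# NIfTI-1 and sidecar I/O, via RNifti. Grid indices are 0-based in files,
# 1-based in R; voxel-center convention; the affine is diagonal in the
# voxel sizes (RAS).

as_nifti_image <- function(arr, voxel) {
  im <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- c(voxel[1:min(3, nd)], rep(1, max(0, nd - 3)))
  RNifti::pixdim(im) <- pd
  im
}

#' Write a simulated acquisition to disk
#'
#' Writes the 4-D signal as NIfTI-1 (float32), the gradient table as FSL
#' `bvals`/`bvecs`, the phantom's ground-truth label and fraction maps as
#' NIfTI, the ROI mask as NIfTI, and a JSON sidecar with the phantom
#' parameters, seeds and a configuration hash.
#'
#' @param dwi A [simulate_dwi()] result (phantom attached).
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"dwi"`).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_dwi <- function(dwi, dir, stem = "dwi") {
  stopifnot(inherits(dwi, "dwi_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c(dwi = p(stem, ".nii.gz"), bvals = p(stem, ".bval"),
             bvecs = p(stem, ".bvec"))
  RNifti::writeNifti(as_nifti_image(dwi$signal, dwi$voxel), paths["dwi"],
                     datatype = "float")
  write_gradients(dwi$scheme, paths["bvals"], paths["bvecs"])
  ph <- dwi$phantom
  if (!is.null(ph)) {
    paths <- c(paths, labels = p(stem, "_truth_labels.nii.gz"),
               fractions = p(stem, "_truth_fractions.nii.gz"),
               mask = p(stem, "_mask.nii.gz"), sidecar = p(stem, ".json"))
    RNifti::writeNifti(as_nifti_image(ph$labels, dwi$voxel),
                       paths["labels"], datatype = "int16")
    RNifti::writeNifti(as_nifti_image(ph$fractions, dwi$voxel),
                       paths["fractions"], datatype = "float")
    RNifti::writeNifti(as_nifti_image(ph$roi + 0L, dwi$voxel),
                       paths["mask"], datatype = "int16")
    meta <- list(region = ph$region, shape = ph$shape, voxel = ph$voxel,
                 gm_fraction = ph$gm_fraction,
                 realized_gm_fraction = ph$realized_gm_fraction,
                 cord_radii = ph$cord_radii, csf_rim = ph$csf_rim,
                 snr = dwi$snr, s0 = dwi$s0,
                 phantom_seed = ph$seed, noise_seed = dwi$seed,
                 tissues = lapply(ph$tissues, function(tm)
                   list(md = tm$md, fa = tm$fa,
                        eigenvalues = tm$eigenvalues, axis = tm$axis)))
    meta$config_hash <- config_hash(meta)
    meta$package_version <- as.character(utils::packageVersion("cordti"))
    jsonlite::write_json(meta, paths["sidecar"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

#' Read a diffusion acquisition from NIfTI + FSL gradient files
#'
#' @param dwi_path 4-D NIfTI file.
#' @param bvals_path,bvecs_path FSL gradient table files.
#' @return A `dwi_volume` (no phantom attached).
#' @export
read_dwi <- function(dwi_path, bvals_path, bvecs_path) {
  im <- RNifti::readNifti(dwi_path)
  if (length(dim(im)) != 4L) stopf("%s is not 4-D", dwi_path)
  scheme <- read_gradients(bvals_path, bvecs_path)
  voxel <- RNifti::pixdim(im)[1:3]
  new_dwi_volume(array(as.numeric(im), dim = dim(im)), scheme, voxel)
}

#' Read a 3-D mask volume
#'
#' @param path NIfTI file; nonzero voxels are in-mask.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L) stopf("%s is not 3-D", path)
  array(as.numeric(im) != 0, dim = dim(im))
}

#' Write FA/MD scalar maps
#'
#' Writes FA, MD and flag volumes as NIfTI plus the per-voxel table
#' (x, y, slice 0-based, md, fa, flag) as CSV.
#'
#' @param maps A [make_scalar_maps()] object.
#' @param dir Output directory.
#' @param stem File stem (default `"maps"`).
#' @return Invisibly, the paths written.
#' @export
write_scalar_maps <- function(maps, dir, stem = "maps") {
  stopifnot(inherits(maps, "scalar_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  v <- maps$values
  idx <- cbind(v$x, v$y, v$slice)
  fa <- array(NA_real_, maps$shape); fa[idx] <- v$fa
  md <- array(NA_real_, maps$shape); md[idx] <- v$md
  fl <- array(0L, maps$shape); fl[idx] <- as.integer(v$flag)
  paths <- c(fa = p(stem, "_fa.nii.gz"), md = p(stem, "_md.nii.gz"),
             flags = p(stem, "_flags.nii.gz"), table = p(stem, ".csv"))
  RNifti::writeNifti(as_nifti_image(fa, maps$voxel), paths["fa"],
                     datatype = "float")
  RNifti::writeNifti(as_nifti_image(md, maps$voxel), paths["md"],
                     datatype = "float")
  RNifti::writeNifti(as_nifti_image(fl, maps$voxel), paths["flags"],
                     datatype = "int16")
  tab <- data.frame(x = v$x - 1L, y = v$y - 1L, slice = v$slice - 1L,
                    md = v$md, fa = v$fa, flag = as.integer(v$flag))
  utils::write.csv(tab, paths["table"], row.names = FALSE)
  invisible(paths)
}

#' Read scalar maps back from a per-voxel CSV
#'
#' @param path CSV written by [write_scalar_maps()].
#' @param shape Grid dimensions `c(nx, ny, nslices)`.
#' @param voxel Voxel sizes in mm.
#' @return A `scalar_maps` object.
#' @export
read_scalar_maps <- function(path, shape, voxel = c(1.2, 1.2, 3.0)) {
  tab <- utils::read.csv(path)
  need <- c("x", "y", "slice", "md", "fa", "flag")
  if (!all(need %in% names(tab))) stopf("%s: missing columns", path)
  values <- data.frame(x = tab$x + 1L, y = tab$y + 1L,
                       slice = tab$slice + 1L, md = tab$md, fa = tab$fa,
                       flag = as.logical(tab$flag))
  structure(list(values = values, shape = as.integer(shape),
                 voxel = as.numeric(voxel)), class = "scalar_maps")
}

#' Write a clustering result
#'
#' Writes the voxel/cluster/tissue/retained table as CSV, the back-mapped
#' label volume as NIfTI, centroids and counts as JSON, and the density
#' surface as a CSV grid.
#'
#' @param model A labeled `cluster_model`.
#' @param maps The `scalar_maps` it was fitted on (for the density
#'   surface).
#' @param dir Output directory.
#' @param stem File stem (default `"cluster"`).
#' @return Invisibly, the paths written.
#' @export
write_cluster <- function(model, maps, dir, stem = "cluster") {
  stopifnot(inherits(model, "cluster_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c(table = p(stem, ".csv"), labels = p(stem, "_labels.nii.gz"),
             centroids = p(stem, "_centroids.json"),
             density = p(stem, "_density.csv"))
  v <- model$values
  tab <- data.frame(x = v$x - 1L, y = v$y - 1L, slice = v$slice - 1L,
                    md = v$md, fa = v$fa, cluster = model$membership,
                    tissue = model$tissue[model$membership],
                    retained = model$retained)
  utils::write.csv(tab, paths["table"], row.names = FALSE)
  labs <- backmap(model)
  RNifti::writeNifti(as_nifti_image(labs$labels, model$voxel),
                     paths["labels"], datatype = "int16")
  info <- list(tissue = model$tissue,
               centroids = apply(model$centroids, 1, as.list),
               counts = model$counts,
               retained_counts = model$retained_counts,
               threshold_frac = model$threshold_frac,
               seed = model$seed, inertia = model$inertia)
  info$config_hash <- config_hash(info)
  jsonlite::write_json(info, paths["centroids"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  surf <- build_density_surface(maps)
  utils::write.csv(surf$counts, paths["density"], row.names = FALSE)
  invisible(paths)
}
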