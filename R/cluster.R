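# Tissue segmentation in (MD, FA) feature space.
#
# Cord voxels form three modes in the FA-versus-MD plane (anisotropic WM,
# less anisotropic GM, fast near-isotropic CSF) joined by a partial-volume
# continuum. k-means finds the modes; a distance restriction then strips
# the continuum before per-tissue statistics are taken.

#' 2-D voxel-density surface over (MD, FA)
#'
#' Histograms the scalar-map voxels over [0, max MD] x [0, 1]; the surface
#' height is the number of voxels with overlapping values and its local
#' maxima are a visual check of how many clusters to expect. Diagnostic
#' only — the clustering itself uses the raw voxel coordinates.
#'
#' @param maps A [make_scalar_maps()] object (flagged voxels are dropped).
#' @param bins Bin count per axis (default 50).
#' @return Object of class `density_surface`: `counts` (bins x bins matrix,
#'   MD along rows), `md_breaks`, `fa_breaks`, `n` (total voxels counted).
#' @export
build_density_surface <- function(maps, bins = 50L) {
  stopifnot(inherits(maps, "scalar_maps"))
  if (bins <= 0L) stopf("bins must be positive")
  v <- maps$values[!maps$values$flag, ]
  if (nrow(v) < 1L) stopf("no unflagged voxels")
  md_breaks <- seq(0, max(v$md, 1e-9), length.out = bins + 1L)
  fa_breaks <- seq(0, 1, length.out = bins + 1L)
  ix <- findInterval(v$md, md_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(pmin(pmax(v$fa, 0), 1), fa_breaks,
                     rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, md_breaks = md_breaks,
                 fa_breaks = fa_breaks, n = nrow(v)),
            class = "density_surface")
}

#' Strict local maxima of a density surface
#'
#' @param surface A [build_density_surface()] result.
#' @param min_count Ignore maxima shorter than this (default 2 voxels).
#' @return Data frame of md, fa bin centers and count, one row per maximum.
#' @export
density_peaks <- function(surface, min_count = 2L) {
  stopifnot(inherits(surface, "density_surface"))
  cnt <- surface$counts
  nb <- dim(cnt)
  pad <- matrix(-Inf, nb[1] + 2L, nb[2] + 2L)
  pad[2:(nb[1] + 1L), 2:(nb[2] + 1L)] <- cnt
  hits <- which(cnt >= min_count, arr.ind = TRUE)
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1] + 1L; j <- hits[r, 2] + 1L
    nbrs <- pad[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    nbrs[2, 2] <- -Inf
    keep[r] <- pad[i, j] > max(nbrs)
  }
  hits <- hits[keep, , drop = FALSE]
  mid <- function(b) (b[-1] + b[-length(b)]) / 2
  data.frame(md = mid(surface$md_breaks)[hits[, 1]],
             fa = mid(surface$fa_breaks)[hits[, 2]],
             count = cnt[hits])
}

#' k-means partition of voxels in (MD, FA) space
#'
#' Lloyd's algorithm with k-means++ seeding, restarted `nstart` times with
#' the best within-cluster sum of squares kept. Distances are Euclidean in
#' (MD in 10^-3 mm^2/s, FA), both order-1 quantities, so no further
#' scaling is applied by default; `scale = TRUE` z-scores both axes first
#' (centroids are still reported in the original units). Flagged voxels
#' are excluded. Deterministic given `seed`.
#'
#' @param maps A [make_scalar_maps()] object.
#' @param k Number of clusters (default 3: WM, GM, CSF).
#' @param seed Integer seed for the k-means++ draws.
#' @param nstart Number of restarts (default 10).
#' @param scale Z-score the axes before clustering (default FALSE).
#' @return Object of class `cluster_model`: `centroids` (k x 2 matrix,
#'   columns md, fa), `membership` (integer per voxel row of `values`),
#'   `retained` (logical, all TRUE before restriction), `values` (the
#'   clustered voxel table), `counts` (pre-restriction sizes),
#'   `retained_counts`, `tissue` (NA until [assign_tissues()]), `inertia`,
#'   `k`, `seed`, `shape`, `voxel`, `threshold_frac` (NA until
#'   [restrict_clusters()]).
#' @export
kmeans_partition <- function(maps, k = 3L, seed = 1L, nstart = 10L,
                             scale = FALSE) {
  stopifnot(inherits(maps, "scalar_maps"))
  v <- maps$values[!maps$values$flag, ]
  X <- cbind(md = v$md, fa = v$fa)
  if (nrow(X) < k) stopf("fewer voxels (%d) than clusters (%d)", nrow(X), k)
  if (nrow(unique(X)) < k) stopf("fewer distinct points than clusters")
  ctr <- c(0, 0); scl <- c(1, 1)
  if (scale) {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  fit <- with_seed(seed, kmeanspp_lloyd(X, k, nstart))
  centroids <- sweep(sweep(fit$centers, 2, scl, "*"), 2, ctr, "+")
  colnames(centroids) <- c("md", "fa")
  structure(list(
    centroids = centroids, membership = fit$cluster,
    retained = rep(TRUE, nrow(X)), values = v,
    counts = tabulate(fit$cluster, k),
    retained_counts = tabulate(fit$cluster, k),
    tissue = rep(NA_character_, k), inertia = fit$inertia,
    k = as.integer(k), seed = as.integer(seed),
    shape = maps$shape, voxel = maps$voxel,
    threshold_frac = NA_real_
  ), class = "cluster_model")
}

# k-means++ seeding + Lloyd refinement via stats::kmeans, best of nstart.
kmeanspp_lloyd <- function(X, k, nstart) {
  n <- nrow(X)
  ux <- unique(X)
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- kmeanspp_init(ux, k)
    fit <- tryCatch(
      stats::kmeans(X, centers = init, iter.max = 100L, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(X, centers = init, iter.max = 200L,
                                       algorithm = "Lloyd"))
      })
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stopf("k-means failed on all restarts")
  list(centers = unname(best$centers), cluster = unname(best$cluster),
       inertia = best$tot.withinss)
}

# k-means++ over the distinct points: first center uniform, then each next
# center drawn with probability proportional to squared distance to the
# nearest chosen center.
kmeanspp_init <- function(ux, k) {
  n <- nrow(ux)
  centers <- matrix(NA_real_, k, ncol(ux))
  centers[1, ] <- ux[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(ux, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j, ] <- ux[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- ux[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(ux, 2, centers[j, ])^2))
  }
  centers
}

#' Restrict clusters to their cores
#'
#' Implements the partial-volume restriction: for each cluster, voxels are
#' kept only if they lie within `threshold_frac` times the distance from
#' their cluster's centroid to the nearest *other* centroid. With the
#' default 0.2, voxels falling in the continuum between centroids — those
#' with the strongest partial-volume mixing — are excluded, while cluster
#' cores (in practice well over half of each cluster) survive.
#'
#' @param model A [kmeans_partition()] result.
#' @param threshold_frac Fraction of the nearest-other-centroid distance
#'   (> 0) used as the per-cluster retention radius.
#' @return The model with `retained`, `retained_counts` and
#'   `threshold_frac` updated.
#' @export
restrict_clusters <- function(model, threshold_frac = 0.2) {
  stopifnot(inherits(model, "cluster_model"))
  if (threshold_frac <= 0) stopf("threshold_frac must be positive")
  ctr <- model$centroids
  k <- model$k
  dc <- as.matrix(stats::dist(ctr))
  diag(dc) <- Inf
  radius <- threshold_frac * apply(dc, 1, min)
  X <- cbind(model$values$md, model$values$fa)
  own <- ctr[model$membership, , drop = FALSE]
  dv <- sqrt(rowSums((X - own)^2))
  model$retained <- dv <= radius[model$membership]
  model$retained_counts <- tabulate(model$membership[model$retained], k)
  model$threshold_frac <- threshold_frac
  model
}

#' Assign tissue identities to clusters
#'
#' The cluster with the highest centroid MD is CSF (fast free diffusion);
#' of the remaining two, the higher-FA centroid is WM and the other GM.
#' The expected cluster-size ordering (WM largest, CSF smallest within a
#' cord ROI) is checked and deviations are reported as warnings, not
#' errors — MD/FA ordering alone is unambiguous for three clusters.
#'
#' @param model A fitted `cluster_model` with k = 3.
#' @return The model with `tissue` set (per-cluster labels "WM", "GM",
#'   "CSF").
#' @export
assign_tissues <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3L) stopf("tissue assignment requires k = 3")
  ctr <- model$centroids
  if (anyDuplicated(round(ctr, 12)))
    stopf("degenerate clustering: coincident centroids")
  tissue <- rep(NA_character_, 3L)
  csf <- which.max(ctr[, "md"])
  rest <- setdiff(1:3, csf)
  wm <- rest[which.max(ctr[rest, "fa"])]
  gm <- setdiff(rest, wm)
  tissue[csf] <- "CSF"; tissue[wm] <- "WM"; tissue[gm] <- "GM"
  counts <- model$counts
  if (counts[wm] < max(counts))
    warnf("WM cluster is not the largest (%d vs max %d)", counts[wm],
          max(counts))
  if (counts[csf] > min(counts))
    warnf("CSF cluster is not the smallest (%d vs min %d)", counts[csf],
          min(counts))
  model$tissue <- tissue
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, %d voxels, inertia %.3f\n",
              x$k, length(x$membership), x$inertia))
  lab <- ifelse(is.na(x$tissue), paste0("cluster ", seq_len(x$k)), x$tissue)
  for (i in seq_len(x$k))
    cat(sprintf("  %-9s centroid (MD %.3f, FA %.3f)  n = %d, retained %d\n",
                lab[i], x$centroids[i, "md"], x$centroids[i, "fa"],
                x$counts[i], x$retained_counts[i]))
  invisible(x)
}

#' Map cluster tissue labels back onto the image grid
#'
#' Projects the feature-space segmentation back to voxel coordinates for
#' anatomical inspection: each retained voxel carries its cluster's tissue
#' label, restriction-excluded voxels are marked "excluded", and grid
#' positions outside the clustered ROI are "background".
#'
#' @param model A labeled `cluster_model` (after [assign_tissues()]).
#' @return Object of class `tissue_labels`: `labels` (integer 3-D array:
#'   0 background, 1 WM, 2 GM, 3 CSF, 4 excluded) with `shape`, `voxel`
#'   and the label `levels`.
#' @export
backmap <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (anyNA(model$tissue)) stopf("assign tissues before back-mapping")
  codes <- c(WM = 1L, GM = 2L, CSF = 3L)
  lab <- array(0L, dim = model$shape)
  v <- model$values
  idx <- cbind(v$x, v$y, v$slice)
  vox_code <- as.integer(ifelse(model$retained,
                                codes[model$tissue[model$membership]], 4L))
  lab[idx] <- vox_code
  structure(list(labels = lab, shape = model$shape, voxel = model$voxel,
                 levels = c(background = 0L, codes, excluded = 4L)),
            class = "tissue_labels")
}

#' Confusion of back-mapped labels against phantom ground truth
#'
#' @param labels A [backmap()] result.
#' @param phantom The source [build_phantom()] object.
#' @return List with `table` (3 x 3 confusion matrix over retained voxels,
#'   truth in rows) and `accuracy` (fraction of retained voxels whose
#'   label matches the dominant ground-truth tissue).
#' @export
backmap_accuracy <- function(labels, phantom) {
  stopifnot(inherits(labels, "tissue_labels"),
            inherits(phantom, "cord_phantom"))
  sel <- labels$labels %in% 1:3
  truth <- factor(phantom$labels[sel], levels = 1:3,
                  labels = c("WM", "GM", "CSF"))
  pred <- factor(labels$labels[sel], levels = 1:3,
                 labels = c("WM", "GM", "CSF"))
  tab <- table(truth = truth, predicted = pred)
  list(table = tab, accuracy = sum(diag(tab)) / sum(tab))
}
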