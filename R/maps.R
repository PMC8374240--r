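#' Voxelwise feature saliency map
#'
#' Evaluates one radiomic feature in the 26-connected neighbourhood of
#' every ROI voxel: the 3x3x3 patch around the voxel (truncated at image
#' borders) is intersected with the ROI, discretized with the global ROI
#' bin edges (so neighbouring values are comparable), and the named
#' feature is computed on the patch. The raw map is min-max normalized
#' over the ROI; a constant raw map normalizes to all zeros. Patches with
#' fewer than 2 in-ROI voxels get value 0.
#'
#' @param v a [volume()].
#' @param roi logical 3D mask.
#' @param feature_name one of the 93 registry names (see
#'   [feature_names()]), e.g. `"glcm_ClusterShade"`.
#' @param n_bins fixed bin number for the global ROI discretization.
#' @return A `saliency_map`: list with the normalized 3D `data` grid (0
#'   outside ROI), `feature_name`, `channel` and the raw value range.
#' @export
saliency_map <- function(v, roi, feature_name, n_bins = 50) {
  v <- as_volume(v)
  if (!feature_name %in% feature_names()) {
    stop("unknown feature name: ", feature_name)
  }
  roi <- array(as.logical(roi), dim(v$data))
  if (!any(roi)) stop("empty ROI")
  family <- sub("_.*$", "", feature_name)
  x <- v$data
  lo <- min(x[roi]); hi <- max(x[roi])
  # global FBN levels (same mapping as discretize_fbn)
  lev_global <- array(0L, dim(x))
  if (hi > lo) {
    lev_global[roi] <- as.integer(
      pmin(n_bins, floor(n_bins * (x[roi] - lo) / (hi - lo)) + 1L))
  } else {
    lev_global[roi] <- 1L
  }
  d <- dim(x)
  raw_map <- array(NA_real_, d)
  w <- which(roi, arr.ind = TRUE)
  for (k in seq_len(nrow(w))) {
    i <- w[k, ]
    rng <- lapply(1:3, function(a) max(1L, i[a] - 1L):min(d[a], i[a] + 1L))
    patch_roi <- roi[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    if (sum(patch_roi) < 2) {
      raw_map[i[1], i[2], i[3]] <- 0
      next
    }
    patch_lev <- lev_global[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    patch_lev[!patch_roi] <- 0L
    dp <- structure(list(
      levels = patch_lev, roi_mask = patch_roi, n_bins = as.integer(n_bins),
      bin_edges = seq(lo, if (hi > lo) hi else lo + n_bins,
                      length.out = n_bins + 1),
      bounding_box = rbind(min = c(1L, 1L, 1L), max = dim(patch_lev)),
      voxel_size_mm = v$voxel_size_mm), class = "discretized_roi")
    val <- switch(family,
      firstorder = first_order(dp, volume(
        x[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
        v$voxel_size_mm, v$channel)),
      glcm = glcm_features(dp),
      glrlm = glrlm_features(dp),
      glszm = glszm_features(dp),
      ngtdm = ngtdm_features(dp),
      gldm = gldm_features(dp))
    raw_map[i[1], i[2], i[3]] <- val[[feature_name]]
  }
  vals <- raw_map[roi]
  rng_v <- range(vals)
  out <- array(0, d)
  if (diff(rng_v) > 0) {
    out[roi] <- (vals - rng_v[1]) / diff(rng_v)
  }
  structure(list(data = out, feature_name = feature_name,
                 channel = v$channel, raw_range = rng_v,
                 voxel_size_mm = v$voxel_size_mm),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %s (%s), raw range [%.4g, %.4g]\n",
              x$feature_name, x$channel, x$raw_range[1], x$raw_range[2]))
  invisible(x)
}
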