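#' Fixed-bin-number intensity discretization
#'
#' Maps ROI intensities to `n_bins` equal-width bins spanning the ROI
#' intensity range (fixed bin number, FBN). Voxel level is
#' `min(n_bins, floor(n_bins * (x - min) / (max - min)) + 1)`; a constant
#' ROI maps every voxel to level 1. The result is cropped to the ROI
#' bounding box plus a 5-voxel padding (clipped at the image border) before
#' any texture-matrix computation.
#'
#' @param v an [volume()] object or 3D array.
#' @param roi logical/0-1 3D array, the region of interest.
#' @param n_bins number of gray levels (default 50).
#' @param padding bounding-box padding in voxels (default 5).
#' @return A `discretized_roi` object: cropped integer `levels` (0 outside
#'   ROI), cropped `roi_mask`, `n_bins`, `bin_edges`, `bounding_box`
#'   (min/max index per axis, pre-crop coordinates) and `voxel_size_mm`.
#' @export
discretize_fbn <- function(v, roi, n_bins = 50, padding = 5) {
  v <- as_volume(v)
  roi <- array(as.logical(roi), dim(v$data))
  if (!any(roi)) stop("empty ROI: cannot discretize")
  stopifnot(n_bins >= 1)
  x <- v$data[roi]
  lo <- min(x); hi <- max(x)
  levels <- array(0L, dim(v$data))
  if (hi > lo) {
    lev <- pmin(n_bins, floor(n_bins * (v$data[roi] - lo) / (hi - lo)) + 1L)
    levels[roi] <- as.integer(lev)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  } else {
    levels[roi] <- 1L
    edges <- c(lo, lo + seq_len(n_bins))  # degenerate range: nominal edges
  }
  bb <- roi_bounding_box(roi, padding)
  idx <- lapply(1:3, function(a) bb[1, a]:bb[2, a])
  structure(list(
    levels = levels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
    roi_mask = roi[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
    n_bins = as.integer(n_bins),
    bin_edges = edges,
    bounding_box = bb,
    voxel_size_mm = v$voxel_size_mm
  ), class = "discretized_roi")
}

# bounding box of a mask with padding, clipped to the grid: 2x3 matrix
# (rows min/max, columns x/y/z)
roi_bounding_box <- function(roi, padding = 5) {
  d <- dim(roi)
  w <- which(roi, arr.ind = TRUE)
  lo <- pmax(1L, apply(w, 2, min) - as.integer(padding))
  hi <- pmin(d, apply(w, 2, max) + as.integer(padding))
  rbind(min = as.integer(lo), max = as.integer(hi))
}
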