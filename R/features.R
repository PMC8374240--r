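#' First-order features
#'
#' The 18 standard first-order features. Intensity statistics are computed
#' on raw ROI values; entropy and uniformity on the discretized levels.
#' Degenerate conventions: skewness and kurtosis are 0 when the ROI variance
#' is 0; entropy of a single occupied bin is 0 and its uniformity is 1.
#' Percentiles use linear interpolation. Variance and the standard deviation
#' inside other features are population quantities (denominator `n`).
#'
#' @param d a [discretize_fbn()] result.
#' @param raw the raw [volume()] the ROI was discretized from.
#' @return Named numeric vector of 18 `firstorder_*` features.
#' @export
first_order <- function(d, raw) {
  raw <- as_volume(raw)
  bb <- d$bounding_box
  idx <- lapply(1:3, function(a) bb[1, a]:bb[2, a])
  x <- raw$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE][d$roi_mask]
  n <- length(x)
  lv <- d$levels[d$roi_mask]
  p <- tabulate(lv, nbins = d$n_bins) / n
  pnz <- p[p > 0]
  m <- mean(x)
  v <- mean((x - m)^2)
  q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE))
  core <- x[x >= q[1] & x <= q[4]]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = prod(d$voxel_size_mm) * sum(x^2),
    Entropy = -sum(pnz * log2(pnz)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = m,
    Median = median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(core - mean(core))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (v > 0) mean((x - m)^3) / v^1.5 else 0,
    Kurtosis = if (v > 0) mean((x - m)^4) / v^2 else 0,
    Variance = v,
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("firstorder_", names(out))
  out
}

# ---- GLCM ------------------------------------------------------------------

# features of one normalized symmetric co-occurrence matrix (sums to 1);
# ng_norm is the discretization depth used by the Idmn/Idn normalizations
# (the matrix itself may be truncated to the highest occupied level)
glcm_features_one <- function(P, ng_norm = nrow(P)) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HX <- ent(px); HY <- ent(py); HXY <- ent(P)
  Pp <- P
  pxy <- outer(px, py)
  nz <- Pp > 0 & pxy > 0
  HXY1 <- -sum(Pp[nz] * log2(pxy[nz]))
  nz2 <- pxy > 0
  HXY2 <- -sum(pxy[nz2] * log2(pxy[nz2]))
  da <- sum(k_diff * pxmy)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  # MCC on present levels only
  keep <- px > 0
  mcc <- if (sum(keep) < 2) 1 else {
    Ps <- P[keep, keep, drop = FALSE]
    pxs <- px[keep]; pys <- py[keep]
    Q <- matrix(0, sum(keep), sum(keep))
    for (kk in seq_len(sum(keep))) {
      Q <- Q + outer(Ps[, kk] / pxs, Ps[, kk] / pys[kk])
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxmy),
    DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng_norm)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng_norm)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * pxpy),
    SumEntropy = ent(pxpy),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc
  )
}

#' Gray-level co-occurrence features
#'
#' Symmetric co-occurrence matrices at distance 1 along the 13 unique 3D
#' directions, each normalized to sum 1; the 24 standard GLCM features are
#' computed per direction and averaged over directions. Directions with no
#' valid voxel pair are skipped. Degenerate conventions: zero marginal
#' variance makes Correlation 1; a single occupied level makes MCC 1 and the
#' information measures 0.
#'
#' @inheritParams first_order
#' @return Named numeric vector of 24 `glcm_*` features.
#' @export
glcm_features <- function(d) {
  # truncate the matrix to the highest occupied level: empty rows/columns
  # contribute nothing to any feature except the Idmn/Idn normalization,
  # which keeps the full discretization depth
  ng_eff <- max(1L, max(d$levels))
  counts <- cpp_glcm(as.integer(d$levels), dim(d$levels), ng_eff)
  feats <- NULL
  for (k in seq_len(13)) {
    M <- counts[, , k]
    s <- sum(M)
    if (s == 0) next
    f <- glcm_features_one(matrix(M, ng_eff) / s, ng_norm = d$n_bins)
    feats <- rbind(feats, f)
  }
  if (is.null(feats)) {  # single-voxel ROI: no pairs in any direction
    f <- glcm_features_one(matrix(c(1, rep(0, ng_eff^2 - 1)), ng_eff),
                           ng_norm = d$n_bins)
    feats <- rbind(f)
  }
  out <- colMeans(feats)
  names(out) <- paste0("glcm_", colnames(feats))
  out
}

# ---- GLRLM -----------------------------------------------------------------

glrlm_features_one <- function(P, n_voxels) {
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  Nr <- sum(P)
  p <- P / Nr
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pnz <- p[p > 0]
  c(
    ShortRunEmphasis = sum(P / j^2) / Nr,
    LongRunEmphasis = sum(P * j^2) / Nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / Nr^2,
    RunPercentage = Nr / n_voxels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (j - mu_j)^2),
    RunEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nr
  )
}

#' Gray-level run length features
#'
#' Runs of equal level along the 13 unique 3D directions; out-of-ROI voxels
#' break runs. The 16 standard GLRLM features are computed per direction and
#' averaged.
#'
#' @inheritParams first_order
#' @return Named numeric vector of 16 `glrlm_*` features.
#' @export
glrlm_features <- function(d) {
  counts <- cpp_glrlm(as.integer(d$levels), dim(d$levels), d$n_bins)
  nvox <- sum(d$roi_mask)
  feats <- NULL
  for (k in seq_len(13)) {
    M <- counts[, , k]
    if (sum(M) == 0) next
    feats <- rbind(feats, glrlm_features_one(M, nvox))
  }
  out <- colMeans(feats)
  names(out) <- paste0("glrlm_", colnames(feats))
  out
}

# ---- GLSZM -----------------------------------------------------------------

#' Gray-level size zone features
#'
#' Zones are 26-connected components of equal discretized level within the
#' ROI; the 16 standard GLSZM features are computed from the zone-size
#' matrix (a single matrix, not direction-dependent).
#'
#' @inheritParams first_order
#' @return Named numeric vector of 16 `glszm_*` features.
#' @export
glszm_features <- function(d) {
  zones <- cpp_glszm(as.integer(d$levels), dim(d$levels))
  nvox <- sum(d$roi_mask)
  ng <- d$n_bins
  smax <- max(zones[, 2])
  P <- matrix(0, ng, smax)
  for (k in seq_len(nrow(zones))) {
    P[zones[k, 1], zones[k, 2]] <- P[zones[k, 1], zones[k, 2]] + 1
  }
  i <- matrix(seq_len(ng), ng, smax)
  j <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  Nz <- sum(P)
  p <- P / Nz
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pnz <- p[p > 0]
  out <- c(
    SmallAreaEmphasis = sum(P / j^2) / Nz,
    LargeAreaEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nz^2,
    SizeZoneNonUniformity = sum(colSums(P)^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    ZonePercentage = Nz / nvox,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (j - mu_j)^2),
    ZoneEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz
  )
  names(out) <- paste0("glszm_", names(out))
  out
}

# ---- NGTDM -----------------------------------------------------------------

#' Neighbouring gray tone difference features
#'
#' Distance-1 26-neighbourhood mean absolute level differences. Degenerate
#' conventions follow the reference tool: a vanishing denominator makes
#' Coarseness 1e6, Busyness and Strength 0; Contrast is 0 when a single
#' level is present.
#'
#' @inheritParams first_order
#' @return Named numeric vector of 5 `ngtdm_*` features.
#' @export
ngtdm_features <- function(d) {
  M <- cpp_ngtdm(as.integer(d$levels), dim(d$levels), d$n_bins)
  nvox <- sum(d$roi_mask)
  present <- which(M[, 1] > 0)
  ni <- M[present, 1]
  si <- M[present, 2]
  pi_ <- ni / nvox
  gi <- present
  ngp <- length(present)
  coarse_den <- sum(pi_ * si)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(gi, gi, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(si) / nvox)
  } else 0
  # denominator runs over all ordered (i, j) pairs of present levels
  busy_den <- sum(abs(outer(gi * pi_, gi * pi_, "-")))
  busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
  cmplx <- sum(outer(seq_len(ngp), seq_len(ngp), Vectorize(function(a, b) {
    abs(gi[a] - gi[b]) * (pi_[a] * si[a] + pi_[b] * si[b]) /
      (pi_[a] + pi_[b])
  }))) / nvox
  strength <- if (sum(si) > 0) {
    sum(outer(seq_len(ngp), seq_len(ngp), Vectorize(function(a, b) {
      (pi_[a] + pi_[b]) * (gi[a] - gi[b])^2
    }))) / sum(si)
  } else 0
  out <- c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
           Complexity = cmplx, Strength = strength)
  names(out) <- paste0("ngtdm_", names(out))
  out
}

# ---- GLDM ------------------------------------------------------------------

#' Gray-level dependence features
#'
#' Dependence of a voxel is one plus the number of in-ROI 26-neighbours at
#' distance 1 whose level differs by at most `alpha` (default 0). The 14
#' standard GLDM features are computed from the gray level x dependence
#' count matrix.
#'
#' @inheritParams first_order
#' @param alpha similarity tolerance in levels (default 0).
#' @return Named numeric vector of 14 `gldm_*` features.
#' @export
gldm_features <- function(d, alpha = 0) {
  P <- cpp_gldm(as.integer(d$levels), dim(d$levels), d$n_bins,
                as.integer(alpha))
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  Nz <- sum(P)
  p <- P / Nz
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pnz <- p[p > 0]
  out <- c(
    SmallDependenceEmphasis = sum(P / j^2) / Nz,
    LargeDependenceEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz
  )
  names(out) <- paste0("gldm_", names(out))
  out
}

# ---- full per-ROI extraction ----------------------------------------------

#' Extract the 93 features for one volume and ROI
#'
#' @param v a [volume()] or 3D array.
#' @param roi logical 3D mask.
#' @param n_bins fixed bin number (default 50).
#' @param padding bounding-box padding in voxels (default 5).
#' @return Named numeric vector of 93 features in registry order.
#' @export
extract_features <- function(v, roi, n_bins = 50, padding = 5) {
  v <- as_volume(v)
  d <- discretize_fbn(v, roi, n_bins = n_bins, padding = padding)
  out <- c(first_order(d, v), glcm_features(d), glrlm_features(d),
           glszm_features(d), ngtdm_features(d), gldm_features(d))
  stopifnot(identical(names(out), feature_names()))
  out
}
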