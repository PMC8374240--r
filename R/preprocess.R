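#' Resample a volume to a target isotropic resolution
#'
#' Tensor-product cubic-spline interpolation: the grid is resampled axis by
#' axis so that the output spans the same physical extent at the target
#' spacing. Voxels are treated as centred at `(i - 0.5) * spacing`. A
#' volume already at the target spacing is returned unchanged.
#'
#' @param v a [volume()].
#' @param target_mm numeric length 1 or 3, positive target spacing in mm.
#' @return A [volume()] at the target spacing.
#' @export
resample_isotropic <- function(v, target_mm) {
  v <- as_volume(v)
  target_mm <- rep(as.numeric(target_mm), length.out = 3)
  if (any(target_mm <= 0)) stop("target spacing must be positive")
  if (isTRUE(all.equal(v$voxel_size_mm, target_mm))) return(v)
  x <- v$data
  d <- dim(x)
  for (a in 1:3) {
    n_in <- dim(x)[a]
    in_mm <- v$voxel_size_mm[a]
    extent <- n_in * in_mm
    n_out <- max(1L, as.integer(round(extent / target_mm[a])))
    if (n_out == n_in && isTRUE(all.equal(in_mm, target_mm[a]))) next
    in_pos <- (seq_len(n_in) - 0.5) * in_mm
    out_pos <- (seq_len(n_out) - 0.5) * target_mm[a]
    if (n_in >= 4) {
      # cubic spline is linear in the data: precompute the weight matrix
      W <- vapply(seq_len(n_in), function(j) {
        e <- numeric(n_in); e[j] <- 1
        stats::spline(in_pos, e, xout = out_pos, method = "fmm")$y
      }, numeric(n_out))
      W <- matrix(W, nrow = n_out)
    } else {
      W <- vapply(seq_len(n_in), function(j) {
        e <- numeric(n_in); e[j] <- 1
        stats::approx(in_pos, e, xout = out_pos, rule = 2)$y
      }, numeric(n_out))
      W <- matrix(W, nrow = n_out)
    }
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(x, perm), nrow = n_in)
    d_new <- dim(x)[perm]
    d_new[1] <- n_out
    x <- aperm(array(W %*% m, d_new), order(perm))
  }
  volume(x, target_mm, v$channel)
}

#' Threshold tissue probability maps into binary masks
#'
#' A voxel enters a tissue mask iff its probability is `>= threshold`
#' (boundary inclusive). Voxels meeting the threshold in more than one
#' tissue are assigned to the highest-probability tissue, ties broken by
#' the priority lesion > nawm > gm > csf. Composites are derived per the
#' study convention: `wm = nawm | lesion` and `tiv` is the union of all
#' four tissues.
#'
#' @param prob_maps named list of 3D probability arrays with (any of the)
#'   names `csf`, `gm`, `nawm`, `lesion`; values in `[0, 1]`. A missing
#'   lesion map is treated as all-zero (controls).
#' @param threshold inclusion threshold, default 0.9.
#' @return An object of class `tissue_masks`: logical arrays `csf`, `gm`,
#'   `nawm`, `lesion`, `wm`, `tiv`.
#' @export
threshold_masks <- function(prob_maps, threshold = 0.9) {
  tissues <- c("lesion", "nawm", "gm", "csf")  # priority order
  have <- intersect(tissues, names(prob_maps))
  if (!all(c("csf", "gm", "nawm") %in% have)) {
    stop("prob_maps must contain csf, gm and nawm maps")
  }
  d <- dim(prob_maps[[have[1]]])
  P <- sapply(tissues, function(t) {
    p <- if (t %in% have) as.numeric(prob_maps[[t]]) else numeric(prod(d))
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    p
  })
  qual <- P >= threshold
  any_q <- rowSums(qual) > 0
  score <- P * qual
  pick <- max.col(score, ties.method = "first")  # first = highest priority
  masks <- lapply(seq_along(tissues), function(k) {
    array(any_q & pick == k, d)
  })
  names(masks) <- tissues
  if (!any(masks$nawm)) stop("empty NAWM mask after thresholding")
  if (!any(masks$gm)) stop("empty GM mask after thresholding")
  masks$wm <- masks$nawm | masks$lesion
  masks$tiv <- masks$csf | masks$gm | masks$nawm | masks$lesion
  structure(masks[c("csf", "gm", "nawm", "lesion", "wm", "tiv")],
            class = "tissue_masks")
}

# monomial design matrix of total degree <= 2 on coordinates scaled to
# [-1, 1] (10 terms); degree kept low so the field cannot chase anatomy
poly_design <- function(d) {
  ax <- lapply(1:3, function(a) {
    s <- seq_len(d[a])
    2 * (s - 1) / max(1, d[a] - 1) - 1
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  terms <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
  terms <- terms[rowSums(terms) <= 2, ]
  as.matrix(mapply(function(i, j, k) g$x^i * g$y^j * g$z^k,
                   terms$i, terms$j, terms$k))
}

#' Bias field correction within the TIV
#'
#' Estimates a smooth multiplicative bias field within the TIV and divides
#' it out, preserving the mean intensity within the TIV. The estimator is
#' a log-domain low-order polynomial fit of tissue-class residuals:
#' intensities are clustered into three classes (CSF / GM / WM regime) by
#' 1-D k-means with deterministic quantile initialization, the class log
#' means are subtracted, and a degree-2 polynomial is fit to the residuals
#' over the whole TIV; clustering and fit are iterated three times so the
#' class assignment is re-estimated on progressively corrected data. If
#' the first-pass field estimate deviates by less than 1% the input is
#' considered bias-free and returned unchanged, which makes the operation
#' idempotent. Constant and non-positive (already normalized) input passes
#' through unchanged: a multiplicative bias model only applies to positive
#' magnitude data. Note that genuinely low-frequency intra-tissue
#' fluctuations are indistinguishable from bias and are partially removed
#' with it.
#'
#' @param v a T1w [volume()].
#' @param tiv logical 3D mask, the total intracranial volume.
#' @return A bias-corrected [volume()].
#' @export
correct_bias <- function(v, tiv) {
  v <- as_volume(v)
  if (v$channel != "T1w") stop("bias correction is applied to T1w only")
  tiv <- array(as.logical(tiv), dim(v$data))
  if (!any(tiv)) stop("empty TIV mask")
  x <- v$data
  tv <- as.vector(tiv)
  w0 <- x[tiv]
  if (stats::sd(w0) == 0) return(v)  # constant image: nothing to estimate
  # a multiplicative bias model only makes sense for positive magnitude
  # data; zero-mean (already normalized) input passes through unchanged
  if (min(w0) <= 0) return(v)
  X <- poly_design(dim(x))
  cur <- log(as.vector(x))
  total <- rep(0, length(cur))
  for (it in 1:3) {
    w <- cur[tv]
    ctr <- unique(quantile(w, c(0.005, 0.55, 0.95), names = FALSE))
    km <- stats::kmeans(w, centers = matrix(ctr), iter.max = 100)
    resid <- w - km$centers[km$cluster]
    fit <- stats::lm.fit(X[tv, , drop = FALSE], resid)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    logf <- as.vector(X %*% beta)
    logf <- logf - mean(logf[tv])
    if (it == 1 && max(abs(logf[tv])) < 0.01) return(v)
    cur <- cur - logf
    total <- total + logf
  }
  total <- total - mean(total[tv])
  out <- as.vector(x) / exp(total)
  out <- out * mean(x[tiv]) / mean(out[tv])
  volume(array(out, dim(x)), v$voxel_size_mm, v$channel)
}

#' Z-normalization within the TIV
#'
#' Applies `(x - mu) / sigma` to every voxel, with the mean and population
#' standard deviation computed over TIV voxels only. Only the
#' arbitrary-unit T1w channel is normalized; quantitative maps carry
#' physical units and must not be rescaled.
#'
#' @inheritParams correct_bias
#' @return A normalized [volume()]: within-TIV mean 0 and SD 1.
#' @export
normalize_tiv <- function(v, tiv) {
  v <- as_volume(v)
  if (v$channel != "T1w") stop("normalization is applied to T1w only")
  tiv <- array(as.logical(tiv), dim(v$data))
  w <- v$data[tiv]
  if (length(w) < 2) stop("TIV must contain at least 2 voxels")
  mu <- mean(w)
  sigma <- sqrt(mean((w - mu)^2))  # population SD
  if (sigma == 0) stop("zero intensity variance within TIV")
  volume((v$data - mu) / sigma, v$voxel_size_mm, v$channel)
}

#' Preprocess one subject
#'
#' Fixed pipeline order: resample (when a target resolution is given) ->
#' threshold probability maps -> bias-correct T1w within TIV -> z-normalize
#' T1w within TIV. Quantitative channels (PD, MT, R1, R2*) pass through
#' untouched apart from resampling.
#'
#' @param subject an `ms_subject`.
#' @param threshold probability threshold for [threshold_masks()].
#' @param target_mm optional isotropic target spacing for
#'   [resample_isotropic()]; `NULL` keeps the native grid.
#' @return The subject with preprocessed `volumes` and a `masks` field
#'   (a `tissue_masks` object).
#' @export
preprocess_subject <- function(subject, threshold = 0.9, target_mm = NULL) {
  stopifnot(inherits(subject, "ms_subject"))
  if (!is.null(target_mm)) {
    vs0 <- subject$volumes[[1]]$voxel_size_mm
    subject$volumes <- lapply(subject$volumes, resample_isotropic, target_mm)
    subject$prob_maps <- lapply(subject$prob_maps, function(p) {
      out <- resample_isotropic(volume(p, vs0, "T1w"), target_mm)$data
      out[out < 0] <- 0
      out[out > 1] <- 1
      out
    })
  }
  masks <- threshold_masks(subject$prob_maps, threshold = threshold)
  if ("T1w" %in% names(subject$volumes)) {
    t1 <- subject$volumes[["T1w"]]
    t1 <- correct_bias(t1, masks$tiv)
    t1 <- normalize_tiv(t1, masks$tiv)
    subject$volumes[["T1w"]] <- t1
  }
  subject$masks <- masks
  subject
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess every subject of a cohort
#'
#' @param cohort an `ms_cohort`.
#' @inheritParams preprocess_subject
#' @return The cohort with preprocessed subjects.
#' @export
preprocess_cohort <- function(cohort, threshold = 0.9, target_mm = NULL) {
  structure(lapply(cohort, preprocess_subject, threshold = threshold,
                   target_mm = target_mm), class = "ms_cohort")
}
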