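#' Stability-selection configuration
#'
#' @param n_iterations number of balanced bootstrap selection iterations
#'   (default 100).
#' @param cohort_size size of each balanced bootstrap cohort (even, default
#'   100: 50 per class).
#' @param distinct_frac_cut low-variance filter: minimum fraction of
#'   distinct values (default 0.10).
#' @param freq_ratio_cut low-variance filter: maximum ratio of the most
#'   frequent to the second most frequent value (default 95/5).
#' @param rs_cut Spearman de-correlation threshold (default 0.85).
#' @param rf_trees trees per random forest (default 100).
#' @param n_features_final `"auto"` (minor-class rule) or a fixed count.
#' @param seed integer seed.
#' @return A `selection_config` object.
#' @export
selection_config <- function(n_iterations = 100, cohort_size = 100,
                             distinct_frac_cut = 0.10,
                             freq_ratio_cut = 95 / 5, rs_cut = 0.85,
                             rf_trees = 100, n_features_final = "auto",
                             seed = 1) {
  stopifnot(cohort_size %% 2 == 0, n_iterations >= 1,
            distinct_frac_cut > 0, freq_ratio_cut > 0, rs_cut > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 cohort_size = as.integer(cohort_size),
                 distinct_frac_cut = distinct_frac_cut,
                 freq_ratio_cut = freq_ratio_cut, rs_cut = rs_cut,
                 rf_trees = as.integer(rf_trees),
                 n_features_final = n_features_final,
                 seed = as.integer(seed)), class = "selection_config")
}

#' Minor-class rule for the signature size
#'
#' Number of features to retain given the number of samples in the minor
#' class: `max(1, round(n / 10))`, so 28 training-minority samples yield a
#' 3-feature signature.
#'
#' @param n_minor_class samples in the minor class (>= 1).
#' @return Integer feature count.
#' @export
n_features_rule <- function(n_minor_class) {
  stopifnot(n_minor_class >= 1)
  max(1L, as.integer(round(n_minor_class / 10)))
}

#' Low-variance feature filter
#'
#' A feature is dropped iff BOTH the fraction of distinct values among
#' observations is below `distinct_frac_cut` AND the frequency ratio of the
#' most frequent to the second most frequent value exceeds
#' `freq_ratio_cut`. Constant features are always dropped.
#'
#' @param x data.frame or matrix of features (observations in rows).
#' @param distinct_frac_cut,freq_ratio_cut thresholds (defaults 0.10 and
#'   95/5).
#' @return Character vector of kept feature names.
#' @export
low_variance_filter <- function(x, distinct_frac_cut = 0.10,
                                freq_ratio_cut = 95 / 5) {
  x <- as.data.frame(x)
  n <- nrow(x)
  keep <- vapply(x, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) == 1) return(FALSE)        # constant
    distinct_frac <- length(tb) / n
    ratio <- as.numeric(tb[1]) / as.numeric(tb[2])
    !(distinct_frac < distinct_frac_cut && ratio > freq_ratio_cut)
  }, logical(1))
  names(x)[keep]
}

#' Pairwise Spearman de-correlation
#'
#' Iteratively finds the feature pair with the largest `|r_S|` above
#' `rs_cut` and drops the member whose mean absolute Spearman correlation
#' with all currently kept other features is larger (tie: the
#' lexicographically later name), until no pair exceeds the cut.
#'
#' @param x data.frame or matrix of features.
#' @param rs_cut threshold on `|r_S|` (default 0.85).
#' @return Character vector of kept feature names.
#' @export
decorrelate <- function(x, rs_cut = 0.85) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) return(names(x))
  R <- suppressWarnings(abs(cor(x, method = "spearman")))
  R[is.na(R)] <- 0
  diag(R) <- 0
  kept <- names(x)
  repeat {
    sub <- R[kept, kept, drop = FALSE]
    mx <- max(sub)
    if (mx <= rs_cut) break
    w <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- kept[w[1]]; b <- kept[w[2]]
    mean_a <- mean(sub[a, setdiff(kept, a)])
    mean_b <- mean(sub[b, setdiff(kept, b)])
    drop <- if (mean_a > mean_b) a
            else if (mean_b > mean_a) b
            else sort(c(a, b))[2]
    kept <- setdiff(kept, drop)
    if (length(kept) < 2) break
  }
  kept
}

#' Random-forest recursive feature elimination
#'
#' Repeatedly fits a random forest (default 100 trees, split candidates
#' `floor(sqrt(p))` for the current feature count `p`) and drops the single
#' lowest-importance feature until `n_target` remain. Survivors are
#' returned ordered by decreasing importance of a final fit.
#'
#' @param x data.frame of features; `y` binary outcome (two classes
#'   present).
#' @param y factor or 0/1 vector.
#' @param n_target number of features to keep.
#' @param rf_trees trees per forest (default 100).
#' @param seed integer seed (one fit per elimination step, seeded
#'   deterministically).
#' @return Character vector of `n_target` names, best first. The attribute
#'   `"rank"` gives the rank (1 = best) of each returned feature.
#' @export
rfe_rf <- function(x, y, n_target, rf_trees = 100, seed = 1) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both outcome classes required")
  stopifnot(ncol(x) >= n_target, n_target >= 1)
  cur <- names(x)
  step <- 0L
  imp <- NULL
  while (length(cur) > n_target) {
    step <- step + 1L
    imp <- rf_importance(x[cur], y, rf_trees, seed + step)
    cur <- setdiff(cur, names(which.min(imp)))
  }
  imp <- rf_importance(x[cur], y, rf_trees, seed + step + 1L)
  out <- names(sort(imp, decreasing = TRUE))
  attr(out, "rank") <- stats::setNames(seq_along(out), out)
  out
}

rf_importance <- function(x, y, rf_trees, seed) {
  fit <- ranger::ranger(
    x = x, y = y, num.trees = rf_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    importance = "impurity", seed = seed, num.threads = 1,
    respect.unordered.factors = TRUE)
  fit$variable.importance
}

#' Balanced-bootstrap stability feature selection
#'
#' The selection pipeline (low-variance filter -> Spearman de-correlation
#' -> RF-based recursive feature elimination down to the minor-class-rule
#' size) is run `n_iterations` times, each time on an extended balanced
#' cohort of `cohort_size` observations drawn with replacement
#' (`cohort_size / 2` per class) from the training slice. Features are
#' ranked by how often they were selected; ties are broken by better mean
#' RFE rank, then by name.
#'
#' @param x data.frame of feature columns (training subset only).
#' @param y binary outcome vector (0/1), same length as `nrow(x)`.
#' @param config a [selection_config()].
#' @return A `selection_result`: `counts` (named selection counts),
#'   `final_signature`, `n_features`, `mean_rank`, `config`, and
#'   `iterations` (per-iteration selected names).
#' @export
stability_select <- function(x, y, config = selection_config()) {
  x <- as.data.frame(x, check.names = FALSE)
  stopifnot(nrow(x) == length(y), length(unique(y)) == 2)
  n_feat <- if (identical(config$n_features_final, "auto")) {
    n_features_rule(min(table(y)))
  } else as.integer(config$n_features_final)
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  half <- config$cohort_size %/% 2
  counts <- stats::setNames(rep(0L, ncol(x)), names(x))
  rank_sum <- stats::setNames(rep(0, ncol(x)), names(x))
  iters <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    set.seed(config$seed + 7919L * it)
    take <- c(sample(idx1, half, replace = TRUE),
              sample(idx0, half, replace = TRUE))
    xb <- x[take, , drop = FALSE]
    yb <- y[take]
    kept <- low_variance_filter(xb, config$distinct_frac_cut,
                                config$freq_ratio_cut)
    if (length(kept) > 1) {
      kept <- decorrelate(xb[kept], config$rs_cut)
    }
    if (length(kept) > n_feat) {
      sel <- rfe_rf(xb[kept], yb, n_feat, config$rf_trees,
                    seed = config$seed + 104729L * it)
    } else {
      sel <- kept
      attr(sel, "rank") <- stats::setNames(seq_along(sel), sel)
    }
    counts[sel] <- counts[sel] + 1L
    rank_sum[sel] <- rank_sum[sel] + attr(sel, "rank")[sel]
    iters[[it]] <- as.character(sel)
  }
  mean_rank <- ifelse(counts > 0, rank_sum / pmax(1L, counts), Inf)
  ord <- order(-counts, mean_rank, names(counts))
  sig <- names(counts)[ord][seq_len(min(n_feat, sum(counts > 0)))]
  structure(list(counts = counts, final_signature = sig,
                 n_features = n_feat, mean_rank = mean_rank,
                 config = config, iterations = iters),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d iterations, signature (n=%d): %s\n",
              x$config$n_iterations, x$n_features,
              paste(x$final_signature, collapse = ", ")))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  print(head(top, 10))
  invisible(x)
}
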