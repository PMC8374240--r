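#' Model configuration
#'
#' Hyperparameters are fixed to the study's stated defaults; there is no
#' tuning loop. RF: 100 trees, `floor(sqrt(p))` split candidates. SVM: RBF
#' kernel, `C = 1`, `gamma = 1 / (p * Var(X))`. LR: L2 penalty with inverse
#' regularization strength `C = 1`.
#'
#' @param model_type `"LR"`, `"SVM"` or `"RF"`.
#' @param rf_trees trees for RF (default 100).
#' @param svm_cost,lr_cost regularization constants (default 1.0).
#' @param n_boot number of bootstrap evaluation cohorts (default 100).
#' @param cohort_size size of each balanced cohort (default 100).
#' @param ci_level confidence level of the reported interval (default 0.90,
#'   empirical 5th/95th percentiles).
#' @param auc_floor admissibility floor on median AUC (default 0.7).
#' @param seed integer seed.
#' @return A `model_config` object.
#' @export
model_config <- function(model_type = "LR", rf_trees = 100, svm_cost = 1.0,
                         lr_cost = 1.0, n_boot = 100, cohort_size = 100,
                         ci_level = 0.90, auc_floor = 0.7, seed = 1) {
  model_type <- match.arg(model_type, c("LR", "SVM", "RF"))
  stopifnot(cohort_size %% 2 == 0)
  structure(list(model_type = model_type, rf_trees = as.integer(rf_trees),
                 svm_cost = svm_cost, lr_cost = lr_cost,
                 n_boot = as.integer(n_boot),
                 cohort_size = as.integer(cohort_size),
                 ci_level = ci_level, auc_floor = auc_floor,
                 seed = as.integer(seed)), class = "model_config")
}

#' Train a frozen classifier on the training slice
#'
#' Fits the configured model on the signature features. SVM and LR inputs
#' are standardized with training-slice statistics, which are frozen into
#' the model together with all coefficients; RF uses raw features. Scores
#' are predicted probability (LR), decision value oriented so that larger
#' means MSP (SVM), and vote fraction (RF). Training is deterministic
#' given the config seed.
#'
#' @param x data.frame of signature feature columns (training slice).
#' @param y binary outcome (0 = HCS, 1 = MSP), both classes present.
#' @param config a [model_config()].
#' @param ids optional subject ids of the training rows, recorded for
#'   leakage checks downstream.
#' @return A `frozen_model`.
#' @export
train_model <- function(x, y, config = model_config(), ids = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required for training")
  p <- ncol(x)
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, function(v) { s <- sd(v); if (s > 0) s else 1 },
                numeric(1))
  xs <- sweep(sweep(as.matrix(x), 2, ctr), 2, scl, "/")
  type <- config$model_type
  fit <- orientation <- gamma <- NULL
  if (type == "LR") {
    # glmnet ridge with lambda = 1 / (n * C) matches the stated L2 objective
    xm <- xs
    if (p == 1) xm <- cbind(xm, `.dummy` = 0)
    fit <- suppressWarnings(
      glmnet::glmnet(xm, factor(y, levels = c(0, 1)),
                     family = "binomial", alpha = 0, standardize = FALSE,
                     lambda = 1 / (length(y) * config$lr_cost)))
  } else if (type == "SVM") {
    gamma <- 1 / (p * max(var(as.vector(xs)), .Machine$double.eps))
    fit <- e1071::svm(x = xs, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = config$svm_cost,
                      gamma = gamma, scale = FALSE)
    dv <- attr(predict(fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    orientation <- if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
  } else {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          num.trees = config$rf_trees,
                          mtry = max(1L, floor(sqrt(p))),
                          probability = TRUE, seed = config$seed,
                          num.threads = 1)
  }
  structure(list(type = type, fit = fit, center = ctr, scale = scl,
                 features = names(x), orientation = orientation,
                 gamma = gamma, config = config,
                 train_ids = ids), class = "frozen_model")
}

#' Predict scores and classes from a frozen model
#'
#' @param object a `frozen_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return Numeric scores (larger = more MSP-like); the attribute
#'   `"class_pred"` holds the 0/1 class decisions (probability or vote
#'   >= 0.5, decision value >= 0).
#' @export
predict.frozen_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(newdata, check.names = FALSE)[object$features])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  if (object$type == "LR") {
    xm <- if (length(object$features) == 1) cbind(xs, `.dummy` = 0) else xs
    s <- as.numeric(predict(object$fit, xm, type = "response"))
    cls <- as.integer(s >= 0.5)
  } else if (object$type == "SVM") {
    dv <- attr(predict(object$fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    s <- object$orientation * dv
    cls <- as.integer(s >= 0)
  } else {
    pr <- predict(object$fit, data = as.data.frame(x), num.threads = 1)
    s <- pr$predictions[, "1"]
    cls <- as.integer(s >= 0.5)
  }
  attr(s, "class_pred") <- cls
  s
}

#' @export
print.frozen_model <- function(x, ...) {
  cat(sprintf("<frozen_model> %s on %d features: %s\n", x$type,
              length(x$features), paste(x$features, collapse = ", ")))
  invisible(x)
}

binary_metrics <- function(score, cls, y) {
  c(accuracy = mean(cls == y),
    auc = auc_score(score, y),
    sensitivity = mean(cls[y == 1] == 1),
    specificity = mean(cls[y == 0] == 0))
}

#' Evaluate a frozen model on balanced bootstrap test cohorts
#'
#' Draws `n_boot` balanced cohorts (`cohort_size / 2` per class, sampled
#' with replacement from the test slice), computes accuracy, AUC,
#' sensitivity (MSP recall) and specificity per cohort, and reports the
#' median with the empirical 5th-95th percentile interval. Test subjects
#' must be disjoint from the training subjects; when ids are available the
#' disjointness is asserted.
#'
#' @param m a `frozen_model`.
#' @param x data.frame with the test-slice feature columns.
#' @param y binary outcome of the test slice (both classes present).
#' @param config a [model_config()] (bootstrap settings and seed).
#' @param ids optional subject ids of the test rows.
#' @return An `eval_report`: per-metric bootstrap values, `median` and `ci`
#'   (5th/95th percentiles).
#' @export
evaluate_bootstrap <- function(m, x, y, config = m$config, ids = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("test slice must contain both classes")
  if (!is.null(ids) && !is.null(m$train_ids) &&
      length(intersect(ids, m$train_ids))) {
    stop("test subjects overlap training subjects: ",
         paste(intersect(ids, m$train_ids), collapse = ", "))
  }
  score <- predict(m, x)
  cls <- attr(score, "class_pred")
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  half <- config$cohort_size %/% 2
  set.seed(config$seed + 31L)
  vals <- t(vapply(seq_len(config$n_boot), function(b) {
    take <- c(sample(idx1, half, replace = TRUE),
              sample(idx0, half, replace = TRUE))
    binary_metrics(score[take], cls[take], y[take])
  }, numeric(4)))
  lo <- (1 - config$ci_level) / 2
  summ <- apply(vals, 2, function(v) {
    c(median = median(v), quantile(v, c(lo, 1 - lo), names = FALSE))
  })
  structure(list(values = vals,
                 median = summ[1, ],
                 ci = rbind(lower = summ[2, ], upper = summ[3, ]),
                 model_type = m$type, config = config,
                 scores = as.numeric(score), labels = y),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d bootstrap cohorts\n", x$model_type,
              nrow(x$values)))
  for (mname in colnames(x$values)) {
    cat(sprintf("  %-12s %.2f (%.2f, %.2f)\n", mname, x$median[mname],
                x$ci["lower", mname], x$ci["upper", mname]))
  }
  invisible(x)
}

# DeLong placement components for one score vector
delong_components <- function(score, y) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       n1 = n1, n0 = n0)
}

#' Paired DeLong comparison of model AUCs
#'
#' Nonparametric test for the difference of correlated ROC AUCs computed
#' from different models' scores on the same test subjects, with
#' Bonferroni correction over model pairs. Identical score vectors give
#' p = 1.
#'
#' @param scores named list of numeric score vectors (one per model, same
#'   subjects in the same order).
#' @param y binary outcome vector.
#' @param alpha corrected significance level (default 0.01).
#' @return data.frame with one row per pair: AUCs, AUC difference
#'   variance, z, raw and Bonferroni-corrected p, significance flag.
#' @export
delong_compare <- function(scores, y, alpha = 0.01) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("degenerate labels")
  stopifnot(length(scores) >= 2, !is.null(names(scores)))
  comp <- lapply(scores, delong_components, y = y)
  pairs <- utils::combn(names(scores), 2)
  npairs <- ncol(pairs)
  out <- lapply(seq_len(npairs), function(k) {
    a <- comp[[pairs[1, k]]]
    b <- comp[[pairs[2, k]]]
    v <- var(a$v10 - b$v10) / a$n1 + var(a$v01 - b$v01) / a$n0
    d <- a$auc - b$auc
    if (v <= 0) {
      z <- 0; p <- 1
    } else {
      z <- d / sqrt(v)
      p <- 2 * pnorm(-abs(z))
    }
    data.frame(model_a = pairs[1, k], model_b = pairs[2, k],
               auc_a = a$auc, auc_b = b$auc, var_diff = v, z = z,
               p = p, p_corrected = min(1, npairs * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_corrected <= alpha
  out
}

#' Pick the model type by counting best-AUC combinations
#'
#' Per (channel, ROI) combination, model types whose median AUC is below
#' the floor are discarded; among survivors the type with the highest
#' median AUC earns a win. The type with most wins is returned; ties go to
#' the model with fewest parameters (LR over SVM over RF).
#'
#' @param results data.frame with columns `combo`, `model_type`,
#'   `median_auc`.
#' @param auc_floor admissibility floor (default 0.7).
#' @return The chosen model type.
#' @export
select_model_type <- function(results, auc_floor = 0.7) {
  stopifnot(all(c("combo", "model_type", "median_auc") %in% names(results)))
  simplicity <- c(LR = 1, SVM = 2, RF = 3)
  wins <- c(LR = 0, SVM = 0, RF = 0)
  any_admissible <- FALSE
  for (cb in unique(results$combo)) {
    sub <- results[results$combo == cb & results$median_auc >= auc_floor, ]
    if (!nrow(sub)) next
    any_admissible <- TRUE
    best <- sub$model_type[sub$median_auc == max(sub$median_auc)]
    wins[best] <- wins[best] + 1
  }
  if (!any_admissible) stop("no admissible model: all median AUCs below floor")
  top <- names(wins)[wins == max(wins)]
  top[which.min(simplicity[top])]
}

#' Permutation-test overfitting audit
#'
#' Randomizes class labels within the training and testing slices
#' separately (preserving class counts), reruns the unmodified pipeline
#' (stability selection, training, bootstrap evaluation), and compares the
#' original and permuted bootstrap AUC distributions with a one-sided
#' Mann-Whitney test for a drop in AUC.
#'
#' @param x_train,y_train,x_test,y_test feature slices and outcomes.
#' @param sel_config a [selection_config()].
#' @param mod_config a [model_config()].
#' @param original optional precomputed `eval_report` for the unpermuted
#'   pipeline (recomputed when `NULL`).
#' @param seed seed for the label permutation.
#' @param n_permutations number of independent label shuffles (default 1);
#'   with more than one, the permuted AUC distributions are pooled, which
#'   stabilizes the permuted median on small test slices.
#' @return A `permutation_audit` list: original and (pooled) permuted AUC
#'   vectors and medians, per-permutation medians, and the one-sided
#'   p-value for the drop.
#' @export
permutation_audit <- function(x_train, y_train, x_test, y_test,
                              sel_config = selection_config(),
                              mod_config = model_config(),
                              original = NULL, seed = 1,
                              n_permutations = 1) {
  run_branch <- function(ytr, yte) {
    sel <- stability_select(x_train, ytr, sel_config)
    m <- train_model(x_train[sel$final_signature], ytr, mod_config)
    evaluate_bootstrap(m, x_test[sel$final_signature], yte, mod_config)
  }
  if (is.null(original)) original <- run_branch(y_train, y_test)
  a_perm <- c()
  perm_medians <- numeric(n_permutations)
  permuted <- NULL
  for (k in seq_len(n_permutations)) {
    set.seed(seed + 53L * k)
    ytr_p <- sample(y_train)
    yte_p <- sample(y_test)
    stopifnot(sum(ytr_p) == sum(y_train), sum(yte_p) == sum(y_test))
    permuted <- run_branch(ytr_p, yte_p)
    perm_medians[k] <- median(permuted$values[, "auc"])
    a_perm <- c(a_perm, permuted$values[, "auc"])
  }
  a_orig <- original$values[, "auc"]
  p <- suppressWarnings(
    wilcox.test(a_orig, a_perm, alternative = "greater", exact = FALSE)$p.value)
  structure(list(auc_original = a_orig, auc_permuted = a_perm,
                 median_original = median(a_orig),
                 median_permuted = median(a_perm),
                 permutation_medians = perm_medians,
                 p_drop = p, significant = p <= 0.01,
                 permuted_report = permuted),
            class = "permutation_audit")
}

#' @export
print.permutation_audit <- function(x, ...) {
  cat(sprintf(
    "<permutation_audit> median AUC %.3f -> %.3f permuted; drop p = %.3g%s\n",
    x$median_original, x$median_permuted, x$p_drop,
    if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Validate a frozen model on an external cohort
#'
#' Applies the model with its frozen coefficients and standardization
#' constants (no refitting) to an external feature table, evaluating on
#' balanced bootstrap cohorts exactly as [evaluate_bootstrap()]. When a
#' `source` label is given, per-source accuracies are reported: for an
#' all-negative source this equals the overall specificity, for an
#' all-positive source the sensitivity.
#'
#' @param m a `frozen_model`.
#' @param x external feature table (identical feature names required).
#' @param y binary outcome of the external cohort.
#' @param config a [model_config()].
#' @param source optional per-row source labels.
#' @return An `eval_report` with an extra `source_accuracy` element.
#' @export
external_validate <- function(m, x, y, config = m$config, source = NULL) {
  missing <- setdiff(m$features, names(x))
  if (length(missing)) {
    stop("validation table lacks feature columns: ",
         paste(missing, collapse = ", "))
  }
  rep <- evaluate_bootstrap(m, x, y, config)
  if (!is.null(source)) {
    score <- predict(m, x)
    cls <- attr(score, "class_pred")
    rep$source_accuracy <- vapply(split(seq_along(y), source), function(ix) {
      mean(cls[ix] == y[ix])
    }, numeric(1))
  }
  rep
}
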