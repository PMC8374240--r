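# tie-aware Mann-Whitney U statistic (number of (pos, neg) pairs with
# x_pos > x_neg, ties counted 1/2) via the rank formula
mann_whitney_u <- function(x, y) {
  # U for x (positive class) vs y (negative class)
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Univariate AUC of a raw score
#'
#' Tie-aware AUC of `score` against binary `outcome` (1 = positive),
#' identical to `U / (n1 * n2)`.
#'
#' @param score numeric vector.
#' @param outcome 0/1 vector.
#' @param fold if `TRUE`, report `max(AUC, 1 - AUC)`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(score, outcome, fold = FALSE) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  a <- mann_whitney_u(pos, neg) / (length(pos) * length(neg))
  if (fold) max(a, 1 - a) else a
}

#' Univariate screening of the feature table
#'
#' Per feature: a two-sided Mann-Whitney test between outcome classes with
#' Bonferroni correction over all tested features; point-biserial
#' correlation with the outcome (t-approximation p-value), flagged when
#' `|r_pb| >= 0.85` and `p <= 0.05`; Spearman correlations with age and
#' with the feature's own ROI volume, flagged when `|r_S| > r_cut`; and the
#' univariate AUC folded to `>= 0.5`. The Mann-Whitney p-value is exact
#' when `n1 * n2 <= 400` and the feature is tie-free, otherwise the normal
#' approximation with tie correction is used. Constant features get p = 1
#' and correlations 0 by convention.
#'
#' @param t a `feature_table`.
#' @param alpha Bonferroni-corrected significance level (default 0.01).
#' @param r_cut Spearman flag threshold (default 0.85).
#' @param auc_cut univariate AUC flag threshold (default 0.75).
#' @return A `univariate_report` data.frame, one row per feature: raw and
#'   corrected Mann-Whitney p, `rpb_outcome` and its p, `rs_age`,
#'   `rs_volume`, `auc_univar`, and logical flag columns.
#' @export
univariate_screen <- function(t, alpha = 0.01, r_cut = 0.85,
                              auc_cut = 0.75) {
  cols <- feature_columns(t)
  y <- t$outcome
  stopifnot(length(unique(y)) == 2, min(table(y)) >= 2)
  m <- length(cols)
  res <- lapply(cols, function(cn) {
    x <- t[[cn]]
    roi <- strsplit(cn, "__", fixed = TRUE)[[1]][2]
    volcol <- paste0(roi, "__roi_volume")
    if (length(unique(x)) == 1) {
      return(data.frame(feature = cn, p_raw = 1, p_corrected = 1,
                        rpb_outcome = 0, rpb_p = 1, rs_age = 0,
                        rs_volume = 0, auc_univar = 0.5,
                        stringsAsFactors = FALSE))
    }
    x1 <- x[y == 1]; x0 <- x[y == 0]
    exact <- (length(x1) * length(x0) <= 400) && !anyDuplicated(x)
    p_raw <- suppressWarnings(
      wilcox.test(x1, x0, exact = exact, correct = !exact)$p.value)
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    rs_age <- suppressWarnings(cor(x, t$age, method = "spearman"))
    rs_vol <- if (volcol %in% names(t)) {
      suppressWarnings(cor(x, t[[volcol]], method = "spearman"))
    } else NA_real_
    data.frame(feature = cn, p_raw = p_raw, p_corrected = min(1, m * p_raw),
               rpb_outcome = unname(ct$estimate), rpb_p = ct$p.value,
               rs_age = ifelse(is.na(rs_age), 0, rs_age),
               rs_volume = ifelse(is.na(rs_vol), 0, rs_vol),
               auc_univar = auc_score(x, y, fold = TRUE),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, res)
  rep$sig_mw <- rep$p_corrected <= alpha
  rep$flag_outcome <- abs(rep$rpb_outcome) >= 0.85 & rep$rpb_p <= 0.05
  rep$flag_age <- abs(rep$rs_age) > r_cut
  rep$flag_volume <- abs(rep$rs_volume) > r_cut
  rep$flag_auc <- rep$auc_univar > auc_cut
  class(rep) <- c("univariate_report", "data.frame")
  rep
}

#' Summarize a univariate report per (channel, ROI)
#'
#' Counts of flagged features per channel x ROI cell, in the style of a
#' cohort-description table: how many features are significantly different
#' between classes, highly correlated with age/volume/outcome, or have
#' univariate AUC above the threshold.
#'
#' @param rep a `univariate_report`.
#' @return data.frame with one row per (channel, roi) and count columns.
#' @export
summarize_screen <- function(rep) {
  parts <- strsplit(rep$feature, "__", fixed = TRUE)
  ch <- vapply(parts, `[[`, character(1), 1)
  roi <- vapply(parts, `[[`, character(1), 2)
  agg <- stats::aggregate(
    cbind(sig_mw = rep$sig_mw, flag_outcome = rep$flag_outcome,
          flag_age = rep$flag_age, flag_volume = rep$flag_volume,
          flag_auc = rep$flag_auc),
    by = list(channel = ch, roi = roi), FUN = sum)
  agg
}
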