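#' Extract the full feature table for a cohort
#'
#' Computes the 93 first-order and texture features for every
#' (subject, channel, ROI) combination and flattens them to one wide row
#' per subject, with outcome and covariate columns. Feature columns are
#' named `<channel>__<roi>__<family>_<Feature>`; per-ROI volumes (voxel
#' count x voxel volume, mm^3) are recorded as `<roi>__roi_volume`.
#' Lesion-only ROIs are never extracted (their volumes are too small; the
#' lesion mask only enters the WM composite).
#'
#' @param cohort an `ms_cohort` of preprocessed subjects (see
#'   [preprocess_cohort()]); each subject must carry nonempty WM, NAWM and
#'   GM masks.
#' @param channels channels to extract; default all channels present.
#' @param rois ROIs among `"WM"`, `"NAWM"`, `"GM"`.
#' @param n_bins fixed bin number for discretization (default 50).
#' @param padding bounding-box padding in voxels (default 5).
#' @return A `feature_table`: data.frame with columns `id`, `outcome`,
#'   `age`, `gender`, `scanner`, the ROI volumes, and
#'   `93 x |channels| x |rois|` feature columns. Attributes record
#'   `n_bins`, `padding`, `channels` and `rois`.
#' @export
extract_all <- function(cohort, channels = NULL,
                        rois = c("WM", "NAWM", "GM"),
                        n_bins = 50, padding = 5) {
  stopifnot(inherits(cohort, "ms_cohort"), length(cohort) >= 1)
  rois <- match.arg(rois, c("WM", "NAWM", "GM"), several.ok = TRUE)
  if (is.null(channels)) channels <- names(cohort[[1]]$volumes)
  rows <- lapply(cohort, function(s) {
    if (is.null(s$masks)) stop(sprintf("subject %s is not preprocessed", s$id))
    roi_masks <- list(WM = s$masks$wm, NAWM = s$masks$nawm, GM = s$masks$gm)
    vv <- voxel_volume_mm3(s$volumes[[1]])
    covs <- data.frame(id = s$id, outcome = s$status, age = s$age,
                       gender = s$gender, scanner = s$scanner,
                       stringsAsFactors = FALSE)
    vols <- as.list(vapply(rois, function(r) sum(roi_masks[[r]]) * vv,
                           numeric(1)))
    names(vols) <- paste0(rois, "__roi_volume")
    feats <- list()
    for (ch in channels) {
      if (is.null(s$volumes[[ch]])) {
        stop(sprintf("subject %s lacks channel %s", s$id, ch))
      }
      for (r in rois) {
        f <- extract_features(s$volumes[[ch]], roi_masks[[r]],
                              n_bins = n_bins, padding = padding)
        bad <- !is.finite(f)
        if (any(bad)) {
          stop(sprintf("non-finite feature for subject=%s channel=%s roi=%s: %s",
                       s$id, ch, r, paste(names(f)[bad], collapse = ", ")))
        }
        names(f) <- paste0(ch, "__", r, "__", names(f))
        feats[[paste(ch, r)]] <- f
      }
    }
    cbind(covs, as.data.frame(c(vols, as.list(unlist(unname(feats)))),
                              check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, class = c("feature_table", "data.frame"),
            n_bins = n_bins, padding = padding,
            channels = channels, rois = rois)
}

#' Names of feature columns in a feature table
#'
#' @param t a `feature_table`.
#' @param channel,roi optional filters; `channel = "qMRIcomb"` selects the
#'   pooled PD, MT, R1 and R2* columns.
#' @return Character vector of matching feature column names.
#' @export
feature_columns <- function(t, channel = NULL, roi = NULL) {
  cols <- grep("__(firstorder|glcm|glrlm|glszm|ngtdm|gldm)_", names(t),
               value = TRUE)
  if (!is.null(channel)) {
    chs <- if (identical(channel, "qMRIcomb")) {
      c("PD", "MT", "R1", "R2*")
    } else channel
    pat <- paste0("^(", paste(gsub("\\*", "\\\\*", chs), collapse = "|"),
                  ")__")
    cols <- grep(pat, cols, value = TRUE)
  }
  if (!is.null(roi)) {
    cols <- grep(paste0("__", roi, "__"), cols, value = TRUE, fixed = TRUE)
  }
  cols
}

#' Write / read a feature table as CSV with a JSON sidecar
#'
#' @param t a `feature_table`.
#' @param path CSV path; metadata (`n_bins`, `padding`, channels, ROIs) is
#'   written next to it as `<path>.json`.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the `feature_table`.
#' @export
write_feature_table <- function(t, path) {
  write.csv(as.data.frame(t), path, row.names = FALSE)
  meta <- list(n_bins = attr(t, "n_bins"), padding = attr(t, "padding"),
               channels = attr(t, "channels"), rois = attr(t, "rois"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(tab, class = c("feature_table", "data.frame"),
            n_bins = meta$n_bins %||% 50, padding = meta$padding %||% 5,
            channels = unlist(meta$channels), rois = unlist(meta$rois))
}
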