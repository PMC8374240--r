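# deterministic stage seed derived from the global seed and a stage name:
# inserting a new stage never shifts another stage's random stream
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 48271 + h * 16807) %% 2147483647)
}

#' Stratified train/test split of a cohort
#'
#' Splits subjects stratified by outcome x scanner; train slots are
#' allocated to strata by largest remainder so that each stratum stays
#' within one subject of the target fraction while the overall train size
#' matches `round(n * fraction)`. Mann-Whitney (age) and Fisher (gender)
#' balance p-values between the resulting subsets are reported.
#'
#' @param cohort an `ms_cohort` or a demographics data.frame with columns
#'   `id`, `status`, `age`, `gender`, `scanner`.
#' @param fraction train fraction (default 0.80).
#' @param seed integer seed.
#' @return list with `train_ids`, `test_ids`, and `balance` (age and
#'   gender p-values).
#' @export
split_cohort <- function(cohort, fraction = 0.80, seed = 1) {
  tab <- if (inherits(cohort, "ms_cohort")) cohort_table(cohort)
         else as.data.frame(cohort)
  stopifnot(fraction > 0.5, fraction < 0.95)
  if (min(table(tab$status)) < 5) stop("need >= 5 subjects per class")
  strata <- interaction(tab$status, tab$scanner, drop = TRUE, sep = ":")
  sizes <- table(strata)
  if (any(sizes < 2)) {
    stop("stratum too small to split: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  target_total <- round(nrow(tab) * fraction)
  raw <- as.numeric(sizes) * fraction
  base <- floor(raw)
  rem <- target_total - sum(base)
  add <- order(raw - base, decreasing = TRUE)[seq_len(max(0, rem))]
  n_train <- base
  n_train[add] <- n_train[add] + 1
  n_train <- pmin(n_train, as.numeric(sizes) - 1)  # keep both sides nonempty
  set.seed(seed)
  train_ids <- character(0)
  for (k in seq_along(sizes)) {
    ids_k <- tab$id[strata == names(sizes)[k]]
    train_ids <- c(train_ids, sample(ids_k, n_train[k]))
  }
  test_ids <- setdiff(tab$id, train_ids)
  in_train <- tab$id %in% train_ids
  age_p <- suppressWarnings(
    wilcox.test(tab$age[in_train], tab$age[!in_train], exact = FALSE)$p.value)
  gender_p <- tryCatch(
    fisher.test(table(in_train, tab$gender))$p.value, error = function(e) 1)
  list(train_ids = sort(train_ids), test_ids = sort(test_ids),
       balance = c(age_p = age_p, gender_p = gender_p))
}

#' Study configuration
#'
#' Bundles everything [run_study()] needs: the development and validation
#' cohort specifications, the split fraction, selection and model
#' settings, the output directory and a global seed from which every
#' stage seed is derived deterministically.
#'
#' @param cohort a [cohort_spec()] for the development cohort.
#' @param validation_cohort a [cohort_spec()] for the external validation
#'   cohort (typically unbalanced: many HCS, few MSP, other scanners), or
#'   `NULL` to skip external validation.
#' @param split_fraction train fraction in (0.5, 0.95), default 0.80.
#' @param selection a [selection_config()].
#' @param model a [model_config()] (the type is chosen by the study; the
#'   other settings apply to all three types).
#' @param output_dir directory for reports, tables and maps; `NULL` keeps
#'   everything in memory.
#' @param n_bins,threshold extraction and mask-threshold settings.
#' @param saliency if `TRUE` (default) compute a saliency map for the top
#'   feature of the best combination.
#' @param global_seed integer master seed.
#' @return A `study_config` object.
#' @export
study_config <- function(cohort = cohort_spec(),
                         validation_cohort = NULL,
                         split_fraction = 0.80,
                         selection = selection_config(),
                         model = model_config(),
                         output_dir = NULL,
                         n_bins = 50, threshold = 0.9,
                         saliency = TRUE,
                         global_seed = 1) {
  stopifnot(split_fraction > 0.5, split_fraction < 0.95)
  structure(list(cohort = cohort, validation_cohort = validation_cohort,
                 split_fraction = split_fraction, selection = selection,
                 model = model, output_dir = output_dir, n_bins = n_bins,
                 threshold = threshold, saliency = isTRUE(saliency),
                 global_seed = as.integer(global_seed)),
            class = "study_config")
}

#' Build a study configuration from a YAML file
#'
#' Top-level keys mirror [study_config()]; `cohort` and
#' `validation_cohort` blocks are parsed by [cohort_spec_from_yaml()],
#' `selection` and `model` blocks by their config constructors.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$cohort)) args$cohort <- cohort_spec_from_yaml(cfg$cohort)
  if (!is.null(cfg$validation_cohort)) {
    args$validation_cohort <- cohort_spec_from_yaml(cfg$validation_cohort)
  }
  if (!is.null(cfg$selection)) {
    args$selection <- do.call(selection_config,
      cfg$selection[names(cfg$selection) %in% names(formals(selection_config))])
  }
  if (!is.null(cfg$model)) {
    args$model <- do.call(model_config,
      cfg$model[names(cfg$model) %in% names(formals(model_config))])
  }
  for (k in c("split_fraction", "output_dir", "n_bins", "threshold",
              "saliency", "global_seed")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(study_config, args)
}

study_combos <- function(channels, rois) {
  qmri <- intersect(c("PD", "MT", "R1", "R2*"), channels)
  combo_channels <- c(channels, if (length(qmri) >= 2) "qMRIcomb")
  expand.grid(channel = combo_channels, roi = rois,
              stringsAsFactors = FALSE)
}

#' Run the full study end to end
#'
#' Generates the development (and, when configured, validation) cohorts,
#' preprocesses them, extracts the feature table, runs the univariate
#' screen, splits the development cohort 80/20, then for every
#' (channel, ROI) combination (each channel plus a pooled qMRI
#' combination when at least two quantitative channels are present) runs
#' stability selection on the training slice and trains and evaluates
#' LR, SVM and RF models on the test slice. The best model type is chosen
#' by counting best-AUC combinations above the admissibility floor; a
#' permutation audit is run for the best combination; T1w models are
#' validated on the external cohort; and a saliency map is computed for
#' the top feature of the best combination. All stage seeds derive from
#' `global_seed`. When `output_dir` is set, the feature table, selection
#' and evaluation reports, performance tables, the saliency map and a
#' manifest with file hashes are written; per-stage wall times go to the
#' plain-text log only, so reruns of the same config produce identical
#' manifests.
#'
#' @param cfg a [study_config()].
#' @return A `study_result` list: `features`, `screen`, `split`,
#'   `selection` and `evaluation` per combination, `delong`,
#'   `model_type`, `performance` table, `permutation`, `validation`,
#'   `saliency` and `manifest`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  out_dir <- cfg$output_dir
  log_lines <- character(0)
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    log_lines <<- c(log_lines, sprintf("%-28s %.2f s", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  gseed <- cfg$global_seed

  dev_spec <- cfg$cohort
  dev_spec$seed <- stage_seed(gseed, "cohort")
  dev <- t_stage("generate development cohort",
                 generate_cohort(dev_spec))
  dev <- t_stage("preprocess development",
                 preprocess_cohort(dev, threshold = cfg$threshold))
  feats <- t_stage("extract features",
                   extract_all(dev, n_bins = cfg$n_bins))
  screen <- t_stage("univariate screen", univariate_screen(feats))
  split <- t_stage("train/test split",
                   split_cohort(dev, cfg$split_fraction,
                                seed = stage_seed(gseed, "split")))
  log_lines <- c(log_lines, sprintf(
    "split balance: age p = %.3f (Mann-Whitney), gender p = %.3f (Fisher)",
    split$balance["age_p"], split$balance["gender_p"]))
  in_train <- feats$id %in% split$train_ids
  combos <- study_combos(attr(feats, "channels"), attr(feats, "rois"))
  selection <- list()
  evaluation <- list()
  delong <- list()
  perf_rows <- list()
  for (k in seq_len(nrow(combos))) {
    ch <- combos$channel[k]; roi <- combos$roi[k]
    key <- paste0(ch, ":", roi)
    cols <- feature_columns(feats, channel = ch, roi = roi)
    sc <- cfg$selection
    sc$seed <- stage_seed(gseed, paste0("select:", key))
    sel <- t_stage(paste("selection", key),
      stability_select(feats[in_train, cols, drop = FALSE],
                       feats$outcome[in_train], sc))
    selection[[key]] <- sel
    sig <- sel$final_signature
    scores <- list()
    evaluation[[key]] <- list()
    for (type in c("LR", "SVM", "RF")) {
      mc <- cfg$model
      mc$model_type <- type
      mc$seed <- stage_seed(gseed, paste0("model:", key, ":", type))
      m <- train_model(feats[in_train, sig, drop = FALSE],
                       feats$outcome[in_train], mc,
                       ids = feats$id[in_train])
      ev <- evaluate_bootstrap(m, feats[!in_train, sig, drop = FALSE],
                               feats$outcome[!in_train], mc,
                               ids = feats$id[!in_train])
      ev$model <- m
      evaluation[[key]][[type]] <- ev
      scores[[type]] <- ev$scores
      perf_rows[[paste(key, type)]] <- data.frame(
        combo = key, channel = ch, roi = roi, model_type = type,
        accuracy = ev$median["accuracy"], median_auc = ev$median["auc"],
        sensitivity = ev$median["sensitivity"],
        specificity = ev$median["specificity"],
        auc_lo = ev$ci["lower", "auc"], auc_hi = ev$ci["upper", "auc"],
        stringsAsFactors = FALSE)
    }
    delong[[key]] <- delong_compare(scores, feats$outcome[!in_train])
  }
  perf <- do.call(rbind, c(perf_rows, make.row.names = FALSE))
  best_type <- select_model_type(perf, cfg$model$auc_floor)
  perf_best <- perf[perf$model_type == best_type, ]
  best_combo <- perf_best$combo[which.max(perf_best$median_auc)]

  # permutation audit for the chosen type on the best combination
  bc_ch <- sub(":.*$", "", best_combo)
  bc_roi <- sub("^.*:", "", best_combo)
  cols <- feature_columns(feats, channel = bc_ch, roi = bc_roi)
  sc <- cfg$selection
  sc$seed <- stage_seed(gseed, paste0("permute-select:", best_combo))
  mcp <- cfg$model
  mcp$model_type <- best_type
  mcp$seed <- stage_seed(gseed, paste0("permute-model:", best_combo))
  permutation <- t_stage("permutation audit",
    permutation_audit(feats[in_train, cols, drop = FALSE],
                      feats$outcome[in_train],
                      feats[!in_train, cols, drop = FALSE],
                      feats$outcome[!in_train],
                      sel_config = sc, mod_config = mcp,
                      original = evaluation[[best_combo]][[best_type]],
                      seed = stage_seed(gseed, "permute-labels")))

  # external validation of the T1w models with frozen coefficients
  validation <- NULL
  if (!is.null(cfg$validation_cohort) &&
      "T1w" %in% attr(feats, "channels")) {
    val_spec <- cfg$validation_cohort
    val_spec$seed <- stage_seed(gseed, "validation-cohort")
    val <- t_stage("generate validation cohort", generate_cohort(val_spec))
    val <- t_stage("preprocess validation",
                   preprocess_cohort(val, threshold = cfg$threshold))
    vfeats <- t_stage("extract validation features",
                      extract_all(val, channels = "T1w",
                                  n_bins = cfg$n_bins))
    validation <- list()
    for (roi in attr(feats, "rois")) {
      key <- paste0("T1w:", roi)
      m <- evaluation[[key]][[best_type]]$model
      mc <- m$config
      mc$seed <- stage_seed(gseed, paste0("validate:", key))
      validation[[key]] <- external_validate(
        m, vfeats, vfeats$outcome, mc,
        source = ifelse(vfeats$outcome == 1, "external_MSP", "external_HCS"))
    }
  }

  # saliency map for the top signature feature of the best combination
  sal <- NULL
  if (cfg$saliency) {
    top_feat <- selection[[best_combo]]$final_signature[1]
    parts <- strsplit(top_feat, "__", fixed = TRUE)[[1]]
    subj <- dev[[match(split$test_ids[1], vapply(dev, `[[`, "", "id"))]]
    roi_mask <- switch(parts[2], WM = subj$masks$wm, NAWM = subj$masks$nawm,
                       GM = subj$masks$gm)
    sal <- t_stage("saliency map",
      saliency_map(subj$volumes[[parts[1]]], roi_mask, parts[3],
                   n_bins = cfg$n_bins))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("msradiomics")),
    global_seed = gseed,
    stage_seeds = list(cohort = stage_seed(gseed, "cohort"),
                       split = stage_seed(gseed, "split")),
    n_subjects = length(dev), n_features = length(feature_columns(feats)),
    combos = names(selection),
    signatures = lapply(selection, `[[`, "final_signature"),
    model_type = best_type, best_combo = best_combo,
    performance = perf)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "selection"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "eval"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
    write_feature_table(feats, file.path(out_dir, "features.csv"))
    for (key in names(selection)) {
      fn <- gsub("[:*]", "_", key)
      jsonlite::write_json(
        list(combo = key,
             counts = as.list(selection[[key]]$counts),
             signature = selection[[key]]$final_signature,
             n_iterations = selection[[key]]$config$n_iterations),
        file.path(out_dir, "selection", paste0(fn, ".json")),
        auto_unbox = TRUE, digits = NA)
      for (type in names(evaluation[[key]])) {
        ev <- evaluation[[key]][[type]]
        jsonlite::write_json(
          list(combo = key, model_type = type,
               median = as.list(ev$median),
               ci_lower = as.list(ev$ci["lower", ]),
               ci_upper = as.list(ev$ci["upper", ]),
               roc = list(score = ev$scores, label = ev$labels)),
          file.path(out_dir, "eval", paste0(fn, "_", type, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
    write.csv(perf, file.path(out_dir, "tables", "performance.csv"),
              row.names = FALSE)
    if (!is.null(validation)) {
      vtab <- do.call(rbind, lapply(names(validation), function(key) {
        ev <- validation[[key]]
        data.frame(combo = key, accuracy = ev$median["accuracy"],
                   auc = ev$median["auc"],
                   sensitivity = ev$median["sensitivity"],
                   specificity = ev$median["specificity"],
                   stringsAsFactors = FALSE)
      }))
      write.csv(vtab, file.path(out_dir, "tables", "validation.csv"),
                row.names = FALSE)
    }
    if (!is.null(sal)) {
      img <- RNifti::asNifti(sal$data)
      RNifti::pixdim(img) <- sal$voxel_size_mm
      RNifti::writeNifti(img, file.path(out_dir, "maps",
        paste0(gsub("[:*]", "_", sal$feature_name), ".nii.gz")))
    }
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
    files <- files[!grepl("manifest\\.json$|log\\.txt$", files)]
    manifest$file_md5 <- as.list(stats::setNames(
      unname(tools::md5sum(files)),
      sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out_dir), "/?"),
          "", files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }

  structure(list(features = feats, screen = screen, split = split,
                 selection = selection, evaluation = evaluation,
                 delong = delong, model_type = best_type,
                 performance = perf, best_combo = best_combo,
                 permutation = permutation, validation = validation,
                 saliency = sal, manifest = manifest, log = log_lines),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d combos, chosen model: %s, best: %s\n",
              length(x$selection), x$model_type, x$best_combo))
  best <- x$performance[x$performance$model_type == x$model_type, ]
  print(best[order(-best$median_auc),
             c("combo", "accuracy", "median_auc", "sensitivity",
               "specificity")], row.names = FALSE)
  invisible(x)
}
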