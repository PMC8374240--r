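sanitize_channel <- function(ch) gsub("\\*", "star", ch)

#' Write / read a cohort as NIfTI files plus a cohort CSV
#'
#' One NIfTI file per subject per channel (`<id>_<channel>.nii.gz`) and per
#' tissue probability map (`<id>_prob_<tissue>.nii.gz`, float), plus
#' `cohort.csv` with id, status, age, gender and scanner. `R2*` is encoded
#' as `R2star` in filenames.
#'
#' @param cohort an `ms_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   the `ms_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) {
    for (ch in names(s$volumes)) {
      v <- s$volumes[[ch]]
      img <- RNifti::asNifti(v$data)
      RNifti::pixdim(img) <- v$voxel_size_mm
      RNifti::writeNifti(img, file.path(
        dir, sprintf("%s_%s.nii.gz", s$id, sanitize_channel(ch))))
    }
    vs <- s$volumes[[1]]$voxel_size_mm
    for (tp in names(s$prob_maps)) {
      img <- RNifti::asNifti(s$prob_maps[[tp]])
      RNifti::pixdim(img) <- vs
      RNifti::writeNifti(img, file.path(
        dir, sprintf("%s_prob_%s.nii.gz", s$id, tp)))
    }
  }
  write.csv(cohort_table(cohort), file.path(dir, "cohort.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param channels channels to read back (default: all five, when present
#'   on disk).
#' @export
read_cohort <- function(dir, channels = c("T1w", "PD", "MT", "R1", "R2*")) {
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(tab)), function(k) {
    id <- tab$id[k]
    volumes <- list()
    for (ch in channels) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", id, sanitize_channel(ch)))
      if (!file.exists(f)) next
      img <- RNifti::readNifti(f)
      volumes[[ch]] <- volume(array(as.numeric(img), dim(img)),
                              RNifti::pixdim(img), ch)
    }
    prob_maps <- list()
    for (tp in c("csf", "gm", "nawm", "lesion")) {
      f <- file.path(dir, sprintf("%s_prob_%s.nii.gz", id, tp))
      if (file.exists(f)) {
        img <- RNifti::readNifti(f)
        prob_maps[[tp]] <- array(as.numeric(img), dim(img))
      }
    }
    structure(list(id = id, status = tab$status[k], age = tab$age[k],
                   gender = tab$gender[k], scanner = tab$scanner[k],
                   volumes = volumes, prob_maps = prob_maps),
              class = "ms_subject")
  })
  structure(subjects, class = "ms_cohort")
}

#' Build a cohort specification from a YAML file
#'
#' The YAML keys mirror the [cohort_spec()] arguments; `effect` is a block
#' with `mean_shift` / `texture_shift` maps (keys `"<channel>:<ROI>"`) and
#' `null_effect`.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A `cohort_spec`.
#' @export
cohort_spec_from_yaml <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  eff <- if (!is.null(cfg$effect)) {
    eargs <- list(null_effect = isTRUE(cfg$effect$null_effect))
    if (!is.null(cfg$effect$mean_shift)) {
      eargs$mean_shift <- unlist(cfg$effect$mean_shift)
    }
    if (!is.null(cfg$effect$texture_shift)) {
      eargs$texture_shift <- unlist(cfg$effect$texture_shift)
    }
    do.call(effect_spec, eargs)
  } else effect_spec()
  args <- cfg[setdiff(names(cfg), "effect")]
  args$effect <- eff
  args <- args[names(args) %in% names(formals(cohort_spec))]
  do.call(cohort_spec, args)
}
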