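# Channel intensity model: documented constants, arbitrary units for T1w and
# plausible physical scales for the qMRI maps (PD in p.u., MT in p.u.,
# R1 and R2* in 1/s). Order: csf, gm, wm.
CHANNEL_MEANS <- list(
  "T1w" = c(csf = 40,   gm = 80,   wm = 110),
  "PD"  = c(csf = 100,  gm = 82,   wm = 70),
  "MT"  = c(csf = 0.3,  gm = 1.2,  wm = 2.0),
  "R1"  = c(csf = 0.25, gm = 0.65, wm = 1.05),
  "R2*" = c(csf = 1,    gm = 15,   wm = 21)
)

# Lesion contrast as a multiplicative factor on the subject's WM mean:
# hypo-intense on T1w and MT, hyper-intense on PD, mildly hypo on R1/R2*
# (demyelination lowers R1 and R2*).
LESION_FACTORS <- c("T1w" = 0.85, "PD" = 1.15, "MT" = 0.70,
                    "R1" = 0.85, "R2*" = 0.80)

#' Class-effect specification for the synthetic cohort
#'
#' Defines the planted differences between MS patients and controls:
#' additive shifts of tissue mean intensity and shifts of the spatial
#' correlation length of intra-tissue fluctuations, per (channel, ROI).
#' Keys are `"<channel>:<ROI>"` with ROI in `WM`, `NAWM`, `GM`; `WM` and
#' `NAWM` both address the lesion-free white matter tissue (the WM ROI is
#' NAWM plus lesions, and lesions carry their own contrast constants).
#'
#' The defaults emulate diffuse qMRI alterations in NAWM and GM of patients
#' (reduced myelin-sensitive MT/R1, mildly increased water-sensitive PD,
#' reduced R2*), with no diffuse T1w effect: conventional T1w contrast only
#' sees the focal lesions.
#'
#' @param mean_shift named numeric vector of additive tissue-mean shifts in
#'   channel units applied to MSP subjects.
#' @param texture_shift named numeric vector of additive shifts (mm) to the
#'   correlation length of the intra-tissue random field for MSP subjects.
#' @param null_effect if `TRUE`, all planted class differences are exactly
#'   zero: mean shifts, texture shifts, lesion contrast and the focal
#'   lesions themselves are suppressed, so the two classes are fully
#'   exchangeable.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(mean_shift = c("MT:NAWM" = -0.10, "MT:GM" = -0.06,
                                       "R1:NAWM" = -0.05, "R1:GM" = -0.03,
                                       "R2*:NAWM" = -1.0, "PD:NAWM" = 2.0),
                        texture_shift = c("MT:NAWM" = 0.5),
                        null_effect = FALSE) {
  structure(list(mean_shift = mean_shift, texture_shift = texture_shift,
                 null_effect = isTRUE(null_effect)),
            class = "effect_spec")
}

effect_lookup <- function(eff, kind, channel, roi) {
  if (eff$null_effect) return(0)
  v <- eff[[kind]]
  if (is.null(v) || !length(v)) return(0)
  keys <- if (roi %in% c("WM", "NAWM")) {
    paste0(channel, ":", c("WM", "NAWM"))
  } else paste0(channel, ":", roi)
  hit <- keys[keys %in% names(v)]
  if (!length(hit)) 0 else sum(v[hit])
}

#' Synthetic cohort specification
#'
#' Parameters of the seeded phantom-cohort generator. The defaults emulate
#' the development dataset the pipeline assumes: 36 patients and 36
#' controls, five image channels, two scanners, 1-mm-class brain geometry
#' downsampled to a desk-scale grid.
#'
#' @param n_hcs,n_msp numbers of healthy controls and MS patients (each >= 2).
#' @param channels image channels to synthesize.
#' @param grid_shape 3 integers (each >= 32), grid size in voxels.
#' @param voxel_size_mm 3 positive reals, voxel spacing.
#' @param n_scanners number of scanner labels assigned round-robin.
#' @param lesion_count_range integer range of focal lesions per patient.
#' @param lesion_radius_range_mm real range of lesion radii (mm).
#' @param effect an [effect_spec()].
#' @param noise_sigma i.i.d. noise SD per channel; a named vector in channel
#'   units, or `NULL` for the default 4% of the channel's WM mean.
#' @param bias_amplitude relative amplitude of the multiplicative
#'   low-frequency bias field applied to T1w (default 0.2).
#' @param subject_sd_frac between-subject SD of tissue means as a fraction
#'   of the tissue mean (default 0.03).
#' @param texture_sigma_mm baseline correlation length of intra-tissue
#'   fluctuations (default 3 mm).
#' @param texture_amp_frac SD of the correlated intra-tissue field as a
#'   fraction of the channel's WM mean (default 0.06).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hcs = 36, n_msp = 36,
                        channels = c("T1w", "PD", "MT", "R1", "R2*"),
                        grid_shape = c(64, 64, 64),
                        voxel_size_mm = c(2.5, 2.5, 2.5),
                        n_scanners = 2,
                        lesion_count_range = c(3, 8),
                        lesion_radius_range_mm = c(4, 6),
                        effect = effect_spec(),
                        noise_sigma = NULL,
                        bias_amplitude = 0.2,
                        subject_sd_frac = 0.03,
                        texture_sigma_mm = 3,
                        texture_amp_frac = 0.06,
                        seed = 1) {
  stopifnot(n_hcs >= 2, n_msp >= 2, all(grid_shape >= 32),
            all(voxel_size_mm > 0), n_scanners >= 1,
            lesion_count_range[1] >= 0,
            diff(lesion_count_range) >= 0,
            lesion_radius_range_mm[1] > 0, bias_amplitude >= 0)
  channels <- match.arg(channels, names(CHANNEL_MEANS), several.ok = TRUE)
  if (is.null(noise_sigma)) {
    noise_sigma <- vapply(channels, function(ch) 0.04 * CHANNEL_MEANS[[ch]]["wm"],
                          numeric(1))
    names(noise_sigma) <- channels
  }
  structure(list(
    n_hcs = as.integer(n_hcs), n_msp = as.integer(n_msp),
    channels = channels, grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    n_scanners = as.integer(n_scanners),
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
    effect = effect, noise_sigma = noise_sigma,
    bias_amplitude = bias_amplitude,
    subject_sd_frac = subject_sd_frac,
    texture_sigma_mm = texture_sigma_mm,
    texture_amp_frac = texture_amp_frac,
    seed = as.integer(seed)), class = "cohort_spec")
}

# ---- geometry --------------------------------------------------------------

# normalized ellipsoid radius field: u <= 1 inside the head, with nested
# shells background -> CSF -> GM -> WM along decreasing u
ellipsoid_u <- function(grid_shape, voxel_size_mm) {
  ext <- grid_shape * voxel_size_mm
  A <- c(0.42, 0.38, 0.40) * ext  # semi-axes in mm, slightly anisotropic
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - ctr[a]) *
                                   voxel_size_mm[a] / A[a])^2)
  u2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  sqrt(u2)
}

U_WM <- 0.62   # WM core: u <= U_WM
U_GM <- 0.88   # GM shell: U_WM < u <= U_GM; CSF: U_GM < u <= 1

# separable Gaussian smoothing with edge-renormalized kernels (constants are
# preserved, probabilities stay in [0, 1])
gsmooth3d <- function(x, sigma_vox) {
  d <- dim(x)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    n <- d[a]
    h <- max(1L, ceiling(3 * s))
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * s^2))
      w * (abs(i - j) <= h)
    })
    K <- K / rowSums(K)
    m <- matrix(aperm(x, c(a, setdiff(1:3, a))), nrow = n)
    sm <- K %*% m
    x <- aperm(array(sm, c(d[a], d[setdiff(1:3, a)])),
               order(c(a, setdiff(1:3, a))))
  }
  x
}

# place n spherical lesions fully inside the WM core; lesions are kept
# pairwise separated (so that requested lesion counts survive as distinct
# probability-map components) when space allows, and are allowed to become
# confluent in crowded configurations. Returns list(centers (n x 3, mm from
# grid center), radii).
place_lesions <- function(n, radius_range, grid_shape, voxel_size_mm,
                          subject_id) {
  ext <- grid_shape * voxel_size_mm
  A <- c(0.42, 0.38, 0.40) * ext
  margin <- 1.5 * max(voxel_size_mm)
  sep <- 3 * max(voxel_size_mm)
  centers <- matrix(NA_real_, n, 3)
  radii <- numeric(n)
  for (k in seq_len(n)) {
    r <- runif(1, radius_range[1], radius_range[2])
    u_max <- U_WM - (r + margin) / min(A)
    if (u_max <= 0) {
      stop(sprintf("subject %s: lesion radius %.1f mm too large to fit inside WM",
                   subject_id, r))
    }
    ok <- FALSE
    for (try in seq_len(1000)) {
      p <- runif(3, -1, 1) * u_max * A
      u_c <- sqrt(sum((p / A)^2))
      if (u_c > u_max) next
      if (k > 1 && try <= 500) {
        dd <- sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                              matrix(p, k - 1, 3, byrow = TRUE))^2))
        if (any(dd < radii[seq_len(k - 1)] + r + sep)) next
      }
      centers[k, ] <- p
      radii[k] <- r
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf("subject %s: could not place lesion %d inside WM",
                   subject_id, k))
    }
  }
  list(centers = centers, radii = radii)
}

# ---- generator -------------------------------------------------------------

#' Generate a seeded synthetic cohort
#'
#' Builds multi-channel brain phantoms with tissue probability maps,
#' class-dependent focal lesions and diffuse mean/texture effects, plus
#' demographics. The brain is a set of nested ellipsoids (background ->
#' CSF -> GM shell -> WM core); per-tissue intensity is tissue mean (with
#' between-subject jitter and, for patients, the planted [effect_spec()]
#' shifts) plus a spatially correlated Gaussian field plus i.i.d. noise;
#' a multiplicative low-frequency bias field is applied to T1w only. MSP
#' subjects receive spherical lesions placed fully inside the WM core with
#' channel-specific lesion contrast. Probability maps are smoothed
#' indicator functions, so downstream thresholding at 0.9 is non-trivial.
#' Ages are uniform on [25, 65]; genders and scanners alternate
#' round-robin.
#'
#' @param spec a [cohort_spec()].
#' @return A list of subjects (class `ms_cohort`); each subject has fields
#'   `id`, `status` (0 = HCS, 1 = MSP), `age`, `gender`, `scanner`,
#'   `volumes` (named list of [volume()]s) and `prob_maps` (named list of
#'   3D probability arrays for `csf`, `gm`, `nawm`, `lesion`; the stored
#'   white-matter map is the lesion-free NAWM probability, lesions have
#'   their own map).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  vs <- spec$voxel_size_mm
  u <- ellipsoid_u(gs, vs)
  ind_wm_all <- u <= U_WM
  ind_gm <- u > U_WM & u <= U_GM
  ind_csf <- u > U_GM & u <= 1
  ctr <- (gs + 1) / 2
  coords <- list(
    x = (seq_len(gs[1]) - ctr[1]) * vs[1],
    y = (seq_len(gs[2]) - ctr[2]) * vs[2],
    z = (seq_len(gs[3]) - ctr[3]) * vs[3]
  )
  n_tot <- spec$n_hcs + spec$n_msp
  status <- rep(c(0L, 1L), c(spec$n_hcs, spec$n_msp))
  ids <- sprintf("%s%02d", ifelse(status == 1, "MSP", "HCS"),
                 c(seq_len(spec$n_hcs), seq_len(spec$n_msp)))
  genders <- rep(c("M", "F"), length.out = n_tot)
  scanners <- paste0("scanner", rep(seq_len(spec$n_scanners),
                                    length.out = n_tot))
  smooth_sigma_vox <- 0.5
  subjects <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    is_msp <- status[s] == 1L
    # lesion geometry (patients only); a null-effect cohort has no lesions
    # either, so the two classes are fully exchangeable
    ind_lesion <- array(FALSE, gs)
    if (is_msp && !spec$effect$null_effect && spec$lesion_count_range[2] > 0) {
      n_les <- if (diff(spec$lesion_count_range) == 0)
        spec$lesion_count_range[1]
      else sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
      if (n_les > 0) {
        les <- place_lesions(n_les, spec$lesion_radius_range_mm, gs, vs,
                             ids[s])
        for (k in seq_len(n_les)) {
          dx2 <- outer(outer((coords$x - les$centers[k, 1])^2,
                             (coords$y - les$centers[k, 2])^2, "+"),
                       (coords$z - les$centers[k, 3])^2, "+")
          ind_lesion <- ind_lesion | (dx2 <= les$radii[k]^2)
        }
        ind_lesion <- ind_lesion & ind_wm_all
      }
    }
    ind_nawm <- ind_wm_all & !ind_lesion
    clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
    prob_maps <- list(
      csf = clamp01(gsmooth3d(ind_csf * 1, smooth_sigma_vox)),
      gm = clamp01(gsmooth3d(ind_gm * 1, smooth_sigma_vox)),
      nawm = clamp01(gsmooth3d(ind_nawm * 1, smooth_sigma_vox)),
      lesion = clamp01(gsmooth3d(ind_lesion * 1, smooth_sigma_vox))
    )
    # trim negligible smoothing tails so distinct lesions keep distinct
    # probability-map components
    prob_maps$lesion[prob_maps$lesion < 0.02] <- 0
    inside <- u <= 1
    volumes <- list()
    for (ch in spec$channels) {
      mu <- CHANNEL_MEANS[[ch]]
      jit <- rnorm(3, 0, spec$subject_sd_frac) # csf, gm, wm relative jitter
      mu_csf <- mu["csf"] * (1 + jit[1])
      mu_gm <- mu["gm"] * (1 + jit[2]) +
        (if (is_msp) effect_lookup(spec$effect, "mean_shift", ch, "GM") else 0)
      mu_nawm <- mu["wm"] * (1 + jit[3]) +
        (if (is_msp) effect_lookup(spec$effect, "mean_shift", ch, "NAWM") else 0)
      les_factor <- if (spec$effect$null_effect) 1 else LESION_FACTORS[[ch]]
      mu_les <- mu_nawm * les_factor
      amp <- spec$texture_amp_frac * mu["wm"]
      sig_nawm <- spec$texture_sigma_mm +
        (if (is_msp) effect_lookup(spec$effect, "texture_shift", ch, "NAWM") else 0)
      sig_gm <- spec$texture_sigma_mm +
        (if (is_msp) effect_lookup(spec$effect, "texture_shift", ch, "GM") else 0)
      f_wm <- gsmooth3d(array(rnorm(prod(gs)), gs), sig_nawm / vs)
      f_wm <- f_wm / sd(f_wm)
      f_gm <- gsmooth3d(array(rnorm(prod(gs)), gs), sig_gm / vs)
      f_gm <- f_gm / sd(f_gm)
      f_csf <- gsmooth3d(array(rnorm(prod(gs)), gs),
                         spec$texture_sigma_mm / vs)
      f_csf <- f_csf / sd(f_csf)
      img <- array(0, gs)
      img[ind_csf] <- mu_csf + amp * f_csf[ind_csf]
      img[ind_gm] <- mu_gm + amp * f_gm[ind_gm]
      img[ind_nawm] <- mu_nawm + amp * f_wm[ind_nawm]
      img[ind_lesion] <- mu_les + amp * f_wm[ind_lesion]
      ns <- spec$noise_sigma[[ch]]
      img[inside] <- img[inside] + rnorm(sum(inside), 0, ns)
      if (ch == "T1w" && spec$bias_amplitude > 0) {
        B <- gsmooth3d(array(rnorm(prod(gs)), gs), 40 / vs)
        B <- B / max(abs(B))
        img <- img * (1 + spec$bias_amplitude * B)
      }
      volumes[[ch]] <- volume(img, vs, ch)
    }
    subjects[[s]] <- structure(list(
      id = ids[s], status = status[s],
      age = runif(1, 25, 65), gender = genders[s], scanner = scanners[s],
      volumes = volumes, prob_maps = prob_maps), class = "ms_subject")
  }
  structure(subjects, class = "ms_cohort")
}

#' @export
`[.ms_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  st <- vapply(x, function(s) s$status, integer(1))
  cat(sprintf("<ms_cohort> %d subjects (%d HCS, %d MSP), channels: %s\n",
              length(x), sum(st == 0), sum(st == 1),
              paste(names(x[[1]]$volumes), collapse = ", ")))
  invisible(x)
}

#' @export
print.ms_subject <- function(x, ...) {
  cat(sprintf("<ms_subject> %s status=%d age=%.1f %s %s channels=%s\n",
              x$id, x$status, x$age, x$gender, x$scanner,
              paste(names(x$volumes), collapse = ",")))
  invisible(x)
}

#' Cohort demographics table
#'
#' @param cohort an `ms_cohort`.
#' @return data.frame with id, status, age, gender, scanner.
#' @export
cohort_table <- function(cohort) {
  data.frame(
    id = vapply(cohort, `[[`, character(1), "id"),
    status = vapply(cohort, `[[`, integer(1), "status"),
    age = vapply(cohort, `[[`, numeric(1), "age"),
    gender = vapply(cohort, `[[`, character(1), "gender"),
    scanner = vapply(cohort, `[[`, character(1), "scanner"),
    stringsAsFactors = FALSE
  )
}
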