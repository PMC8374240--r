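test_that("generation is bitwise deterministic given the seed", {
  spec <- cohort_spec(n_hcs = 2, n_msp = 2, channels = "MT",
                      grid_shape = c(32, 32, 32),
                      effect = effect_spec(null_effect = TRUE), seed = 17)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
})

test_that("lesions appear only in patients, as separated components in WM", {
  spec <- cohort_spec(n_hcs = 2, n_msp = 3, channels = "MT",
                      grid_shape = c(40, 40, 40),
                      lesion_count_range = c(2, 2),
                      lesion_radius_range_mm = c(4, 5), seed = 23)
  co <- generate_cohort(spec)
  for (s in co) {
    if (s$status == 0) {
      expect_true(all(s$prob_maps$lesion == 0), label = s$id)
    } else {
      supp <- array(s$prob_maps$lesion > 0, dim(s$prob_maps$lesion))
      comp <- bf_glszm(array(as.integer(supp), dim(supp)))
      expect_equal(nrow(comp), 2L, label = s$id)
      # lesion support lies inside the WM support (nawm + lesion indicator)
      wm_supp <- (s$prob_maps$nawm + s$prob_maps$lesion) > 0
      expect_true(all(wm_supp[supp]), label = s$id)
    }
  }
})

test_that("oversized lesions raise an error naming the subject", {
  spec <- cohort_spec(n_hcs = 2, n_msp = 2, channels = "MT",
                      grid_shape = c(32, 32, 32),
                      lesion_count_range = c(1, 1),
                      lesion_radius_range_mm = c(60, 60), seed = 2)
  expect_error(generate_cohort(spec), "MSP01")
})

test_that("tissue probabilities sum to at most one everywhere", {
  co <- small_cohort()
  s <- co[[length(co)]]
  tot <- s$prob_maps$csf + s$prob_maps$gm + s$prob_maps$nawm +
    s$prob_maps$lesion
  expect_lte(max(tot), 1 + 1e-8)
  expect_gte(min(tot), 0)
})

test_that("a planted mean shift moves the class tissue means by that amount", {
  shift <- -0.3
  eff <- effect_spec(mean_shift = c("MT:WM" = shift), texture_shift = c())
  spec <- cohort_spec(n_hcs = 6, n_msp = 6, channels = "MT",
                      grid_shape = c(32, 32, 32), lesion_count_range = c(0, 0),
                      effect = eff, seed = 31)
  co <- generate_cohort(spec)
  wm_mean <- vapply(co, function(s) {
    wm <- (s$prob_maps$nawm + s$prob_maps$lesion) >= 0.99
    mean(s$volumes$MT$data[wm])
  }, numeric(1))
  status <- vapply(co, `[[`, integer(1), "status")
  observed <- mean(wm_mean[status == 1]) - mean(wm_mean[status == 0])
  # planted shift recovered within the between-subject noise tolerance
  expect_equal(observed, shift, tolerance = 0.35)
  expect_lt(observed, -0.15)
})

test_that("null-effect cohorts show no class leakage in tissue means", {
  n_seeds <- 30
  pvals <- matrix(NA_real_, n_seeds, 2)
  for (k in seq_len(n_seeds)) {
    spec <- cohort_spec(n_hcs = 5, n_msp = 5, channels = "MT",
                        grid_shape = c(32, 32, 32),
                        effect = effect_spec(null_effect = TRUE),
                        seed = 1000 + k)
    co <- generate_cohort(spec)
    tiss_means <- t(vapply(co, function(s) {
      c(nawm = mean(s$volumes$MT$data[s$prob_maps$nawm >= 0.99]),
        gm = mean(s$volumes$MT$data[s$prob_maps$gm >= 0.99]))
    }, numeric(2)))
    status <- vapply(co, `[[`, integer(1), "status")
    pvals[k, 1] <- t.test(tiss_means[status == 1, 1],
                          tiss_means[status == 0, 1])$p.value
    pvals[k, 2] <- t.test(tiss_means[status == 1, 2],
                          tiss_means[status == 0, 2])$p.value
  }
  # ~5% rejections at alpha = 0.05: allow generous binomial slack
  rej <- mean(pvals < 0.05)
  expect_lt(rej, 0.20)
})

test_that("demographics follow the documented assignment rules", {
  co <- small_cohort()
  tab <- cohort_table(co)
  expect_true(all(tab$age >= 25 & tab$age <= 65))
  expect_equal(tab$gender, rep(c("M", "F"), length.out = nrow(tab)))
  expect_equal(sort(unique(tab$scanner)), c("scanner1", "scanner2"))
  expect_equal(tab$status, rep(c(0L, 1L), each = 3))
})

test_that("cohorts round-trip through NIfTI files and the cohort CSV", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir, channels = c("T1w", "MT"))
  expect_equal(length(back), length(co))
  expect_equal(back[[1]]$id, co[[1]]$id)
  expect_equal(back[[1]]$volumes$MT$data, co[[1]]$volumes$MT$data,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back[[1]]$volumes$MT$voxel_size_mm, co[[1]]$volumes$MT$voxel_size_mm)
  expect_equal(back[[4]]$prob_maps$lesion, co[[4]]$prob_maps$lesion,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("cohort specs can be described in YAML", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_hcs: 4", "n_msp: 4", "channels: [MT, R1]",
    "grid_shape: [32, 32, 32]", "seed: 9",
    "effect:", "  null_effect: false",
    "  mean_shift:", "    'MT:WM': -0.2"), yml)
  spec <- cohort_spec_from_yaml(yml)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_hcs, 4L)
  expect_equal(spec$channels, c("MT", "R1"))
  expect_equal(spec$effect$mean_shift[["MT:WM"]], -0.2)
})
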