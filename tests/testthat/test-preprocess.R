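test_that("resampling is exact on identity, constants and linear ramps", {
  set.seed(3)
  v <- volume(array(rnorm(5^3), c(5, 5, 5)), c(1, 1, 1))
  same <- resample_isotropic(v, 1)
  expect_equal(same$data, v$data, tolerance = 1e-9)

  vc <- volume(array(4.2, c(6, 6, 6)), c(2, 2, 2))
  out <- resample_isotropic(vc, 1.5)
  expect_equal(dim(out$data), c(8L, 8L, 8L))
  expect_equal(range(out$data), c(4.2, 4.2), tolerance = 1e-9)

  # linear ramp along x at 2 mm resampled to 1 mm: cubic splines reproduce
  # polynomials of degree <= 3 exactly
  n <- 10
  ramp <- array(rep((seq_len(n) - 0.5) * 2, times = n * n), c(n, n, n))
  vr <- volume(ramp, c(2, 2, 2))
  out <- resample_isotropic(vr, 1)
  expected <- (seq_len(20) - 0.5) * 1
  interior <- 3:18
  expect_equal(out$data[interior, 1, 1], expected[interior], tolerance = 1e-6)
  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("mask thresholding is boundary-inclusive with priority conflicts", {
  d <- c(2, 2, 1)
  mk <- function(...) array(c(...), d)
  pm <- list(csf = mk(0.90, 0, 0, 0), gm = mk(0, 0.95, 0, 0.2),
             nawm = mk(0, 0, 0.95, 0.91), lesion = mk(0, 0, 0.97, 0))
  m <- threshold_masks(pm, 0.9)
  expect_true(m$csf[1, 1, 1])        # 0.90 is included (>= threshold)
  expect_true(m$gm[2, 1, 1])
  # voxel 3: nawm 0.95 vs lesion 0.97 -> lesion wins, wm contains it anyway
  expect_true(m$lesion[1, 2, 1])
  expect_false(m$nawm[1, 2, 1])
  expect_true(m$wm[1, 2, 1])
  expect_true(m$nawm[2, 2, 1])
  # composites
  expect_equal(m$wm, m$nawm | m$lesion)
  expect_equal(m$tiv, m$csf | m$gm | m$nawm | m$lesion)

  all_half <- list(csf = mk(0.5, 0.5, 0.5, 0.5), gm = mk(0.5, 0.5, 0.5, 0.5),
                   nawm = mk(0.5, 0.5, 0.5, 0.5))
  expect_error(threshold_masks(all_half, 0.9), "empty")
})

test_that("masks are pairwise disjoint and WM composition holds per class", {
  co <- small_cohort()
  for (s in co) {
    m <- s$masks
    expect_equal(sum(m$csf & m$gm), 0)
    expect_equal(sum(m$gm & m$nawm), 0)
    expect_equal(sum(m$nawm & m$lesion), 0)
    expect_equal(m$wm, m$nawm | m$lesion)
    if (s$status == 0) expect_equal(m$wm, m$nawm)  # controls: WM == NAWM
    else expect_gt(sum(m$lesion), 0)
  }
})

test_that("bias correction recovers a planted smooth field and is gentle
           on clean input", {
  # phantom generated without bias and with fine intra-tissue texture, so
  # "bias-free" is well defined (low-frequency texture is ambiguous with
  # bias by nature)
  spec <- cohort_spec(n_hcs = 2, n_msp = 2, channels = "T1w",
                      grid_shape = c(32, 32, 32),
                      lesion_count_range = c(1, 2),
                      lesion_radius_range_mm = c(4, 5),
                      bias_amplitude = 0, texture_sigma_mm = 1.5,
                      texture_amp_frac = 0.03, seed = 42)
  s <- generate_cohort(spec)[[1]]
  tiv <- threshold_masks(s$prob_maps)$tiv
  raw <- s$volumes$T1w

  # clean input passes through nearly unchanged
  out0 <- correct_bias(raw, tiv)
  rel0 <- abs(out0$data[tiv] - raw$data[tiv]) / mean(raw$data[tiv])
  expect_lt(max(rel0), 0.02)

  # planted low-order 20% field is removed to within 5%
  d <- dim(raw$data)
  g <- function(n) 2 * (seq_len(n) - 1) / (n - 1) - 1
  fx <- outer(outer(g(d[1]), 0.6 * g(d[2]), "+"), 0.3 * g(d[3]), "+")
  field <- 1 + 0.2 * fx / max(abs(fx))
  biased <- volume(raw$data * field, raw$voxel_size_mm, "T1w")
  fixed <- correct_bias(biased, tiv)
  rel <- abs(fixed$data[tiv] - raw$data[tiv]) / mean(raw$data[tiv])
  expect_lt(max(rel), 0.05)
  # mean within TIV preserved
  expect_equal(mean(fixed$data[tiv]), mean(biased$data[tiv]),
               tolerance = 1e-6)

  # constant image stays constant
  vc <- volume(array(7, d), raw$voxel_size_mm, "T1w")
  expect_equal(correct_bias(vc, tiv)$data, vc$data)
})

test_that("TIV normalization uses the population SD over TIV voxels only", {
  d <- c(3, 1, 1)
  v <- volume(array(c(1, 2, 3), d), channel = "T1w")
  tiv <- array(TRUE, d)
  out <- normalize_tiv(v, tiv)
  expect_equal(as.vector(out$data), c(-1.224744871, 0, 1.224744871),
               tolerance = 1e-8)

  # voxels outside TIV never enter mu/sigma but are transformed
  d2 <- c(4, 1, 1)
  v2 <- volume(array(c(1, 2, 3, 1000), d2), channel = "T1w")
  tiv2 <- array(c(TRUE, TRUE, TRUE, FALSE), d2)
  out2 <- normalize_tiv(v2, tiv2)
  expect_equal(as.vector(out2$data[1:3]), c(-1.224744871, 0, 1.224744871),
               tolerance = 1e-8)
  expect_gt(out2$data[4], 100)

  # idempotence
  out3 <- normalize_tiv(out2, tiv2)
  expect_equal(out3$data, out2$data, tolerance = 1e-9)
  vc <- volume(array(5, d), channel = "T1w")
  expect_error(normalize_tiv(vc, tiv), "variance")
  expect_error(normalize_tiv(volume(array(1:8, c(2,2,2)), channel = "MT"),
                             array(TRUE, c(2,2,2))), "T1w")
})

test_that("re-running preprocessing on its own output is a no-op for T1w", {
  spec <- cohort_spec(n_hcs = 2, n_msp = 2, channels = "T1w",
                      grid_shape = c(32, 32, 32), seed = 77)
  co <- generate_cohort(spec)
  once <- preprocess_subject(co[[1]])
  twice <- preprocess_subject(once)
  expect_lt(max(abs(twice$volumes$T1w$data - once$volumes$T1w$data)), 1e-6)
  expect_equal(twice$masks, once$masks)
  # within-TIV mean 0, SD 1 after the first pass
  w <- once$volumes$T1w$data[once$masks$tiv]
  expect_equal(mean(w), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((w - mean(w))^2)), 1, tolerance = 1e-9)
})
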