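test_that("fixed-bin-number discretization follows the level formula", {
  v <- volume(array(c(0, 0.5, 1.0, 0), c(4, 1, 1)))
  roi <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  d <- discretize_fbn(v, roi, n_bins = 2, padding = 0)
  expect_equal(as.integer(d$levels[d$roi_mask]), c(1L, 2L, 2L))

  # constant ROI: single occupied bin at level 1
  vc <- volume(array(7, c(3, 3, 3)))
  dc <- discretize_fbn(vc, array(TRUE, c(3, 3, 3)), n_bins = 50)
  expect_true(all(dc$levels == 1L))

  # levels always within [1, n_bins]
  set.seed(1)
  vr <- volume(array(rnorm(4^3), c(4, 4, 4)))
  dr <- discretize_fbn(vr, array(TRUE, c(4, 4, 4)), n_bins = 50)
  expect_gte(min(dr$levels), 1L)
  expect_lte(max(dr$levels), 50L)
  expect_error(discretize_fbn(vr, array(FALSE, c(4, 4, 4))), "empty ROI")
})

test_that("bounding box crop keeps 5-voxel padding clipped at borders", {
  v <- volume(array(rnorm(20^3), c(20, 20, 20)))
  roi <- array(FALSE, c(20, 20, 20))
  roi[9:12, 9:12, 2:4] <- TRUE
  d <- discretize_fbn(v, roi, n_bins = 10, padding = 5)
  expect_equal(unname(d$bounding_box["min", ]), c(4L, 4L, 1L))
  expect_equal(unname(d$bounding_box["max", ]), c(17L, 17L, 9L))
})

test_that("first-order features match hand computation and conventions", {
  v <- volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  roi <- array(TRUE, c(4, 1, 1))
  f <- extract_features(v, roi, n_bins = 4)
  expect_equal(f[["firstorder_Mean"]], 2.5)
  expect_equal(f[["firstorder_Variance"]], 1.25)  # population variance
  expect_equal(f[["firstorder_Range"]], 3)
  expect_equal(f[["firstorder_Energy"]], 1 + 4 + 9 + 16)

  # constant ROI conventions
  vc <- volume(array(5, c(3, 3, 3)))
  fc <- extract_features(vc, array(TRUE, c(3, 3, 3)), n_bins = 50)
  expect_equal(fc[["firstorder_Mean"]], 5)
  expect_equal(fc[["firstorder_Median"]], 5)
  expect_equal(fc[["firstorder_Variance"]], 0)
  expect_equal(fc[["firstorder_Skewness"]], 0)
  expect_equal(fc[["firstorder_Uniformity"]], 1)
  expect_equal(fc[["firstorder_Entropy"]], 0)
})

test_that("the registry has 93 features and extraction returns them all", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 93L)
  expect_equal(as.vector(table(reg$family)[c("firstorder", "glcm", "glrlm",
                                             "glszm", "ngtdm", "gldm")]),
               c(18L, 24L, 16L, 16L, 5L, 14L))
  # headline feature names from the study are extractable
  expect_true("firstorder_Minimum" %in% reg$feature)
  expect_true("glcm_ClusterShade" %in% reg$feature)
  expect_true("gldm_LargeDependenceHighGrayLevelEmphasis" %in% reg$feature)
  expect_true("gldm_SmallDependenceLowGrayLevelEmphasis" %in% reg$feature)
  set.seed(2)
  v <- volume(array(rnorm(6^3), c(6, 6, 6)))
  f <- extract_features(v, array(TRUE, c(6, 6, 6)))
  expect_named(f, reg$feature)
  expect_true(all(is.finite(f)))
})

test_that("GLCM matches brute-force pair enumeration on the line example", {
  lev <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  d <- dro_from_levels(lev, n_bins = 2)
  counts <- cpp_mat("cpp_glcm", as.integer(lev), dim(lev), 2L)
  oracle <- bf_glcm(lev, 2)
  expect_equal(unclass(counts), oracle, ignore_attr = TRUE)
  # z-axis direction: symmetrized counts sum to 6
  M <- counts[, , 3]
  expect_equal(sum(M), 6)
  expect_equal(M[1, 1], 2)
  expect_equal(M[1, 2], 1)
  expect_equal(M[2, 1], 1)
  expect_equal(M[2, 2], 2)
  # joint entropy of the normalized matrix {2/6, 2/6, 1/6, 1/6}
  P <- M / sum(M)
  expect_equal(-sum(P * log2(P)), 1.918296, tolerance = 1e-6)
  f <- glcm_features(d)
  expect_true(is.finite(f[["glcm_JointEntropy"]]))
})

test_that("constant ROI GLCM uses the degenerate conventions", {
  d <- dro_from_levels(array(1L, c(3, 3, 3)), n_bins = 50)
  f <- glcm_features(d)
  expect_equal(f[["glcm_ClusterShade"]], 0)
  expect_equal(f[["glcm_Correlation"]], 1)  # zero-variance convention
  expect_equal(f[["glcm_JointEntropy"]], 0)
  expect_equal(f[["glcm_MaximumProbability"]], 1)
})

test_that("GLRLM matches run enumeration on the 1x1x5 example", {
  lev <- array(c(1L, 1L, 1L, 2L, 2L), c(1, 1, 5))
  counts <- cpp_mat("cpp_glrlm", as.integer(lev), dim(lev), 2L)
  oracle <- bf_glrlm(lev, 2)
  # same max-run-length padding before comparing
  expect_equal(unclass(counts)[, 1:5, ], oracle[, 1:5, ], ignore_attr = TRUE)
  # z-axis direction: one run of length 3 (level 1), one of length 2 (level 2)
  M <- counts[, , 3]
  expect_equal(M[1, 3], 1)
  expect_equal(M[2, 2], 1)
  expect_equal(sum(M), 2)
})

test_that("constant 3x3x3 ROI yields one 27-voxel zone and sane NGTDM", {
  lev <- array(1L, c(3, 3, 3))
  zones <- cpp_mat("cpp_glszm", as.integer(lev), dim(lev))
  expect_equal(nrow(zones), 1L)
  expect_equal(zones[1, 2], 27L)
  d <- dro_from_levels(lev, n_bins = 4)
  f <- ngtdm_features(d)
  # all neighbour differences are zero: coarseness takes its cap convention
  expect_equal(f[["ngtdm_Coarseness"]], 1e6)
  expect_equal(f[["ngtdm_Contrast"]], 0)
  g <- glszm_features(d)
  expect_equal(g[["glszm_ZonePercentage"]], 1 / 27)
})

test_that("all matrix families match brute force on random 5x5x5 grids", {
  set.seed(99)
  n_grids <- 25
  for (k in seq_len(n_grids)) {
    lev <- random_level_grid(c(5, 5, 5), n_levels = 4)
    ng <- 4L
    dims <- dim(lev)
    expect_equal(unclass(cpp_mat("cpp_glcm", as.integer(lev), dims, ng)),
                 bf_glcm(lev, ng), ignore_attr = TRUE)
    bf_rl <- bf_glrlm(lev, ng)
    got_rl <- unclass(cpp_mat("cpp_glrlm", as.integer(lev), dims, ng))
    expect_equal(got_rl[, seq_len(dim(bf_rl)[2]), ], bf_rl,
                 ignore_attr = TRUE)
    zones <- cpp_mat("cpp_glszm", as.integer(lev), dims)
    bz <- bf_glszm(lev)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_equal(key(zones), key(bz))
    expect_equal(unclass(cpp_mat("cpp_ngtdm", as.integer(lev), dims, ng)),
                 bf_ngtdm(lev, ng), ignore_attr = TRUE)
    expect_equal(unclass(cpp_mat("cpp_gldm", as.integer(lev), dims, ng, 0L)),
                 bf_gldm(lev, ng), ignore_attr = TRUE)
  }
})

test_that("mass conservation holds for every matrix family", {
  set.seed(7)
  for (k in 1:5) {
    lev <- random_level_grid(c(6, 5, 4), n_levels = 4)
    nvox <- sum(lev > 0)
    dims <- dim(lev)
    rl <- cpp_mat("cpp_glrlm", as.integer(lev), dims, 4L)
    for (dd in 1:13) {
      M <- rl[, , dd]
      expect_equal(sum(M %*% diag(seq_len(ncol(M)))), nvox)
    }
    zones <- cpp_mat("cpp_glszm", as.integer(lev), dims)
    expect_equal(sum(zones[, 2]), nvox)
    gd <- cpp_mat("cpp_gldm", as.integer(lev), dims, 4L, 0L)
    expect_equal(sum(gd), nvox)
    nt <- cpp_mat("cpp_ngtdm", as.integer(lev), dims, 4L)
    expect_equal(sum(nt[, 1]), nvox)
  }
})

test_that("features are translation invariant and monotone-transform stable", {
  set.seed(5)
  core <- array(rnorm(4^3), c(4, 4, 4))
  pad <- function(offset, big = 12) {
    arr <- array(0, c(big, big, big))
    roi <- array(FALSE, c(big, big, big))
    arr[offset + 1:4, offset + 1:4, offset + 1:4] <- core
    roi[offset + 1:4, offset + 1:4, offset + 1:4] <- TRUE
    list(v = volume(arr), roi = roi)
  }
  a <- pad(1); b <- pad(5)
  fa <- extract_features(a$v, a$roi, n_bins = 8)
  fb <- extract_features(b$v, b$roi, n_bins = 8)
  expect_equal(fa, fb, tolerance = 1e-12)

  # affine intensity transform leaves all texture families unchanged
  v2 <- volume(3 * core + 10)
  roi <- array(TRUE, c(4, 4, 4))
  f1 <- extract_features(volume(core), roi, n_bins = 8)
  f2 <- extract_features(v2, roi, n_bins = 8)
  texture <- grep("^(glcm|glrlm|glszm|ngtdm|gldm)_",
                  feature_names(), value = TRUE)
  expect_equal(f1[texture], f2[texture], tolerance = 1e-10)
  expect_equal(f2[["firstorder_Mean"]], 3 * f1[["firstorder_Mean"]] + 10)
})

test_that("extract_all produces the advertised column structure", {
  ft <- small_feature_table()
  expect_s3_class(ft, "feature_table")
  # 2 channels x 3 ROIs x 93 features
  expect_equal(length(feature_columns(ft)), 2 * 3 * 93)
  expect_equal(length(feature_columns(ft, channel = "MT", roi = "WM")), 93)
  expect_true(all(c("id", "outcome", "age", "gender", "scanner",
                    "WM__roi_volume", "NAWM__roi_volume",
                    "GM__roi_volume") %in% names(ft)))
  expect_false(anyNA(ft))
  # identical inputs give identical rows
  co <- small_cohort()
  twin <- structure(list(co[[1]], co[[1]]), class = "ms_cohort")
  twin[[2]]$id <- "copy"
  ft2 <- extract_all(twin, channels = "MT", rois = "WM")
  expect_equal(unname(unlist(ft2[1, feature_columns(ft2)])),
               unname(unlist(ft2[2, feature_columns(ft2)])))
})
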