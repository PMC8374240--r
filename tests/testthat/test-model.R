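make_xy <- function(n = 60, p = 3, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), n / 2)  # alternating, so any slice has both classes
  x <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("f", 1:p))))
  x$f1 <- x$f1 + effect * y
  list(x = x, y = y)
}

test_that("training is deterministic and separates separable data", {
  d <- make_xy()
  for (type in c("LR", "SVM", "RF")) {
    cfg <- model_config(type, seed = 4)
    m1 <- train_model(d$x, d$y, cfg)
    m2 <- train_model(d$x, d$y, cfg)
    s1 <- predict(m1, d$x)
    s2 <- predict(m2, d$x)
    expect_equal(as.numeric(s1), as.numeric(s2), label = type)
    expect_gt(auc_score(as.numeric(s1), d$y), 0.9)
  }
  # LR on a perfectly separable one-feature problem: training AUC 1
  d1 <- make_xy(p = 1, effect = 10)
  m <- train_model(d1$x, d1$y, model_config("LR"))
  expect_equal(auc_score(as.numeric(predict(m, d1$x)), d1$y), 1.0)
  expect_error(train_model(d$x, rep(1, nrow(d$x)), model_config("LR")),
               "classes")
})

test_that("LR recovers the sign pattern of a planted logistic model", {
  set.seed(8)
  n <- 1000
  x <- as.data.frame(matrix(rnorm(n * 3), n,
                            dimnames = list(NULL, c("up", "down", "null"))))
  eta <- 1.5 * x$up - 2 * x$down
  y <- rbinom(n, 1, plogis(eta))
  m <- train_model(x, y, model_config("LR"))
  beta <- as.numeric(coef(m$fit))[-1][1:3]
  expect_gt(beta[1], 0.5)
  expect_lt(beta[2], -0.5)
  expect_lt(abs(beta[3]), 0.3)
})

test_that("bootstrap evaluation reports the documented metric structure", {
  d <- make_xy(n = 30, effect = 10, seed = 3)
  cfg <- model_config("LR", seed = 6)
  m <- train_model(d$x[1:20, ], d$y[1:20], cfg, ids = paste0("s", 1:20))
  ev <- evaluate_bootstrap(m, d$x[21:30, ], d$y[21:30], cfg,
                           ids = paste0("s", 21:30))
  expect_equal(nrow(ev$values), 100)
  expect_true(all(ev$values >= 0 & ev$values <= 1))
  # near-perfect separation: every bootstrap AUC is 1
  expect_equal(unname(ev$median["auc"]), 1.0)
  expect_equal(unname(ev$ci[, "auc"]), c(1, 1))
  # CIs contain their medians
  for (mt in colnames(ev$values)) {
    expect_gte(ev$median[mt], ev$ci["lower", mt])
    expect_lte(ev$median[mt], ev$ci["upper", mt])
  }
  # determinism
  ev2 <- evaluate_bootstrap(m, d$x[21:30, ], d$y[21:30], cfg)
  expect_identical(ev$values, ev2$values)
  # leakage guard: overlapping ids error
  expect_error(evaluate_bootstrap(m, d$x[1:10, ], d$y[1:10], cfg,
                                  ids = paste0("s", 1:10)), "overlap")
  expect_error(evaluate_bootstrap(m, d$x[21:30, ], rep(1, 10), cfg), "class")
})

test_that("a constant score yields AUC 0.5 by the tie convention", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(auc_score(rep(0.3, 20), y), 0.5)
})

test_that("DeLong test: identical scores give p 1 and variance matches a
           paired bootstrap oracle", {
  set.seed(13)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  s1 <- rnorm(n) + y
  s2 <- 0.7 * s1 + 0.5 * rnorm(n)
  res_same <- delong_compare(list(a = s1, b = s1), y)
  expect_equal(res_same$p, 1)
  res <- delong_compare(list(a = s1, b = s2), y)
  # AUC point estimates obey the Mann-Whitney identity
  expect_equal(res$auc_a, auc_score(s1, y), tolerance = 1e-12)
  expect_equal(res$auc_b, auc_score(s2, y), tolerance = 1e-12)
  # paired bootstrap oracle for the variance of the AUC difference
  B <- 2000
  diffs <- vapply(seq_len(B), function(b) {
    ix <- c(sample(which(y == 0), n / 2, TRUE),
            sample(which(y == 1), n / 2, TRUE))
    auc_score(s1[ix], y[ix]) - auc_score(s2[ix], y[ix])
  }, numeric(1))
  expect_equal(res$var_diff, var(diffs), tolerance = 0.15)
  expect_error(delong_compare(list(a = s1, b = s2), rep(1, n)), "degenerate")
})

test_that("DeLong agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  n <- 50
  y <- rep(c(0, 1), each = n / 2)
  s1 <- rnorm(n) + 0.8 * y
  s2 <- rnorm(n) + 0.5 * y
  mine <- delong_compare(list(a = s1, b = s2), y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
})

test_that("model-type choice counts best-AUC wins above the floor", {
  res <- data.frame(
    combo = rep(c("MT:WM", "R1:WM", "T1w:GM"), each = 3),
    model_type = rep(c("LR", "SVM", "RF"), 3),
    median_auc = c(0.9, 0.85, 0.65,   # LR wins
                   0.8, 0.88, 0.65,   # SVM wins
                   0.95, 0.8, 0.65))  # LR wins
  expect_equal(select_model_type(res), "LR")
  # type below the floor everywhere is never returned
  res2 <- res
  res2$median_auc[res2$model_type == "LR"] <- 0.65
  expect_equal(select_model_type(res2), "SVM")
  res3 <- res
  res3$median_auc <- 0.5
  expect_error(select_model_type(res3), "no admissible")
  # tie on wins resolves to the simpler model
  res4 <- data.frame(combo = c("a", "a", "b", "b"),
                     model_type = c("LR", "RF", "LR", "RF"),
                     median_auc = c(0.9, 0.95, 0.95, 0.9))
  expect_equal(select_model_type(res4), "LR")
})

test_that("permutation labels preserve class counts and frozen models are
           reusable on external tables", {
  d <- make_xy(n = 40, effect = 5, seed = 23)
  tr <- 1:30; te <- 31:40
  sc <- selection_config(n_iterations = 5, cohort_size = 20, seed = 2)
  mc <- model_config("LR", seed = 2)
  aud <- permutation_audit(d$x[tr, ], d$y[tr], d$x[te, ], d$y[te],
                           sel_config = sc, mod_config = mc, seed = 3)
  expect_length(aud$auc_original, 100)
  expect_length(aud$auc_permuted, 100)
  expect_true(aud$p_drop >= 0 && aud$p_drop <= 1)

  m <- train_model(d$x[tr, ], d$y[tr], mc)
  src <- rep(c("external_HCS", "external_MSP"), each = 5)
  yv <- rep(c(0, 1), each = 5)
  ev <- external_validate(m, d$x[te, ], yv, mc, source = src)
  score <- predict(m, d$x[te, ])
  cls <- attr(score, "class_pred")
  expect_equal(unname(ev$source_accuracy["external_HCS"]),
               mean(cls[1:5] == 0))   # all-negative source == specificity
  expect_equal(unname(ev$source_accuracy["external_MSP"]),
               mean(cls[6:10] == 1))  # all-positive source == sensitivity
  # frozen application is repeatable
  expect_identical(as.numeric(predict(m, d$x[te, ])),
                   as.numeric(predict(m, d$x[te, ])))
  expect_error(external_validate(m, d$x[te, 1:2], yv, mc), "f3")
})
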