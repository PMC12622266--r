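test_that("combined-cutoff rule is a strict conjunction with conservative ties", {
  rule <- msti_mouse_rule()
  feat <- data.frame(t1_ms = c(700, 784, 900, 700),
                     mtr_per_cm3 = c(2000, 2000, 2000, 2000),
                     adc_e3 = c(1.0, 1.0, 1.0, 0.88))
  calls <- classify_by_cutoffs(feat, rule)
  expect_equal(calls, c("lysable",     # all three cutoffs satisfied
                        "nonlysable",  # T1 at the boundary: strict <784
                        "nonlysable",  # one violated conjunct suffices
                        "nonlysable")) # ADC at the boundary: strict >0.88
  expect_error(classify_by_cutoffs(data.frame(t1_ms = 1), rule),
               "unknown rule parameter")
  feat$t1_ms[1] <- NA
  expect_warning(calls2 <- classify_by_cutoffs(feat, rule), "missing")
  expect_true(is.na(calls2[1]))
})

test_that("cutoff classification equals a brute-force conjunction oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    feat <- data.frame(t1_ms = runif(n, 400, 1200),
                       mtr_per_cm3 = runif(n, 500, 5000),
                       adc_e3 = runif(n, 0.3, 1.8))
    thr <- c(runif(1, 400, 1200), runif(1, 500, 5000), runif(1, 0.3, 1.8))
    dirs <- sample(c("below", "above"), 3, replace = TRUE)
    rule <- msti_cutoff_rule(names(feat), thr, dirs)
    got <- classify_by_cutoffs(feat, rule)
    oracle <- vapply(seq_len(n), function(i) {
      ok <- TRUE
      for (j in 1:3) {
        v <- feat[i, j]
        ok <- ok && if (dirs[j] == "below") v < thr[j] else v > thr[j]
      }
      if (ok) "lysable" else "nonlysable"
    }, character(1))
    expect_identical(got, oracle)
  }
})

test_that("logistic lysis probability reproduces the published model", {
  # published coefficients at the reported human group medians
  expect_equal(lysis_probability(606, 0.67), 0.8075, tolerance = 1e-4)
  expect_equal(lysis_probability(765, 1.23), 0.5570, tolerance = 1e-4)
  z <- msti_human_coefficients(0, 0, 0)
  expect_equal(lysis_probability(1234, 0.9, z), 0.5)
  # numerically stable far into both tails, strictly inside (0, 1)
  p_lo <- lysis_probability(2e5, 1)        # eta ~ -1200
  p_hi <- lysis_probability(-2e5, 1)       # eta ~ +1200
  expect_true(p_lo > 0 && p_hi < 1)
  expect_error(lysis_probability(NA, 1), "non-finite")
  # strictly decreasing in T1 and in ADC under the published negative betas
  t1g <- seq(300, 1200, by = 50)
  expect_true(all(diff(lysis_probability(t1g, 1.0)) < 0))
  adcg <- seq(0.3, 1.9, by = 0.1)
  expect_true(all(diff(lysis_probability(700, adcg)) < 0))
})

test_that("logistic fitting recovers generating coefficients and flags pathologies", {
  set.seed(77)
  n <- 5000
  feat <- data.frame(t1_ms = runif(n, 450, 1000), adc_e3 = runif(n, 0.4, 1.8))
  y <- rbinom(n, 1, lysis_probability(feat$t1_ms, feat$adc_e3))
  f <- fit_logistic(feat, y)
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  se <- setNames(f$coefficients$se, f$coefficients$term)
  truth <- c("(Intercept)" = 5.37, t1_ms = -0.006, adc_e3 = -0.448)
  for (term in names(truth))
    expect_lt(abs(est[term] - truth[term]), 3 * se[term])
  expect_false(f$separation)
  expect_true(f$converged)
  # odds ratios exponentiate the coefficients
  expect_equal(f$coefficients$odds_ratio, exp(f$coefficients$estimate))
  # nesting: two-predictor training AUC >= either single predictor
  expect_gte(f$auc + 1e-9, fit_logistic(feat, y, predictors = "t1_ms")$auc)
  expect_gte(f$auc + 1e-9, fit_logistic(feat, y, predictors = "adc_e3")$auc)
  # null case: outcome independent of predictors
  y0 <- rbinom(n, 1, 0.5)
  f0 <- fit_logistic(feat, y0)
  expect_equal(f0$auc, 0.5, tolerance = 0.05)
  expect_equal(f0$coefficients$odds_ratio[-1], c(1, 1), tolerance = 0.2)
  # complete separation is flagged, not silently reported
  sep <- data.frame(t1_ms = c(1:5, 11:15), adc_e3 = rep(1, 10))
  fs <- fit_logistic(sep, c(rep(1, 5), rep(0, 5)), predictors = "t1_ms")
  expect_true(fs$separation)
  # singular design rejected
  dup <- data.frame(t1_ms = feat$t1_ms, t1_copy = feat$t1_ms)
  expect_error(fit_logistic(dup, y, predictors = c("t1_ms", "t1_copy")),
               "singular")
})

test_that("cross-check: in-package logistic fit agrees with direct IRLS", {
  # small fixed dataset; oracle = one Newton/IRLS solve written out here
  set.seed(5)
  X <- cbind(1, runif(60, 450, 1000), runif(60, 0.4, 1.8))
  y <- rbinom(60, 1, 0.5)
  b <- rep(0, 3)
  for (it in 1:50) {
    eta <- as.vector(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    b <- b + solve(t(X) %*% (X * W), t(X) %*% (y - mu))
  }
  f <- fit_logistic(data.frame(t1_ms = X[, 2], adc_e3 = X[, 3]), y)
  expect_equal(f$coefficients$estimate, as.vector(b), tolerance = 1e-6)
})

test_that("probability heatmap paints slices with the stated colormap", {
  mask <- array(FALSE, c(4, 4, 5))
  mask[2:3, 2:3, 2:4] <- TRUE
  preds <- data.frame(slice_index = 1:3, P = c(0, 0.5, 1),
                      call = c("nonlysable", "nonlysable", "lysable"))
  hm <- probability_heatmap(preds, mask)
  expect_equal(unique(hm$volume[, , 2][mask[, , 2]]), 0)
  expect_equal(unique(hm$volume[, , 4][mask[, , 4]]), 1)
  expect_true(all(is.na(hm$volume[, , 1])))
  # montage: first pane pure red, middle yellow, last pure green
  pane <- function(j, ch) hm$montage[, (j - 1) * 4 + 1:4, ch]
  expect_equal(max(pane(1, 1)), 1); expect_equal(max(pane(1, 2)), 0.15)
  expect_equal(max(pane(2, 1)), 1); expect_equal(max(pane(2, 2)), 1)
  expect_equal(max(pane(3, 1)), 0.15); expect_equal(max(pane(3, 2)), 1)
  # monotone P gradient gives monotone voxel values along the slice axis
  grad <- data.frame(slice_index = 1:3, P = c(0.2, 0.5, 0.9))
  hv <- probability_heatmap(grad, mask)$volume
  means <- vapply(2:4, function(z) mean(hv[, , z], na.rm = TRUE), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_error(probability_heatmap(preds[1:2, ], mask), "slice count mismatch")
  # file outputs
  pre <- file.path(withr::local_tempdir(), "hm")
  probability_heatmap(preds, mask, out_prefix = pre)
  expect_true(file.exists(paste0(pre, "_heatmap.nii.gz")))
  expect_true(file.exists(paste0(pre, "_montage.png")))
  expect_true(file.exists(paste0(pre, "_slices.csv")))
})

test_that("predict_lysis dispatches cohort-appropriate models", {
  feat <- data.frame(subject_id = "s", slice_index = 0:1,
                     t1_ms = c(650, 900), mtr_per_cm3 = c(2000, 2000),
                     adc_e3 = c(1.0, 1.2))
  pm <- predict_lysis(feat, "mouse-cutoffs")
  expect_equal(pm$call, c("lysable", "nonlysable"))
  expect_true(all(is.na(pm$P)))
  ph <- predict_lysis(feat, "human-logistic", prob_threshold = 0.5)
  expect_equal(ph$P, lysis_probability(feat$t1_ms, feat$adc_e3))
  expect_equal(ph$call, ifelse(ph$P > 0.5, "lysable", "nonlysable"))
})
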