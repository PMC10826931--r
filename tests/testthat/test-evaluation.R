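test_that("auroc handles perfect ordering, ties and random instances", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
  withr::with_seed(301, {
    for (i in 1:40) {
      n <- sample(10:30, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.4))
      s <- round(runif(n), 2)   # coarse scores force ties
      expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("auroc agrees with pROC and flips under score negation", {
  withr::with_seed(302, {
    y <- rbinom(80, 1, 0.3); y[1:2] <- c(0, 1)
    s <- rnorm(80)
    expect_equal(auroc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
    expect_equal(auroc(-s, y), 1 - auroc(s, y), tolerance = 1e-12)
  })
})

test_that("DeLong variance matches the naive structural-components loop", {
  withr::with_seed(303, {
    for (i in 1:30) {
      y <- c(1, 1, 0, 0, rbinom(36, 1, 0.5))
      s <- round(rnorm(40), 1)
      r <- delong_ci(s, y)
      expect_equal(r$variance, oracle_delong_variance(s, y), tolerance = 1e-12)
      expect_equal(r$auc, oracle_auroc(s, y), tolerance = 1e-12)
      # monotone transforms leave the variance untouched
      r2 <- delong_ci(exp(2 * s), y)
      expect_equal(r2$variance, r$variance, tolerance = 1e-12)
    }
  })
})

test_that("DeLong CI matches pROC and degenerates cleanly at separation", {
  withr::with_seed(304, {
    y <- rbinom(60, 1, 0.4); y[1:4] <- c(1, 1, 0, 0)
    s <- rnorm(60)
    mine <- delong_ci(s, y)
    theirs <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                           method = "delong")
    expect_equal(mine$ci, as.numeric(theirs[c(1, 3)]), tolerance = 1e-9)
  })
  perfect <- delong_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$variance, 0)
  expect_equal(perfect$ci, c(1, 1))
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("confusion tables reproduce the published-cell arithmetic", {
  # 486 tn / 8 fp / 44 fn / 54 tp, the held-out confusion of the flags stack
  labels <- rep(c(0, 0, 1, 1), c(486, 8, 44, 54))
  scores <- rep(c(0.1, 0.9, 0.1, 0.9), c(486, 8, 44, 54))
  ct <- confusion_at_threshold(scores, labels, 0.5)
  expect_equal(c(ct$tn, ct$fp, ct$fn, ct$tp), c(486, 8, 44, 54))
  expect_equal(ct$tn + ct$fp + ct$fn + ct$tp, 592)
  expect_equal(ct$ppv, 54 / 62)
  expect_equal(round(ct$ppv, 3), 0.871)
  expect_equal(ct$sensitivity, 54 / 98)
  expect_equal(ct$specificity, 486 / 494)
  all_pos <- confusion_at_threshold(c(0.2, 0.8), c(0, 1), threshold = 0)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$fn, 0)
})

test_that("undefined confusion ratios are unknown, never zero", {
  ct <- confusion_at_threshold(c(0.9, 0.8), c(1, 1), threshold = 0.5)
  expect_true(is.na(ct$specificity))
  expect_true(is.na(ct$npv))
  expect_equal(ct$sensitivity, 1)
})

test_that("roc points span (0,0) to (1,1)", {
  withr::with_seed(305, {
    y <- rbinom(50, 1, 0.4); y[1:2] <- c(0, 1)
    s <- rnorm(50)
    pts <- roc_points(s, y)
    expect_equal(unlist(pts[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  })
})

test_that("per-predictor importance scores and ranks behave per contract", {
  withr::with_seed(306, {
    y <- rbinom(1000, 1, 0.3); y[1:2] <- c(0, 1)
    flip <- as.logical(rbinom(1000, 1, 0.1))
    noisy <- ifelse(flip, 1 - y, y)
    X <- cbind(exact = y, noisy = noisy, constant = rep(2, 1000),
               z_anti = 1 - y, random = rnorm(1000))
    imp <- variable_importance(X, y)
    expect_equal(imp$score[imp$column == "exact"], 1.0)
    expect_equal(imp$rank[imp$column == "exact"], 1)   # name breaks the tie
    expect_equal(imp$score[imp$column == "constant"], 0.5)
    expect_equal(imp$score[imp$column == "z_anti"], 1.0)   # direction-agnostic
    expect_equal(imp$auc[imp$column == "z_anti"], 0.0)
    expect_equal(imp$rank[imp$column == "z_anti"], 2)
    expect_equal(imp$auc[imp$column == "noisy"], oracle_auroc(noisy, y),
                 tolerance = 1e-12)
    expect_setequal(imp$rank, 1:5)
  })
})

test_that("parity tests run Yates-corrected pairwise proportion comparisons", {
  rep0 <- parity_tests(c(a = 8, b = 8), c(a = 200, b = 200))
  expect_equal(rep0$tests$statistic, 0)
  expect_equal(rep0$tests$p_value, 1)
  rep1 <- parity_tests(c(a = 20, b = 20), c(a = 400, b = 400))
  expect_gte(rep1$tests$statistic, 0)
  expect_gte(rep1$tests$p_value, 0.99)
  # cross-check one pair against prop.test directly
  rep2 <- parity_tests(c(m = 36, f = 2), c(m = 315, f = 123))
  ref <- stats::prop.test(c(36, 2), c(315, 123))
  expect_equal(rep2$tests$statistic, unname(ref$statistic))
  expect_equal(rep2$tests$p_value, ref$p.value)
  expect_warning(rep3 <- parity_tests(c(a = 1, b = 2, c = 0),
                                      c(a = 10, b = 20, c = 0)), "zero denominator")
  expect_equal(nrow(rep3$tests), 1)
  expect_error(suppressWarnings(parity_tests(c(a = 1, b = 0), c(a = 10, b = 0))),
               "at least 2")
  rep4 <- parity_tests(c(a = 5, b = 10, c = 2), c(a = 50, b = 50, c = 50),
                       adjust = "holm")
  expect_equal(nrow(rep4$tests), 3)
  expect_true(all(rep4$tests$p_adjusted >= rep4$tests$p_value))
})

test_that("ICC(2,1) matches the two-way ANOVA oracle and its edge cases", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  r <- icc(m)
  expect_equal(r$icc_value, oracle_icc21(m), tolerance = 1e-12)
  withr::with_seed(307, {
    for (i in 1:10) {
      mm <- matrix(rnorm(14, sd = 2) + rep(rnorm(7, sd = 3), 2), ncol = 2)
      expect_equal(icc(mm)$icc_value, oracle_icc21(mm), tolerance = 1e-10)
    }
  })
  same <- cbind(c(1, 5, 3, 9, 7, 2), c(1, 5, 3, 9, 7, 2))
  expect_equal(icc(same)$icc_value, 1.0)
  flat <- matrix(4, nrow = 6, ncol = 2)
  rflat <- icc(flat)
  expect_true(is.na(rflat$icc_value))
  expect_match(rflat$note, "undefined")
  bad <- m; bad[2, 1] <- NA
  expect_error(icc(bad), "missing")
  expect_error(icc(m[1:4, ]), "subjects")
  expect_error(icc(m[, 1, drop = FALSE]), "raters")
})
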