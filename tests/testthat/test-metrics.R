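test_that("binarize applies the boundary rule and is monotone in threshold", {
  s <- matrix(c(0.5, 0.49, 0, 1), 2, 2)
  b <- binarize(s, 0.5)
  expect_equal(b, matrix(c(1, 0, 0, 1), 2, 2))
  expect_true(all(binarize(matrix(0, 3, 2)) == 0))
  set.seed(1)
  sc <- matrix(runif(60), 10, 6)
  expect_true(all(binarize(sc, 0.9) <= binarize(sc, 0.1)))
  expect_error(binarize(sc, 1.2), "threshold")
})

test_that("precision/recall/F1 follow their defining ratios", {
  r <- precision_recall_f1(list(TP = 8, FP = 2, FN = 4, TN = 6))
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 8 / 12)
  expect_equal(r$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  expect_false(r$degenerate)
  # harmonic mean of equal values is the value itself
  expect_equal(precision_recall_f1(list(TP = 5, FP = 0, FN = 0))$f1, 1)
  # zero-denominator cases return 0 with the flag, never NaN
  z <- precision_recall_f1(list(TP = 0, FP = 0, FN = 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$degenerate)
  # F1 lies between min and max of P and R
  set.seed(2)
  for (i in 1:50) {
    cc <- list(TP = rpois(1, 5) + 1, FP = rpois(1, 3), FN = rpois(1, 3))
    m <- precision_recall_f1(cc)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("confusion counts partition the record set", {
  set.seed(3)
  pred <- rbinom(40, 1, 0.5); truth <- rbinom(40, 1, 0.3)
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 40)
})

test_that("AUROC equals the Mann-Whitney pair count and its invariances hold", {
  # exhaustive pair counting on a 6-record toy set
  s <- c(0.9, 0.8, 0.35, 0.7, 0.2, 0.35)
  y <- c(1, 0, 1, 1, 0, 0)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1, ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(auroc(s, y), brute)
  # perfect separation and chance level
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(4)
  big_s <- runif(4000); big_y <- rbinom(4000, 1, 0.5)
  expect_equal(auroc(big_s, big_y), 0.5, tolerance = 0.05)
  # invariance under strictly monotone transforms
  expect_equal(auroc(qlogis(s), y), auroc(s, y))
  expect_equal(auroc(s^3, y), auroc(s, y))
  # degenerate labels are undefined
  expect_true(is.na(auroc(s, rep(1, 6))))
  # duplicated record set leaves tie-free AUROC unchanged
  s2 <- c(0.9, 0.8, 0.4, 0.7, 0.2, 0.3)
  expect_equal(auroc(rep(s2, 2), rep(y, 2)), auroc(s2, y))
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- runif(200); y <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(auroc(s, y), ref, tolerance = 1e-12)
})

test_that("evaluation reports per-class and macro metrics consistently", {
  toy <- toy_scores()
  rep <- evaluate_model(cbind(toy$scores, toy$scores, toy$scores),
                        data = NULL, labels = cbind(toy$y, toy$y, toy$y))
  expect_equal(nrow(rep$per_class), 6)
  expect_equal(rep$macro$f1, mean(rep$per_class$f1), tolerance = 1e-12)
  expect_equal(rep$macro$auroc, mean(rep$per_class$auroc), tolerance = 1e-12)
  # single-class columns are flagged undefined and excluded from the macro
  y2 <- cbind(toy$y, matrix(1, 6, 1))
  s2 <- cbind(toy$scores, runif(6))
  rep2 <- evaluate_model(s2, data = NULL, labels = y2)
  expect_true(rep2$per_class$undefined[3])
  expect_equal(rep2$macro$f1, mean(rep2$per_class$f1[1:2]), tolerance = 1e-12)
  expect_error(evaluate_model(toy$scores[0, , drop = FALSE], data = NULL,
                              labels = toy$y[0, , drop = FALSE]), "empty")
})

test_that("published validation and generalization tables are internally consistent", {
  for (tab in list(cltc_validation_table(), ccfc_validation_table(),
                   cltc_generalization_table(), ccfc_generalization_table())) {
    f1 <- f1_score(tab$precision, tab$recall)
    expect_true(all(abs(f1 - tab$f1) <= 0.1))
  }
  expect_equal(mean(cltc_validation_table()$f1), 82.7, tolerance = 0.06)
  expect_equal(mean(cltc_generalization_table()$f1), 69.9, tolerance = 0.06)
})
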