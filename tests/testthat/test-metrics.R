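test_that("confusion counts match an element-wise tally", {
  expect_identical(confusionCounts(rep(TRUE, 5), rep(TRUE, 5)),
                   c(tp = 5L, fp = 0L, fn = 0L, tn = 0L))
  y <- c(TRUE, FALSE, TRUE)
  cc <- confusionCounts(y, !y)
  expect_identical(cc[["tp"]], 0L)
  expect_identical(cc[["tn"]], 0L)
  set.seed(20)
  for (k in 1:10) {
    t_ <- runif(50) > 0.5; p_ <- runif(50) > 0.5
    expect_identical(confusionCounts(t_, p_), bfConfusion(t_, p_))
  }
  expect_error(confusionCounts(TRUE, logical(0)), class = "ubm_input_error")
})

test_that("binary metrics evaluate the standard formulas", {
  m <- binaryMetrics(c(tp = 8, fp = 2, fn = 1, tn = 9))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.8889, tolerance = 1e-4)
  expect_equal(m$specificity, 0.8182, tolerance = 1e-4)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$npv, 0.9)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)
  expect_identical(m$ci_method, "wilson")
  perf <- binaryMetrics(c(tp = 7, fp = 0, fn = 0, tn = 13))
  expect_true(all(unlist(perf[c("accuracy", "sensitivity", "specificity",
                                "ppv", "npv", "f1")]) == 1))
  expect_equal(perf$mcc, 1)
  # all-positive predictions leave npv (and specificity) undefined
  deg <- binaryMetrics(c(tp = 5, fp = 5, fn = 0, tn = 0))
  expect_true("npv" %in% deg$undefined)
  expect_true(is.na(deg$npv))
})

test_that("binary metrics agree with brute-force evaluation on random tables", {
  set.seed(33)
  for (k in 1:50) {
    cc <- c(tp = sample(0:30, 1), fp = sample(0:30, 1),
            fn = sample(0:30, 1), tn = sample(1:30, 1))
    m <- binaryMetrics(cc)
    n <- sum(cc)
    expect_equal(m$accuracy, (cc[["tp"]] + cc[["tn"]]) / n, tolerance = 1e-12)
    if (!"mcc" %in% m$undefined)
      expect_equal(m$mcc, bfMcc(cc), tolerance = 1e-12)
    if (!"f1" %in% m$undefined)
      expect_equal(m$f1, 2 * cc[["tp"]] / (2 * cc[["tp"]] + cc[["fp"]] +
                                             cc[["fn"]]), tolerance = 1e-12)
  }
})

test_that("Wilson intervals behave at the boundaries and match prop.test", {
  ci <- proportionCI(100, 100)
  expect_equal(unname(ci["high"]), 1)
  ci2 <- proportionCI(50, 100)
  expect_equal(unname(ci2["low"]), 0.4038, tolerance = 1e-4)
  expect_equal(unname(ci2["high"]), 0.5962, tolerance = 1e-4)
  set.seed(4)
  for (k in 1:20) {
    n <- sample(5:200, 1); s <- sample(0:n, 1)
    w <- proportionCI(s, n)
    expect_true(w["low"] >= 0 && w["high"] <= 1 && w["low"] <= w["high"])
    pt <- suppressWarnings(stats::prop.test(s, n, correct = FALSE))$conf.int
    expect_equal(unname(w), as.numeric(pt), tolerance = 1e-9)
  }
  expect_error(proportionCI(5, 3), class = "ubm_input_error")
})

test_that("AUC follows the rank formulation with tie handling", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(5)
  for (k in 1:10) {
    sc <- round(runif(30), 1)  # coarse scores force ties
    lb <- runif(30) > 0.4
    if (length(unique(lb)) < 2) next
    r <- rocAuc(sc, lb)
    expect_equal(r$auc, bfAuc(sc, lb), tolerance = 1e-12)
    # invariant under strictly increasing transforms
    expect_equal(rocAuc(exp(3 * sc), lb)$auc, r$auc, tolerance = 1e-12)
    # curve endpoints
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  }
  # cross-check against an independent implementation
  set.seed(6)
  sc <- runif(60); lb <- runif(60) > 0.5
  expect_equal(rocAuc(sc, lb)$auc,
               as.numeric(suppressMessages(pROC::auc(lb, sc,
                                                     direction = "<"))),
               tolerance = 1e-12)
  expect_error(rocAuc(runif(5), rep(TRUE, 5)), class = "ubm_undefined_metric")
})

test_that("chi-square accuracy comparison matches the Pearson formula", {
  eq <- chiSquareAccuracyDiff(30, 40, 30, 40)
  expect_equal(unname(eq), c(0, 1))
  d <- chiSquareAccuracyDiff(90, 100, 70, 100)
  expect_equal(unname(d["statistic"]), 12.5, tolerance = 1e-9)
  expect_equal(unname(d["p_value"]), 4.07e-4, tolerance = 1e-2)
  sw <- chiSquareAccuracyDiff(70, 100, 90, 100)
  expect_equal(unname(sw["statistic"]), unname(d["statistic"]))
  set.seed(7)
  for (k in 1:10) {
    na_ <- sample(20:80, 1); nb <- sample(20:80, 1)
    ca <- sample(1:(na_ - 1), 1); cb <- sample(1:(nb - 1), 1)
    got <- chiSquareAccuracyDiff(ca, na_, cb, nb)
    expect_equal(unname(got["statistic"]), bfChisq(ca, na_, cb, nb),
                 tolerance = 1e-9)
  }
  expect_error(chiSquareAccuracyDiff(5, 0, 1, 2), class = "ubm_input_error")
})

test_that("Cohen's kappa matches its definition and null behaviour", {
  expect_equal(cohensKappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # worked 2x2 table: a=20, b=5, c=10, d=15
  ra <- c(rep("x", 25), rep("y", 25))
  rb <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  expect_equal(cohensKappa(ra, rb), 0.4, tolerance = 1e-12)
  set.seed(8)
  ks <- vapply(1:20, function(i) {
    a <- sample(c("p", "q"), 500, replace = TRUE)
    b <- sample(c("p", "q"), 500, replace = TRUE)
    cohensKappa(a, b)
  }, numeric(1))
  expect_true(all(abs(ks) <= 0.15))
  expect_lte(abs(mean(ks)), 0.1)
  set.seed(9)
  for (k in 1:10) {
    a <- sample(letters[1:3], 40, replace = TRUE)
    b <- sample(letters[1:3], 40, replace = TRUE)
    expect_equal(cohensKappa(a, b), bfKappa(a, b), tolerance = 1e-12)
  }
})

test_that("kappa and MCC coincide on 2x2 tables with symmetric marginals", {
  tab <- c(tp = 40, fp = 10, fn = 10, tn = 40)
  truth <- c(rep(TRUE, 50), rep(FALSE, 50))
  pred <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 40))
  expect_equal(cohensKappa(truth, pred), binaryMetrics(tab)$mcc,
               tolerance = 1e-12)
})

test_that("multi-class accuracy and confusion table follow the tally", {
  cls <- INTEGRATED_CLASSES
  expect_equal(multiclassAccuracy(cls, cls)$accuracy, 1)
  expect_equal(multiclassAccuracy(cls, rev(cls))$accuracy, 0)
  set.seed(10)
  t_ <- sample(cls, 40, replace = TRUE)
  p_ <- sample(cls, 40, replace = TRUE)
  mc <- multiclassAccuracy(t_, p_)
  expect_equal(mc$accuracy, mean(t_ == p_), tolerance = 1e-12)
  expect_identical(sum(mc$confusion), 40L)
  expect_identical(unname(diag(mc$confusion)[1]),
                   sum(t_ == "pure_pb" & p_ == "pure_pb"))
  expect_error(multiclassAccuracy(cls, cls[1:2]), class = "ubm_input_error")
})
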