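# synthetic feature tables for classifier-level tests (no rendering)
makeFeatures <- function(n, seed = 0) {
  set.seed(seed)
  f <- data.frame(matrix(rnorm(n * 8), n))
  colnames(f) <- featureSchema()
  f
}

test_that("patient-grouped splitting honours the 3:1 convention", {
  f <- makeFeatures(32)
  pat <- rep(sprintf("p%d", 1:8), each = 4)
  ds <- labeledDataset(f, rep(c(TRUE, FALSE), 16), pat)
  sp <- splitDataset(ds, seed = 1)
  expect_identical(nrow(sp$train$features), 24L)
  expect_identical(nrow(sp$test$features), 8L)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  # different seeds give different partitions of the same sizes
  sp2 <- splitDataset(ds, seed = 2)
  expect_identical(nrow(sp2$test$features), 8L)
  expect_false(setequal(sp$test$patient_id, sp2$test$patient_id))
  # reproducible
  sp3 <- splitDataset(ds, seed = 1)
  expect_identical(sp$test$patient_id, sp3$test$patient_id)
  # uneven patients: the fraction is met up to one patient's worth
  pat2 <- c(rep("a", 10), rep("b", 3), rep("c", 3), rep("d", 4))
  ds2 <- labeledDataset(makeFeatures(20), rep(TRUE, 20), pat2)
  for (s in 1:5) {
    spl <- splitDataset(ds2, seed = s)
    expect_lte(abs(nrow(spl$test$features) - 5), 10)
    expect_length(intersect(spl$train$patient_id, spl$test$patient_id), 0)
  }
  one <- labeledDataset(makeFeatures(4), rep(TRUE, 4), rep("a", 4))
  expect_error(splitDataset(one, 1), class = "ubm_split_error")
})

test_that("training is deterministic and leak-free across the bank", {
  f <- makeFeatures(120, seed = 3)
  y <- f$iris_curvature_um + 0.5 * f$contact_ratio > 0
  ds <- labeledDataset(f, y, rep(sprintf("p%d", 1:30), each = 4))
  sp <- splitDataset(ds, seed = 0)
  for (alg in ALGORITHM_IDS) {
    m1 <- trainModel(sp$train, alg, "PB", seed = 5)
    m2 <- trainModel(sp$train, alg, "PB", seed = 5)
    p1 <- predictMechanism(m1, sp$test$features)
    p2 <- predictMechanism(m2, sp$test$features)
    expect_identical(p1$probability, p2$probability)
    expect_true(all(p1$probability >= 0 & p1$probability <= 1))
    # standardization constants come from the training rows only
    raw <- as.matrix(sp$train$features[, featureSchema()])
    expect_equal(unname(m1@center), unname(colMeans(raw)), tolerance = 1e-12)
  }
  bad <- labeledDataset(f, rep(TRUE, nrow(f)), ds$patient_id)
  expect_error(trainModel(bad, "RF", "PB"), class = "ubm_degenerate_labels")
})

test_that("separable features give perfect training accuracy for SVM and LR", {
  f <- makeFeatures(80, seed = 4)
  y <- f$it_spur750_um > 0
  ds <- labeledDataset(f, y, rep(sprintf("p%d", 1:20), each = 4))
  for (alg in c("SVM", "LR")) {
    m <- trainModel(ds, alg, "TPI", seed = 0)
    pr <- predictMechanism(m, ds$features)
    expect_identical(mean(pr$call == y), 1)
  }
})

test_that("permuted labels yield held-out MCC near zero", {
  f <- makeFeatures(160, seed = 6)
  y <- f$iris_curvature_um > 0
  pat <- rep(sprintf("p%d", 1:40), each = 4)
  mccs <- vapply(1:50, function(rep_i) {
    set.seed(rep_i)
    yp <- sample(y)
    ds <- labeledDataset(f, yp, pat)
    sp <- splitDataset(ds, seed = rep_i)
    m <- trainModel(sp$train, "LR", "PB", seed = rep_i)
    pr <- predictMechanism(m, sp$test$features)
    cc <- confusionCounts(sp$test$labels, pr$call)
    v <- binaryMetrics(cc)$mcc
    if (is.na(v)) 0 else v
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("prediction applies the threshold with the >= convention", {
  # zero-coefficient logistic model scores exactly 0.5 everywhere
  m <- new("TrainedModel", algorithm = "LR", target = "PB",
           fit = list(coefficients = rep(0, 9)),
           schema = featureSchema(),
           center = stats::setNames(rep(0, 8), featureSchema()),
           scale = stats::setNames(rep(1, 8), featureSchema()),
           medians = stats::setNames(rep(0, 8), featureSchema()),
           threshold = 0.5, seed = 0L, platt = c(NA_real_, NA_real_))
  pr <- predictMechanism(m, makeFeatures(5))
  expect_identical(pr$probability, rep(0.5, 5))
  expect_true(all(pr$call))
  wrong <- makeFeatures(3)[, 1:4]
  expect_error(predictMechanism(m, wrong), class = "ubm_schema_error")
})

test_that("model selection ranks MCC first with the documented tie-breaks", {
  tab <- data.frame(algorithm = c("SVM", "RF"), mcc = c(0.84, 0.83),
                    f1 = c(0.1, 0.9), accuracy = c(0.5, 0.9),
                    sensitivity = c(0.5, 0.9))
  expect_identical(tab$algorithm[modelSelectionOrder(tab)[1]], "SVM")
  tab2 <- data.frame(algorithm = c("RF", "GBDT"), mcc = c(0.8, 0.8),
                     f1 = c(0.85, 0.9), accuracy = c(0.9, 0.8),
                     sensitivity = c(0.9, 0.8))
  expect_identical(tab2$algorithm[modelSelectionOrder(tab2)[1]], "GBDT")
  tab3 <- data.frame(algorithm = c("LR", "SVM", "XGB", "GBDT", "RF"),
                     mcc = 0.7, f1 = 0.7, accuracy = 0.7, sensitivity = 0.7)
  expect_identical(tab3$algorithm[modelSelectionOrder(tab3)[1]], "RF")
  # undefined metrics rank below any defined value
  tab4 <- data.frame(algorithm = c("RF", "LR"), mcc = c(NA, 0.1),
                     f1 = c(1, 0.2), accuracy = c(1, 0.6),
                     sensitivity = c(1, 0.6))
  expect_identical(tab4$algorithm[modelSelectionOrder(tab4)[1]], "LR")
})

test_that("selectBestModel evaluates candidates on the validation set", {
  f <- makeFeatures(120, seed = 8)
  y <- f$contact_ratio > 0
  ds <- labeledDataset(f, y, rep(sprintf("p%d", 1:30), each = 4))
  sp <- splitDataset(ds, seed = 3)
  cands <- lapply(c("RF", "LR"), function(a)
    trainModel(sp$train, a, "ALCB", seed = 0))
  best <- selectBestModel(cands, sp$test)
  met <- attr(best, "selection_metrics")
  expect_identical(nrow(met), 2L)
  expect_identical(met$algorithm[1], best@algorithm)
  expect_true(all(diff(met$mcc) <= 1e-12))
  expect_error(selectBestModel(list(), sp$test), class = "ubm_selection_error")
})
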