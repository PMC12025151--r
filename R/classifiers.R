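#' Assemble a labeled dataset for one mechanism target
#'
#' @param features data frame of feature rows (see [extractFeatureRow()]).
#' @param labels logical vector, one per row: mechanism present.
#' @param patient_id character/factor vector of patient grouping keys.
#' @return List of class `ubm_labeled_dataset` with aligned components.
#' @export
labeledDataset <- function(features, labels, patient_id) {
  if (nrow(features) != length(labels) || length(labels) != length(patient_id))
    .ubmStop("ubm_input_error",
             "features, labels and patient ids must be aligned")
  structure(list(features = features, labels = as.logical(labels),
                 patient_id = as.character(patient_id)),
            class = "ubm_labeled_dataset")
}

#' Patient-grouped random train/test split
#'
#' Randomly partitions patients (never single images) so that roughly a
#' quarter of the images land in the test set - the 3:1 convention - and no
#' patient contributes to both sides. Reproducible for a fixed seed.
#'
#' @param ds a [labeledDataset()].
#' @param seed integer seed.
#' @param test_fraction target image fraction in the test set (default 0.25);
#'   met up to one patient's worth of images.
#' @return List with `train` and `test`, both `ubm_labeled_dataset`.
#' @export
splitDataset <- function(ds, seed = 0L, test_fraction = 0.25) {
  patients <- unique(ds$patient_id)
  if (length(patients) < 2L)
    .ubmStop("ubm_split_error", "at least two patients required to split")
  n <- length(ds$labels)
  target <- test_fraction * n
  shuffled <- .withSeed(seed, sample(patients))
  sizes <- table(ds$patient_id)[shuffled]
  csum <- cumsum(as.integer(sizes))
  k <- which(csum >= target)[1]
  if (is.na(k)) k <- length(shuffled)
  # do not let the overshooting patient push the fraction further from the
  # target than stopping one patient earlier would
  if (k > 1 && abs(csum[k - 1] - target) < abs(csum[k] - target)) k <- k - 1
  test_pat <- shuffled[seq_len(k)]
  in_test <- ds$patient_id %in% test_pat
  list(train = labeledDataset(ds$features[!in_test, , drop = FALSE],
                              ds$labels[!in_test], ds$patient_id[!in_test]),
       test = labeledDataset(ds$features[in_test, , drop = FALSE],
                             ds$labels[in_test], ds$patient_id[in_test]))
}

#' Default hyperparameters of the classifier bank
#'
#' Read from the configuration file shipped with the package
#' (`inst/config/hyperparameters.yaml`); library defaults for each family.
#'
#' @return Named list, one entry per algorithm.
#' @export
classifierHyperparameters <- function() {
  path <- system.file("config", "hyperparameters.yaml", package = "UBMbiometry")
  yaml::read_yaml(path)
}

# design matrix in schema order, median-imputed and standardized
.prepareMatrix <- function(features, schema, medians, center, scale) {
  missing_cols <- setdiff(schema, colnames(features))
  if (length(missing_cols))
    .ubmStop("ubm_schema_error", "feature columns missing: %s",
             paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, schema, drop = FALSE])
  storage.mode(X) <- "double"
  for (j in seq_along(schema)) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- medians[j]
  }
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' Train one binary mechanism classifier
#'
#' Fits the pipeline median imputation of undefined features, per-feature
#' standardization (constants from the training rows only) and one of the
#' five classifier families with the pinned default hyperparameters
#' ([classifierHyperparameters()]). The decision threshold is 0.5 and the
#' fit is deterministic for a fixed seed (SVM probabilities come from a
#' deterministic Platt calibration of the decision values fitted on the
#' training set).
#'
#' @param train a [labeledDataset()] with both label values present.
#' @param algorithm one of [ALGORITHM_IDS].
#' @param target one of [MECHANISM_TARGETS].
#' @param seed integer training seed.
#' @param threshold decision threshold (default 0.5).
#' @return A [TrainedModel-class].
#' @export
trainModel <- function(train, algorithm, target, seed = 0L, threshold = 0.5) {
  algorithm <- match.arg(algorithm, ALGORITHM_IDS)
  target <- match.arg(target, MECHANISM_TARGETS)
  y <- train$labels
  if (length(unique(y)) < 2L)
    .ubmStop("ubm_degenerate_labels",
             "training labels contain a single class")
  schema <- featureSchema()
  raw <- as.matrix(train$features[, schema, drop = FALSE])
  storage.mode(raw) <- "double"
  medians <- apply(raw, 2, function(v) {
    m <- stats::median(v[is.finite(v)])
    if (!is.finite(m)) 0 else m
  })
  imputed <- raw
  for (j in seq_along(schema)) {
    bad <- !is.finite(imputed[, j])
    if (any(bad)) imputed[bad, j] <- medians[j]
  }
  center <- colMeans(imputed)
  scale <- apply(imputed, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(imputed, 2, center, "-"), 2, scale, "/")
  hp <- classifierHyperparameters()[[algorithm]]
  platt <- c(NA_real_, NA_real_)
  fit <- .withSeed(seed, switch(algorithm,
    RF = randomForest::randomForest(
      x = X, y = factor(y, levels = c(FALSE, TRUE)),
      ntree = hp$ntree, mtry = max(1, floor(sqrt(ncol(X))))),
    GBDT = xgboost::xgboost(
      X, factor(y, levels = c(FALSE, TRUE)),
      objective = "binary:logistic", nrounds = hp$nrounds,
      max_depth = hp$max_depth, learning_rate = hp$eta,
      reg_lambda = hp$lambda, reg_alpha = hp$alpha,
      subsample = hp$subsample, verbosity = 0, nthreads = 1,
      seed = as.integer(seed)),
    XGB = xgboost::xgboost(
      X, factor(y, levels = c(FALSE, TRUE)),
      objective = "binary:logistic", nrounds = hp$nrounds,
      max_depth = hp$max_depth, learning_rate = hp$eta,
      reg_lambda = hp$lambda, verbosity = 0, nthreads = 1,
      seed = as.integer(seed)),
    SVM = e1071::svm(x = X, y = factor(y, levels = c(FALSE, TRUE)),
                     kernel = hp$kernel, cost = hp$cost,
                     gamma = if (identical(hp$gamma, "scale"))
                       1 / ncol(X) else hp$gamma),
    LR = suppressWarnings(stats::glm.fit(
      x = cbind(1, X), y = as.numeric(y),
      family = stats::binomial()))
  ))
  if (algorithm == "SVM") {
    dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                          "decision.values"))
    pl <- suppressWarnings(stats::glm.fit(x = cbind(1, dv), y = as.numeric(y),
                                          family = stats::binomial()))
    platt <- as.numeric(pl$coefficients)
    platt[!is.finite(platt)] <- 0
  }
  new("TrainedModel", algorithm = algorithm, target = target, fit = fit,
      schema = schema, center = center, scale = scale, medians = medians,
      threshold = threshold, seed = as.integer(seed), platt = platt)
}

#' Predict mechanism presence for feature rows
#'
#' Applies the model's imputation/standardization pipeline and returns the
#' predicted probability and the boolean call (probability at or above the
#' threshold counts as present).
#'
#' @param model a [TrainedModel-class].
#' @param features data frame of feature rows conforming to the schema.
#' @return Data frame with columns `probability` and `call`.
#' @export
predictMechanism <- function(model, features) {
  X <- .prepareMatrix(features, model@schema, model@medians,
                      model@center, model@scale)
  p <- switch(model@algorithm,
    RF = stats::predict(model@fit, X, type = "prob")[, "TRUE"],
    GBDT = ,
    XGB = as.numeric(stats::predict(model@fit, X, type = "response")),
    SVM = {
      dv <- as.numeric(attr(stats::predict(model@fit, X,
                                           decision.values = TRUE),
                            "decision.values"))
      stats::plogis(model@platt[1] + model@platt[2] * dv)
    },
    LR = as.numeric(stats::plogis(cbind(1, X) %*% model@fit$coefficients))
  )
  p <- pmin(pmax(as.numeric(p), 0), 1)
  data.frame(probability = p, call = p >= model@threshold)
}

#' Rank classifier candidates by the selection criterion
#'
#' Orders a metric table by MCC, then F1, then accuracy, then sensitivity,
#' with a final fixed algorithm-order tie-break (RF < GBDT < XGB < SVM <
#' LR) making the chain total and deterministic. Undefined metrics rank
#' below any defined value.
#'
#' @param metrics data frame with columns `algorithm`, `mcc`, `f1`,
#'   `accuracy`, `sensitivity`.
#' @return Integer permutation ordering rows from best to worst.
#' @export
modelSelectionOrder <- function(metrics) {
  neg <- function(v) { v[!is.finite(v)] <- -Inf; -v }
  order(neg(metrics$mcc), neg(metrics$f1), neg(metrics$accuracy),
        neg(metrics$sensitivity),
        match(metrics$algorithm, ALGORITHM_IDS))
}

#' Select the best candidate model on a validation set
#'
#' Evaluates every candidate on the validation dataset and applies the
#' MCC-first ranking of [modelSelectionOrder()].
#'
#' @param candidates list of [TrainedModel-class] objects.
#' @param validation a [labeledDataset()].
#' @return The selected [TrainedModel-class], with the validation metric
#'   table attached as attribute `"selection_metrics"`.
#' @export
selectBestModel <- function(candidates, validation) {
  if (!length(candidates))
    .ubmStop("ubm_selection_error", "no candidate models supplied")
  tab <- do.call(rbind, lapply(candidates, function(m) {
    pred <- predictMechanism(m, validation$features)
    cc <- confusionCounts(validation$labels, pred$call)
    met <- binaryMetrics(cc)
    data.frame(algorithm = m@algorithm, mcc = met$mcc, f1 = met$f1,
               accuracy = met$accuracy, sensitivity = met$sensitivity,
               stringsAsFactors = FALSE)
  }))
  ord <- modelSelectionOrder(tab)
  best <- candidates[[ord[1]]]
  attr(best, "selection_metrics") <- tab[ord, , drop = FALSE]
  best
}

#' Train the full bank and select the best model per mechanism
#'
#' Convenience wrapper: fits all five algorithms on the training split for
#' one target and selects the best on the validation split.
#'
#' @param train,validation [labeledDataset()] splits.
#' @param target one of [MECHANISM_TARGETS].
#' @param seed training seed shared across the bank.
#' @return The selected [TrainedModel-class].
#' @export
trainAndSelect <- function(train, validation, target, seed = 0L) {
  candidates <- lapply(ALGORITHM_IDS, function(a)
    trainModel(train, a, target, seed = seed))
  selectBestModel(candidates, validation)
}
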