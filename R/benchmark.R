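#' Parameter-recovery study over the synthetic anatomy grid
#'
#' Renders `n` synthetic masks with anatomy drawn uniformly over the
#' validation grid (root thickness 300-600 um, sagitta -100-400 um,
#' contact fraction 0-1, random orientation), runs the full feature
#' extraction on each, and tabulates measurement errors against the
#' analytic ground truth. This is the package's central
#' measure-after-render loop.
#'
#' @param n number of masks.
#' @param seed master seed.
#' @return Data frame of per-mask errors with a `summary` attribute: median
#'   absolute errors of the three thickness features (um), median relative
#'   sagitta error, median absolute contact-ratio error, and the fraction
#'   of masks with spur localization error within 10 px.
#' @export
parameterRecoveryGrid <- function(n = 100, seed = 0) {
  params <- .withSeed(seed, lapply(seq_len(n), function(i) {
    t_root <- stats::runif(1, 300, 600)
    anatomyParams(
      iris_thickness_root_um = t_root,
      iris_thickness_pupil_um = min(stats::runif(1, 250, 350), 0.9 * t_root),
      bowing_sagitta_um = stats::runif(1, -100, 400),
      ciliary_contact_fraction = stats::runif(1, 0, 1),
      iris_length_um = stats::runif(1, 3800, 4600),
      orientation = sample(c("left", "right"), 1))
  }))
  rows <- lapply(seq_len(n), function(i) {
    r <- renderMask(params[[i]], seed = (seed * 1013 + i) %%
                      .Machine$integer.max)
    fr <- extractFeatureRow(r$mask, image_id = sprintf("grid%03d", i))
    tr <- r$truth
    data.frame(
      err_it_spur500 = fr$it_spur500_um - tr$it_spur500_um,
      err_it_spur750 = fr$it_spur750_um - tr$it_spur750_um,
      err_it_root500 = fr$it_root500_um - tr$it_root500_um,
      err_sagitta = fr$iris_curvature_um - tr$sagitta_um,
      true_sagitta = tr$sagitta_um,
      err_contact = fr$contact_ratio - tr$contact_ratio,
      spur_err_px = sqrt(sum((c(fr$spur_row, fr$spur_col) - tr$spur)^2)))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    median_abs_err_it_spur500_um = stats::median(abs(out$err_it_spur500)),
    median_abs_err_it_spur750_um = stats::median(abs(out$err_it_spur750)),
    median_abs_err_it_root500_um = stats::median(abs(out$err_it_root500)),
    median_rel_err_sagitta = stats::median(abs(out$err_sagitta) /
                                             pmax(abs(out$true_sagitta), 1)),
    median_abs_err_contact_ratio = stats::median(abs(out$err_contact)),
    spur_within_10px_fraction = mean(out$spur_err_px <= 10))
  out
}

#' End-to-end synthetic classification benchmark
#'
#' Samples a patient-grouped synthetic cohort with an equal four-class
#' mixture, extracts features for every image, fits the five-algorithm
#' bank per mechanism on a patient-grouped 3:1 split, selects the best
#' model by the MCC-first criterion, and evaluates the three selected
#' binary models and the integrated four-way assessment on the held-out
#' images.
#'
#' @param n cohort size.
#' @param seed master seed (cohort, split and training).
#' @return List with `binary_accuracy` (named numeric for PB/TPI/ALCB),
#'   `integrated_accuracy`, `selected` (named character of chosen
#'   algorithms), `auc` (named numeric), `n_test`, and the underlying
#'   `features` and `labels` tables.
#' @export
syntheticBenchmark <- function(n = 400, seed = 0) {
  cohort <- sampleCohort(cohortSpec(n, seed = seed))
  feats <- do.call(rbind, lapply(seq_len(n), function(i)
    extractFeatureRow(cohort$masks[[i]],
                      image_id = cohort$labels$image_id[i])))
  labels <- cohort$labels
  acc <- auc <- stats::setNames(numeric(3), MECHANISM_TARGETS)
  selected <- stats::setNames(character(3), MECHANISM_TARGETS)
  calls <- list(); test_idx <- NULL
  for (target in MECHANISM_TARGETS) {
    y <- labels[[tolower(target)]]
    ds <- labeledDataset(feats, y, labels$patient_id)
    spl <- splitDataset(ds, seed = seed)
    best <- trainAndSelect(spl$train, spl$test, target, seed = seed)
    pred <- predictMechanism(best, spl$test$features)
    cc <- confusionCounts(spl$test$labels, pred$call)
    acc[target] <- (cc[["tp"]] + cc[["tn"]]) / sum(cc)
    auc[target] <- rocAuc(pred$probability, spl$test$labels)$auc
    selected[target] <- best@algorithm
    calls[[target]] <- pred$call
    if (is.null(test_idx))
      test_idx <- match(spl$test$features$image_id, labels$image_id)
  }
  integrated <- integrateMechanisms(calls$PB, calls$TPI, calls$ALCB)
  mc <- multiclassAccuracy(labels$class[test_idx], integrated)
  list(binary_accuracy = acc, integrated_accuracy = mc$accuracy,
       selected = selected, auc = auc, n_test = length(test_idx),
       confusion = mc$confusion, features = feats, labels = labels)
}
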