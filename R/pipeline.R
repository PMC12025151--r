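#' Build a run configuration for the end-to-end pipeline
#'
#' A single configuration object (optionally loaded from YAML) is the
#' source of truth for a run; every artifact is stamped with its hash and
#' seed so any published run is reconstructible from config + seed alone.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param n cohort size for the simulate stage.
#' @param mode acquisition mode.
#' @param seed master seed for simulation, splitting and training.
#' @param class_weights optional named mixture weights over
#'   [INTEGRATED_CLASSES].
#' @param boundary_jitter_px jitter amplitude for the renderer.
#' @param test_fraction patient-grouped test fraction for the split.
#' @return List of class `ubm_run_config`.
#' @export
runConfig <- function(out_dir, n = 80L, mode = "half_frame", seed = 0L,
                      class_weights = NULL, boundary_jitter_px = 0.3,
                      test_fraction = 0.25) {
  structure(list(out_dir = out_dir, n = as.integer(n), mode = mode,
                 seed = as.integer(seed), class_weights = class_weights,
                 boundary_jitter_px = boundary_jitter_px,
                 test_fraction = test_fraction),
            class = "ubm_run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with the fields of [runConfig()].
#' @return List of class `ubm_run_config`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

.configHash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small deterministic rolling hash; avoids an external digest dependency
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stageLog <- function(stage, msg, t0 = NULL) {
  dur <- if (is.null(t0)) "" else
    sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0)
  message(sprintf("[%s] %s%s", stage, msg, dur))
}

.requireArtifact <- function(path, produced_by) {
  if (!file.exists(path))
    .ubmStop("ubm_dependency_error",
             "missing artifact '%s'; run stage '%s' first",
             basename(path), produced_by)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stage (or all stages in dependency order):
#' `simulate` renders a synthetic cohort to indexed PNG masks plus
#' ground-truth and label CSVs; `features` extracts the per-image feature
#' table; `train` fits the five-algorithm bank per mechanism and selects
#' the best model each; `assess` produces the per-image integrated
#' assessments; `evaluate` writes the metric report mirroring the
#' mechanism-by-mechanism table structure. Re-running with an identical
#' config reproduces identical CSV/JSON artifacts.
#'
#' @param config a [runConfig()].
#' @param stage one of `"simulate"`, `"features"`, `"train"`, `"assess"`,
#'   `"evaluate"`, `"all"`.
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config,
                        stage = c("all", "simulate", "features", "train",
                                  "assess", "evaluate")) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "features", "train", "assess", "evaluate") else stage
  for (s in stages) {
    t0 <- as.numeric(Sys.time())
    switch(s,
      simulate = .stageSimulate(config),
      features = .stageFeatures(config),
      train = .stageTrain(config),
      assess = .stageAssess(config),
      evaluate = .stageEvaluate(config))
    .stageLog(s, "done", t0)
  }
  manifest <- list(config_hash = .configHash(config), seed = config$seed,
                   version = as.character(utils::packageVersion("UBMbiometry")),
                   stages = stages)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

.stageSimulate <- function(config) {
  spec <- cohortSpec(config$n, class_weights = config$class_weights,
                     mode = config$mode,
                     boundary_jitter_px = config$boundary_jitter_px,
                     seed = config$seed)
  cohort <- sampleCohort(spec)
  mask_dir <- file.path(config$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (i in seq_along(cohort$masks))
    writeMask(cohort$masks[[i]],
              file.path(mask_dir, paste0(cohort$labels$image_id[i], ".png")))
  truth <- do.call(rbind, lapply(seq_along(cohort$truth), function(i) {
    tr <- cohort$truth[[i]]
    data.frame(image_id = cohort$labels$image_id[i],
               spur_row = tr$spur[["row"]], spur_col = tr$spur[["col"]],
               root_row = tr$root[["row"]], root_col = tr$root[["col"]],
               it_spur500_um = tr$it_spur500_um,
               it_spur750_um = tr$it_spur750_um,
               it_root500_um = tr$it_root500_um,
               sagitta_um = tr$sagitta_um,
               contact_ratio = tr$contact_ratio,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth, file.path(config$out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(config$out_dir, "labels.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

.stageFeatures <- function(config) {
  labels_path <- .requireArtifact(file.path(config$out_dir, "labels.csv"),
                                  "simulate")
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  mask_dir <- file.path(config$out_dir, "masks")
  rows <- lapply(labels$image_id, function(id) {
    mask <- readMask(file.path(mask_dir, paste0(id, ".png")),
                     mode = config$mode)
    extractFeatureRow(mask, image_id = id)
  })
  feats <- do.call(rbind, rows)
  utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

.stageTrain <- function(config) {
  feats <- utils::read.csv(
    .requireArtifact(file.path(config$out_dir, "features.csv"), "features"),
    stringsAsFactors = FALSE)
  labels <- utils::read.csv(
    .requireArtifact(file.path(config$out_dir, "labels.csv"), "simulate"),
    stringsAsFactors = FALSE)
  stopifnot(identical(feats$image_id, labels$image_id))
  bundle <- list()
  split_info <- NULL
  for (target in MECHANISM_TARGETS) {
    lab <- labels[[tolower(target)]]
    ds <- labeledDataset(feats, lab, labels$patient_id)
    sp <- splitDataset(ds, seed = config$seed,
                       test_fraction = config$test_fraction)
    bundle[[target]] <- trainAndSelect(sp$train, sp$test, target,
                                       seed = config$seed)
    if (is.null(split_info))
      split_info <- data.frame(image_id = feats$image_id,
                               in_test = feats$image_id %in%
                                 sp$test$features$image_id)
  }
  saveRDS(bundle, file.path(config$out_dir, "models.rds"))
  utils::write.csv(split_info, file.path(config$out_dir, "split.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

.stageAssess <- function(config) {
  bundle <- readRDS(
    .requireArtifact(file.path(config$out_dir, "models.rds"), "train"))
  labels <- utils::read.csv(
    .requireArtifact(file.path(config$out_dir, "labels.csv"), "simulate"),
    stringsAsFactors = FALSE)
  mask_dir <- file.path(config$out_dir, "masks")
  recs <- lapply(labels$image_id, function(id) {
    mask <- readMask(file.path(mask_dir, paste0(id, ".png")),
                     mode = config$mode)
    assessImage(mask, bundle, image_id = id)
  })
  out <- do.call(rbind, recs)
  utils::write.csv(out, file.path(config$out_dir, "assessments.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

.stageEvaluate <- function(config) {
  calls <- utils::read.csv(
    .requireArtifact(file.path(config$out_dir, "assessments.csv"), "assess"),
    stringsAsFactors = FALSE)
  labels <- utils::read.csv(
    .requireArtifact(file.path(config$out_dir, "labels.csv"), "simulate"),
    stringsAsFactors = FALSE)
  split <- utils::read.csv(
    .requireArtifact(file.path(config$out_dir, "split.csv"), "train"),
    stringsAsFactors = FALSE)
  test_ids <- split$image_id[split$in_test]
  idx <- calls$image_id %in% test_ids
  report <- list(seed = config$seed, n_test = sum(idx))
  for (target in MECHANISM_TARGETS) {
    lt <- tolower(target)
    cc <- confusionCounts(labels[[lt]][idx], calls[[lt]][idx])
    met <- binaryMetrics(cc)
    # a small held-out set can be single-class; flag the AUC as undefined
    roc <- tryCatch(rocAuc(calls[[paste0("p_", lt)]][idx], labels[[lt]][idx]),
                    ubm_undefined_metric = function(e) list(auc = NA_real_))
    report[[target]] <- list(
      confusion = as.list(cc),
      accuracy = met$accuracy, sensitivity = met$sensitivity,
      specificity = met$specificity, ppv = met$ppv, npv = met$npv,
      f1 = met$f1, mcc = met$mcc, auc = roc$auc,
      accuracy_ci = as.list(stats::setNames(
        as.numeric(proportionCI(cc[["tp"]] + cc[["tn"]], sum(cc))),
        c("low", "high"))))
  }
  mc <- multiclassAccuracy(labels$class[idx], calls$integrated_class[idx])
  report$integrated <- list(accuracy = mc$accuracy,
                            confusion = as.data.frame(mc$confusion))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(NULL)
}
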