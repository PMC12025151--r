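#' Integrated four-way angle-closure mechanism category
#'
#' Maps the three binary mechanism verdicts to the final assessment class:
#' pupillary block alone is `pure_pb`; thick peripheral iris and/or an
#' anteriorly located ciliary body without pupillary block is
#' `pure_non_pb`; pupillary block together with at least one of the other
#' two is `mm` (multiple mechanisms); none of the three is `others`.
#' Total and vectorized over the eight boolean combinations.
#'
#' @param pb,tpi,alcb logical vectors (recycled to a common length).
#' @return Factor with levels [INTEGRATED_CLASSES].
#' @examples
#' integrateMechanisms(TRUE, FALSE, FALSE)   # pure_pb
#' integrateMechanisms(TRUE, TRUE, TRUE)     # mm
#' @export
integrateMechanisms <- function(pb, tpi, alcb) {
  n <- max(length(pb), length(tpi), length(alcb))
  pb <- rep_len(as.logical(pb), n)
  tpi <- rep_len(as.logical(tpi), n)
  alcb <- rep_len(as.logical(alcb), n)
  out <- ifelse(pb & !tpi & !alcb, "pure_pb",
         ifelse(!pb & (tpi | alcb), "pure_non_pb",
         ifelse(pb, "mm", "others")))
  factor(out, levels = INTEGRATED_CLASSES)
}

#' Assess one image with a bundle of mechanism models
#'
#' Runs the full per-image pipeline: feature extraction, the three binary
#' mechanism predictions, and the integrated four-way category, with full
#' provenance retained. Deterministic and side-effect free.
#'
#' @param mask a [SegmentationMask-class].
#' @param bundle named list of [TrainedModel-class] objects with entries
#'   `PB`, `TPI` and `ALCB`.
#' @param image_id identifier recorded in the record.
#' @return One-row `data.frame` with columns `image_id`, `p_pb`, `p_tpi`,
#'   `p_alcb`, `pb`, `tpi`, `alcb`, `integrated_class`, plus the feature
#'   row as attribute `"features"`.
#' @export
assessImage <- function(mask, bundle, image_id = "image") {
  if (!all(MECHANISM_TARGETS %in% names(bundle)))
    .ubmStop("ubm_input_error",
             "bundle must contain models named PB, TPI and ALCB")
  for (t in MECHANISM_TARGETS)
    if (bundle[[t]]@target != t)
      .ubmStop("ubm_input_error", "bundle entry %s has target %s",
               t, bundle[[t]]@target)
  row <- extractFeatureRow(mask, image_id = image_id)
  pr <- lapply(MECHANISM_TARGETS, function(t)
    predictMechanism(bundle[[t]], row))
  names(pr) <- MECHANISM_TARGETS
  rec <- data.frame(
    image_id = image_id,
    p_pb = pr$PB$probability, p_tpi = pr$TPI$probability,
    p_alcb = pr$ALCB$probability,
    pb = pr$PB$call, tpi = pr$TPI$call, alcb = pr$ALCB$call,
    integrated_class = as.character(
      integrateMechanisms(pr$PB$call, pr$TPI$call, pr$ALCB$call)),
    stringsAsFactors = FALSE
  )
  attr(rec, "features") <- row
  rec
}
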