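#' @import methods
NULL

#' Tissue label codes used throughout the package
#'
#' Integer encoding of the tissue classes in a segmentation raster:
#' 0 = background, 1 = iris, 2 = sclera, 3 = ciliary body.
#'
#' @format Named integer vector of length 4.
#' @export
TISSUE_CODES <- c(background = 0L, iris = 1L, sclera = 2L, ciliary_body = 3L)

#' Acquisition modes supported by the scanner geometry model
#'
#' `"half_frame"` images cover a 9.75 mm x 6.00 mm field,
#' `"panorama"` images a 15.50 mm x 9.50 mm field.
#'
#' @format Character vector of length 2.
#' @export
ACQUISITION_MODES <- c("half_frame", "panorama")

# scan ranges in mm (width across columns, height down rows)
.SCAN_RANGE_MM <- list(
  half_frame = c(width = 9.75, height = 6.00),
  panorama   = c(width = 15.50, height = 9.50)
)

#' Segmentation mask of a single-angle anterior-segment image
#'
#' An S4 container for a tissue-label raster together with its acquisition
#' geometry. The `labels` slot is an integer H x W matrix with values from
#' [TISSUE_CODES] (0 background, 1 iris, 2 sclera, 3 ciliary body), indexed
#' `[row, col]` with a 0-based subpixel coordinate convention downstream
#' (point `(r, c)` sits at physical `(r * sy, c * sx)` micrometres from the
#' top-left corner). `spacing` holds the per-axis pixel pitch in um/px
#' (`x` across columns, `y` down rows); the two axes are in general unequal
#' and all physical measurements in the package honour that anisotropy.
#' `flipped` records whether [normalizeOrientation()] mirrored the raster.
#'
#' @slot labels integer matrix of tissue codes.
#' @slot mode one of [ACQUISITION_MODES].
#' @slot spacing named numeric vector `c(x = , y = )`, um per pixel.
#' @slot flipped logical flag set by orientation normalization.
#' @seealso [readMask()], [validateMask()], [spacingForMode()]
#' @export
setClass("SegmentationMask",
  representation(labels = "matrix", mode = "character",
                 spacing = "numeric", flipped = "logical"),
  validity = function(object) {
    msg <- character()
    lab <- object@labels
    if (!is.numeric(lab) && !is.integer(lab))
      msg <- c(msg, "labels must be a numeric/integer matrix")
    else if (!all(lab %in% 0:3))
      msg <- c(msg, "labels must only contain tissue codes 0,1,2,3")
    if (length(object@mode) != 1L || !object@mode %in% ACQUISITION_MODES)
      msg <- c(msg, "mode must be one of 'half_frame', 'panorama'")
    sp <- object@spacing
    if (length(sp) != 2L || !all(c("x", "y") %in% names(sp)))
      msg <- c(msg, "spacing must be a named numeric vector c(x=, y=)")
    else if (!all(is.finite(sp)) || any(sp <= 0))
      msg <- c(msg, "spacing must be strictly positive and finite")
    if (length(object@flipped) != 1L || is.na(object@flipped))
      msg <- c(msg, "flipped must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SegmentationMask
#'
#' @param labels integer H x W matrix of tissue codes (0-3).
#' @param mode acquisition mode, one of [ACQUISITION_MODES].
#' @param spacing optional named numeric `c(x=, y=)` in um/px; computed from
#'   `mode` and the raster dimensions via [spacingForMode()] when `NULL`.
#' @param flipped logical; whether the raster has been mirrored during
#'   orientation normalization.
#' @return A [SegmentationMask-class] object.
#' @examples
#' m <- SegmentationMask(matrix(0L, 8, 10), "half_frame")
#' pixelSpacing(m)
#' @export
SegmentationMask <- function(labels, mode = "half_frame", spacing = NULL,
                             flipped = FALSE) {
  storage.mode(labels) <- "integer"
  if (is.null(spacing))
    spacing <- spacingForMode(mode, ncol(labels), nrow(labels))
  new("SegmentationMask", labels = labels, mode = mode,
      spacing = spacing, flipped = flipped)
}

#' @describeIn SegmentationMask-class raster dimensions `c(rows, cols)`.
#' @param x a `SegmentationMask`.
#' @export
setMethod("dim", "SegmentationMask", function(x) dim(x@labels))

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SegmentationMask: %d x %d px, mode '%s'%s\n",
              d[1], d[2], object@mode,
              if (object@flipped) " (flipped)" else ""))
  cat(sprintf("  spacing: %.4f x %.4f um/px (x, y)\n",
              object@spacing["x"], object@spacing["y"]))
  counts <- tabulate(object@labels + 1L, nbins = 4L)
  cat(sprintf("  pixels: background %d, iris %d, sclera %d, ciliary %d\n",
              counts[1], counts[2], counts[3], counts[4]))
})

#' @rdname maskAccessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname maskAccessors
#' @export
setGeneric("acquisitionMode", function(x) standardGeneric("acquisitionMode"))
#' @rdname maskAccessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname maskAccessors
#' @export
setGeneric("isFlipped", function(x) standardGeneric("isFlipped"))

#' Accessors for SegmentationMask slots
#'
#' @param x a [SegmentationMask-class].
#' @return `maskLabels`: the integer label matrix; `acquisitionMode`: the
#'   mode string; `pixelSpacing`: named numeric `c(x=, y=)` in um/px;
#'   `isFlipped`: logical.
#' @name maskAccessors
NULL

#' @rdname maskAccessors
#' @export
setMethod("maskLabels", "SegmentationMask", function(x) x@labels)
#' @rdname maskAccessors
#' @export
setMethod("acquisitionMode", "SegmentationMask", function(x) x@mode)
#' @rdname maskAccessors
#' @export
setMethod("pixelSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname maskAccessors
#' @export
setMethod("isFlipped", "SegmentationMask", function(x) x@flipped)

#' Scleral spur location
#'
#' Subpixel scleral-spur location anchoring all distance-referenced
#' biometry. `point` is `c(row, col)` in the 0-based subpixel convention,
#' `method` records the localization heuristic so alternatives can be
#' swapped in, and `quality` is a confidence score in `[0, 1]` (1 when the
#' sclerociliary interface touches the iris, decaying linearly over the
#' quality normalization distance).
#'
#' @slot point numeric `c(row, col)`.
#' @slot method character tag of the localization procedure.
#' @slot quality numeric in `[0, 1]`.
#' @seealso [locateScleralSpur()]
#' @export
setClass("SpurPoint",
  representation(point = "numeric", method = "character", quality = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@point) != 2L || !all(is.finite(object@point)))
      msg <- c(msg, "point must be finite numeric c(row, col)")
    if (length(object@quality) != 1L || is.na(object@quality) ||
        object@quality < 0 || object@quality > 1)
      msg <- c(msg, "quality must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SpurPoint
#'
#' @param point numeric `c(row, col)` subpixel location.
#' @param method character tag of the localization procedure.
#' @param quality score in `[0, 1]`.
#' @return A [SpurPoint-class] object.
#' @export
SpurPoint <- function(point, method = "manual", quality = 1) {
  point <- as.numeric(point)
  names(point) <- c("row", "col")
  new("SpurPoint", point = point, method = method, quality = quality)
}

setMethod("show", "SpurPoint", function(object) {
  cat(sprintf("SpurPoint: (row %.2f, col %.2f), method '%s', quality %.3f\n",
              object@point[1], object@point[2], object@method, object@quality))
})

#' @rdname spurAccessors
#' @export
setGeneric("spurLocation", function(x) standardGeneric("spurLocation"))
#' @rdname spurAccessors
#' @export
setGeneric("spurQuality", function(x) standardGeneric("spurQuality"))

#' Accessors for SpurPoint slots
#'
#' @param x a [SpurPoint-class].
#' @return `spurLocation`: numeric `c(row, col)`; `spurQuality`: numeric.
#' @name spurAccessors
NULL

#' @rdname spurAccessors
#' @export
setMethod("spurLocation", "SpurPoint", function(x) x@point)
#' @rdname spurAccessors
#' @export
setMethod("spurQuality", "SpurPoint", function(x) x@quality)

#' Mechanism classifier algorithm identifiers
#'
#' The five classifier families in the bank, in their fixed tie-break order:
#' random forest, gradient-boosted decision trees, extreme gradient
#' boosting, support vector machine, logistic regression.
#'
#' @format Character vector of length 5.
#' @export
ALGORITHM_IDS <- c("RF", "GBDT", "XGB", "SVM", "LR")

#' Mechanism targets of the binary classifiers
#' @format Character vector of length 3.
#' @export
MECHANISM_TARGETS <- c("PB", "TPI", "ALCB")

#' A fitted binary mechanism classifier
#'
#' Bundles the fitted model with everything needed to reproduce its
#' predictions: the ordered feature schema, the training-set imputation
#' medians for undefined measurements, the training-set standardization
#' constants, the decision threshold and the training seed.
#'
#' @slot algorithm one of [ALGORITHM_IDS].
#' @slot target one of [MECHANISM_TARGETS].
#' @slot fit fitted model object (class depends on `algorithm`).
#' @slot schema ordered character vector of feature column names.
#' @slot center,scale named numeric standardization constants (train only).
#' @slot medians named numeric imputation values for undefined features.
#' @slot threshold decision probability threshold in (0, 1).
#' @slot seed integer training seed.
#' @slot platt numeric `c(intercept, slope)` of the Platt calibration used
#'   for SVM decision values (NA for other algorithms).
#' @seealso [trainModel()], [predictMechanism()]
#' @export
setClass("TrainedModel",
  representation(algorithm = "character", target = "character", fit = "ANY",
                 schema = "character", center = "numeric", scale = "numeric",
                 medians = "numeric", threshold = "numeric", seed = "integer",
                 platt = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@algorithm %in% ALGORITHM_IDS)
      msg <- c(msg, "algorithm must be one of RF, GBDT, XGB, SVM, LR")
    if (!object@target %in% MECHANISM_TARGETS)
      msg <- c(msg, "target must be one of PB, TPI, ALCB")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold >= 1)
      msg <- c(msg, "threshold must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s classifier for %s (threshold %.2f, seed %d)\n",
              object@algorithm, object@target, object@threshold, object@seed))
  cat(sprintf("  schema: %s\n", paste(object@schema, collapse = ", ")))
})

#' Integrated four-way assessment categories
#'
#' `pure_pb` (only pupillary block), `pure_non_pb` (thick peripheral iris
#' and/or anteriorly located ciliary body without pupillary block), `mm`
#' (pupillary block together with at least one non-PB mechanism), `others`
#' (none of the three mechanisms).
#'
#' @format Character vector of length 4.
#' @export
INTEGRATED_CLASSES <- c("pure_pb", "pure_non_pb", "mm", "others")

# classed error helper; all package errors also inherit "ubm_error"
.ubmStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "ubm_error", "error", "condition")))
}
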