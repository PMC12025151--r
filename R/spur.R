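#' Automatic scleral-spur localization
#'
#' Deterministic heuristic anchored in the anatomy of the spur as the inner
#' scleral protrusion at the ciliary-body attachment: (1) candidate points
#' are the subpixel boundary points of the sclera that lie within
#' `adjacency_tol_px` pixels of the ciliary-body component (the
#' sclerociliary interface); (2) the spur is the candidate minimizing the
#' physical distance to the iris component, with ties broken by smaller
#' row, then smaller column. The quality score is
#' `1 - d_iris / quality_scale_um` clipped to `[0, 1]`, where `d_iris` is
#' that minimal distance in micrometres.
#'
#' @param mask a valid, orientation-normalized [SegmentationMask-class].
#' @param adjacency_tol_px pixel tolerance defining the sclerociliary
#'   interface (default 2 px).
#' @param quality_scale_um normalization distance for the quality score
#'   (default 500 um).
#' @return A [SpurPoint-class] with method tag
#'   `"sclerociliary_interface_nearest_iris"`.
#' @export
locateScleralSpur <- function(mask, adjacency_tol_px = 2,
                              quality_scale_um = 500) {
  .assertValid(mask)
  scl_b <- regionBoundary(mask, "sclera")
  d_cb <- .tissueDistPx(mask, "ciliary_body")
  near <- .sampleBilinear(d_cb, scl_b) <= adjacency_tol_px
  cand <- scl_b[near, , drop = FALSE]
  if (!nrow(cand))
    .ubmStop("ubm_spur_not_found",
             "sclera and ciliary body are not adjacent; no spur candidates")
  iris_b <- regionBoundary(mask, "iris")
  sp <- pixelSpacing(mask)
  # exact physical distance of each candidate to the iris boundary
  dmin <- vapply(seq_len(nrow(cand)), function(i) {
    min(.physDistMany(cand[i, ], iris_b, sp))
  }, numeric(1))
  ord <- order(round(dmin, 9), cand[, 1], cand[, 2])
  best <- ord[1]
  q <- min(max(1 - dmin[best] / quality_scale_um, 0), 1)
  SpurPoint(cand[best, ], method = "sclerociliary_interface_nearest_iris",
            quality = q)
}
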