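#' Physical pixel spacing for an acquisition mode
#'
#' Converts the fixed scan range of an acquisition geometry into per-axis
#' pixel pitches. Half-frame images cover 9.75 mm x 6.00 mm, panorama
#' images 15.50 mm x 9.50 mm; the pitch is the scan range divided by the
#' actual raster dimensions, so non-standard rasters degrade gracefully.
#'
#' @param mode one of [ACQUISITION_MODES].
#' @param width_px,height_px raster dimensions in pixels (columns, rows).
#' @return Named numeric `c(x = , y = )`, micrometres per pixel.
#' @examples
#' spacingForMode("half_frame", 1024, 655)  # 9.5215 x 9.1603 um/px
#' @export
spacingForMode <- function(mode, width_px, height_px) {
  mode <- match.arg(mode, ACQUISITION_MODES)
  if (!is.finite(width_px) || !is.finite(height_px) ||
      width_px <= 0 || height_px <= 0)
    .ubmStop("ubm_invalid_geometry",
             "raster dimensions must be strictly positive (got %s x %s)",
             width_px, height_px)
  rng <- .SCAN_RANGE_MM[[mode]]
  c(x = unname(rng["width"]) * 1000 / width_px,
    y = unname(rng["height"]) * 1000 / height_px)
}

#' Physical distance between two subpixel points
#'
#' Euclidean distance in micrometres after per-axis scaling by the pixel
#' pitch. Points are `c(row, col)`; the two axes carry different pitches in
#' both acquisition modes, so all physical measurements must go through
#' this function rather than a scalar pitch.
#'
#' @param a,b numeric `c(row, col)` points.
#' @param spacing named numeric `c(x=, y=)` in um/px (see [pixelSpacing()]).
#' @return Distance in micrometres.
#' @examples
#' sp <- spacingForMode("half_frame", 1024, 655)
#' physicalDistance(c(0, 0), c(0, 100), sp)
#' @export
physicalDistance <- function(a, b, spacing) {
  sqrt(((a[2] - b[2]) * spacing["x"])^2 + ((a[1] - b[1]) * spacing["y"])^2)[[1]]
}

# vectorized distance from one point to an n x 2 matrix of (row, col) points
.physDistMany <- function(p, pts, spacing) {
  sqrt(((pts[, 2] - p[2]) * spacing[["x"]])^2 +
       ((pts[, 1] - p[1]) * spacing[["y"]])^2)
}

#' Default palette mapping raw PNG values to tissue codes
#'
#' Names are the raw 8-bit pixel values found in the file, values are the
#' tissue codes of [TISSUE_CODES].
#'
#' @return Named integer vector.
#' @export
defaultPalette <- function() {
  stats::setNames(0:3, as.character(0:3))
}

#' Read a tissue-label mask from a grayscale/indexed PNG
#'
#' Pixel values are mapped to tissue codes through `palette`; any value not
#' covered by the palette is an error. The physical spacing is computed
#' from the actual raster dimensions, so the pair round-trips bit-exactly
#' with [writeMask()].
#'
#' @param path PNG file path.
#' @param mode acquisition mode of the image.
#' @param palette named integer vector mapping raw pixel values (names) to
#'   tissue codes (values); see [defaultPalette()].
#' @return A [SegmentationMask-class].
#' @export
readMask <- function(path, mode = "half_frame", palette = defaultPalette()) {
  if (!file.exists(path))
    .ubmStop("ubm_io_error", "cannot read mask file '%s'", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # indexed read as gray/RGB
  raw <- round(img * 255)
  vals <- sort(unique(as.vector(raw)))
  known <- as.integer(names(palette))
  if (!all(vals %in% known))
    .ubmStop("ubm_palette_error",
             "pixel value(s) %s not covered by the palette",
             paste(setdiff(vals, known), collapse = ", "))
  lab <- matrix(palette[as.character(raw)], nrow(raw), ncol(raw))
  SegmentationMask(lab, mode = mode)
}

#' Write a tissue-label mask as an 8-bit grayscale PNG
#'
#' Inverse of [readMask()] under the same palette: each tissue code is
#' written as the raw value that maps to it.
#'
#' @param mask a [SegmentationMask-class].
#' @param path output PNG path.
#' @param palette named integer vector as in [readMask()].
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path, palette = defaultPalette()) {
  inv <- stats::setNames(as.integer(names(palette)), as.character(palette))
  lab <- maskLabels(mask)
  raw <- matrix(inv[as.character(lab)], nrow(lab), ncol(lab))
  png::writePNG(raw / 255, path)
  invisible(path)
}

# --- connected components -------------------------------------------------

# label connected components of a binary matrix; EBImage::bwlabel is
# 4-connective, so 8-connectivity is obtained by merging labels that touch
# diagonally (union-find over diagonal label pairs)
.labelComponents <- function(bin, connectivity = 8L) {
  lab <- EBImage::bwlabel(bin != 0)
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  n <- max(lab)
  if (n <= 1L || connectivity == 4L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(n), findRoot, integer(1))
    remap <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

# sizes of components, descending
.componentSizes <- function(lab) {
  if (max(lab) == 0L) return(integer())
  sort(tabulate(lab[lab > 0]), decreasing = TRUE)
}

# binary matrix of the single dominant component of a tissue, with
# sub-threshold speckle removed; NULL when the tissue is absent
.tissueComponent <- function(mask, tissue, min_px = 50L) {
  code <- if (is.character(tissue)) TISSUE_CODES[[tissue]] else as.integer(tissue)
  compute <- function() {
    bin <- maskLabels(mask) == code
    if (!any(bin)) return(NULL)
    lab <- .labelComponents(bin)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_px)
    # speckle removal must not erase a tissue that has no large component;
    # validation reports that case separately
    main <- if (length(keep)) keep[which.max(sizes[keep])] else which.max(sizes)
    lab == main
  }
  if (min_px == 50L) .maskMemo(mask, paste0("comp_", code), compute)
  else compute()
}

# memoized pixel distance map to a tissue component
.tissueDistPx <- function(mask, tissue) {
  code <- if (is.character(tissue)) TISSUE_CODES[[tissue]] else as.integer(tissue)
  .maskMemo(mask, paste0("dist_", code), function() {
    comp <- .tissueComponent(mask, code)
    if (is.null(comp)) return(NULL)
    .distToPx(comp)
  })
}

# n x 2 (row, col) indices of TRUE cells (0-based rows/cols)
.whichRC <- function(bin) {
  idx <- which(bin)
  cbind(row = (idx - 1L) %% nrow(bin), col = (idx - 1L) %/% nrow(bin))
}

# TRUE where bin has an 8-neighbour in other
.adjacent8 <- function(bin, other) {
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- other
  near <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    near <- near | pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  bin & near
}

# pixel-unit euclidean distance of every pixel to the nearest TRUE of bin
.distToPx <- function(bin) {
  d <- EBImage::distmap(matrix(as.numeric(!bin), nrow(bin), ncol(bin)))
  matrix(as.numeric(d), nrow(bin), ncol(bin))
}

# bilinear interpolation of a numeric pixel field at subpixel (row, col)
# points; symmetric under raster mirroring, unlike nearest-pixel rounding
.sampleBilinear <- function(m, pts) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(pts[, 1], 0), H - 1)
  c <- pmin(pmax(pts[, 2], 0), W - 1)
  r0 <- pmin(floor(r), H - 2); c0 <- pmin(floor(c), W - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fr) * (1 - fc) + m[i01] * (1 - fr) * fc +
    m[i10] * fr * (1 - fc) + m[i11] * fr * fc
}

# sample a pixel matrix at subpixel (row, col) points by nearest pixel;
# floor(x + 0.5) rather than round() so that integer translations of the
# raster shift the sampling rigidly (round-half-to-even is parity-bound)
.samplePx <- function(m, pts) {
  r <- pmin(pmax(floor(pts[, 1] + 0.5) + 1L, 1L), nrow(m))
  c <- pmin(pmax(floor(pts[, 2] + 0.5) + 1L, 1L), ncol(m))
  m[cbind(r, c)]
}

# --- validation -----------------------------------------------------------

#' Validate a segmentation mask against the structural rules
#'
#' Checks, without fixing anything: presence of the iris, sclera and
#' ciliary-body classes; a single connected component (8-connectivity) per
#' class once speckle below `min_px` pixels is disregarded; and
#' 8-adjacency of the iris to the ciliary body (the anatomical insertion).
#' Mirrors the exclusion of images with incomplete angle structures.
#'
#' @param mask a [SegmentationMask-class].
#' @param min_px small-object threshold in pixels; components below it are
#'   treated as segmentation speckle.
#' @return List with `valid` (logical) and `failures` (character vector of
#'   failed rules, empty when valid).
#' @export
validateMask <- function(mask, min_px = 50L) {
  if (min_px == 50L)
    return(.maskMemo(mask, "validation", function() .validateMaskImpl(mask, 50L)))
  .validateMaskImpl(mask, min_px)
}

.validateMaskImpl <- function(mask, min_px) {
  failures <- character()
  lab <- maskLabels(mask)
  tissues <- c(iris = 1L, sclera = 2L, ciliary_body = 3L)
  comps <- list()
  for (nm in names(tissues)) {
    bin <- lab == tissues[[nm]]
    if (!any(bin)) {
      failures <- c(failures, sprintf("missing class %d (%s)", tissues[[nm]], nm))
      next
    }
    cl <- .labelComponents(bin)
    sizes <- tabulate(cl[cl > 0])
    big <- sum(sizes >= min_px)
    if (big == 0L)
      failures <- c(failures, sprintf(
        "no %s component of at least %d px", nm, min_px))
    else if (big > 1L)
      failures <- c(failures, sprintf("multiple %s components", nm))
    else
      comps[[nm]] <- cl == which(sizes >= min_px)
  }
  if (!is.null(comps$iris) && !is.null(comps$ciliary_body)) {
    if (!any(.adjacent8(comps$iris, comps$ciliary_body)))
      failures <- c(failures, "iris not adjacent to ciliary body")
  }
  list(valid = length(failures) == 0L, failures = failures)
}

.assertValid <- function(mask) {
  rep <- validateMask(mask)
  if (!rep$valid)
    .ubmStop("ubm_validation_error", "mask fails validation: %s",
             paste(rep$failures, collapse = "; "))
  invisible(rep)
}

# --- orientation ----------------------------------------------------------

# column (0-based, possibly fractional) of the angle recess: mean column of
# the iris pixels closest to the sclera
.recessColumn <- function(mask) {
  iris <- .tissueComponent(mask, "iris")
  scl <- .tissueComponent(mask, "sclera")
  if (is.null(iris) || is.null(scl))
    .ubmStop("ubm_orientation_error",
             "iris and sclera required to determine orientation")
  d <- .tissueDistPx(mask, "sclera")
  di <- d[iris]
  cols <- (.whichRC(iris))[, 2]
  near <- di <= min(di) + 0.5
  mean(cols[near])
}

#' Normalize the left/right orientation of a single-angle mask
#'
#' Each image contains one side of the anterior chamber angle; this mirrors
#' the raster horizontally when needed so the angle recess (the iris-sclera
#' approach region) lies in the left half. The `flipped` slot records the
#' action. Applying the function twice is the identity.
#'
#' @param mask a valid [SegmentationMask-class].
#' @return The mask, mirrored if necessary.
#' @export
normalizeOrientation <- function(mask) {
  rc <- .recessColumn(mask)
  mid <- (ncol(maskLabels(mask)) - 1) / 2
  if (isTRUE(all.equal(rc, mid)))
    .ubmStop("ubm_orientation_error",
             "angle recess is exactly central; orientation undeterminable")
  if (rc > mid) {
    lab <- maskLabels(mask)[, ncol(maskLabels(mask)):1, drop = FALSE]
    SegmentationMask(lab, mode = acquisitionMode(mask),
                     spacing = pixelSpacing(mask),
                     flipped = !isFlipped(mask))
  } else mask
}

# --- boundaries -----------------------------------------------------------

#' Subpixel boundary contour of a tissue region
#'
#' Marching-squares iso-contour at the 0.5 level of the tissue indicator
#' (dominant component, speckle removed), computed with
#' [grDevices::contourLines()] on a zero-padded raster. Returns the outer
#' loop as an ordered, closed polygon in subpixel `(row, col)` coordinates
#' (first vertex repeated as the last).
#'
#' @param mask a [SegmentationMask-class].
#' @param tissue tissue name (`"iris"`, `"sclera"`, `"ciliary_body"`) or code.
#' @return Numeric n x 2 matrix with columns `row`, `col`.
#' @export
regionBoundary <- function(mask, tissue) {
  code <- if (is.character(tissue)) TISSUE_CODES[[tissue]] else as.integer(tissue)
  .maskMemo(mask, paste0("bound_", code), function() {
    comp <- .tissueComponent(mask, code)
    if (is.null(comp))
      .ubmStop("ubm_missing_class", "tissue '%s' absent from mask", tissue)
    .binaryBoundary(comp)
  })
}

# outer 0.5 iso-contour of a binary matrix, closed, (row, col) 0-based
.binaryBoundary <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- comp
  cl <- grDevices::contourLines(x = seq_len(H + 2) - 2, y = seq_len(W + 2) - 2,
                                z = pad, levels = 0.5)
  if (!length(cl))
    .ubmStop("ubm_missing_class", "no iso-contour found for region")
  areas <- vapply(cl, function(ct) {
    x <- ct$x; y <- ct$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
  }, numeric(1))
  ct <- cl[[which.max(areas)]]
  pts <- cbind(row = ct$x, col = ct$y)
  if (any(pts[1, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
  pts
}

# physical polyline length in um of an open (row, col) polyline
.polylineLength <- function(pts, spacing) {
  if (nrow(pts) < 2L) return(0)
  dr <- diff(pts[, 1]) * spacing[["y"]]
  dc <- diff(pts[, 2]) * spacing[["x"]]
  sum(sqrt(dr^2 + dc^2))
}
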