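#' Intersections of a physical circle with a contour
#'
#' Finds all points where a contour crosses the circle of radius
#' `radius_um` (physical micrometres, honouring the anisotropic pixel
#' pitch) centred at `center`. Crossings are located by linear
#' interpolation of the signed radial residual along each contour segment
#' and returned in contour-traversal order. The list may be empty.
#'
#' @param contour n x 2 `(row, col)` polygon/polyline, as from
#'   [regionBoundary()].
#' @param center numeric `c(row, col)`.
#' @param radius_um circle radius in micrometres (> 0).
#' @param spacing named numeric `c(x=, y=)` um/px.
#' @return m x 2 matrix of subpixel `(row, col)` crossing points.
#' @export
circleCrossings <- function(contour, center, radius_um, spacing) {
  if (radius_um <= 0)
    .ubmStop("ubm_invalid_geometry", "radius must be positive")
  if (nrow(contour) < 2L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  # subdivide long segments: the radial residual is only near-linear over
  # sub-pixel steps, and a long segment may cross the circle twice
  seg_len <- sqrt(rowSums((contour[-1, , drop = FALSE] -
                           contour[-nrow(contour), , drop = FALSE])^2))
  if (any(seg_len > 0.5)) {
    pieces <- pmax(1L, ceiling(seg_len / 0.25))
    idx0 <- rep(seq_along(pieces), pieces)
    tfrac <- unlist(lapply(pieces, function(k) (seq_len(k) - 1) / k))
    dense <- contour[idx0, , drop = FALSE] +
      tfrac * (contour[idx0 + 1L, , drop = FALSE] -
               contour[idx0, , drop = FALSE])
    contour <- rbind(dense, contour[nrow(contour), ])
  }
  f <- .physDistMany(center, contour, spacing) - radius_um
  n <- nrow(contour)
  f1 <- f[-n]; f2 <- f[-1]
  hit_zero <- which(f1 == 0)
  hit_cross <- which(f1 * f2 < 0)
  tail_zero <- if (f[n] == 0 && !all(contour[n, ] == contour[1, ])) n else integer()
  idx <- sort(c(hit_zero, hit_cross, tail_zero))
  t <- numeric(length(idx))
  crossing <- idx %in% hit_cross
  t[crossing] <- f[idx[crossing]] / (f[idx[crossing]] - f[idx[crossing] + 1L])
  a <- contour[idx, , drop = FALSE]
  b <- contour[pmin(idx + 1L, n), , drop = FALSE]
  out <- a + t * (b - a)
  colnames(out) <- c("row", "col")
  out
}

#' Local iris thickness on a measurement circle
#'
#' Intersects the circle of radius `radius_um` centred at `center` with the
#' iris boundary, splits the circle into arcs between consecutive crossings
#' (ordered by angle), keeps the arcs whose midpoint lies inside the iris,
#' and returns the physical chord length between the endpoints of the
#' selected arc - the local iris thickness. When several arcs qualify the
#' one whose midpoint is nearest `ref_point` is selected (the peripheral
#' measurement site by construction); ties break on the smaller start
#' angle.
#'
#' @param mask a valid [SegmentationMask-class].
#' @param center numeric `c(row, col)` circle centre (scleral spur or iris
#'   root).
#' @param radius_um circle radius in micrometres.
#' @param ref_point numeric `c(row, col)` reference used to disambiguate
#'   multiple qualifying arcs; defaults to `center`.
#' @return Thickness in micrometres.
#' @export
irisThicknessOnCircle <- function(mask, center, radius_um, ref_point = NULL) {
  if (is.null(ref_point)) ref_point <- center
  contour <- regionBoundary(mask, "iris")
  sp <- pixelSpacing(mask)
  cr <- circleCrossings(contour, center, radius_um, sp)
  if (nrow(cr) < 2L)
    .ubmStop("ubm_measurement_undefined",
             "circle of radius %.0f um at (%.1f, %.1f) does not cross the iris twice (found %d crossings)",
             radius_um, center[1], center[2], nrow(cr))
  iris <- .tissueComponent(mask, "iris")
  # angles in physical coordinates about the centre
  theta <- atan2((cr[, 1] - center[1]) * sp[["y"]],
                 (cr[, 2] - center[2]) * sp[["x"]])
  ord <- order(theta)
  cr <- cr[ord, , drop = FALSE]
  theta <- theta[ord]
  n <- nrow(cr)
  nxt <- c(seq_len(n)[-1], 1L)
  span <- (theta[nxt] - theta) %% (2 * pi)
  span[span == 0] <- 2 * pi
  mid_theta <- theta + span / 2
  mid <- cbind(row = center[1] + radius_um * sin(mid_theta) / sp[["y"]],
               col = center[2] + radius_um * cos(mid_theta) / sp[["x"]])
  inside <- .samplePx(iris, mid) &
    mid[, 1] >= 0 & mid[, 1] <= nrow(iris) - 1 &
    mid[, 2] >= 0 & mid[, 2] <= ncol(iris) - 1
  if (!any(inside))
    .ubmStop("ubm_measurement_undefined",
             "no circle arc of radius %.0f um lies inside the iris", radius_um)
  cand <- which(inside)
  dref <- .physDistMany(ref_point, mid[cand, , drop = FALSE], sp)
  pick <- cand[order(round(dref, 9), theta[cand])][1]
  physicalDistance(cr[pick, ], cr[nxt[pick], ], sp)
}

#' Iris root point
#'
#' Centroid of the iris pixels that are 8-adjacent to the ciliary-body
#' component - the insertion zone where the iris attaches to the ciliary
#' body. Deterministic.
#'
#' @param mask a valid [SegmentationMask-class].
#' @return Numeric `c(row, col)` subpixel point.
#' @export
irisRootPoint <- function(mask) {
  .maskMemo(mask, "root", function() .irisRootPointImpl(mask))
}

.irisRootPointImpl <- function(mask) {
  iris <- .tissueComponent(mask, "iris")
  cb <- .tissueComponent(mask, "ciliary_body")
  if (is.null(iris) || is.null(cb))
    .ubmStop("ubm_root_not_found", "iris or ciliary body absent")
  adj <- .adjacent8(iris, cb)
  if (!any(adj))
    .ubmStop("ubm_root_not_found", "iris is not adjacent to the ciliary body")
  rc <- .whichRC(adj)
  c(row = mean(rc[, 1]), col = mean(rc[, 2]))
}

#' Thick-peripheral-iris (TPI) feature group
#'
#' Iris thickness where circles of 500 and 750 um radius centred on the
#' scleral spur cross the iris, plus the thickness on a 500 um circle
#' centred at the iris root. Fields whose circle misses the iris are
#' returned as `NA` (the undefined marker); the row is still emitted and
#' classifiers impute such fields with training medians.
#'
#' @param mask a valid [SegmentationMask-class].
#' @param spur a [SpurPoint-class].
#' @return Named numeric `c(it_spur500_um, it_spur750_um, it_root500_um)`.
#' @export
extractTpiFeatures <- function(mask, spur) {
  root <- irisRootPoint(mask)
  sp_pt <- spurLocation(spur)
  safe <- function(expr) tryCatch(expr, ubm_measurement_undefined = function(e) NA_real_)
  c(it_spur500_um = safe(irisThicknessOnCircle(mask, sp_pt, 500, ref_point = root)),
    it_spur750_um = safe(irisThicknessOnCircle(mask, sp_pt, 750, ref_point = root)),
    it_root500_um = safe(irisThicknessOnCircle(mask, root, 500, ref_point = sp_pt)))
}

# posterior (larger-row) envelope of the iris: one subpixel point per
# column spanned by the iris component, ordered root->pupil (left->right
# after orientation normalization)
.posteriorEnvelope <- function(mask) {
  iris <- .tissueComponent(mask, "iris")
  idx <- which(iris, arr.ind = TRUE)
  ymax <- tapply(idx[, 1], idx[, 2], max)
  cols <- as.integer(names(ymax))
  cbind(row = as.numeric(ymax) - 1, col = cols - 1)  # 0-based
}

#' Pupillary-block (PB) feature group
#'
#' Iris curvature is measured on the posterior iris surface (the side
#' facing the ciliary body and lens, i.e. larger rows after orientation
#' normalization): the surface is taken per image column, a chord is drawn
#' from its root end to its pupil end, and the curvature is the extremal
#' signed perpendicular physical distance from the surface to that chord -
#' positive when the iris bows anteriorly (toward the cornea/sclera side),
#' negative for posterior bowing. Root insertion is the physical distance
#' from the scleral spur to the iris root point.
#'
#' @param mask a valid, orientation-normalized [SegmentationMask-class].
#' @param spur a [SpurPoint-class].
#' @return Named numeric `c(iris_curvature_um, root_insertion_um)`.
#' @export
extractPbFeatures <- function(mask, spur) {
  env <- .posteriorEnvelope(mask)
  if (nrow(env) < 3L)
    .ubmStop("ubm_centerline_error", "iris posterior surface degenerate")
  sp <- pixelSpacing(mask)
  x <- env[, 2] * sp[["x"]]; y <- env[, 1] * sp[["y"]]
  n <- length(x)
  L <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  if (L == 0)
    .ubmStop("ubm_centerline_error", "iris chord degenerate")
  # signed perpendicular distance; positive toward smaller rows (anterior)
  d <- -((x[n] - x[1]) * (y - y[1]) - (y[n] - y[1]) * (x - x[1])) / L
  curv <- d[which.max(abs(d))]
  root <- irisRootPoint(mask)
  c(iris_curvature_um = unname(curv),
    root_insertion_um = physicalDistance(spurLocation(spur), root, sp))
}

#' Iris centerline
#'
#' Morphological skeleton (Zhang-Suen thinning) of the iris component,
#' pruned to its longest geodesic path and oriented to start at the end
#' nearest the iris root.
#'
#' @param mask a valid [SegmentationMask-class].
#' @return Ordered m x 2 `(row, col)` polyline from root end to pupil end.
#' @export
irisCenterline <- function(mask) {
  iris <- .tissueComponent(mask, "iris")
  if (is.null(iris))
    .ubmStop("ubm_missing_class", "iris absent from mask")
  # thin within the component bounding box (plus margin) for speed
  rc <- .whichRC(iris)
  r0 <- max(min(rc[, 1]) - 1, 0); r1 <- min(max(rc[, 1]) + 1, nrow(iris) - 1)
  c0 <- max(min(rc[, 2]) - 1, 0); c1 <- min(max(rc[, 2]) + 1, ncol(iris) - 1)
  crop <- iris[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE]
  skel <- .thinZhangSuen(crop)
  pts <- .whichRC(skel)
  pts[, 1] <- pts[, 1] + r0; pts[, 2] <- pts[, 2] + c0
  if (nrow(pts) < 3L)
    .ubmStop("ubm_centerline_error", "iris skeleton degenerate (%d points)",
             nrow(pts))
  sp <- pixelSpacing(mask)
  path <- .longestGeodesic(pts, sp)
  root <- irisRootPoint(mask)
  d_first <- physicalDistance(path[1, ], root, sp)
  d_last <- physicalDistance(path[nrow(path), ], root, sp)
  if (d_last < d_first) path <- path[nrow(path):1, , drop = FALSE]
  colnames(path) <- c("row", "col")
  path
}

# Zhang-Suen binary thinning, vectorized over the whole raster
.thinZhangSuen <- function(bin) {
  img <- bin
  shift <- function(m, dr, dc) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(img, 1, 0);  p3 <- shift(img, 1, -1)
      p4 <- shift(img, 0, -1); p5 <- shift(img, -1, -1)
      p6 <- shift(img, -1, 0); p7 <- shift(img, -1, 1)
      p8 <- shift(img, 0, 1);  p9 <- shift(img, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1)
        cond <- img & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        cond <- img & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) { img <- img & !cond; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# longest geodesic path over 8-adjacent skeleton pixels (two-sweep)
.longestGeodesic <- function(pts, spacing) {
  n <- nrow(pts)
  dr <- outer(pts[, 1], pts[, 1], "-")
  dc <- outer(pts[, 2], pts[, 2], "-")
  adj <- abs(dr) <= 1 & abs(dc) <= 1
  diag(adj) <- FALSE
  w <- sqrt((dr * spacing[["y"]])^2 + (dc * spacing[["x"]])^2)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w[edges]
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  d0 <- igraph::distances(g, v = main[1])[1, main]
  v1 <- main[which.max(d0)]
  d1 <- igraph::distances(g, v = v1)[1, main]
  v2 <- main[which.max(d1)]
  path <- igraph::shortest_paths(g, from = v1, to = v2)$vpath[[1]]
  pts[as.integer(path), , drop = FALSE]
}

#' Anterior surface of the ciliary body
#'
#' Extracts the maximal connected arc of the ciliary-body boundary that
#' faces the iris or the anterior chamber: a boundary vertex belongs to the
#' arc when the iris lies within 500 um and either is the nearest
#' non-ciliary, non-background tissue or the vertex directly faces
#' background (anterior chamber) above; the path to the iris must not pass
#' back through the ciliary body itself (which screens out the far-side
#' boundary).
#'
#' @param mask a valid, orientation-normalized [SegmentationMask-class].
#' @param reach_um how far the iris may be for a vertex to count as
#'   iris-facing (default 500 um).
#' @return List with `surface` (ordered open m x 2 `(row, col)` polyline),
#'   `iris_dist_px` and `iris_dist_um` (per-vertex distance to the iris
#'   boundary).
#' @export
ciliaryAnteriorSurface <- function(mask, reach_um = 500) {
  cbb <- regionBoundary(mask, "ciliary_body")
  cbb <- cbb[-nrow(cbb), , drop = FALSE]  # drop closing duplicate
  n <- nrow(cbb)
  iris_b <- regionBoundary(mask, "iris")
  cb <- .tissueComponent(mask, "ciliary_body")
  sp <- pixelSpacing(mask)
  lab <- maskLabels(mask)
  # nearest iris boundary vertex for every ciliary boundary vertex, then
  # refined to exact point-to-segment distance on the adjacent segments
  nI <- nrow(iris_b)
  d_px <- numeric(n); d_um <- numeric(n); nearest <- integer(n)
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    drm <- outer(cbb[s:e, 1], iris_b[, 1], "-")
    dcm <- outer(cbb[s:e, 2], iris_b[, 2], "-")
    um2 <- (drm * sp[["y"]])^2 + (dcm * sp[["x"]])^2
    nearest[s:e] <- max.col(-um2, ties.method = "first")
  }
  j1 <- pmax(nearest - 1L, 1L); j2 <- pmin(nearest + 1L, nI)
  d_um <- pmin(
    .segmentDistance(cbb, iris_b[j1, , drop = FALSE],
                     iris_b[nearest, , drop = FALSE], sp[["x"]], sp[["y"]]),
    .segmentDistance(cbb, iris_b[nearest, , drop = FALSE],
                     iris_b[j2, , drop = FALSE], sp[["x"]], sp[["y"]]))
  d_px <- pmin(
    .segmentDistance(cbb, iris_b[j1, , drop = FALSE],
                     iris_b[nearest, , drop = FALSE], 1, 1),
    .segmentDistance(cbb, iris_b[nearest, , drop = FALSE],
                     iris_b[j2, , drop = FALSE], 1, 1))
  # the path to the nearest iris point must not cross the ciliary interior
  # (screens out the far-side boundary; at apposition distances the iris is
  # trivially on the outward side, and midpoint rounding would be noise)
  midpts <- (cbb + iris_b[nearest, , drop = FALSE]) / 2
  mid_in_cb <- .samplePx(cb, midpts) & d_px > 3
  d_scl_px <- .samplePx(.tissueDistPx(mask, "sclera"), cbb)
  # faces background directly above (within 3 px)
  r0 <- floor(cbb[, 1] + 0.5) + 1L
  c0 <- pmin(pmax(floor(cbb[, 2] + 0.5) + 1L, 1L), ncol(lab))
  bg_above <- rep(FALSE, n)
  for (k in 1:3) {
    rk <- pmax(r0 - k, 1L)
    bg_above <- bg_above | lab[cbind(rk, c0)] == 0L
  }
  anterior <- d_um <= reach_um & (d_px < d_scl_px | bg_above) & !mid_in_cb
  if (!any(anterior))
    .ubmStop("ubm_surface_not_found",
             "no anterior ciliary surface facing the iris or chamber")
  # bridge isolated classification flickers before extracting the arc
  anterior <- .closeFlagGaps(anterior, tol = 8L)
  run <- .longestCircularRun(anterior)
  list(surface = cbb[run, , drop = FALSE],
       iris_dist_px = d_px[run], iris_dist_um = d_um[run])
}

# exact distance from points P to segments A->B (rows aligned), in the
# metric given by the per-axis weights (wx on columns, wy on rows)
.segmentDistance <- function(P, A, B, wx, wy) {
  vx <- (B[, 2] - A[, 2]) * wx; vy <- (B[, 1] - A[, 1]) * wy
  px <- (P[, 2] - A[, 2]) * wx; py <- (P[, 1] - A[, 1]) * wy
  L2 <- vx^2 + vy^2
  t <- ifelse(L2 > 0, pmax(0, pmin(1, (px * vx + py * vy) / L2)), 0)
  sqrt((px - t * vx)^2 + (py - t * vy)^2)
}

# fill FALSE runs of length <= tol that sit between TRUE runs (circular)
.closeFlagGaps <- function(flag, tol = 8L) {
  n <- length(flag)
  if (all(flag) || !any(flag)) return(flag)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (k == 1L || k == length(r$values)) next
    if (!r$values[k] && r$lengths[k] <= tol)
      flag[starts[k]:ends[k]] <- TRUE
  }
  # circular wrap: combined first+last FALSE run
  if (!r$values[1] && !r$values[length(r$values)] &&
      r$lengths[1] + r$lengths[length(r$values)] <= tol) {
    flag[starts[1]:ends[1]] <- TRUE
    flag[starts[length(r$values)]:n] <- TRUE
  }
  flag
}

# indices of the longest circular run of TRUE values, in order
.longestCircularRun <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(seq_len(n))
  ext <- c(flag, flag)
  best_len <- 0L; best_start <- 1L; cur <- 0L
  for (i in seq_len(2L * n)) {
    if (ext[i]) {
      cur <- cur + 1L
      if (cur > best_len && i - cur + 1L <= n) {
        best_len <- min(cur, n); best_start <- i - cur + 1L
      }
    } else cur <- 0L
  }
  ((best_start - 1L) + seq_len(best_len) - 1L) %% n + 1L
}

#' Anteriorly-located-ciliary-body (ALCB) feature group
#'
#' Measures the arc length of the anterior ciliary-body surface in contact
#' with the posterior iris (within `eps_contact_px` pixels, since
#' sub-resolution apposition cannot be resolved) and its ratio to the total
#' anterior-surface arc length. Arc lengths are computed on the
#' physically-scaled polyline.
#'
#' @param mask a valid, orientation-normalized [SegmentationMask-class].
#' @param eps_contact_px contact tolerance in pixels (default 2).
#' @return Named numeric `c(contact_len_um, anterior_len_um, contact_ratio)`.
#' @export
extractAlcbFeatures <- function(mask, eps_contact_px = 2) {
  surf <- ciliaryAnteriorSurface(mask)
  sp <- pixelSpacing(mask)
  pts <- surf$surface
  m <- nrow(pts)
  if (m < 2L)
    .ubmStop("ubm_surface_not_found", "anterior ciliary surface degenerate")
  seg <- sqrt((diff(pts[, 1]) * sp[["y"]])^2 + (diff(pts[, 2]) * sp[["x"]])^2)
  contact_v <- .closeFlagGaps(surf$iris_dist_px <= eps_contact_px, tol = 4L)
  contact_seg <- contact_v[-m] & contact_v[-1]
  anterior_len <- sum(seg)
  contact_len <- sum(seg[contact_seg])
  c(contact_len_um = contact_len, anterior_len_um = anterior_len,
    contact_ratio = if (anterior_len > 0) contact_len / anterior_len else 0)
}

#' Extract the full per-image feature row
#'
#' Orchestrates orientation normalization, spur localization and the three
#' feature groups (PB, TPI, ALCB) into a single one-row data frame with
#' provenance. Undefined sub-measurements are carried as `NA` markers; only
#' hard validation failures abort.
#'
#' @param mask a [SegmentationMask-class]; validated and
#'   orientation-normalized internally.
#' @param image_id identifier recorded in the row.
#' @param spur optional [SpurPoint-class] override; located automatically
#'   when `NULL`.
#' @return One-row `data.frame` with columns `image_id`, `it_spur500_um`,
#'   `it_spur750_um`, `it_root500_um`, `iris_curvature_um`,
#'   `root_insertion_um`, `contact_len_um`, `anterior_len_um`,
#'   `contact_ratio`, `spur_row`, `spur_col`, `flipped`, `mode`.
#' @export
extractFeatureRow <- function(mask, image_id = "image", spur = NULL) {
  .assertValid(mask)
  mask <- normalizeOrientation(mask)
  if (is.null(spur)) spur <- locateScleralSpur(mask)
  tpi <- extractTpiFeatures(mask, spur)
  pb <- extractPbFeatures(mask, spur)
  alcb <- tryCatch(extractAlcbFeatures(mask),
                   ubm_surface_not_found = function(e)
                     c(contact_len_um = NA_real_, anterior_len_um = NA_real_,
                       contact_ratio = NA_real_))
  pt <- spurLocation(spur)
  data.frame(image_id = image_id,
             it_spur500_um = tpi[["it_spur500_um"]],
             it_spur750_um = tpi[["it_spur750_um"]],
             it_root500_um = tpi[["it_root500_um"]],
             iris_curvature_um = pb[["iris_curvature_um"]],
             root_insertion_um = pb[["root_insertion_um"]],
             contact_len_um = alcb[["contact_len_um"]],
             anterior_len_um = alcb[["anterior_len_um"]],
             contact_ratio = alcb[["contact_ratio"]],
             spur_row = pt[["row"]], spur_col = pt[["col"]],
             flipped = isFlipped(mask), mode = acquisitionMode(mask),
             stringsAsFactors = FALSE)
}

#' Feature column names used by the mechanism classifiers
#' @return Character vector of the eight geometric feature columns.
#' @export
featureSchema <- function() {
  c("it_spur500_um", "it_spur750_um", "it_root500_um", "iris_curvature_um",
    "root_insertion_um", "contact_len_um", "anterior_len_um", "contact_ratio")
}
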