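# Shared fixtures and independent oracles for the test suite.
# Rendered masks are cached per (params-signature, seed) so repeated use
# across test files does not re-render.

.fixture_env <- new.env()

defaultRender <- function(seed = 1, ...) {
  key <- paste0("r_", seed, "_", paste(deparse(substitute(list(...))),
                                       collapse = ""))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- renderMask(anatomyParams(...), seed = seed)
  .fixture_env[[key]]
}

# translate every tissue of a mask by (dr, dc), background-filled
translateMask <- function(mask, dr, dc) {
  lab <- maskLabels(mask)
  H <- nrow(lab); W <- ncol(lab)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- lab[rs - dr, cs - dc]
  SegmentationMask(out, acquisitionMode(mask), pixelSpacing(mask),
                   isFlipped(mask))
}

# translate only one tissue class (used to break adjacency contracts)
shiftTissue <- function(mask, code, dr, dc) {
  lab <- maskLabels(mask)
  H <- nrow(lab); W <- ncol(lab)
  moved <- matrix(0L, H, W)
  bin <- lab == code
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  moved[rs, cs] <- bin[rs - dr, cs - dc] * code
  lab[bin] <- 0L
  lab[moved > 0] <- code
  SegmentationMask(lab, acquisitionMode(mask), pixelSpacing(mask),
                   isFlipped(mask))
}

mirrorMask <- function(mask) {
  lab <- maskLabels(mask)
  SegmentationMask(lab[, ncol(lab):1, drop = FALSE], acquisitionMode(mask),
                   pixelSpacing(mask), isFlipped(mask))
}

# hand-built uniform iris band with a circular-arc midline of known
# sagitta, plus a ciliary blob at the left (root) end; physical units
bandMask <- function(sagitta_um = 0, thickness_um = 350, W = 1024L, H = 655L) {
  sp <- spacingForMode("half_frame", W, H)
  lab <- matrix(0L, H, W)
  x <- (seq_len(W) - 1) * sp[["x"]]
  x0 <- 100 * sp[["x"]]; x1 <- 924 * sp[["x"]]
  L <- x1 - x0
  ymid <- 320 * sp[["y"]]
  dev <- function(u) {
    if (abs(sagitta_um) < 1e-9) return(rep(0, length(u)))
    rho <- L^2 / (8 * abs(sagitta_um)) + abs(sagitta_um) / 2
    sign(sagitta_um) * (sqrt(pmax(rho^2 - (u - L / 2)^2, 0)) -
                          (rho - abs(sagitta_um)))
  }
  inb <- x >= x0 & x <= x1
  mid <- ymid - dev(x[inb] - x0)
  top <- mid - thickness_um / 2; bot <- mid + thickness_um / 2
  cols <- which(inb)
  for (k in seq_along(cols)) {
    r0 <- max(ceiling(top[k] / sp[["y"]]), 0)
    r1 <- min(floor(bot[k] / sp[["y"]]), H - 1)
    if (r1 >= r0) lab[(r0 + 1):(r1 + 1), cols[k]] <- 1L
  }
  # ciliary blob adjacent below the band's left end
  rr <- floor(bot[1] / sp[["y"]]) + 1
  lab[(rr + 1):(rr + 12), 95:115] <- 3L
  SegmentationMask(lab, "half_frame")
}

# --- brute-force oracles ---------------------------------------------------

bfConfusion <- function(t, p) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(t)) {
    if (t[i] && p[i]) tp <- tp + 1L
    else if (!t[i] && p[i]) fp <- fp + 1L
    else if (t[i] && !p[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

bfAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

bfKappa <- function(a, b) {
  lv <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- 0
  for (l in lv) pe <- pe + mean(a == l) * mean(b == l)
  (po - pe) / (1 - pe)
}

bfChisq <- function(ca, na_, cb, nb) {
  obs <- matrix(c(ca, na_ - ca, cb, nb - cb), 2, byrow = TRUE)
  n <- sum(obs)
  exp_ <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - exp_)^2 / exp_)
}

bfMcc <- function(cc) {
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]; tn <- cc[["tn"]]
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# dense-sampling oracle for circle crossings: walk the contour at 0.01 px
# steps and report sign-change locations of the radial residual
bfCircleCrossings <- function(contour, center, radius_um, spacing) {
  out <- NULL
  for (i in seq_len(nrow(contour) - 1)) {
    a <- contour[i, ]; b <- contour[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / 0.01)))
    pts <- cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
    f <- sqrt(((pts[, 2] - center[2]) * spacing[["x"]])^2 +
              ((pts[, 1] - center[1]) * spacing[["y"]])^2) - radius_um
    sw <- which(f[-length(f)] * f[-1] < 0 | f[-length(f)] == 0)
    if (length(sw)) out <- rbind(out, pts[sw, , drop = FALSE])
  }
  out
}

# feature columns used in equivariance comparisons
featCols <- function() {
  c("it_spur500_um", "it_spur750_um", "it_root500_um", "iris_curvature_um",
    "root_insertion_um", "contact_len_um", "anterior_len_um", "contact_ratio")
}
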