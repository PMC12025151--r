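# Parametric single-angle anterior-segment phantom.
#
# The scene is laid out in physical micrometre coordinates (x rightward
# along columns, y downward along rows) with the angle recess on the left,
# then rasterized at the pitch of the requested acquisition mode:
#   - sclera: an ~800 um band whose inner boundary runs gently down-left of
#     the spur and climbs steeply (the corneoscleral wall) to its right;
#   - iris: a band whose posterior surface is a circular arc from root to
#     pupil with the requested sagitta, with a linear thickness profile and
#     a short taper into the root insertion;
#   - ciliary body: a wedge under the iris root whose anterior edge tracks
#     the posterior iris; apposition ("contact") is rendered as a ~1.2 px
#     gap - inside the 2 px contact tolerance of the feature extractor but
#     beyond 8-adjacency, so the adjacency-defined iris root stays at the
#     anatomical insertion. The root end itself slightly overlaps the
#     ciliary body to guarantee the insertion adjacency.
# Boundary jitter is added to the continuous curves before rasterization,
# so ground truth stays analytic (computed on the unjittered curves).

.SPUR_X_UM <- 1500
.SPUR_Y_UM <- 2800
.ROOT_DX_UM <- 60
.ROOT_DY_UM <- 25
.SCLERA_THICK_UM <- 800
.CB_TRACK_UM <- 1500   # extent of the ciliary anterior edge along the iris
.TAPER_UM <- 400       # iris thickness taper length at the root insertion

#' Anatomy parameters for the synthetic anterior-segment renderer
#'
#' @param mode acquisition mode (defines the pixel pitch).
#' @param width_px,height_px raster dimensions.
#' @param iris_thickness_root_um peripheral (root-side) iris thickness; the
#'   plateau value reached after the short insertion taper.
#' @param iris_thickness_pupil_um iris thickness at the pupil end; the
#'   profile is linear between the two.
#' @param bowing_sagitta_um signed sagitta of the posterior iris surface
#'   over its root-to-pupil chord; positive bows anteriorly (pupillary
#'   block configuration), negative posteriorly.
#' @param iris_length_um root-to-pupil chord length.
#' @param ciliary_contact_fraction fraction (0-1) of the tracked ciliary
#'   anterior edge in apposition with the posterior iris.
#' @param spur_offset_x_um,spur_offset_y_um translation of the whole angle
#'   complex, for equivariance experiments.
#' @param boundary_jitter_px amplitude (pixels) of the smooth boundary
#'   jitter.
#' @param orientation `"left"` or `"right"` (mirrored scene).
#' @return A validated list of class `ubm_anatomy_params`.
#' @export
anatomyParams <- function(mode = "half_frame", width_px = 1024L,
                          height_px = 655L,
                          iris_thickness_root_um = 450,
                          iris_thickness_pupil_um = 300,
                          bowing_sagitta_um = 150,
                          iris_length_um = 4000,
                          ciliary_contact_fraction = 0.5,
                          spur_offset_x_um = 0, spur_offset_y_um = 0,
                          boundary_jitter_px = 0.3,
                          orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode, ACQUISITION_MODES)
  p <- list(mode = mode, width_px = as.integer(width_px),
            height_px = as.integer(height_px),
            iris_thickness_root_um = iris_thickness_root_um,
            iris_thickness_pupil_um = iris_thickness_pupil_um,
            bowing_sagitta_um = bowing_sagitta_um,
            iris_length_um = iris_length_um,
            ciliary_contact_fraction = ciliary_contact_fraction,
            spur_offset_x_um = spur_offset_x_um,
            spur_offset_y_um = spur_offset_y_um,
            boundary_jitter_px = boundary_jitter_px,
            orientation = orientation)
  if (p$iris_thickness_root_um <= 0 || p$iris_thickness_pupil_um <= 0)
    .ubmStop("ubm_render_error", "iris thicknesses must be positive")
  if (p$ciliary_contact_fraction < 0 || p$ciliary_contact_fraction > 1)
    .ubmStop("ubm_render_error", "ciliary_contact_fraction must lie in [0, 1]")
  if (p$iris_length_um <= 2 * .TAPER_UM)
    .ubmStop("ubm_render_error", "iris_length_um too short")
  if (abs(p$bowing_sagitta_um) >= p$iris_length_um / 4)
    .ubmStop("ubm_render_error", "sagitta too large for the iris chord")
  class(p) <- "ubm_anatomy_params"
  p
}

# circular-arc sagitta profile over a chord of length L: deviation at
# position u in [0, L], signed like s
.arcDeviation <- function(u, L, s) {
  if (abs(s) < 1e-9) return(rep(0, length(u)))
  rho <- L^2 / (8 * abs(s)) + abs(s) / 2
  dev <- sqrt(pmax(rho^2 - (u - L / 2)^2, 0)) - (rho - abs(s))
  sign(s) * dev
}

# iris thickness profile over arc position u (taper + linear segment);
# a 20 um floor keeps the insertion at least two pixel rows thick so the
# root attachment survives rasterization
.thicknessProfile <- function(u, L, t_root, t_pupil) {
  t_plateau <- t_root + (t_pupil - t_root) * pmax(u - .TAPER_UM, 0) / (L - .TAPER_UM)
  pmax(pmin(u / .TAPER_UM, 1) * t_plateau, 20)
}

# continuous scene geometry (no jitter); all in um, left orientation
.sceneGeometry <- function(params) {
  xs <- .SPUR_X_UM + params$spur_offset_x_um
  ys <- .SPUR_Y_UM + params$spur_offset_y_um
  root <- c(x = xs + .ROOT_DX_UM, y = ys + .ROOT_DY_UM)
  L <- params$iris_length_um
  s <- params$bowing_sagitta_um
  list(
    spur = c(x = xs, y = ys), root = root, L = L, s = s,
    # inner scleral boundary
    y_in = function(x) {
      ifelse(x <= xs, ys + 0.15 * (xs - x),
             ys - pmin(2.75 * (x - xs), 1400))
    },
    posterior = function(u) root[["y"]] - .arcDeviation(u, L, s),
    thickness = function(u) .thicknessProfile(u, L,
                                              params$iris_thickness_root_um,
                                              params$iris_thickness_pupil_um),
    # gap between ciliary anterior edge and posterior iris along the
    # tracked extent; negative near the root = insertion overlap, then the
    # apposition gap g_c over the contact advance, then a standoff beyond
    # the contact tolerance at the raster's pitch yet within iris-facing
    # reach, shallow enough not to inflate the anterior arc length
    gap = function(u, g_c, standoff) {
      adv <- params$ciliary_contact_fraction * .CB_TRACK_UM
      g_in <- 1.6 * u - 25
      out <- g_c + (standoff - g_c) * pmin(pmax(u - adv, 0) / 50, 1)
      pmin(g_in, out)
    }
  )
}

# analytic circle-chord thickness on the continuous curves: distance
# between the crossings of the circle with the posterior and anterior
# surfaces (the same construction the raster measurement uses)
.gtThickness <- function(geom, center_xy, radius_um) {
  u <- seq(0, geom$L, by = 1)
  xs <- geom$root[["x"]] + u
  post <- cbind(xs, geom$posterior(u))
  ant <- cbind(xs, geom$posterior(u) - geom$thickness(u))
  crossOne <- function(curve) {
    f <- sqrt((curve[, 1] - center_xy[1])^2 + (curve[, 2] - center_xy[2])^2) -
      radius_um
    i <- which(f[-length(f)] * f[-1] < 0)
    if (!length(i)) return(NULL)
    i <- i[1]
    t <- f[i] / (f[i] - f[i + 1])
    curve[i, ] + t * (curve[i + 1, ] - curve[i, ])
  }
  p <- crossOne(post); a <- crossOne(ant)
  if (is.null(p) || is.null(a)) return(NA_real_)
  sqrt(sum((p - a)^2))
}

# smooth per-column jitter curve (unit-sd smoothed gaussian noise)
.jitterCurve <- function(n, amplitude_um) {
  if (amplitude_um <= 0) return(rep(0, n))
  raw <- stats::rnorm(n + 60)
  sm <- stats::filter(raw, rep(1 / 31, 31), sides = 2)
  sm <- sm[31:(30 + n)]
  sm[is.na(sm)] <- 0
  s <- stats::sd(sm)
  if (s == 0) return(rep(0, n))
  amplitude_um * as.numeric(sm) / s
}

#' Render a synthetic single-angle anterior-segment mask
#'
#' Deterministic for a fixed `(params, seed)` pair. Returns the label
#' raster together with the analytic ground truth of everything the
#' feature-extraction stage measures: spur and root locations, the three
#' circle-crossing thicknesses (computed on the continuous pre-raster
#' curves), the sagitta, the contact ratio, and the mechanism labels
#' implied by the generator's class conventions (pupillary block when the
#' sagitta exceeds 200 um, thick peripheral iris when the 750 um
#' spur-circle thickness exceeds 500 um, anterior ciliary body when the
#' contact fraction exceeds 0.4 - separability conventions of the
#' generator, not clinical cut-offs).
#'
#' @param params an [anatomyParams()] list.
#' @param seed integer seed for the boundary jitter.
#' @return List with `mask` (a [SegmentationMask-class]) and `truth`
#'   (list of ground-truth values).
#' @export
renderMask <- function(params, seed = 0L) {
  if (!inherits(params, "ubm_anatomy_params")) params <- do.call(anatomyParams, params)
  W <- params$width_px; H <- params$height_px
  sp <- spacingForMode(params$mode, W, H)
  sx <- sp[["x"]]; sy <- sp[["y"]]
  geom <- .sceneGeometry(params)
  g_c <- 1.2 * sy  # apposition gap: < 2 px contact tolerance, > adjacency
  standoff <- max(40, 3.5 * sy)  # non-contact gap, safely > 2 px
  xs <- geom$spur[["x"]]; ys <- geom$spur[["y"]]
  xr <- geom$root[["x"]]; yr <- geom$root[["y"]]
  L <- geom$L
  x <- (seq_len(W) - 1) * sx

  amp <- params$boundary_jitter_px * sy
  jit <- .withSeed(seed, list(
    sclera_in = .jitterCurve(W, amp), sclera_out = .jitterCurve(W, amp),
    posterior = .jitterCurve(W, amp), anterior = .jitterCurve(W, amp),
    cb_bottom = .jitterCurve(W, amp)
  ))

  y_in <- geom$y_in(x) + jit$sclera_in
  y_out <- y_in - .SCLERA_THICK_UM + jit$sclera_out - jit$sclera_in

  u <- x - xr
  # a short stub left of the root keeps the adjacency-defined insertion
  # centroid centred on the true root point
  iris_cols <- u >= -15 & u <= L
  uc <- pmax(u, 0)
  post <- rep(NA_real_, W); ant <- rep(NA_real_, W)
  post[iris_cols] <- geom$posterior(uc[iris_cols]) + jit$posterior[iris_cols]
  ant[iris_cols] <- post[iris_cols] - geom$thickness(uc[iris_cols]) +
    jit$anterior[iris_cols] - jit$posterior[iris_cols]
  ant <- pmin(ant, post)  # jitter must not invert the surfaces

  # ciliary wedge
  x_left <- xs - 600
  x_tip <- xr + .CB_TRACK_UM
  cb_cols <- x >= x_left & x <= x_tip
  cbtop <- rep(NA_real_, W)
  seg_scl <- cb_cols & x <= xs
  cbtop[seg_scl] <- y_in[seg_scl] - 5          # 1 px into the sclera
  seg_face <- cb_cols & x > xs & x < xr
  cbtop[seg_face] <- ys + (x[seg_face] - xs) / (xr - xs) * ((yr - 10) - ys)
  seg_track <- cb_cols & x >= xr
  ut <- x[seg_track] - xr
  post_tr <- geom$posterior(ut) + jit$posterior[seg_track]
  g_tr <- geom$gap(ut, g_c, standoff)
  top_tr <- post_tr + g_tr
  # apposition columns: pin the ciliary top exactly two pixel rows below
  # the iris bottom row - within the 2 px contact tolerance but never
  # 8-adjacent, even across sloped row transitions
  appose <- g_tr > 0 & g_tr <= g_c + 1e-9
  top_tr[appose] <- (floor(post_tr[appose] / sy) + 3) * sy
  cbtop[seg_track] <- top_tr
  h <- 1200 + (15 - 1200) * (x - x_left) / (x_tip - x_left)
  cbbot <- cbtop + pmax(h + jit$cb_bottom, 5)

  # degenerate-overlap guard: iris must stay clear of the sclera
  if (any(ant[iris_cols] <= y_in[iris_cols] + 2 * sy))
    .ubmStop("ubm_render_error",
             "iris overlaps the sclera for these parameters")
  if (max(cbbot[cb_cols]) > (H - 2) * sy || min(y_out) < sy)
    .ubmStop("ubm_render_error", "anatomy exceeds the image canvas")

  lab <- matrix(0L, H, W)
  fill <- function(lab, cols, ytop, ybot, code) {
    for (ci in which(cols)) {
      r0 <- ceiling(ytop[ci] / sy); r1 <- floor(ybot[ci] / sy)
      if (is.na(r0) || is.na(r1) || r1 < r0) next
      r0 <- max(r0, 0); r1 <- min(r1, H - 1)
      if (r1 >= r0) lab[(r0 + 1):(r1 + 1), ci] <- code
    }
    lab
  }
  lab <- fill(lab, cb_cols, cbtop, cbbot, TISSUE_CODES[["ciliary_body"]])
  lab <- fill(lab, rep(TRUE, W), y_out, y_in, TISSUE_CODES[["sclera"]])
  lab <- fill(lab, iris_cols, ant, post, TISSUE_CODES[["iris"]])

  flipped_scene <- params$orientation == "right"
  if (flipped_scene) lab <- lab[, W:1, drop = FALSE]

  it500 <- .gtThickness(geom, geom$spur, 500)
  it750 <- .gtThickness(geom, geom$spur, 750)
  itroot <- .gtThickness(geom, geom$root, 500)
  # spur/root ground truth is reported in the orientation-normalized
  # (left-opening) frame that all downstream measurements use; for
  # orientation = "right" the rendered raster is its mirror image
  truth <- list(
    spur = c(row = ys / sy, col = xs / sx),
    root = c(row = yr / sy, col = xr / sx),
    it_spur500_um = it500, it_spur750_um = it750, it_root500_um = itroot,
    sagitta_um = geom$s,
    contact_ratio = params$ciliary_contact_fraction,
    root_insertion_um = sqrt(.ROOT_DX_UM^2 + .ROOT_DY_UM^2),
    anterior_track_um = .CB_TRACK_UM,
    pb = geom$s > 200,
    tpi = !is.na(it750) && it750 > 500,
    alcb = params$ciliary_contact_fraction > 0.4,
    orientation = params$orientation,
    seed = seed
  )
  list(mask = SegmentationMask(lab, mode = params$mode), truth = truth)
}

# evaluate expr with a temporary RNG state
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic cohort
#'
#' @param n number of images.
#' @param class_weights named numeric mixture weights over
#'   [INTEGRATED_CLASSES]; image counts are allocated by largest remainder.
#' @param images_per_patient maximum images sharing one synthetic patient
#'   id (the clinical quadrant convention; default 4).
#' @param mode acquisition mode of the cohort.
#' @param boundary_jitter_px jitter amplitude passed to every render.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return A validated list of class `ubm_cohort_spec`.
#' @export
cohortSpec <- function(n, class_weights = NULL, images_per_patient = 4L,
                       mode = "half_frame", boundary_jitter_px = 0.3,
                       seed = 0L) {
  if (n < 1) .ubmStop("ubm_spec_error", "cohort size must be at least 1")
  if (is.null(class_weights))
    class_weights <- stats::setNames(rep(0.25, 4), INTEGRATED_CLASSES)
  if (!all(INTEGRATED_CLASSES %in% names(class_weights)))
    .ubmStop("ubm_spec_error", "class_weights must cover all four classes")
  class_weights <- class_weights[INTEGRATED_CLASSES]
  if (any(class_weights < 0) || abs(sum(class_weights) - 1) > 1e-8)
    .ubmStop("ubm_spec_error", "class_weights must be nonnegative and sum to 1")
  structure(list(n = as.integer(n), class_weights = class_weights,
                 images_per_patient = as.integer(images_per_patient),
                 mode = mode, boundary_jitter_px = boundary_jitter_px,
                 seed = as.integer(seed)),
            class = "ubm_cohort_spec")
}

# largest-remainder allocation of n among weights (deterministic)
.allocateCounts <- function(n, weights) {
  raw <- n * weights
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# class-conditional anatomy draw; margins around the generator label
# thresholds keep the four classes controllably separable
.drawClassParams <- function(cls, spec) {
  pb <- cls %in% c("pure_pb", "mm")
  subtype <- if (cls %in% c("pure_non_pb", "mm"))
    sample(c("tpi", "alcb", "both"), 1) else "none"
  tpi <- subtype %in% c("tpi", "both")
  alcb <- subtype %in% c("alcb", "both")
  t_root <- if (tpi) stats::runif(1, 560, 650) else stats::runif(1, 300, 450)
  anatomyParams(
    mode = spec$mode,
    iris_thickness_root_um = t_root,
    iris_thickness_pupil_um = min(stats::runif(1, 250, 350), 0.9 * t_root),
    bowing_sagitta_um = if (pb) stats::runif(1, 250, 400)
                        else stats::runif(1, -100, 150),
    iris_length_um = stats::runif(1, 3800, 4600),
    ciliary_contact_fraction = if (alcb) stats::runif(1, 0.55, 0.95)
                               else stats::runif(1, 0.05, 0.30),
    boundary_jitter_px = spec$boundary_jitter_px,
    orientation = sample(c("left", "right"), 1)
  )
}

#' Sample a patient-grouped synthetic cohort
#'
#' Draws per-image anatomy parameters from class-conditional ranges,
#' renders every mask, and groups consecutive images of a class into
#' synthetic patients of up to `images_per_patient` images (no patient
#' spans two classes). Fully reproducible from the master seed.
#'
#' @param spec a [cohortSpec()].
#' @return List with `masks` (list of [SegmentationMask-class]), `truth`
#'   (list of per-image ground-truth lists) and `labels` (data frame with
#'   `image_id`, `patient_id`, `class`, `pb`, `tpi`, `alcb`, `seed`).
#' @export
sampleCohort <- function(spec) {
  counts <- .allocateCounts(spec$n, spec$class_weights)
  classes <- rep(INTEGRATED_CLASSES, counts)
  params <- .withSeed(spec$seed,
                      lapply(classes, .drawClassParams, spec = spec))
  masks <- vector("list", spec$n)
  truth <- vector("list", spec$n)
  image_seeds <- (as.numeric(spec$seed) * 1009 + seq_len(spec$n)) %%
    .Machine$integer.max
  for (i in seq_len(spec$n)) {
    r <- renderMask(params[[i]], seed = as.integer(image_seeds[i]))
    masks[[i]] <- r$mask
    truth[[i]] <- r$truth
  }
  patient_id <- character(spec$n)
  pid <- 0L
  for (cls in INTEGRATED_CLASSES) {
    idx <- which(classes == cls)
    if (!length(idx)) next
    grp <- ceiling(seq_along(idx) / spec$images_per_patient)
    patient_id[idx] <- sprintf("P%04d", pid + grp)
    pid <- pid + max(grp)
  }
  labels <- data.frame(
    image_id = sprintf("img%04d", seq_len(spec$n)),
    patient_id = patient_id,
    class = classes,
    pb = vapply(truth, `[[`, logical(1), "pb"),
    tpi = vapply(truth, `[[`, logical(1), "tpi"),
    alcb = vapply(truth, `[[`, logical(1), "alcb"),
    seed = as.integer(image_seeds),
    stringsAsFactors = FALSE
  )
  list(masks = masks, truth = truth, labels = labels)
}
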