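#' Default tunable parameters of the synthetic field generator
#'
#' Central registry of the staining-physics constants the generator assumes.
#' Values can be overridden through the `pars` argument of [field_spec()].
#'
#' \describe{
#'   \item{gain}{grey-levels per arbitrary unit (AU) of fluorescence; the
#'     calibration that links rendered FITC brightness to the AU scale used
#'     for grading (default 100: a 100 AU cell has mean FITC 10000 on the
#'     16-bit scale).}
#'   \item{background_frac}{uniform background level as a fraction of the
#'     16-bit dynamic range (default 0.02).}
#'   \item{read_noise_frac}{Gaussian read-noise sigma as a fraction of the
#'     dynamic range (default 0.01); Poisson shot noise is applied on top of
#'     the rendered grey values.}
#'   \item{dapi_level}{mean DAPI grey value inside nuclei (default 15000).}
#'   \item{lobe_dist, lobe_a, lobe_b}{nuclear lobe geometry: radial offset of
#'     lobe centres and ellipse semi-axes, pixels (defaults 7.5, 9.5, 7;
#'     about a 22 px cell radius at 40x magnification scale).}
#'   \item{r_rim, r_cyto}{perinuclear rim and cytoplasm zone outer radii in
#'     pixels measured from the nucleus boundary (defaults 3 and 12).}
#'   \item{rim_frac_cyto}{relative rim brightness of a cytoplasmic pattern
#'     (default 0.35; keeps rim/cytoplasm ratio well below 1).}
#'   \item{cyto_frac_nuclear}{relative cytoplasm brightness of a
#'     nuclear/perinuclear pattern (default 0.08; rim/cytoplasm ratio well
#'     above 1).}
#'   \item{min_sep, margin}{minimum centre-to-centre distance between placed
#'     cells and minimum distance from the image border, pixels.}
#'   \item{artifact_px}{edge length of a planted saturated artifact block.}
#' }
#'
#' @return named list of defaults.
#' @export
generator_defaults <- function() {
  list(gain = 100, background_frac = 0.02, read_noise_frac = 0.01,
       dapi_level = 15000, lobe_dist = 7.5, lobe_a = 9.5, lobe_b = 7,
       r_rim = 3, r_cyto = 12, rim_frac_cyto = 0.35, cyto_frac_nuclear = 0.08,
       min_sep = 64, margin = 34, artifact_px = 32, retry_budget = 200L,
       agg_members = 5L, agg_sep = 28, agg_bend = 0.7, agg_bridge_r = 13)
}

.patterns <- c("cytoplasmic", "nuclear", "atypical", "negative")
.fixations <- c("ethN", "formN")
.grades <- c("-", "+/-", "+", "++", "+++", "++++")

#' Specification of one synthetic field of view
#'
#' @param n_cells number of single neutrophils to place (>= 0).
#' @param pattern staining pattern: one of `"cytoplasmic"`, `"nuclear"`,
#'   `"atypical"`, `"negative"`. Under formalin fixation (`"formN"`) a
#'   `"nuclear"` request is rendered as cytoplasmic: formalin immobilizes
#'   MPO-type antigens, so the perinuclear relocation seen on ethanol-fixed
#'   cells does not occur. The ground truth records both the requested and
#'   the rendered pattern.
#' @param fixation `"ethN"` or `"formN"`.
#' @param intensity_au target mean cell FITC fluorescence in arbitrary units.
#' @param blur_sigma Gaussian optical blur in pixels (0 = perfectly focused).
#' @param n_aggregates number of fused multi-cell clumps to plant.
#' @param n_artifacts number of saturated artifact blocks to plant.
#' @param image_shape integer length-2, rows x columns (default 1024 x 1024).
#' @param seed integer master seed; fully determines the output.
#' @param pars named list overriding [generator_defaults()].
#' @return object of class `anca_field_spec`.
#' @export
field_spec <- function(n_cells = 6L, pattern = "negative", fixation = "ethN",
                       intensity_au = 0, blur_sigma = 1, n_aggregates = 0L,
                       n_artifacts = 0L, image_shape = c(1024L, 1024L),
                       seed = 1L, pars = list()) {
  pattern <- match.arg(pattern, .patterns)
  fixation <- match.arg(fixation, .fixations)
  stopifnot(n_cells >= 0, blur_sigma >= 0, intensity_au >= 0,
            n_aggregates >= 0, n_artifacts >= 0, length(image_shape) == 2L)
  structure(list(n_cells = as.integer(n_cells), pattern = pattern,
                 fixation = fixation, intensity_au = intensity_au,
                 blur_sigma = blur_sigma, n_aggregates = as.integer(n_aggregates),
                 n_artifacts = as.integer(n_artifacts),
                 image_shape = as.integer(image_shape), seed = as.integer(seed),
                 pars = utils::modifyList(generator_defaults(), pars)),
            class = "anca_field_spec")
}

# union-of-ellipses nucleus mask evaluated on its bounding box
.render_lobes <- function(center, lobes, shape) {
  ext <- max(sqrt(lobes$dr^2 + lobes$dc^2) + pmax(lobes$a, lobes$b)) + 2
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(shape[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(shape[2], ceiling(center[2] + ext))
  rr <- r0:r1; cc <- c0:c1
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  m <- matrix(FALSE, length(rr), length(cc))
  for (k in seq_len(nrow(lobes))) {
    cy <- center[1] + lobes$dr[k]; cx <- center[2] + lobes$dc[k]
    ct <- cos(lobes$theta[k]); st <- sin(lobes$theta[k])
    X <- (R - cy) * ct + (C - cx) * st
    Y <- -(R - cy) * st + (C - cx) * ct
    m <- m | (X * X / lobes$a[k]^2 + Y * Y / lobes$b[k]^2 <= 1)
  }
  list(mask = m, r0 = r0, c0 = c0)
}

# lobe layout for one cell: n lobes on a ring, long axis radial, jittered;
# bilobed nuclei sit closer together (opposed lobes would otherwise pinch
# deeply enough for the watershed to cut them apart)
.cell_lobes <- function(n_lobes, p) {
  phi0 <- stats::runif(1, 0, 2 * pi)
  ang <- phi0 + 2 * pi * (seq_len(n_lobes) - 1) / n_lobes +
    stats::rnorm(n_lobes, 0, 0.12)
  d <- p$lobe_dist * (if (n_lobes == 2L) 0.65 else 1) *
    stats::runif(n_lobes, 0.9, 1.1)
  data.frame(dr = d * sin(ang), dc = d * cos(ang),
             a = p$lobe_a * stats::runif(n_lobes, 0.9, 1.1),
             b = p$lobe_b * stats::runif(n_lobes, 0.9, 1.1),
             theta = ang + stats::rnorm(n_lobes, 0, 0.15))
}

# rejection placement of points with pairwise and border constraints;
# `existing` points keep their own (larger) exclusion radius `existing_sep`
.place <- function(n, shape, margin, min_sep, existing, existing_sep, budget) {
  n_ex <- nrow(existing)
  pts <- existing
  sep <- rep(existing_sep, n_ex)
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(budget)) {
      cand <- c(stats::runif(1, margin, shape[1] - margin),
                stats::runif(1, margin, shape[2] - margin))
      if (nrow(pts) == 0L ||
          all(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >=
                pmax(sep, min_sep))) {
        pts <- rbind(pts, cand); sep <- c(sep, min_sep); ok <- TRUE; break
      }
    }
    if (ok) placed <- placed + 1L
  }
  list(points = pts, placed = placed, n_existing = n_ex)
}

# distance-band zones around one nucleus mask (bbox-local, via EDT)
.nucleus_bands <- function(mask, r0, c0, shape, r_rim, r_cyto) {
  pad <- ceiling(r_cyto) + 2L
  pr0 <- max(1L, r0 - pad); pc0 <- max(1L, c0 - pad)
  pr1 <- min(shape[1], r0 + nrow(mask) - 1L + pad)
  pc1 <- min(shape[2], c0 + ncol(mask) - 1L + pad)
  big <- matrix(TRUE, pr1 - pr0 + 1L, pc1 - pc0 + 1L)
  big[(r0 - pr0 + 1L):(r0 - pr0 + nrow(mask)),
      (c0 - pc0 + 1L):(c0 - pc0 + ncol(mask))] <- !mask
  dm <- as.matrix(EBImage::distmap(EBImage::Image(big * 1)))
  nuc <- !big
  rim <- dm > 0 & dm <= r_rim
  cyto <- dm > r_rim & dm <= r_cyto
  to_idx <- function(m) {
    w <- which(m, arr.ind = TRUE)
    (w[, 2] + pc0 - 2L) * shape[1] + (w[, 1] + pr0 - 1L)
  }
  list(nucleus = to_idx(nuc), rim = to_idx(rim), cyto = to_idx(cyto))
}

#' Generate one synthetic two-channel neutrophil field
#'
#' Renders lobed DAPI nuclei plus optional fused aggregates, paints the FITC
#' channel according to the requested staining pattern, applies Gaussian
#' optical blur and shot + read noise (Poisson shot noise in its Gaussian
#' regime plus Gaussian read noise), and returns the field together with its
#' ground truth. Output is fully determined by the seed.
#'
#' FITC pattern geometry (zone radii from [generator_defaults()]):
#' cytoplasmic patterns carry granular signal in the cytoplasm zone with a
#' dim perinuclear rim (rim/cytoplasm mean ratio < 1); nuclear/perinuclear
#' patterns cover nucleus and rim with faint cytoplasm (ratio >> 1); atypical
#' patterns are flat across the whole cell, violating both dominance rules;
#' negative cells receive background only. Cell templates are scaled so that
#' the noiseless mean FITC over the whole cell equals `intensity_au * gain`.
#'
#' @param spec an `anca_field_spec` from [field_spec()].
#' @param keep_clean if `TRUE`, the noiseless pre-blur renders are returned
#'   in `truth$clean` (used by calibration and tests).
#' @return list with `field` (an `anca_field`) and `truth` (class
#'   `anca_truth`): per-cell centres, lobe counts, rendered and requested
#'   patterns, aggregate flags, per-cell AU, nucleus/rim/cytoplasm pixel
#'   index sets, planted artifacts and any placement shortfall.
#' @export
generate_field <- function(spec, keep_clean = FALSE) {
  stopifnot(inherits(spec, "anca_field_spec"))
  p <- spec$pars
  shape <- spec$image_shape
  rendered_pattern <- spec$pattern
  if (spec$fixation == "formN" && spec$pattern == "nuclear")
    rendered_pattern <- "cytoplasmic"   # antigen immobilized by formalin

  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4L)  # placement/geometry, speckle, noise DAPI, noise FITC

  bg <- p$background_frac * 65535
  read_sd <- p$read_noise_frac * 65535

  # --- placement ---------------------------------------------------------
  set.seed(sub[1])
  agg_margin <- p$margin + 72
  res_a <- .place(spec$n_aggregates, shape, agg_margin, p$min_sep + 120,
                  matrix(numeric(0), 0, 2), p$min_sep + 120, p$retry_budget)
  res_c <- .place(spec$n_cells, shape, p$margin, p$min_sep,
                  res_a$points, p$min_sep + 72, p$retry_budget)
  agg_centers <- res_a$points
  centers <- if (res_c$placed > 0)
    res_c$points[nrow(agg_centers) + seq_len(res_c$placed), , drop = FALSE]
  else matrix(numeric(0), 0, 2)
  shortfall <- (spec$n_cells - res_c$placed) + (spec$n_aggregates - res_a$placed)

  # geometry + per-cell brightness, drawn in placement stream for determinism
  units <- list()  # each: centre, lobes, is_aggregate, clump id
  clump <- 0L
  for (k in seq_len(nrow(agg_centers))) {
    clump <- clump + 1L
    # bent chain of cells fused by confluent chromatin bridges: one
    # connected object with a smooth distance map (no deep saddles, so the
    # lobe-preserving watershed keeps it whole) and a strongly non-convex
    # outline that the convexity filter removes (solidity ~0.70)
    n_mem <- p$agg_members
    sep <- p$agg_sep
    ang <- stats::runif(1, 0, 2 * pi)
    pos <- agg_centers[k, ]
    for (m in seq_len(n_mem)) {
      units[[length(units) + 1L]] <- list(center = pos,
                                          lobes = .cell_lobes(3L, p),
                                          aggregate = TRUE, clump = clump)
      pos <- pos + sep * c(sin(ang), cos(ang))
      ang <- ang + p$agg_bend + stats::rnorm(1, 0, 0.1)
    }
  }
  for (k in seq_len(nrow(centers))) {
    nl <- sample(2:4, 1, prob = c(0.2, 0.6, 0.2))
    units[[length(units) + 1L]] <- list(center = centers[k, ],
                                        lobes = .cell_lobes(nl, p),
                                        aggregate = FALSE, clump = NA_integer_)
  }
  n_units <- length(units)
  dapi_b <- stats::runif(max(n_units, 1), 0.85, 1.15)
  au_cell <- spec$intensity_au * stats::runif(max(n_units, 1), 0.8, 1.2)

  # --- speckle (granular stain texture) -----------------------------------
  # white multiplicative gamma speckle, mean 1; spatial correlation of the
  # rendered granules is set by the optical blur applied downstream
  set.seed(sub[2])
  spk <- matrix(stats::rgamma(prod(shape), shape = 2, rate = 2),
                shape[1], shape[2])

  # --- render -------------------------------------------------------------
  clean_d <- matrix(bg, shape[1], shape[2])
  clean_f <- matrix(bg, shape[1], shape[2])
  cells <- vector("list", n_units)
  masks <- vector("list", n_units)
  rects <- matrix(integer(0), 0, 4)   # dirty rectangles for localized blur
  for (k in seq_len(n_units)) {
    u <- units[[k]]
    rl <- .render_lobes(u$center, u$lobes, shape)
    ex <- ceiling(p$r_cyto) + 2L
    rects <- rbind(rects, c(rl$r0 - ex, rl$r0 + nrow(rl$mask) - 1L + ex,
                            rl$c0 - ex, rl$c0 + ncol(rl$mask) - 1L + ex))
    bands <- .nucleus_bands(rl$mask, rl$r0, rl$c0, shape, p$r_rim, p$r_cyto)
    nuc <- bands$nucleus; rim <- bands$rim; cyt <- bands$cyto
    clean_d[nuc] <- bg + p$dapi_level * dapi_b[k] * (1 + 0.1 * (spk[nuc] - 1))
    if (rendered_pattern != "negative" && au_cell[k] > 0) {
      w_n <- w_r <- w_c <- NULL
      if (rendered_pattern == "cytoplasmic") {
        w_n <- rep(0.02, length(nuc))
        w_r <- p$rim_frac_cyto * spk[rim]
        w_c <- spk[cyt]
      } else if (rendered_pattern == "nuclear") {
        w_n <- 1 + 0.15 * (spk[nuc] - 1)
        w_r <- 1 + 0.15 * (spk[rim] - 1)
        w_c <- rep(p$cyto_frac_nuclear, length(cyt))
      } else {  # atypical: flat positive across the whole cell
        w_n <- 1 + 0.1 * (spk[nuc] - 1)
        w_r <- 1 + 0.1 * (spk[rim] - 1)
        w_c <- 1 + 0.1 * (spk[cyt] - 1)
      }
      s <- au_cell[k] * p$gain / mean(c(w_n, w_r, w_c))
      clean_f[nuc] <- clean_f[nuc] + s * w_n
      clean_f[rim] <- clean_f[rim] + s * w_r
      clean_f[cyt] <- clean_f[cyt] + s * w_c
    }
    cells[[k]] <- data.frame(cell = k, row = u$center[1], col = u$center[2],
                             n_lobes = nrow(u$lobes),
                             pattern = rendered_pattern,
                             requested_pattern = spec$pattern,
                             is_aggregate = u$aggregate, clump = u$clump,
                             area_px = length(nuc), au = au_cell[k])
    masks[[k]] <- list(nucleus = nuc, rim = rim, cyto = cyt)
  }
  # confluent chromatin bridges along each clump's chain (DAPI only)
  if (clump > 0L) {
    for (cl in seq_len(clump)) {
      mem <- which(vapply(units, function(u)
        isTRUE(!is.na(u$clump) && u$clump == cl), logical(1)))
      for (m in seq_along(mem)[-1]) {
        a <- units[[mem[m - 1L]]]$center
        b <- units[[mem[m]]]$center
        lvl <- p$dapi_level * dapi_b[mem[1L]]
        br <- p$agg_bridge_r
        for (t in seq(0, 1, length.out = 10)) {
          ctr <- a + t * (b - a)
          r0 <- max(1L, floor(ctr[1] - br)); r1 <- min(shape[1], ceiling(ctr[1] + br))
          c0 <- max(1L, floor(ctr[2] - br)); c1 <- min(shape[2], ceiling(ctr[2] + br))
          if (r1 < r0 || c1 < c0) next
          RR <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
          CC <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
          disc <- (RR - ctr[1])^2 + (CC - ctr[2])^2 <= br^2
          blk <- clean_d[r0:r1, c0:c1]
          val <- bg + lvl * (1 + 0.1 * (spk[r0:r1, c0:c1] - 1))
          blk[disc] <- pmax(blk[disc], val[disc])
          clean_d[r0:r1, c0:c1] <- blk
        }
      }
    }
  }

  cells <- if (n_units > 0) do.call(rbind, cells) else
    data.frame(cell = integer(), row = numeric(), col = numeric(),
               n_lobes = integer(), pattern = character(),
               requested_pattern = character(), is_aggregate = logical(),
               clump = integer(), area_px = integer(), au = numeric())

  # --- artifacts: saturated blocks (rendered above range, clamp to 65535) --
  artifacts <- data.frame(row = integer(), col = integer(), size = integer())
  if (spec$n_artifacts > 0) {
    a <- p$artifact_px
    for (k in seq_len(spec$n_artifacts)) {
      r0 <- sample.int(shape[1] - a + 1L, 1)
      c0 <- sample.int(shape[2] - a + 1L, 1)
      clean_d[r0:(r0 + a - 1L), c0:(c0 + a - 1L)] <- 3 * 65535
      clean_f[r0:(r0 + a - 1L), c0:(c0 + a - 1L)] <- 3 * 65535
      artifacts <- rbind(artifacts, data.frame(row = r0, col = c0, size = a))
      rects <- rbind(rects, c(r0, r0 + a - 1L, c0, c0 + a - 1L))
    }
  }

  # --- optics + noise ------------------------------------------------------
  # blur only the content rectangles: the rest of the scene is constant
  # background, which Gaussian filtering leaves unchanged
  bd <- .blur_rects(clean_d, spec$blur_sigma, rects)
  bf <- .blur_rects(clean_f, spec$blur_sigma, rects)
  # shot + read noise: Poisson shot noise in its Gaussian regime (the
  # rendered grey values are >> 100 everywhere, where Normal(m, sqrt(m)) is
  # indistinguishable from Poisson(m)) combined with Gaussian read noise
  noisy <- function(m, s) {
    set.seed(s)
    v <- m + stats::rnorm(length(m)) * sqrt(pmax(m, 0) + read_sd^2)
    matrix(pmin(pmax(round(v), 0), 65535), nrow(m), ncol(m))
  }
  dapi <- noisy(bd, sub[3])
  fitc <- noisy(bf, sub[4])

  truth <- structure(list(cells = cells, masks = masks, artifacts = artifacts,
                          placement_shortfall = shortfall,
                          sample_pattern = rendered_pattern,
                          requested_pattern = spec$pattern,
                          spec = spec),
                     class = "anca_truth")
  if (keep_clean) truth$clean <- list(dapi = clean_d, fitc = clean_f)
  field <- field_image(dapi, fitc,
                       metadata = list(seed = spec$seed, fixation = spec$fixation,
                                       pattern = rendered_pattern))
  list(field = field, truth = truth)
}

#' @export
print.anca_truth <- function(x, ...) {
  cat(sprintf("<anca_truth> %d cell(s), %d aggregate member(s), %d artifact(s), shortfall %d\n",
              sum(!x$cells$is_aggregate), sum(x$cells$is_aggregate),
              nrow(x$artifacts), x$placement_shortfall))
  invisible(x)
}

# AU band centres per grade and fixation; positivity edge anchored at
# 40 AU (ethN) / 30 AU (formN)
.grade_au_centers <- function(fixation) {
  if (fixation == "ethN")
    c("-" = 5, "+/-" = 30, "+" = 60, "++" = 100, "+++" = 140, "++++" = 180)
  else
    c("-" = 4, "+/-" = 22, "+" = 50, "++" = 90, "+++" = 130, "++++" = 170)
}

#' Generate a five-field synthetic sample
#'
#' A sample is imaged as five fields sharing pattern and fixation; cell
#' counts are jittered per field so that the sample pools at least
#' `min_total_cells` (default 20) single cells.
#'
#' @param pattern,fixation as in [field_spec()].
#' @param grade target ordinal intensity grade (`"-"` .. `"++++"`); sets the
#'   sample AU at the centre of the corresponding grade band with a ±10%
#'   sample-level jitter.
#' @param seed master seed for the sample.
#' @param n_fields number of fields (default 5).
#' @param image_shape,pars passed to [field_spec()].
#' @param min_total_cells minimum pooled single-cell count.
#' @param cells_per_field range to draw per-field cell counts from.
#' @return list of `n_fields` elements, each `list(field, truth)`, with
#'   attributes `pattern`, `grade`, `fixation`, `au` (sample target AU).
#' @export
generate_sample <- function(pattern, grade = "++", fixation = "ethN", seed = 1L,
                            n_fields = 5L, image_shape = c(1024L, 1024L),
                            min_total_cells = 20L, cells_per_field = 4:7,
                            pars = list()) {
  pattern <- match.arg(pattern, .patterns)
  fixation <- match.arg(fixation, .fixations)
  grade <- match.arg(grade, .grades)
  set.seed(seed)
  field_seeds <- sample.int(.Machine$integer.max - 1L, n_fields)
  au <- .grade_au_centers(fixation)[[grade]] * stats::runif(1, 0.9, 1.1)
  counts <- sample(cells_per_field, n_fields, replace = TRUE)
  while (sum(counts) < min_total_cells)
    counts[sample.int(n_fields, 1)] <- counts[sample.int(n_fields, 1)] + 1L
  au_jit <- stats::runif(n_fields, 0.97, 1.03)
  out <- lapply(seq_len(n_fields), function(i) {
    generate_field(field_spec(n_cells = counts[i], pattern = pattern,
                              fixation = fixation,
                              intensity_au = au * au_jit[i],
                              image_shape = image_shape,
                              seed = field_seeds[i], pars = pars))
  })
  attr(out, "pattern") <- pattern
  attr(out, "grade") <- grade
  attr(out, "fixation") <- fixation
  attr(out, "au") <- au
  out
}

#' Generate a labelled synthetic cohort specification
#'
#' Emulates a training-set design: `n_positive` ANCA-positive samples drawn
#' over patterns by `positive_mix` (default 5/7 cytoplasmic, 2/7
#' nuclear-type, mirroring a 50 PR3 / 20 MPO specificity split at n = 70)
#' with grades cycled over `grades`, plus `n_negative` negative samples.
#' Field rendering is deferred: each row carries the per-sample seed, so
#' samples are realized on demand with [generate_sample()].
#'
#' @param n_positive,n_negative sample counts (>= 0).
#' @param fixation substrate profile for the whole cohort.
#' @param seed master seed; per-sample seeds derive from it.
#' @param positive_mix named fractions over patterns for positive samples.
#' @param grades grades cycled across positive samples.
#' @return data.frame of class `anca_cohort`: `sample_id`, `label`
#'   (positive/negative), `pattern` (requested), `grade`, `fixation`, `seed`.
#' @export
generate_cohort <- function(n_positive, n_negative, fixation = "ethN",
                            seed = 1L,
                            positive_mix = c(cytoplasmic = 5 / 7, nuclear = 2 / 7),
                            grades = c("+", "++", "+++", "++++")) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  fixation <- match.arg(fixation, .fixations)
  n_by <- round(positive_mix * n_positive)
  # largest-share residual correction so counts sum exactly to n_positive
  while (sum(n_by) > n_positive) n_by[which.max(n_by)] <- n_by[which.max(n_by)] - 1L
  while (sum(n_by) < n_positive) n_by[which.max(positive_mix)] <- n_by[which.max(positive_mix)] + 1L
  pat <- rep(names(n_by), n_by)
  grd <- unlist(lapply(n_by, function(n) rep_len(grades, n)), use.names = FALSE)
  n <- n_positive + n_negative
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1))[seq_len(n)]
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    label = c(rep("positive", n_positive), rep("negative", n_negative)),
    pattern = c(pat, rep("negative", n_negative)),
    grade = c(grd, rep("-", n_negative)),
    fixation = fixation, seed = seeds,
    stringsAsFactors = FALSE)
  class(df) <- c("anca_cohort", "data.frame")
  df
}

#' Write a synthetic field to disk as TIFF plus ground-truth sidecar
#'
#' The image is stored as a 2-page 16-bit grey TIFF with lossless deflate
#' compression (page 0 = DAPI, page 1 = FITC); the ground truth and the
#' generating specification go to a JSON sidecar `<stem>.truth.json`
#' (per-cell records, artifacts and shortfall; pixel index sets are omitted
#' from the sidecar and reconstructed by re-running the generator with the
#' stored spec when needed). Arrays round-trip exactly through
#' [read_field()].
#'
#' @param field an `anca_field`.
#' @param truth the matching `anca_truth`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(field, truth, path) {
  stopifnot(inherits(field, "anca_field"), inherits(truth, "anca_truth"))
  ok <- try(tiff::writeTIFF(list(field$dapi / 65535, field$fitc / 65535),
                            path, bits.per.sample = 16L,
                            compression = "deflate"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF to ", path, ": ", attr(ok, "condition")$message)
  spec <- truth$spec
  sidecar <- list(
    spec = list(n_cells = spec$n_cells, pattern = spec$pattern,
                fixation = spec$fixation, intensity_au = spec$intensity_au,
                blur_sigma = spec$blur_sigma, n_aggregates = spec$n_aggregates,
                n_artifacts = spec$n_artifacts, image_shape = spec$image_shape,
                seed = spec$seed),
    seed = spec$seed,
    sample_pattern = truth$sample_pattern,
    requested_pattern = truth$requested_pattern,
    placement_shortfall = truth$placement_shortfall,
    cells = truth$cells,
    artifacts = truth$artifacts)
  jsonlite::write_json(sidecar,
                       paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                              ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
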