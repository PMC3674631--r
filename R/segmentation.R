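#' Histogram-based nucleus thresholding of the DAPI channel
#'
#' Gaussian pre-smoothing (sigma 1 px) followed by Otsu's histogram
#' threshold, hole filling, and removal of objects below `min_area`. A guard
#' against blank scenes requires the Otsu threshold to clear the image
#' median by five robust standard deviations (MAD); a field with no nuclei
#' therefore yields an empty mask rather than a noise split.
#'
#' @param dapi numeric matrix (DAPI channel, 16-bit scale).
#' @param sigma pre-smoothing sigma in pixels.
#' @param min_area minimum object area in pixels (default 120).
#' @return logical matrix, `TRUE` on nucleus pixels.
#' @export
threshold_nuclei <- function(dapi, sigma = 1, min_area = 120L) {
  stopifnot(is.matrix(dapi))
  empty <- matrix(FALSE, nrow(dapi), ncol(dapi))
  if (max(dapi) <= min(dapi)) return(empty)
  x <- dapi / 65535
  sm <- .sep_gauss(x, sigma)
  th <- EBImage::otsu(EBImage::Image(sm), range = range(sm), levels = 256L)
  # blank-scene guard on a pixel subsample (robust location/scale)
  sub <- sm[seq(1L, length(sm), by = 7L)]
  if (th <= stats::median(sub) + 5 * stats::mad(sub)) return(empty)
  mask <- sm > th
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = nlab)
    if (any(areas < min_area)) {
      small <- c(FALSE, areas < min_area)   # index by label + 1
      mask[small[lab + 1L]] <- FALSE
    }
  }
  mask
}

#' Split touching nuclei by watershed on the distance transform
#'
#' Runs a watershed on the Euclidean distance transform of the binary
#' nucleus mask. Shallow local maxima of the distance map — the signature of
#' the lobes of a single neutrophil nucleus — are merged by the depth
#' criterion `h` (a candidate object is only kept as separate if its
#' distance-map peak rises at least `h` px above the point of contact with
#' its neighbour), so lobed nuclei stay single objects while genuinely
#' touching nuclei are split.
#'
#' @param mask logical matrix from [threshold_nuclei()].
#' @param h merge depth in pixels (default 2).
#' @return integer label matrix (`LabelImage`): 0 = background, objects
#'   numbered consecutively from 1.
#' @export
split_touching <- function(mask, h = 2) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = h, ext = 1)
  out <- as.matrix(lab)
  # relabel consecutively
  ids <- sort(unique(out[out > 0]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    out[out > 0] <- remap[out[out > 0]]
  }
  storage.mode(out) <- "integer"
  out
}

# lattice-point solidity: object area / number of lattice points inside the
# convex hull of the pixel centres (hull contains all centres, so <= 1)
.solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(1)
  pts <- cbind(cols, rows)            # chull works in xy
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]     # clockwise order from chull
  k <- nrow(hp)
  if (k < 3L) return(1)
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  RR <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  CC <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  inside <- matrix(TRUE, nrow(RR), ncol(RR))
  for (i in seq_len(k)) {
    a <- hp[i, ]; b <- hp[if (i == k) 1L else i + 1L, ]
    # chull returns clockwise in xy: interior is to the right of each edge
    cr <- (b[1] - a[1]) * (RR - a[2]) - (b[2] - a[2]) * (CC - a[1])
    inside <- inside & (cr <= 1e-9)
  }
  hull_px <- sum(inside)
  if (hull_px <= 0) return(1)
  min(n / hull_px, 1)
}

#' Rim and cytoplasm zones around a single nucleus
#'
#' Zones are distance bands of the Euclidean distance transform around the
#' nucleus: the perinuclear rim covers distances (0, `r_rim`] and the
#' cytoplasm zone (`r_rim`, `r_cyto`], i.e. morphological dilations by
#' `r_rim` and `r_cyto` minus the inner sets. Bands are clipped at the image
#' border. Nucleus, rim and cytoplasm are pairwise disjoint by construction.
#'
#' @param nucleus_mask logical matrix with a single nucleus (non-empty).
#' @param r_rim,r_cyto outer radii of rim and cytoplasm bands, pixels.
#' @return list of logical matrices `rim` and `cytoplasm`.
#' @export
zone_decomposition <- function(nucleus_mask, r_rim = 3, r_cyto = 12) {
  stopifnot(is.matrix(nucleus_mask))
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  if (r_cyto <= r_rim) stop("r_cyto must exceed r_rim")
  dm <- as.matrix(EBImage::distmap(EBImage::Image((!nucleus_mask) * 1)))
  list(rim = dm > 0 & dm <= r_rim,
       cytoplasm = dm > r_rim & dm <= r_cyto)
}

# field-level zone maps: distance bands assigned to the nearest nucleus
# (geodesic Voronoi via seeded region growing), so no pixel serves two cells
.zone_maps <- function(labels, r_rim = 3, r_cyto = 12) {
  fg <- labels > 0
  dm <- as.matrix(EBImage::distmap(EBImage::Image((!fg) * 1)))
  reach <- fg | (dm <= r_cyto)
  vor <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labels), ncol(labels))),
                            seeds = EBImage::Image(labels),
                            mask = EBImage::Image(reach * 1))
  vor <- as.matrix(vor)
  storage.mode(vor) <- "integer"
  list(dist = dm, voronoi = vor,
       rim = vor * (dm > 0 & dm <= r_rim),
       cyto = vor * (dm > r_rim & dm <= r_cyto))
}

#' Filter segmented objects and decompose survivors into zones
#'
#' Objects are removed when their solidity (area / convex-hull area) falls
#' below `solidity_min` — the signature of fused cell aggregates —, when
#' their area lies outside `[area_min, area_max]`, or when they touch the
#' image border (truncated cytoplasm zones bias the descriptors). Surviving
#' nuclei are decomposed into perinuclear rim and cytoplasm zones; where
#' cells compete for the same pixels, each pixel goes to the nearest
#' nucleus.
#'
#' @param labels integer label matrix from [split_touching()].
#' @param config list overriding defaults `solidity_min = 0.80`,
#'   `area_min = 120`, `area_max = 4000`, `r_rim = 3`, `r_cyto = 12`.
#' @return list of `CellObject`s (class `anca_cell`): `label`, linear pixel
#'   index vectors `nucleus`, `rim`, `cytoplasm`, `area_px`, `solidity`,
#'   `touches_border`, `centroid`, and `keep`/`reason` for excluded objects.
#'   Only kept objects carry zones. The list has attribute `"excluded"` with
#'   the reason table.
#' @export
filter_objects <- function(labels, config = list()) {
  stopifnot(is.matrix(labels))
  cfg <- utils::modifyList(list(solidity_min = 0.80, area_min = 120,
                                area_max = 4000, r_rim = 3, r_cyto = 12),
                           config)
  nr <- nrow(labels); nc <- ncol(labels)
  nlab <- max(labels)
  if (nlab == 0L) {
    out <- list()
    attr(out, "excluded") <- data.frame(label = integer(), reason = character())
    return(out)
  }
  idx_by <- split(which(labels > 0), labels[labels > 0])
  keep <- logical(nlab); reason <- character(nlab)
  sol <- area <- numeric(nlab); border <- logical(nlab)
  cent <- matrix(0, nlab, 2)
  for (k in seq_len(nlab)) {
    idx <- idx_by[[as.character(k)]]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    area[k] <- length(idx)
    border[k] <- any(rows == 1L | rows == nr | cols == 1L | cols == nc)
    sol[k] <- .solidity(rows, cols)
    cent[k, ] <- c(mean(rows), mean(cols))
    if (border[k]) reason[k] <- "touches_border"
    else if (area[k] < cfg$area_min) reason[k] <- "too_small"
    else if (area[k] > cfg$area_max) reason[k] <- "too_large"
    else if (sol[k] < cfg$solidity_min) reason[k] <- "low_solidity_aggregate"
    else keep[k] <- TRUE
  }
  # zones only for kept objects; competing cells resolved by nearest nucleus
  kept_labels <- labels
  kept_labels[!(labels %in% which(keep))] <- 0L
  zm <- if (any(keep)) .zone_maps(kept_labels, cfg$r_rim, cfg$r_cyto) else NULL
  rim_by <- cyto_by <- list()
  if (!is.null(zm)) {
    nzr <- which(zm$rim > 0)
    rim_by <- split(nzr, zm$rim[nzr])
    nzc <- which(zm$cyto > 0)
    cyto_by <- split(nzc, zm$cyto[nzc])
  }
  cells <- vector("list", sum(keep))
  ci <- 0L
  for (k in which(keep)) {
    ci <- ci + 1L
    cells[[ci]] <- structure(
      list(label = k,
           nucleus = idx_by[[as.character(k)]],
           rim = if (!is.null(rim_by[[as.character(k)]]))
             rim_by[[as.character(k)]] else integer(0),
           cytoplasm = if (!is.null(cyto_by[[as.character(k)]]))
             cyto_by[[as.character(k)]] else integer(0),
           area_px = area[k], solidity = sol[k],
           touches_border = border[k], centroid = cent[k, ]),
      class = "anca_cell")
  }
  attr(cells, "excluded") <- data.frame(label = which(!keep),
                                        reason = reason[!keep],
                                        solidity = sol[!keep],
                                        area = area[!keep])
  attr(cells, "all_stats") <- data.frame(label = seq_len(nlab), area = area,
                                         solidity = sol, border = border,
                                         keep = keep)
  cells
}

#' Segment a DAPI field into accepted neutrophils
#'
#' Convenience wrapper: [threshold_nuclei()] then [split_touching()] then
#' [filter_objects()].
#'
#' @param dapi DAPI channel matrix.
#' @param config list merged over segmentation defaults; entries `sigma`,
#'   `min_area`, `h` feed the first two stages, the rest [filter_objects()].
#' @return as [filter_objects()], with attribute `"labels"` (the label
#'   matrix before filtering).
#' @export
segment_field <- function(dapi, config = list()) {
  cfg <- utils::modifyList(list(sigma = 1, min_area = 120, h = 2), config)
  mask <- threshold_nuclei(dapi, sigma = cfg$sigma, min_area = cfg$min_area)
  labels <- split_touching(mask, h = cfg$h)
  cells <- filter_objects(labels, cfg)
  attr(cells, "labels") <- labels
  cells
}
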