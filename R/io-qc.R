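#' Construct a two-channel field-of-view image
#'
#' A `FieldImage` holds the paired DAPI (nuclear counterstain) and FITC
#' (antibody signal) channels of one microscope field as integer grey-value
#' matrices on the 16-bit scale (0..65535), plus free-form metadata.
#'
#' @param dapi,fitc numeric matrices of identical shape, values in 0..65535.
#' @param pixel_size optional physical pixel size in micrometres.
#' @param metadata named list of acquisition metadata.
#' @return object of class `anca_field`.
#' @export
field_image <- function(dapi, fitc, pixel_size = NULL, metadata = list()) {
  stopifnot(is.matrix(dapi), is.matrix(fitc))
  if (!identical(dim(dapi), dim(fitc)))
    stop("DAPI and FITC channels must have identical dimensions")
  if (min(dapi) < 0 || max(dapi) > 65535 || min(fitc) < 0 || max(fitc) > 65535)
    stop("channel values must lie within the 16-bit range 0..65535")
  structure(list(dapi = dapi, fitc = fitc, pixel_size = pixel_size,
                 metadata = metadata),
            class = "anca_field")
}

#' @export
print.anca_field <- function(x, ...) {
  cat(sprintf("<anca_field> %d x %d px; DAPI range [%d, %d]; FITC range [%d, %d]\n",
              nrow(x$dapi), ncol(x$dapi),
              min(x$dapi), max(x$dapi), min(x$fitc), max(x$fitc)))
  invisible(x)
}

#' Read a two-channel field image from a multi-page TIFF
#'
#' Page 0 is the DAPI channel and page 1 the FITC channel. Both pages must be
#' single-sample grey images; 16-bit data is read as-is and 8-bit data is
#' accepted with linear up-scaling by 257 (so 255 maps to 65535), flagged in
#' the metadata as `scaled_from_8bit`. A JSON sidecar `<stem>.truth.json`
#' written by [write_fixture()] is attached to the metadata when present.
#'
#' @param path path to a 2-page grey TIFF.
#' @return an `anca_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 2L)
    stop(sprintf("expected a 2-page TIFF (DAPI, FITC), found %d page(s) in %s",
                 length(pages), path))
  meta <- list(source = path)
  chans <- lapply(seq_along(pages), function(k) {
    pg <- pages[[k]]
    bits <- attr(pg, "bits.per.sample")
    if (length(dim(pg)) != 2L)
      stop("page ", k - 1L, " is not a single-sample grey image")
    m <- matrix(as.numeric(pg), nrow(pg), ncol(pg))
    if (!is.null(bits) && bits == 8L) {
      m <- m * 257          # 255 -> 65535
      meta$scaled_from_8bit <<- TRUE
    } else if (!is.null(bits) && bits != 16L) {
      stop("unsupported bit depth ", bits, " on page ", k - 1L,
           " (expected 8 or 16)")
    }
    m
  })
  sidecar <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                    ".truth.json")
  if (file.exists(sidecar))
    meta$truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  field_image(chans[[1]], chans[[2]], metadata = meta)
}

#' Autofocus score from grey-scale transitions
#'
#' Sharpness is scored on the DAPI channel as the contrast statistic of the
#' grey-level co-occurrence matrix (Q = 64 levels, symmetric, offsets (0,1)
#' and (1,0) averaged):
#' \deqn{\mathrm{contrast} = \sum_{i,j} p(i,j)\,(i-j)^2.}
#' Quantization uses a fixed bin width (the 16-bit dynamic range divided by
#' Q) anchored at the observed minimum, so the score is invariant to adding
#' a constant to all pixels and, unlike min-max quantization, does not
#' re-scale the constant camera-noise floor as defocus compresses the
#' dynamic range — which keeps the score strictly decreasing along a blur
#' series. Defocus suppresses sharp grey-scale transitions between
#' neighbouring pixels; a constant image has no transitions and scores
#' exactly 0.
#'
#' @param dapi numeric matrix (DAPI channel).
#' @param levels GLCM quantization levels.
#' @return list with `value` (>= 0) and `method`.
#' @export
focus_score <- function(dapi, levels = 64L) {
  stopifnot(is.matrix(dapi), length(dapi) > 0L)
  lo <- min(dapi)
  g <- glcm_stats(dapi, levels = levels, range = c(lo, lo + 65535))
  list(value = g$contrast, method = "glcm_contrast")
}

#' Select the best-focused plane of a DAPI stack
#'
#' @param stack list of DAPI matrices (candidate focal planes).
#' @return integer index (1-based) of the plane with the highest
#'   [focus_score()]; ties resolve to the lowest index.
#' @export
select_focus <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("stack must be a non-empty list of image matrices")
  scores <- vapply(stack, function(m) focus_score(m)$value, numeric(1))
  which.max(scores)
}

#' Tile-based scene quality control
#'
#' Divides the image into tiles of `tile_px` x `tile_px` pixels (edge tiles
#' may be smaller) and computes per-tile GLCM sharpness (contrast) and
#' homogeneity. A tile is flagged when its saturated-pixel fraction exceeds
#' `saturation_frac` or its homogeneity falls below `homogeneity_floor`
#' (bright artifacts and debris saturate the camera and break the smooth
#' grey-scale statistics of a well-formed scene). The field passes when the
#' flagged fraction is at most `max_flagged_frac`.
#'
#' @param image numeric matrix.
#' @param tile_px tile edge length in pixels (>= 8).
#' @param thresholds list with `saturation_frac` (default 0.01),
#'   `homogeneity_floor` (default 0.05), `max_flagged_frac` (default 0.25)
#'   and `saturation_level` (default 65535).
#' @return object of class `anca_tile_qc`: tile grid dimensions, per-tile
#'   `sharpness` and `homogeneity` matrices, per-tile `saturated_frac`,
#'   logical `flagged` matrix, the flagged-tile indices and `field_pass`.
#' @export
tile_qc <- function(image, tile_px = 128L, thresholds = list()) {
  stopifnot(is.matrix(image))
  tile_px <- as.integer(tile_px)
  if (tile_px < 8L) stop("tile_px must be at least 8")
  th <- utils::modifyList(list(saturation_frac = 0.01,
                               homogeneity_floor = 0.05,
                               max_flagged_frac = 0.25,
                               saturation_level = 65535), thresholds)
  nr <- nrow(image); nc <- ncol(image)
  rb <- unique(c(seq(1L, nr, by = tile_px), nr + 1L))
  cb <- unique(c(seq(1L, nc, by = tile_px), nc + 1L))
  ntr <- length(rb) - 1L; ntc <- length(cb) - 1L
  sharp <- homog <- satf <- matrix(NA_real_, ntr, ntc)
  for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
    tile <- image[rb[i]:(rb[i + 1L] - 1L), cb[j]:(cb[j + 1L] - 1L), drop = FALSE]
    g <- glcm_stats(tile)
    sharp[i, j] <- g$contrast
    homog[i, j] <- g$homogeneity
    satf[i, j] <- mean(tile >= th$saturation_level)
  }
  flagged <- satf > th$saturation_frac | homog < th$homogeneity_floor
  structure(list(tile_px = tile_px, grid = c(ntr, ntc),
                 row_breaks = rb, col_breaks = cb,
                 sharpness = sharp, homogeneity = homog,
                 saturated_frac = satf, flagged = flagged,
                 flagged_tiles = which(flagged),
                 flagged_frac = mean(flagged),
                 field_pass = mean(flagged) <= th$max_flagged_frac,
                 thresholds = th),
            class = "anca_tile_qc")
}

#' @export
print.anca_tile_qc <- function(x, ...) {
  cat(sprintf("<anca_tile_qc> %d x %d tiles of %d px; %d flagged (%.1f%%); field %s\n",
              x$grid[1], x$grid[2], x$tile_px, length(x$flagged_tiles),
              100 * x$flagged_frac, if (x$field_pass) "PASS" else "FAIL"))
  invisible(x)
}
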