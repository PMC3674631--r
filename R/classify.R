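.eps_int <- 1e-6 * 65535   # ratio guard: 1e-6 of the dynamic range

#' Default classification thresholds
#'
#' The positivity cutoff and the six-level grade bin edges are anchored at
#' the functional assay sensitivity of the reading system: 40 AU on
#' ethanol-fixed and 30 AU on formalin-fixed neutrophils. Bins are
#' half-open, `[0,e1) = "-"`, `[e1,e2) = "+/-"`, ..., `[e5,Inf) = "++++"`,
#' with the second edge equal to the positivity cutoff. The topological
#' thresholds separate the two basic pattern geometries: `tau_p` is the
#' minimum rim/cytoplasm mean ratio declaring perinuclear (nuclear) signal,
#' `tau_c` the minimum cytoplasm/cell dominance declaring cytoplasmic
#' signal, and `tau_t` a floor on GLCM contrast of the cytoplasm zone (the
#' granular texture of a true cytoplasmic stain).
#'
#' @param fixation `"ethN"` or `"formN"`.
#' @return object of class `anca_thresholds`: `fixation`,
#'   `positivity_cutoff_au`, `grade_edges` (5 ascending AU edges), `tau_p`,
#'   `tau_c`, `tau_t`, `gain` (grey-levels per AU).
#' @export
default_thresholds <- function(fixation = c("ethN", "formN")) {
  fixation <- match.arg(fixation)
  edges <- if (fixation == "ethN") c(20, 40, 80, 120, 160)
           else c(15, 30, 70, 110, 150)
  structure(list(fixation = fixation,
                 positivity_cutoff_au = edges[2],
                 grade_edges = edges,
                 tau_p = 1.5, tau_c = 1.3, tau_t = 0.5,
                 gain = generator_defaults()$gain),
            class = "anca_thresholds")
}

#' @export
print.anca_thresholds <- function(x, ...) {
  cat(sprintf("<anca_thresholds> %s: cutoff %.3g AU; edges %s; tau_p %.3g tau_c %.3g tau_t %.3g\n",
              x$fixation, x$positivity_cutoff_au,
              paste(signif(x$grade_edges, 4), collapse = "/"),
              x$tau_p, x$tau_c, x$tau_t))
  invisible(x)
}

#' Write / read a threshold set as structured JSON
#'
#' @param thresholds an `anca_thresholds`.
#' @param path file path.
#' @return `read_thresholds` returns the `anca_thresholds`; `write_thresholds`
#'   returns `path` invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "anca_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "anca_thresholds")
}

#' Per-cell descriptor vector from the FITC channel
#'
#' Background (median FITC over non-cell pixels of the field) is subtracted,
#' floored at zero, before zone statistics. Regional descriptors are the
#' mean and total corrected FITC of nucleus, rim and cytoplasm zones and the
#' whole-cell mean; topological descriptors are the rim/cytoplasm ratio
#' (rho), the nucleus/cell ratio (nu) and the cytoplasm/cell dominance;
#' texture descriptors are GLCM statistics of the cytoplasm zone quantized
#' over a brightness-normalized range (0 to twice the cell mean), so texture
#' is comparable across staining intensities. All ratios carry an
#' epsilon-guard of 1e-6 of the dynamic range. A cell with any zone below
#' 10 px is flagged unreliable and dropped from sample aggregation.
#'
#' @param cell an `anca_cell` from [filter_objects()].
#' @param fitc FITC channel matrix.
#' @param background scalar background grey value; see
#'   [estimate_background()].
#' @return object of class `anca_descriptors`.
#' @export
extract_descriptors <- function(cell, fitc, background) {
  stopifnot(inherits(cell, "anca_cell"), is.matrix(fitc))
  g <- function(idx) pmax(fitc[idx] - background, 0)
  vn <- g(cell$nucleus); vr <- g(cell$rim); vc <- g(cell$cytoplasm)
  nuc_mean <- if (length(vn)) mean(vn) else 0
  rim_mean <- if (length(vr)) mean(vr) else 0
  cyto_mean <- if (length(vc)) mean(vc) else 0
  cell_mean <- if (length(vn) + length(vr) + length(vc) > 0)
    mean(c(vn, vr, vc)) else 0
  rho <- rim_mean / (cyto_mean + .eps_int)
  nu <- nuc_mean / (cell_mean + .eps_int)
  dominance <- cyto_mean / (cell_mean + .eps_int)
  # texture over the cytoplasm zone, masked within its bounding box
  tex <- list(contrast = 0, homogeneity = 1, correlation = 0, entropy = 0)
  if (length(cell$cytoplasm) >= 10L) {
    nr <- nrow(fitc)
    rows <- ((cell$cytoplasm - 1L) %% nr) + 1L
    cols <- ((cell$cytoplasm - 1L) %/% nr) + 1L
    rr <- range(rows); cr <- range(cols)
    sub <- matrix(0, rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
    msk <- matrix(FALSE, nrow(sub), ncol(sub))
    sub[cbind(rows - rr[1] + 1L, cols - cr[1] + 1L)] <- vc
    msk[cbind(rows - rr[1] + 1L, cols - cr[1] + 1L)] <- TRUE
    tex <- glcm_stats(sub, mask = msk,
                      range = c(0, 2 * max(cell_mean, .eps_int)))
  }
  reliable <- length(cell$nucleus) >= 10L && length(cell$rim) >= 10L &&
    length(cell$cytoplasm) >= 10L
  structure(list(nuc_mean = nuc_mean, rim_mean = rim_mean,
                 cyto_mean = cyto_mean, cell_mean = cell_mean,
                 nuc_total = sum(vn), rim_total = sum(vr), cyto_total = sum(vc),
                 rho = rho, nu = nu, dominance = dominance,
                 contrast = tex$contrast, homogeneity = tex$homogeneity,
                 correlation = tex$correlation, entropy = tex$entropy,
                 solidity = cell$solidity, area_px = cell$area_px,
                 reliable = reliable),
            class = "anca_descriptors")
}

#' Median background of a field
#'
#' @param fitc FITC channel matrix.
#' @param cells list of `anca_cell`s; their nucleus/rim/cytoplasm pixels are
#'   excluded from the background estimate.
#' @return scalar median grey value over non-cell pixels.
#' @export
estimate_background <- function(fitc, cells = list()) {
  excl <- unlist(lapply(cells, function(cl) c(cl$nucleus, cl$rim, cl$cytoplasm)),
                 use.names = FALSE)
  # median over a subsample of non-cell pixels (the background is uniform;
  # the subsample keeps the estimate cheap on large fields)
  v <- if (length(excl)) fitc[-excl] else as.vector(fitc)
  if (length(v) > 50000L) v <- v[seq(1L, length(v), length.out = 50000L)]
  stats::median(v)
}

#' Sample-level fluorescence intensity in arbitrary units
#'
#' The sample AU is the median over reliable cells of the
#' background-corrected cell mean, divided by the calibration gain
#' (grey-levels per AU). The median is robust against residual artifacts; a
#' sum-based aggregate (total cell fluorescence) is available via
#' `method = "sum"`.
#'
#' @param descriptors list of `anca_descriptors`.
#' @param calibration list with `gain` (default [generator_defaults()]
#'   gain).
#' @param method `"median"` (default) or `"sum"` (mean of per-cell totals,
#'   scaled by gain and mean cell area).
#' @return scalar AU.
#' @export
sample_intensity_au <- function(descriptors, calibration = list(),
                                method = c("median", "sum")) {
  method <- match.arg(method)
  cal <- utils::modifyList(list(gain = generator_defaults()$gain), calibration)
  ok <- vapply(descriptors, function(d) isTRUE(d$reliable), logical(1))
  if (!any(ok)) stop("no reliable cells: sample fails QC")
  d <- descriptors[ok]
  if (method == "median") {
    stats::median(vapply(d, `[[`, numeric(1), "cell_mean")) / cal$gain
  } else {
    tot <- vapply(d, function(x) x$nuc_total + x$rim_total + x$cyto_total,
                  numeric(1))
    npx <- vapply(d, function(x) x$area_px, numeric(1))
    mean(tot) / (mean(npx) * cal$gain)
  }
}

#' Six-level ordinal intensity grade
#'
#' Half-open bins over AU: `[0,e1) = "-"`, `[e1,e2) = "+/-"`, `[e2,e3) =
#' "+"`, `[e3,e4) = "++"`, `[e4,e5) = "+++"`, `[e5,Inf) = "++++"`. A
#' boundary value belongs to the higher grade, so the positivity cutoff
#' (edge 2) itself grades `"+"`.
#'
#' @param au fluorescence intensity in AU (>= 0).
#' @param fixation substrate profile (selects default edges).
#' @param thresholds an `anca_thresholds`; default from
#'   [default_thresholds()].
#' @return object of class `anca_grade`: `level` (label), `code` (0..5),
#'   `au`.
#' @export
grade_intensity <- function(au, fixation = "ethN",
                            thresholds = default_thresholds(fixation)) {
  if (!is.finite(au) || au < 0) stop("au must be a non-negative number")
  edges <- thresholds$grade_edges
  stopifnot(length(edges) == 5L, !is.unsorted(edges, strictly = TRUE))
  code <- findInterval(au, edges)       # [e_i, e_{i+1}) -> i
  structure(list(level = .grades[code + 1L], code = code, au = au),
            class = "anca_grade")
}

#' @export
print.anca_grade <- function(x, ...) {
  cat(sprintf("<anca_grade> %s (code %d) at %.2f AU\n", x$level, x$code, x$au))
  invisible(x)
}

#' Classify one cell's staining pattern
#'
#' Decision rules on the descriptor vector, applied in order: a cell whose
#' background-corrected mean is below the positivity cutoff is negative;
#' on ethanol-fixed substrate, a rim/cytoplasm ratio of at least `tau_p`
#' declares nuclear/perinuclear signal; otherwise cytoplasm dominance of at
#' least `tau_c` together with granular texture (GLCM contrast >= `tau_t`)
#' declares cytoplasmic; anything else is atypical. The formalin profile
#' skips the nuclear branch (three classes only: MPO-type antigens cannot
#' relocate to the nuclear periphery).
#'
#' @param d an `anca_descriptors`.
#' @param fixation substrate profile.
#' @param thresholds an `anca_thresholds`.
#' @return pattern label, one of `"cytoplasmic"`, `"nuclear"`, `"atypical"`,
#'   `"negative"`.
#' @export
classify_cell <- function(d, fixation = "ethN",
                          thresholds = default_thresholds(fixation)) {
  stopifnot(inherits(d, "anca_descriptors"))
  au_cell <- d$cell_mean / thresholds$gain
  if (au_cell < thresholds$positivity_cutoff_au) return("negative")
  if (fixation == "ethN" && d$rho >= thresholds$tau_p) return("nuclear")
  if (d$dominance >= thresholds$tau_c && d$contrast >= thresholds$tau_t)
    return("cytoplasmic")
  "atypical"
}

#' Aggregate per-cell calls into a sample result
#'
#' Cells are pooled across the sample's QC-passed fields. Fewer than
#' `min_cells` (default 20) reliable cells yields `qc_status =
#' "insufficient_cells"` and no pattern call. Otherwise the sample AU and
#' grade come from [sample_intensity_au()] and [grade_intensity()], and the
#' pattern is the modal pattern over positive cells (ties resolve to
#' atypical, the conservative call that triggers manual review). A sample
#' graded `"-"` or `"+/-"` is always reported negative.
#'
#' @param descriptors pooled list of `anca_descriptors` (QC-passed fields).
#' @param fixation substrate profile.
#' @param thresholds an `anca_thresholds`.
#' @param calibration list with `gain`.
#' @param min_cells minimum pooled reliable cell count.
#' @param n_fields_total,n_fields_passed field bookkeeping for the QC
#'   status; if no field passed, `qc_status = "failed_field_qc"`.
#' @return object of class `anca_sample_result`: `fixation`,
#'   `n_cells_analyzed`, `au`, `grade`, `pattern`, `qc_status`,
#'   `cell_patterns`.
#' @export
aggregate_sample <- function(descriptors, fixation = "ethN",
                             thresholds = default_thresholds(fixation),
                             calibration = list(gain = thresholds$gain),
                             min_cells = 20L,
                             n_fields_total = NA_integer_,
                             n_fields_passed = NA_integer_) {
  res <- list(fixation = fixation, n_cells_analyzed = 0L,
              au = NA_real_, grade = NA_character_, grade_code = NA_integer_,
              pattern = NA_character_, qc_status = "ok",
              cell_patterns = character(0))
  class(res) <- "anca_sample_result"
  if (!is.na(n_fields_passed) && n_fields_passed == 0L) {
    res$qc_status <- "failed_field_qc"
    return(res)
  }
  ok <- vapply(descriptors, function(d) isTRUE(d$reliable), logical(1))
  d <- descriptors[ok]
  res$n_cells_analyzed <- length(d)
  if (length(d) > 0) {
    res$au <- sample_intensity_au(d, calibration)
    g <- grade_intensity(res$au, fixation, thresholds)
    res$grade <- g$level; res$grade_code <- g$code
  }
  if (length(d) < min_cells) {
    res$qc_status <- "insufficient_cells"
    return(res)
  }
  calls <- vapply(d, classify_cell, character(1),
                  fixation = fixation, thresholds = thresholds)
  res$cell_patterns <- calls
  if (res$grade_code <= 1L) {          # "-" or "+/-" forces negative
    res$pattern <- "negative"
    return(res)
  }
  pos <- calls[calls != "negative"]
  if (length(pos) == 0L) {
    res$pattern <- "negative"
    return(res)
  }
  tab <- table(pos)
  top <- names(tab)[tab == max(tab)]
  res$pattern <- if (length(top) > 1L) "atypical" else top
  res
}

#' @export
print.anca_sample_result <- function(x, ...) {
  cat(sprintf("<anca_sample_result> %s: %s / grade %s (%.1f AU), %d cells, qc %s\n",
              x$fixation, x$pattern, x$grade, x$au, x$n_cells_analyzed,
              x$qc_status))
  invisible(x)
}

# midpoint separator: midpoint of the gap when classes separate, else the
# error-minimizing cut (ties -> midpoint of the tied range)
.fit_cut <- function(lo_vals, hi_vals) {
  if (!length(lo_vals) || !length(hi_vals)) return(NA_real_)
  if (max(lo_vals) < min(hi_vals))
    return((max(lo_vals) + min(hi_vals)) / 2)
  cand <- sort(unique(c(lo_vals, hi_vals)))
  mids <- (cand[-1] + cand[-length(cand)]) / 2
  err <- vapply(mids, function(m)
    sum(lo_vals >= m) + sum(hi_vals < m), numeric(1))
  best <- mids[err == min(err)]
  (min(best) + max(best)) / 2
}

#' Fit classification thresholds on a labelled cohort
#'
#' The positivity cutoff is the midpoint between the highest negative-sample
#' AU and the lowest positive-sample AU when the classes separate, otherwise
#' the cut minimizing training misclassifications (ties resolve to the
#' midpoint of the tied range). The topological thresholds `tau_p` and
#' `tau_c` are fitted the same way on cell-level rho (nuclear vs other
#' positive cells) and dominance (cytoplasmic vs other positive cells)
#' distributions when both classes are present, else kept at defaults. The
#' grade edges keep their default spacing with edge 2 re-anchored at the
#' fitted cutoff (edge 1 at half the cutoff). Deterministic given its input.
#'
#' @param sample_au data.frame with columns `au` and `label`
#'   ("positive"/"negative").
#' @param cell_stats optional data.frame with columns `rho`, `dominance`,
#'   `pattern` (ground-truth cell pattern) for positive cells.
#' @param fixation substrate profile.
#' @return fitted `anca_thresholds`.
#' @export
fit_thresholds <- function(sample_au, cell_stats = NULL, fixation = "ethN") {
  stopifnot(all(c("au", "label") %in% names(sample_au)))
  pos <- sample_au$au[sample_au$label == "positive"]
  neg <- sample_au$au[sample_au$label == "negative"]
  if (!length(pos) || !length(neg))
    stop("cohort must contain both positive and negative samples")
  thr <- default_thresholds(fixation)
  cutoff <- .fit_cut(neg, pos)
  thr$positivity_cutoff_au <- cutoff
  e <- thr$grade_edges
  upper <- e[3:5]
  for (i in seq_along(upper))
    upper[i] <- max(upper[i], (if (i == 1) cutoff else upper[i - 1]) + 1)
  thr$grade_edges <- c(cutoff / 2, cutoff, upper)
  if (!is.null(cell_stats) && nrow(cell_stats)) {
    nuc <- cell_stats$rho[cell_stats$pattern == "nuclear"]
    oth <- cell_stats$rho[cell_stats$pattern %in% c("cytoplasmic", "atypical")]
    tp <- .fit_cut(oth, nuc)
    if (is.finite(tp)) thr$tau_p <- tp
    cy <- cell_stats$dominance[cell_stats$pattern == "cytoplasmic"]
    at <- cell_stats$dominance[cell_stats$pattern == "atypical"]
    tc <- .fit_cut(at, cy)
    if (is.finite(tc)) thr$tau_c <- tc
  }
  thr
}
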