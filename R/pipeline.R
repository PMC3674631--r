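#' Run configuration for the end-to-end pipeline
#'
#' @param fixation substrate profile.
#' @param thresholds an `anca_thresholds` (default for the fixation).
#' @param qc list of tile-QC thresholds (see [tile_qc()]); `tile_px` sets
#'   the tile size.
#' @param segmentation list of segmentation parameters (see
#'   [segment_field()]).
#' @param calibration list with `gain` (grey-levels per AU).
#' @param min_cells minimum pooled cell count per sample.
#' @return object of class `anca_run_config`.
#' @export
run_config <- function(fixation = "ethN",
                       thresholds = default_thresholds(fixation),
                       qc = list(), segmentation = list(),
                       calibration = list(gain = thresholds$gain),
                       min_cells = 20L) {
  structure(list(fixation = fixation, thresholds = thresholds,
                 qc = utils::modifyList(list(tile_px = 128L), qc),
                 segmentation = segmentation, calibration = calibration,
                 min_cells = as.integer(min_cells)),
            class = "anca_run_config")
}

#' Process one field: QC, segmentation, descriptor extraction
#'
#' @param field an `anca_field`.
#' @param config an `anca_run_config`.
#' @return list with `qc` (an `anca_tile_qc`), `cells` (list of
#'   `anca_cell`), `descriptors` (list of `anca_descriptors`),
#'   `background`, and `log` (per-object discard reasons).
#' @export
process_field <- function(field, config = run_config()) {
  stopifnot(inherits(field, "anca_field"))
  qc <- tile_qc(field$dapi, tile_px = config$qc$tile_px,
                thresholds = config$qc)
  if (!qc$field_pass)
    return(list(qc = qc, cells = list(), descriptors = list(),
                background = NA_real_,
                log = data.frame(label = NA_integer_,
                                 reason = "failed_field_qc")))
  cells <- segment_field(field$dapi, config$segmentation)
  bg <- estimate_background(field$fitc, cells)
  desc <- lapply(cells, extract_descriptors, fitc = field$fitc,
                 background = bg)
  excl <- attr(cells, "excluded")
  unrel <- which(!vapply(desc, `[[`, logical(1), "reliable"))
  log <- rbind(
    if (!is.null(excl) && nrow(excl))
      data.frame(label = excl$label, reason = excl$reason)
    else data.frame(label = integer(), reason = character()),
    if (length(unrel))
      data.frame(label = vapply(cells[unrel], `[[`, numeric(1), "label"),
                 reason = "unreliable_descriptor")
    else data.frame(label = integer(), reason = character()))
  list(qc = qc, cells = cells, descriptors = desc, background = bg, log = log)
}

#' Run the full pipeline on the fields of one sample
#'
#' Fields failing tile QC are excluded; cells from the remaining fields are
#' pooled and aggregated into a sample result.
#'
#' @param fields list of `anca_field`s (or of `list(field, truth)` pairs as
#'   returned by [generate_sample()]).
#' @param config an `anca_run_config`.
#' @return an `anca_sample_result` with attribute `"fields"` holding the
#'   per-field processing output.
#' @export
run_fields <- function(fields, config = run_config()) {
  if (length(fields) == 0L) stop("no fields supplied")
  fields <- lapply(fields, function(f) if (inherits(f, "anca_field")) f else f$field)
  per <- lapply(fields, process_field, config = config)
  passed <- vapply(per, function(x) x$qc$field_pass, logical(1))
  pooled <- do.call(c, c(lapply(per[passed], `[[`, "descriptors"), list()))
  if (is.null(pooled)) pooled <- list()
  res <- aggregate_sample(pooled, fixation = config$fixation,
                          thresholds = config$thresholds,
                          calibration = config$calibration,
                          min_cells = config$min_cells,
                          n_fields_total = length(fields),
                          n_fields_passed = sum(passed))
  attr(res, "fields") <- per
  res
}

#' Run one sample from a directory of field TIFFs
#'
#' Reads every `*.tif`/`*.tiff` in the directory with [read_field()]
#' (unreadable files are logged and skipped) and calls [run_fields()].
#'
#' @param sample_dir directory holding at least one field TIFF.
#' @param config an `anca_run_config`.
#' @return an `anca_sample_result`.
#' @export
run_sample <- function(sample_dir, config = run_config()) {
  paths <- list.files(sample_dir, pattern = "\\.tiff?$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(paths) == 0L)
    stop("no field TIFFs found in ", sample_dir)
  fields <- list(); skipped <- character(0)
  for (p in paths) {
    f <- try(read_field(p), silent = TRUE)
    if (inherits(f, "try-error")) skipped <- c(skipped, p) else
      fields[[length(fields) + 1L]] <- f
  }
  if (length(fields) == 0L) stop("no readable fields in ", sample_dir)
  res <- run_fields(fields, config)
  attr(res, "skipped") <- skipped
  res
}

#' Run the pipeline over a synthetic cohort
#'
#' Realizes each cohort row with [generate_sample()] and runs the full
#' pipeline; returns per-sample results plus pooled cell-level statistics
#' (with their ground-truth pattern) for threshold fitting.
#'
#' @param cohort an `anca_cohort` from [generate_cohort()].
#' @param config an `anca_run_config`.
#' @param image_shape field dimensions for the rendered samples.
#' @param n_fields,cells_per_field passed to [generate_sample()].
#' @param progress print a dot every 10 samples.
#' @return list with `samples` (data.frame: sample_id, label, true pattern
#'   and grade, automated au, grade, pattern, qc_status, n_cells) and
#'   `cells` (data.frame of per-cell rho, dominance, contrast, cell AU and
#'   ground-truth pattern).
#' @export
run_cohort <- function(cohort, config = run_config(cohort$fixation[1]),
                       image_shape = c(512L, 512L), n_fields = 5L,
                       cells_per_field = 4:7, progress = FALSE) {
  stopifnot(inherits(cohort, "anca_cohort"))
  srows <- vector("list", nrow(cohort))
  crows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rw <- cohort[i, ]
    flds <- generate_sample(rw$pattern, rw$grade, rw$fixation, seed = rw$seed,
                            n_fields = n_fields, image_shape = image_shape,
                            cells_per_field = cells_per_field)
    res <- run_fields(flds, config)
    # rendered (ground-truth) sample pattern after any fixation remapping
    rendered <- flds[[1]]$truth$sample_pattern
    srows[[i]] <- data.frame(sample_id = rw$sample_id, label = rw$label,
                             true_pattern = rendered, true_grade = rw$grade,
                             au = res$au, grade = res$grade,
                             pattern = res$pattern, qc_status = res$qc_status,
                             n_cells = res$n_cells_analyzed,
                             stringsAsFactors = FALSE)
    per <- attr(res, "fields")
    d <- do.call(c, lapply(per, `[[`, "descriptors"))
    if (length(d)) {
      ok <- vapply(d, `[[`, logical(1), "reliable")
      d <- d[ok]
      if (length(d))
        crows[[i]] <- data.frame(
          sample_id = rw$sample_id,
          rho = vapply(d, `[[`, numeric(1), "rho"),
          dominance = vapply(d, `[[`, numeric(1), "dominance"),
          contrast = vapply(d, `[[`, numeric(1), "contrast"),
          au = vapply(d, `[[`, numeric(1), "cell_mean") /
            config$calibration$gain,
          pattern = rendered, label = rw$label,
          stringsAsFactors = FALSE)
    }
    if (progress && i %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  list(samples = do.call(rbind, srows),
       cells = do.call(rbind, crows))
}

#' Validation report: automated calls vs reference labels
#'
#' Rebuilds, from aligned per-sample rows, the agreement surface of a
#' visual-vs-automated comparison: the pattern confusion matrix with its
#' quadratic-weighted and unweighted kappa, the 2x2 positive/negative
#' collapse with the exact McNemar test, and (when six-level grades are
#' supplied) the 6x6 grade matrix with its weighted kappa.
#'
#' @param results data.frame with `sample_id`, `pattern`, and optionally
#'   `grade` (automated calls).
#' @param references data.frame with `sample_id`, `pattern`, optionally
#'   `grade` (reference labels), and optionally `group` for per-group
#'   counts.
#' @param pattern_levels category order for the pattern matrix (default:
#'   the levels present, ordered cytoplasmic, nuclear, atypical, negative).
#' @return object of class `anca_validation`: `pattern_cm`, `kappa_pattern`
#'   (quadratic), `kappa_pattern_unweighted`, `binary_cm`, `mcnemar`,
#'   `kappa_binary`, optionally `grade_cm` + `kappa_grade`, `per_group`,
#'   and the aligned `rows`.
#' @export
run_validation <- function(results, references, pattern_levels = NULL) {
  stopifnot(all(c("sample_id", "pattern") %in% names(results)),
            all(c("sample_id", "pattern") %in% names(references)))
  orphans <- c(setdiff(results$sample_id, references$sample_id),
               setdiff(references$sample_id, results$sample_id))
  if (length(orphans))
    stop("unmatched sample ids: ", paste(orphans, collapse = ", "))
  ref <- references[match(results$sample_id, references$sample_id), ]
  if (is.null(pattern_levels))
    pattern_levels <- intersect(c("cytoplasmic", "nuclear", "atypical", "negative"),
                                unique(c(ref$pattern, results$pattern)))
  rows <- data.frame(sample_id = results$sample_id,
                     ref_pattern = ref$pattern, auto_pattern = results$pattern,
                     stringsAsFactors = FALSE)
  pcm <- confusion_matrix(list(rows$ref_pattern, rows$auto_pattern),
                          pattern_levels)
  out <- list(pattern_cm = pcm,
              kappa_pattern = cohens_kappa(pcm, "quadratic"),
              kappa_pattern_unweighted = cohens_kappa(pcm, "identity"),
              rows = rows)
  # binary collapse on patterns: negative vs any positive pattern
  bin <- function(x) ifelse(x == "negative", "negative", "positive")
  bcm <- confusion_matrix(list(bin(rows$ref_pattern), bin(rows$auto_pattern)),
                          c("negative", "positive"))
  out$binary_cm <- bcm
  out$mcnemar <- mcnemar_exact(bcm)
  out$kappa_binary <- cohens_kappa(bcm, "identity")
  if ("grade" %in% names(results) && "grade" %in% names(references)) {
    gcm <- confusion_matrix(list(ref$grade, results$grade), .grades)
    out$grade_cm <- gcm
    out$kappa_grade <- cohens_kappa(gcm, "quadratic")
    out$rows$ref_grade <- ref$grade
    out$rows$auto_grade <- results$grade
  }
  if ("group" %in% names(references)) {
    out$per_group <- as.data.frame(table(group = ref$group,
                                         agreement = rows$ref_pattern ==
                                           rows$auto_pattern))
  }
  class(out) <- "anca_validation"
  out
}

#' @export
print.anca_validation <- function(x, ...) {
  cat("Validation report over", nrow(x$rows), "samples\n")
  cat(sprintf("  pattern kappa (quadratic): %.3f; unweighted: %.3f\n",
              x$kappa_pattern$kappa, x$kappa_pattern_unweighted$kappa))
  cat(sprintf("  pos/neg McNemar: diff %.2f%%, p = %.4f\n",
              100 * x$mcnemar$diff, x$mcnemar$p))
  if (!is.null(x$kappa_grade))
    cat(sprintf("  grade kappa (quadratic): %.3f\n", x$kappa_grade$kappa))
  invisible(x)
}
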