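#' Confusion matrix from paired ratings
#'
#' @param pairs data.frame or list with two equal-length vectors: first
#'   rater (rows, e.g. visual) and second rater (columns, e.g. automated).
#' @param labels character vector of ordered category labels; order is
#'   significant for weighted agreement statistics.
#' @return object of class `anca_confusion`: integer matrix with dimnames,
#'   attribute `n`.
#' @export
confusion_matrix <- function(pairs, labels) {
  a <- pairs[[1]]; b <- pairs[[2]]
  stopifnot(length(a) == length(b))
  bad <- setdiff(unique(c(a, b)), labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(a, levels = labels), factor(b, levels = labels))
  m <- matrix(as.integer(m), length(labels), length(labels),
              dimnames = list(labels, labels))
  structure(m, class = c("anca_confusion", "matrix"), n = sum(m))
}

#' Build an `anca_confusion` from a counts matrix
#'
#' @param counts square non-negative integer matrix (rows = rater A,
#'   columns = rater B), with or without dimnames.
#' @param labels optional ordered labels (defaults to rownames).
#' @return an `anca_confusion`.
#' @export
as_confusion <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  m <- matrix(as.integer(round(counts)), nrow(counts), ncol(counts),
              dimnames = list(labels, labels))
  structure(m, class = c("anca_confusion", "matrix"), n = sum(m))
}

#' Read / write a labelled confusion matrix as CSV
#'
#' CSV dialect: first column holds the row (rater A) labels, header the
#' column (rater B) labels.
#'
#' @param path CSV file.
#' @return an `anca_confusion`.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(df))
}

#' @rdname read_confusion_csv
#' @param cm an `anca_confusion` to write.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' Packaged rater-agreement tables
#'
#' Transcribed published comparisons of visual vs automated ANCA IIF
#' interpretation of a 342-sample test set: six-level intensity grades
#' (`"grade"`) and pattern calls (`"pattern"`), each on ethanol- and
#' formalin-fixed substrates. Rows are visual, columns automated.
#'
#' @param table `"grade"` or `"pattern"`.
#' @param fixation `"ethN"` or `"formN"`.
#' @return an `anca_confusion`.
#' @export
anca_reference_table <- function(table = c("grade", "pattern"),
                                 fixation = c("ethN", "formN")) {
  table <- match.arg(table); fixation <- match.arg(fixation)
  f <- system.file("extdata",
                   sprintf("%s_%s.csv",
                           if (table == "grade") "grade6" else "pattern",
                           fixation),
                   package = "ancaiif", mustWork = TRUE)
  read_confusion_csv(f)
}

.weight_matrix <- function(k, weighting) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weighting,
         identity = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2,
         stop("unknown weighting: ", weighting))
}

#' Cohen's kappa with identity, linear or quadratic weights
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with weighted
#' observed and expected agreement, agreement weights
#' w_ij = 1 - (|i-j|/(k-1))^q (q = 1 linear, q = 2 quadratic) or the
#' identity (unweighted kappa). The standard error is the Fleiss-Cohen
#' large-sample formula and the 95% CI is kappa +/- 1.96 se. Quadratic
#' weighting is the default for ordinal scales: distant disagreements are
#' penalized by squared category distance.
#'
#' @param cm an `anca_confusion` (or square counts matrix).
#' @param weighting `"quadratic"` (default), `"linear"`, or `"identity"`.
#' @return object of class `anca_kappa`: `kappa`, `weighting`, `se`, `ci95`,
#'   `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(cm, weighting = c("quadratic", "linear", "identity")) {
  weighting <- match.arg(weighting)
  m <- unclass(as.matrix(cm))
  k <- nrow(m)
  n <- sum(m)
  if (n <= 0) stop("empty confusion matrix")
  if (k < 2L) stop("need at least two categories")
  p <- m / n
  w <- .weight_matrix(k, weighting)
  pi. <- rowSums(p); p.j <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi., p.j))
  if (1 - pe <= .Machine$double.eps)
    stop("degenerate margins: expected agreement is 1")
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen asymptotic SE of weighted kappa
  wbar_i <- as.vector(w %*% p.j)        # row-wise expected weight
  wbar_j <- as.vector(t(w) %*% pi.)     # column-wise expected weight
  wd <- w - outer(wbar_i, wbar_j, "+") * (1 - kap)
  var_k <- (sum(p * wd^2) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  structure(list(kappa = kap, weighting = weighting, se = se,
                 ci95 = c(kap - 1.96 * se, kap + 1.96 * se),
                 p_o = po, p_e = pe, n = n),
            class = "anca_kappa")
}

#' @export
print.anca_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weights): %.3f (se %.4f, 95%% CI %.3f to %.3f), n = %d\n",
              x$weighting, x$kappa, x$se, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Collapse a six-level grade table to positive/negative
#'
#' @param cm6 an `anca_confusion` over the six ordinal grades
#'   `-, +/-, +, ++, +++, ++++`.
#' @param borderline_policy `"as_negative"` (default: `-` and `+/-` count as
#'   negative) or `"as_positive"` (only `-` is negative).
#' @return 2x2 `anca_confusion` with labels `negative`, `positive`.
#' @export
collapse_binary <- function(cm6,
                            borderline_policy = c("as_negative", "as_positive")) {
  borderline_policy <- match.arg(borderline_policy)
  m <- unclass(as.matrix(cm6))
  stopifnot(nrow(m) == 6L, ncol(m) == 6L)
  neg <- if (borderline_policy == "as_negative") 1:2 else 1L
  pos <- setdiff(1:6, neg)
  out <- rbind(c(sum(m[neg, neg]), sum(m[neg, pos])),
               c(sum(m[pos, neg]), sum(m[pos, pos])))
  as_confusion(out, c("negative", "positive"))
}

#' Exact McNemar test on a paired 2x2 agreement table
#'
#' Tests the difference of paired proportions through the discordant cells
#' b (rater A negative / B positive) and c (A positive / B negative):
#' exact p = min(1, 2 P(X <= min(b, c))) with X ~ Binomial(b + c, 1/2),
#' symmetric in (b, c); by convention p = 1 and diff = 0 when b + c = 0.
#' The reported difference is (b - c)/n with a Wald 95% CI. A
#' chi-square variant with continuity correction is available for large
#' discordant counts via `method = "chisq"`.
#'
#' @param cm2 2x2 `anca_confusion` (rows rater A, columns rater B).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return object of class `anca_mcnemar`: `b`, `c`, `n`, `diff`
#'   (proportion), `ci95`, `p`, `method`.
#' @export
mcnemar_exact <- function(cm2, method = c("exact", "chisq")) {
  method <- match.arg(method)
  m <- unclass(as.matrix(cm2))
  stopifnot(nrow(m) == 2L, ncol(m) == 2L)
  b <- m[1, 2]; cc <- m[2, 1]; n <- sum(m)
  if (b + cc == 0) {
    p <- 1
    diff <- 0
    ci <- c(0, 0)
  } else {
    p <- if (method == "exact")
      min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    else {
      x2 <- (abs(b - cc) - 1)^2 / (b + cc)
      stats::pchisq(x2, df = 1, lower.tail = FALSE)
    }
    diff <- (b - cc) / n
    se <- sqrt(b + cc - (b - cc)^2 / n) / n
    ci <- diff + c(-1.96, 1.96) * se
  }
  structure(list(b = b, c = cc, n = n, diff = diff, ci95 = ci, p = p,
                 method = method),
            class = "anca_mcnemar")
}

#' @export
print.anca_mcnemar <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, diff = %.2f%% (95%% CI %.2f to %.2f%%), p = %.4f\n",
              x$method, x$b, x$c, 100 * x$diff, 100 * x$ci95[1],
              100 * x$ci95[2], x$p))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table at fixed margins (the classical two-sided
#' convention, as implemented by [stats::fisher.test()]).
#'
#' @param table 2x2 non-negative counts matrix.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == 2L, ncol(m) == 2L, all(m >= 0))
  stats::fisher.test(m)$p.value
}

#' Inter-assay coefficient of variation profile
#'
#' @param replicates named list of numeric vectors (AU replicates per
#'   sample across runs, each length >= 2) or a data.frame with columns
#'   `sample` and `au`.
#' @return object of class `anca_cv`: data.frame with `sample`, `mean_au`,
#'   `sd_au`, `cv_pct` (100 sd/mean, `NA` and flagged when the mean is 0),
#'   `n_runs`, `undefined`.
#' @export
interassay_cv <- function(replicates) {
  if (is.data.frame(replicates))
    replicates <- split(replicates$au, replicates$sample)
  stopifnot(length(replicates) > 0)
  rows <- lapply(names(replicates), function(nm) {
    v <- replicates[[nm]]
    if (length(v) < 2) stop("sample ", nm, " has fewer than 2 replicates")
    m <- mean(v)
    data.frame(sample = nm, mean_au = m, sd_au = stats::sd(v),
               cv_pct = if (m == 0) NA_real_ else 100 * stats::sd(v) / m,
               n_runs = length(v), undefined = m == 0)
  })
  structure(do.call(rbind, rows), class = c("anca_cv", "data.frame"))
}

#' Functional assay sensitivity
#'
#' The lowest AU level whose inter-assay CV falls below the cutoff
#' (default 20%): the smallest fluorescence intensity the assay measures
#' reproducibly.
#'
#' @param profile an `anca_cv`, or data.frame with `mean_au` and `cv_pct`.
#' @param cutoff_pct CV cutoff in percent (default 20).
#' @return list with `sensitivity_au` (`NA` if not reached), `reached`,
#'   `cutoff_pct`.
#' @export
functional_sensitivity <- function(profile, cutoff_pct = 20) {
  stopifnot(nrow(profile) >= 1)
  ok <- !is.na(profile$cv_pct) & profile$cv_pct < cutoff_pct
  if (!any(ok))
    return(list(sensitivity_au = NA_real_, reached = FALSE,
                cutoff_pct = cutoff_pct))
  list(sensitivity_au = min(profile$mean_au[ok]), reached = TRUE,
       cutoff_pct = cutoff_pct)
}
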