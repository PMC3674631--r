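test_that("descriptors are zero-safe on an empty FITC channel", {
  g <- generate_field(tiny_spec(n_cells = 2, pattern = "negative", seed = 30))
  cells <- segment_field(g$field$dapi)
  zero <- matrix(0, 256, 256)
  d <- extract_descriptors(cells[[1]], zero, background = 0)
  expect_identical(d$cell_mean, 0)
  expect_identical(d$rho, 0)       # epsilon-guarded 0/0
  expect_identical(d$contrast, 0)
  expect_true(is.finite(d$nu) && is.finite(d$dominance))
})

test_that("descriptor geometry separates the staining patterns", {
  for (pat in c("nuclear", "cytoplasmic")) {
    g <- generate_field(tiny_spec(n_cells = 4, pattern = pat,
                                  intensity_au = 80, seed = 33))
    cells <- segment_field(g$field$dapi)
    bg <- estimate_background(g$field$fitc, cells)
    for (cl in cells) {
      d <- extract_descriptors(cl, g$field$fitc, bg)
      if (pat == "nuclear") expect_gt(d$rho, 1)
      else {
        expect_lt(d$rho, 1)
        expect_gt(d$cyto_mean, d$rim_mean)
      }
    }
  }
})

test_that("sample AU is the calibrated median of cell means", {
  mk <- function(cm) structure(list(cell_mean = cm, reliable = TRUE),
                               class = "anca_descriptors")
  gain <- generator_defaults()$gain
  expect_equal(sample_intensity_au(list(mk(gain * 50), mk(gain * 50),
                                        mk(gain * 50))), 50)
  expect_equal(sample_intensity_au(list(mk(gain * 12))), 12)  # median of one
  expect_equal(sample_intensity_au(list(mk(gain * 10), mk(gain * 20),
                                        mk(gain * 90))), 20)
  expect_error(sample_intensity_au(list(structure(list(reliable = FALSE),
                                                  class = "anca_descriptors"))),
               "QC")
})

test_that("AU recovery stays within ten percent across seeds", {
  err <- vapply(1:10, function(s) {
    flds <- generate_sample("cytoplasmic", "++", "ethN", seed = 1000 + s,
                            image_shape = c(512L, 512L))
    res <- run_fields(flds, run_config("ethN"))
    abs(res$au - attr(flds, "au")) / attr(flds, "au")
  }, numeric(1))
  expect_true(all(err < 0.10))
})

test_that("intensity grading uses half-open bins anchored at 40/30 AU", {
  expect_identical(grade_intensity(0, "ethN")$level, "-")
  expect_identical(grade_intensity(40, "ethN")$level, "+")     # boundary up
  expect_identical(grade_intensity(39.999, "ethN")$level, "+/-")
  expect_identical(grade_intensity(20, "ethN")$level, "+/-")
  expect_identical(grade_intensity(1e6, "ethN")$level, "++++")
  expect_identical(grade_intensity(30, "formN")$level, "+")
  expect_identical(grade_intensity(29.9, "formN")$level, "+/-")
  expect_error(grade_intensity(-1, "ethN"), "non-negative")
  # monotone non-decreasing and exhaustive over au >= 0
  au <- seq(0, 250, by = 0.5)
  codes <- vapply(au, function(a) grade_intensity(a, "ethN")$code, integer(1))
  expect_true(all(diff(codes) >= 0))
  expect_true(all(codes %in% 0:5))
})

test_that("cell classification follows the decision rules per fixation", {
  thr <- default_thresholds("ethN")
  mk <- function(au, rho, dom, con) structure(
    list(cell_mean = au * thr$gain, rho = rho, dominance = dom,
         contrast = con, reliable = TRUE), class = "anca_descriptors")
  expect_identical(classify_cell(mk(10, 5, 2, 9), "ethN", thr), "negative")
  expect_identical(classify_cell(mk(80, 5, 0.3, 9), "ethN", thr), "nuclear")
  expect_identical(classify_cell(mk(80, 0.4, 1.6, 9), "ethN", thr),
                   "cytoplasmic")
  expect_identical(classify_cell(mk(80, 1.0, 1.0, 9), "ethN", thr), "atypical")
  # formalin profile has no nuclear branch
  thf <- default_thresholds("formN")
  expect_identical(classify_cell(mk(80, 5, 1.6, 9), "formN", thf),
                   "cytoplasmic")
  expect_identical(classify_cell(mk(80, 5, 1.0, 9), "formN", thf), "atypical")
})

test_that("generator cells classify to their rendered pattern", {
  for (pat in c("nuclear", "cytoplasmic", "atypical")) {
    g <- generate_field(tiny_spec(n_cells = 4, pattern = pat,
                                  intensity_au = 90, seed = 44))
    cells <- segment_field(g$field$dapi)
    bg <- estimate_background(g$field$fitc, cells)
    calls <- vapply(cells, function(cl)
      classify_cell(extract_descriptors(cl, g$field$fitc, bg), "ethN"),
      character(1))
    expect_true(all(calls == pat))
  }
  # nuclear-spec cells under formalin classify cytoplasmic
  g <- generate_field(tiny_spec(n_cells = 4, pattern = "nuclear",
                                fixation = "formN", intensity_au = 90,
                                seed = 45))
  cells <- segment_field(g$field$dapi)
  bg <- estimate_background(g$field$fitc, cells)
  calls <- vapply(cells, function(cl)
    classify_cell(extract_descriptors(cl, g$field$fitc, bg), "formN"),
    character(1))
  expect_true(all(calls == "cytoplasmic"))
})

test_that("sample aggregation enforces the 20-cell minimum and modal call", {
  thr <- default_thresholds("ethN")
  mk <- function(au, rho = 0.4, dom = 1.6, con = 9) structure(
    list(cell_mean = au * thr$gain, rho = rho, dominance = dom,
         contrast = con, reliable = TRUE), class = "anca_descriptors")
  few <- replicate(19, mk(90), simplify = FALSE)
  r1 <- aggregate_sample(few, "ethN", thr)
  expect_identical(r1$qc_status, "insufficient_cells")
  expect_true(is.na(r1$pattern))
  enough <- replicate(20, mk(90), simplify = FALSE)
  r2 <- aggregate_sample(enough, "ethN", thr)
  expect_identical(r2$qc_status, "ok")
  expect_identical(r2$pattern, "cytoplasmic")
  expect_identical(r2$grade, "++")
  # modal positive-cell pattern: 12 cytoplasmic / 5 nuclear / 3 atypical
  mixed <- c(replicate(12, mk(90), simplify = FALSE),
             replicate(5, mk(90, rho = 5, dom = 0.3), simplify = FALSE),
             replicate(3, mk(90, rho = 1, dom = 1), simplify = FALSE))
  expect_identical(aggregate_sample(mixed, "ethN", thr)$pattern, "cytoplasmic")
  # tie resolves to atypical (the conservative manual-review call)
  tied <- c(replicate(10, mk(90), simplify = FALSE),
            replicate(10, mk(90, rho = 5, dom = 0.3), simplify = FALSE))
  expect_identical(aggregate_sample(tied, "ethN", thr)$pattern, "atypical")
  # borderline grade forces a negative pattern call
  dim_cells <- replicate(25, mk(25), simplify = FALSE)
  r3 <- aggregate_sample(dim_cells, "ethN", thr)
  expect_identical(r3$grade, "+/-")
  expect_identical(r3$pattern, "negative")
})

test_that("threshold fitting is the midpoint rule and deterministic", {
  sa <- data.frame(au = c(5, 8, 12, 48, 60, 90),
                   label = c(rep("negative", 3), rep("positive", 3)))
  thr <- fit_thresholds(sa, fixation = "ethN")
  expect_equal(thr$positivity_cutoff_au, 30)        # midpoint of 12 and 48
  expect_equal(thr$grade_edges[2], 30)
  expect_error(fit_thresholds(data.frame(au = 1, label = "positive")),
               "both positive and negative")
  # non-separable classes: minimize training misclassifications
  sa2 <- data.frame(au = c(5, 50, 10, 45, 60, 90),
                    label = c("negative", "negative", rep("positive", 4)))
  thr2 <- fit_thresholds(sa2, fixation = "ethN")
  miscls <- sum(sa2$au[sa2$label == "negative"] >= thr2$positivity_cutoff_au) +
    sum(sa2$au[sa2$label == "positive"] < thr2$positivity_cutoff_au)
  expect_lte(miscls, 2)
  expect_identical(thr2$positivity_cutoff_au,
                   fit_thresholds(sa2, fixation = "ethN")$positivity_cutoff_au)
})

test_that("threshold sets round-trip exactly through their JSON config", {
  thr <- default_thresholds("formN")
  thr$positivity_cutoff_au <- 31.257891234567
  p <- file.path(withr::local_tempdir(), "thr.json")
  write_thresholds(thr, p)
  back <- read_thresholds(p)
  expect_equal(back$positivity_cutoff_au, thr$positivity_cutoff_au,
               tolerance = 1e-12)
  expect_equal(back$grade_edges, thr$grade_edges)
  expect_identical(back$fixation, "formN")
})
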