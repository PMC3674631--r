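test_that("an empty spec renders background-only images with empty truth", {
  g <- generate_field(tiny_spec(n_cells = 0, pattern = "negative", seed = 1))
  expect_identical(nrow(g$truth$cells), 0L)
  expect_identical(g$truth$placement_shortfall, 0L)
  # background + noise only: nothing approaches the DAPI nuclear level
  expect_lt(max(g$field$dapi), 8000)
  expect_lt(max(g$field$fitc), 8000)
})

test_that("equal seeds give identical fields; different seeds differ", {
  sp <- tiny_spec(n_cells = 5, pattern = "nuclear", intensity_au = 60,
                  seed = 9)
  a <- generate_field(sp)
  b <- generate_field(sp)
  expect_identical(a$field$dapi, b$field$dapi)
  expect_identical(a$field$fitc, b$field$fitc)
  expect_identical(a$truth$cells, b$truth$cells)
  sp2 <- tiny_spec(n_cells = 5, pattern = "nuclear", intensity_au = 60,
                   seed = 10)
  expect_false(identical(generate_field(sp2)$field$fitc, a$field$fitc))
})

test_that("nuclear pattern renders rim-dominant FITC on the clean render", {
  g <- generate_field(field_spec(n_cells = 12, pattern = "nuclear",
                                 fixation = "ethN", intensity_au = 80,
                                 seed = 7, image_shape = c(512L, 512L)),
                      keep_clean = TRUE)
  expect_identical(nrow(g$truth$cells), 12L)
  bg <- generator_defaults()$background_frac * 65535
  for (k in seq_len(12)) {
    m <- g$truth$masks[[k]]
    rho <- mean(g$truth$clean$fitc[m$rim] - bg) /
      mean(g$truth$clean$fitc[m$cyto] - bg)
    expect_gt(rho, 1)
  }
})

test_that("cytoplasmic pattern renders cytoplasm-dominant FITC", {
  g <- generate_field(tiny_spec(n_cells = 6, pattern = "cytoplasmic",
                                intensity_au = 80, seed = 8),
                      keep_clean = TRUE)
  bg <- generator_defaults()$background_frac * 65535
  for (k in seq_len(6)) {
    m <- g$truth$masks[[k]]
    rho <- mean(g$truth$clean$fitc[m$rim] - bg) /
      mean(g$truth$clean$fitc[m$cyto] - bg)
    expect_lt(rho, 1)
  }
})

test_that("rendered mean cell FITC matches the requested AU calibration", {
  p <- generator_defaults()
  for (pat in c("cytoplasmic", "nuclear", "atypical")) {
    g <- generate_field(tiny_spec(n_cells = 4, pattern = pat,
                                  intensity_au = 70, seed = 31),
                        keep_clean = TRUE)
    bg <- p$background_frac * 65535
    for (k in seq_len(4)) {
      m <- g$truth$masks[[k]]
      px <- c(m$nucleus, m$rim, m$cyto)
      cell_mean <- mean(g$truth$clean$fitc[px] - bg)
      expect_equal(cell_mean, g$truth$cells$au[k] * p$gain,
                   tolerance = 1e-6)
    }
  }
})

test_that("formalin fixation renders nuclear-type input as cytoplasmic", {
  g <- generate_field(tiny_spec(n_cells = 4, pattern = "nuclear",
                                fixation = "formN", intensity_au = 80,
                                seed = 12), keep_clean = TRUE)
  expect_identical(unique(g$truth$cells$pattern), "cytoplasmic")
  expect_identical(unique(g$truth$cells$requested_pattern), "nuclear")
  bg <- generator_defaults()$background_frac * 65535
  m <- g$truth$masks[[1]]
  rho <- mean(g$truth$clean$fitc[m$rim] - bg) /
    mean(g$truth$clean$fitc[m$cyto] - bg)
  expect_lt(rho, 1)
})

test_that("ground-truth records match rendered connected components", {
  g <- generate_field(field_spec(n_cells = 7, pattern = "cytoplasmic",
                                 intensity_au = 60, seed = 19,
                                 image_shape = c(512L, 512L),
                                 n_aggregates = 1), keep_clean = TRUE)
  dapi <- g$truth$clean$dapi
  comp <- EBImage::bwlabel(EBImage::Image((dapi > 8000) * 1))
  n_comp <- as.integer(max(comp))
  n_singles <- sum(!g$truth$cells$is_aggregate)
  n_clumps <- length(unique(stats::na.omit(g$truth$cells$clump)))
  expect_identical(n_comp, n_singles + n_clumps)
  # non-aggregate nucleus pixel sets are pairwise disjoint
  idx <- unlist(lapply(g$truth$masks[!g$truth$cells$is_aggregate],
                       `[[`, "nucleus"))
  expect_identical(anyDuplicated(idx), 0L)
})

test_that("pattern separability narrows as read noise grows", {
  # rim/cytoplasm ratio measured on the generator's own ground-truth zones,
  # so the overlap reflects the noise knob alone, not segmentation
  margin <- function(noise_frac) {
    rhos <- function(pat) {
      g <- generate_field(tiny_spec(
        n_cells = 5, pattern = pat, intensity_au = 60, seed = 77,
        pars = list(read_noise_frac = noise_frac)))
      bg <- generator_defaults()$background_frac * 65535
      vapply(g$truth$masks, function(m)
        mean(pmax(g$field$fitc[m$rim] - bg, 0)) /
          (mean(pmax(g$field$fitc[m$cyto] - bg, 0)) + 1e-6), numeric(1))
    }
    min(rhos("nuclear")) - max(rhos("cytoplasmic"))
  }
  m <- vapply(c(0.01, 0.05, 0.12), margin, numeric(1))
  expect_gt(m[1], 0)             # default noise: distributions do not overlap
  expect_true(all(diff(m) < 0))  # overlap grows with the noise knob
})

test_that("five-field samples pool at least twenty cells and are reproducible", {
  s <- generate_sample("cytoplasmic", "++", "ethN", seed = 5,
                       image_shape = c(256L, 256L))
  expect_length(s, 5L)
  expect_gte(sum(vapply(s, function(f) nrow(f$truth$cells), integer(1))), 20L)
  s2 <- generate_sample("cytoplasmic", "++", "ethN", seed = 5,
                        image_shape = c(256L, 256L))
  for (i in 1:5)
    expect_identical(s[[i]]$field$fitc, s2[[i]]$field$fitc)
})

test_that("cohort specifications follow the requested design", {
  coh <- generate_cohort(70, 100, "ethN", seed = 1)
  expect_identical(nrow(coh), 170L)
  expect_identical(sum(coh$label == "positive"), 70L)
  expect_identical(sum(coh$pattern == "cytoplasmic"), 50L)
  expect_identical(sum(coh$pattern == "nuclear"), 20L)
  expect_true(all(coh$pattern[coh$label == "negative"] == "negative"))
  coh2 <- generate_cohort(0, 3, "formN", seed = 2)
  expect_identical(nrow(coh2), 3L)
  expect_true(all(coh2$label == "negative"))
  # deterministic given the seed
  expect_identical(coh, generate_cohort(70, 100, "ethN", seed = 1))
})

test_that("fixtures round-trip exactly through TIFF plus sidecar", {
  g <- generate_field(tiny_spec(n_cells = 3, pattern = "atypical",
                                intensity_au = 50, seed = 23))
  tf <- file.path(withr::local_tempdir(), "field.tif")
  write_fixture(g$field, g$truth, tf)
  r <- read_field(tf)
  expect_true(all(r$dapi == g$field$dapi))
  expect_true(all(r$fitc == g$field$fitc))
  # sidecar reproduces the generating spec
  sc <- r$metadata$truth$spec
  expect_identical(as.integer(sc$seed), 23L)
  expect_identical(sc$pattern, "atypical")
  expect_identical(as.integer(sc$n_cells), 3L)
  # written file is a 2-page 16-bit grey TIFF
  pages <- tiff::readTIFF(tf, all = TRUE, info = TRUE, as.is = TRUE)
  expect_length(pages, 2L)
  expect_identical(attr(pages[[1]], "bits.per.sample"), 16L)
  # identical seeds give byte-identical files
  tf2 <- file.path(withr::local_tempdir(), "field2.tif")
  write_fixture(generate_field(tiny_spec(n_cells = 3, pattern = "atypical",
                                         intensity_au = 50, seed = 23))$field,
                g$truth, tf2)
  expect_identical(unname(tools::md5sum(tf)), unname(tools::md5sum(tf2)))
})
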