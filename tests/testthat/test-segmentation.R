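test_that("blank and noise-only fields yield empty masks", {
  expect_false(any(threshold_nuclei(matrix(0, 64, 64))))
  g <- generate_field(tiny_spec(n_cells = 0, pattern = "negative", seed = 2))
  expect_false(any(threshold_nuclei(g$field$dapi)))
})

test_that("well-separated nuclei segment to the ground-truth count", {
  g <- generate_field(field_spec(n_cells = 12, pattern = "negative", seed = 4,
                                 image_shape = c(512L, 512L)))
  mask <- threshold_nuclei(g$field$dapi)
  comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_identical(as.integer(max(comp)), 12L)
})

test_that("sub-threshold debris below the minimum area is removed", {
  g <- generate_field(tiny_spec(n_cells = 3, pattern = "negative", seed = 6))
  dapi <- g$field$dapi
  # plant a bright speckle of ~50 px, well under the 120 px area gate
  dapi[20:26, 20:27] <- 15000
  mask <- threshold_nuclei(dapi)
  expect_false(any(mask[20:26, 20:27]))
  # the real nuclei survive
  expect_identical(as.integer(max(EBImage::bwlabel(EBImage::Image(mask * 1)))), 3L)
})

test_that("watershed splits touching discs but preserves lobed nuclei", {
  m <- matrix(FALSE, 128, 128)
  RR <- row(m); CC <- col(m)
  r <- 20
  pair <- ((RR - 64)^2 + (CC - 52)^2 <= r^2) |
    ((RR - 64)^2 + (CC - 52 - 1.2 * r)^2 <= r^2)
  expect_identical(max(split_touching(pair, h = 2)), 2L)
  # non-touching objects: label count equals component count
  three <- ((RR - 30)^2 + (CC - 30)^2 <= 100) |
    ((RR - 90)^2 + (CC - 90)^2 <= 100) |
    ((RR - 30)^2 + (CC - 98)^2 <= 100)
  expect_identical(max(split_touching(three, h = 2)), 3L)
  # a single lobed nucleus from the generator stays one object
  g <- generate_field(tiny_spec(n_cells = 1, pattern = "negative", seed = 14))
  lab <- split_touching(threshold_nuclei(g$field$dapi), h = 2)
  expect_identical(max(lab), 1L)
})

test_that("convexity filtering keeps discs and trilobed nuclei, drops clumps", {
  m <- matrix(FALSE, 96, 96)
  disc <- (row(m) - 48)^2 + (col(m) - 48)^2 <= 169
  cells <- filter_objects(split_touching(disc))
  expect_length(cells, 1L)
  expect_gte(cells[[1]]$solidity, 0.99)
  # generator single cells measure well above the 0.80 gate
  g <- generate_field(field_spec(n_cells = 6, pattern = "negative", seed = 16,
                                 image_shape = c(512L, 512L)))
  sc <- segment_field(g$field$dapi)
  expect_length(sc, 6L)
  expect_true(all(vapply(sc, `[[`, numeric(1), "solidity") > 0.80))
  # a fused clump measures below the gate and is excluded
  ga <- generate_field(field_spec(n_cells = 0, pattern = "negative", seed = 18,
                                  image_shape = c(512L, 512L),
                                  n_aggregates = 1))
  sa <- segment_field(ga$field$dapi)
  expect_length(sa, 0L)
  ex <- attr(sa, "excluded")
  expect_identical(ex$reason, "low_solidity_aggregate")
  expect_lt(ex$solidity, 0.80)
})

test_that("filtering is idempotent and never increases the object count", {
  g <- generate_field(field_spec(n_cells = 5, pattern = "negative", seed = 22,
                                 image_shape = c(512L, 512L),
                                 n_aggregates = 1))
  labels <- split_touching(threshold_nuclei(g$field$dapi))
  cells <- filter_objects(labels)
  expect_lte(length(cells), max(labels))
  # rebuild a label image holding only kept nuclei and refilter
  relab <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(cells)) relab[cells[[i]]$nucleus] <- i
  cells2 <- filter_objects(relab)
  expect_identical(length(cells2), length(cells))
  expect_identical(lapply(cells2, `[[`, "nucleus"),
                   lapply(cells, `[[`, "nucleus"))
})

test_that("zones are disjoint distance bands with near-analytic areas", {
  m <- matrix(FALSE, 64, 64)
  disc <- (row(m) - 32)^2 + (col(m) - 32)^2 <= 100
  z <- zone_decomposition(disc, r_rim = 3, r_cyto = 12)
  expect_false(any(z$rim & disc))
  expect_false(any(z$rim & z$cytoplasm))
  expect_false(any(z$cytoplasm & disc))
  # the rim equals the dilation difference computed independently, with a
  # structuring element built from the same Euclidean disc criterion
  kern <- matrix(0, 7, 7)
  kern[(row(kern) - 4)^2 + (col(kern) - 4)^2 <= 9] <- 1
  dil <- as.matrix(EBImage::dilate(EBImage::Image(disc * 1), kern)) > 0
  expect_true(all(z$rim == (dil & !disc)))
  # pixel count close to the continuous annulus pi(13^2 - 10^2); the lattice
  # band is biased slightly narrow (about half a pixel per boundary)
  expect_lt(abs(sum(z$rim) - pi * (13^2 - 10^2)) / (pi * (13^2 - 10^2)), 0.075)
  expect_error(zone_decomposition(matrix(FALSE, 8, 8)), "empty")
})

test_that("zone areas grow monotonically with their radii", {
  m <- matrix(FALSE, 80, 80)
  disc <- (row(m) - 40)^2 + (col(m) - 40)^2 <= 100
  rims <- vapply(c(2, 3, 5), function(r)
    sum(zone_decomposition(disc, r_rim = r, r_cyto = 20)$rim), numeric(1))
  cytos <- vapply(c(8, 12, 16), function(r)
    sum(zone_decomposition(disc, r_rim = 3, r_cyto = r)$cytoplasm), numeric(1))
  expect_true(all(diff(rims) > 0))
  expect_true(all(diff(cytos) > 0))
})

test_that("adjacent cells never share zone pixels (nearest-nucleus rule)", {
  g <- generate_field(tiny_spec(n_cells = 2, pattern = "negative", seed = 25,
                                pars = list(min_sep = 40)))
  cells <- segment_field(g$field$dapi)
  expect_length(cells, 2L)
  all_zone <- c(cells[[1]]$rim, cells[[1]]$cytoplasm,
                cells[[2]]$rim, cells[[2]]$cytoplasm)
  expect_identical(anyDuplicated(all_zone), 0L)
})
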