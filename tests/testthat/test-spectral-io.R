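test_that("raw 16-bit cubes round trip bit-exactly through TIFF + sidecar", {
  set.seed(11)
  px <- array(sample(0:65535, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
  edges <- rbind(c(450, 465), c(470, 485), c(490, 505))
  cube <- spectral_cube(px, edges, kind = "raw")
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$kind, "raw")
  expect_identical(back$band_edges, cube$band_edges)
  expect_true(all(back$pixels == px))
})

test_that("transmittance cubes (values above 1 included) round trip through float TIFF", {
  set.seed(12)
  px <- array(runif(4 * 4 * 3, 0, 1.04), c(4, 4, 3))
  cube <- spectral_cube(px, rbind(c(450, 465), c(470, 485), c(490, 505)),
    kind = "transmittance"
  )
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$kind, "transmittance")
  expect_equal(back$pixels, px, tolerance = 1e-6)
})

test_that("a degenerate single-band zero cube reads back as written", {
  cube <- spectral_cube(array(0, c(2, 2, 1)), cbind(450, 455), kind = "raw")
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_equal(dim(back$pixels), c(2, 2, 1))
  expect_true(all(back$pixels == 0))
})

test_that("page/sidecar count mismatch and malformed grids are format errors", {
  cube <- random_cube()
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  write_wavelength_sidecar(paste0(path, ".wl"), rbind(c(450, 465), c(470, 485)),
    kind = "transmittance"
  )
  expect_error(read_cube(path), class = "eospec_error_format")
  expect_error(
    spectral_cube(array(0, c(2, 2, 2)), rbind(c(470, 485), c(450, 465))),
    class = "eospec_error_format"
  )
  expect_error(
    spectral_cube(array(0, c(2, 2, 2)), rbind(c(450, 480), c(470, 485))),
    class = "eospec_error_format"
  )
})

test_that("the 55-band instrument sidecar reads as 55 point-sampled bands", {
  path <- withr::local_tempfile(fileext = ".wl")
  write_wavelength_sidecar(path, grid_55band())
  side <- read_wavelength_sidecar(path)
  expect_equal(nrow(side$band_edges), 55L)
  expect_equal(side$band_edges[, 1], seq(450, 720, by = 5), ignore_attr = TRUE)
  expect_equal(side$band_edges[, 1], side$band_edges[, 2], ignore_attr = TRUE)
})

test_that("transmittance is the per-band specimen/reference ratio", {
  set.seed(13)
  edges <- cbind(450 + 20 * 0:4, 465 + 20 * 0:4)
  sig <- array(runif(2 * 2 * 5, 100, 60000), c(2, 2, 5))
  specimen <- spectral_cube(sig, edges, kind = "raw")

  # specimen == reference -> transmittance 1 (white-area behaviour)
  same <- compute_transmittance(specimen, specimen)
  expect_equal(same$pixels, array(1, c(2, 2, 5)))
  expect_identical(same$kind, "transmittance")

  # zero specimen -> zero transmittance
  zero <- spectral_cube(array(0, c(2, 2, 5)), edges, kind = "raw")
  expect_equal(compute_transmittance(zero, specimen)$pixels, array(0, c(2, 2, 5)))

  # random case matches elementwise division, vector and cube references
  ref_vec <- runif(5, 1000, 50000)
  tr <- compute_transmittance(specimen, ref_vec)
  expect_equal(tr$pixels, sweep(sig, 3, ref_vec, "/"), tolerance = 1e-12)
  ref_cube <- spectral_cube(array(runif(20, 100, 60000), c(2, 2, 5)), edges, "raw")
  tr2 <- compute_transmittance(specimen, ref_cube)
  expect_equal(tr2$pixels, sig / ref_cube$pixels, tolerance = 1e-12)
  expect_identical(tr2$band_edges, specimen$band_edges)

  expect_error(compute_transmittance(specimen, runif(4)),
    class = "eospec_error_dimension"
  )
})

test_that("zero reference entries are floored, not divided by", {
  edges <- cbind(c(450, 470), c(465, 485))
  specimen <- spectral_cube(array(1, c(1, 1, 2)), edges, "raw")
  tr <- compute_transmittance(specimen, c(0, 1))
  expect_true(all(is.finite(tr$pixels)))
  expect_equal(tr$pixels[1, 1, 1], 1 / (1e-6 * 1))
})

test_that("optional clipping clamps transmittance to [0, 1.05]", {
  edges <- cbind(450, 465)
  specimen <- spectral_cube(array(3, c(1, 1, 1)), edges, "raw")
  expect_equal(compute_transmittance(specimen, 1)$pixels[1, 1, 1], 3)
  expect_equal(compute_transmittance(specimen, 1, clip = TRUE)$pixels[1, 1, 1], 1.05)
})

test_that("band averaging groups sequentially with a partial final group", {
  set.seed(14)
  # 1x1x7 spectrum, groups {1-3},{4-6},{7}
  v <- runif(7)
  cube <- spectral_cube(
    array(v, c(1, 1, 7)),
    cbind(450 + 10 * 0:6, 455 + 10 * 0:6), "transmittance"
  )
  out <- band_average(cube, 3)
  expect_equal(dim(out$pixels)[3], 3L)
  expect_equal(
    as.numeric(out$pixels[1, 1, ]),
    c(mean(v[1:3]), mean(v[4:6]), v[7])
  )
  expect_equal(out$band_edges[, 1], c(450, 480, 510), ignore_attr = TRUE)
  expect_equal(out$band_edges[, 2], c(475, 505, 515), ignore_attr = TRUE)

  # constant spectra are unchanged by averaging
  const <- spectral_cube(array(0.7, c(2, 2, 7)), cube$band_edges, "transmittance")
  expect_true(all(band_average(const, 2)$pixels == 0.7))

  # group_size 1 is the identity
  same <- band_average(cube, 1)
  expect_equal(same$pixels, cube$pixels)
  expect_equal(same$band_edges, cube$band_edges)

  expect_error(band_average(cube, 8), class = "eospec_error_parameter")
  expect_error(band_average(cube, 0), class = "eospec_error_parameter")
})

test_that("averaging the 55-band grid in fours reproduces the 14-band table", {
  set.seed(15)
  cube <- spectral_cube(array(runif(2 * 2 * 55), c(2, 2, 55)), grid_55band(),
    kind = "transmittance"
  )
  out <- band_average(cube, 4)
  expect_equal(dim(out$pixels)[3], 14L)
  expect_equal(out$band_edges, grid_14band(), ignore_attr = TRUE)
  # last group averages the remaining 3 bands
  expect_equal(
    out$pixels[, , 14],
    (cube$pixels[, , 53] + cube$pixels[, , 54] + cube$pixels[, , 55]) / 3
  )
})

test_that("band averaging commutes with transmittance for group-constant references", {
  set.seed(16)
  edges <- cbind(450 + 5 * 0:7, 455 + 5 * 0:7)
  sig <- array(runif(3 * 3 * 8, 100, 60000), c(3, 3, 8))
  specimen <- spectral_cube(sig, edges, "raw")
  ref <- rep(runif(2, 1000, 50000), each = 4) # constant within each group of 4
  ref_cube <- spectral_cube(
    array(rep(ref, each = 9), c(3, 3, 8)), edges, "raw"
  )
  a <- band_average(compute_transmittance(specimen, ref), 4)
  b <- compute_transmittance(band_average(specimen, 4), band_average(ref_cube, 4))
  expect_equal(a$pixels, b$pixels, tolerance = 1e-12)
})

test_that("labeled spectra extraction is per-pixel, per-class, row-major", {
  set.seed(17)
  h <- 10L
  w <- 10L
  cube <- random_cube(h, w, 4)
  labels <- matrix(0L, h, w)
  classes <- c("nucleus", "cytoplasm", "rbc", "fiber", "white")
  for (k in seq_along(classes)) labels[k, 1:10] <- k # 10 px per class
  mask <- roi_mask(labels, stats::setNames(classes, 1:5))

  out <- extract_labeled_spectra(cube, mask, classes)
  expect_equal(ncol(out$spectra), 50L)
  expect_equal(as.vector(table(out$labels)[classes]), rep(10L, 5))

  # single labeled pixel comes back verbatim
  one <- matrix(0L, h, w)
  one[3, 7] <- 1L
  single <- extract_labeled_spectra(cube, roi_mask(one, c("1" = "rbc")), "rbc")
  expect_equal(as.numeric(single$spectra[, 1]), as.numeric(cube$pixels[3, 7, ]))

  # row-major order: pixels of row k come out in column order
  first_class <- out$spectra[, out$labels == "nucleus"]
  expected <- t(sapply(1:4, function(b) cube$pixels[1, 1:10, b]))
  expect_equal(unname(first_class), unname(expected))

  # empty class warns; all-empty errors
  two <- roi_mask(one, c("1" = "rbc", "2" = "fiber"))
  expect_warning(res <- extract_labeled_spectra(cube, two, c("rbc", "fiber")))
  expect_equal(ncol(res$spectra), 1L)
  empty <- roi_mask(matrix(0L, h, w), c("1" = "rbc"))
  expect_error(
    suppressWarnings(extract_labeled_spectra(cube, empty, "rbc")),
    class = "eospec_error_data"
  )
  expect_error(extract_labeled_spectra(cube, mask, "vessel"),
    class = "eospec_error_parameter"
  )
})

test_that("phantom class means recovered from extracted spectra match the endmembers", {
  scene <- small_phantom(seed = 3L)
  dyes <- he_dye_spectra(scene$cube$band_edges)
  models <- scene$params$config$models
  spectra <- extract_labeled_spectra(
    scene$cube, scene$truth,
    c("nucleus", "cytoplasm", "rbc", "white")
  )
  for (cl in unique(spectra$labels)) {
    got <- rowMeans(spectra$spectra[, spectra$labels == cl, drop = FALSE])
    want <- endmember_transmittance(models[[cl]], dyes)
    # within-class cv 2% + sensor noise 0.5%: class means sit well within one sd
    expect_lt(max(abs(got - want) / want), 0.021)
  }
})

test_that("the phantom's white area transmits 1 up to noise", {
  scene <- small_phantom(seed = 4L)
  white <- scene$truth$labels == 5L
  for (b in c(1L, 7L, 14L)) {
    plane <- scene$cube$pixels[, , b]
    expect_lt(abs(mean(plane[white]) - 1), 0.01)
  }
})

test_that("label masks round trip through PNG", {
  labels <- matrix(sample(0:6, 48, replace = TRUE), 6, 8)
  path <- withr::local_tempfile(fileext = ".png")
  cn <- stats::setNames(
    c("nucleus", "cytoplasm", "rbc", "fiber", "white", "eosinophil"), 1:6
  )
  write_label_mask(roi_mask(labels, cn), path)
  back <- read_label_mask(path, cn)
  expect_identical(back$labels, labels)
})
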