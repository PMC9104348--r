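# tiny handcrafted dataset: 4 pixels, peaks at known m/z
tiny_msi <- function() {
  coords <- data.frame(x = c(1, 2, 1, 2), y = c(1, 1, 2, 2))
  mz <- list(c(200, 700), c(200, 700), c(200, 500), c(500, 700))
  int <- list(c(10, 40), c(20, 80), c(30, 30), c(5, 5))
  msi_dataset(coords, mz, int, mz_range = c(150, 1200))
}

test_that("msi_dataset validates coordinates and spectra", {
  expect_error(msi_dataset(data.frame(x = integer(0), y = integer(0)),
                           list(), list()), "empty pixel")
  d <- tiny_msi()
  expect_equal(nrow(d$coords), 4)
  bad <- data.frame(x = c(1, 1), y = c(1, 1))
  expect_error(msi_dataset(bad, list(1, 1), list(1, 1)), "unique")
  expect_error(msi_dataset(data.frame(x = 1, y = 1), list(c(2, 1)), list(c(1, 1))),
               "ascending")
})

test_that("TIC normalisation yields unit-sum pixels, preserving ratios", {
  d <- tiny_msi()
  tn <- tic_normalize(d)
  sums <- vapply(tn$dataset$intensity, sum, numeric(1))
  expect_equal(sums, rep(1, 4), tolerance = 1e-12)
  # relative intensities within a pixel unchanged
  expect_equal(tn$dataset$intensity[[1]][2] / tn$dataset$intensity[[1]][1],
               d$intensity[[1]][2] / d$intensity[[1]][1])
  # doubling all raw intensities of a pixel leaves its normalised spectrum
  d2 <- d
  d2$intensity[[1]] <- d2$intensity[[1]] * 2
  tn2 <- tic_normalize(d2)
  expect_equal(tn2$dataset$intensity[[1]], tn$dataset$intensity[[1]])
  # all-zero pixel excluded and reported
  d3 <- d
  d3$intensity[[4]] <- c(0, 0)
  tn3 <- tic_normalize(d3)
  expect_equal(tn3$excluded, 4L)
  expect_equal(nrow(tn3$dataset$coords), 3)
})

test_that("ion images window correctly and add up to the TIC image", {
  d <- tiny_msi()
  img <- ion_image(d, 700, window_da = 0.001)
  expect_equal(img$intensity, c(40, 80, 0, 5))
  # a window missing the peak by 0.002 returns zeros
  expect_equal(ion_image(d, 700.002, window_da = 0.001)$intensity,
               rep(0, 4))
  expect_error(ion_image(d, 700, window_da = 0), "positive")
  # additivity: images over a partition of the axis sum to the TIC
  tic <- vapply(d$intensity, sum, numeric(1))
  parts <- ion_image(d, 200, 0.5)$intensity +
    ion_image(d, 500, 0.5)$intensity + ion_image(d, 700, 0.5)$intensity
  expect_equal(parts, tic)
})

test_that("pixel matrix columns are flattened ion images", {
  d <- tiny_msi()
  pm <- build_pixel_matrix(d, c(700, 999), tol_da = 0.001)
  expect_equal(dim(pm), c(4, 2))
  expect_equal(unname(pm[, 1]), ion_image(d, 700, 0.001)$intensity)
  expect_equal(attr(pm, "empty_columns"), 2L)
  expect_error(build_pixel_matrix(d, numeric(0)), "empty")
})

test_that("bisecting k-means: k=1 trivial, separable populations exact", {
  set.seed(3)
  d <- tiny_msi()
  pm <- build_pixel_matrix(d, c(200, 500, 700), tol_da = 0.5)
  seg1 <- bisecting_kmeans_segment(pm, k = 1)
  expect_equal(seg1$cluster, rep(0L, 4))
  # two well-separated planted populations
  pop <- rbind(matrix(rep(c(100, 1), each = 20), 20),
               matrix(rep(c(1, 100), each = 20), 20))
  pop <- pop + matrix(runif(80), 40, 2)
  seg <- bisecting_kmeans_segment(pop, k = 2, seed = 5)
  truth <- rep(0:1, each = 20)
  expect_equal(mclust::adjustedRandIndex(seg$cluster, truth), 1)
  expect_error(bisecting_kmeans_segment(pop, k = 50), "exceeds")
})

test_that("segmentation is seeded-deterministic with decreasing split SSE", {
  ph <- generate_msi_phantom(25, 25, 30, seed = 4)
  pm <- build_pixel_matrix(ph$dataset, ph$truth$mz)
  a <- bisecting_kmeans_segment(pm, k = 4, seed = 11)
  b <- bisecting_kmeans_segment(pm, k = 4, seed = 11)
  expect_identical(a$cluster, b$cluster)
  expect_true(all(a$split_tree$sse_after < a$split_tree$sse_before))
  # contiguous ids from 0
  expect_setequal(unique(a$cluster), 0:3)
})

test_that("three-region phantom is recovered at k=3", {
  ph <- generate_msi_phantom(30, 30, 50, seed = 7)
  pm <- build_pixel_matrix(ph$dataset, ph$truth$mz)
  seg <- bisecting_kmeans_segment(pm, k = 3, seed = 7)
  ari <- mclust::adjustedRandIndex(seg$cluster, ph$truth$region)
  expect_gte(ari, 0.9)
})

test_that("raising between-region contrast raises recovery at fixed noise", {
  aris <- vapply(c(0.5, 1.5, 3), function(contrast) {
    eff <- list(healthy = 1,
                HGSC = 2^(contrast * c(1, -1, 1, -1, 1) / 2),
                necrotic = 2^(contrast * c(-1, 1, -1, 1, -1) / 2))
    ph <- generate_msi_phantom(20, 20, 5, region_effects = eff, seed = 21,
                               mean_counts = 60)
    pm <- build_pixel_matrix(ph$dataset, ph$truth$mz)
    seg <- bisecting_kmeans_segment(pm, k = 3, seed = 3)
    mclust::adjustedRandIndex(seg$cluster, ph$truth$region)
  }, numeric(1))
  expect_true(all(diff(aris) >= -1e-9))
  expect_gt(aris[3], aris[1])
})

test_that("tissue effects planted at 3x serum stay in the 2-7x envelope", {
  # serum-scale planted log2 fold changes for 10 features
  serum_fc <- c(0.5, -0.6, 0.8, -0.4, 0.7, -0.9, 0.45, -0.5, 0.65, -0.7)
  eff <- list(healthy = 1, HGSC = 2^(3 * serum_fc), necrotic = 1)
  ph <- generate_msi_phantom(24, 24, 10, region_effects = eff, seed = 13,
                             mean_counts = 2000)
  pm <- build_pixel_matrix(ph$dataset, ph$truth$mz)
  tissue_fc <- region_log2fc(pm, ph$truth$region, "HGSC", "healthy")
  amp <- mean(abs(tissue_fc)) / mean(abs(serum_fc))
  expect_gte(amp, 2)
  expect_lte(amp, 7)
})

test_that("region fold changes behave on identity and planted cases", {
  pm <- matrix(c(8, 8, 2, 2, 4, 4, 4, 4), 4, 2)
  labels <- c("A", "A", "B", "B")
  expect_equal(unname(region_log2fc(pm, labels, "A", "A")), c(0, 0))
  expect_equal(unname(region_log2fc(pm, labels, "A", "B")), c(2, 0))
  expect_error(region_log2fc(pm, labels, "A", "nope"), "empty region")
})

test_that("imzML round-trips through disk within storage precision", {
  ph <- generate_msi_phantom(8, 6, 12, seed = 5)
  d <- withr::local_tempdir()
  path <- file.path(d, "phantom.imzML")
  write_imzml(ph$dataset, path)
  expect_true(file.exists(file.path(d, "phantom.ibd")))
  back <- load_imzml(path)
  expect_equal(nrow(back$coords), nrow(ph$dataset$coords))
  # m/z stored as 64-bit: exact; intensity as 32-bit float
  expect_identical(back$mz, ph$dataset$mz)
  for (i in seq_along(back$intensity)) {
    expect_equal(back$intensity[[i]], ph$dataset$intensity[[i]],
                 tolerance = 1e-6)
  }
  expect_equal(back$polarity, "-")
  # structural sanity of the XML itself
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "mzML")
  expect_error(load_imzml(file.path(d, "missing.imzML")), "not found")
  file.remove(file.path(d, "phantom.ibd"))
  expect_error(load_imzml(path), "binary file not found")
})

test_that("region raster writes a readable plain-text map", {
  ph <- generate_msi_phantom(6, 4, 3, seed = 2)
  d <- withr::local_tempdir()
  p <- file.path(d, "regions.txt")
  write_region_raster(ph$dataset$coords, ph$truth$region, p)
  lines <- readLines(p)
  expect_length(lines, 4)
  expect_equal(length(strsplit(lines[1], "\t")[[1]]), 6)
})
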