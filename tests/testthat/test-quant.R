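# Hounsfield tissue-fraction mass and voxel-counting volume quantification.

test_that("tissue fraction hits the decomposition endpoints exactly", {
  expect_equal(as.vector(tissue_fraction(-1000)), 0)
  expect_equal(as.vector(tissue_fraction(50)), 1)
  expect_equal(as.vector(tissue_fraction(-475)), 0.5)
  expect_error(tissue_fraction(NaN), "finite")
})

test_that("out-of-range HU values are clamped and counted", {
  tf <- tissue_fraction(c(-1200, -1000, 0, 60, 50))
  expect_equal(as.vector(tf), c(0, 0, 1000 / 1050, 1, 1))
  expect_identical(attr(tf, "n_clamped"), 2L)
})

test_that("voxel mass follows the density product rule", {
  vox <- 0.625 * 0.625 * 0.5 * 1e-3 # clinical voxel in cm^3
  expect_equal(as.vector(voxel_mass(50, vox)), vox * 1.053)
  expect_equal(as.vector(voxel_mass(50, vox)), 2.05664062e-4,
               tolerance = 1e-8)
  expect_equal(as.vector(voxel_mass(-1000, 1)), 0)
  expect_equal(as.vector(voxel_mass(-475, 1)), 0.5265)
  expect_error(voxel_mass(0, -1), "positive")
})

test_that("measurements reproduce the closed form on uniform volumes", {
  dm <- c(100, 100, 100) # one million voxels
  vol <- image_volume(array(50, dm), spacing = c(0.625, 0.625, 0.5))
  labs <- label_map(array(3L, dm), spacing = c(0.625, 0.625, 0.5))
  m <- measure_lobes(vol, labs)
  expect_equal(m$volume_ml[m$region == "RUL"], 195.3125)
  expect_equal(m$mass_g[m$region == "RUL"], 205.6640625)
  expect_equal(m$mass_g[m$region == "GLOBAL"], 205.6640625)
  expect_equal(m$mass_g[m$region == "LUL"], 0) # empty lobe, no error
  expect_equal(m$voxels[m$region == "LUL"], 0)
})

test_that("lobar masses and volumes always sum to the global row", {
  withr::local_seed(11)
  for (rep in 1:5) {
    dm <- c(12, 12, 12)
    vol <- image_volume(array(runif(prod(dm), -1024, 60), dm))
    labs <- label_map(array(sample(0:6, prod(dm), TRUE), dm))
    m <- measure_lobes(vol, labs)
    expect_equal(m$mass_g[7], sum(m$mass_g[1:6]), tolerance = 1e-12)
    expect_identical(m$voxels[7], sum(m$voxels[1:6])) # counts are exact
    expect_equal(m$volume_ml[7], sum(m$volume_ml[1:6]), tolerance = 1e-15)
    expect_true(all(m$mass_g >= 0))
  }
})

test_that("mass is linear in the air-referenced HU scale before clamping", {
  withr::local_seed(4)
  dm <- c(10, 10, 10)
  hu <- array(runif(prod(dm), -1000, 50), dm)
  labs <- label_map(array(1L, dm))
  m1 <- measure_lobes(image_volume(hu), labs)
  alpha <- 0.4
  m2 <- measure_lobes(image_volume(-1000 + alpha * (hu + 1000)), labs)
  expect_equal(m2$mass_g[7], alpha * m1$mass_g[7], tolerance = 1e-12)
})

test_that("volume depends only on voxel counts and spacing", {
  dm <- c(10, 10, 10)
  labs <- label_map(array(2L, dm), spacing = c(0.625, 0.625, 0.5))
  a <- measure_lobes(image_volume(array(-900, dm), c(0.625, 0.625, 0.5)), labs)
  b <- measure_lobes(image_volume(array(49, dm), c(0.625, 0.625, 0.5)), labs)
  expect_identical(a$volume_ml, b$volume_ml)
  expect_error(
    measure_lobes(image_volume(array(0, c(9, 10, 10))), labs),
    "share grid")
})
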