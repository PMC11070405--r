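# Synthetic phantom generator: determinism, partition structure, ground
# truth consistency, and the acquisition/observer perturbation models.

test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- phantom_spec(shape = c(48, 48, 48))
  a <- generate_phantom(spec, seed = 17)
  b <- generate_phantom(spec, seed = 17)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels$data, b$truth$labels$data)
  expect_identical(a$truth$centerline, b$truth$centerline)
  c <- generate_phantom(spec, seed = 18)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("truth labels tile the lung and trees stay inside it", {
  ph <- small_phantom()
  lab <- ph$truth$labels$data
  lung <- lab > 0L
  expect_setequal(unique(as.vector(lab)), 0:6)
  # per-lobe voxel counts add up to the lung exactly (partition identity)
  expect_identical(sum(sapply(1:6, function(l) sum(lab == l))), sum(lung))
  expect_true(all(lab[ph$truth$tree_mask$data] > 0L))
  # centerline points lie on the tree, seeds on the centerline of their lobe
  cl <- ph$truth$centerline
  expect_true(all(ph$truth$tree_mask$data[cbind(cl$i, cl$j, cl$k)]))
  sd <- ph$truth$seeds
  expect_identical(sd$lobe_label, 1:6)
  expect_true(all(ph$truth$tree_mask$data[cbind(sd$i, sd$j, sd$k)]))
})

test_that("noise-free phantoms have exactly two HU levels inside the lung", {
  ph <- constant_phantom()
  lung <- ph$truth$labels$data > 0L
  expect_identical(sort(unique(as.vector(ph$volume$data[lung]))), c(-750, 30))
})

test_that("truth masses equal the closed-form decomposition on noise-free phantoms", {
  ph <- constant_phantom()
  meas <- measure_lobes(ph$volume, ph$truth$labels)
  truth <- ph$truth$measurements
  expect_equal(meas$mass_g, truth$mass_g, tolerance = 1e-12)
  expect_equal(meas$volume_ml, truth$volume_ml, tolerance = 1e-12)
  # global equals the sum of the lobes by construction
  expect_equal(truth$mass_g[7], sum(truth$mass_g[1:6]), tolerance = 1e-12)
})

test_that("re-acquisition with zero perturbation is the identity", {
  ph <- constant_phantom()
  spec0 <- phantom_spec(shape = c(64, 64, 64), reacq_noise_sd = 0,
                        reacq_motion_voxels = 0, reacq_drift_hu = c(0, 0))
  again <- simulate_reacquisition(ph$volume, spec0, seed = 2)
  expect_identical(again$data, ph$volume$data)
})

test_that("pure HU drift shifts the lung mean by exactly the drift", {
  ph <- constant_phantom()
  spec_d <- phantom_spec(shape = c(64, 64, 64), reacq_noise_sd = 0,
                         reacq_motion_voxels = 0, reacq_drift_hu = c(10, 10))
  shifted <- simulate_reacquisition(ph$volume, spec_d, seed = 2)
  lung <- ph$truth$labels$data > 0L
  expect_equal(mean(shifted$data[lung]) - mean(ph$volume$data[lung]), 10,
               tolerance = 1e-6)
})

test_that("re-acquisition is deterministic per seed and attaches its motion", {
  ph <- small_phantom()
  spec <- ph$truth$spec
  a <- simulate_reacquisition(ph$volume, spec, seed = 5)
  b <- simulate_reacquisition(ph$volume, spec, seed = 5)
  expect_identical(a$data, b$data)
  tr <- attr(a, "transform")
  expect_s3_class(tr, "rigid_transform")
  expect_lte(max(abs(tr$translation / spec$spacing)), spec$reacq_motion_voxels)
})

test_that("observer jitter keeps seeds on the tree and respects the radius", {
  ph <- small_phantom()
  expect_identical(simulate_observer_variation(ph$truth, seed = 1, radius = 0),
                   ph$truth$seeds)
  j <- simulate_observer_variation(ph$truth, seed = 1, radius = 2)
  expect_identical(j, simulate_observer_variation(ph$truth, seed = 1, radius = 2))
  expect_true(all(ph$truth$tree_mask$data[cbind(j$i, j$j, j$k)]))
  d <- sqrt((j$i - ph$truth$seeds$i)^2 + (j$j - ph$truth$seeds$j)^2 +
              (j$k - ph$truth$seeds$k)^2)
  expect_lte(max(d), 2)
})

test_that("phantom artifacts round-trip through disk", {
  dir <- withr::local_tempdir()
  ph <- constant_phantom()
  write_phantom(ph, dir)
  lab <- read_volume(file.path(dir, "truth_labels.nii.gz"), "labels")
  expect_identical(lab$data, ph$truth$labels$data)
  seeds <- read_seeds(file.path(dir, "seeds.csv"))
  expect_equal(seeds, ph$truth$seeds, ignore_attr = TRUE)
})
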