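# Fast-marching arrival maps and argmin lobar assignment.

test_that("arrival times are exact for axis-aligned propagation", {
  bm <- binary_mask(array(TRUE, c(21, 21, 21)))
  seeds <- seed_set(1, 11, 11, 11)
  tm <- fast_march(bm, seeds)
  expect_equal(tm[12, 11, 11], 1.0)
  expect_equal(tm[11, 10, 11], 1.0)
  expect_equal(tm[21, 11, 11], 10.0) # axis-aligned is exact at any range
  expect_equal(tm[11, 11, 1], 10.0)
  expect_equal(tm[11, 11, 11], 0.0)
  expect_true(all(tm >= 0))
})

test_that("arrival maps respect anisotropic spacing and the mask", {
  m <- array(TRUE, c(15, 15, 15))
  m[8, , ] <- FALSE # impassable wall ...
  m[8, 8, 8] <- TRUE # ... with a single gate
  bm <- binary_mask(m, spacing = c(0.625, 0.625, 0.5))
  tm <- fast_march(bm, seed_set(1, 4, 8, 8))
  expect_true(all(is.infinite(tm[!m])))
  # through-the-gate distance exceeds the straight-line distance
  expect_gt(tm[12, 2, 2], sqrt(sum((c(12 - 4, 2 - 8, 2 - 8) *
                                      bm$spacing)^2)))
  expect_equal(tm[5, 8, 8], 0.625)
  expect_error(fast_march(bm, seed_set(1, 8, 2, 2)), "outside")
})

test_that("assignment takes the argmin with ties to the lower label", {
  m <- array(TRUE, c(21, 9, 9))
  bm <- binary_mask(m)
  subtrees <- seed_set(c(1, 2), c(6, 16), c(5, 5), c(5, 5))
  lab <- assign_lobes(bm, rbind(subtrees,
                                seed_set(3:6, rep(1, 4), 1:4, rep(1, 4))))
  expect_identical(lab$data[4, 5, 5], 1L)  # strictly closer to seed 1
  expect_identical(lab$data[18, 5, 5], 2L) # strictly closer to seed 2
  expect_identical(lab$data[11, 5, 5], 1L) # exact tie -> lower label
})

test_that("labels tile the lung mask and include every subtree voxel", {
  ph <- small_phantom()
  res <- small_run()
  lab <- res$labels$data
  lung <- res$lung_mask$data
  expect_true(all(lab[lung] >= 1L))
  expect_true(all(lab[!lung] == 0L))
  st <- res$subtrees
  on_lung <- lung[cbind(st$i, st$j, st$k)]
  expect_gte(mean(lab[cbind(st$i, st$j, st$k)][on_lung] ==
                    st$lobe_label[on_lung]), 1)
})

test_that("enlarging a seed set never increases arrival times", {
  withr::local_seed(7)
  m <- random_blob_mask(c(20, 20, 20))
  bm <- binary_mask(m)
  idx <- which(m, arr.ind = TRUE)
  a <- idx[sample.int(nrow(idx), 2), , drop = FALSE]
  b <- rbind(a, idx[sample.int(nrow(idx), 2), , drop = FALSE])
  ta <- fast_march(bm, seed_set(rep(1, 2), a[, 1], a[, 2], a[, 3]))
  tb <- fast_march(bm, seed_set(rep(1, 4), b[, 1], b[, 2], b[, 3]))
  expect_true(all(tb[m] <= ta[m] + 1e-12))
})

test_that("relabeling lobes permutes the assignment on tie-free voxels", {
  ph <- small_phantom()
  res <- small_run()
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  st <- res$subtrees
  st_perm <- st
  st_perm$lobe_label <- perm[st$lobe_label]
  suppressWarnings({
    lab1 <- assign_lobes(res$lung_mask, st)
    lab2 <- assign_lobes(res$lung_mask, st_perm)
  })
  relabeled <- array(0L, dim(lab1$data))
  nz <- lab1$data > 0L
  relabeled[nz] <- perm[lab1$data[nz]]
  # the tie rule (lowest label) is applied after permutation, so only
  # exactly equidistant voxels may differ; everywhere else: identical
  maps <- lapply(1:6, function(l)
    fast_march(res$lung_mask, st[st$lobe_label == l, ]))
  flat <- vapply(maps, as.vector, numeric(length(maps[[1]])))
  gap <- apply(flat[as.vector(nz), ], 1,
               function(r) { s <- sort(r); s[2] - s[1] })
  tie_free <- gap > 0
  expect_identical(relabeled[nz][tie_free], lab2$data[nz][tie_free])
  expect_gte(mean(relabeled[nz] == lab2$data[nz]), 0.995)
})

test_that("running argmin equals materialising all six maps", {
  ph <- constant_phantom()
  res <- memo("const_run", run_pipeline(ph$volume, ph$truth$seeds,
                                        phantom_config()))
  maps <- lapply(1:6, function(l)
    fast_march(res$lung_mask, res$subtrees[res$subtrees$lobe_label == l, ]))
  streamed <- assign_lobes(res$lung_mask, res$subtrees)
  flat <- vapply(maps, as.vector, numeric(length(maps[[1]])))
  manual <- max.col(-flat, "first")
  got <- suppressWarnings(assign_lobes(res$lung_mask,
                                       arrival_maps = maps,
                                       subtrees = res$subtrees))
  reached <- is.finite(flat[cbind(seq_along(manual), manual)])
  lung <- as.vector(res$lung_mask$data)
  expect_identical(as.vector(got$data)[lung & reached],
                   as.integer(manual)[lung & reached])
  expect_identical(streamed$data, got$data)
})

test_that("territory summaries count every labelled voxel once", {
  ph <- small_phantom()
  res <- small_run()
  ts <- territory_summary(res$labels)
  expect_identical(sum(ts$voxels), sum(res$lung_mask$data))
  expect_equal(sum(ts$percent), 100, tolerance = 1e-9)
  one <- label_map(array(2L, c(4, 4, 4)))
  ts1 <- territory_summary(one)
  expect_equal(ts1$percent[2], 100)
  expect_warning(territory_summary(label_map(array(0L, c(4, 4, 4)))), "empty")
})
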