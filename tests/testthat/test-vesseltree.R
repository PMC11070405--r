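# Arterial tree growing, centerline thinning, and lobar subtree partition.

n_components <- function(mask, connectivity = 26L) {
  lab <- mcplobes:::cpp_label_components(as.logical(mask), dim(mask),
                                         connectivity)
  attr(lab, "n_components")
}

test_that("region growing recovers the tree exactly on noise-free phantoms", {
  ph <- constant_phantom()
  lung <- binary_mask(ph$truth$labels$data > 0, ph$volume$spacing)
  vessels <- segment_arteries(ph$volume, lung, ph$truth$seeds)
  expect_identical(vessels$data, ph$truth$tree_mask$data)
})

test_that("region growing tolerates realistic noise", {
  ph <- small_phantom()
  res <- small_run()
  expect_gte(dice(res$vessel_mask$data, ph$truth$tree_mask$data), 0.90)
})

test_that("seeds off the vessels are rejected by name", {
  ph <- constant_phantom()
  lung <- segment_lungs(ph$volume, min_component_ml = 1)
  bad <- ph$truth$seeds
  bad$i[2] <- bad$i[2] + 15 # drop into parenchyma
  expect_error(segment_arteries(ph$volume, lung, bad), "seed 2")
})

test_that("thinning keeps straight lines and shrinks solids to connected cores", {
  line <- array(FALSE, c(9, 9, 9))
  line[2:8, 5, 5] <- TRUE
  sk <- extract_centerline(binary_mask(line))
  expect_identical(nrow(sk), 7L)
  expect_true(all(sk$j == 5 & sk$k == 5))

  cube <- array(FALSE, c(11, 11, 11))
  cube[2:10, 2:10, 2:10] <- TRUE
  skc <- extract_centerline(binary_mask(cube))
  expect_lt(nrow(skc), 9^3)
  sk_mask <- array(FALSE, c(11, 11, 11))
  sk_mask[cbind(skc$i, skc$j, skc$k)] <- TRUE
  expect_identical(n_components(sk_mask), 1L)
  expect_true(all(cube[cbind(skc$i, skc$j, skc$k)])) # skeleton within mask
})

test_that("thinning preserves the component count of the phantom tree", {
  ph <- small_phantom()
  tree <- ph$truth$tree_mask
  sk <- extract_centerline(tree)
  sk_mask <- array(FALSE, dim(tree$data))
  sk_mask[cbind(sk$i, sk$j, sk$k)] <- TRUE
  expect_identical(n_components(sk_mask), n_components(tree$data))
  expect_true(all(tree$data[cbind(sk$i, sk$j, sk$k)]))
  expect_error(extract_centerline(binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("six disjoint subtrees are wholly labeled by their own markers", {
  dm <- c(30, 10, 10)
  cl <- dplyr::bind_rows(lapply(1:6, function(l) {
    tibble::tibble(i = (l - 1) * 5 + 1:4, j = 5, k = 5)
  }))
  markers <- seed_set(1:6, (0:5) * 5 + 2, rep(5, 6), rep(5, 6))
  out <- partition_subtrees(cl, markers, c(1, 1, 1))
  expect_identical(nrow(out), nrow(cl))
  for (l in 1:6)
    expect_true(all(out$lobe_label[out$i %in% ((l - 1) * 5 + 1:4)] == l))
})

test_that("geodesic labels split a Y at the midpoint with ties to the lower label", {
  # stem (5,1..4), left arm to (2,7), right arm to (8,7); unit spacing
  cl <- tibble::tibble(
    i = c(5, 5, 5, 5, 4, 3, 2, 6, 7, 8),
    j = c(1, 2, 3, 4, 5, 6, 7, 5, 6, 7),
    k = 2)
  markers <- seed_set(c(1, 2), c(2, 8), c(7, 7), c(2, 2))
  out <- partition_subtrees(cl, markers, c(1, 1, 1), required_labels = 1:2)
  lab <- out$lobe_label[order(out$i * 100 + out$j)]
  key <- out[, c("i", "j", "lobe_label")]
  get <- function(i, j) key$lobe_label[key$i == i & key$j == j]
  # left arm -> 1, right arm -> 2
  expect_identical(c(get(3, 6), get(4, 5)), c(1L, 1L))
  expect_identical(c(get(7, 6), get(6, 5)), c(2L, 2L))
  # junction and stem are exactly equidistant: lower label wins
  expect_identical(get(5, 4), 1L)
  expect_identical(c(get(5, 3), get(5, 2), get(5, 1)), c(1L, 1L, 1L))
})

test_that("partition is invariant to marker order and needs every lobe", {
  ph <- constant_phantom()
  res <- memo("const_run", run_pipeline(ph$volume, ph$truth$seeds,
                                        phantom_config()))
  cl <- res$centerline
  mk <- ph$truth$seeds
  a <- partition_subtrees(cl, mk, ph$volume$spacing)
  b <- partition_subtrees(cl, mk[sample.int(6), ], ph$volume$spacing)
  expect_identical(a, b)
  expect_error(partition_subtrees(cl, mk[-3, ], ph$volume$spacing), "RUL")
})

test_that("geodesic labeling agrees with an igraph Dijkstra oracle", {
  skip_if_not_installed("igraph")
  withr::local_seed(42)
  dm <- c(24, 24, 24)
  spacing <- c(0.625, 0.625, 0.5)
  for (trial in 1:3) {
    # random connected skeleton from a self-avoiding-ish random walk
    mask <- array(FALSE, dm)
    p <- c(12, 12, 12)
    pts <- matrix(p, 1)
    for (s in 1:400) {
      p <- pmin(pmax(p + sample(c(-1, 0, 1), 3, TRUE), 1), dm)
      pts <- rbind(pts, p)
    }
    pts <- unique(pts)
    mask[pts] <- TRUE
    cl <- tibble::tibble(i = pts[, 1], j = pts[, 2], k = pts[, 3])
    mi <- sample.int(nrow(pts), 6)
    markers <- seed_set(1:6, pts[mi, 1], pts[mi, 2], pts[mi, 3])
    got <- partition_subtrees(cl, markers, spacing)
    dmat <- sapply(1:6, function(l) {
      d <- oracle_dijkstra(mask, pts[mi[l], , drop = FALSE], spacing)
      d[cbind(cl$i, cl$j, cl$k)]
    })
    want <- max.col(-dmat, "first")
    best <- dmat[cbind(seq_len(nrow(cl)), want)]
    gap <- apply(dmat, 1, function(r) diff(sort(r)[1:2])) # near-tie guard
    cmp <- is.finite(best) & (!is.finite(gap) | gap > 1e-6)
    expect_identical(got$lobe_label[cmp], as.integer(want[cmp]))
  }
})

test_that("at least 99 percent of phantom centerline points get the right lobe", {
  ph <- small_phantom()
  res <- small_run()
  truth_cl <- ph$truth$centerline
  joined <- dplyr::inner_join(res$subtrees, truth_cl,
                              by = c("i", "j", "k"),
                              suffix = c("", "_truth"))
  expect_gt(nrow(joined), 500)
  expect_gte(mean(joined$lobe_label == joined$lobe_label_truth), 0.99)
})
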