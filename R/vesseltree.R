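# Pulmonary arterial tree extraction, centerline skeletonization, and
# marker-based partition of the centerline into six lobar subtrees.
#
# The study's workstation steps are formalised as: seeded 26-connected region
# growing over soft-tissue-density voxels inside the lung, topology-
# preserving 3D thinning, and a geodesic (along-skeleton) nearest-marker
# partition needing only one user click per lobe.

#' Seed / marker table
#'
#' Seeds and markers are tibbles with columns `lobe_label` (0 for unlabeled
#' growth seeds, 1-6 for lobar markers) and 1-based voxel indices `i, j, k`.
#'
#' @param lobe_label Integer vector in 0..6.
#' @param i,j,k Integer voxel indices (1-based).
#' @return A tibble with the four columns.
#' @export
seed_set <- function(lobe_label, i, j, k) {
  assert_that(all(lobe_label %in% 0:6), "lobe_label must be in 0..6")
  tibble::tibble(lobe_label = as.integer(lobe_label), i = as.integer(i),
                 j = as.integer(j), k = as.integer(k))
}

#' Read / write seed tables as CSV
#'
#' @param path CSV file with columns `lobe_label, i, j, k`.
#' @param seeds A seed tibble (see [seed_set()]).
#' @return `read_seeds()` returns the seed tibble; `write_seeds()` returns
#'   `path` invisibly.
#' @export
read_seeds <- function(path) {
  df <- read.csv(path)
  seed_set(df$lobe_label, df$i, df$j, df$k)
}

#' @rdname read_seeds
#' @export
write_seeds <- function(seeds, path) {
  write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}

#' Segment the pulmonary arterial tree
#'
#' 26-connected region growing from the given seeds over voxels with
#' `HU >= hu_low` inside the lung mask.
#'
#' @param vol [image_volume] of HU values.
#' @param lung_mask [binary_mask] from [segment_lungs()].
#' @param seeds Seed tibble; every seed must lie inside the lung mask at
#'   `HU >= hu_low` (vessels sit near soft-tissue density, far above the
#'   air-dominated parenchyma).
#' @param hu_low Lower HU bound of vessel density (default -100 HU).
#' @return A [binary_mask] of the arterial tree.
#' @export
segment_arteries <- function(vol, lung_mask, seeds, hu_low = -100) {
  dm <- dim(vol$data)
  assert_that(in_grid(seeds, dm), "seed outside the volume grid")
  allowed <- vol$data >= hu_low & lung_mask$data
  at <- cbind(seeds$i, seeds$j, seeds$k)
  bad <- which(!allowed[at])
  if (length(bad) > 0)
    rlang::abort(sprintf(
      "seed %d at (%d, %d, %d) is below %g HU or outside the lung mask",
      bad[1], seeds$i[bad[1]], seeds$j[bad[1]], seeds$k[bad[1]], hu_low))
  out <- cpp_region_grow(as.logical(allowed), dm, seed_matrix0(seeds))
  dim(out) <- dm
  binary_mask(out, vol$spacing, vol$origin)
}

#' Extract vessel centerlines
#'
#' Topology-preserving 3D thinning (sequential directional erosion of simple
#' points, keeping curve endpoints) reducing the vessel mask to a one-voxel
#' wide skeleton.  The skeleton is a subset of the mask and preserves the
#' number of connected components.
#'
#' @param vessel_mask [binary_mask] of the arterial tree.
#' @return Tibble of skeleton voxel indices (`i, j, k`, 1-based).
#' @export
extract_centerline <- function(vessel_mask) {
  assert_that(any(vessel_mask$data), "extract_centerline(): empty vessel mask")
  dm <- dim(vessel_mask$data)
  sk <- cpp_thin3d(as.logical(vessel_mask$data), dm)
  dim(sk) <- dm
  idx <- which(sk, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3])
}

#' Partition the centerline into six lobar subtrees
#'
#' Assigns every centerline point the label of the geodesically nearest
#' marker, where distance is measured along the 26-connected skeleton graph
#' with Euclidean inter-voxel edge lengths in mm.  Markers are snapped to the
#' nearest centerline point (at most 3 voxels away).  Exact geodesic ties go
#' to the lower lobe label; points unreachable from every marker fall back to
#' the Euclidean nearest marker with a warning.
#'
#' @param centerline Tibble `i, j, k` from [extract_centerline()].
#' @param markers Seed tibble with at least one marker per required lobe.
#' @param spacing Voxel spacing in mm.
#' @param required_labels Lobe labels that must each have a marker (default
#'   all six).
#' @return A subtree set: tibble `lobe_label, i, j, k` covering the whole
#'   centerline, with `lobe_label` in 1..6.
#' @export
partition_subtrees <- function(centerline, markers, spacing,
                               required_labels = 1:6) {
  markers <- markers[markers$lobe_label > 0, ]
  missing_lobe <- setdiff(required_labels, unique(markers$lobe_label))
  assert_that(length(missing_lobe) == 0,
              sprintf("no marker for lobe(s): %s",
                      paste(lobe_regions()[missing_lobe], collapse = ", ")))
  n <- nrow(centerline)
  cpts <- as.matrix(centerline[, c("i", "j", "k")])
  # snap each marker to the nearest centerline point (tolerance 3 voxels)
  snapped <- integer(nrow(markers))
  for (m in seq_len(nrow(markers))) {
    d2 <- (cpts[, 1] - markers$i[m])^2 + (cpts[, 2] - markers$j[m])^2 +
      (cpts[, 3] - markers$k[m])^2
    best <- which.min(d2)
    assert_that(d2[best] <= 9,
                sprintf("marker %d is farther than 3 voxels from the centerline", m))
    snapped[m] <- best
  }
  dm <- apply(cpts, 2, max) # a bounding grid is enough for linear indices
  lin <- as.integer(cpts[, 1] - 1 + dm[1] * (cpts[, 2] - 1 + dm[2] * (cpts[, 3] - 1)))
  present <- sort(unique(markers$lobe_label))
  dists <- matrix(Inf, n, length(present))
  for (li in seq_along(present)) {
    src <- snapped[markers$lobe_label == present[li]] - 1L
    dists[, li] <- cpp_skeleton_geodesic(lin, as.integer(dm), spacing,
                                         as.integer(src))
  }
  # argmin with exact ties going to the lower label
  col <- max.col(-dists, ties.method = "first")
  lab <- present[col]
  unreached <- !is.finite(dists[cbind(seq_len(n), col)])
  if (any(unreached)) {
    rlang::warn(sprintf(
      "%d centerline point(s) unreachable along the skeleton; assigned by Euclidean nearest marker",
      sum(unreached)))
    mk <- as.matrix(markers[, c("i", "j", "k")])
    for (p in which(unreached)) {
      d2 <- colSums((t(mk) - cpts[p, ])^2 * spacing^2)
      lab[p] <- markers$lobe_label[order(d2, markers$lobe_label)[1]]
    }
  }
  tibble::tibble(lobe_label = as.integer(lab), i = cpts[, 1], j = cpts[, 2],
                 k = cpts[, 3])
}
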