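# Synthetic swine-lung CT phantoms with ground truth.
#
# The phantom emulates what the pipeline needs from a noncontrast swine chest
# CT: air-dominated parenchyma in two lungs plus the porcine accessory lobe,
# six lobar territories separated by fissure-like (gently rippled) surfaces,
# one bifurcating arterial subtree per lobe at soft-tissue attenuation, and a
# repeat acquisition with noise, small rigid motion and HU drift.  The truth
# labels come from the geometric partition alone -- the pipeline must recover
# them from the vessels, never from the fissures.

# Lobe geometry in fractions of the physical grid extent.  Proportions
# loosely follow the swine lobar mass ranking (RLL and LLL largest, the
# accessory lobe smallest) without targeting specific values.
phantom_geometry <- function() {
  list(
    right = list(center = c(0.32, 0.50, 0.52), semi = c(0.20, 0.30, 0.375)),
    left  = list(center = c(0.75, 0.50, 0.50), semi = c(0.165, 0.275, 0.355)),
    al    = list(center = c(0.48, 0.64, 0.23), semi = c(0.095, 0.10, 0.125)),
    left_split_z = 0.52,   # LUL above, LLL below
    right_split_z1 = 0.62, # RUL above
    right_split_z2 = 0.48, # RML between, RLL below
    ripple_amp_frac = 0.015,
    ripple_cycles = 1.5
  )
}

#' Phantom specification
#'
#' Parameters of the synthetic swine-lung CT generator.  The HU model places
#' parenchyma mid-range of the air--tissue decomposition and vessels near
#' pure tissue; the re-acquisition model mimics a second helical scan of the
#' same animal a few minutes later (additive noise, small rigid motion,
#' global HU drift).
#'
#' @param shape Grid size in voxels, length 3.
#' @param spacing Voxel spacing in mm (default the clinical 0.625 x 0.625 x
#'   0.5 mm geometry).
#' @param hu_parenchyma,hu_vessel,hu_background `(mean, sd)` of the Gaussian
#'   HU model for lung parenchyma, vessels, and surrounding soft tissue.
#' @param psf_sigma_mm Gaussian point-spread blur applied to the
#'   lung/background interface (mm).  Real scanners blur the pleural
#'   boundary in every acquisition; without it the phantom's first
#'   acquisition would have an unphysically sharp boundary while a rigidly
#'   moved re-acquisition would not, biasing paired mass comparisons.
#'   Vessels are painted after the blur (interior structures; HU blending is
#'   mass-neutral because mass is linear in HU).  Set 0 for exactly
#'   piecewise-constant phantoms.
#' @param tree_depth Bifurcation generations per lobar subtree.  Branches
#'   run from their entry point to the (jittered) centroid of the
#'   sub-territory they supply, which is then split in two for the children,
#'   so terminal branches cover each lobe roughly uniformly.
#' @param radius_decay Per-generation decay of branch radius.
#' @param root_radius_mm Radius of the lobar root branches (mm).
#' @param reacq_noise_sd Additive Gaussian noise SD of the repeat acquisition
#'   (HU).
#' @param reacq_motion_voxels Maximum rigid translation per axis between
#'   acquisitions, in voxels.
#' @param reacq_rotation_deg Maximum rigid rotation per axis between
#'   acquisitions (deg).
#' @param reacq_drift_hu Global HU drift range `c(lo, hi)` of the repeat
#'   acquisition; a scalar `d` means `c(-d, d)`.
#' @param jitter_radius Observer seed/marker jitter radius in voxels.
#' @param subject_scale_sd SD of the per-phantom anatomical scale factor
#'   applied to all lung semi-axes (animals differ in size; 0.05 gives a
#'   realistic ~15\% between-subject lung-volume CV).
#' @param split_jitter_sd SD of the per-phantom jitter of each lobar split
#'   surface position, as a fraction of the grid z-extent (fissure positions
#'   vary between animals).
#' @return A `phantom_spec` object (list of validated parameters).
#' @seealso [generate_phantom()], [simulate_reacquisition()],
#'   [simulate_observer_variation()]
#' @export
phantom_spec <- function(shape = c(128, 128, 128),
                         spacing = c(0.625, 0.625, 0.5),
                         hu_parenchyma = c(-750, 40),
                         hu_vessel = c(30, 15),
                         hu_background = c(40, 10),
                         psf_sigma_mm = 0.6,
                         tree_depth = 6,
                         radius_decay = 0.75,
                         root_radius_mm = 1.4,
                         reacq_noise_sd = 20,
                         reacq_motion_voxels = 2,
                         reacq_rotation_deg = 0,
                         reacq_drift_hu = 5,
                         jitter_radius = 2,
                         subject_scale_sd = 0.05,
                         split_jitter_sd = 0.015) {
  assert_that(length(shape) == 3 && all(shape >= 16),
              "shape must be three integers >= 16")
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be three positive numbers")
  for (p in list(hu_parenchyma, hu_vessel, hu_background))
    assert_that(length(p) == 2 && p[2] >= 0, "HU models are (mean, sd) with sd >= 0")
  if (length(reacq_drift_hu) == 1) reacq_drift_hu <- c(-1, 1) * abs(reacq_drift_hu)
  assert_that(reacq_noise_sd >= 0 && reacq_motion_voxels >= 0 &&
                reacq_rotation_deg >= 0 && jitter_radius >= 0,
              "perturbation parameters must be nonnegative")
  structure(list(shape = as.integer(shape), spacing = as.double(spacing),
                 hu_parenchyma = hu_parenchyma, hu_vessel = hu_vessel,
                 hu_background = hu_background, psf_sigma_mm = psf_sigma_mm,
                 tree_depth = tree_depth,
                 radius_decay = radius_decay,
                 root_radius_mm = root_radius_mm,
                 reacq_noise_sd = reacq_noise_sd,
                 reacq_motion_voxels = reacq_motion_voxels,
                 reacq_rotation_deg = reacq_rotation_deg,
                 reacq_drift_hu = reacq_drift_hu,
                 jitter_radius = jitter_radius,
                 subject_scale_sd = subject_scale_sd,
                 split_jitter_sd = split_jitter_sd,
                 geometry = phantom_geometry()),
            class = "phantom_spec")
}

# analytic membership tests -------------------------------------------------

ellipsoid_norm2 <- function(p, ell, extent) {
  c0 <- ell$center * extent
  ax <- ell$semi * extent
  sum(((p - c0) / ax)^2)
}

ripple_at <- function(p, spec) {
  g <- spec$geometry
  extent <- spec$shape * spec$spacing
  g$ripple_amp_frac * extent[3] *
    sin(2 * pi * g$ripple_cycles * p[1] / extent[1]) *
    sin(2 * pi * g$ripple_cycles * p[2] / extent[2])
}

# TRUE if point p (mm) lies in lobe `label`, with `shrink` scaling the
# ellipsoids and `band_margin` (mm) pulled in from the split surfaces
inside_lobe_point <- function(p, label, spec, shrink = 1, band_margin = 0) {
  g <- spec$geometry
  extent <- spec$shape * spec$spacing
  shrunk <- function(ell) list(center = ell$center, semi = ell$semi * shrink)
  in_al <- ellipsoid_norm2(p, shrunk(g$al), extent) < 1
  rp <- ripple_at(p, spec)
  z <- p[3]
  if (label == 6) return(in_al)
  if (ellipsoid_norm2(p, g$al, extent) < 1) return(FALSE) # AL carved out
  if (label %in% 1:2) {
    if (ellipsoid_norm2(p, shrunk(g$left), extent) >= 1) return(FALSE)
    zc <- g$left_split_z * extent[3] + rp
    return(if (label == 1) z > zc + band_margin else z <= zc - band_margin)
  }
  if (ellipsoid_norm2(p, shrunk(g$right), extent) >= 1) return(FALSE)
  z1 <- g$right_split_z1 * extent[3] + rp
  z2 <- g$right_split_z2 * extent[3] + rp
  switch(label,
         NULL, NULL,
         z > z1 + band_margin,
         z <= z1 - band_margin && z > z2 + band_margin,
         z <= z2 - band_margin)
}

# vectorised truth labels for the whole grid
phantom_labels <- function(spec) {
  g <- spec$geometry
  dm <- spec$shape
  extent <- dm * spec$spacing
  x <- (seq_len(dm[1]) - 1) * spec$spacing[1]
  y <- (seq_len(dm[2]) - 1) * spec$spacing[2]
  z <- (seq_len(dm[3]) - 1) * spec$spacing[3]
  enorm <- function(ell) {
    a1 <- ((x - ell$center[1] * extent[1]) / (ell$semi[1] * extent[1]))^2
    a2 <- ((y - ell$center[2] * extent[2]) / (ell$semi[2] * extent[2]))^2
    a3 <- ((z - ell$center[3] * extent[3]) / (ell$semi[3] * extent[3]))^2
    outer(outer(a1, a2, "+"), a3, "+")
  }
  in_right <- enorm(g$right) < 1
  in_left <- enorm(g$left) < 1
  in_al <- enorm(g$al) < 1
  ripple <- g$ripple_amp_frac * extent[3] *
    outer(sin(2 * pi * g$ripple_cycles * x / extent[1]),
          sin(2 * pi * g$ripple_cycles * y / extent[2]))
  zarr <- array(rep(z, each = dm[1] * dm[2]), dm)
  rarr <- array(rep(ripple, times = dm[3]), dm)
  lab <- array(0L, dm)
  lab[in_left & zarr > g$left_split_z * extent[3] + rarr] <- 1L
  lab[in_left & zarr <= g$left_split_z * extent[3] + rarr] <- 2L
  sel <- in_right & !in_al
  lab[sel & zarr > g$right_split_z1 * extent[3] + rarr] <- 3L
  lab[sel & zarr <= g$right_split_z1 * extent[3] + rarr &
        zarr > g$right_split_z2 * extent[3] + rarr] <- 4L
  lab[sel & zarr <= g$right_split_z2 * extent[3] + rarr] <- 5L
  lab[in_al] <- 6L
  lab
}

# recursive bifurcating tree ------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

# Demand-driven bifurcating tree: each branch runs from its entry point to
# the centroid of the sub-territory it supplies, then splits that territory
# in two along its principal axis and recurses.  This emulates how arterial
# trees ramify to perfuse their whole territory (the anatomical premise of
# vessel-based lobar assignment) and guarantees roughly uniform terminal
# coverage of every lobe.  Random endpoint jitter adds biological
# irregularity.
grow_lobe_tree <- function(spec, label, root, pts_mm) {
  segs <- list()
  max_retry <- 12
  inside <- function(p) isTRUE(inside_lobe_point(p, label, spec,
                                                 shrink = 0.92,
                                                 band_margin = 0.4))
  target_point <- function(pts, sigma) {
    c0 <- colMeans(pts)
    for (try in seq_len(max_retry)) {
      cand <- if (try < max_retry) c0 + rnorm(3, 0, sigma) else c0
      if (inside(cand)) return(cand)
    }
    # nonconvex pocket: snap to the territory voxel nearest its centroid
    d2 <- rowSums(sweep(pts, 2, c0)^2)
    ord <- order(d2)
    for (o in head(ord, 200)) if (inside(pts[o, ])) return(pts[o, ])
    rlang::abort(sprintf(
      "phantom tree for lobe %s could not stay inside its region",
      lobe_regions()[label]))
  }
  grow <- function(p0, pts, level, radius) {
    spread <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
    p1 <- target_point(pts, 0.15 * spread)
    segs[[length(segs) + 1]] <<- c(p0, p1, radius, label)
    if (level >= spec$tree_depth || nrow(pts) < 20) return()
    ax <- principal_axis(pts)
    side <- c(sweep(pts, 2, colMeans(pts)) %*% ax) > 0
    for (half in list(pts[side, , drop = FALSE], pts[!side, , drop = FALSE])) {
      if (nrow(half) >= 10)
        grow(p1, half, level + 1, max(radius * spec$radius_decay, 0.55))
    }
  }
  ax <- principal_axis(pts_mm)
  side <- c(sweep(pts_mm, 2, root) %*% ax) > 0
  for (half in list(pts_mm[side, , drop = FALSE], pts_mm[!side, , drop = FALSE]))
    grow(root, half, 1, spec$root_radius_mm)
  segs
}

principal_axis <- function(pts) {
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  unit(ev$vectors[, 1])
}

# points every ~0.4 mm along every branch axis, as 1-based voxel indices
segments_to_centerline <- function(segs, spec) {
  out <- lapply(segs, function(s) {
    p0 <- s[1:3]; p1 <- s[4:6]
    n <- max(2, ceiling(sqrt(sum((p1 - p0)^2)) / 0.4))
    t <- seq(0, 1, length.out = n)
    pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
                 p0[2] + t * (p1[2] - p0[2]),
                 p0[3] + t * (p1[3] - p0[3]))
    idx <- round(sweep(pts, 2, spec$spacing, "/")) + 1
    idx <- pmax(idx, 1)
    idx <- sweep(idx, 2, spec$shape, pmin)
    tibble::tibble(lobe_label = s[8], i = idx[, 1], j = idx[, 2], k = idx[, 3])
  })
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Generate a synthetic swine-lung CT phantom
#'
#' Builds the HU volume and its complete ground truth: lobar label map from
#' the geometric partition, arterial tree mask, per-lobe centerline points,
#' root seeds/markers, and closed-form per-lobe mass and volume computed from
#' the noiseless HU model.
#'
#' @param spec A [phantom_spec].
#' @param seed Integer seed; the phantom is a pure function of
#'   `(spec, seed)`.
#' @return A list with elements `volume` ([image_volume]) and `truth`, where
#'   `truth` contains `labels` ([label_map]), `tree_mask` ([binary_mask]),
#'   `centerline` (tibble `lobe_label, i, j, k`), `seeds` (tibble, one root
#'   marker per lobe), and `measurements` (tibble of truth mass/volume per
#'   region).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1) {
  with_seed(seed, {
    # per-subject anatomy: scale the lungs and jitter the fissure positions
    scale <- max(0.8, min(1.2, rnorm(1, 1, spec$subject_scale_sd)))
    g <- spec$geometry
    for (nm in c("right", "left", "al")) g[[nm]]$semi <- g[[nm]]$semi * scale
    for (nm in c("left_split_z", "right_split_z1", "right_split_z2"))
      g[[nm]] <- g[[nm]] + rnorm(1, 0, spec$split_jitter_sd)
    spec$geometry <- g
    dm <- spec$shape
    lab <- phantom_labels(spec)
    lung <- lab > 0L

    # one demand-driven tree per lobe, rooted near the lobe centroid
    segs <- list()
    seeds <- list()
    for (l in 1:6) {
      idx <- which(lab == l, arr.ind = TRUE)
      if (nrow(idx) > 20000) idx <- idx[sample.int(nrow(idx), 20000), ]
      pts <- sweep(idx - 1, 2, spec$spacing, "*")
      centroid <- colMeans(pts)
      if (!inside_lobe_point(centroid, l, spec, shrink = 0.92,
                             band_margin = 0.4)) {
        # centroid can fall outside for strongly curved caps; use the inner
        # voxel nearest the centroid instead
        d2 <- rowSums(sweep(pts, 2, centroid)^2)
        ord <- order(d2)
        found <- FALSE
        for (o in head(ord, 500)) {
          if (inside_lobe_point(pts[o, ], l, spec, 0.92, 0.4)) {
            centroid <- pts[o, ]; found <- TRUE; break
          }
        }
        if (!found)
          rlang::abort(sprintf("no admissible root found for lobe %s",
                               lobe_regions()[l]))
      }
      segs <- c(segs, grow_lobe_tree(spec, l, centroid, pts))
      root_idx <- as.integer(round(centroid / spec$spacing) + 1)
      seeds[[l]] <- tibble::tibble(lobe_label = l, i = root_idx[1],
                                   j = root_idx[2], k = root_idx[3])
    }
    seg_mat <- do.call(rbind, segs)
    tree <- cpp_draw_tubes(dm, spec$spacing, seg_mat[, 1:7, drop = FALSE])
    dim(tree) <- dm
    tree <- tree & lung
    centerline <- segments_to_centerline(segs, spec)
    keep <- tree[cbind(centerline$i, centerline$j, centerline$k)]
    centerline <- centerline[keep, ]

    # HU model: blurred pleural interface, then sharp vessels, then noise
    base <- array(spec$hu_background[1], dm)
    base[lung] <- spec$hu_parenchyma[1]
    if (spec$psf_sigma_mm > 0) {
      base <- cpp_gauss_blur(base, dm, spec$psf_sigma_mm / spec$spacing)
      dim(base) <- dm
    }
    base[tree] <- spec$hu_vessel[1]
    noise_sd <- array(spec$hu_background[2], dm)
    noise_sd[lung] <- spec$hu_parenchyma[2]
    noise_sd[tree] <- spec$hu_vessel[2]
    hu <- base + rnorm(prod(dm), 0, 1) * noise_sd

    truth_meas <- phantom_truth_measurements(lab, tree, spec)
    list(volume = image_volume(hu, spec$spacing),
         truth = list(labels = label_map(lab, spec$spacing),
                      tree_mask = binary_mask(tree, spec$spacing),
                      centerline = centerline,
                      seeds = dplyr::bind_rows(seeds),
                      measurements = truth_meas,
                      spec = spec, seed = seed))
  })
}

# closed-form truth mass/volume from the noiseless two-level HU model
phantom_truth_measurements <- function(lab, tree, spec) {
  consts <- decomposition_constants()
  vox_ml <- mm3_to_ml(voxel_volume_mm3(spec$spacing))
  tf_par <- tissue_fraction(spec$hu_parenchyma[1], consts)
  tf_ves <- tissue_fraction(spec$hu_vessel[1], consts)
  rows <- lapply(1:6, function(l) {
    n_ves <- sum(tree[lab == l])
    n_all <- sum(lab == l)
    tibble::tibble(region = lobe_regions()[l], label = l, voxels = n_all,
                   volume_ml = n_all * vox_ml,
                   mass_g = ((n_all - n_ves) * tf_par + n_ves * tf_ves) *
                     vox_ml * consts$rho_tissue)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out,
                   tibble::tibble(region = "GLOBAL", label = NA_integer_,
                                  voxels = sum(out$voxels),
                                  volume_ml = sum(out$volume_ml),
                                  mass_g = sum(out$mass_g)))
}

#' Simulate a repeat acquisition
#'
#' Applies a random rigid motion (uniform within the spec's translation and
#' rotation ranges), adds independent Gaussian HU noise, and a global HU
#' drift drawn uniformly from the spec's drift range.  Deterministic per
#' seed.  With all perturbation ranges zero the input is returned unchanged.
#'
#' @param vol [image_volume] from [generate_phantom()].
#' @param spec The [phantom_spec] that generated `vol`.
#' @param seed Integer seed.
#' @return An [image_volume] with attribute `"transform"` holding the applied
#'   [rigid_transform].
#' @export
simulate_reacquisition <- function(vol, spec, seed = 1) {
  assert_that(spec$reacq_motion_voxels < min(dim(vol$data)) / 2,
              "motion range exceeds the grid extent")
  with_seed(seed, {
    tmax <- spec$reacq_motion_voxels * vol$spacing
    trans <- runif(3, -tmax, tmax)
    rot <- runif(3, -spec$reacq_rotation_deg, spec$reacq_rotation_deg) * pi / 180
    drift <- runif(1, spec$reacq_drift_hu[1], spec$reacq_drift_hu[2])
    tr <- rigid_transform(euler_to_rotation(rot[1], rot[2], rot[3]), trans)
    if (max(abs(trans)) == 0 && max(abs(rot)) == 0) {
      out <- vol$data
    } else {
      out <- resample_rigid(vol, vol, tr, fill = spec$hu_background[1])$data
    }
    if (spec$reacq_noise_sd > 0)
      out <- out + rnorm(length(out), 0, spec$reacq_noise_sd)
    out <- out + drift
    res <- image_volume(out, vol$spacing, vol$origin)
    attr(res, "transform") <- tr
    res
  })
}

#' Simulate another observer's seed placement
#'
#' Jitters every growth seed and lobar marker by a uniform random integer
#' offset of Euclidean norm at most `radius` voxels, rejection-sampling so
#' that every jittered point stays on the arterial tree (as an observer
#' clicking on vessels would).  Deterministic per seed.
#'
#' @param truth The `truth` element of a [generate_phantom()] result.
#' @param seed Integer seed.
#' @param radius Jitter radius in voxels (default from the phantom spec).
#' @return A tibble of seeds with the same columns as `truth$seeds`.
#' @export
simulate_observer_variation <- function(truth, seed = 1, radius = NULL) {
  radius <- radius %||% truth$spec$jitter_radius
  seeds <- truth$seeds
  if (radius == 0) return(seeds)
  tree <- truth$tree_mask$data
  dm <- dim(tree)
  offs <- as.matrix(expand.grid(i = -radius:radius, j = -radius:radius,
                                k = -radius:radius))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  with_seed(seed, {
    for (r in seq_len(nrow(seeds))) {
      ok <- FALSE
      for (try in 1:100) {
        o <- offs[sample.int(nrow(offs), 1), ]
        p <- c(seeds$i[r], seeds$j[r], seeds$k[r]) + o
        if (all(p >= 1) && all(p <= dm) && tree[p[1], p[2], p[3]]) {
          seeds$i[r] <- p[1]; seeds$j[r] <- p[2]; seeds$k[r] <- p[3]
          ok <- TRUE
          break
        }
      }
      if (!ok)
        rlang::abort(sprintf(
          "could not keep jittered seed %d on the arterial tree", r))
    }
    seeds
  })
}

#' Write phantom truth artifacts to disk
#'
#' Writes the phantom volume and truth label map as NIfTI, the centerline and
#' seed tables as CSV (`lobe_label, i, j, k`, 1-based voxel indices), and the
#' truth measurements as CSV.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, "phantom.nii.gz"))
  write_volume(phantom$truth$labels, file.path(dir, "truth_labels.nii.gz"))
  write_volume(phantom$truth$tree_mask, file.path(dir, "truth_tree.nii.gz"))
  write.csv(phantom$truth$centerline, file.path(dir, "truth_centerline.csv"),
            row.names = FALSE)
  write.csv(phantom$truth$seeds, file.path(dir, "seeds.csv"), row.names = FALSE)
  write.csv(phantom$truth$measurements, file.path(dir, "truth_measurements.csv"),
            row.names = FALSE)
  invisible(dir)
}
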