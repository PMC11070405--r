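# Rigid inter-acquisition registration.
#
# Paired same-session acquisitions of an intubated, breath-held animal differ
# by small rigid motion only, so a 6-DOF transform with a mean-squared-HU
# metric is sufficient.  Registration is optional in the pipeline: per-
# acquisition totals need no voxel correspondence; it exists for side-by-side
# assignment-map comparison.

#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal within 1e-8, det +1).
#' @param translation Length-3 translation in mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.double(rotation), 3, 3)
  assert_that(max(abs(crossprod(rotation) - diag(3))) < 1e-8,
              "rotation must be orthonormal within 1e-8")
  assert_that(abs(det(rotation) - 1) < 1e-8, "rotation must have determinant +1")
  assert_that(length(translation) == 3 && all(is.finite(translation)),
              "translation must be three finite numbers (mm)")
  structure(list(rotation = rotation, translation = as.double(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> |t| = %.3f mm, rotation angle = %.3f deg\n",
              sqrt(sum(x$translation^2)), ang))
  invisible(x)
}

rotation_angle_deg <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c))) * 180 / pi
}

euler_to_rotation <- function(rx, ry, rz) {
  # intrinsic rotations about x, then y, then z (angles in radians)
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Save / load a rigid transform as JSON
#'
#' The sidecar stores the rotation row-major and the translation in mm.
#'
#' @param transform A [rigid_transform].
#' @param path JSON file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns the [rigid_transform].
#' @export
write_transform <- function(transform, path) {
  obj <- list(rotation_row_major = as.vector(t(transform$rotation)),
              translation_mm = transform$translation)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                  obj$translation_mm)
}

grid_center_mm <- function(vol) vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing

#' Resample a volume under a rigid transform
#'
#' Samples `moving` on the grid of `fixed` after applying the transform
#' (rotation about the fixed-grid centre, then translation) by trilinear
#' interpolation.  Trilinear interpolation cannot overshoot, so values stay
#' within the input range; voxels mapping outside the moving volume are set
#' to `fill`.
#'
#' @param moving,fixed [image_volume] objects.
#' @param transform A [rigid_transform] mapping fixed-grid world points into
#'   the moving volume.
#' @param fill Value for voxels without support (default: minimum of
#'   `moving`).
#' @return An [image_volume] on the grid of `fixed`.
#' @export
resample_rigid <- function(moving, fixed, transform, fill = NULL) {
  fill <- fill %||% min(moving$data)
  out <- cpp_resample_rigid(as.double(moving$data), dim(moving$data),
                            moving$spacing, moving$origin,
                            dim(fixed$data), fixed$spacing, fixed$origin,
                            transform$rotation, transform$translation,
                            grid_center_mm(fixed))
  out[is.na(out)] <- fill
  dim(out) <- dim(fixed$data)
  image_volume(out, fixed$spacing, fixed$origin)
}

mse_metric <- function(theta, moving, fixed, stride, margin_vox = 6) {
  tr <- rigid_transform(euler_to_rotation(theta[4], theta[5], theta[6]),
                        theta[1:3])
  # compare over an eroded interior: voxels near the grid boundary carry
  # overlap/fill wedges whose area varies with the transform, which would
  # otherwise bias the optimum away from the true alignment
  idx <- lapply(dim(fixed$data), function(n) {
    s <- seq(1, n, by = stride)
    s[s > margin_vox & s <= n - margin_vox]
  })
  sub_f <- fixed$data[idx[[1]], idx[[2]], idx[[3]]]
  origin <- fixed$origin + (vapply(idx, `[`, 1, 1) - 1) * fixed$spacing
  # sample moving at the decimated interior fixed positions
  out <- cpp_resample_rigid(as.double(moving$data), dim(moving$data),
                            moving$spacing, moving$origin,
                            dim(sub_f), fixed$spacing * stride, origin,
                            tr$rotation, tr$translation, grid_center_mm(fixed))
  ok <- !is.na(out)
  if (mean(ok) < 0.2) return(1e12)
  mean((out[ok] - sub_f[ok])^2)
}

#' Rigid registration of two CT acquisitions
#'
#' Estimates the 6-DOF rigid transform (translation in mm, rotation about the
#' fixed-grid centre) that minimises the mean squared HU difference, using a
#' two-level coarse-to-fine search (Nelder-Mead at stride 2, refined at full
#' resolution), and returns the moving volume resampled onto the fixed grid.
#'
#' @param moving,fixed [image_volume] objects sharing voxel spacing.
#' @return A list with elements `transform` ([rigid_transform]) and
#'   `resampled` ([image_volume] on the fixed grid).
#' @export
register_rigid <- function(moving, fixed) {
  assert_that(max(abs(moving$spacing - fixed$spacing)) < 1e-9,
              "register_rigid(): volumes must share voxel spacing")
  assert_that(sd(moving$data) > 0 && sd(fixed$data) > 0,
              "register_rigid(): constant volume, similarity metric undefined")
  if (identical(dim(moving$data), dim(fixed$data)) &&
      isTRUE(all.equal(moving$data, fixed$data, tolerance = 0))) {
    return(list(transform = rigid_transform(),
                resampled = image_volume(moving$data, fixed$spacing,
                                         fixed$origin)))
  }
  # coarse integer-voxel translation search, then per-axis rotation sweeps,
  # then two Nelder-Mead refinement levels
  theta <- rep(0, 6)
  best <- mse_metric(theta, moving, fixed, 4L)
  steps <- expand.grid(i = -5:5, j = -5:5, k = -5:5)
  for (r in seq_len(nrow(steps))) {
    cand <- c(as.numeric(steps[r, ]) * fixed$spacing, 0, 0, 0)
    val <- mse_metric(cand, moving, fixed, 4L)
    if (val < best) { best <- val; theta <- cand }
  }
  for (ax in 4:6) {
    for (ang in setdiff(seq(-6, 6, by = 0.75), 0) * pi / 180) {
      cand <- theta
      cand[ax] <- ang
      val <- mse_metric(cand, moving, fixed, 4L)
      if (val < best) { best <- val; theta <- cand }
    }
  }
  scale <- c(rep(2 * max(fixed$spacing), 3), rep(2 * pi / 180, 3))
  for (stride in c(2L, 1L)) {
    fit <- stats::optim(theta, mse_metric, moving = moving, fixed = fixed,
                        stride = stride, method = "Nelder-Mead",
                        control = list(maxit = if (stride == 2L) 400 else 60,
                                       reltol = 1e-10, parscale = scale))
    theta <- fit$par
  }
  tr <- rigid_transform(euler_to_rotation(theta[4], theta[5], theta[6]),
                        theta[1:3])
  list(transform = tr, resampled = resample_rigid(moving, fixed, tr))
}
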