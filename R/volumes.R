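# Volumetric containers and NIfTI input/output.
#
# All grids are plain R arrays in NIfTI voxel order (x fastest), indexed
# 1-based.  World coordinates are origin + (index - 1) * spacing, in mm;
# oblique orientations are not supported.

HU_MIN <- -1024
HU_MAX <- 3071

new_grid <- function(data, spacing, origin, class) {
  structure(list(data = data,
                 spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = class)
}

check_grid_geometry <- function(data, spacing, origin) {
  assert_that(length(dim(data)) == 3 && all(dim(data) >= 2),
              "volume data must be a 3D array with every axis of length >= 2")
  assert_that(length(spacing) == 3 && all(is.finite(spacing)) && all(spacing > 0),
              "spacing must be three strictly positive numbers (mm)")
  assert_that(length(origin) == 3 && all(is.finite(origin)),
              "origin must be three finite numbers (mm)")
}

#' CT image volume
#'
#' A 3D grid of Hounsfield units together with its voxel spacing and world
#' origin.  Values outside the representable CT range \[-1024, 3071\] HU are
#' clamped with a warning, and non-finite values are rejected.
#'
#' @param data 3D numeric array of HU values (axis order x, y, z; x fastest).
#' @param spacing Voxel spacing `(sx, sy, sz)` in mm, all positive.
#' @param origin World coordinates of voxel (1, 1, 1) in mm.
#' @return An `image_volume` object: a list with elements `data`, `spacing`
#'   and `origin`.
#' @seealso [read_volume()], [write_volume()], [binary_mask()], [label_map()]
#' @export
#' @examples
#' vol <- image_volume(array(-750, c(4, 4, 4)), spacing = c(0.625, 0.625, 0.5))
#' vol$spacing
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid_geometry(data, spacing, origin)
  assert_that(all(is.finite(data)), "HU values must all be finite")
  n_out <- sum(data < HU_MIN | data > HU_MAX)
  if (n_out > 0) {
    rlang::warn(sprintf(
      "%d voxel(s) outside [%d, %d] HU were clamped", n_out, HU_MIN, HU_MAX))
    data[data < HU_MIN] <- HU_MIN
    data[data > HU_MAX] <- HU_MAX
  }
  storage.mode(data) <- "double"
  new_grid(data, spacing, origin, "image_volume")
}

#' Binary voxel mask
#'
#' @param data 3D logical array on the parent volume's grid.
#' @inheritParams image_volume
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid_geometry(data, spacing, origin)
  assert_that(is.logical(data) && !anyNA(data),
              "mask data must be logical without missing values")
  new_grid(data, spacing, origin, "binary_mask")
}

#' Lobar label map
#'
#' Integer voxel grid with 0 for background and labels 1-6 for the lobar
#' territories in the order given by [lobe_regions()].
#'
#' @param data 3D integer array with values in `0:6`.
#' @inheritParams image_volume
#' @return A `label_map` object.
#' @export
label_map <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid_geometry(data, spacing, origin)
  assert_that(!anyNA(data) && all(data %in% 0:6),
              "label map values must be integers in 0..6")
  storage.mode(data) <- "integer"
  new_grid(data, spacing, origin, "label_map")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.2f mL)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              mm3_to_ml(sum(x$data) * voxel_volume_mm3(x$spacing))))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- tabulate(x$data, nbins = 6)
  cat(sprintf("<label_map> %s voxels; labelled: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%s=%d", lobe_regions(), tab), collapse = " ")))
  invisible(x)
}

nifti_geometry <- function(img, path) {
  pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  dir <- xf[1:3, 1:3]
  sp <- as.double(pd[1:3])
  # axis-aligned check: off-diagonal of the direction matrix must vanish
  offdiag <- dir; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-3 * max(sp)) {
    rlang::abort(sprintf("'%s' has an oblique orientation, which is not supported",
                         path))
  }
  list(spacing = sp, origin = as.double(xf[1:3, 4]))
}

#' Read a NIfTI volume
#'
#' Reads a scalar 3D NIfTI-1 image, applying any header scale slope/intercept,
#' and returns it with the voxel spacing and origin taken from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind One of `"image"`, `"mask"`, `"labels"`: controls whether the
#'   payload is interpreted as HU, binary, or integer lobar labels.
#' @return An [image_volume], [binary_mask] or [label_map].
#' @export
read_volume <- function(path, kind = c("image", "mask", "labels")) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), sprintf("file '%s' does not exist", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  dm <- dim(a)
  if (length(dm) == 4 && dm[4] == 1) dm <- dm[1:3]
  attributes(a) <- NULL
  dim(a) <- dm # plain array, no image attributes
  assert_that(length(dm) == 3,
              sprintf("'%s' is not a 3D scalar image (dims: %s)",
                      path, paste(dm, collapse = "x")))
  assert_that(is.numeric(a), sprintf("'%s' has a non-scalar datatype", path))
  geo <- nifti_geometry(img, path)
  switch(kind,
    image  = image_volume(a, geo$spacing, geo$origin),
    mask   = binary_mask(a != 0, geo$spacing, geo$origin),
    labels = label_map(round(a), geo$spacing, geo$origin))
}

#' Write a volume, mask or label map as NIfTI-1
#'
#' Integer payloads (masks, label maps) are stored as int16 and round-trip
#' bit-exactly; HU images are stored as float32.
#'
#' @param vol An [image_volume], [binary_mask] or [label_map].
#' @param path Output path (`.nii` or `.nii.gz`); its directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_that(dir.exists(dirname(path)),
              sprintf("directory '%s' does not exist", dirname(path)))
  a <- vol$data
  datatype <- "float"
  if (inherits(vol, "binary_mask") || inherits(vol, "label_map")) {
    a <- array(as.integer(a), dim(a))
    datatype <- "int16"
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- vol$spacing
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
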