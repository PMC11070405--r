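# Internal helpers shared across modules.

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# voxel volume in mm^3 / mL for a spacing triple
voxel_volume_mm3 <- function(spacing) prod(spacing)
mm3_to_ml <- function(mm3) mm3 * 1e-3

# seeds/markers are tibbles with columns lobe_label, i, j, k (1-based voxel
# indices); convert to the 0-based integer matrix the C++ kernels expect
seed_matrix0 <- function(seeds) {
  m <- as.matrix(seeds[, c("i", "j", "k")])
  storage.mode(m) <- "integer"
  m - 1L
}

in_grid <- function(seeds, dm) {
  all(seeds$i >= 1 & seeds$i <= dm[1] &
      seeds$j >= 1 & seeds$j <= dm[2] &
      seeds$k >= 1 & seeds$k <= dm[3])
}

#' Dice similarity coefficient of two binary masks
#'
#' Spatial-overlap score \eqn{2|A \cap B| / (|A| + |B|)} used throughout the
#' package to compare recovered segmentations against phantom ground truth.
#'
#' @param a,b Logical arrays (or [binary_mask] objects) of identical shape.
#' @return A number in \[0, 1\]; 1 for identical non-empty masks. Two empty
#'   masks give `NaN`.
#' @export
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
#' dice(a, b)
dice <- function(a, b) {
  if (inherits(a, "binary_mask")) a <- a$data
  if (inherits(b, "binary_mask")) b <- b$data
  assert_that(identical(dim(a), dim(b)), "dice(): masks must share a grid")
  2 * sum(a & b) / (sum(a) + sum(b))
}

# run expr with a temporarily fixed RNG state
with_seed <- function(seed, expr) withr::with_seed(seed, expr)

# derive a distinct child seed (kept below 2^31)
child_seed <- function(seed, salt) {
  (as.double(seed) * 2654435.0 + salt * 97.0) %% 2147483647
}
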