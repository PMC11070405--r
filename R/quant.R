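# Mass and volume quantification.
#
# Mass uses the linear HU decomposition between pure air (-1000 HU) and pure
# tissue (50 HU): the non-air volumetric fraction of a voxel is
#   T_f = (HU - HU_air) / (HU_tissue - HU_air),
# and its mass is T_f * voxel volume (cm^3) * 1.053 g/mL, the lung
# parenchymal tissue density.  Volume is voxel counting: count * voxel
# volume, mm^3 converted to mL.  All unit conversions are centralised here.

#' Air--tissue decomposition constants
#'
#' @param hu_tissue HU of pure tissue (default 50).
#' @param hu_air HU of pure air (default -1000).
#' @param rho_tissue Lung parenchymal tissue density in g/mL (default 1.053).
#' @return A `decomposition_constants` list.
#' @export
decomposition_constants <- function(hu_tissue = 50, hu_air = -1000,
                                    rho_tissue = 1.053) {
  assert_that(hu_tissue > hu_air, "hu_tissue must exceed hu_air")
  assert_that(rho_tissue > 0, "rho_tissue must be positive")
  structure(list(hu_tissue = hu_tissue, hu_air = hu_air,
                 rho_tissue = rho_tissue),
            class = "decomposition_constants")
}

#' Non-air tissue fraction of a voxel
#'
#' Linear decomposition `(hu - hu_air) / (hu_tissue - hu_air)`, clamped to
#' \[0, 1\] (dense vessels above 50 HU would otherwise exceed 1, and values
#' below -1000 HU would go negative).  The number of clamped values is
#' reported in the `"n_clamped"` attribute.
#'
#' @param hu Numeric vector/array of HU values (finite).
#' @param consts [decomposition_constants()].
#' @return Fractions in \[0, 1\], same shape as `hu`.
#' @export
#' @examples
#' tissue_fraction(c(-1000, -475, 50))
tissue_fraction <- function(hu, consts = decomposition_constants()) {
  assert_that(all(is.finite(hu)), "tissue_fraction(): non-finite HU value")
  tf <- (hu - consts$hu_air) / (consts$hu_tissue - consts$hu_air)
  n_clamped <- sum(tf < 0 | tf > 1)
  tf <- pmin(pmax(tf, 0), 1)
  attr(tf, "n_clamped") <- n_clamped
  tf
}

#' Mass of a voxel from its HU value
#'
#' @param hu HU value(s).
#' @param voxel_volume_cm3 Voxel volume in cm^3 (positive).
#' @param consts [decomposition_constants()].
#' @return Mass in grams: `tissue_fraction(hu) * voxel_volume_cm3 *
#'   rho_tissue`.
#' @export
#' @examples
#' voxel_mass(-475, 1) # half-tissue voxel of 1 cm^3
voxel_mass <- function(hu, voxel_volume_cm3, consts = decomposition_constants()) {
  assert_that(voxel_volume_cm3 > 0, "voxel volume must be positive")
  tf <- tissue_fraction(hu, consts)
  out <- as.vector(tf) * voxel_volume_cm3 * consts$rho_tissue
  attr(out, "n_clamped") <- attr(tf, "n_clamped")
  out
}

#' Lobar and global mass/volume measurements
#'
#' Sums voxel masses (Hounsfield tissue-fraction decomposition) and voxel
#' counts per lobar territory and globally.  The global row aggregates
#' labels 1-6, so lobar masses add up to the global mass by construction.
#'
#' @param vol [image_volume] sharing the grid of `labels`.
#' @param labels [label_map] of lobar territories.
#' @param consts [decomposition_constants()].
#' @param acquisition_id,observer_id Identifiers carried into the output.
#' @return A tibble of class `lobar_measurements`: columns `acquisition_id`,
#'   `observer_id`, `region` (`LUL, LLL, RUL, RML, RLL, AL, GLOBAL`),
#'   `label`, `voxels`, `volume_ml`, `mass_g`, with the number of clamped
#'   voxels in attribute `"n_clamped"`.
#' @export
measure_lobes <- function(vol, labels, consts = decomposition_constants(),
                          acquisition_id = NA_character_,
                          observer_id = NA_character_) {
  assert_that(identical(dim(vol$data), dim(labels$data)) &&
                max(abs(vol$spacing - labels$spacing)) < 1e-9,
              "measure_lobes(): volume and labels must share grid and spacing")
  vox_cm3 <- voxel_volume_mm3(vol$spacing) * 1e-3
  vox_ml <- vox_cm3 # 1 cm^3 = 1 mL
  lab <- as.integer(labels$data)
  sel <- lab > 0L
  tf <- tissue_fraction(vol$data[sel], consts)
  n_clamped <- attr(tf, "n_clamped")
  lab_sel <- lab[sel]
  mass_by_lobe <- vapply(1:6, function(l) sum(tf[lab_sel == l]), 0) *
    vox_cm3 * consts$rho_tissue
  counts <- tabulate(lab_sel, nbins = 6)
  out <- tibble::tibble(
    acquisition_id = acquisition_id, observer_id = observer_id,
    region = c(lobe_regions(), "GLOBAL"),
    label = c(1:6, NA_integer_),
    voxels = c(counts, sum(counts)),
    volume_ml = c(counts, sum(counts)) * vox_ml,
    mass_g = c(mass_by_lobe, sum(mass_by_lobe)))
  attr(out, "n_clamped") <- n_clamped
  class(out) <- c("lobar_measurements", class(out))
  out
}
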