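#' Tissue and material labels
#'
#' The simulation recognises seven materials: the six used for the neck
#' anatomy (air, skin, adipose, muscle, bone, tumor) plus water for the
#' calibration phantom. Voxel grids store labels as 0-based integer codes in
#' this order.
#'
#' @return Character vector of the seven labels, in code order.
#' @export
tissue_levels <- function() {
  c("air", "skin", "adipose", "muscle", "bone", "tumor", "water")
}

tissue_code <- function(label) {
  idx <- match(label, tissue_levels())
  if (anyNA(idx)) {
    abort(paste0("unknown tissue label: ",
                 paste(unique(label[is.na(idx)]), collapse = ", ")))
  }
  idx - 1L
}

tissue_label <- function(code) {
  tissue_levels()[code + 1L]
}

#' Default nominal mass densities by tissue
#'
#' Nominal densities (g/cm^3) used when building synthetic phantoms. Values
#' are the usual radiotherapy bulk densities: air 0.0012, skin 1.09,
#' adipose 0.95, muscle 1.05, cortical-ish bone 1.85, tumor 1.04 (soft
#' tissue), water 1.0.
#'
#' @return Named numeric vector over [tissue_levels()].
#' @export
default_tissue_densities <- function() {
  c(air = 0.0012, skin = 1.09, adipose = 0.95, muscle = 1.05,
    bone = 1.85, tumor = 1.04, water = 1.00)
}

#' Default density-to-tissue calibration table
#'
#' Piecewise-constant stand-in for a CT scanner calibration curve: a density
#' d maps to the label of the first interval containing it, with interval
#' upper edges at 0.05 (air), 0.95 (adipose), 1.2 (muscle) and infinity
#' (bone). A value exactly on a threshold takes the lower interval's label.
#'
#' @return Tibble with columns `upper` (g/cm^3, strictly increasing) and
#'   `tissue`.
#' @export
default_density_calibration <- function() {
  tibble(upper = c(0.05, 0.95, 1.2, Inf),
         tissue = c("air", "adipose", "muscle", "bone"))
}

#' Map a mass density to a tissue label
#'
#' Applies a piecewise-constant calibration table: the label of the first
#' interval whose upper edge is >= the density. Densities exactly on a
#' threshold take the lower interval's label.
#'
#' @param density Numeric vector of mass densities, g/cm^3 (must be >= 0).
#' @param calibration Tibble with strictly increasing `upper` thresholds and
#'   `tissue` labels; defaults to [default_density_calibration()].
#' @return Character vector of tissue labels, same length as `density`.
#' @export
#' @examples
#' density_to_tissue(c(0.0012, 1.05, 1.85))
density_to_tissue <- function(density, calibration = default_density_calibration()) {
  if (any(density < 0)) abort("density must be non-negative")
  up <- calibration$upper
  if (is.unsorted(up, strictly = TRUE)) {
    abort("calibration thresholds must be strictly increasing")
  }
  if (!is.infinite(up[length(up)])) {
    abort("calibration must cover [0, Inf): last threshold must be Inf")
  }
  # first interval containing the value; ties go to the lower interval
  idx <- findInterval(density, up, left.open = TRUE) + 1L
  calibration$tissue[idx]
}
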