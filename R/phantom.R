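#' Voxelized phantom grids
#'
#' A `voxel_grid` holds tissue labels and mass densities on a regular 3D
#' lattice. Coordinates are millimetres in a right-handed frame with
#' +x toward the patient's left, +y anterior and +z superior; gantry angle
#' 0 corresponds to a beam travelling along -y (downward onto a supine
#' patient). Voxels are addressed by their centers; `origin` is the world
#' position of the center of voxel (1,1,1).
#'
#' @param tissue Integer 3D array of 0-based tissue codes (see
#'   [tissue_levels()]) or character array of labels.
#' @param density Numeric 3D array of mass densities, g/cm^3, same dims.
#' @param spacing Numeric length-3 voxel spacing in mm, all > 0.
#' @param origin Numeric length-3 world position (mm) of the first voxel
#'   center.
#' @return An object of class `voxel_grid` with fields `tissue`, `density`,
#'   `dims`, `spacing`, `origin`.
#' @export
voxel_grid <- function(tissue, density, spacing = c(1, 1, 1.3),
                       origin = NULL) {
  if (is.character(tissue)) {
    dims <- dim(tissue)
    tissue <- array(tissue_code(tissue), dim = dims)
  }
  tissue <- array(as.integer(tissue), dim = dim(tissue))
  dims <- dim(tissue)
  if (length(dims) != 3L) abort("tissue must be a 3D array")
  if (!identical(dim(density), dims)) abort("density dims must match tissue dims")
  if (length(spacing) != 3L || any(spacing <= 0)) abort("spacing must be 3 positive values")
  if (any(density < 0)) abort("density must be non-negative")
  bad <- tissue < 0L | tissue >= length(tissue_levels())
  if (any(bad)) abort("tissue codes out of range")
  if (any(density[tissue == 0L] >= 0.01)) {
    abort("air voxels must have density < 0.01 g/cm^3")
  }
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  structure(
    list(tissue = tissue, density = array(as.double(density), dim = dims),
         dims = dims, spacing = as.double(spacing),
         origin = as.double(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  tab <- table(tissue_label(x$tissue))
  cat("  tissues: ", paste0(names(tab), " (", as.integer(tab), ")",
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Voxel-center coordinates along one axis
#' @param grid A [voxel_grid()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of world coordinates (mm) of voxel centers.
#' @export
voxel_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Voxel volume in mm^3
#' @param grid A [voxel_grid()].
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Linear (1-based) voxel index of world positions
#'
#' @param grid A [voxel_grid()].
#' @param x,y,z World coordinates, mm (must lie inside the grid).
#' @return Integer vector of 1-based linear indices into the grid arrays.
#' @export
voxel_index <- function(grid, x, y, z) {
  lo <- grid$origin - grid$spacing / 2
  ix <- floor((x - lo[1]) / grid$spacing[1])
  iy <- floor((y - lo[2]) / grid$spacing[2])
  iz <- floor((z - lo[3]) / grid$spacing[3])
  if (any(ix < 0 | ix >= grid$dims[1] | iy < 0 | iy >= grid$dims[2] |
            iz < 0 | iz >= grid$dims[3])) {
    abort("position outside the grid")
  }
  as.integer(ix + grid$dims[1] * (iy + grid$dims[2] * iz) + 1)
}

#' Total phantom mass in kg
#' @param grid A [voxel_grid()].
#' @export
grid_mass_kg <- function(grid) {
  # density g/cm^3 = 1e-3 g/mm^3; volume mm^3 -> grams -> kg
  sum(grid$density) * voxel_volume(grid) * 1e-3 * 1e-3
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default neck geometry descriptor
#'
#' Geometry of the synthetic neck: a cylinder of muscle wrapped in an
#' adipose layer and a skin shell, with a central-anterior air lumen
#' (airway), a posterior bone cylinder (vertebral body stand-in), and an
#' ellipsoidal tumor lateral to the lumen. All lengths in mm; transverse
#' offsets are (x, y) from the neck axis, anterior = +y.
#'
#' @return Named list of geometry parameters.
#' @export
default_neck_geometry <- function() {
  list(
    neck_radius = 50,
    skin_thickness = 2,
    adipose_thickness = 5,
    airway_radius = 8, airway_center = c(0, 14),
    vertebra_radius = 12, vertebra_center = c(0, -22),
    tumor_center = c(17, 8, 0), tumor_radii = c(8, 8, 10),
    z_extent = 78,
    air_margin = 4,
    density_jitter_sd = 0.02
  )
}

#' Generate a synthetic voxelized neck phantom
#'
#' Builds the concentric neck anatomy described by a geometry descriptor:
#' skin shell, adipose layer, muscle bulk, posterior bone cylinder, central
#' air lumen, and a tumor ellipsoid lateral to the lumen. Per-voxel
#' densities are drawn as tissue nominal density plus seeded Gaussian
#' jitter (air is left at its nominal density).
#'
#' @param params Geometry descriptor as from [default_neck_geometry()];
#'   entries override the defaults.
#' @param spacing Voxel spacing mm, default `c(1, 1, 1.3)`.
#' @param seed Integer seed for the density jitter.
#' @param densities Named nominal densities, default
#'   [default_tissue_densities()].
#' @return A [voxel_grid()].
#' @export
#' @examples
#' ph <- generate_neck_phantom(seed = 1)
#' table(tissue_levels()[ph$tissue + 1])
generate_neck_phantom <- function(params = list(), spacing = c(1, 1, 1.3),
                                  seed = 1L,
                                  densities = default_tissue_densities()) {
  p <- utils::modifyList(default_neck_geometry(), params)
  stopifnot(p$neck_radius > 0, p$skin_thickness > 0, p$adipose_thickness > 0,
            p$airway_radius > 0, p$vertebra_radius > 0, all(p$tumor_radii > 0))

  half_xy <- p$neck_radius + p$air_margin
  dims <- c(2 * ceiling(half_xy / spacing[1]) + 1,
            2 * ceiling(half_xy / spacing[2]) + 1,
            2 * ceiling(p$z_extent / 2 / spacing[3]) + 1)
  origin <- -(dims - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]

  # transverse radius^2 field, recycled over z
  r2 <- outer(xs^2, ys^2, `+`)
  lab2 <- array(0L, dim = dims[1:2])  # air
  R <- p$neck_radius
  lab2[r2 <= R^2] <- tissue_code("muscle")
  ad_out <- R - p$skin_thickness
  ad_in <- ad_out - p$adipose_thickness
  lab2[r2 <= ad_out^2 & r2 > ad_in^2] <- tissue_code("adipose")
  lab2[r2 <= R^2 & r2 > ad_out^2] <- tissue_code("skin")
  vb <- outer((xs - p$vertebra_center[1])^2, (ys - p$vertebra_center[2])^2, `+`)
  lab2[vb <= p$vertebra_radius^2 & lab2 == tissue_code("muscle")] <- tissue_code("bone")
  aw <- outer((xs - p$airway_center[1])^2, (ys - p$airway_center[2])^2, `+`)
  lumen <- aw <= p$airway_radius^2 & lab2 != 0L

  tissue <- array(rep(lab2, times = dims[3]), dim = dims)

  # tumor ellipsoid, assigned only where muscle (it must sit inside the body)
  tc <- p$tumor_center; tr <- p$tumor_radii
  ell <- outer(outer((xs - tc[1])^2 / tr[1]^2, (ys - tc[2])^2 / tr[2]^2, `+`),
               (zs - tc[3])^2 / tr[3]^2, `+`)
  tum <- ell <= 1 & tissue == tissue_code("muscle")
  if (!any(tum)) {
    abort("tumor ellipsoid does not intersect the muscle region of the body")
  }
  tissue[tum] <- tissue_code("tumor")
  tissue[array(rep(lumen, times = dims[3]), dim = dims)] <- 0L

  density <- array(densities[tissue_label(tissue)], dim = dims)
  if (p$density_jitter_sd > 0) {
    jit <- with_local_seed(seed, array(rnorm(prod(dims), 0, p$density_jitter_sd),
                                       dim = dims))
    nonair <- tissue != 0L
    density[nonair] <- pmax(density[nonair] + jit[nonair], 0.1)
  }
  voxel_grid(tissue, density, spacing = spacing, origin = origin)
}

#' Generate a uniform water calibration phantom
#'
#' A rectangular block of water, density 1.0 g/cm^3 throughout, used for
#' monitor-unit calibration. The third (z) dimension is the depth direction
#' of the calibration beam.
#'
#' @param dims_cm Length-3 extents in cm, default `c(30, 30, 50)`.
#' @param spacing Voxel spacing in mm, default 2 mm isotropic.
#' @return A [voxel_grid()] labelled water throughout.
#' @export
#' @examples
#' wp <- generate_water_phantom(c(30, 30, 50))
#' wp$dims  # 150 x 150 x 250
generate_water_phantom <- function(dims_cm = c(30, 30, 50), spacing = c(2, 2, 2)) {
  if (any(dims_cm <= 0)) abort("phantom extents must be positive")
  dims <- as.integer(round(dims_cm * 10 / spacing))
  tissue <- array(tissue_code("water"), dim = dims)
  density <- array(1.0, dim = dims)
  voxel_grid(tissue, density, spacing = spacing)
}
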