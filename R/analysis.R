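#' Monitor-unit calibration from a water-phantom run
#'
#' Reads the per-particle dose `D_d` at the beam-axis voxel nearest the
#' calibration depth (default 15 mm below the entrance surface, beam along
#' -z) and computes the number of source particles per monitor unit as
#' `N = 1 cGy / D_d`, so that scaling any per-particle quantity by `N x MU`
#' converts it to physical units.
#'
#' @param dose A per-particle `dose_grid` from the calibration geometry.
#' @param depth_mm Calibration depth below the entrance (+z) surface, mm.
#' @return A `mu_calibration`: list with `D_d` (Gy/particle), `N`
#'   (particles/MU), `depth_mm`, `voxel` (index triple used).
#' @export
calibrate_mu <- function(dose, depth_mm = 15) {
  stopifnot(inherits(dose, "dose_grid"))
  xs <- dose$origin[1] + (seq_len(dose$dims[1]) - 1) * dose$spacing[1]
  ys <- dose$origin[2] + (seq_len(dose$dims[2]) - 1) * dose$spacing[2]
  zs <- dose$origin[3] + (seq_len(dose$dims[3]) - 1) * dose$spacing[3]
  cx <- mean(range(xs)); cy <- mean(range(ys))
  z_surf <- max(zs) + dose$spacing[3] / 2
  vox <- c(which.min(abs(xs - cx)), which.min(abs(ys - cy)),
           which.min(abs(zs - (z_surf - depth_mm))))
  D_d <- dose$dose[vox[1], vox[2], vox[3]]
  if (D_d <= 0) abort("zero dose at the calibration point")
  structure(list(D_d = D_d, N = 0.01 / D_d, depth_mm = depth_mm,
                 voxel = vox),
            class = "mu_calibration")
}

#' @export
print.mu_calibration <- function(x, ...) {
  cat("<mu_calibration> D_d = ", signif(x$D_d, 4), " Gy/particle, N = ",
      signif(x$N, 4), " particles/MU\n", sep = "")
  invisible(x)
}

#' Scale a per-particle quantity to physical units
#'
#' Multiplies by the calibrated particles-per-MU and the delivered monitor
#' units; applies uniformly to dose grids, emission grids, photon counts or
#' plain numbers.
#'
#' @param x Per-particle quantity (numeric, array, or `dose_grid`).
#' @param cal A [calibrate_mu()] result.
#' @param mu_total Delivered monitor units (>= 0).
#' @return `x` scaled by `N x mu_total` (a `dose_grid` keeps its class,
#'   with units flag set to "physical").
#' @export
scale_to_physical <- function(x, cal, mu_total) {
  stopifnot(inherits(cal, "mu_calibration"), mu_total >= 0)
  if (inherits(x, "dose_grid")) {
    x$dose <- x$dose * cal$N * mu_total
    x$energy_mev <- x$energy_mev * cal$N * mu_total
    x$units <- "physical"
    return(x)
  }
  x * cal$N * mu_total
}

default_band_threshold <- function(band) {
  if (isTRUE(all.equal(band, c(500, 1200)))) 0.05
  else if (isTRUE(all.equal(band, c(710, 720)))) 0.10
  else 0
}

exits_in_band <- function(exits, band) {
  filter(exits, .data$wavelength_nm >= band[1], .data$wavelength_nm <= band[2])
}

#' Attach surface-mesh element ids to exit records
#'
#' @param exits Exit-record tibble from [trace_optical_photons()].
#' @param mesh The [extract_surface_mesh()] of the same grid.
#' @return `exits` with an `element_id` column.
#' @export
exits_with_elements <- function(exits, mesh) {
  exits$element_id <- match_mesh_elements(mesh, exits$exit_voxel,
                                          exits$exit_face)
  exits
}

# element ids within Chebyshev distance 1 (voxel indices) of each element;
# approximately the 3x3 patch on flat surface regions
mesh_neighbor_sets <- function(mesh) {
  dims <- attr(mesh, "dims")
  key <- function(ix, iy, iz) ix + (dims[1] + 2) * (iy + (dims[2] + 2) * iz)
  n <- nrow(mesh)
  vox_key <- key(mesh$ix, mesh$iy, mesh$iz)
  uk <- sort(unique(vox_key))
  by_vox <- split(mesh$element_id, factor(match(vox_key, uk), levels = seq_along(uk)))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  # element x 27 candidate voxel keys, matched in one vectorized pass
  cand <- match(rep(vox_key, times = 27) +
                  rep(key(offs$dx + 1, offs$dy, offs$dz) - key(1, 0, 0),
                      each = n),
                uk)
  dim(cand) <- c(n, 27)
  lapply(seq_len(n), function(i) {
    ks <- cand[i, ]
    unlist(by_vox[ks[!is.na(ks)]], use.names = FALSE)
  })
}

#' Surface light intensity map
#'
#' Bins surface-exit records onto the mesh elements of the phantom surface
#' (photons per mm^2 within a wavelength band), optionally median-filters
#' each element over its face-adjacent neighbourhood, and zeroes values
#' below a fraction of the map maximum (defaults: 5% for the full
#' 500-1200 nm band, 10% for the narrow 710-720 nm band).
#'
#' @param exits Exit records.
#' @param mesh Surface mesh.
#' @param band Wavelength band `(lo, hi)` nm within 500-1200.
#' @param filter Apply the median filter (default FALSE).
#' @param threshold_fraction Threshold as fraction of the maximum; NULL
#'   uses the band-specific default.
#' @return A `surface_map`: tibble with `element_id`, `count`, `area`,
#'   `value` (photons/mm^2), with processing provenance in attributes.
#' @export
surface_intensity_map <- function(exits, mesh, band = c(500, 1200),
                                  filter = FALSE, threshold_fraction = NULL) {
  if (band[1] < LAMBDA_MIN || band[2] > LAMBDA_MAX || band[1] > band[2]) {
    abort("band must lie within 500-1200 nm")
  }
  if (is.null(threshold_fraction)) threshold_fraction <- default_band_threshold(band)
  sel <- exits_in_band(exits, band)
  if (!"element_id" %in% names(sel)) sel <- exits_with_elements(sel, mesh)
  cnt <- table(factor(sel$element_id, levels = mesh$element_id))
  map <- tibble(element_id = mesh$element_id,
                count = as.numeric(cnt),
                area = mesh$area,
                value = as.numeric(cnt) / mesh$area)
  if (filter) {
    nbrs <- mesh_neighbor_sets(mesh)
    v <- map$value
    map$value <- vapply(seq_along(v),
                        function(i) stats::median(v[nbrs[[i]]]), numeric(1))
  }
  if (threshold_fraction > 0 && any(map$value > 0)) {
    map$value[map$value < threshold_fraction * max(map$value)] <- 0
  }
  attr(map, "band") <- band
  attr(map, "filtered") <- filter
  attr(map, "threshold_fraction") <- threshold_fraction
  class(map) <- c("surface_map", class(map))
  map
}

#' Cherenkov light spectrum
#'
#' Wavelength histogram of a photon bank or exit-record set over
#' contiguous bins spanning 500-1200 nm, normalized to peak = 1 (or to
#' unit sum).
#'
#' @param photons Tibble with a `wavelength_nm` column (emitted bank,
#'   surface exits, or a region-restricted subset).
#' @param bin_nm Bin width, nm (default 10).
#' @param normalization `"peak"` (max bin = 1) or `"sum"`.
#' @return A `cherenkov_spectrum` tibble with `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`, `intensity`.
#' @export
compute_spectrum <- function(photons, bin_nm = 10, normalization = "peak") {
  if (nrow(photons) == 0) abort("empty photon selection")
  breaks <- seq(LAMBDA_MIN, LAMBDA_MAX, by = bin_nm)
  if (breaks[length(breaks)] < LAMBDA_MAX) breaks <- c(breaks, LAMBDA_MAX)
  h <- graphics::hist(photons$wavelength_nm, breaks = breaks, plot = FALSE)
  intensity <- h$counts /
    if (normalization == "peak") max(h$counts) else sum(h$counts)
  out <- tibble(bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
                bin_mid = h$mids, count = h$counts, intensity = intensity)
  attr(out, "normalization") <- normalization
  class(out) <- c("cherenkov_spectrum", class(out))
  out
}

#' Identify the tumor spot on the patient surface
#'
#' Builds the (unthresholded) surface map of tumor-born exits and takes the
#' largest face-connected component of elements at or above
#' `spot_fraction` of the map maximum (default 50%). Ties between equal
#' components go to the one containing the smallest element id.
#'
#' @param exits Exit records carrying `born_in_tumor`.
#' @param mesh Surface mesh.
#' @param spot_fraction Fraction of the maximum (default 0.5).
#' @param filter Median-filter the tumor-born map before thresholding
#'   (default TRUE; smooths counting noise).
#' @return A `surface_region`: list with `element_ids` and `descriptor`.
#' @export
identify_tumor_spot <- function(exits, mesh, spot_fraction = 0.5,
                                filter = TRUE) {
  tb <- filter(exits, .data$born_in_tumor)
  if (nrow(tb) == 0) {
    abort("no tumor-born surface exits: tumor is optically unreachable at this photon budget")
  }
  map <- surface_intensity_map(tb, mesh, band = c(LAMBDA_MIN, LAMBDA_MAX),
                               filter = filter, threshold_fraction = 0)
  keep <- which(map$value >= spot_fraction * max(map$value))
  # connected components over the face-adjacency of the selected elements
  nbrs <- mesh_neighbor_sets(mesh)
  keep_set <- logical(nrow(mesh))
  keep_set[keep] <- TRUE
  comp <- integer(nrow(mesh))
  ncomp <- 0
  for (s in keep) {
    if (comp[s] != 0) next
    ncomp <- ncomp + 1
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nb <- nbrs[[cur]]
      nb <- nb[keep_set[nb] & comp[nb] == 0]
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp[keep], nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_elem <- vapply(best, function(cmp) min(which(comp == cmp)),
                         numeric(1))
    best <- best[which.min(first_elem)]
  }
  surface_region(which(comp == best), "tumor-spot", mesh)
}

#' Construct a surface region
#' @param element_ids Mesh element ids (nonempty).
#' @param descriptor Free-text descriptor (e.g. "tumor-spot", "full").
#' @param mesh The mesh the ids refer to.
#' @return A `surface_region`.
#' @export
surface_region <- function(element_ids, descriptor, mesh) {
  element_ids <- sort(unique(element_ids))
  if (length(element_ids) == 0) abort("surface region is empty")
  if (!all(element_ids %in% mesh$element_id)) {
    abort("region references elements not in the mesh")
  }
  structure(list(element_ids = element_ids, descriptor = descriptor),
            class = "surface_region")
}

#' The full surface as a region
#' @param mesh Surface mesh.
#' @export
full_surface_region <- function(mesh) {
  surface_region(mesh$element_id, "full", mesh)
}

#' @export
print.surface_region <- function(x, ...) {
  cat("<surface_region> ", x$descriptor, ", ", length(x$element_ids),
      " elements\n", sep = "")
  invisible(x)
}

#' Reduced measurement area around the tumor spot
#'
#' All surface elements of the anterior half of the phantom lying within an
#' axis-aligned band of the given width along the left-right (x) axis,
#' centered on the spot's area-weighted centroid and spanning the full
#' superior-inferior extent. Shipped defaults in the analyses are widths of
#' 100 and 80 mm.
#'
#' @param spot A `surface_region` (typically the tumor spot).
#' @param mesh Surface mesh.
#' @param width_mm Band width along x, mm (> 0).
#' @return A `surface_region`.
#' @export
make_reduced_area <- function(spot, mesh, width_mm) {
  if (width_mm <= 0) abort("width must be positive")
  sel <- mesh[mesh$element_id %in% spot$element_ids, ]
  cx0 <- sum(sel$cx * sel$area) / sum(sel$area)
  y_mid <- (max(mesh$cy) + min(mesh$cy)) / 2
  ids <- mesh$element_id[mesh$cy >= y_mid &
                           abs(mesh$cx - cx0) <= width_mm / 2]
  if (length(ids) == 0) abort("reduced-area band contains no surface elements")
  surface_region(ids, paste0("reduced-area ", width_mm, " mm"), mesh)
}

#' Origin distribution of surface light
#'
#' 3D histogram (photons per mm^3 per voxel) of the birth positions of the
#' photons whose exit element lies in a surface region: where in the
#' tissue the light emerging on that part of the surface was emitted.
#'
#' @param exits Exit records with `element_id` and `birth_voxel` columns
#'   (see [exits_with_elements()]).
#' @param region A `surface_region`; NULL means the whole surface.
#' @param grid The [voxel_grid()].
#' @param band Optional wavelength band restriction.
#' @return An `emission_grid`: list with `values` (photons/mm^3 array),
#'   `counts`, grid geometry.
#' @export
origin_distribution <- function(exits, region = NULL, grid,
                                band = NULL) {
  sel <- exits
  if (!is.null(band)) sel <- exits_in_band(sel, band)
  if (!is.null(region)) {
    sel <- filter(sel, .data$element_id %in% region$element_ids)
  }
  counts <- array(0, dim = grid$dims)
  if (nrow(sel) > 0) {
    tab <- table(sel$birth_voxel)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  structure(list(values = counts / voxel_volume(grid), counts = counts,
                 dims = grid$dims, spacing = grid$spacing,
                 origin = grid$origin),
            class = "emission_grid")
}

#' Similarity between two spatial light distributions
#'
#' Histogram intersection after normalizing each distribution to unit sum:
#' `sum_v min(a_v, b_v)`, in \[0, 1\]; 1 iff the normalized distributions
#' coincide, 0 for disjoint supports.
#'
#' @param dist_a,dist_b `emission_grid`s (or plain arrays) on identical
#'   grids.
#' @return Scalar in \[0, 1\].
#' @export
region_similarity <- function(dist_a, dist_b) {
  a <- if (inherits(dist_a, "emission_grid")) dist_a$values else dist_a
  b <- if (inherits(dist_b, "emission_grid")) dist_b$values else dist_b
  if (!identical(dim(a), dim(b))) abort("distributions must share a grid")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 || sb == 0) abort("cannot compare an all-zero distribution")
  sum(pmin(a / sa, b / sb))
}

#' Zero out values below a fraction of the maximum
#'
#' @param x Numeric array, or `dose_grid`/`emission_grid`.
#' @param fraction Cut-off fraction in \[0, 1\] (e.g. 0.01 for the emission
#'   displays, 0.10 for dose displays).
#' @return Same shape as `x` with sub-threshold values set to zero.
#' @export
apply_fraction_cutoff <- function(x, fraction) {
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  cut_arr <- function(a) {
    if (any(a > 0)) a[a < fraction * max(a)] <- 0
    a
  }
  if (inherits(x, "dose_grid")) {
    x$dose <- cut_arr(x$dose)
    return(x)
  }
  if (inherits(x, "emission_grid")) {
    x$values <- cut_arr(x$values)
    x$counts <- cut_arr(x$counts)
    return(x)
  }
  cut_arr(x)
}
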