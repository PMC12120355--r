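#' Sample an exponential free path
#'
#' `-log(u) / mu_t`; with `mu_t = 0` the path is infinite (straight flight
#' to the boundary).
#'
#' @param mu_t Total interaction coefficient, 1/mm (>= 0).
#' @param u Uniform variates in (0, 1).
#' @return Path lengths in mm (possibly `Inf`).
#' @export
sample_free_path <- function(mu_t, u) {
  if (any(u <= 0 | u >= 1)) abort("u must lie strictly inside (0, 1)")
  if (any(mu_t < 0)) abort("mu_t must be non-negative")
  len <- max(length(mu_t), length(u))
  mu <- rep_len(mu_t, len)
  path <- -log(rep_len(u, len)) / mu
  path[mu == 0] <- Inf
  path
}

#' Henyey-Greenstein deflection cosine
#'
#' Closed-form inverse-CDF sample of the Henyey-Greenstein phase function
#' with anisotropy `g`; `g = 0` degenerates to isotropic scattering
#' (`cos theta = 2u - 1`). The mean deflection cosine equals `g`.
#'
#' @param g Anisotropy factor in (-1, 1).
#' @param u Uniform variates; drawn internally if omitted.
#' @param n_samples Number of samples when `u` is omitted.
#' @return Deflection cosines in \[-1, 1\].
#' @export
#' @examples
#' scatter_hg(0.9, u = 0.5)  # ~0.9855
scatter_hg <- function(g, u = NULL, n_samples = 1) {
  if (abs(g) >= 1) abort("anisotropy g must satisfy |g| < 1")
  if (is.null(u)) u <- runif(n_samples)
  if (abs(g) < 1e-12) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  (1 + g^2 - f^2) / (2 * g)
}

#' Unpolarized Fresnel reflectance
#'
#' @param cos_i Cosine of the incidence angle (w.r.t. the surface normal).
#' @param n_in,n_out Refractive indices on the incidence and transmission
#'   sides.
#' @return Reflectance in \[0, 1\] (1 beyond the critical angle).
#' @export
#' @examples
#' fresnel_reflectance(1, 1.4, 1)  # (0.4/2.4)^2 ~ 0.0278
fresnel_reflectance <- function(cos_i, n_in, n_out) {
  s2 <- (n_in / n_out)^2 * (1 - cos_i^2)
  if (s2 >= 1) return(1)
  cos_t <- sqrt(1 - s2)
  rs <- (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t)
  rp <- (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i)
  (rs^2 + rp^2) / 2
}

#' Boundary interaction at a refractive-index step
#'
#' Decides reflection versus refraction by the unpolarized Fresnel
#' reflectance (total internal reflection beyond the critical angle) and
#' returns the outgoing direction: specular reflection or Snell refraction.
#' With `n_in == n_out` the photon always transmits unchanged.
#'
#' @param direction Incident unit direction.
#' @param normal Outward unit surface normal (pointing into the `n_out`
#'   medium).
#' @param n_in,n_out Refractive indices (>= 1).
#' @param u Uniform variate deciding reflect vs refract; drawn if omitted.
#' @return List with `direction` (unit vector) and `transmitted` (logical).
#' @export
boundary_interaction <- function(direction, normal, n_in, n_out, u = NULL) {
  if (n_in < 1 || n_out < 1) abort("refractive indices must be >= 1")
  if (is.null(u)) u <- runif(1)
  cos_i <- sum(direction * normal)
  if (cos_i < 0) abort("direction must point toward the interface (d . n > 0)")
  R <- fresnel_reflectance(cos_i, n_in, n_out)
  if (u < R) {
    d <- direction - 2 * cos_i * normal
    list(direction = d / sqrt(sum(d^2)), transmitted = FALSE)
  } else {
    eta <- n_in / n_out
    cos_t <- sqrt(1 - eta^2 * (1 - cos_i^2))
    d <- eta * direction - (eta * cos_i - cos_t) * normal
    list(direction = d / sqrt(sum(d^2)), transmitted = TRUE)
  }
}

#' Trace optical photons through the voxel grid
#'
#' Propagates each photon of a bank by exponential path sampling with
#' voxel-by-voxel (3D DDA) accumulation of the spectrally interpolated
#' local attenuation, Henyey-Greenstein scattering with the local
#' anisotropy, absorption with probability `mu_a / mu_t` at each
#' interaction, and Fresnel reflection/refraction at tissue-air interfaces
#' (interior tissue-tissue interfaces are index-matched). Photon fates are
#' `absorbed`, `exited` or `capped` (event cap reached; treated as
#' absorbed for energy bookkeeping). Each photon keeps its birth position
#' so the origin of surface light remains computable.
#'
#' @param bank Photon bank tibble with columns `x`, `y`, `z` (current
#'   position, mm), `dx`, `dy`, `dz` (unit direction), `wavelength_nm`,
#'   and optionally birth columns (`birth_x` .., `birth_voxel`,
#'   `born_in_tumor`), which are passed through to the exit records.
#' @param grid A [voxel_grid()].
#' @param props Optical property table, default
#'   [default_optical_properties()].
#' @param fresnel Apply Fresnel boundaries at the surface (default TRUE);
#'   otherwise photons escape freely on first contact with air.
#' @param event_cap Maximum scattering/boundary events per photon
#'   (default 1e6).
#' @param score_fluence Also accumulate the track-length fluence estimator
#'   per voxel (mm of path per voxel; divide by voxel volume for mm^-2).
#' @return List with `photons` (the bank plus `status`, `n_events`,
#'   absorbed voxel indices), `exits` (tibble of surface-exit records) and
#'   optionally `fluence` (3D array).
#' @export
trace_optical_photons <- function(bank, grid,
                                  props = default_optical_properties(),
                                  fresnel = TRUE, event_cap = 1e6,
                                  score_fluence = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (nrow(bank) == 0) abort("empty photon bank")
  # a bank traced from birth: current position is the birth position
  if (!"birth_x" %in% names(bank)) {
    bank$birth_x <- bank$x; bank$birth_y <- bank$y; bank$birth_z <- bank$z
  }
  if (!"birth_voxel" %in% names(bank) || anyNA(bank$birth_voxel)) {
    bank$birth_voxel <- voxel_index(grid, bank$birth_x, bank$birth_y,
                                    bank$birth_z)
  }
  if (!"born_in_tumor" %in% names(bank)) {
    bank$born_in_tumor <- grid$tissue[bank$birth_voxel] ==
      tissue_code("tumor")
  }
  om <- optical_props_matrices(props)
  pos <- cbind(bank$x, bank$y, bank$z)
  dir <- cbind(bank$dx, bank$dy, bank$dz)
  res <- cpp_trace_optical(pos, dir, bank$wavelength_nm,
                           grid$tissue, grid$density,
                           as.integer(grid$dims), grid$spacing, grid$origin,
                           om$lambda, om$mu_a, om$mu_s, om$g, om$n_tissue,
                           fresnel, event_cap, score_fluence)
  photons <- bank
  photons$status <- c("absorbed", "exited", "capped")[res$status + 1L]
  photons$n_events <- res$n_events
  photons$end_voxel <- ifelse(is.na(res$abs_voxel), res$exit_voxel,
                              res$abs_voxel)
  exited <- which(res$status == 1L)
  exits <- tibble(
    photon_id = exited,
    exit_x = res$exit_pos[exited, 1],
    exit_y = res$exit_pos[exited, 2],
    exit_z = res$exit_pos[exited, 3],
    exit_dx = res$exit_dir[exited, 1],
    exit_dy = res$exit_dir[exited, 2],
    exit_dz = res$exit_dir[exited, 3],
    exit_voxel = res$exit_voxel[exited],
    exit_face = res$exit_face[exited],
    wavelength_nm = bank$wavelength_nm[exited]
  )
  for (col in c("birth_x", "birth_y", "birth_z", "birth_voxel",
                "born_in_tumor")) {
    if (col %in% names(bank)) exits[[col]] <- bank[[col]][exited]
  }
  out <- list(photons = photons, exits = exits)
  if (score_fluence) {
    out$fluence <- array(res$fluence, dim = grid$dims)
  }
  out
}
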