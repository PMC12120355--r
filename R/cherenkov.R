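#' Speed ratio of an electron
#'
#' beta = v/c for an electron of kinetic energy `energy_mev`,
#' `sqrt(1 - (m_e c^2 / (E + m_e c^2))^2)` with `m_e c^2 = 0.511` MeV.
#'
#' @param energy_mev Kinetic energy, MeV (>= 0).
#' @return beta in \[0, 1).
#' @export
electron_beta <- function(energy_mev) {
  if (any(energy_mev < 0)) abort("kinetic energy must be non-negative")
  sqrt(1 - (MEC2 / (energy_mev + MEC2))^2)
}

#' Cherenkov kinetic-energy threshold
#'
#' The kinetic energy at which an electron's speed equals the phase velocity
#' of light in a medium of refractive index `n` (the condition beta * n = 1):
#' `m_e c^2 * (1 / sqrt(1 - n^-2) - 1)`. Below this energy no Cherenkov
#' light is emitted. For n <= 1 the threshold is infinite (emission is
#' impossible, e.g. in air at optical densities).
#'
#' @param n Refractive index (> 0).
#' @return Threshold kinetic energy in MeV (`Inf` for n <= 1).
#' @export
#' @examples
#' cherenkov_threshold_energy(1.4)   # ~0.219 MeV, i.e. ~0.2 MeV in soft tissue
cherenkov_threshold_energy <- function(n) {
  if (any(n <= 0)) abort("refractive index must be positive")
  ifelse(n <= 1, Inf, MEC2 * (1 / sqrt(1 - 1 / n^2) - 1))
}

#' Frank-Tamm photon yield over a wavelength band
#'
#' Expected number of Cherenkov photons emitted per mm of path by a particle
#' of charge number `z` and speed ratio `beta` in a medium of refractive
#' index `n`, integrated over wavelengths `[lambda1, lambda2]` nm. This is
#' the closed-form integral of the Frank-Tamm spectral density
#' `(2 pi z^2 / 137.036) (1 - 1/(beta^2 n^2)) / lambda^2`:
#' the band yield is `(2 pi z^2 / 137.036) (1 - 1/(beta^2 n^2))
#' (1/lambda1 - 1/lambda2)`. Zero below the Cherenkov condition
#' `beta * n > 1`.
#'
#' @param beta Speed ratio in (0, 1\].
#' @param n Refractive index.
#' @param z Charge number of the emitting particle (1 for electrons).
#' @param lambda1,lambda2 Band edges in nm, `lambda1 < lambda2`.
#' @return Expected photons per mm of path.
#' @export
#' @examples
#' frank_tamm_yield(1, 1.33, 1, 400, 700)  # ~21.4 photons/mm
frank_tamm_yield <- function(beta, n, z = 1, lambda1 = LAMBDA_MIN,
                             lambda2 = LAMBDA_MAX) {
  if (any(lambda1 >= lambda2)) abort("need lambda1 < lambda2")
  if (any(beta <= 0) || any(beta > 1)) abort("beta must be in (0, 1]")
  bn2 <- (beta * n)^2
  ifelse(bn2 > 1,
         2 * pi * z^2 / INV_ALPHA * (1 - 1 / bn2) *
           (1 / lambda1 - 1 / lambda2) * 1e6,
         0)
}

#' Sample Cherenkov photon wavelengths
#'
#' Inverse-CDF sampling of the 1/lambda^2 Frank-Tamm spectral density over
#' `[lambda1, lambda2]`: `lambda = 1 / (1/lambda1 - u (1/lambda1 -
#' 1/lambda2))`.
#'
#' @param n_samples Number of wavelengths to draw.
#' @param lambda1,lambda2 Band edges, nm.
#' @param u Optional uniform variates (for deterministic checks).
#' @return Wavelengths in nm.
#' @export
sample_cherenkov_wavelength <- function(n_samples, lambda1 = LAMBDA_MIN,
                                        lambda2 = LAMBDA_MAX, u = NULL) {
  if (lambda1 >= lambda2) abort("need lambda1 < lambda2")
  if (is.null(u)) u <- runif(n_samples)
  1 / (1 / lambda1 - u * (1 / lambda1 - 1 / lambda2))
}

#' Sample Cherenkov photons emitted along an electron step
#'
#' Draws wavelengths from the 1/lambda^2 density and directions on the
#' Cherenkov cone of half-angle `theta_c` (`cos theta_c = 1/(beta n)`)
#' about the parent electron direction, with uniform azimuth. Requires the
#' emission condition `beta * n > 1`.
#'
#' @param beta Electron speed ratio.
#' @param n Refractive index of the medium.
#' @param lambda1,lambda2 Band edges, nm.
#' @param parent_dir Unit direction of the parent electron.
#' @param n_samples Number of photons.
#' @return Tibble with `wavelength_nm`, `dx`, `dy`, `dz`.
#' @export
sample_cherenkov_photon <- function(beta, n, lambda1 = LAMBDA_MIN,
                                    lambda2 = LAMBDA_MAX,
                                    parent_dir = c(0, 0, 1), n_samples = 1) {
  if (beta * n <= 1) abort("below the Cherenkov condition: beta * n <= 1")
  lam <- sample_cherenkov_wavelength(n_samples, lambda1, lambda2)
  ct <- 1 / (beta * n)
  phi <- runif(n_samples, 0, 2 * pi)
  dirs <- t(vapply(phi, function(ph) deflect_dir(parent_dir, ct, ph),
                   numeric(3)))
  tibble(wavelength_nm = lam, dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
}

# rotate unit vector by polar cosine ct and azimuth phi (same convention as
# the C++ kernel)
deflect_dir <- function(d, ct, phi) {
  st <- sqrt(max(0, 1 - ct^2))
  if (abs(d[3]) > 0.999999) {
    out <- c(st * cos(phi), st * sin(phi), ct * sign(d[3]))
  } else {
    den <- sqrt(1 - d[3]^2)
    out <- c(
      st * (d[1] * d[3] * cos(phi) - d[2] * sin(phi)) / den + d[1] * ct,
      st * (d[2] * d[3] * cos(phi) + d[1] * sin(phi)) / den + d[2] * ct,
      -st * cos(phi) * den + d[3] * ct
    )
  }
  out / sqrt(sum(out^2))
}

#' Sample Compton scattering events
#'
#' Draws scattering cosines from the Klein-Nishina differential
#' cross-section by rejection sampling and applies Compton kinematics
#' `E' = E / (1 + (E/0.511)(1 - cos theta))`; the electron receives
#' `E - E'`.
#'
#' @param energy_mev Incident photon energy, MeV.
#' @param n_samples Number of events.
#' @return Tibble with `cos_theta`, `scattered_mev`, `electron_mev`.
#' @export
compton_scatter <- function(energy_mev, n_samples = 1) {
  if (energy_mev <= 0) abort("photon energy must be positive")
  m <- cpp_sample_compton(n_samples, energy_mev)
  tibble(cos_theta = m[, 1], scattered_mev = m[, 2], electron_mev = m[, 3])
}

#' Compton scattered-photon energy at a given angle
#'
#' @param energy_mev Incident photon energy, MeV.
#' @param cos_theta Scattering cosine.
#' @return Scattered photon energy, MeV.
#' @export
compton_scattered_energy <- function(energy_mev, cos_theta) {
  energy_mev / (1 + energy_mev / MEC2 * (1 - cos_theta))
}
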