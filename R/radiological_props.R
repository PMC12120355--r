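#' Klein-Nishina total cross-section per electron
#'
#' Closed-form total Compton cross-section for a photon of energy `E` (MeV)
#' on a free electron, in cm^2.
#'
#' @param energy_mev Photon energies, MeV.
#' @return Cross-sections in cm^2 per electron.
#' @export
klein_nishina_total <- function(energy_mev) {
  r_e <- 2.8179403262e-13  # classical electron radius, cm
  k <- energy_mev / MEC2
  2 * pi * r_e^2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

# electron collision mass stopping power of water, MeV cm^2 / g
# (ICRU-style anchor values, log-log interpolated)
water_stopping_anchors <- function() {
  data.frame(
    e = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5, 1, 2, 3, 4, 6),
    s = c(22.56, 11.84, 6.603, 4.115, 2.793, 2.355, 2.034,
          1.849, 1.824, 1.846, 1.870, 1.911)
  )
}

#' Default radiological property tables
#'
#' Per-tissue tables over photon/electron energy of the linear attenuation
#' coefficient split into its Compton and photoelectric components (1/mm, at
#' the tissue's nominal density) and of the electron collision stopping
#' power (MeV/mm at nominal density). Compton attenuation is the
#' Klein-Nishina total cross-section times the electron density
#' (`rho * N_A * Z/A`); the photoelectric component uses an effective-Z
#' power-law approximation `~ Z_eff^3.6 / E^3` (anchored to the water photoelectric cross-section at 10 keV); stopping powers use the
#' water collision stopping-power curve scaled by mass density (the mass
#' stopping powers of soft tissues differ from water by only a few
#' percent). All tables are config-overridable. The emitting-particle
#' charge number `z` used by the Frank-Tamm yield is 1 (electron).
#'
#' @param energy_mev Energy grid, MeV; default 80 log-spaced points over
#'   0.01-6 MeV.
#' @param densities Nominal densities, default [default_tissue_densities()].
#' @return Tibble with columns `tissue`, `energy_mev`, `mu_compton_per_mm`,
#'   `mu_pe_per_mm`, `stopping_mev_per_mm`, `ref_density`; attribute
#'   `z_charge = 1`.
#' @export
default_radiological_properties <- function(
    energy_mev = exp(seq(log(0.01), log(6), length.out = 80)),
    densities = default_tissue_densities()) {
  z_over_a <- c(air = 0.499, skin = 0.550, adipose = 0.556, muscle = 0.550,
                bone = 0.515, tumor = 0.550, water = 0.555)
  z_eff <- c(air = 7.64, skin = 7.40, adipose = 6.30, muscle = 7.50,
             bone = 13.80, tumor = 7.50, water = 7.42)
  n_avog <- 6.02214076e23
  anchors <- water_stopping_anchors()
  s_water <- exp(approx(log(anchors$e), log(anchors$s),
                        xout = log(energy_mev), rule = 2)$y)
  sigma <- klein_nishina_total(energy_mev)

  out <- lapply(tissue_levels(), function(t) {
    rho <- densities[[t]]
    n_e <- rho * n_avog * z_over_a[[t]]              # electrons per cm^3
    mu_c <- sigma * n_e / 10                          # 1/mm
    mu_pe <- 3.6e-09 * z_eff[[t]]^3.6 / energy_mev^3 * rho / 10
    tibble(tissue = t, energy_mev = energy_mev,
           mu_compton_per_mm = mu_c, mu_pe_per_mm = mu_pe,
           stopping_mev_per_mm = s_water * rho / 10,
           ref_density = rho)
  })
  res <- bind_rows(out)
  attr(res, "z_charge") <- 1
  res
}

check_rad_props <- function(props) {
  need <- c("tissue", "energy_mev", "mu_compton_per_mm", "mu_pe_per_mm",
            "stopping_mev_per_mm", "ref_density")
  if (!all(need %in% names(props))) {
    abort(paste("radiological table must have columns:",
                paste(need, collapse = ", ")))
  }
  if (any(props$mu_compton_per_mm <= 0) || any(props$stopping_mev_per_mm <= 0)) {
    abort("attenuation and stopping power must be strictly positive")
  }
  invisible(props)
}

# energy grid + matrices in tissue-code order for the C++ kernels
rad_props_matrices <- function(props = default_radiological_properties()) {
  check_rad_props(props)
  eg <- sort(unique(props$energy_mev))
  tl <- tissue_levels()
  grab <- function(col) {
    m <- matrix(0, length(eg), length(tl))
    for (j in seq_along(tl)) {
      tab <- props[props$tissue == tl[j], ]
      tab <- tab[order(tab$energy_mev), ]
      m[, j] <- approx(tab$energy_mev, tab[[col]], xout = eg, rule = 2)$y
    }
    m
  }
  ref <- vapply(tl, function(t) props$ref_density[props$tissue == t][1], numeric(1))
  list(energy = eg, mu_compton = grab("mu_compton_per_mm"),
       mu_pe = grab("mu_pe_per_mm"), stopping = grab("stopping_mev_per_mm"),
       ref_density = unname(ref),
       z_charge = attr(props, "z_charge") %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
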