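#' Default spectrally resolved tissue optical properties
#'
#' Ships per-tissue tables of absorption coefficient `mu_a` (1/mm),
#' scattering coefficient `mu_s` (1/mm), Henyey-Greenstein anisotropy `g`
#' and refractive index `n` on a 10 nm wavelength grid over 500-1200 nm.
#'
#' The defaults are smooth parametric approximations of the literature
#' families for skin, adipose, muscle, bone and a head-and-neck tumor:
#' absorption is modelled as a hemoglobin-like visible band (strong below
#' ~600 nm, with a weak deoxy-like 760 nm feature), a water fraction
#' (rising absorption beyond ~900 nm), a lipid 930 nm feature for adipose,
#' and a melanin-like term for skin; reduced scattering follows a power law
#' `a * (lambda/500)^-b` converted to `mu_s` through `g`. They are
#' approximations intended to reproduce the qualitative spectral shape
#' (visible absorption >> near-infrared absorption), not any specific
#' measurement, and are fully overridable: any table with the same columns
#' can be passed wherever a `props` argument is accepted. The anisotropy
#' curves of tumor and adipose coincide by construction. Refractive indices
#' are wavelength-independent (skin 1.42, adipose 1.44, muscle 1.40, bone
#' 1.55, tumor 1.40, water 1.33, air 1.0).
#'
#' @param lambda_nm Wavelength grid, default `seq(500, 1200, by = 10)`.
#' @return Tibble with columns `tissue`, `lambda_nm`, `mu_a_per_mm`,
#'   `mu_s_per_mm`, `g`, `n`.
#' @export
default_optical_properties <- function(lambda_nm = seq(500, 1200, by = 10)) {
  lam <- lambda_nm

  water_tab <- data.frame(
    l = c(500, 550, 600, 650, 700, 750, 800, 850, 900, 950,
          1000, 1050, 1100, 1150, 1200),
    a = c(3e-05, 4e-05, 2e-04, 3e-04, 6e-04, 2.6e-03, 2.0e-03, 4.0e-03,
          6.8e-03, 2.7e-02, 3.6e-02, 1.2e-02, 1.7e-02, 5.0e-02, 1.0e-01)
  )
  mua_water <- approx(water_tab$l, water_tab$a, xout = lam)$y

  # hemoglobin-like normalized band shape: strong 500-600 nm, weak NIR tail
  hb <- exp(-((lam - 545) / 18)^2) +
    0.85 * exp(-((lam - 575) / 15)^2) +
    0.35 * exp(-pmax(lam - 500, 0) / 30) +
    0.016 * exp(-pmax(lam - 600, 0) / 150) +
    0.030 * exp(-((lam - 760) / 30)^2)
  lipid <- 0.012 * exp(-((lam - 930) / 20)^2)
  melanin <- (lam / 500)^-3

  g_soft <- function(g0) g0 + 0.02 * (lam - 500) / 700

  mk <- function(tissue, mua, musp, g, n) {
    tibble(tissue = tissue, lambda_nm = lam,
           mu_a_per_mm = mua, mu_s_per_mm = musp / (1 - g), g = g, n = n)
  }

  bind_rows(
    mk("air", rep(0, length(lam)), rep(0, length(lam)), rep(0, length(lam)), 1.0),
    mk("skin", 0.06 * hb + 0.50 * mua_water + 0.04 * melanin + 0.004,
       2.2 * (lam / 500)^-1.5, g_soft(0.90), 1.42),
    mk("adipose", 0.015 * hb + 0.20 * mua_water + lipid + 0.003,
       1.2 * (lam / 500)^-0.7, g_soft(0.92), 1.44),
    mk("muscle", 0.12 * hb + 0.75 * mua_water + 0.003,
       0.95 * (lam / 500)^-1.0, g_soft(0.93), 1.40),
    mk("bone", 0.035 * hb + 0.30 * mua_water + 0.004,
       2.0 * (lam / 500)^-0.3, g_soft(0.92), 1.55),
    mk("tumor", 0.15 * hb + 0.80 * mua_water + 0.003,
       1.1 * (lam / 500)^-1.2, g_soft(0.92), 1.40),
    mk("water", mua_water, rep(3e-04, length(lam)), rep(0, length(lam)), 1.33)
  )
}

check_optical_props <- function(props) {
  need <- c("tissue", "lambda_nm", "mu_a_per_mm", "mu_s_per_mm", "g", "n")
  if (!all(need %in% names(props))) {
    abort(paste("optical property table must have columns:",
                paste(need, collapse = ", ")))
  }
  if (any(props$mu_a_per_mm < 0) || any(props$mu_s_per_mm < 0)) {
    abort("mu_a and mu_s must be non-negative")
  }
  if (any(props$n < 1) || any(abs(props$g) >= 1)) {
    abort("need n >= 1 and |g| < 1")
  }
  invisible(props)
}

#' Evaluate tissue optical properties at given wavelengths
#'
#' Linear interpolation of the per-tissue tables; evaluation exactly at a
#' tabulated wavelength returns the table value.
#'
#' @param label Tissue label (one of [tissue_levels()]).
#' @param lambda_nm Wavelengths in nm, all within 500-1200.
#' @param props Property table, default [default_optical_properties()].
#' @return Tibble with columns `tissue`, `lambda_nm`, `mu_a_per_mm`,
#'   `mu_s_per_mm`, `g`, `n`.
#' @export
#' @examples
#' tissue_properties("muscle", c(550, 800))
tissue_properties <- function(label, lambda_nm,
                              props = default_optical_properties()) {
  check_optical_props(props)
  if (length(label) != 1L) abort("one tissue label at a time")
  if (!label %in% props$tissue) abort(paste("unknown tissue label:", label))
  if (any(lambda_nm < LAMBDA_MIN | lambda_nm > LAMBDA_MAX)) {
    abort("wavelength outside the supported 500-1200 nm range")
  }
  tab <- props[props$tissue == label, ]
  tab <- tab[order(tab$lambda_nm), ]
  interp <- function(y) approx(tab$lambda_nm, y, xout = lambda_nm)$y
  tibble(tissue = label, lambda_nm = lambda_nm,
         mu_a_per_mm = interp(tab$mu_a_per_mm),
         mu_s_per_mm = interp(tab$mu_s_per_mm),
         g = interp(tab$g),
         n = interp(tab$n))
}

#' Per-tissue refractive index used for Cherenkov emission and boundaries
#'
#' A single refractive index per tissue, evaluated from the optical table at
#' a reference wavelength (default 700 nm, the middle of the band; the
#' shipped default indices are wavelength-independent anyway).
#'
#' @param props Optical property table.
#' @param lambda_ref Reference wavelength, nm.
#' @return Named numeric vector over [tissue_levels()].
#' @export
tissue_refractive_index <- function(props = default_optical_properties(),
                                    lambda_ref = 700) {
  vapply(tissue_levels(), function(t) {
    tissue_properties(t, lambda_ref, props)$n
  }, numeric(1))
}

# lambda grid + L x T matrices in tissue-code order, for the C++ kernels
optical_props_matrices <- function(props = default_optical_properties()) {
  check_optical_props(props)
  lam <- sort(unique(props$lambda_nm))
  tl <- tissue_levels()
  grab <- function(col) {
    m <- matrix(0, length(lam), length(tl))
    for (j in seq_along(tl)) {
      tab <- props[props$tissue == tl[j], ]
      tab <- tab[order(tab$lambda_nm), ]
      m[, j] <- approx(tab$lambda_nm, tab[[col]], xout = lam)$y
    }
    m
  }
  list(lambda = lam, mu_a = grab("mu_a_per_mm"), mu_s = grab("mu_s_per_mm"),
       g = grab("g"), n_tissue = unname(tissue_refractive_index(props)))
}
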