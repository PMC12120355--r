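#' Run settings for the radiation/optical transport kernels
#'
#' @param step_mm Electron step length, mm (default 0.1).
#' @param e_cutoff_mev Electron energy cutoff; residual energy is deposited
#'   locally (default 0.01 MeV).
#' @param x_cutoff_mev X-ray energy cutoff (default 0.01 MeV).
#' @param z_charge Charge number of the Cherenkov-emitting particle
#'   (default 1, electron).
#' @param lambda1,lambda2 Cherenkov scoring band, nm (default 500-1200).
#' @param analog Analog (Poisson integer) Cherenkov emission; set FALSE for
#'   expected-value (variance-reduced) emission scoring without a photon
#'   bank.
#' @param keep_prob Probability of keeping each emitted photon in the bank
#'   (uniform thinning for memory control; emission grids are unaffected).
#' @param bank_cap Maximum photons stored in the bank.
#' @param birth_tissue Restrict the bank to photons born in this tissue
#'   label (e.g. "tumor"); NULL keeps all.
#' @return List of settings.
#' @export
run_settings <- function(step_mm = 0.1, e_cutoff_mev = 0.01,
                         x_cutoff_mev = 0.01, z_charge = 1,
                         lambda1 = LAMBDA_MIN, lambda2 = LAMBDA_MAX,
                         analog = TRUE, keep_prob = 1, bank_cap = Inf,
                         birth_tissue = NULL) {
  list(step_mm = step_mm, e_cutoff_mev = e_cutoff_mev,
       x_cutoff_mev = x_cutoff_mev, z_charge = z_charge,
       lambda1 = lambda1, lambda2 = lambda2, analog = analog,
       keep_prob = keep_prob, bank_cap = bank_cap,
       birth_tissue = birth_tissue)
}

birth_filter_code <- function(settings) {
  if (is.null(settings$birth_tissue)) -1L else tissue_code(settings$birth_tissue)
}

#' Transport X-ray photons through a voxel grid
#'
#' Exponential free paths against the heterogeneous total attenuation
#' (ray marching voxel by voxel), interaction channel chosen by the local
#' Compton/photoelectric ratio; photoelectric absorption deposits the full
#' photon energy locally, Compton scattering spawns a secondary electron
#' (Klein-Nishina sampled) and the scattered photon continues until
#' absorption, escape, or the energy cutoff.
#'
#' @param photons Tibble with `x`, `y`, `z`, `dx`, `dy`, `dz`,
#'   `energy_mev`.
#' @param grid A [voxel_grid()].
#' @param rad_props Radiological table, default
#'   [default_radiological_properties()].
#' @param settings [run_settings()].
#' @return List: `deposit` (3D array, MeV), `electrons` (tibble with
#'   `x,y,z,dx,dy,dz,energy_mev,history`), `deposited`, `escaped`
#'   (per-history MeV).
#' @export
transport_xray <- function(photons, grid,
                           rad_props = default_radiological_properties(),
                           settings = run_settings()) {
  rm_ <- rad_props_matrices(rad_props)
  res <- cpp_transport_xray(cbind(photons$x, photons$y, photons$z),
                            cbind(photons$dx, photons$dy, photons$dz),
                            photons$energy_mev,
                            grid$tissue, grid$density,
                            as.integer(grid$dims), grid$spacing, grid$origin,
                            rm_$energy, rm_$mu_compton, rm_$mu_pe,
                            rm_$ref_density, settings$x_cutoff_mev)
  list(deposit = array(res$deposit, dim = grid$dims),
       electrons = tibble(x = res$e_pos[, 1], y = res$e_pos[, 2],
                          z = res$e_pos[, 3],
                          dx = res$e_dir[, 1], dy = res$e_dir[, 2],
                          dz = res$e_dir[, 3],
                          energy_mev = res$e_energy,
                          history = res$e_history),
       deposited = res$deposited, escaped = res$escaped)
}

bank_to_tibble <- function(bank_list, grid) {
  m <- length(bank_list$wavelength)
  if (m == 0) {
    return(tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                  dx = numeric(0), dy = numeric(0), dz = numeric(0),
                  wavelength_nm = numeric(0),
                  birth_x = numeric(0), birth_y = numeric(0),
                  birth_z = numeric(0), birth_voxel = integer(0),
                  born_in_tumor = logical(0)))
  }
  vox1 <- bank_list$voxel + 1L
  tibble(
    x = bank_list$pos[, 1], y = bank_list$pos[, 2], z = bank_list$pos[, 3],
    dx = bank_list$dir[, 1], dy = bank_list$dir[, 2], dz = bank_list$dir[, 3],
    wavelength_nm = bank_list$wavelength,
    birth_x = bank_list$pos[, 1], birth_y = bank_list$pos[, 2],
    birth_z = bank_list$pos[, 3],
    birth_voxel = vox1,
    born_in_tumor = grid$tissue[vox1] == tissue_code("tumor")
  )
}

#' Transport electrons with continuous slowing down and Cherenkov emission
#'
#' Straight-line stepping (default 0.1 mm): each step deposits
#' `stopping power x step x density scaling` at the step midpoint; while
#' the electron energy exceeds the local Cherenkov threshold the step emits
#' `Poisson(Frank-Tamm yield x step)` photons at the midpoint with
#' mid-step `beta` (cone angle `cos theta_c = 1/(beta n)`, `1/lambda^2`
#' wavelengths). The track ends below the cutoff (deposited locally) or on
#' grid exit.
#'
#' @param electrons Tibble with `x,y,z,dx,dy,dz,energy_mev`.
#' @param grid A [voxel_grid()].
#' @param opt_props Optical table (for refractive indices), default
#'   [default_optical_properties()].
#' @param rad_props Radiological table (stopping powers), default
#'   [default_radiological_properties()].
#' @param settings [run_settings()].
#' @return List: `deposit` (3D array MeV), `emission` (3D array, photon
#'   counts or expected counts), `bank` (Cherenkov photon tibble),
#'   `deposited`, `escaped` (per-track MeV), `n_emitted` (total photons
#'   emitted, before any bank thinning).
#' @export
transport_electron <- function(electrons, grid,
                               opt_props = default_optical_properties(),
                               rad_props = default_radiological_properties(),
                               settings = run_settings()) {
  rm_ <- rad_props_matrices(rad_props)
  om <- optical_props_matrices(opt_props)
  res <- cpp_transport_electron(cbind(electrons$x, electrons$y, electrons$z),
                                cbind(electrons$dx, electrons$dy, electrons$dz),
                                electrons$energy_mev,
                                grid$tissue, grid$density,
                                as.integer(grid$dims), grid$spacing,
                                grid$origin,
                                rm_$energy, rm_$stopping, rm_$ref_density,
                                om$n_tissue,
                                settings$z_charge, settings$lambda1,
                                settings$lambda2, settings$step_mm,
                                settings$e_cutoff_mev,
                                birth_filter_code(settings),
                                settings$keep_prob,
                                min(settings$bank_cap, 2^31),
                                settings$analog)
  list(deposit = array(res$deposit, dim = grid$dims),
       emission = array(res$emission, dim = grid$dims),
       bank = bank_to_tibble(res$bank, grid),
       deposited = res$deposited, escaped = res$escaped,
       n_emitted = res$n_emitted)
}

#' Score absorbed dose from an energy-deposit grid
#'
#' Dose (Gy) = deposited energy (MeV) x 1.602e-13 J/MeV divided by the
#' voxel mass (voxel volume x local density).
#'
#' @param deposit 3D array of deposited energy per voxel, MeV.
#' @param grid The [voxel_grid()] the deposits were scored on.
#' @param units `"per-particle"` or `"physical"` flag carried on the
#'   result.
#' @return A `dose_grid`: list with `dose` (3D array, Gy), `energy_mev`,
#'   grid geometry and the units flag.
#' @export
score_dose <- function(deposit, grid, units = "per-particle") {
  if (any(deposit < 0)) abort("negative energy deposit")
  if (any(deposit > 0 & grid$density == 0)) {
    abort("energy deposited in a zero-density voxel")
  }
  mass_kg <- grid$density * voxel_volume(grid) * 1e-6
  dose <- array(0, dim = grid$dims)
  nz <- mass_kg > 0
  dose[nz] <- deposit[nz] * JOULE_PER_MEV / mass_kg[nz]
  structure(list(dose = dose, energy_mev = deposit, dims = grid$dims,
                 spacing = grid$spacing, origin = grid$origin, units = units),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(x$dims, collapse = " x "), " voxels, max ",
      signif(max(x$dose), 4), " Gy (", x$units, ")\n", sep = "")
  invisible(x)
}

#' Simulate radiation delivery of a treatment plan
#'
#' Samples beam photons across all control points (allocated in proportion
#' to their MU weights), transports X-rays and secondary electrons through
#' the phantom, scores dose and Cherenkov emission, and (optionally)
#' traces the emitted optical photons to the surface.
#'
#' @param plan A [build_plan()] treatment plan.
#' @param grid A [voxel_grid()] phantom.
#' @param n_photons Number of primary photons.
#' @param opt_props,rad_props Property tables.
#' @param settings [run_settings()].
#' @param spectrum Source spectrum, default [default_6mv_spectrum()].
#' @param trace_optics Trace the Cherenkov bank to the surface
#'   (default TRUE).
#' @param fresnel,event_cap Optical boundary model and event cap, see
#'   [trace_optical_photons()].
#' @return A `cherenkov_sim` object: list with `dose` ([score_dose()]
#'   result per particle), `emission` (3D photon-count array), `bank`,
#'   `photons`/`exits` from the optical trace, energy-balance vectors and
#'   run metadata.
#' @export
simulate_plan <- function(plan, grid, n_photons = 1e4,
                          opt_props = default_optical_properties(),
                          rad_props = default_radiological_properties(),
                          settings = run_settings(),
                          spectrum = default_6mv_spectrum(),
                          trace_optics = TRUE, fresnel = TRUE,
                          event_cap = 1e6) {
  cps <- plan_control_points(plan)
  if (sum(cps$mu_weight) == 0 || n_photons == 0) {
    n_per <- rep(0L, nrow(cps))
  } else {
    n_per <- as.vector(stats::rmultinom(1, n_photons,
                                        cps$mu_weight / sum(cps$mu_weight)))
  }
  photons <- bind_rows(lapply(which(n_per > 0), function(i) {
    sample_beam_photons(n_per[i], cps$gantry_deg[i],
                        plan$beams[[cps$beam[i]]]$aperture,
                        spectrum, plan$isocenter, plan$sad)
  }))
  simulate_photons(photons, grid, opt_props, rad_props, settings,
                   trace_optics, fresnel, event_cap,
                   meta = list(modality = plan$modality,
                               mu_total = plan_mu_total(plan)))
}

#' Simulate an explicit photon set (shared backend)
#'
#' @inheritParams simulate_plan
#' @param photons Photon tibble as from [sample_beam_photons()].
#' @param meta Extra metadata stored on the result.
#' @return A `cherenkov_sim` object (see [simulate_plan()]).
#' @export
simulate_photons <- function(photons, grid,
                             opt_props = default_optical_properties(),
                             rad_props = default_radiological_properties(),
                             settings = run_settings(),
                             trace_optics = TRUE, fresnel = TRUE,
                             event_cap = 1e6, meta = list()) {
  if (nrow(photons) == 0) {
    out <- list(dose = score_dose(array(0, dim = grid$dims), grid),
                emission = array(0, dim = grid$dims),
                bank = bank_to_tibble(list(wavelength = numeric(0)), grid),
                deposited = numeric(0), escaped = numeric(0),
                n_emitted = 0, energy_in = numeric(0), n_primaries = 0L,
                grid = grid, meta = meta)
    class(out) <- "cherenkov_sim"
    return(out)
  }
  rm_ <- rad_props_matrices(rad_props)
  om <- optical_props_matrices(opt_props)
  res <- cpp_simulate_beam(cbind(photons$x, photons$y, photons$z),
                           cbind(photons$dx, photons$dy, photons$dz),
                           photons$energy_mev,
                           grid$tissue, grid$density,
                           as.integer(grid$dims), grid$spacing, grid$origin,
                           rm_$energy, rm_$mu_compton, rm_$mu_pe,
                           rm_$stopping, rm_$ref_density, om$n_tissue,
                           settings$z_charge, settings$lambda1,
                           settings$lambda2, settings$step_mm,
                           settings$e_cutoff_mev, settings$x_cutoff_mev,
                           birth_filter_code(settings), settings$keep_prob,
                           min(settings$bank_cap, 2^31), settings$analog)
  bank <- bank_to_tibble(res$bank, grid)
  out <- list(
    dose = score_dose(array(res$deposit, dim = grid$dims), grid),
    emission = array(res$emission, dim = grid$dims),
    bank = bank,
    deposited = res$deposited, escaped = res$escaped,
    n_emitted = res$n_emitted,
    energy_in = photons$energy_mev,
    n_primaries = nrow(photons),
    grid = grid,
    meta = meta
  )
  if (trace_optics && nrow(bank) > 0) {
    tr <- trace_optical_photons(bank, grid, opt_props, fresnel, event_cap)
    out$photons <- tr$photons
    out$exits <- tr$exits
  }
  class(out) <- "cherenkov_sim"
  out
}

#' @export
print.cherenkov_sim <- function(x, ...) {
  cat("<cherenkov_sim> ", x$n_primaries, " primaries, ",
      round(x$n_emitted), " Cherenkov photons emitted",
      if (!is.null(x$exits)) paste0(", ", nrow(x$exits), " surface exits"),
      "\n", sep = "")
  invisible(x)
}
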