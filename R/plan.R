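#' Parametric 6 MV photon energy spectrum
#'
#' Histogram model of a 6 MV linac bremsstrahlung spectrum used in place of
#' vendor phase-space data: spectral density proportional to
#' `E * exp(-E / 1.0 MeV)` truncated to 0.25-6 MeV, tabulated in 0.25 MeV
#' bins. Its mean energy is ~1.9 MeV, within the 1.5-2.5 MeV range
#' expected of a 6 MV beam. Replace with any tibble of `e_lo`, `e_hi`,
#' `weight` to change the model; a single zero-width bin gives a
#' monoenergetic beam.
#'
#' @return Tibble with columns `e_lo`, `e_hi` (MeV) and `weight`.
#' @export
default_6mv_spectrum <- function() {
  edges <- seq(0.25, 6, by = 0.25)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  w <- mids * exp(-mids / 1.0)
  tibble(e_lo = head(edges, -1), e_hi = tail(edges, -1), weight = w / sum(w))
}

#' Monoenergetic spectrum model
#' @param energy_mev The single photon energy, MeV.
#' @return Spectrum tibble with one zero-width bin.
#' @export
monoenergetic_spectrum <- function(energy_mev) {
  tibble(e_lo = energy_mev, e_hi = energy_mev, weight = 1)
}

#' Sample photon energies from a spectrum model
#' @param spectrum Tibble with `e_lo`, `e_hi`, `weight`.
#' @param n Number of samples.
#' @return Energies in MeV.
#' @export
sample_spectrum_energy <- function(spectrum, n) {
  i <- sample.int(nrow(spectrum), n, replace = TRUE, prob = spectrum$weight)
  spectrum$e_lo[i] + runif(n) * (spectrum$e_hi[i] - spectrum$e_lo[i])
}

#' Mean energy of a spectrum model
#' @param spectrum Tibble with `e_lo`, `e_hi`, `weight`.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum((spectrum$e_lo + spectrum$e_hi) / 2 * spectrum$weight) /
    sum(spectrum$weight)
}

#' Gantry rigid transform
#'
#' The gantry angle is the angle between the beam direction and the
#' direction of gravity: at 0 degrees the beam travels along -y (downward
#' onto a supine patient, entering through the anterior surface), and
#' angles increase toward the patient's left, so the beam direction is
#' `(-sin g, -cos g, 0)`. The source sits `sad` mm from the isocenter on
#' the ray opposite the beam axis. The isocenter-plane in-beam axes are
#' `u = (cos g, -sin g, 0)` (transverse) and `v = (0, 0, 1)` (superior).
#'
#' @param gantry_deg Gantry angle in degrees, \[0, 360).
#' @param isocenter Isocenter position, mm.
#' @param sad Source-axis distance, mm (> 0).
#' @return List with `source`, `beam_dir`, `u`, `v`.
#' @export
#' @examples
#' gantry_transform(90)$beam_dir  # (-1, 0, 0): from patient left to right
gantry_transform <- function(gantry_deg, isocenter = c(0, 0, 0), sad = 1000) {
  if (sad <= 0) abort("source-axis distance must be positive")
  gr <- gantry_deg * pi / 180
  beam_dir <- c(-sin(gr), -cos(gr), 0)
  list(source = isocenter - sad * beam_dir,
       beam_dir = beam_dir,
       u = c(cos(gr), -sin(gr), 0),
       v = c(0, 0, 1))
}

#' Binary aperture mask
#'
#' A boolean mask on a regular cell grid in the isocenter plane, standing
#' in for the multileaf collimator: open cells transmit, closed cells
#' block. The default is a centered open rectangle.
#'
#' @param width_mm,height_mm Open field size in the transverse (u) and
#'   superior (v) directions, mm.
#' @param cell_mm Cell size, default 2.5 mm.
#' @param extent_mm Full mask extent (defaults to the field size).
#' @return List with `mask` (logical matrix, u by v), `cell_mm`.
#' @export
aperture_mask <- function(width_mm = 50, height_mm = 50, cell_mm = 2.5,
                          extent_mm = NULL) {
  if (is.null(extent_mm)) extent_mm <- max(width_mm, height_mm)
  ncell <- max(1L, ceiling(extent_mm / cell_mm))
  centers <- (seq_len(ncell) - (ncell + 1) / 2) * cell_mm
  mask <- outer(abs(centers) <= width_mm / 2, abs(centers) <= height_mm / 2, FUN = "&")
  list(mask = mask, cell_mm = cell_mm)
}

aperture_cell_centers <- function(aperture) {
  nu <- nrow(aperture$mask); nv <- ncol(aperture$mask)
  open <- which(aperture$mask, arr.ind = TRUE)
  cbind(u = (open[, 1] - (nu + 1) / 2) * aperture$cell_mm,
        v = (open[, 2] - (nv + 1) / 2) * aperture$cell_mm)
}

#' Build an IMRT or VMAT treatment plan
#'
#' The shipped defaults reproduce the delivery characteristics of the two
#' studied treatments: IMRT with two fixed beams, a left-lateral beam at
#' gantry 90 deg (8 control points, 157.5 MU) and a right-anterior-oblique
#' beam at 278 deg (10 control points, 155.1 MU); VMAT with two 114-control-
#' point arcs, 100 to 260 deg counter-clockwise (360.7 MU) and 260 back to
#' 100 deg clockwise (306.6 MU). MU totals are split uniformly across
#' control points unless per-point weights are supplied. Nominal energy
#' 6 MV; 20 fractions.
#'
#' @param config List with `modality` ("IMRT" or "VMAT") and optionally
#'   `beams` (each with `name`, `gantry_deg` (scalar for IMRT) or
#'   `gantry_start`/`gantry_stop`, `n_cp`, `mu_total`, optional
#'   `mu_weights`, optional `aperture`), `isocenter`, `sad`, `fractions`,
#'   `aperture`.
#' @return A `treatment_plan` object.
#' @export
#' @examples
#' plan <- build_plan(list(modality = "IMRT"))
#' sum(plan$beams[[1]]$control_points$mu_weight)  # 157.5
build_plan <- function(config = list(modality = "IMRT")) {
  modality <- toupper(config$modality %||% "IMRT")
  default_beams <- if (modality == "IMRT") {
    list(
      list(name = "LT LAT", gantry_deg = 90, n_cp = 8, mu_total = 157.5),
      list(name = "RAO", gantry_deg = 278, n_cp = 10, mu_total = 155.1)
    )
  } else if (modality == "VMAT") {
    list(
      list(name = "CCW", gantry_start = 100, gantry_stop = 260, n_cp = 114,
           mu_total = 360.7),
      list(name = "CW", gantry_start = 260, gantry_stop = 100, n_cp = 114,
           mu_total = 306.6)
    )
  } else {
    abort("modality must be IMRT or VMAT")
  }
  beams_cfg <- config$beams %||% default_beams
  aperture_default <- config$aperture %||% aperture_mask()

  beams <- lapply(beams_cfg, function(b) {
    n_cp <- b$n_cp %||% 1L
    gantry <- if (!is.null(b$gantry_deg)) {
      rep(b$gantry_deg, n_cp)
    } else {
      seq(b$gantry_start, b$gantry_stop, length.out = n_cp)
    }
    gantry <- gantry %% 360
    mu_total <- b$mu_total %||% 0
    mu_w <- b$mu_weights %||% rep(mu_total / n_cp, n_cp)
    if (length(mu_w) != n_cp) abort("mu_weights length must equal n_cp")
    if (abs(sum(mu_w) - mu_total) > 1e-6 * max(1, mu_total)) {
      abort("per-control-point MU weights do not sum to the beam MU total")
    }
    if (any(mu_w < 0)) abort("MU weights must be non-negative")
    list(name = b$name %||% "beam",
         control_points = tibble(cp = seq_len(n_cp), gantry_deg = gantry,
                                 mu_weight = mu_w),
         aperture = b$aperture %||% aperture_default,
         mu_total = mu_total)
  })
  structure(
    list(modality = modality, beams = beams,
         nominal_energy_mv = config$nominal_energy_mv %||% 6,
         isocenter = config$isocenter %||% c(0, 0, 0),
         sad = config$sad %||% 1000,
         fractions = config$fractions %||% 20),
    class = "treatment_plan"
  )
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat("<treatment_plan> ", x$modality, ", ", length(x$beams),
      " beam(s)/arc(s), ", x$nominal_energy_mv, " MV, ",
      x$fractions, " fractions\n", sep = "")
  for (b in x$beams) {
    g <- range(b$control_points$gantry_deg)
    cat(sprintf("  %-8s %3d CPs, %7.1f MU, gantry %g%s\n", b$name,
                nrow(b$control_points), b$mu_total, g[1],
                if (diff(g) > 0) paste0(" to ", g[2]) else ""))
  }
  invisible(x)
}

#' Flatten a plan to a control-point table
#' @param plan A `treatment_plan`.
#' @return Tibble with `beam`, `beam_name`, `cp`, `gantry_deg`, `mu_weight`.
#' @export
plan_control_points <- function(plan) {
  bind_rows(lapply(seq_along(plan$beams), function(i) {
    b <- plan$beams[[i]]
    mutate(b$control_points, beam = i, beam_name = b$name, .before = 1)
  }))
}

#' Total monitor units of a plan
#' @param plan A `treatment_plan`.
#' @export
plan_mu_total <- function(plan) sum(vapply(plan$beams, `[[`, numeric(1), "mu_total"))

#' Sample beam photons for one control point
#'
#' Point-source model: photons originate at the gantry source position and
#' are directed through points drawn uniformly over the open cells of the
#' control point's aperture mask in the isocenter plane; energies are drawn
#' from the spectrum model.
#'
#' @param n Number of photons.
#' @param gantry_deg Gantry angle, degrees.
#' @param aperture Aperture from [aperture_mask()] (must have open cells).
#' @param spectrum Energy spectrum tibble, default [default_6mv_spectrum()].
#' @param isocenter,sad Geometry, mm.
#' @return Tibble with `x`, `y`, `z`, `dx`, `dy`, `dz`, `energy_mev`,
#'   `weight`.
#' @export
sample_beam_photons <- function(n, gantry_deg, aperture = aperture_mask(),
                                spectrum = default_6mv_spectrum(),
                                isocenter = c(0, 0, 0), sad = 1000) {
  cells <- aperture_cell_centers(aperture)
  if (nrow(cells) == 0) abort("aperture has no open cells")
  gt <- gantry_transform(gantry_deg, isocenter, sad)
  pick <- sample.int(nrow(cells), n, replace = TRUE)
  uu <- cells[pick, 1] + runif(n, -0.5, 0.5) * aperture$cell_mm
  vv <- cells[pick, 2] + runif(n, -0.5, 0.5) * aperture$cell_mm
  target <- cbind(isocenter[1] + uu * gt$u[1] + vv * gt$v[1],
                  isocenter[2] + uu * gt$u[2] + vv * gt$v[2],
                  isocenter[3] + uu * gt$u[3] + vv * gt$v[3])
  d <- sweep(target, 2, gt$source)
  d <- d / sqrt(rowSums(d^2))
  tibble(x = gt$source[1], y = gt$source[2], z = gt$source[3],
         dx = d[, 1], dy = d[, 2], dz = d[, 3],
         energy_mev = sample_spectrum_energy(spectrum, n), weight = 1)
}

#' Sample photons for the monitor-unit calibration geometry
#'
#' Source on the +z axis at `ssd` mm above the water surface, directed
#' through a `field_mm` x `field_mm` square drawn uniformly at the phantom
#' surface (beam axis along -z through the phantom center).
#'
#' @param n Number of photons.
#' @param grid Water phantom [voxel_grid()].
#' @param ssd Source-surface distance, mm (default 1000).
#' @param field_mm Field side length at the surface, mm (default 100).
#' @param spectrum Energy spectrum, default [default_6mv_spectrum()].
#' @return Photon tibble as in [sample_beam_photons()].
#' @export
sample_calibration_photons <- function(n, grid, ssd = 1000, field_mm = 100,
                                       spectrum = default_6mv_spectrum()) {
  z_surf <- max(voxel_centers(grid, 3)) + grid$spacing[3] / 2
  cx <- mean(range(voxel_centers(grid, 1)))
  cy <- mean(range(voxel_centers(grid, 2)))
  src <- c(cx, cy, z_surf + ssd)
  px <- cx + runif(n, -0.5, 0.5) * field_mm
  py <- cy + runif(n, -0.5, 0.5) * field_mm
  d <- cbind(px - src[1], py - src[2], z_surf - src[3])
  d <- d / sqrt(rowSums(d^2))
  tibble(x = src[1], y = src[2], z = src[3],
         dx = d[, 1], dy = d[, 2], dz = d[, 3],
         energy_mev = sample_spectrum_energy(spectrum, n), weight = 1)
}
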