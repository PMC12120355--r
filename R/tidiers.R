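#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a monitor-unit calibration
#' @param x A `mu_calibration`.
#' @param ... Unused.
#' @return One-row tibble with `D_d_gy_per_particle`, `particles_per_mu`,
#'   `depth_mm`.
#' @exportS3Method generics::tidy
tidy.mu_calibration <- function(x, ...) {
  tibble(D_d_gy_per_particle = x$D_d, particles_per_mu = x$N,
         depth_mm = x$depth_mm)
}

#' Tidy a simulation result: per-tissue dose and emission summary
#' @param x A `cherenkov_sim`.
#' @param ... Unused.
#' @return Tibble with one row per tissue present in the phantom.
#' @exportS3Method generics::tidy
tidy.cherenkov_sim <- function(x, ...) {
  lab <- tissue_label(as.vector(x$grid$tissue))
  tibble(tissue = lab,
         dose_gy = as.vector(x$dose$dose),
         emission = as.vector(x$emission)) %>%
    group_by(.data$tissue) %>%
    summarise(n_voxels = n(),
              mean_dose_gy = mean(.data$dose_gy),
              max_dose_gy = max(.data$dose_gy),
              photons_emitted = sum(.data$emission),
              .groups = "drop")
}

#' One-row summary of a simulation run
#' @param x A `cherenkov_sim`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cherenkov_sim <- function(x, ...) {
  tibble(
    n_primaries = x$n_primaries,
    energy_in_mev = sum(x$energy_in),
    energy_deposited_mev = sum(x$deposited),
    energy_escaped_mev = sum(x$escaped),
    n_cherenkov_emitted = x$n_emitted,
    n_bank = nrow(x$bank),
    n_surface_exits = if (is.null(x$exits)) NA_integer_ else nrow(x$exits)
  )
}

#' Plot a Cherenkov spectrum
#' @param object A `cherenkov_spectrum` from [compute_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cherenkov_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid,
                                       y = .data$intensity)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "wavelength (nm)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

face_for_view <- function(view) {
  switch(view, left = 1L, right = 2L, anterior = 3L, posterior = 4L,
         superior = 5L, inferior = 6L,
         abort("view must be one of left/right/anterior/posterior/superior/inferior"))
}

#' Plot a surface light map
#'
#' Projects the elements of one viewing face (default anterior, the +y
#' faces) onto the two transverse axes and fills by intensity.
#'
#' @param map A `surface_map` from [surface_intensity_map()].
#' @param mesh The surface mesh the map was built on.
#' @param view Viewing direction (default "anterior").
#' @return A ggplot.
#' @export
plot_surface_map <- function(map, mesh, view = "anterior") {
  face <- face_for_view(view)
  df <- inner_join(as_tibble(mesh), as_tibble(map), by = "element_id")
  df <- df[df$face == face, ]
  ax <- if (face %in% 1:2) c("cy", "cz") else if (face %in% 3:4) c("cx", "cz")
        else c("cx", "cy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression(photons / mm^2)) +
    ggplot2::labs(x = paste(substr(ax[1], 2, 2), "(mm)"),
                  y = paste(substr(ax[2], 2, 2), "(mm)"),
                  title = paste(view, "surface light")) +
    ggplot2::theme_minimal()
}

#' Plot the central-axis depth-dose curve
#'
#' Dose along -z from the entrance surface on the beam axis (the
#' calibration geometry), averaged over the four central voxel columns.
#'
#' @param dose A `dose_grid`.
#' @return A ggplot.
#' @export
plot_depth_dose <- function(dose) {
  d <- dose$dims
  icx <- c(floor((d[1] + 1) / 2), ceiling((d[1] + 1) / 2))
  icy <- c(floor((d[2] + 1) / 2), ceiling((d[2] + 1) / 2))
  prof <- apply(dose$dose[icx, icy, , drop = FALSE], 3, mean)
  zs <- dose$origin[3] + (seq_len(d[3]) - 1) * dose$spacing[3]
  depth <- max(zs) + dose$spacing[3] / 2 - zs
  df <- tibble(depth_mm = depth, dose = prof)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = paste0("dose (Gy, ", dose$units, ")")) +
    ggplot2::theme_minimal()
}
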