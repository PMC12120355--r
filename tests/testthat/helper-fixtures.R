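# shared fixtures, built in code and cached for the test session

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

neck_fixture <- function() fixture("neck", function() generate_neck_phantom(seed = 1))

neck_mesh_fixture <- function() {
  fixture("neck_mesh", function() extract_surface_mesh(neck_fixture()))
}

# homogeneous optical medium: every non-air tissue gets the same mu_a, mu_s,
# g, n (used for closed-form transport oracles)
uniform_optical_props <- function(mu_a, mu_s, g, n = 1.4) {
  p <- default_optical_properties()
  air <- p$tissue == "air"
  p$mu_a_per_mm <- ifelse(air, 0, mu_a)
  p$mu_s_per_mm <- ifelse(air, 0, mu_s)
  p$g <- ifelse(air, 0, g)
  p$n <- ifelse(air, 1, n)
  p
}

# homogeneous cube of one tissue
uniform_grid <- function(tissue, side, spacing = 1, density = NULL) {
  dens <- density %||% unname(default_tissue_densities()[tissue])
  dims <- rep(side, length.out = 3)
  voxel_grid(array(cherenkovrt:::tissue_code(tissue), dim = dims),
             array(dens, dim = dims), spacing = rep(spacing, 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pencil photon bank aimed along +z starting just inside the lower z face
pencil_bank <- function(n, grid, wavelength = 700) {
  tibble::tibble(x = 0, y = 0,
                 z = min(voxel_centers(grid, 3)) - grid$spacing[3] * 0.49,
                 dx = 0, dy = 0, dz = 1, wavelength_nm = wavelength)[rep(1, n), ]
}

# synthetic radiological table: flat attenuation dominated by one channel
make_slab_props <- function(mu_pe_per_mm, mu_c_per_mm = 1e-12) {
  rp <- default_radiological_properties()
  rp$mu_pe_per_mm <- mu_pe_per_mm
  rp$mu_compton_per_mm <- mu_c_per_mm
  rp
}
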