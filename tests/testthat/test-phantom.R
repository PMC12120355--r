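test_that("neck phantom has the expected voxel size and layered anatomy", {
  ph <- neck_fixture()
  expect_equal(ph$spacing, c(1, 1, 1.3))
  labs <- tissue_levels()[ph$tissue + 1]
  expect_setequal(unique(labs),
                  c("air", "skin", "adipose", "muscle", "bone", "tumor"))
  # concentric structure on the central slice: skin outside adipose outside
  # muscle
  mid <- (ph$dims[3] + 1) / 2
  sl <- ph$tissue[, , mid]
  xs <- voxel_centers(ph, 1); ys <- voxel_centers(ph, 2)
  r <- sqrt(outer(xs^2, ys^2, `+`))
  for (t in c("skin", "adipose")) {
    expect_true(min(r[sl == cherenkovrt:::tissue_code(t)]) >
                  max(r[sl == cherenkovrt:::tissue_code("tumor")]))
  }
  # air everywhere outside the neck radius
  expect_true(all(sl[r > default_neck_geometry()$neck_radius + 1.5] == 0))
  # tumor voxels form one nonempty connected blob (an ellipsoid is convex;
  # check plane-wise contiguity of its z extent)
  tz <- apply(ph$tissue == cherenkovrt:::tissue_code("tumor"), 3, any)
  expect_true(any(tz))
  expect_equal(sum(diff(which(tz)) > 1), 0)
})

test_that("tumor voxel count matches the lattice-point oracle", {
  # brute-force oracle: count 1 mm lattice points inside a (5,5,5) ellipsoid
  co <- expand.grid(x = -6:6, y = -6:6, z = -6:6)
  oracle <- sum(co$x^2 / 25 + co$y^2 / 25 + co$z^2 / 25 <= 1)
  ph <- generate_neck_phantom(
    params = list(tumor_center = c(17, 0, 0), tumor_radii = c(5, 5, 5)),
    spacing = c(1, 1, 1), seed = 1)
  n_tum <- sum(ph$tissue == cherenkovrt:::tissue_code("tumor"))
  expect_equal(n_tum, oracle)
  expect_lt(abs(n_tum - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)
})

test_that("density jitter is seeded and zero jitter gives exact densities", {
  a <- generate_neck_phantom(seed = 7)
  b <- generate_neck_phantom(seed = 7)
  c <- generate_neck_phantom(seed = 8)
  expect_identical(a$density, b$density)
  expect_identical(a$tissue, c$tissue)     # labels never depend on the seed
  expect_false(identical(a$density, c$density))

  nj <- generate_neck_phantom(params = list(density_jitter_sd = 0), seed = 1)
  mus <- nj$density[nj$tissue == cherenkovrt:::tissue_code("muscle")]
  expect_true(all(mus == default_tissue_densities()[["muscle"]]))
})

test_that("tumor entirely outside the body is rejected", {
  expect_error(
    generate_neck_phantom(params = list(tumor_center = c(200, 0, 0)),
                          seed = 1),
    "tumor"
  )
})

test_that("water phantom is uniform water with the right dimensions and mass", {
  wp <- generate_water_phantom(c(30, 30, 50), spacing = c(2, 2, 2))
  expect_equal(wp$dims, c(150L, 150L, 250L))
  expect_true(all(wp$tissue == cherenkovrt:::tissue_code("water")))
  expect_true(all(wp$density == 1))
  expect_equal(grid_mass_kg(wp), 45)
  expect_error(generate_water_phantom(c(-1, 30, 50)), "positive")
})

test_that("density-to-tissue mapping follows the calibration table", {
  expect_equal(density_to_tissue(0.0012), "air")
  expect_equal(density_to_tissue(1.85), "bone")
  expect_equal(density_to_tissue(c(0.5, 1.0, 1.3)),
               c("adipose", "muscle", "bone"))
  # a value exactly on a threshold takes the lower interval's label
  expect_equal(density_to_tissue(0.05), "air")
  expect_equal(density_to_tissue(0.95), "adipose")
  expect_error(density_to_tissue(-0.1), "non-negative")
  bad <- tibble::tibble(upper = c(1, 0.5, Inf), tissue = c("a", "b", "c"))
  expect_error(density_to_tissue(0.2, bad), "increasing")
})

test_that("optical properties interpolate linearly and match tables exactly", {
  props <- default_optical_properties()
  # air is optically void
  air <- tissue_properties("air", c(500, 777, 1200))
  expect_true(all(air$mu_a_per_mm == 0 & air$mu_s_per_mm == 0 & air$n == 1))
  # tumor and adipose anisotropy overlap at every tabulated wavelength
  lam <- sort(unique(props$lambda_nm))
  expect_equal(tissue_properties("tumor", lam)$g,
               tissue_properties("adipose", lam)$g)
  # tabulated wavelengths reproduce table values exactly
  tab <- props[props$tissue == "muscle" & props$lambda_nm == 700, ]
  got <- tissue_properties("muscle", 700)
  expect_identical(got$mu_a_per_mm, tab$mu_a_per_mm)
  expect_identical(got$mu_s_per_mm, tab$mu_s_per_mm)
  # midway between grid points -> mean of neighbours
  nb <- tissue_properties("muscle", c(700, 710))
  expect_equal(tissue_properties("muscle", 705)$mu_a_per_mm,
               mean(nb$mu_a_per_mm))
  expect_error(tissue_properties("muscle", 499), "range")
  expect_error(tissue_properties("cartilage", 700), "unknown")
})

test_that("surface mesh enumerates exposed faces with exact areas", {
  # single non-air voxel surrounded by air: 6 elements
  tis <- array(0L, dim = c(3, 3, 3)); tis[2, 2, 2] <- 3L
  den <- array(0, dim = c(3, 3, 3)); den[2, 2, 2] <- 1.05
  g1 <- voxel_grid(tis, den, spacing = c(1, 1, 1.3))
  m1 <- extract_surface_mesh(g1)
  expect_equal(nrow(m1), 6)
  # x-facing element area = product of the transverse spacings = 1 x 1.3
  expect_equal(m1$area[m1$face == 1], 1.3)
  expect_equal(m1$area[m1$face == 5], 1.0)

  # 2x1x1 block: 10 exposed faces (enumerated by hand)
  tis2 <- array(0L, dim = c(4, 3, 3)); tis2[2:3, 2, 2] <- 3L
  den2 <- array(0, dim = c(4, 3, 3)); den2[2:3, 2, 2] <- 1.05
  m2 <- extract_surface_mesh(voxel_grid(tis2, den2, spacing = c(1, 1, 1)))
  expect_equal(nrow(m2), 10)

  # mesh closure: signed face areas cancel along each axis for an interior
  # body
  expect_equal(sum(m2$nx * m2$area), 0)
  expect_equal(sum(m2$ny * m2$area), 0)
  expect_equal(sum(m2$nz * m2$area), 0)

  expect_error(extract_surface_mesh(
    voxel_grid(array(0L, dim = c(2, 2, 2)), array(0, dim = c(2, 2, 2)))),
    "air")
})

test_that("neck surface mesh closes and covers every tissue-air face once", {
  mesh <- neck_mesh_fixture()
  expect_equal(sum(mesh$nx * mesh$area), 0)
  expect_equal(sum(mesh$ny * mesh$area), 0)
  expect_true(all(mesh$area > 0))
  expect_false(any(duplicated(mesh[, c("ix", "iy", "iz", "face")])))
})
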