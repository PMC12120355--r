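# a tiny 3x3x3 solid box with a known mesh, and hand-made exit records
box_fixture <- function() {
  fixture("box", function() {
    tis <- array(0L, dim = c(5, 5, 5))
    tis[2:4, 2:4, 2:4] <- cherenkovrt:::tissue_code("muscle")
    den <- array(0, dim = c(5, 5, 5))
    den[2:4, 2:4, 2:4] <- 1.05
    g <- voxel_grid(tis, den, spacing = c(1, 1, 1.3))
    list(grid = g, mesh = extract_surface_mesh(g))
  })
}

# an exit record landing on a given mesh element
exit_on <- function(mesh, element_id, wavelength = 700, born_in_tumor = TRUE,
                    birth_voxel = 1L) {
  e <- mesh[mesh$element_id == element_id, ]
  tibble::tibble(
    photon_id = NA_integer_, exit_x = e$cx, exit_y = e$cy, exit_z = e$cz,
    exit_dx = e$nx, exit_dy = e$ny, exit_dz = e$nz,
    exit_voxel = e$ix + attr(mesh, "dims")[1] *
      (e$iy - 1 + attr(mesh, "dims")[2] * (e$iz - 1)),
    exit_face = e$face, wavelength_nm = wavelength,
    birth_x = 0, birth_y = 0, birth_z = 0,
    birth_voxel = birth_voxel, born_in_tumor = born_in_tumor)
}

test_that("MU calibration arithmetic and scaling are linear and exact", {
  tis <- array(cherenkovrt:::tissue_code("water"), dim = c(11, 11, 20))
  grid <- voxel_grid(tis, array(1, dim = c(11, 11, 20)), spacing = c(2, 2, 2))
  dep <- array(0, dim = grid$dims)
  # put known dose at the axis voxel nearest 15 mm depth: z index counts
  # from the bottom, the surface is at the top (+z)
  dep[6, 6, 13] <- 2e-11 / 1.602176634e-13 * (8 * 1e-6)  # -> 2e-11 Gy
  dg <- score_dose(dep, grid)
  cal <- calibrate_mu(dg, depth_mm = 15)
  expect_equal(cal$D_d, 2e-11, tolerance = 1e-9)
  expect_equal(cal$N, 5e8, tolerance = 1e-6)
  # self-consistency: 1 MU yields exactly 1 cGy at the calibration point
  expect_equal(scale_to_physical(cal$D_d, cal, 1), 0.01)
  # doubling every deposit doubles D_d and halves N
  cal2 <- calibrate_mu(score_dose(dep * 2, grid), depth_mm = 15)
  expect_equal(cal2$D_d, 2 * cal$D_d)
  expect_equal(cal2$N, cal$N / 2)
  # scaling examples and linearity
  expect_equal(scale_to_physical(1e-11, cal, 157.5), 0.787, tolerance = 1e-2)
  expect_equal(scale_to_physical(1e-11, cal, 0), 0)
  expect_equal(scale_to_physical(3e-11, cal, 20),
               2 * scale_to_physical(3e-11, cal, 10))
  # zero dose at the calibration point is an error
  expect_error(calibrate_mu(score_dose(array(0, dim = grid$dims), grid)),
               "zero dose")
})

test_that("surface maps count photons per area with mass balance", {
  bx <- box_fixture()
  ex <- dplyr::bind_rows(
    exit_on(bx$mesh, 1)[rep(1, 3), ],
    exit_on(bx$mesh, 2)[rep(1, 5), ],
    exit_on(bx$mesh, 3, wavelength = 715)
  )
  map <- surface_intensity_map(ex, bx$mesh, filter = FALSE,
                               threshold_fraction = 0)
  a1 <- bx$mesh$area[1]
  expect_equal(map$value[map$element_id == 1], 3 / a1)
  # a -z face element of the default-like spacing has area 1 x 1 = 1;
  # an x face has 1 x 1.3
  expect_equal(sort(unique(bx$mesh$area)), c(1, 1.3))
  # mass balance: sum(value x area) equals the exit count in band
  expect_equal(sum(map$value * map$area), nrow(ex))
  # threshold_fraction = 1 keeps only the argmax elements
  m1 <- surface_intensity_map(ex, bx$mesh, threshold_fraction = 1)
  expect_equal(which(m1$value > 0), which.max(map$value))
  # band defaults: 5% for the full band, 10% for 710-720 nm
  expect_equal(attr(surface_intensity_map(ex, bx$mesh), "threshold_fraction"),
               0.05)
  expect_equal(attr(surface_intensity_map(ex, bx$mesh, band = c(710, 720)),
                    "threshold_fraction"), 0.10)
  # empty band selection: all-zero map, not an error
  m0 <- surface_intensity_map(ex[0, ], bx$mesh, threshold_fraction = 0)
  expect_true(all(m0$value == 0))
  expect_error(surface_intensity_map(ex, bx$mesh, band = c(400, 700)),
               "band")
})

test_that("spectra are peak-normalized wavelength histograms", {
  one <- tibble::tibble(wavelength_nm = rep(755, 10))
  sp <- compute_spectrum(one)
  expect_equal(sum(sp$intensity == 1), 1)
  expect_true(all(sp$intensity[sp$bin_lo != 750] == 0))
  expect_true(all(diff(sp$bin_lo) == 10))
  expect_error(compute_spectrum(one[0, ]), "empty")
  # emitted Cherenkov spectrum follows the 1/lambda^2 law bin by bin
  set.seed(31)
  bank <- tibble::tibble(wavelength_nm = sample_cherenkov_wavelength(1e6))
  spe <- compute_spectrum(bank, bin_nm = 50, normalization = "sum")
  expected <- (1 / spe$bin_lo - 1 / spe$bin_hi) / (1 / 500 - 1 / 1200)
  expect_equal(spe$intensity, expected, tolerance = 0.02)
})

test_that("the tumor spot is the largest connected high-intensity component", {
  bx <- box_fixture()
  # all tumor-born exits on one element -> the spot is that element
  ex1 <- exit_on(bx$mesh, 7)[rep(1, 4), ]
  spot1 <- identify_tumor_spot(ex1, bx$mesh, filter = FALSE)
  expect_equal(spot1$element_ids, 7)
  # two disjoint clusters: larger one wins
  top <- bx$mesh$element_id[bx$mesh$face == 5]   # +z faces, 3x3 patch
  bot <- bx$mesh$element_id[bx$mesh$face == 6]
  ex2 <- dplyr::bind_rows(
    do.call(dplyr::bind_rows, lapply(top[1:3], function(e) exit_on(bx$mesh, e))),
    do.call(dplyr::bind_rows, lapply(bot[1:2], function(e) exit_on(bx$mesh, e)))
  )
  spot2 <- identify_tumor_spot(ex2, bx$mesh, filter = FALSE)
  expect_setequal(spot2$element_ids, top[1:3])
  # equal clusters: tie broken toward the smaller minimum element id
  ex3 <- dplyr::bind_rows(
    do.call(dplyr::bind_rows, lapply(top[1:2], function(e) exit_on(bx$mesh, e))),
    do.call(dplyr::bind_rows, lapply(bot[1:2], function(e) exit_on(bx$mesh, e)))
  )
  spot3 <- identify_tumor_spot(ex3, bx$mesh, filter = FALSE)
  expect_equal(min(spot3$element_ids),
               min(c(min(top[1:2]), min(bot[1:2]))))
  # no tumor-born exits: informative error
  ex_no <- exit_on(bx$mesh, 1, born_in_tumor = FALSE)
  expect_error(identify_tumor_spot(ex_no, bx$mesh), "unreachable")
})

test_that("origin distributions histogram births by exit region", {
  bx <- box_fixture()
  ex <- dplyr::bind_rows(
    exit_on(bx$mesh, 1, birth_voxel = 32L)[rep(1, 3), ],
    exit_on(bx$mesh, 2, birth_voxel = 33L)[rep(1, 2), ],
    exit_on(bx$mesh, 9, birth_voxel = 62L)
  )
  ex <- exits_with_elements(ex, bx$mesh)
  full <- origin_distribution(ex, NULL, bx$grid)
  expect_equal(sum(full$counts), nrow(ex))
  expect_equal(sum(full$values) * voxel_volume(bx$grid), nrow(ex))
  one <- origin_distribution(ex, surface_region(1, "e1", bx$mesh), bx$grid)
  expect_equal(sum(one$counts), 3)
  expect_equal(one$counts[32], 3)
  # nested regions are monotone voxel-wise
  sub <- origin_distribution(ex, surface_region(c(1, 2), "s", bx$mesh), bx$grid)
  expect_true(all(sub$counts <= full$counts))
  expect_true(all(one$counts <= sub$counts))
})

test_that("reduced areas saturate, contain the spot, and can be empty", {
  mesh <- neck_mesh_fixture()
  # a synthetic anterior spot near x = 10
  sel <- mesh$element_id[mesh$face == 3 & abs(mesh$cx - 10) < 3 &
                           abs(mesh$cz) < 5]
  spot <- surface_region(sel, "tumor-spot", mesh)
  r10 <- make_reduced_area(spot, mesh, 100)
  r2 <- make_reduced_area(spot, mesh, 20)
  expect_true(all(r2$element_ids %in% r10$element_ids))
  expect_true(all(spot$element_ids %in% r10$element_ids))
  # saturation: a band wider than the phantom is the whole anterior half
  rall <- make_reduced_area(spot, mesh, 1e4)
  y_mid <- (max(mesh$cy) + min(mesh$cy)) / 2
  expect_setequal(rall$element_ids, mesh$element_id[mesh$cy >= y_mid])
  expect_error(make_reduced_area(spot, mesh, -5), "positive")
})

test_that("region similarity is a bounded symmetric overlap", {
  a <- array(c(0.5, 0.5, 0), dim = c(3, 1, 1))
  b <- array(c(0.5, 0, 0.5), dim = c(3, 1, 1))
  expect_equal(region_similarity(a, a), 1)
  expect_equal(region_similarity(a, b), 0.5)
  expect_equal(region_similarity(a, b), region_similarity(b, a))
  disj <- array(c(0, 0, 1), dim = c(3, 1, 1))
  expect_equal(region_similarity(a, disj), 0)
  # scale invariance through normalization
  expect_equal(region_similarity(a * 7, b * 0.1), 0.5)
  expect_error(region_similarity(a, array(0, dim = c(3, 1, 1))), "zero")
  expect_error(region_similarity(a, array(1, dim = c(2, 1, 1))), "grid")
})

test_that("fraction cut-offs zero sub-threshold values only", {
  g <- array(c(10, 5, 0.05), dim = c(3, 1, 1))
  expect_equal(as.vector(apply_fraction_cutoff(g, 0)), c(10, 5, 0.05))
  expect_equal(as.vector(apply_fraction_cutoff(g, 0.01)), c(10, 5, 0))
  expect_equal(as.vector(apply_fraction_cutoff(g, 1)), c(10, 0, 0))
  expect_error(apply_fraction_cutoff(g, 1.5), "fraction")
})
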