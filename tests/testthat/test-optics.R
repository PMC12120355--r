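test_that("free-path sampling inverts the exponential law", {
  expect_equal(sample_free_path(2, exp(-1)), 0.5)
  expect_identical(sample_free_path(0, 0.3), Inf)
  expect_error(sample_free_path(1, 0), "inside")
  expect_error(sample_free_path(1, 1), "inside")
  expect_error(sample_free_path(-1, 0.5), "non-negative")
  set.seed(21)
  paths <- sample_free_path(0.5, runif(1e6))
  # exponential mean 1/mu within 3 standard errors (sd = mean)
  expect_lt(abs(mean(paths) - 2), 3 * 2 / sqrt(1e6))
})

test_that("Henyey-Greenstein sampling matches its closed form and moments", {
  expect_equal(scatter_hg(0, u = 0.75), 0.5)
  expect_equal(scatter_hg(0.9, u = 0.5), 0.98550, tolerance = 1e-5)
  expect_error(scatter_hg(1), "anisotropy")
  expect_error(scatter_hg(-1.2), "anisotropy")
  set.seed(22)
  ct <- scatter_hg(0.8, n_samples = 1e6)
  expect_true(all(ct >= -1 & ct <= 1))
  # first moment of HG equals g
  expect_lt(abs(mean(ct) - 0.8), 3 * stats::sd(ct) / sqrt(1e6))
  # g = 0 degenerates to isotropic
  u <- runif(1e4)
  expect_equal(scatter_hg(0, u = u), 2 * u - 1)
})

test_that("Fresnel boundaries reflect, refract and totally internally reflect", {
  expect_equal(fresnel_reflectance(1, 1.4, 1), (0.4 / 2.4)^2, tolerance = 1e-12)
  # matched indices always transmit with unchanged direction
  b <- boundary_interaction(c(0, 0.6, 0.8), c(0, 0, 1), 1.4, 1.4, u = 0.999)
  expect_true(b$transmitted)
  expect_equal(b$direction, c(0, 0.6, 0.8))
  # beyond the critical angle: always reflects
  crit <- asin(1 / 1.4)
  d <- c(sin(crit + 0.05), 0, cos(crit + 0.05))
  b2 <- boundary_interaction(d, c(0, 0, 1), 1.4, 1, u = 0.9999999)
  expect_false(b2$transmitted)
  expect_equal(b2$direction, c(d[1], 0, -d[3]))
  # Snell's law at a refracting transmission
  d3 <- c(sin(0.3), 0, cos(0.3))
  b3 <- boundary_interaction(d3, c(0, 0, 1), 1.4, 1, u = 0.99)
  expect_true(b3$transmitted)
  expect_equal(b3$direction[1], 1.4 * sin(0.3), tolerance = 1e-12)
})

test_that("optical transmission through an absorbing slab is Beer-Lambert", {
  set.seed(23)
  L <- 10; mu_a <- 0.2
  grid <- uniform_grid("muscle", c(21, 21, L), spacing = 1)
  pr <- uniform_optical_props(mu_a, 0, 0, n = 1)
  n <- 1e5
  tr <- trace_optical_photons(pencil_bank(n, grid), grid, pr, fresnel = FALSE)
  transmitted <- sum(tr$exits$exit_face == 5) / n
  p_th <- exp(-mu_a * L)
  expect_lt(abs(transmitted - p_th), 4 * sqrt(p_th * (1 - p_th) / n))
})

test_that("photon fates are exhaustive, deterministic and air-births rejected", {
  ph <- neck_fixture()
  set.seed(24)
  # scattering-dominated band: a mixed population of fates
  ctrs <- expand.grid(x = seq(-30, 30, by = 6), y = seq(-30, 30, by = 6))
  keep <- sqrt(ctrs$x^2 + ctrs$y^2) < 40 &
    ph$tissue[cbind(ctrs$x + 55, ctrs$y + 55, 31)] != 0
  bank <- tibble::tibble(x = ctrs$x[keep], y = ctrs$y[keep], z = 0,
                         dx = 0, dy = 0, dz = 1,
                         wavelength_nm = 620)
  bank <- bank[rep(seq_len(nrow(bank)), 40), ]
  run1 <- withr::with_seed(99, trace_optical_photons(bank, ph, event_cap = 200))
  run2 <- withr::with_seed(99, trace_optical_photons(bank, ph, event_cap = 200))
  expect_identical(run1$photons$status, run2$photons$status)
  expect_identical(run1$exits, run2$exits)
  tab <- table(run1$photons$status)
  expect_equal(sum(tab), nrow(bank))   # births = absorbed + exited + capped
  expect_equal(nrow(run1$exits), sum(run1$photons$status == "exited"))
  # birth position of every exit lies in a non-air voxel
  exv <- run1$exits
  expect_true(all(ph$tissue[exv$birth_voxel] != 0L))

  air_bank <- tibble::tibble(x = 0, y = 14, z = 0, dx = 1, dy = 0, dz = 0,
                             wavelength_nm = 700)
  expect_error(trace_optical_photons(air_bank, ph), "air")
})

test_that("with no absorption every photon eventually exits", {
  set.seed(25)
  grid <- uniform_grid("muscle", 15)
  pr <- uniform_optical_props(0, 2, 0.5, n = 1)
  tr <- trace_optical_photons(pencil_bank(2000, grid), grid, pr,
                              fresnel = FALSE, event_cap = 1e6)
  expect_true(all(tr$photons$status == "exited"))
})

test_that("fluence around an isotropic point source follows diffusion theory", {
  set.seed(26)
  side <- 101
  grid <- uniform_grid("muscle", side)
  mu_a <- 0.002; mu_sp <- 1
  pr <- uniform_optical_props(mu_a, mu_sp, 0, n = 1)
  np <- 2e5
  phi <- runif(np, 0, 2 * pi); ct <- runif(np, -1, 1); st <- sqrt(1 - ct^2)
  bank <- tibble::tibble(x = 0, y = 0, z = 0,
                         dx = st * cos(phi), dy = st * sin(phi), dz = ct,
                         wavelength_nm = 700)
  tr <- trace_optical_photons(bank, grid, pr, fresnel = FALSE,
                              score_fluence = TRUE)
  ctr <- (side + 1) / 2
  ii <- expand.grid(x = 1:side, y = 1:side, z = 1:side)
  r <- sqrt((ii$x - ctr)^2 + (ii$y - ctr)^2 + (ii$z - ctr)^2)
  fl <- as.vector(tr$fluence) / np
  D <- 1 / (3 * (mu_a + mu_sp)); mu_eff <- sqrt(mu_a / D)
  for (rr in c(5, 10, 15, 20)) {
    sim <- mean(fl[abs(r - rr) < 0.5])
    th <- exp(-mu_eff * rr) / (4 * pi * D * rr)
    expect_lt(abs(sim / th - 1), 0.15)
  }
})

test_that("surface exits carry consistent element geometry", {
  ph <- neck_fixture()
  mesh <- neck_mesh_fixture()
  set.seed(27)
  bank <- tibble::tibble(x = 30, y = 0, z = 0, dx = 1, dy = 0, dz = 0,
                         wavelength_nm = 800,
                         birth_x = 30, birth_y = 0, birth_z = 0,
                         birth_voxel = NA_integer_,
                         born_in_tumor = FALSE)[rep(1, 500), ]
  tr <- trace_optical_photons(bank, ph)
  ex <- exits_with_elements(tr$exits, mesh)
  expect_true(all(!is.na(ex$element_id)))
  geom <- mesh[match(ex$element_id, mesh$element_id), ]
  # exit position lies on the element face to within half a voxel
  expect_true(all(abs(ex$exit_x - geom$cx) <= 0.51 * max(ph$spacing)))
  expect_true(all(abs(ex$exit_y - geom$cy) <= 0.51 * max(ph$spacing)))
  expect_true(all(abs(ex$exit_z - geom$cz) <= 0.66 * max(ph$spacing)))
})
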