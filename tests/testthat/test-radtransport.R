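test_that("X-ray transmission through a pure-photoelectric slab is exp(-mu L)", {
  set.seed(11)
  L <- 20
  grid <- uniform_grid("water", c(41, 41, L), spacing = 1)
  mu <- 0.08
  rp <- make_slab_props(mu)
  n <- 1e5
  photons <- tibble::tibble(
    x = 0, y = 0, z = min(voxel_centers(grid, 3)) - 5,
    dx = 0, dy = 0, dz = 1, energy_mev = 2)[rep(1, n), ]
  res <- transport_xray(photons, grid, rp)
  transmitted <- mean(res$escaped == photons$energy_mev)
  p_th <- exp(-mu * L)
  expect_lt(abs(transmitted - p_th), 4 * sqrt(p_th * (1 - p_th) / n))
  # every interaction was photoelectric: all energy stays in the grid
  expect_equal(sum(res$deposit) + sum(res$escaped), sum(photons$energy_mev))
})

test_that("a vacuum grid lets photons escape with full energy", {
  tis <- array(0L, dim = c(5, 5, 5))
  grid <- voxel_grid(tis, array(0, dim = c(5, 5, 5)))
  photons <- tibble::tibble(x = 0, y = 0, z = -10, dx = 0, dy = 0, dz = 1,
                            energy_mev = 3)[rep(1, 10), ]
  res <- transport_xray(photons, grid)
  expect_true(all(res$escaped == 3))
  expect_true(all(res$deposit == 0))
  expect_equal(nrow(res$electrons), 0)
})

test_that("X-ray histories conserve energy exactly", {
  set.seed(12)
  grid <- uniform_grid("muscle", 31)
  photons <- tibble::tibble(
    x = runif(2000, -5, 5), y = runif(2000, -5, 5), z = -25,
    dx = 0, dy = 0, dz = 1, energy_mev = runif(2000, 0.2, 6))
  res <- transport_xray(photons, grid)
  handed_to_electrons <- vapply(seq_len(2000), function(i) {
    sum(res$electrons$energy_mev[res$electrons$history == i])
  }, numeric(1))
  balance <- res$deposited + res$escaped + handed_to_electrons -
    photons$energy_mev
  expect_lt(max(abs(balance)), 1e-9)
  expect_equal(sum(res$deposit), sum(res$deposited), tolerance = 1e-12)
})

test_that("electrons below threshold deposit everything and emit nothing", {
  grid <- uniform_grid("muscle", 31)
  # 0.15 MeV < 0.219 MeV threshold for n = 1.4 soft tissue
  el <- tibble::tibble(x = 0, y = 0, z = 0, dx = 0, dy = 0, dz = 1,
                       energy_mev = 0.15)[rep(1, 50), ]
  res <- transport_electron(el, grid)
  expect_equal(res$n_emitted, 0)
  expect_equal(nrow(res$bank), 0)
  expect_equal(sum(res$deposit), sum(el$energy_mev), tolerance = 1e-12)
  expect_true(all(res$escaped == 0))
})

test_that("Cherenkov photon count matches the CSDA step-sum oracle", {
  set.seed(13)
  grid <- uniform_grid("water", 61)
  n <- 1e4
  el <- tibble::tibble(x = 0, y = 0, z = -20, dx = 0, dy = 0, dz = 1,
                       energy_mev = 1)[rep(1, n), ]
  res <- transport_electron(el, grid, settings = run_settings(bank_cap = 0))
  # deterministic oracle: sum the Frank-Tamm yield along the same stepping
  rp <- cherenkovrt:::rad_props_matrices()
  wcol <- which(tissue_levels() == "water")
  E <- 1; expected <- 0; step <- 0.1
  while (E > 0.01) {
    S <- stats::approx(rp$energy, rp$stopping[, wcol], xout = E,
                       rule = 2)$y
    dE <- S * step; st <- step
    if (dE >= E) { st <- E / S; dE <- E }
    b <- electron_beta(E - dE / 2)
    expected <- expected + frank_tamm_yield(b, 1.33, 1, 500, 1200) * st
    E <- E - dE
  }
  mean_count <- res$n_emitted / n
  se <- sqrt(expected / n)   # Poisson counts: var = mean
  expect_lt(abs(mean_count - expected), 3 * se)
  # exact per-track energy balance
  expect_lt(max(abs(el$energy_mev - res$deposited - res$escaped)), 1e-12)
})

test_that("no Cherenkov photon is born below the local emission condition", {
  set.seed(14)
  ph <- neck_fixture()
  el <- tibble::tibble(x = runif(200, -10, 25), y = runif(200, -10, 20),
                       z = 0, dx = 0, dy = 0, dz = 1,
                       energy_mev = runif(200, 0.25, 3))
  res <- transport_electron(el, ph)
  if (nrow(res$bank) > 0) {
    n_tis <- tissue_refractive_index()[tissue_label(ph$tissue[res$bank$birth_voxel])]
    # every banked photon was born in a medium where emission is possible
    expect_true(all(n_tis > 1))
    expect_true(all(ph$tissue[res$bank$birth_voxel] != 0L))
    expect_true(all(res$bank$wavelength_nm >= 500 &
                      res$bank$wavelength_nm <= 1200))
  }
  expect_gt(nrow(res$bank), 0)
})

test_that("dose scoring divides energy by the voxel mass", {
  tis <- array(cherenkovrt:::tissue_code("muscle"), dim = c(1, 1, 1))
  grid <- voxel_grid(tis, array(1, dim = c(1, 1, 1)), spacing = c(1, 1, 1.3))
  dep <- array(1, dim = c(1, 1, 1))  # 1 MeV
  dg <- score_dose(dep, grid)
  expect_equal(dg$dose[1, 1, 1], 1.602176634e-13 / 1.3e-6)
  expect_equal(dg$dose[1, 1, 1], 1.232e-7, tolerance = 1e-3)
  # no deposits -> all zero
  expect_true(all(score_dose(array(0, dim = c(1, 1, 1)), grid)$dose == 0))
  # doubling density halves dose
  grid2 <- voxel_grid(tis, array(2, dim = c(1, 1, 1)), spacing = c(1, 1, 1.3))
  expect_equal(score_dose(dep, grid2)$dose[1, 1, 1], dg$dose[1, 1, 1] / 2)
  # energy in a zero-density voxel is an error
  grid0 <- voxel_grid(array(0L, dim = c(1, 1, 1)), array(0, dim = c(1, 1, 1)))
  expect_error(score_dose(dep, grid0), "zero-density")
})

test_that("water depth dose builds up to a maximum beyond the surface", {
  set.seed(15)
  wp <- generate_water_phantom(c(10, 10, 30), spacing = c(2, 2, 2))
  photons <- sample_calibration_photons(3e4, wp, field_mm = 60)
  sim <- simulate_photons(photons, wp, trace_optics = FALSE,
                          settings = run_settings(analog = FALSE))
  d <- sim$dose$dims
  blk <- (d[1] / 2 - 4):(d[1] / 2 + 5)
  prof <- apply(sim$dose$dose[blk, blk, , drop = FALSE], 3, mean)
  prof <- rev(prof)  # order by increasing depth
  # build-up: the maximum is below the surface, then the curve decays
  expect_gt(which.max(prof), 2)
  expect_lt(which.max(prof), 20)
  expect_lt(mean(prof[100:140]), max(prof))
  expect_lt(prof[140], prof[which.max(prof)] * 0.9)
})
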