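test_that("SED reference points match the closed form and are w-consistent", {
  refs <- reference_energies(remodel_params())
  expect_equal(refs$psi_U, 6.6^2 / (2 * 17000 * 1.649), tolerance = 1e-12)
  expect_equal(refs$psi_U, 7.7694e-4, tolerance = 1e-4)
  # psi_U does not depend on the lazy-zone width
  r2 <- reference_energies(remodel_params(w = 0.2))
  r5 <- reference_energies(remodel_params(w = 0.5))
  expect_equal(r2$psi_U, r5$psi_U)
  # increasing w lowers psi_L (shrinks the resorption region)
  expect_lt(r5$psi_L, r2$psi_L)
  # degenerate zero-width zone collapses all three references
  p0 <- remodel_params(); p0$w <- 0
  r0 <- reference_energies(p0)
  expect_equal(r0$psi_ref, r0$psi_U)
  expect_equal(r0$psi_L, r0$psi_U)
  expect_error(remodel_params(w = 1.5), "w")
})

test_that("cubic density-modulus law and its inverse round-trip", {
  expect_equal(density_modulus_law(1), 3790)
  expect_equal(density_modulus_law(1.649), 16994, tolerance = 1e-4)
  expect_equal(density_from_modulus(3790), 1)
  rho <- c(0.3, 0.9, 1.4, 1.73)
  expect_equal(density_from_modulus(density_modulus_law(rho)), rho)
  expect_error(density_modulus_law(0), "rho")
  expect_error(density_from_modulus(-5), "E")
})

test_that("surface-area density vanishes at the bounds and is positive inside", {
  p <- remodel_params()
  expect_equal(surface_area_density(p$rho_min, p), 0)
  expect_equal(surface_area_density(p$rho_max, p), 0)
  expect_gt(surface_area_density(1.0, p), 0)
  mid <- seq(p$rho_min + 0.01, p$rho_max - 0.01, length.out = 50)
  expect_true(all(surface_area_density(mid, p) > 0))
  expect_error(surface_area_density(2.0, p), "rho")
})

test_that("SED remodelling rate has a lazy zone and linear excess response", {
  p <- remodel_params()
  refs <- reference_energies(p)
  mid <- (refs$psi_L + refs$psi_U) / 2
  expect_equal(sed_remodelling_rate(mid, 1.0, p), 0)
  expect_equal(sed_remodelling_rate(refs$psi_L + 1e-9, 1.0, p), 0)
  # at maximum density the free surface vanishes: no remodelling at any psi
  expect_equal(sed_remodelling_rate(10 * refs$psi_U, p$rho_max, p), 0)
  # linear in the stimulus excess
  d1 <- sed_remodelling_rate(refs$psi_U + 1e-4, 1.0, p)
  d2 <- sed_remodelling_rate(refs$psi_U + 2e-4, 1.0, p)
  expect_gt(d1, 0)
  expect_equal(d2 / d1, 2, tolerance = 1e-9)
  # resorption below the lazy zone
  expect_lt(sed_remodelling_rate(refs$psi_L / 2, 1.0, p), 0)
})

test_that("single element under the homeostatic stress finds the fixed point", {
  for (rho0 in c(0.5, 1.0, 1.3)) {
    r <- remodel_single_element(rho0, 6.6, days = 2000)
    expect_equal(r$rho, 1.649, tolerance = 1e-3)
    expect_equal(r$E, 17000, tolerance = 0.01)
    # monotone convergence from below
    expect_true(all(diff(r$series$rho) >= -1e-12))
  }
  # from above the fixed point the element sits inside the lazy zone
  r_hi <- remodel_single_element(1.7, 6.6, days = 200)
  expect_equal(r_hi$rho, 1.7, tolerance = 1e-9)
})

test_that("S-N fit recovers a decreasing-in-stress, increasing-in-density law", {
  sn <- sn_constants()
  expect_lt(sn$H, 0)
  expect_gt(sn$K, 0)
  p <- remodel_params()
  expect_gt(cycles_to_failure(50, 1.7, p), cycles_to_failure(100, 1.7, p))
  expect_gt(cycles_to_failure(50, 2.0, p), cycles_to_failure(50, 1.7, p))
  # log-linear form: doubling sigma scales Nf by 2^H
  ratio <- cycles_to_failure(80, 1.7, p) / cycles_to_failure(40, 1.7, p)
  expect_equal(ratio, 2^sn$H, tolerance = 1e-9)
  expect_error(cycles_to_failure(0, 1.7, p), "sigma")
})

test_that("damage accumulates only above the homeostatic stress", {
  p <- remodel_params()
  st <- bone_state(1.649)
  # homeostatic loading: formation equals repair by construction
  st1 <- damage_update(st, p$sigma_U, dt = 30, p)
  expect_equal(st1$delta_omega, 0)
  # overload accumulates
  st2 <- st
  for (i in 1:30) st2 <- damage_update(st2, 60, dt = 1, p)
  expect_gt(st2$delta_omega, 0)
  # unloading repairs the stimulus back toward zero
  st3 <- st2
  for (i in 1:2000) st3 <- damage_update(st3, 0, dt = 1, p)
  expect_lte(st3$delta_omega, st2$delta_omega)
  expect_gte(st3$delta_omega, 0)
  expect_lte(max(st2$omega), 1)
})

test_that("damage resorption activates above omega_crit and respects a(rho)", {
  p <- remodel_params()
  st <- bone_state(1.0)
  expect_equal(damage_resorption_rate(st, p), 0)
  st$delta_omega <- omega_crit(1.0, p) + 1e-4
  expect_lt(damage_resorption_rate(st, p), 0)
  st_min <- bone_state(p$rho_min)
  st_min$delta_omega <- 1
  expect_equal(damage_resorption_rate(st_min, p), 0)  # a(rho_min) = 0
})

test_that("damage resorption outpaces SED resorption at the reference state", {
  p <- remodel_params()
  st <- bone_state(1.0)
  st$delta_omega <- omega_crit(1.0, p) + 1e-4
  dmg <- abs(damage_resorption_rate(st, p))
  sed <- abs(sed_remodelling_rate(0, 1.0, p))   # maximal SED resorption drive
  expect_gt(dmg, sed)
})

test_that("time controls scale exactly as specified", {
  p <- remodel_params()
  fs <- remodel_time_scales(0.35, 0, p)
  expect_equal(fs$sed, 0.5)
  expect_equal(fs$damage, 1)
  fs2 <- remodel_time_scales(0.1, 0, p)
  expect_equal(fs2$sed, 1)
  fs3 <- remodel_time_scales(0, 0.0125, p)
  expect_equal(fs3$damage, 0.5)
})

test_that("density never leaves its bounds under random stimulus trajectories", {
  p <- remodel_params()
  set.seed(5)
  rho <- stats::runif(30, p$rho_min, p$rho_max)
  cap <- p$drho_max / p$month
  for (step in 1:500) {
    psi <- 10^stats::runif(30, -5, -2)
    rate <- sed_remodelling_rate(psi, rho, p)
    drho <- clamp(rate * 1, -cap, cap)
    rho <- ossify:::bounded_density_step(rho, drho, p)
    expect_true(all(rho >= p$rho_min & rho <= p$rho_max))
  }
})
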