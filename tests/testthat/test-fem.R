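test_that("deviatoric strain follows the octahedral formula", {
  expect_equal(deviatoric_strain(0.01, 0.01, 0.01), 0)
  expect_equal(deviatoric_strain(0.01, 0, 0), 0.009428, tolerance = 1e-4)
  # permutation symmetry
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  e <- c(0.013, -0.004, 0.0021)
  vals <- vapply(perms, function(p) deviatoric_strain(e[p[1]], e[p[2]], e[p[3]]),
                 numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-15))
})

test_that("fluid velocity magnitude is the Euclidean norm", {
  expect_equal(fluid_velocity_magnitude(c(3, 0, 0)), 3)
  expect_equal(fluid_velocity_magnitude(c(1, 2, 2)), 3)
  expect_equal(fluid_velocity_magnitude(c(0, 0)), 0)
  expect_equal(fluid_velocity_magnitude(rbind(c(3, 4), c(0, 1))), c(5, 1))
})

test_that("strain energy density per density matches the closed form", {
  sigma <- diag(c(6.6, 0, 0))
  eps <- diag(c(6.6 / 17000, -0.1, -0.1))  # only the 11 term carries energy
  eps[2, 2] <- eps[3, 3] <- 0              # keep the product clean
  psi <- element_strain_energy_density(sigma, eps, 1.649)
  expect_equal(psi, 6.6^2 / (2 * 17000 * 1.649), tolerance = 1e-12)
  expect_equal(psi, 7.769e-4, tolerance = 1e-4)
  expect_equal(element_strain_energy_density(sigma * 0, eps, 1.2), 0)
  # quadratic scaling
  k <- 3
  psi_k <- element_strain_energy_density(k * sigma, k * eps, 1.649)
  expect_equal(psi_k / psi, k^2, tolerance = 1e-12)
  expect_error(element_strain_energy_density(sigma, eps, 0), "rho")
})

test_that("zero load produces identically zero fields", {
  snap <- solve_daily_loading(toy_mesh(), toy_materials(), 0,
                              cache = toy_cache())
  expect_true(all(snap$eps_dev == 0))
  expect_true(all(snap$wf_mag == 0))
  expect_true(all(snap$psi == 0))
})

test_that("response is linear in the applied load", {
  mesh <- toy_mesh(); mat <- toy_materials(); cache <- toy_cache()
  s1 <- solve_daily_loading(mesh, mat, 70, cache = cache)
  s2 <- solve_daily_loading(mesh, mat, 140, cache = cache)
  expect_equal(s2$eps_dev, 2 * s1$eps_dev, tolerance = 1e-9)
  expect_equal(s2$wf_mag, 2 * s1$wf_mag, tolerance = 1e-9)
  expect_equal(s2$psi, 4 * s1$psi, tolerance = 1e-9)  # quadratic in load
})

test_that("global equilibrium: fixed-end reaction equals the applied load", {
  snap <- solve_daily_loading(toy_mesh(), toy_materials(), 70,
                              cache = toy_cache())
  expect_equal(snap$reaction, 70, tolerance = 1e-6)
})

test_that("fields are non-negative and finite", {
  snap <- solve_daily_loading(toy_mesh(), toy_materials(), 140,
                              cache = toy_cache())
  expect_true(all(is.finite(snap$eps_dev)) && all(snap$eps_dev >= 0))
  expect_true(all(is.finite(snap$wf_mag)) && all(snap$wf_mag >= 0))
  expect_true(all(is.finite(snap$psi)) && all(snap$psi >= 0))
})

terzaghi_series <- function(y_over_H, Tv, nterms = 200) {
  m <- 0:nterms
  M <- (2 * m + 1) * pi / 2
  vapply(y_over_H, function(y) {
    sum(4 / ((2 * m + 1) * pi) * sin(M * y) * exp(-M^2 * Tv))
  }, numeric(1))
}

test_that("1D consolidation matches the Terzaghi series within 2%", {
  E <- 10; nu <- 0.3; k <- 0.01; H <- 10
  mesh <- make_fixture("consolidation_column", height = H, nz = 40)
  # near-incompressible constituents so the analytic assumptions hold
  mat <- poro_materials(E = E, nu = nu, permeability = k, porosity = 0.8,
                        Ks = 1e9, Kf = 1e9, rho = 1, n = nrow(mesh$elems))
  Mconf <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  cv <- k * Mconf
  Tv <- 0.2
  t_end <- Tv * H^2 / cv
  snap <- solve_daily_loading(mesh, mat, 1, duration = t_end, n_sub = 80,
                              ramp = FALSE, return_history = TRUE)
  p <- snap$p
  # depth below the drained (loaded, top) surface, normalized
  y <- (H - mesh$nodes[, 2]) / H
  keep <- y > 0.2          # skip the steep boundary layer near the drain
  expected <- terzaghi_series(y[keep], Tv)
  expect_true(all(abs(p[keep] - expected) <= 0.02),
              label = sprintf("max |p - series| = %.4f",
                              max(abs(p[keep] - expected))))
})

test_that("long-time drained limit recovers the elastic solution", {
  E <- 10; nu <- 0.3; k <- 0.01; H <- 10
  mesh <- make_fixture("consolidation_column", height = H, nz = 20)
  mat <- poro_materials(E = E, nu = nu, permeability = k, porosity = 0.8,
                        Ks = 1e9, Kf = 1e9, rho = 1, n = nrow(mesh$elems))
  snap <- solve_daily_loading(mesh, mat, 1, duration = 1e5, n_sub = 40,
                              ramp = FALSE)
  expect_lt(max(abs(snap$p)), 1e-3)
  # confined column: settlement = sigma H / Mconf
  Mconf <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  top <- which(abs(mesh$nodes[, 2] - H) < 1e-8)[1]
  expect_equal(abs(snap$u[top, 2]), 1 * H / Mconf, tolerance = 0.01)
})

test_that("an unconstrained mesh raises a singular-system error", {
  mesh <- make_fixture("consolidation_column", height = 5, nz = 4)
  mesh$boundary$fixed <- integer(0)
  mesh$constrain_x <- FALSE
  mat <- poro_materials(E = 10, nu = 0.3, permeability = 0.01, porosity = 0.8,
                        Ks = 1e9, Kf = 1e9, rho = 1, n = nrow(mesh$elems))
  expect_error(solve_daily_loading(mesh, mat, 1), "singular|system")
})

test_that("poro_materials rejects non-physical inputs", {
  expect_error(poro_materials(E = -1, nu = 0.3, permeability = 1, porosity = 0.5,
                              Ks = 10, Kf = 10, rho = 1), "modulus")
  expect_error(poro_materials(E = 1, nu = 0.6, permeability = 1, porosity = 0.5,
                              Ks = 10, Kf = 10, rho = 1), "Poisson")
  expect_error(poro_materials(E = 1, nu = 0.3, permeability = 1, porosity = 1.5,
                              Ks = 10, Kf = 10, rho = 1), "porosity")
})

test_that("solution is mesh-convergent under refinement", {
  # mean focus stimulus fields on two successive refinements differ < 5%
  run_fields <- function(h) {
    mesh <- build_fracture_model(geometry_spec("unplated", mesh_target_size = h))
    mat <- assign_region_materials(mesh)
    snap <- solve_daily_loading(mesh, mat, 70)
    foc <- mesh$region == "callus_focus"
    c(eps = mean(snap$eps_dev[foc]), ifm = interfragmentary_movement(mesh, snap))
  }
  f1 <- run_fields(2.5)
  f2 <- run_fields(1.25)
  expect_lt(abs(f1[["ifm"]] - f2[["ifm"]]) / f2[["ifm"]], 0.05)
  expect_lt(abs(f1[["eps"]] - f2[["eps"]]) / f2[["eps"]], 0.15)
})
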