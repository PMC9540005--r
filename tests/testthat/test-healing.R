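test_that("biophysical stimulus reproduces the band edges", {
  expect_equal(biophysical_stimulus(0.0375, 0), 1)
  expect_equal(biophysical_stimulus(0.1125, 0), 3)     # fibrous edge
  expect_equal(biophysical_stimulus(0, 0.03), 0.01)    # resorption edge
  expect_equal(biophysical_stimulus(0.0375, 3), 2)     # both contributions
  expect_error(biophysical_stimulus(-0.1, 0), "non-negative")
})

test_that("tissue membership is crisp outside and linear inside fuzzy zones", {
  TM <- tissue_membership(c(2, 1, 3.2, 0.5, 0.005, 2.9))
  expect_equal(unname(TM[1, ]), c(0, 1, 0, 0, 0))           # cartilage band
  expect_equal(unname(TM[2, c("c", "ib")]), c(0.5, 0.5))    # zone midpoint
  expect_equal(unname(TM[3, "f"]), 1)                       # above 3.15
  expect_equal(unname(TM[4, ]), c(0, 0, 1, 0, 0))           # immature band
  expect_equal(unname(TM[5, "resorb"]), 1)                  # below 0.0095
  # inside the fibrous zone [2.85, 3.15]: linear crossfade
  expect_equal(unname(TM[6, "f"]), (2.9 - 2.85) / 0.3)
  expect_equal(unname(TM[6, "c"]), 1 - (2.9 - 2.85) / 0.3)
})

test_that("membership rows always sum to one with at most two active bands", {
  S <- c(0, 10^seq(-3, 1.2, length.out = 400))
  TM <- tissue_membership(S)
  expect_true(all(abs(rowSums(TM) - 1) < 1e-12))
  expect_true(all(TM >= 0 & TM <= 1))
  expect_true(all(rowSums(TM > 0) <= 2))
})

test_that("cell differentiation follows the potency hierarchy", {
  p <- mechano_reg_params()
  cells <- matrix(0, 1, 4, dimnames = list(NULL, c("f", "c", "ib", "mb")))
  TM <- cbind(f = 0, c = 0, ib = 0, mb = 1, resorb = 0)
  d <- cell_density_rates(cells, cm = 1, TM, p)
  expect_equal(unname(d[1, ]), c(0, 0, 0, 0.15))     # Fmb * (1-0) * cm
  # no membership, no differentiation
  d0 <- cell_density_rates(cells, 1, TM * 0, p)
  expect_true(all(d0 == 0))
  # logistic saturation at full density
  cells[1, "mb"] <- 1
  dsat <- cell_density_rates(cells, 1, TM, p)
  expect_equal(unname(dsat[1, "mb"]), 0)
  # fibroblasts also feed chondrocytes
  cells <- matrix(c(0.5, 0, 0, 0), 1, dimnames = list(NULL, c("f", "c", "ib", "mb")))
  TMc <- cbind(f = 0, c = 1, ib = 0, mb = 0, resorb = 0)
  dc <- cell_density_rates(cells, 0.25, TMc, p)
  expect_equal(unname(dc[1, "c"]), 0.3 * (0.25 + 0.5))
})

test_that("tissue production, replacement and closure follow the priority rules", {
  p <- mechano_reg_params()
  nm <- c("f", "c", "ib", "mb")
  cells <- matrix(c(0, 0, 0, 1), 1, dimnames = list(NULL, nm))
  frac <- matrix(0, 1, 4, dimnames = list(NULL, nm))
  TM <- cbind(f = 0, c = 0, ib = 0, mb = 1, resorb = 0)
  d <- tissue_fraction_rates(frac, cells, TM, p)
  expect_equal(unname(d[1, "mb"]), 0.1)              # Qmb * (1-0) * cmb
  frac[1, "mb"] <- 1
  expect_equal(unname(tissue_fraction_rates(frac, cells, TM, p)[1, "mb"]), 0)
  # closure
  frac <- matrix(c(0.2, 0.3, 0.1, 0), 1, dimnames = list(NULL, nm))
  expect_equal(granulation_fraction(frac), 0.4)
  # replacement: mature production consumes lower tissue proportionally
  cells <- matrix(c(0, 0, 0, 1), 1, dimnames = list(NULL, nm))
  d2 <- tissue_fraction_rates(frac, cells, TM, p)
  mtot <- 0.6
  expect_equal(unname(d2[1, "c"]), -0.1 * 1 * 0.3 / mtot)
  expect_equal(unname(d2[1, "f"]), -0.1 * 1 * 0.2 / mtot)
  # resorption removes bone fractions
  TMr <- cbind(f = 0, c = 0, ib = 0, mb = 0, resorb = 1)
  fr <- matrix(c(0, 0, 0.4, 0.2), 1, dimnames = list(NULL, nm))
  dr <- tissue_fraction_rates(fr, cells, TMr, p)
  expect_equal(unname(dr[1, "ib"]), -p$Q_ib * 0.4)
  expect_equal(unname(dr[1, "mb"]), -p$Q_mb * 0.2)
})

test_that("healing time scale caps the per-increment fraction change", {
  expect_equal(healing_time_scale(0.1), 0.5)
  expect_equal(healing_time_scale(0.05), 1)
  expect_equal(healing_time_scale(0), 1)
  expect_error(healing_time_scale(-0.1), "non-negative")
})

test_that("rule of mixtures interpolates tissue moduli with cell maturity", {
  p <- mechano_reg_params()
  nm <- c("f", "c", "ib", "mb")
  frac <- matrix(0, 1, 4, dimnames = list(NULL, nm))
  cells <- matrix(0, 1, 4, dimnames = list(NULL, nm))
  expect_equal(mixture_modulus(frac, cells, p), p$E_gran)   # pure granulation
  frac2 <- matrix(c(0, 0.5, 0, 0.5), 1, dimnames = list(NULL, nm))
  cells2 <- matrix(c(0, 1, 0, 1), 1, dimnames = list(NULL, nm))
  expect_equal(mixture_modulus(frac2, cells2, p), 0.5 * 500 + 0.5 * 6000)
  # convexity: E_raw within the range of constituent moduli
  set.seed(7)
  for (i in 1:50) {
    f <- stats::runif(4); f <- f / sum(f) * stats::runif(1)
    fr <- matrix(f, 1, dimnames = list(NULL, nm))
    cl <- matrix(stats::runif(4), 1, dimnames = list(NULL, nm))
    E <- mixture_modulus(fr, cl, p)
    expect_gte(E, p$E_gran * (1 - sum(f)))
    expect_lte(E, 6000)
  }
})

test_that("smoothed modulus is the dt-weighted trailing average", {
  # constant history
  expect_equal(smoothed_modulus(1:10, rep(1, 10),
                                matrix(100, 10, 1), 10), 100)
  # linear ramp 0 -> 100 over the window, uniform dt, midpoint sampling
  E <- matrix((1:10 - 0.5) * 10, 10, 1)
  expect_equal(smoothed_modulus(1:10, rep(1, 10), E, 10), 50)
  # single entry
  expect_equal(smoothed_modulus(2, 2, matrix(42, 1, 1), 2), 42)
  expect_error(smoothed_modulus(numeric(0), numeric(0),
                                matrix(0, 0, 1), 0), "empty")
  # only the trailing window counts
  E2 <- matrix(c(rep(1000, 5), rep(10, 10)), 15, 1)
  expect_equal(smoothed_modulus(1:15, rep(1, 15), E2, 15, window = 10), 10)
})

test_that("fractions stay conserved and bounded under randomized stimuli", {
  p <- mechano_reg_params()
  set.seed(11)
  n <- 25
  nm <- c("f", "c", "ib", "mb")
  cells <- matrix(0, n, 4, dimnames = list(NULL, nm))
  frac <- matrix(0, n, 4, dimnames = list(NULL, nm))
  for (step in 1:300) {
    S <- 10^stats::runif(n, -3, 1)
    TM <- tissue_membership(S, p)
    cm <- stats::runif(n)
    dt <- stats::runif(1, 0.1, 1)
    dc <- cell_density_rates(cells, cm, TM, p)
    dm <- tissue_fraction_rates(frac, cells, TM, p)
    f <- healing_time_scale(max(abs(dm)) * dt, p)
    dme <- dm * dt * f
    cells <- clamp(cells + dc * dt * f, 0, 1)
    frac <- clamp(frac + dme, 0, 1)
    s <- rowSums(frac)
    frac[s > 1, ] <- frac[s > 1, , drop = FALSE] / s[s > 1]
    expect_true(all(abs(dme) <= p$dm_max + 1e-12))
    expect_true(all(frac >= 0 & frac <= 1))
    expect_true(all(cells >= 0 & cells <= 1))
    expect_true(all(granulation_fraction(frac) >= -1e-9))
    expect_true(all(rowSums(frac) + granulation_fraction(frac) - 1 < 1e-9))
  }
})

test_that("without mature-bone membership no mature bone ever forms", {
  p <- mechano_reg_params()
  nm <- c("f", "c", "ib", "mb")
  cells <- matrix(0, 5, 4, dimnames = list(NULL, nm))
  frac <- matrix(0, 5, 4, dimnames = list(NULL, nm))
  set.seed(3)
  for (step in 1:200) {
    S <- stats::runif(5, 0.3, 2.9)   # cartilage / immature bands only
    TM <- tissue_membership(S, p)
    expect_true(all(TM[, "mb"] == 0))
    dc <- cell_density_rates(cells, 1, TM, p)
    dm <- tissue_fraction_rates(frac, cells, TM, p)
    cells <- clamp(cells + dc * 0.5, 0, 1)
    frac <- clamp(frac + dm * 0.5, 0, 1)
  }
  expect_true(all(cells[, "mb"] == 0))
  expect_true(all(frac[, "mb"] == 0))
})
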