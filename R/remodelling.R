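# Coupled strain/damage-adaptive bone remodelling.
#
# Each bone element remodels its apparent density toward a site-specific
# homeostatic strain-energy-density (SED) window.  The reference stimulus
# psi_ref = sigma_U^2 / (2 E_U rho_U) / (1 + w) is placed so that the
# upper bound psi_U = psi_ref (1 + w) is independent of the lazy-zone
# width w: bone loaded at the homeostatic stress always remodels
# positively to the homeostatic modulus.  Density maps to stiffness by
# the cubic law E = 3790 rho^3 and rates scale with the internal free
# surface area a(rho), which vanishes at rho_min and rho_max.  Fatigue
# damage accumulates by Miner's rule against an S-N life law
# log10 Nf = H log10 sigma + J T + K rho + M, and resorbs bone rapidly
# once the accumulated stimulus exceeds a critical level anchored at a
# 3500 microstrain criterion.

#' Remodelling parameter set
#'
#' @param ... overrides for: sigma_U (6.6 MPa), E_U (17000 MPa), rho_U
#'   (1.649 g/cm^3), w (lazy-zone width, 0.35), tau (130 g^2 mm^-2 J^-1
#'   per month), drho_max (0.175 g/cm^3 per month), rho_min (0.01),
#'   rho_max (1.73), Cd (0.1e8), temperature (37 C), N (loading cycles
#'   per day, 1), month (30 days), crit_strain (3500 microstrain),
#'   ddmg_max (density change per damage increment, 0.00625 g/cm^3),
#'   sn (list H, J, K, M; default fitted to the shipped synthetic S-N
#'   table).
#' @return object of class `remodel_params`.
#' @export
remodel_params <- function(...) {
  p <- list(
    sigma_U = 6.6, E_U = 17000, rho_U = 1.649,
    w = 0.35, tau = 130, drho_max = 0.175,
    rho_min = 0.01, rho_max = 1.73,
    Cd = 0.1e8, temperature = 37, N = 1, month = MONTH_DAYS,
    crit_strain = 3500e-6, ddmg_max = 0.00625,
    sn = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stopf("unknown remodelling parameter '%s'", unknown[1L])
  p[names(dots)] <- dots
  if (p$w <= 0 || p$w >= 1) stopf("'w' (lazy-zone width) must lie in (0, 1)")
  if (!(p$rho_min < p$rho_U && p$rho_U < p$rho_max)) {
    stopf("'rho_U' must lie strictly between rho_min and rho_max")
  }
  if (p$tau <= 0 || p$Cd <= 0) stopf("'tau' and 'Cd' must be positive")
  if (is.null(p$sn)) p$sn <- sn_constants()
  class(p) <- "remodel_params"
  p
}

#' Homeostatic SED reference points
#'
#' psi_ref = sigma_U^2/(2 E_U rho_U)/(1+w); psi_U = psi_ref (1+w) (width
#' independent); psi_L = psi_ref (1-w).
#'
#' @param params a [remodel_params()].
#' @return list(psi_ref, psi_U, psi_L), MPa cm^3/g.
#' @export
reference_energies <- function(params = remodel_params()) {
  if (params$w >= 1) stopf("'w' must be < 1")
  base <- params$sigma_U^2 / (2 * params$E_U * params$rho_U)
  psi_ref <- base / (1 + params$w)
  list(psi_ref = psi_ref, psi_U = psi_ref * (1 + params$w),
       psi_L = psi_ref * (1 - params$w))
}

#' Cubic density-modulus law for cortical bone
#' @param rho apparent density, g/cm^3 (> 0).
#' @return elastic modulus E = 3790 rho^3, MPa.
#' @export
density_modulus_law <- function(rho) {
  if (any(rho <= 0)) stopf("'rho' must be positive")
  3790 * rho^3
}

#' Inverse of the cubic density-modulus law
#' @param E elastic modulus, MPa (> 0).
#' @return apparent density (E/3790)^(1/3), g/cm^3.
#' @export
density_from_modulus <- function(E) {
  if (any(E <= 0)) stopf("'E' must be positive")
  (E / 3790)^(1 / 3)
}

#' Internal free surface area per unit volume
#'
#' Quintic in the porosity-like coordinate p = 1 - x, x the density
#' normalized to [rho_min, rho_max], following the shape of Martin's
#' published surface-area curve with a small linear correction so the
#' curve vanishes exactly at both density bounds (no remodelling at
#' minimum or maximum density).
#'
#' @param rho apparent density, g/cm^3, within [rho_min, rho_max].
#' @param params a [remodel_params()].
#' @return a(rho), mm^2/mm^3 (>= 0).
#' @export
surface_area_density <- function(rho, params = remodel_params()) {
  if (any(rho < params$rho_min - 1e-9) || any(rho > params$rho_max + 1e-9)) {
    stopf("'rho' outside [rho_min, rho_max] = [%g, %g]",
          params$rho_min, params$rho_max)
  }
  x <- clamp((rho - params$rho_min) / (params$rho_max - params$rho_min), 0, 1)
  p <- 1 - x
  m <- 32.3 * p - 93.9 * p^2 + 134 * p^3 - 101 * p^4 + 28.8 * p^5
  m1 <- 32.3 - 93.9 + 134 - 101 + 28.8       # residual at p = 1
  pmax(m - m1 * p, 0)
}

#' SED-driven remodelling rate
#'
#' Formation at a(rho) tau' (psi - psi_U) above the lazy zone, resorption
#' at a(rho) tau' (psi - psi_L) below it, zero inside [psi_L, psi_U];
#' tau' = tau / month converts the monthly time constant to days.
#'
#' @param psi SED stimulus, MPa cm^3/g.
#' @param rho apparent density, g/cm^3.
#' @param params a [remodel_params()].
#' @return drho/dt in g/cm^3 per day.
#' @export
sed_remodelling_rate <- function(psi, rho, params = remodel_params()) {
  refs <- reference_energies(params)
  a <- surface_area_density(rho, params)
  tau_day <- params$tau / params$month
  rate <- numeric(length(psi))
  hi <- psi > refs$psi_U
  lo <- psi < refs$psi_L
  rate[hi] <- (a * tau_day * (psi - refs$psi_U))[hi]
  rate[lo] <- (a * tau_day * (psi - refs$psi_L))[lo]
  rate
}

# ---- fatigue damage ------------------------------------------------------

sn_env <- new.env(parent = emptyenv())

#' S-N (cycles-to-failure) law constants
#'
#' Least-squares fit of log10 Nf = H log10 sigma + J T + K rho + M to the
#' shipped cycles-to-failure table.  The packaged table
#' (`carter_sn_synthetic.csv`) is a synthetic stand-in for the historical
#' cortical-bone fatigue data set: it encodes the field's typical S-N
#' slope for cortical bone, a shorter life at body temperature than at
#' room temperature, and a longer life at higher apparent density.
#'
#' @param path optional path to a CSV with columns sigma_mpa, temp_c,
#'   rho_gcc, cycles_to_failure.
#' @return list with H, J, K, M.
#' @export
sn_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(sn_env$default)) return(sn_env$default)
    path <- system.file("extdata", "carter_sn_synthetic.csv",
                        package = "ossify")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.csv(path)
  need <- c("sigma_mpa", "temp_c", "rho_gcc", "cycles_to_failure")
  if (!all(need %in% names(tab))) {
    stopf("S-N table must have columns %s", paste(need, collapse = ", "))
  }
  fit <- stats::lm(log10(cycles_to_failure) ~ log10(sigma_mpa) + temp_c + rho_gcc,
                   data = tab)
  co <- signif(stats::coef(fit), 12)   # canonical digits: JSON round-trip safe
  out <- list(H = unname(co["log10(sigma_mpa)"]), J = unname(co["temp_c"]),
              K = unname(co["rho_gcc"]), M = unname(co["(Intercept)"]))
  if (cache) sn_env$default <- out
  out
}

#' Cycles to fatigue failure at a stress level
#'
#' `Nf = 10^(H log10 sigma + J T + K rho + M)` with T the body
#' temperature fixed in the parameter set.
#'
#' @param sigma stress amplitude, MPa (> 0, vectorized).
#' @param rho apparent density, g/cm^3.
#' @param params a [remodel_params()].
#' @return number of cycles to failure.
#' @export
cycles_to_failure <- function(sigma, rho, params = remodel_params()) {
  if (any(sigma <= 0)) stopf("'sigma' must be positive")
  sn <- params$sn
  10^(sn$H * log10(sigma) + sn$J * params$temperature + sn$K * rho + sn$M)
}

#' Initialize per-element bone remodelling state
#' @param rho0 initial apparent densities.
#' @return object of class `bone_state` with density, modulus, total
#'   damage omega and damage stimulus delta_omega.
#' @export
bone_state <- function(rho0) {
  st <- list(rho = rho0, E = density_modulus_law(rho0),
             omega = numeric(length(rho0)),
             delta_omega = numeric(length(rho0)))
  class(st) <- "bone_state"
  st
}

#' Miner's-rule damage update
#'
#' Formation rate omega_dot = N/Nf(sigma, rho) per day; repair rate tied
#' to the homeostatic stress, omega_dot_RE = N/Nf(sigma_U, rho), so
#' homeostatic loading accumulates no damage stimulus.  delta_omega
#' integrates (omega_dot - omega_dot_RE) dt floored at zero; omega tracks
#' total accumulated damage, capped at 1.
#'
#' @param state a `bone_state`.
#' @param sigma per-element stress, MPa (>= 0).
#' @param dt increment, days.
#' @param params a [remodel_params()].
#' @return the updated `bone_state`.
#' @export
damage_update <- function(state, sigma, dt, params = remodel_params()) {
  sig <- pmax(sigma, 0)
  wdot <- ifelse(sig > 0, params$N / cycles_to_failure(pmax(sig, 1e-12),
                                                       state$rho, params), 0)
  wdot_re <- params$N / cycles_to_failure(params$sigma_U, state$rho, params)
  state$delta_omega <- pmax(state$delta_omega + (wdot - wdot_re) * dt, 0)
  state$omega <- pmin(state$omega + wdot * dt, 1)
  state
}

#' Critical damage stimulus
#'
#' Anchored at the 3500 microstrain criterion: the damage stimulus that
#' one month of daily loading at sigma = E(rho) * 3500e-6 would
#' accumulate at the local density (floored at zero where that stress
#' does not exceed the homeostatic repair level).
#'
#' @param rho apparent density, g/cm^3.
#' @param params a [remodel_params()].
#' @return omega_crit per element.
#' @export
omega_crit <- function(rho, params = remodel_params()) {
  sig_crit <- density_modulus_law(rho) * params$crit_strain
  wdot <- params$N / cycles_to_failure(sig_crit, rho, params)
  wdot_re <- params$N / cycles_to_failure(params$sigma_U, rho, params)
  pmax((wdot - wdot_re) * params$month, 0)
}

#' Damage-driven resorption rate
#'
#' Zero until the damage stimulus exceeds omega_crit; above it, density
#' is removed at a(rho) Cd N delta_omega per day (a deliberately fast
#' process bounded per increment by the damage time control).
#'
#' @param state a `bone_state`.
#' @param params a [remodel_params()].
#' @return drho/dt, g/cm^3 per day (<= 0).
#' @export
damage_resorption_rate <- function(state, params = remodel_params()) {
  a <- surface_area_density(state$rho, params)
  crit <- omega_crit(state$rho, params)
  active <- state$delta_omega > crit & state$delta_omega > 0
  rate <- numeric(length(state$rho))
  rate[active] <- -(a * params$Cd * params$N * state$delta_omega)[active]
  rate
}

# Geometric approach to the density bounds: a forward-Euler density step is
# limited to half the remaining distance to the bound it moves toward, so a
# trajectory asymptotes to rho_min/rho_max (where a(rho) = 0) instead of
# overshooting onto the bound and freezing there.
bounded_density_step <- function(rho, drho, params) {
  drho <- pmin(drho, 0.5 * (params$rho_max - rho))
  drho <- pmax(drho, -0.5 * (rho - params$rho_min))
  clamp(rho + drho, params$rho_min, params$rho_max)
}

#' Remodelling time-control scale factors
#'
#' The SED factor keeps the monthly-equivalent density change below
#' drho_max; the damage factor keeps the per-increment damage-driven
#' density change below ddmg_max.  Both are <= 1; the driver applies the
#' minimum of all controls.
#'
#' @param drho_sed_monthly attempted SED density change per month
#'   (magnitude).
#' @param drho_damage_incr attempted damage density change in this
#'   increment (magnitude).
#' @param params a [remodel_params()].
#' @return list(sed, damage) scale factors.
#' @export
remodel_time_scales <- function(drho_sed_monthly, drho_damage_incr,
                                params = remodel_params()) {
  f_sed <- if (max(drho_sed_monthly, 0) > params$drho_max) {
    params$drho_max / max(drho_sed_monthly)
  } else 1
  f_dmg <- if (max(drho_damage_incr, 0) > params$ddmg_max) {
    params$ddmg_max / max(drho_damage_incr)
  } else 1
  list(sed = f_sed, damage = f_dmg)
}
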