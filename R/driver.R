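# Simulation driver: staged post-operative loading, the per-increment
# solve/update sequence, the global adaptive time step (minimum of the
# healing, SED and damage controls), bony-union detection and the
# healing -> remodelling phase transition.

#' Post-operative loading schedule
#'
#' Four phases: indirect loading (constant initial load to day 28),
#' walking with crutches (ramp to day 56), imperfect gait (ramp to day
#' 112) and perfect gait (300% body weight) thereafter.  Conditions
#' LC_A..LC_E are force-controlled with initial loads of 10/12.5/15/
#' 17.5/20% of the 700 N body-weight force (70, 87.5, 105, 122.5,
#' 140 N).  LC_F..LC_H are the plated-model schedules, stress-controlled
#' with initial magnitudes reconstructed to interpolate between the
#' LC_E level and the 6.6 MPa peak of LC_H.
#'
#' @param condition "LC_A".."LC_H".
#' @param body_weight_N body-weight force, N (70 kg patient, default 700).
#' @param crutch_fraction fraction of body weight borne at the end of the
#'   crutch-walking phase (day 56), default 0.5.
#' @param gait_stress nominal perfect-gait stress used by the
#'   stress-controlled schedules, MPa.
#' @return object of class `load_schedule` with piecewise-linear knots.
#' @export
load_schedule <- function(condition = c("LC_A", "LC_B", "LC_C", "LC_D",
                                        "LC_E", "LC_F", "LC_G", "LC_H"),
                          body_weight_N = 700, crutch_fraction = 0.5,
                          gait_stress = 6.6) {
  condition <- match.arg(condition)
  init_N <- c(LC_A = 0.100, LC_B = 0.125, LC_C = 0.150, LC_D = 0.175,
              LC_E = 0.200)
  init_MPa <- c(LC_F = 2.6, LC_G = 4.6, LC_H = 6.6)
  if (condition %in% names(init_N)) {
    unit <- "N"
    p0 <- init_N[[condition]] * body_weight_N
    crutch <- max(p0, crutch_fraction * body_weight_N)
    gait <- 3 * body_weight_N
  } else {
    unit <- "MPa"
    p0 <- init_MPa[[condition]]
    crutch <- max(p0, crutch_fraction * gait_stress / 3)
    gait <- gait_stress
  }
  knots <- data.frame(day = c(0, 28, 56, 112, 365),
                      value = c(p0, p0, crutch, gait, gait))
  if (any(knots$value < 0)) stopf("load magnitudes must be non-negative")
  out <- list(condition = condition, unit = unit, knots = knots,
              body_weight_N = body_weight_N)
  class(out) <- "load_schedule"
  out
}

#' @export
print.load_schedule <- function(x, ...) {
  cat(sprintf("<load_schedule> %s (%s): %s\n", x$condition, x$unit,
              paste(sprintf("d%g=%g", x$knots$day, x$knots$value),
                    collapse = ", ")))
  invisible(x)
}

#' Applied load magnitude at a given day
#'
#' Piecewise-linear interpolation of the schedule knots.
#'
#' @param schedule a [load_schedule()].
#' @param t day, within the schedule span.
#' @return load magnitude in the schedule's unit (N or MPa).
#' @export
applied_load <- function(schedule, t) {
  kn <- schedule$knots
  if (any(t < min(kn$day) - 1e-9) || any(t > max(kn$day) + 1e-9)) {
    stopf("'t' = %g outside the schedule span [%g, %g]", t[1],
          min(kn$day), max(kn$day))
  }
  stats::approx(kn$day, kn$value, xout = clamp(t, min(kn$day), max(kn$day)),
                rule = 2)$y
}

# convert a schedule magnitude into the solver's force unit for this mesh;
# stress-valued schedules are nominal stresses on the cortical cross-section
load_to_force <- function(mesh, schedule, value) {
  ro <- mesh$spec$cortex_outer_radius; ri <- mesh$spec$cortex_inner_radius
  wall <- pi * (ro^2 - ri^2)
  if (mesh$mode == "axisymmetric") {
    if (schedule$unit == "N") value else value * wall
  } else {
    # plane strain, unit thickness: stress times loaded wall width
    sigma <- if (schedule$unit == "MPa") value else value / wall
    sigma * 2 * (ro - ri)
  }
}

#' Bony-union check
#'
#' TRUE when the callus focus is bridged by an adjacency-connected chain
#' of elements whose bone volume fraction (immature + mature) reaches the
#' union threshold, linking the two cortical fragment faces.
#'
#' @param mesh a `mesh_model`.
#' @param bone_fraction per-element bone volume fraction (all elements).
#' @param threshold union threshold on the bone fraction (default 0.5).
#' @return logical.
#' @export
union_check <- function(mesh, bone_fraction, threshold = 0.5) {
  spanning_path_exists(mesh, bone_fraction >= threshold)
}

#' Healing-to-remodelling transition check
#'
#' TRUE once union is achieved and the mean per-day modulus change a
#' candidate SED remodelling step would produce on the callus focus
#' exceeds the mean per-day modulus change produced by fracture healing,
#' both averaged over the trailing window.  The transition latches.
#'
#' @param history data.frame with columns t, dE_heal, dE_sed (per-day
#'   magnitudes).
#' @param union has bony union occurred?
#' @param window trailing window, days.
#' @param latched previously latched state.
#' @return logical.
#' @export
transition_check <- function(history, union, window = 10, latched = FALSE) {
  if (latched) return(TRUE)
  if (!union || !nrow(history)) return(FALSE)
  keep <- history$t >= max(history$t) - window
  mean(history$dE_sed[keep]) > mean(history$dE_heal[keep])
}

#' Simulation configuration
#'
#' @param geometry a [geometry_spec()].
#' @param schedule a [load_schedule()].
#' @param healing a [mechano_reg_params()].
#' @param remodel a [remodel_params()].
#' @param D MSC diffusion coefficient, mm^2/day.
#' @param damage include damage-based remodelling (TRUE = "D" runs,
#'   FALSE = "ND").
#' @param duration simulated span, days.
#' @param dt0,dt_min,dt_max,dt_growth adaptive time-step controls, days.
#' @param union_deadline day after which a missing union is declared a
#'   non-union (default 112 + 60).
#' @param load_duration,n_sub daily loading event duration (s) and
#'   implicit sub-steps.
#' @param max_increments hard cap on accepted increments.
#' @param seed reserved; default algorithms are deterministic.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = geometry_spec("unplated"),
                              schedule = load_schedule("LC_A"),
                              healing = mechano_reg_params(),
                              remodel = remodel_params(),
                              D = 0.1, damage = TRUE, duration = 365,
                              dt0 = 0.5, dt_min = 0.25, dt_max = 1,
                              dt_growth = 1.2, union_deadline = 172,
                              load_duration = 1, n_sub = 4L,
                              max_increments = 4000L, seed = NULL) {
  check_number(duration, "duration", 0, Inf, strict_lo = TRUE)
  check_number(D, "D", 0, Inf, strict_lo = TRUE)
  if (!(dt_min <= dt0 && dt0 <= dt_max)) {
    stopf("need dt_min <= dt0 <= dt_max (got %g, %g, %g)", dt_min, dt0, dt_max)
  }
  cfg <- list(geometry = geometry, schedule = schedule, healing = healing,
              remodel = remodel, D = D, damage = isTRUE(damage),
              duration = duration, dt0 = dt0, dt_min = dt_min,
              dt_max = dt_max, dt_growth = dt_growth,
              union_deadline = union_deadline,
              load_duration = load_duration, n_sub = as.integer(n_sub),
              max_increments = as.integer(max_increments), seed = seed)
  class(cfg) <- "simulation_config"
  cfg
}

#' Initialize a simulation state for manual stepping
#'
#' Builds the mesh, FE cache, diffusion and tissue/bone states of a run so
#' it can be advanced increment by increment with [advance_increment()].
#'
#' @param config a [simulation_config()].
#' @return a state environment.
#' @export
init_simulation <- function(config) init_sim(config)

# ---- internal simulation state -------------------------------------------

init_sim <- function(config) {
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  st$mesh <- build_fracture_model(config$geometry)
  st$cache <- fem_cache(st$mesh)
  st$tab <- default_material_table()
  st$idx_cal <- which(st$mesh$region %in% CALLUS_REGIONS)
  st$idx_focus <- which(st$mesh$region == "callus_focus")
  st$idx_cortex <- which(st$mesh$region == "cortex")
  st$tissue <- tissue_state(length(st$idx_cal), config$healing)
  st$diff <- diffusion_state(st$mesh, D = config$D)
  st$bone_idx <- st$idx_cortex
  st$bone <- bone_state(rep(config$remodel$rho_U, length(st$idx_cortex)))
  st$t <- 0; st$dt <- config$dt0; st$phase <- "healing"
  st$union <- FALSE; st$union_day <- NA_real_; st$trans_day <- NA_real_
  st$status <- "running"
  st$metrics <- data.frame(t = numeric(0), dE_heal = numeric(0),
                           dE_sed = numeric(0))
  st$series <- list(); st$dt_log <- numeric(0); st$n <- 0L
  st
}

current_materials <- function(st) {
  mesh <- st$mesh; tab <- st$tab
  base <- assign_region_materials(mesh, tab, E_gran = st$cfg$healing$E_gran)
  E <- base$E; nu <- base$nu; perm <- base$permeability
  por <- base$porosity; Kf <- base$Kf; rho <- base$rho
  rp <- st$cfg$remodel
  if (st$phase == "healing") {
    i <- st$idx_cal
    E[i] <- pmax(st$tissue$E_smoothed, 1e-3)
    mp <- callus_mixture_properties(st$tissue$frac, tab)
    perm[i] <- mp$permeability; nu[i] <- mp$nu
    por[i] <- mp$porosity; Kf[i] <- mp$Kf
    rho[i] <- clamp(density_from_modulus(E[i]), 0.05, rp$rho_max)
  }
  # remodelling elements follow the cubic law; poro side-properties
  # interpolate from immature-bone to cortical values with density
  i <- st$bone_idx
  E[i] <- pmax(st$bone$E, 1e-3)
  x <- clamp((st$bone$rho - rp$rho_min) / (rp$rho_max - rp$rho_min), 0, 1)
  perm[i] <- 10^(-1 - 4 * x)           # mm^4/(N s): 1e-1 -> 1e-5
  nu[i] <- 0.3 + 0.07 * x
  por[i] <- 0.8 - 0.76 * x
  rho[i] <- st$bone$rho
  poro_materials(E, nu, perm, por, base$Ks, Kf, rho)
}

bone_fraction_all <- function(st) {
  bf <- numeric(nrow(st$mesh$elems))
  if (st$phase == "healing") {
    bf[st$idx_cal] <- st$tissue$frac[, "ib"] + st$tissue$frac[, "mb"]
  } else {
    bf[st$idx_cal] <- 1          # post-transition callus is bone
  }
  bf
}

#' Advance the coupled simulation by one accepted increment
#'
#' Sequence: solve the daily loading event; form healing and remodelling
#' trial updates; compute all time-scale factors and accept the increment
#' at dt * min(factors) (bounded below by dt_min with per-process caps);
#' apply the tissue, density, damage and diffusion updates; evaluate
#' union and transition; advance time and grow the next dt geometrically
#' up to dt_max.
#'
#' @param st simulation state environment from the internal initializer.
#' @return the state, invisibly (modified in place).
#' @export
advance_increment <- function(st) {
  cfg <- st$cfg; mesh <- st$mesh; hp <- cfg$healing; rp <- cfg$remodel
  dt <- min(st$dt, cfg$duration - st$t)
  dt <- max(dt, 1e-6)
  mat <- current_materials(st)
  raw <- applied_load(cfg$schedule, min(st$t, max(cfg$schedule$knots$day)))
  Fz <- load_to_force(mesh, cfg$schedule, raw)
  snap <- solve_daily_loading(mesh, mat, Fz, duration = cfg$load_duration,
                              n_sub = cfg$n_sub, cache = st$cache)

  healing <- st$phase == "healing"
  f_frac <- 1
  if (healing) {
    S <- biophysical_stimulus(snap$eps_dev[st$idx_cal],
                              snap$wf_mag[st$idx_cal], hp)
    TM <- tissue_membership(S, hp)
    cm_el <- element_concentration(mesh, st$diff)[st$idx_cal]
    dc <- cell_density_rates(st$tissue$cells, cm_el, TM, hp)
    dm <- tissue_fraction_rates(st$tissue$frac, st$tissue$cells, TM, hp)
    max_dm <- max(abs(dm)) * dt
    f_frac <- healing_time_scale(max_dm, hp)
  }

  # remodelling trial on the active bone set
  psi_b <- snap$psi[st$bone_idx]
  sig_b <- snap$sigma_vm[st$bone_idx]
  rate_sed <- sed_remodelling_rate(psi_b, st$bone$rho, rp)
  bone_trial <- st$bone
  if (cfg$damage) {
    bone_trial <- damage_update(bone_trial, sig_b, dt, rp)
    rate_dmg <- damage_resorption_rate(bone_trial, rp)
  } else rate_dmg <- numeric(length(psi_b))
  fs <- remodel_time_scales(max(abs(rate_sed)) * rp$month,
                            max(abs(rate_dmg)) * dt, rp)

  f <- min(1, f_frac, fs$sed, fs$damage)
  dt_eff <- max(dt * f, min(cfg$dt_min, dt))

  # apply healing updates (per-process caps guard the dt floor)
  if (healing) {
    dmm <- dm * dt_eff
    mx <- max(abs(dmm))
    if (mx > hp$dm_max) dmm <- dmm * (hp$dm_max / mx)
    cells <- clamp(st$tissue$cells + dc * dt_eff, 0, 1)
    frac <- clamp(st$tissue$frac + dmm, 0, 1)
    s <- rowSums(frac)
    over <- s > 1
    if (any(over)) frac[over, ] <- frac[over, ] / s[over]
    st$tissue$cells <- cells
    st$tissue$frac <- frac
    E_prev <- st$tissue$E_smoothed
    st$tissue$E_raw <- mixture_modulus(frac, cells, hp)
    st$tissue$hist_t <- c(st$tissue$hist_t, st$t + dt_eff)
    st$tissue$hist_dt <- c(st$tissue$hist_dt, dt_eff)
    st$tissue$hist_E <- rbind(st$tissue$hist_E, st$tissue$E_raw)
    keep <- st$tissue$hist_t > st$t + dt_eff - hp$window - 1e-9
    st$tissue$hist_t <- st$tissue$hist_t[keep]
    st$tissue$hist_dt <- st$tissue$hist_dt[keep]
    st$tissue$hist_E <- st$tissue$hist_E[keep, , drop = FALSE]
    st$tissue$E_smoothed <- smoothed_modulus(st$tissue$hist_t,
                                             st$tissue$hist_dt,
                                             st$tissue$hist_E,
                                             st$t + dt_eff, hp$window)
  }

  # apply remodelling updates
  drho <- clamp(rate_sed * dt_eff, -rp$drho_max * dt_eff / rp$month,
                rp$drho_max * dt_eff / rp$month)
  if (cfg$damage) {
    st$bone <- damage_update(st$bone, sig_b, dt_eff, rp)
    ddmg <- pmax(damage_resorption_rate(st$bone, rp) * dt_eff, -rp$ddmg_max)
  } else ddmg <- 0
  st$bone$rho <- bounded_density_step(st$bone$rho, drho + ddmg, rp)
  st$bone$E <- density_modulus_law(st$bone$rho)

  # transition metrics on the callus focus
  if (healing) {
    foc <- match(st$idx_focus, st$idx_cal)
    dE_heal <- mean(abs(st$tissue$E_smoothed[foc] - E_prev[foc])) / dt_eff
    rho_h <- clamp(density_from_modulus(pmax(st$tissue$E_smoothed[foc], 1e-3)),
                   rp$rho_min, rp$rho_max)
    rate_h <- sed_remodelling_rate(snap$psi[st$idx_focus], rho_h, rp)
    rate_h <- clamp(rate_h, -rp$drho_max / rp$month, rp$drho_max / rp$month)
    dE_sed <- mean(abs(3 * 3790 * rho_h^2 * rate_h))
    st$metrics <- rbind(st$metrics,
                        data.frame(t = st$t + dt_eff, dE_heal = dE_heal,
                                   dE_sed = dE_sed))
    st$metrics <- st$metrics[st$metrics$t >= st$t + dt_eff - hp$window - 1e-9, ]

    # MSC infiltration
    st$diff <- update_boundary_concentration(st$diff, dt_eff)
    st$diff <- diffuse_step(mesh, st$diff, dt_eff)

    if (!st$union) {
      bf <- bone_fraction_all(st)
      if (any(bf[st$idx_focus] >= hp$bone_fraction_union) &&
          union_check(mesh, bf, hp$bone_fraction_union)) {
        st$union <- TRUE
        st$union_day <- st$t + dt_eff
      }
    }
    if (st$union && transition_check(st$metrics, st$union, hp$window)) {
      st$phase <- "remodelling"
      st$trans_day <- st$t + dt_eff
      rho0 <- clamp(density_from_modulus(pmax(st$tissue$E_smoothed, 1e-3)),
                    rp$rho_min, rp$rho_max)
      st$bone_idx <- c(st$idx_cortex, st$idx_cal)
      st$bone <- bone_state(c(st$bone$rho, rho0))
    }
  }

  st$t <- st$t + dt_eff
  st$dt <- min(cfg$dt_max, dt_eff * cfg$dt_growth)
  st$dt_log <- c(st$dt_log, dt_eff)
  st$n <- st$n + 1L
  st$last_snap <- snap

  foc_E <- if (st$phase == "healing") {
    mean(st$tissue$E_smoothed[match(st$idx_focus, st$idx_cal)])
  } else mean(st$bone$E[match(st$idx_focus, st$bone_idx)])
  cal_E <- if (st$phase == "healing") mean(st$tissue$E_smoothed) else {
    mean(st$bone$E[match(st$idx_cal, st$bone_idx)])
  }
  ctx_rho <- mean(st$bone$rho[match(st$idx_cortex, st$bone_idx)])
  st$series[[st$n]] <- data.frame(
    t = st$t, dt = dt_eff, load = raw, mean_focus_E = foc_E,
    mean_callus_E = cal_E, mean_cortex_rho = ctx_rho,
    phase = st$phase, union = st$union)
  invisible(st)
}

#' Run a coupled fracture-repair simulation
#'
#' Integrates the healing phase (MSC diffusion + mechano-regulated tissue
#' differentiation) until bony union hands the callus to the remodelling
#' phase, then SED/damage remodelling to the end of the simulated year.
#' A run with no union by the deadline terminates as a non-union.
#'
#' @param config a [simulation_config()].
#' @param verbose print progress every 50 increments.
#' @return object of class `simulation_result`.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  if (!inherits(config, "simulation_config")) {
    stopf("'config' must be a simulation_config")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- init_sim(config)
  while (st$t < config$duration - 1e-9) {
    if (st$n >= config$max_increments) {
      warning("increment cap reached before the end of the simulated span")
      break
    }
    advance_increment(st)
    if (st$phase == "healing" && !st$union && st$t >= config$union_deadline) {
      st$status <- "non_union"
      break
    }
    if (verbose && st$n %% 50L == 0L) {
      message(sprintf("day %7.2f  dt %5.3f  phase %s  focus E %8.1f",
                      st$t, st$dt, st$phase,
                      st$series[[st$n]]$mean_focus_E))
    }
  }
  if (st$status == "running") {
    st$status <- if (st$union) "healed" else "non_union"
  }
  res <- list(
    series = do.call(rbind, st$series),
    union_day = st$union_day, transition_day = st$trans_day,
    status = st$status, increments = st$n, dt_log = st$dt_log,
    mesh = st$mesh, config = config,
    final = list(phase = st$phase, tissue = st$tissue, bone = st$bone,
                 bone_idx = st$bone_idx, diffusion = st$diff,
                 snapshot = st$last_snap)
  )
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s / %s: status %s\n",
              x$config$geometry$variant, x$config$schedule$condition,
              x$status))
  cat(sprintf("  union day %s, transition day %s, %d increments, final t %.1f d\n",
              format(x$union_day), format(x$transition_day), x$increments,
              max(x$series$t)))
  cat(sprintf("  final mean focus E %.1f MPa, mean cortex rho %.3f g/cm^3\n",
              utils::tail(x$series$mean_focus_E, 1),
              utils::tail(x$series$mean_cortex_rho, 1)))
  invisible(x)
}
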