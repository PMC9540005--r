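# Configuration round-tripping, result serialization and programmatic
# fixtures.  Configs are a nested key tree stored as JSON; every value is
# resolved against the package defaults so a written config re-loads
# bit-exactly.

config_to_list <- function(config) {
  g <- unclass(config$geometry)
  s <- unclass(config$schedule)
  s$knots <- as.list(s$knots)
  h <- unclass(config$healing)
  h$thresholds <- as.list(h$thresholds)
  r <- unclass(config$remodel)
  list(geometry = g, schedule = s, healing = h, remodel = r,
       D = config$D, damage = config$damage, duration = config$duration,
       dt0 = config$dt0, dt_min = config$dt_min, dt_max = config$dt_max,
       dt_growth = config$dt_growth, union_deadline = config$union_deadline,
       load_duration = config$load_duration, n_sub = config$n_sub,
       max_increments = config$max_increments, seed = config$seed)
}

config_from_list <- function(x) {
  top_known <- c("geometry", "schedule", "healing", "remodel", "D", "damage",
                 "duration", "dt0", "dt_min", "dt_max", "dt_growth",
                 "union_deadline", "load_duration", "n_sub",
                 "max_increments", "seed")
  unknown <- setdiff(names(x), top_known)
  if (length(unknown)) stopf("unknown configuration key '%s'", unknown[1L])

  geometry <- do.call(geometry_spec, x$geometry %||% list())

  s <- x$schedule %||% list()
  schedule <- load_schedule(s$condition %||% "LC_A",
                            body_weight_N = s$body_weight_N %||% 700)
  if (!is.null(s$knots)) {
    schedule$knots <- data.frame(day = unlist(s$knots$day),
                                 value = unlist(s$knots$value))
  }
  if (!is.null(s$unit)) schedule$unit <- s$unit

  h <- x$healing %||% list()
  if (!is.null(h$thresholds)) h$thresholds <- unlist(h$thresholds)
  if (!is.null(h$tissue_moduli)) {
    h$tissue_moduli <- lapply(h$tissue_moduli, unlist)
  }
  healing <- do.call(mechano_reg_params, h)

  r <- x$remodel %||% list()
  if (!is.null(r$sn)) r$sn <- as.list(unlist(r$sn))
  remodel <- do.call(remodel_params, r)

  simulation_config(
    geometry = geometry, schedule = schedule, healing = healing,
    remodel = remodel, D = x$D %||% 0.1, damage = x$damage %||% TRUE,
    duration = x$duration %||% 365, dt0 = x$dt0 %||% 0.5,
    dt_min = x$dt_min %||% 0.25, dt_max = x$dt_max %||% 1,
    dt_growth = x$dt_growth %||% 1.2,
    union_deadline = x$union_deadline %||% 172,
    load_duration = x$load_duration %||% 1, n_sub = x$n_sub %||% 4L,
    max_increments = x$max_increments %||% 4000L, seed = x$seed)
}

#' Load a simulation configuration from a JSON file
#'
#' Unset keys resolve to the packaged defaults; unknown keys and invariant
#' violations raise errors naming the offending key.
#'
#' @param path JSON configuration file.
#' @return a [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  config_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a fully resolved configuration to JSON
#'
#' @param config a [simulation_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write simulation outputs
#'
#' Emits `series.csv` (per-increment time series), `config.json` (resolved
#' configuration), `final_state.vtk` (mesh snapshot with per-element state
#' as cell data) and `manifest.txt`, and returns the manifest.
#'
#' @param result a `simulation_result`.
#' @param dir output directory (created if missing).
#' @return the manifest as a named list, invisibly.
#' @export
write_outputs <- function(result, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  }
  utils::write.csv(result$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  write_config(result$config, file.path(dir, "config.json"))
  cd <- snapshot_cell_data(result)
  write_vtk(result$mesh, file.path(dir, "final_state.vtk"), cell_data = cd,
            point_data = list(c_m = result$final$diffusion$c_m))
  manifest <- list(
    package = "ossify",
    version = as.character(utils::packageVersion("ossify")),
    config_md5 = unname(tools::md5sum(file.path(dir, "config.json"))),
    status = result$status,
    increments = result$increments,
    union_day = result$union_day,
    transition_day = result$transition_day,
    dt_log = paste(signif(result$dt_log, 6), collapse = " ")
  )
  writeLines(paste0(names(manifest), ": ",
                    vapply(manifest, as.character, character(1))),
             file.path(dir, "manifest.txt"))
  invisible(manifest)
}

# assemble per-element cell data for export
snapshot_cell_data <- function(result) {
  mesh <- result$mesh
  m <- nrow(mesh$elems)
  f <- result$final
  idx_cal <- which(mesh$region %in% CALLUS_REGIONS)
  E <- numeric(m); rho <- rep(NA_real_, m); omega <- rep(0, m)
  m_b <- numeric(m)
  if (f$phase == "healing" || is.null(f$bone_idx)) {
    E[idx_cal] <- f$tissue$E_smoothed
  }
  E[f$bone_idx] <- f$bone$E
  rho[f$bone_idx] <- f$bone$rho
  omega[f$bone_idx] <- f$bone$omega
  if (length(idx_cal) == nrow(f$tissue$frac)) {
    m_b[idx_cal] <- f$tissue$frac[, "ib"] + f$tissue$frac[, "mb"]
  }
  list(region = as.integer(factor(mesh$region, levels = REGION_LEVELS)),
       E = E, rho = ifelse(is.na(rho), 0, rho), omega = omega,
       bone_fraction = m_b,
       eps_dev = f$snapshot$eps_dev %||% numeric(m),
       psi = f$snapshot$psi %||% numeric(m))
}

#' Programmatic test fixtures
#'
#' * `calibration_osteotomy`: axisymmetric ovine-metatarsus osteotomy
#'   (3 mm gap, external-fixator spring) with a constant 500 N load.
#' * `single_element`: a single-element site-specific remodelling rig
#'   (see [remodel_single_element()]).
#' * `consolidation_column`: laterally confined 1D poroelastic column for
#'   consolidation benchmarks (drained at the loaded top).
#' * `toy_callus`: coarse unplated model for fast end-to-end runs.
#'
#' @param name fixture name.
#' @param ... overrides passed to the underlying constructors.
#' @return fixture object (see details).
#' @export
make_fixture <- function(name = c("calibration_osteotomy", "single_element",
                                  "consolidation_column", "toy_callus"),
                         ...) {
  name <- match.arg(name)
  switch(name,
    calibration_osteotomy = {
      spec <- geometry_spec("calibration", ...)
      sched <- load_schedule("LC_A")
      sched$knots <- data.frame(day = c(0, 365), value = c(500, 500))
      sched$condition <- "calibration_500N"
      cfg <- simulation_config(geometry = spec, schedule = sched)
      list(mesh = build_fracture_model(spec), config = cfg)
    },
    single_element = {
      args <- list(...)
      list(rho0 = args$rho0 %||% 1.0, driver = remodel_single_element)
    },
    consolidation_column = {
      args <- list(...)
      H <- args$height %||% 10
      nz <- args$nz %||% 40L
      mesh <- structured_mesh(c(0, 1), seq(0, H, length.out = nz + 1L),
                              function(x, z) rep("cortex", length(x)),
                              mode = "plane")
      mesh$constrain_x <- TRUE
      tol <- 1e-8
      top <- which(abs(mesh$nodes[, 2] - H) < tol)
      bot <- which(abs(mesh$nodes[, 2]) < tol)
      mesh$boundary <- list(loaded = top, fixed = bot, axis = integer(0),
                            drainage = top, msc_source = top)
      mesh$focus_seeds <- list(upper = integer(0), lower = integer(0))
      mesh$spec <- list(fixator_stiffness = 0)
      mesh
    },
    toy_callus = {
      spec <- geometry_spec("unplated", mesh_target_size = 2.5, ...)
      simulation_config(geometry = spec)
    })
}

#' Site-specific remodelling of a single bone element
#'
#' Drives one element with a daily uniaxial stress: psi =
#' sigma^2 / (2 E(rho) rho), density update by [sed_remodelling_rate()]
#' with the monthly density cap, plus optional Miner's-rule damage.
#'
#' @param rho0 initial apparent density, g/cm^3.
#' @param sigma daily uniaxial stress, MPa.
#' @param days simulated span.
#' @param dt time step, days.
#' @param params a [remodel_params()].
#' @param damage include damage-based resorption.
#' @return list(rho, E, series) with the density trajectory.
#' @export
remodel_single_element <- function(rho0, sigma, days = 365, dt = 1,
                                   params = remodel_params(),
                                   damage = FALSE) {
  st <- bone_state(rho0)
  ts <- seq(dt, days, by = dt)
  out <- numeric(length(ts))
  cap <- params$drho_max * dt / params$month
  for (i in seq_along(ts)) {
    psi <- sigma^2 / (2 * st$E * st$rho)
    drho <- clamp(sed_remodelling_rate(psi, st$rho, params) * dt, -cap, cap)
    dd <- 0
    if (damage && sigma > 0) {
      st <- damage_update(st, sigma, dt, params)
      dd <- max(damage_resorption_rate(st, params) * dt, -params$ddmg_max)
    }
    st$rho <- bounded_density_step(st$rho, drho + dd, params)
    st$E <- density_modulus_law(st$rho)
    out[i] <- st$rho
  }
  list(rho = st$rho, E = st$E, series = data.frame(t = ts, rho = out))
}
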