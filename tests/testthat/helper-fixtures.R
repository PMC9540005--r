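# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

toy_mesh <- function() {
  cached("toy_mesh", function() {
    build_fracture_model(geometry_spec("unplated", mesh_target_size = 3.5))
  })
}

toy_cache <- function() cached("toy_cache", function() fem_cache(toy_mesh()))

toy_materials <- function() {
  cached("toy_materials", function() assign_region_materials(toy_mesh()))
}

# finer unplated mesh: 3 axial element rows across the gap
fine_mesh <- function() {
  cached("fine_mesh", function() {
    build_fracture_model(geometry_spec("unplated", mesh_target_size = 1.25))
  })
}

# fast coarse run configuration used by driver/acceptance tests
toy_config <- function(condition = "LC_A", variant = "unplated", gap = 3,
                       damage = TRUE, duration = 365, target = 3.5) {
  simulation_config(
    geometry = geometry_spec(variant, fracture_gap = gap,
                             mesh_target_size = target),
    schedule = load_schedule(condition), damage = damage,
    duration = duration, dt_min = 0.5)
}

run_cached <- function(key, ...) {
  cached(key, function() run_simulation(toy_config(...)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
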