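# MSC infiltration into the fracture callus.
#
# The migration of mesenchymal stem cells (and, implicitly, blood-vessel
# ingrowth) is a mass-diffusion problem dc/dt = D lap(c) solved on the
# callus subdomain of the mechanics mesh.  The source boundary (soft
# tissue, marrow and periosteal interfaces of the callus) carries a
# Dirichlet concentration that ramps from 0 to saturation with the
# first-order law c_b' = D (c_max - c_b), removing the start-up artifact
# of a hard c = 1 boundary at t = 0.  Concentrations are relative, in
# [0, 1]; D is in mm^2/day.

#' Create the MSC diffusion state for a mesh
#'
#' @param mesh a `mesh_model`.
#' @param D diffusion coefficient, mm^2/day.
#' @param c_max saturation concentration (relative units).
#' @return object of class `diffusion_state`: nodal concentrations (zero
#'   everywhere at t = 0), current boundary concentration and the
#'   assembled lumped-mass / stiffness operators on the callus subdomain.
#' @export
diffusion_state <- function(mesh, D = 0.1, c_max = 1.0) {
  check_number(D, "D", 0, Inf, strict_lo = TRUE)
  cal <- which(mesh$region %in% CALLUS_REGIONS)
  if (!length(cal)) stopf("mesh has no callus elements to diffuse on")
  if (!length(mesh$boundary$msc_source)) stopf("mesh has no MSC source boundary set")
  axisym <- mesh$mode == "axisymmetric"
  n <- nrow(mesh$nodes)
  iH <- integer(0); jH <- integer(0); vH <- numeric(0); mlump <- numeric(n)
  for (e in cal) {
    nd <- mesh$elems[e, ]
    X <- mesh$nodes[nd, , drop = FALSE]
    He <- matrix(0, 4, 4)
    for (g in seq_len(4L)) {
      ep <- elem_point(X, GAUSS_PTS[g, 1], GAUSS_PTS[g, 2], axisym)
      He <- He + ep$w * crossprod(ep$Bp)
      mlump[nd] <- mlump[nd] + ep$w * ep$N
    }
    iH <- c(iH, rep(nd, times = 4L))
    jH <- c(jH, rep(nd, each = 4L))
    vH <- c(vH, as.vector(D * He))
  }
  active <- sort(unique(as.vector(mesh$elems[cal, ])))
  state <- list(
    c_m = numeric(n), c_b = 0, D = D, c_max = c_max, t = 0,
    active = active,
    dirichlet = intersect(mesh$boundary$msc_source, active),
    H = Matrix::sparseMatrix(i = iH, j = jH, x = vH, dims = c(n, n)),
    M = mlump, callus_elements = cal
  )
  class(state) <- "diffusion_state"
  state
}

#' @export
print.diffusion_state <- function(x, ...) {
  cat(sprintf("<diffusion_state> t = %.3g d, c_b = %.4g, %d active nodes\n",
              x$t, x$c_b, length(x$active)))
  invisible(x)
}

#' Advance the boundary-concentration ramp
#'
#' Discrete first-order filling `c_b <- c_b + D (c_max - c_b) dt`; the
#' boundary concentration approaches saturation monotonically without
#' overshoot (dt is additionally safe-guarded against D dt > 1).
#'
#' @param state a `diffusion_state`.
#' @param dt time step, days (> 0).
#' @return the updated state.
#' @export
update_boundary_concentration <- function(state, dt) {
  if (!is_number(dt) || dt <= 0) stopf("'dt' must be a positive number of days")
  step <- min(state$D * dt, 1)
  state$c_b <- state$c_b + step * (state$c_max - state$c_b)
  state
}

#' One implicit diffusion step on the callus
#'
#' Backward-Euler step of the lumped-mass FE diffusion system with the
#' current boundary concentration imposed on the MSC source surface.
#' Nodal values are clamped to [0, c_b], which enforces the discrete
#' maximum principle exactly.
#'
#' @param mesh the `mesh_model` the state was built on.
#' @param state a `diffusion_state`.
#' @param dt time step, days (> 0).
#' @return the updated state.
#' @export
diffuse_step <- function(mesh, state, dt) {
  if (!is_number(dt) || dt <= 0) stopf("'dt' must be a positive number of days")
  act <- state$active
  dir <- state$dirichlet
  free <- setdiff(act, dir)
  c_new <- state$c_m
  c_new[dir] <- state$c_b
  A <- Matrix::Diagonal(x = state$M) + dt * state$H
  rhs <- state$M[free] * state$c_m[free] -
    as.numeric(A[free, dir, drop = FALSE] %*% c_new[dir])
  c_new[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs))
  c_new[act] <- clamp(c_new[act], 0, state$c_b)
  state$c_m <- c_new
  state$t <- state$t + dt
  state
}

#' Element-level MSC concentration
#'
#' Integration-point (centroid) concentration of every callus element by
#' interpolation of nodal values; elements outside the callus get 0.
#'
#' @param mesh a `mesh_model`.
#' @param state a `diffusion_state`.
#' @return numeric vector over all elements.
#' @export
element_concentration <- function(mesh, state) {
  out <- numeric(nrow(mesh$elems))
  cal <- state$callus_elements
  out[cal] <- rowMeans(matrix(state$c_m[mesh$elems[cal, ]], ncol = 4L))
  out
}
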