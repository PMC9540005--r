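# Linear biphasic (poroelastic, u-p) finite-element core.
#
# Bilinear quads with displacement and pore-pressure degrees of freedom at
# every node, 2x2 Gauss quadrature, in either axisymmetric (r, z) or plane
# strain (x, z) mode.  One "daily loading event" is a short transient
# consolidation solve (ramp-and-hold over `duration` seconds) whose
# peak-in-time deviatoric strain and relative fluid velocity feed the
# mechano-regulation stimulus, plus a drained elastic solve whose stress
# and strain energy density feed the remodelling stimulus.
#
# Unit system: mm, N, MPa, s (within a loading event); permeability in
# mm^4/(N s); fluid velocity reported in um/s.
#
# The loaded end is tied to a single master axial degree of freedom
# (rigid end platen), so loads are applied as total force in N
# (axisymmetric) or N per mm thickness (plane strain).  An optional
# external-fixator spring grounds the master DOF.

GP <- 1 / sqrt(3)
GAUSS_PTS <- rbind(c(-GP, -GP), c(GP, -GP), c(GP, GP), c(-GP, GP))

shape_q4 <- function(xi, eta) {
  N <- 0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
                (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
  dN <- 0.25 * rbind(
    c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
    c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
  list(N = N, dN = dN)
}

# element integration data at one point
elem_point <- function(X, xi, eta, axisym) {
  s <- shape_q4(xi, eta)
  J <- s$dN %*% X                       # 2x2
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (detJ <= 0) stopf("degenerate mesh: inverted element (detJ <= 0)")
  dNdx <- solve(J, s$dN)                # 2x4, rows d/dx, d/dz
  r <- sum(s$N * X[, 1])
  w <- detJ * if (axisym) 2 * pi * r else 1
  k <- if (axisym) 4L else 3L
  Bu <- matrix(0, k, 8)
  ix <- seq(1, 8, by = 2)               # ux dofs
  iz <- seq(2, 8, by = 2)               # uz dofs
  if (axisym) {
    Bu[1, ix] <- dNdx[1, ]              # e_rr
    Bu[2, iz] <- dNdx[2, ]              # e_zz
    Bu[3, ix] <- s$N / r                # e_theta
    Bu[4, ix] <- dNdx[2, ]              # g_rz
    Bu[4, iz] <- dNdx[1, ]
    bvol <- Bu[1, ] + Bu[2, ] + Bu[3, ]
  } else {
    Bu[1, ix] <- dNdx[1, ]              # e_xx
    Bu[2, iz] <- dNdx[2, ]              # e_zz
    Bu[3, ix] <- dNdx[2, ]              # g_xz
    Bu[3, iz] <- dNdx[1, ]
    bvol <- Bu[1, ] + Bu[2, ]
  }
  list(N = s$N, Bu = Bu, Bp = dNdx, bvol = bvol, w = w)
}

d_lambda_mu <- function(axisym) {
  if (axisym) {
    Dl <- matrix(0, 4, 4); Dl[1:3, 1:3] <- 1
    Dm <- diag(c(2, 2, 2, 1))
  } else {
    Dl <- matrix(0, 3, 3); Dl[1:2, 1:2] <- 1
    Dm <- diag(c(2, 2, 1))
  }
  list(Dl = Dl, Dm = Dm)
}

#' Precompute element integration data and DOF maps for a mesh
#'
#' Geometry-dependent quantities (shape-function gradients, quadrature
#' weights, material-independent element matrices, DOF numbering with the
#' loaded-end rigid tie) are computed once and reused across increments.
#'
#' @param mesh a `mesh_model`.
#' @return an environment used by [solve_daily_loading()].
#' @export
fem_cache <- function(mesh) {
  axisym <- mesh$mode == "axisymmetric"
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  D2 <- d_lambda_mu(axisym)

  # dof numbering with loaded-end uz tied to one master dof
  ux_raw <- 2L * seq_len(n) - 1L
  uz_raw <- 2L * seq_len(n)
  loaded <- mesh$boundary$loaded
  if (length(loaded)) uz_raw[loaded] <- 2L * loaded[1L]
  used <- sort(unique(c(ux_raw, uz_raw)))
  remap <- integer(2L * n); remap[used] <- seq_along(used)
  udof <- cbind(remap[ux_raw], remap[uz_raw])
  nu <- length(used)
  master <- if (length(loaded)) udof[loaded[1L], 2L] else NA_integer_

  el <- vector("list", m)
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    c0 <- elem_point(X, 0, 0, axisym)
    Km <- matrix(0, 8, 8)
    Qe <- matrix(0, 8, 4); He <- matrix(0, 4, 4); Se <- matrix(0, 4, 4)
    W <- 0
    for (g in seq_len(4L)) {
      ep <- elem_point(X, GAUSS_PTS[g, 1], GAUSS_PTS[g, 2], axisym)
      W <- W + ep$w
      Km <- Km + ep$w * crossprod(ep$Bu, D2$Dm %*% ep$Bu)
      # volumetric coupling uses the centroid (mean-dilatation) operator to
      # avoid volumetric locking in the nearly incompressible undrained limit
      Qe <- Qe + ep$w * tcrossprod(c0$bvol, ep$N)
      He <- He + ep$w * crossprod(ep$Bp)
      Se <- Se + ep$w * tcrossprod(ep$N)
    }
    # selective reduced integration of the lambda (volumetric) stiffness
    Kl <- W * tcrossprod(c0$bvol)
    el[[e]] <- list(Kl = Kl, Km = Km, Q = Qe, H = He, S = Se,
                    Bu0 = c0$Bu, Bp0 = c0$Bp,
                    ud = as.vector(t(udof[mesh$elems[e, ], ])),
                    pd = mesh$elems[e, ])
  }

  # global triplet index vectors (values filled per assembly)
  iK <- unlist(lapply(el, function(x) rep(x$ud, times = 8L)))
  jK <- unlist(lapply(el, function(x) rep(x$ud, each = 8L)))
  iQ <- unlist(lapply(el, function(x) rep(x$ud, times = 4L)))
  jQ <- unlist(lapply(el, function(x) rep(x$pd, each = 8L)))
  iH <- unlist(lapply(el, function(x) rep(x$pd, times = 4L)))
  jH <- unlist(lapply(el, function(x) rep(x$pd, each = 4L)))

  cache <- new.env(parent = emptyenv())
  cache$axisym <- axisym
  cache$n <- n; cache$m <- m; cache$nu <- nu
  cache$udof <- udof; cache$master <- master
  cache$el <- el
  cache$idx <- list(iK = iK, jK = jK, iQ = iQ, jQ = jQ, iH = iH, jH = jH)
  # Dirichlet displacement dofs: fixed end fully, axis radial, optional
  # laterally-confined column mode
  fixed_u <- unique(c(as.vector(udof[mesh$boundary$fixed, ])))
  if (length(mesh$boundary$axis)) {
    fixed_u <- unique(c(fixed_u, udof[mesh$boundary$axis, 1L]))
  }
  if (isTRUE(mesh$constrain_x)) fixed_u <- unique(c(fixed_u, udof[, 1L]))
  if (!length(fixed_u)) {
    stopf("singular poroelastic system: mesh has no displacement constraints")
  }
  cache$fixed_u <- sort(fixed_u)
  cache$fixed_p <- sort(unique(mesh$boundary$drainage))
  cache
}

lame <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

assemble_blocks <- function(mesh, cache, mat) {
  lm_ <- lame(mat$E, mat$nu)
  s_stor <- mat$porosity / mat$Kf + (1 - mat$porosity) / mat$Ks
  el <- cache$el
  m <- cache$m
  vK <- vector("list", m); vQ <- vector("list", m)
  vH <- vector("list", m); vS <- vector("list", m)
  for (e in seq_len(m)) {
    ee <- el[[e]]
    vK[[e]] <- as.vector(lm_$lambda[e] * ee$Kl + lm_$mu[e] * ee$Km)
    vQ[[e]] <- as.vector(ee$Q)
    vH[[e]] <- as.vector(mat$permeability[e] * ee$H)
    vS[[e]] <- as.vector(s_stor[e] * ee$S)
  }
  idx <- cache$idx
  K <- Matrix::sparseMatrix(i = idx$iK, j = idx$jK, x = unlist(vK),
                            dims = c(cache$nu, cache$nu))
  Q <- Matrix::sparseMatrix(i = idx$iQ, j = idx$jQ, x = unlist(vQ),
                            dims = c(cache$nu, cache$n))
  H <- Matrix::sparseMatrix(i = idx$iH, j = idx$jH, x = unlist(vH),
                            dims = c(cache$n, cache$n))
  S <- Matrix::sparseMatrix(i = idx$iH, j = idx$jH, x = unlist(vS),
                            dims = c(cache$n, cache$n))
  list(K = K, Q = Q, H = H, S = S)
}

# per-element strain vector(s) from full displacement vector
elem_strains <- function(cache, ufull) {
  vapply(cache$el, function(ee) as.vector(ee$Bu0 %*% ufull[ee$ud]),
         numeric(if (cache$axisym) 4L else 3L))
}

principal_from_voigt <- function(eps, axisym) {
  # eps: k x m matrix of centroid strains
  if (axisym) {
    e1 <- eps[1, ]; e2 <- eps[2, ]; e3 <- eps[3, ]; g <- eps[4, ]
  } else {
    e1 <- eps[1, ]; e2 <- eps[2, ]; e3 <- rep(0, ncol(eps)); g <- eps[3, ]
  }
  cc <- (e1 + e2) / 2
  rr <- sqrt(((e1 - e2) / 2)^2 + (g / 2)^2)
  rbind(cc + rr, cc - rr, e3)
}

#' Octahedral deviatoric strain from principal strains
#'
#' `(2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`; zero for purely
#' volumetric deformation and symmetric under permutation of inputs.
#'
#' @param eps1,eps2,eps3 principal strains (vectorized).
#' @return dimensionless deviatoric strain, >= 0.
#' @export
deviatoric_strain <- function(eps1, eps2, eps3) {
  (2 / 3) * sqrt((eps1 - eps2)^2 + (eps2 - eps3)^2 + (eps3 - eps1)^2)
}

#' Magnitude of the relative fluid velocity
#'
#' @param wf numeric vector (one velocity) or matrix with one velocity per
#'   row, in um/s.
#' @return Euclidean norm(s), um/s.
#' @export
fluid_velocity_magnitude <- function(wf) {
  if (is.matrix(wf)) sqrt(rowSums(wf^2)) else sqrt(sum(wf^2))
}

#' Strain energy density per unit apparent density
#'
#' `psi = U / rho` with `U = stress : strain / 2`.  Inputs may be 3x3
#' tensors or Voigt vectors with engineering shear components.
#'
#' @param stress,strain matching tensors (MPa, -).
#' @param rho apparent density, g/cm^3 (> 0).
#' @return psi in MPa cm^3/g (= J/g).
#' @export
element_strain_energy_density <- function(stress, strain, rho) {
  if (!all(rho > 0)) stopf("'rho' must be positive")
  U <- sum(stress * strain) / 2
  U / rho
}

stress_fields <- function(cache, eps, mat) {
  lm_ <- lame(mat$E, mat$nu)
  m <- cache$m
  if (cache$axisym) {
    tr <- eps[1, ] + eps[2, ] + eps[3, ]
    s1 <- lm_$lambda * tr + 2 * lm_$mu * eps[1, ]
    s2 <- lm_$lambda * tr + 2 * lm_$mu * eps[2, ]
    s3 <- lm_$lambda * tr + 2 * lm_$mu * eps[3, ]
    s4 <- lm_$mu * eps[4, ]
    U <- 0.5 * (s1 * eps[1, ] + s2 * eps[2, ] + s3 * eps[3, ] + s4 * eps[4, ])
    # principal stresses: in-plane pair + hoop
    cc <- (s1 + s2) / 2; rr <- sqrt(((s1 - s2) / 2)^2 + s4^2)
    p1 <- cc + rr; p2 <- cc - rr; p3 <- s3
  } else {
    tr <- eps[1, ] + eps[2, ]
    s1 <- lm_$lambda * tr + 2 * lm_$mu * eps[1, ]
    s2 <- lm_$lambda * tr + 2 * lm_$mu * eps[2, ]
    s3 <- lm_$lambda * tr                      # out-of-plane
    s4 <- lm_$mu * eps[3, ]
    U <- 0.5 * (s1 * eps[1, ] + s2 * eps[2, ] + s4 * eps[3, ])
    cc <- (s1 + s2) / 2; rr <- sqrt(((s1 - s2) / 2)^2 + s4^2)
    p1 <- cc + rr; p2 <- cc - rr; p3 <- s3
  }
  vm <- sqrt(0.5 * ((p1 - p2)^2 + (p2 - p3)^2 + (p3 - p1)^2))
  list(U = U, vm = vm, sigma_axial = s2)
}

reduce_solve <- function(A, b, free) {
  x <- numeric(length(b))
  sol <- tryCatch(Matrix::solve(A[free, free, drop = FALSE], b[free]),
                  error = function(e) {
                    stopf("singular poroelastic system (unconstrained mesh?): %s",
                          conditionMessage(e))
                  })
  if (any(!is.finite(as.numeric(sol)))) {
    stopf("singular poroelastic system (unconstrained mesh?)")
  }
  x[free] <- as.numeric(sol)
  x
}

#' Solve one daily loading event
#'
#' Runs (a) a transient ramp-and-hold consolidation solve over `duration`
#' seconds, tracking the peak-in-time per-element deviatoric strain and
#' fluid-velocity magnitude, and (b) a drained elastic solve at full load,
#' providing per-element stress and strain-energy density.
#'
#' @param mesh a `mesh_model`.
#' @param materials a `poro_materials` data.frame (one row per element).
#' @param load total axial compressive force: N (axisymmetric) or N per mm
#'   thickness (plane strain).
#' @param duration loading-event duration in seconds.
#' @param n_sub number of implicit sub-steps.
#' @param cache optional [fem_cache()]; computed if NULL.
#' @param fixator_stiffness axial spring (N/mm) grounding the loaded end.
#' @param ramp ramp the load linearly over the event (TRUE) or apply it as
#'   a step at the first sub-step (FALSE).
#' @param return_history keep the pore-pressure field after each sub-step.
#' @return an object of class `field_snapshot`.
#' @export
solve_daily_loading <- function(mesh, materials, load, duration = 1,
                                n_sub = 4L, cache = NULL,
                                fixator_stiffness = NULL, ramp = TRUE,
                                return_history = FALSE) {
  if (is.null(cache)) cache <- fem_cache(mesh)
  kfix <- fixator_stiffness %||% (mesh$spec$fixator_stiffness %||% 0)
  m <- cache$m
  if (load == 0) {
    zero <- rep(0, m)
    out <- list(eps_dev = zero, wf_mag = zero, sigma_vm = zero,
                sigma_axial = zero, psi = zero, U = zero,
                u = matrix(0, cache$n, 2), p = rep(0, cache$n),
                reaction = 0, load = 0)
    class(out) <- "field_snapshot"
    return(out)
  }
  blocks <- assemble_blocks(mesh, cache, materials)
  K <- blocks$K
  if (kfix > 0 && !is.na(cache$master)) {
    K[cache$master, cache$master] <- K[cache$master, cache$master] + kfix
  }
  tau <- duration / n_sub
  A <- rbind(cbind(K, -blocks$Q),
             cbind(Matrix::t(blocks$Q), blocks$S + tau * blocks$H))
  free <- setdiff(seq_len(cache$nu + cache$n),
                  c(cache$fixed_u, cache$nu + cache$fixed_p))
  Af <- A[free, free, drop = FALSE]
  LU <- tryCatch(Matrix::lu(Af), error = function(e) {
    stopf("singular poroelastic system (unconstrained mesh?): %s",
          conditionMessage(e))
  })
  u <- numeric(cache$nu); p <- numeric(cache$n)
  eps_dev_max <- rep(0, m); wf_max <- rep(0, m)
  perm <- materials$permeability
  hist <- if (return_history) vector("list", n_sub) else NULL
  f <- numeric(cache$nu)
  for (s in seq_len(n_sub)) {
    frac <- if (ramp) s / n_sub else 1
    f[] <- 0
    f[cache$master] <- -load * frac
    rhs <- c(f, as.numeric(Matrix::t(blocks$Q) %*% u + blocks$S %*% p))
    x <- numeric(cache$nu + cache$n)
    sol <- as.numeric(Matrix::solve(LU, rhs[free]))
    if (any(!is.finite(sol))) {
      stopf("singular poroelastic system (unconstrained mesh?)")
    }
    x[free] <- sol
    u <- x[seq_len(cache$nu)]
    p <- x[cache$nu + seq_len(cache$n)]
    eps <- elem_strains(cache, u)
    pr <- principal_from_voigt(eps, cache$axisym)
    ed <- deviatoric_strain(pr[1, ], pr[2, ], pr[3, ])
    eps_dev_max <- pmax(eps_dev_max, ed)
    # Darcy velocity at element centroid, mm/s -> um/s
    gp1 <- vapply(cache$el, function(ee) as.vector(ee$Bp0 %*% p[ee$pd]),
                  numeric(2L))
    wf <- MM_S_TO_UM_S * perm * sqrt(gp1[1, ]^2 + gp1[2, ]^2)
    wf_max <- pmax(wf_max, wf)
    if (return_history) hist[[s]] <- list(t = s * tau, p = p)
  }

  # drained elastic solve at full load for stress / SED
  fd <- numeric(cache$nu); fd[cache$master] <- -load
  free_u <- setdiff(seq_len(cache$nu), cache$fixed_u)
  ud <- reduce_solve(K, fd, free_u)
  eps_d <- elem_strains(cache, ud)
  sf <- stress_fields(cache, eps_d, materials)
  psi <- sf$U / materials$rho

  # reaction at the fixed end (z components) from the drained system
  resid <- as.numeric(K %*% ud - fd)
  fixed_uz <- cache$udof[mesh$boundary$fixed, 2L]
  reaction <- sum(resid[unique(fixed_uz)])

  unode <- cbind(u[cache$udof[, 1L]], u[cache$udof[, 2L]])
  out <- list(eps_dev = eps_dev_max, wf_mag = wf_max, sigma_vm = sf$vm,
              sigma_axial = sf$sigma_axial, psi = psi, U = sf$U,
              u = unode, p = p,
              u_drained = cbind(ud[cache$udof[, 1L]], ud[cache$udof[, 2L]]),
              reaction = reaction, load = load, history = hist)
  class(out) <- "field_snapshot"
  out
}

#' @export
print.field_snapshot <- function(x, ...) {
  cat(sprintf("<field_snapshot> %d elements; max eps_dev %.4g, max wf %.4g um/s, max psi %.4g J/g\n",
              length(x$eps_dev), max(x$eps_dev), max(x$wf_mag), max(x$psi)))
  invisible(x)
}

#' Inter-fragmentary movement across the fracture gap
#'
#' Relative axial displacement of the two cortical fragment end faces,
#' from the end-of-event consolidation displacement field.
#'
#' @param mesh a `mesh_model`.
#' @param snapshot a `field_snapshot` from [solve_daily_loading()].
#' @return absolute IFM in mm.
#' @export
interfragmentary_movement <- function(mesh, snapshot) {
  g2 <- mesh$spec$fracture_gap / 2
  ri <- mesh$spec$cortex_inner_radius; ro <- mesh$spec$cortex_outer_radius
  tol <- 1e-8
  rr <- abs(mesh$nodes[, 1])
  on_band <- rr >= ri - tol & rr <= ro + tol
  up <- which(abs(mesh$nodes[, 2] - g2) < tol & on_band)
  lo <- which(abs(mesh$nodes[, 2] + g2) < tol & on_band)
  if (!length(up) || !length(lo)) stopf("fracture faces not found on mesh")
  abs(mean(snapshot$u[up, 2]) - mean(snapshot$u[lo, 2]))
}
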