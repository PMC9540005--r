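# Idealized fracture geometries as labelled structured quad meshes.
#
# The long bone is a smooth co-axial cylinder (cortex + marrow) with a
# transverse fracture gap surrounded by a callus split into three zones:
# outer callus (periosteal bulge), callus focus (between the cortical
# fragment ends) and inner callus (endosteal, inside the marrow cavity).
# Unplated and calibration variants are meshed axisymmetrically in (r, z);
# the plated variant is a plane-strain half-section in (x, z) with a
# titanium strip bonded to one cortical surface, spanning the gap.

REGION_LEVELS <- c("cortex", "marrow", "inner_callus", "callus_focus",
                   "outer_callus", "plate")
CALLUS_REGIONS <- c("inner_callus", "callus_focus", "outer_callus")

#' Geometry specification for an idealized fracture model
#'
#' All dimensions are in millimetres.  Defaults for the tibia variants are
#' a 10 mm outer cortical radius with a 5 mm wall; the calibration variant
#' mimics an ovine metatarsus osteotomy (3 mm gap) stabilised by an axial
#' external fixator, represented as a linear spring in parallel with the
#' tissue column.
#'
#' @param variant one of "unplated", "plated", "calibration".
#' @param fracture_gap axial gap between the cortical fragment ends (mm).
#' @param cortex_outer_radius,cortex_inner_radius cortical wall radii (mm).
#' @param callus_extent radial thickness of the outer callus bulge (mm).
#' @param callus_axial_extent axial extent of the outer callus beyond the
#'   gap half-width (mm).
#' @param inner_callus_axial_extent axial extent of the endosteal callus
#'   beyond the gap half-width (mm).
#' @param model_length total axial length of the meshed bone segment (mm).
#' @param plate_thickness,plate_modulus,plate_halflength plate strip
#'   geometry (mm) and elastic modulus (MPa); plated variant only.
#' @param fixator_stiffness axial stiffness (N/mm) of an external fixator
#'   acting in parallel with the bone; 0 disables it.
#' @param mesh_target_size target element edge length (mm).
#' @return an object of class `geometry_spec`.
#' @export
geometry_spec <- function(variant = c("unplated", "plated", "calibration"),
                          fracture_gap = 3,
                          cortex_outer_radius = NULL,
                          cortex_inner_radius = NULL,
                          callus_extent = NULL,
                          callus_axial_extent = NULL,
                          inner_callus_axial_extent = NULL,
                          model_length = NULL,
                          plate_thickness = 4,
                          plate_modulus = 110000,
                          plate_halflength = NULL,
                          fixator_stiffness = NULL,
                          mesh_target_size = 2.5) {
  variant <- match.arg(variant)
  calib <- variant == "calibration"
  spec <- list(
    variant = variant,
    fracture_gap = fracture_gap,
    cortex_outer_radius = cortex_outer_radius %||% (if (calib) 9 else 11.3),
    cortex_inner_radius = cortex_inner_radius %||% 5,
    callus_extent = callus_extent %||% (if (calib) 3 else 2.5),
    callus_axial_extent = callus_axial_extent %||% (if (calib) 8 else 10),
    inner_callus_axial_extent = inner_callus_axial_extent %||% 5,
    model_length = model_length %||% (if (calib) 48 else 60),
    plate_thickness = plate_thickness,
    plate_modulus = plate_modulus,
    plate_halflength = plate_halflength %||% 20,
    fixator_stiffness = fixator_stiffness %||% (if (calib) 450 else 0),
    mesh_target_size = mesh_target_size
  )
  check_number(spec$fracture_gap, "fracture_gap", 0, Inf, strict_lo = TRUE)
  check_number(spec$mesh_target_size, "mesh_target_size", 0, Inf,
               strict_lo = TRUE)
  check_number(spec$cortex_outer_radius, "cortex_outer_radius", 0, Inf,
               strict_lo = TRUE)
  if (spec$cortex_inner_radius >= spec$cortex_outer_radius) {
    stopf("cortex_inner_radius (%g) must be smaller than cortex_outer_radius (%g)",
          spec$cortex_inner_radius, spec$cortex_outer_radius)
  }
  if (spec$fracture_gap > 2 * spec$callus_axial_extent) {
    stopf("fracture_gap (%g mm) exceeds the axial extent of the callus (%g mm)",
          spec$fracture_gap, 2 * spec$callus_axial_extent)
  }
  half <- spec$model_length / 2
  if (spec$fracture_gap / 2 + spec$callus_axial_extent >= half ||
      (variant == "plated" && spec$plate_halflength >= half)) {
    stopf("model_length (%g mm) too short for the callus/plate extents",
          spec$model_length)
  }
  check_number(spec$fixator_stiffness, "fixator_stiffness", 0, Inf)
  class(spec) <- "geometry_spec"
  spec
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("<geometry_spec> %s, gap %g mm, cortex r = [%g, %g] mm, h = %g mm\n",
              x$variant, x$fracture_gap, x$cortex_inner_radius,
              x$cortex_outer_radius, x$mesh_target_size))
  invisible(x)
}

# subdivide [a, b] with steps close to h
subdivide <- function(a, b, h) {
  n <- max(1L, as.integer(round((b - a) / h)))
  seq(a, b, length.out = n + 1L)
}

breaks_from <- function(criticals, h) {
  criticals <- sort(unique(criticals))
  out <- criticals[1]
  for (i in seq_len(length(criticals) - 1L)) {
    out <- c(out, subdivide(criticals[i], criticals[i + 1L], h)[-1L])
  }
  out
}

# Structured quad mesh on a tensor grid; elements whose region_fun returns
# NA are dropped.  Shared by the fracture builder and test fixtures.
structured_mesh <- function(xbreaks, zbreaks, region_fun,
                            mode = c("axisymmetric", "plane")) {
  mode <- match.arg(mode)
  nx <- length(xbreaks); nz <- length(zbreaks)
  nodes <- cbind(rep(xbreaks, times = nz), rep(zbreaks, each = nx))
  nid <- function(i, j) (j - 1L) * nx + i
  ii <- rep(seq_len(nx - 1L), times = nz - 1L)
  jj <- rep(seq_len(nz - 1L), each = nx - 1L)
  elems <- cbind(nid(ii, jj), nid(ii + 1L, jj), nid(ii + 1L, jj + 1L),
                 nid(ii, jj + 1L))
  xc <- (xbreaks[ii] + xbreaks[ii + 1L]) / 2
  zc <- (zbreaks[jj] + zbreaks[jj + 1L]) / 2
  region <- region_fun(xc, zc)
  keep <- !is.na(region)
  elems <- elems[keep, , drop = FALSE]
  region <- region[keep]
  centers <- cbind(xc[keep], zc[keep])
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  mesh <- list(
    nodes = nodes[used, , drop = FALSE],
    elems = matrix(remap[elems], ncol = 4L),
    region = region,
    centers = centers,
    mode = mode
  )
  mesh$areas <- quad_areas(mesh$nodes, mesh$elems)
  if (any(mesh$areas <= 0)) stopf("degenerate mesh: inverted elements found")
  mesh$adjacency <- quad_adjacency(mesh$elems)
  class(mesh) <- "mesh_model"
  mesh
}

quad_areas <- function(nodes, elems) {
  x <- matrix(nodes[elems, 1L], ncol = 4L)
  z <- matrix(nodes[elems, 2L], ncol = 4L)
  0.5 * abs((x[, 1] * z[, 2] - x[, 2] * z[, 1]) +
            (x[, 2] * z[, 3] - x[, 3] * z[, 2]) +
            (x[, 3] * z[, 4] - x[, 4] * z[, 3]) +
            (x[, 4] * z[, 1] - x[, 1] * z[, 4]))
}

# edge-sharing neighbours: m x 4 matrix, NA where no neighbour
quad_adjacency <- function(elems) {
  m <- nrow(elems)
  e1 <- elems[, c(1, 2, 3, 4)]
  e2 <- elems[, c(2, 3, 4, 1)]
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  key <- paste(a, b)
  elem_of <- rep(seq_len(m), 4L)
  sp <- split(elem_of, key)
  adj <- matrix(NA_integer_, m, 4L)
  for (grp in sp) {
    if (length(grp) == 2L) {
      i <- grp[1L]; j <- grp[2L]
      adj[i, which(is.na(adj[i, ]))[1L]] <- j
      adj[j, which(is.na(adj[j, ]))[1L]] <- i
    }
  }
  adj
}

boundary_edges <- function(elems) {
  e1 <- as.vector(elems[, c(1, 2, 3, 4)])
  e2 <- as.vector(elems[, c(2, 3, 4, 1)])
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  key <- paste(a, b)
  once <- !(key %in% key[duplicated(key)])
  cbind(e1[once], e2[once], rep(seq_len(nrow(elems)), 4L)[once])
}

#' Build an idealized fracture model mesh
#'
#' Produces a labelled quad mesh (regions: cortex, marrow, inner callus,
#' callus focus, outer callus and, for the plated variant, plate) with
#' boundary sets for loading, fixation, pore-fluid drainage and the MSC
#' source surface (exterior callus surface plus the callus interfaces with
#' marrow and cortex).
#'
#' @param spec a [geometry_spec()].
#' @return an object of class `mesh_model`.
#' @export
build_fracture_model <- function(spec) {
  if (!inherits(spec, "geometry_spec")) stopf("'spec' must be a geometry_spec")
  ri <- spec$cortex_inner_radius; ro <- spec$cortex_outer_radius
  ce <- spec$callus_extent; g2 <- spec$fracture_gap / 2
  zca <- g2 + spec$callus_axial_extent
  zic <- g2 + spec$inner_callus_axial_extent
  half <- spec$model_length / 2
  h <- spec$mesh_target_size
  plated <- spec$variant == "plated"
  pt <- spec$plate_thickness; ph <- spec$plate_halflength

  zcrit <- c(0, g2, zic, zca, half)
  if (plated) zcrit <- c(zcrit, ph)
  zb_half <- breaks_from(zcrit, h)
  zbreaks <- c(-rev(zb_half[-1L]), zb_half)

  radial_region <- function(r, z) {
    out <- rep(NA_character_, length(r))
    out[r <= ri & abs(z) <= zic] <- "inner_callus"
    out[r <= ri & abs(z) > zic] <- "marrow"
    mid <- r > ri & r <= ro
    out[mid & abs(z) <= g2] <- "callus_focus"
    out[mid & abs(z) > g2] <- "cortex"
    outc <- r > ro & r <= ro + ce
    out[outc & abs(z) <= zca] <- "outer_callus"
    out
  }

  if (!plated) {
    xbreaks <- breaks_from(c(0, ri, ro, ro + ce), h)
    mesh <- structured_mesh(xbreaks, zbreaks, radial_region, "axisymmetric")
  } else {
    xcrit <- c(-(ro + ce), -ro, -ri, 0, ri, ro, ro + pt, ro + pt + ce)
    xbreaks <- breaks_from(xcrit, h)
    region_fun <- function(x, z) {
      out <- radial_region(abs(x), z)
      band_plate <- x > ro & x <= ro + pt
      out[band_plate] <- ifelse(abs(z[band_plate]) <= ph, "plate",
                                NA_character_)
      band_cal <- x > ro + pt & x <= ro + pt + ce
      out[band_cal] <- ifelse(abs(z[band_cal]) <= zca, "outer_callus",
                              NA_character_)
      # mirror side keeps its callus bulge from radial_region(|x|)
      out
    }
    mesh <- structured_mesh(xbreaks, zbreaks, region_fun, "plane")
  }
  mesh$spec <- spec
  mesh <- add_boundary_sets(mesh)
  mesh
}

add_boundary_sets <- function(mesh) {
  nodes <- mesh$nodes; elems <- mesh$elems; region <- mesh$region
  tol <- 1e-8
  zmax <- max(nodes[, 2]); zmin <- min(nodes[, 2])
  is_callus <- region %in% CALLUS_REGIONS
  be <- boundary_edges(elems)
  bnodes <- unique(c(be[, 1], be[, 2]))

  # load is introduced through the cortical wall at the proximal end (the
  # marrow column is not tied to the platen)
  ri <- mesh$spec$cortex_inner_radius; ro <- mesh$spec$cortex_outer_radius
  rr <- abs(nodes[, 1])
  loaded <- which(abs(nodes[, 2] - zmax) < tol & rr >= ri - tol & rr <= ro + tol)
  fixed <- which(abs(nodes[, 2] - zmin) < tol)
  axis <- if (mesh$mode == "axisymmetric") {
    which(abs(nodes[, 1]) < tol)
  } else integer(0)

  # exterior surface nodes of callus elements, excluding the end planes
  cal_b <- unique(c(be[is_callus[be[, 3]], 1], be[is_callus[be[, 3]], 2]))
  cal_b <- setdiff(cal_b, c(loaded, fixed, axis))
  drainage <- cal_b

  # MSC sources: surrounding soft tissue (exterior callus surface), bone
  # marrow (inner-callus/marrow interface) and the periosteal cambium
  # (outer-callus/cortex interface).  The cortical fracture faces bounding
  # the callus focus are NOT a cell source: the focus is populated by
  # diffusion from the periphery.
  touching <- function(region_a, region_b) {
    in_a <- region %in% region_a
    na <- unique(as.vector(elems[in_a, ]))
    in_b <- region %in% region_b
    nb <- unique(as.vector(elems[in_b, ]))
    intersect(na, nb)
  }
  # the endosteal (inner cortical) wall is bathed in marrow, so the whole
  # inner-callus contact with marrow and cortex acts as the marrow source
  # Note: the cortical fracture faces bounding the callus focus are not a
  # source surface; only their corner rings, which lie on the periosteal /
  # endosteal surfaces proper, carry the boundary concentration.
  marrow_iface <- touching("inner_callus", c("marrow", "cortex"))
  periosteum <- touching("outer_callus", "cortex")
  msc_source <- sort(unique(c(drainage, marrow_iface, periosteum)))

  # spanning-path terminals: callus-focus elements edge-adjacent to cortex
  focus <- which(region == "callus_focus")
  upper_seed <- integer(0); lower_seed <- integer(0)
  for (e in focus) {
    nb <- mesh$adjacency[e, ]
    nb <- nb[!is.na(nb)]
    cx <- nb[region[nb] == "cortex"]
    if (length(cx)) {
      if (any(mesh$centers[cx, 2] > mesh$centers[e, 2])) {
        upper_seed <- c(upper_seed, e)
      }
      if (any(mesh$centers[cx, 2] < mesh$centers[e, 2])) {
        lower_seed <- c(lower_seed, e)
      }
    }
  }
  mesh$boundary <- list(loaded = loaded, fixed = fixed, axis = axis,
                        drainage = drainage, msc_source = msc_source)
  mesh$focus_seeds <- list(upper = unique(upper_seed),
                           lower = unique(lower_seed))
  mesh
}

#' @export
print.mesh_model <- function(x, ...) {
  cat(sprintf("<mesh_model> %s, %d nodes, %d elements\n", x$mode,
              nrow(x$nodes), nrow(x$elems)))
  print(table(x$region))
  invisible(x)
}

#' Region areas of a mesh (plain 2D section areas, mm^2)
#' @param mesh a `mesh_model`.
#' @return named numeric vector of per-region areas.
#' @export
region_areas <- function(mesh) {
  tapply(mesh$areas, mesh$region, sum)
}

#' Does a chain of predicate-true callus-focus elements bridge the gap?
#'
#' Breadth-first search over the edge-adjacency graph restricted to
#' callus-focus elements satisfying `predicate`, from elements touching
#' the upper cortical fragment face to elements touching the lower one.
#'
#' @param mesh a `mesh_model`.
#' @param predicate either a logical vector over all elements or a
#'   function taking the mesh and returning one.
#' @return TRUE if a bridging path exists.
#' @export
spanning_path_exists <- function(mesh, predicate) {
  if (is.function(predicate)) predicate <- predicate(mesh)
  if (!is.logical(predicate) || length(predicate) != nrow(mesh$elems)) {
    stopf("'predicate' must be a logical vector over all %d elements",
          nrow(mesh$elems))
  }
  focus_ok <- (mesh$region == "callus_focus") & predicate & !is.na(predicate)
  start <- intersect(mesh$focus_seeds$upper, which(focus_ok))
  goal <- intersect(mesh$focus_seeds$lower, which(focus_ok))
  if (!length(start) || !length(goal)) return(FALSE)
  seen <- logical(nrow(mesh$elems))
  queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    e <- queue[[1L]]; queue <- queue[-1L]
    if (e %in% goal) return(TRUE)
    nb <- mesh$adjacency[e, ]
    nb <- nb[!is.na(nb)]
    nb <- nb[focus_ok[nb] & !seen[nb]]
    if (length(nb)) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  FALSE
}
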