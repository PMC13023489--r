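# Transient diffusion on an axisymmetric finite-volume mesh.
#
# The governing equation is the diffusion limit of the scalar transport
# equation: dphi/dt = div(D grad phi), with phi the drug concentration
# (kg/m^3), no convection and no reaction/uptake source. All exterior
# surfaces are zero-flux (natural in the finite-volume discretisation);
# interfaces between regions are ordinary interior faces, so drug passes
# freely across them subject to the face diffusivity.

#' Piecewise-constant diffusivity map
#'
#' Assigns a diffusivity (m^2/s) to each mesh region, with optional overrides
#' for specific region-pair interfaces. By default the diffusivity of a face
#' between unlike regions is the harmonic mean of the two cell values, the
#' standard flux-continuous choice for material interfaces; an `interface`
#' entry such as `list("balloon:wall" = 2e-12)` replaces that face value
#' directly (pair names sorted alphabetically, joined by `:`).
#'
#' @param balloon,plaque,wall Region diffusivities (m^2/s); non-negative.
#' @param interface Optional named list of face-diffusivity overrides.
#' @return An object of class `diffusivity_map`.
#' @export
diffusivity_map <- function(balloon = 0, plaque = 0, wall = 0,
                            interface = list()) {
  vals <- c(balloon = balloon, plaque = plaque, wall = wall)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    dcb_abort("diffusivities must be finite and non-negative", "dcb_validation_error")
  }
  if (length(interface)) {
    iv <- unlist(interface)
    if (any(!is.finite(iv)) || any(iv < 0)) {
      dcb_abort("interface diffusivities must be finite and non-negative",
                "dcb_validation_error")
    }
  }
  structure(list(region = vals, interface = interface), class = "diffusivity_map")
}

harmonic_mean <- function(a, b) {
  out <- numeric(length(a))
  nz <- a > 0 & b > 0
  out[nz] <- 2 * a[nz] * b[nz] / (a[nz] + b[nz])
  out
}

#' Assemble the finite-volume diffusion operator
#'
#' Builds the sparse stiffness matrix `K` of the semi-discrete system
#' `V dphi/dt = -K phi` on the active cells of the mesh, where `V` are the
#' axisymmetric cell volumes. `K` is symmetric positive semi-definite with
#' zero row sums (discrete conservation: constants are in its null space),
#' and `-V^{-1} K` is an M-matrix generator, so backward-Euler stepping
#' preserves non-negativity.
#'
#' @param mesh An [mesh_geometry()] mesh.
#' @param dmap A [diffusivity_map()].
#' @return An object of class `diffusion_operator` holding `K` (sparse),
#'   `V` (cell volumes) and a factorisation cache.
#' @export
assemble_operator <- function(mesh, dmap) {
  if (!inherits(mesh, "axi_mesh")) {
    dcb_abort("'mesh' must be an 'axi_mesh'", "dcb_validation_error")
  }
  if (!inherits(dmap, "diffusivity_map")) {
    dcb_abort("'dmap' must be a 'diffusivity_map'", "dcb_validation_error")
  }
  f <- mesh$faces
  Dcell <- dmap$region[mesh$cell_region]
  Dface <- harmonic_mean(Dcell[f$a], Dcell[f$b])
  if (length(dmap$interface)) {
    na <- REGION_NAMES[f$region_a]
    nb <- REGION_NAMES[f$region_b]
    key <- ifelse(na < nb, paste(na, nb, sep = ":"), paste(nb, na, sep = ":"))
    for (k in names(dmap$interface)) {
      Dface[key == k] <- dmap$interface[[k]]
    }
  }
  g <- Dface * f$area / f$dist  # face conductance (m^3/s)
  keep <- g > 0
  i <- c(f$a[keep], f$b[keep], f$a[keep], f$b[keep])
  j <- c(f$b[keep], f$a[keep], f$a[keep], f$b[keep])
  x <- c(-g[keep], -g[keep], g[keep], g[keep])
  K <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(mesh$n, mesh$n))
  structure(
    list(K = K, V = mesh$vol, n = mesh$n, mesh = mesh, cache = new.env(parent = emptyenv())),
    class = "diffusion_operator")
}

# Cached Cholesky factorisation of (V/dt + K) for a given dt.
step_factor <- function(op, dt) {
  key <- sprintf("%.17g", dt)
  fact <- op$cache[[key]]
  if (is.null(fact)) {
    A <- Matrix::Diagonal(x = op$V / dt) + op$K
    fact <- tryCatch(
      Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                       LDL = FALSE),
      error = function(e) dcb_abort(
        paste("implicit-step factorisation failed:", conditionMessage(e)),
        "dcb_numerical_error"))
    op$cache[[key]] <- fact
  }
  fact
}

#' Advance the concentration field by implicit time steps
#'
#' Performs `nsteps` backward-Euler steps of length `dt`:
#' `(V/dt + K) phi_new = (V/dt) phi_old`. The scheme is unconditionally
#' stable, conserves total mass `sum(phi * V)` exactly (up to linear-solver
#' round-off) under the all-zero-flux boundaries, and preserves
#' non-negativity. The sparse Cholesky factorisation is cached in the
#' operator and reused across steps and calls with the same `dt`.
#'
#' @param field Numeric vector of cell concentrations (kg/m^3).
#' @param op An [assemble_operator()] result.
#' @param dt Time-step length (s), positive.
#' @param nsteps Number of steps to take.
#' @return The advanced concentration field.
#' @export
advance <- function(field, op, dt, nsteps = 1L) {
  if (!inherits(op, "diffusion_operator")) {
    dcb_abort("'op' must be a 'diffusion_operator'", "dcb_validation_error")
  }
  stopifnot_positive(dt, "dt")
  if (length(field) != op$n) {
    dcb_abort("field length does not match operator size", "dcb_validation_error")
  }
  fact <- step_factor(op, dt)
  w <- op$V / dt
  phi <- field
  for (s in seq_len(nsteps)) {
    phi <- as.numeric(Matrix::solve(fact, w * phi, system = "A"))
  }
  if (any(!is.finite(phi))) {
    dcb_abort("implicit step produced non-finite concentrations", "dcb_numerical_error")
  }
  phi
}

#' Drug mass contained in a set of regions
#'
#' Sums `phi * V` over all cells whose region label is in `regions`.
#'
#' @param field Concentration field (kg/m^3).
#' @param mesh The `axi_mesh` the field lives on.
#' @param regions Character vector of region names (subset of
#'   `c("balloon", "plaque", "wall")`).
#' @return Mass in kg.
#' @export
region_mass <- function(field, mesh, regions) {
  unknown <- setdiff(regions, REGION_NAMES)
  if (length(unknown)) {
    dcb_abort(sprintf("unknown region label(s): %s", paste(unknown, collapse = ", ")),
              "dcb_validation_error")
  }
  codes <- REGION_CODES[regions]
  sel <- mesh$cell_region %in% codes
  sum(field[sel] * mesh$vol[sel])
}
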