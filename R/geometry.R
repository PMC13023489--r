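# Parametric post-dilation geometry of a balloon-dilated (stenotic) vessel
# segment, and its discretisation into a structured axisymmetric mesh.
#
# The configuration modelled is the state *after* balloon inflation: the
# balloon shell is pressed flush against the inner surface of the plaque (or
# of the wall where no plaque is present), with no fluid gap. The structural
# mechanics that produce this state are outside the model; the geometry is
# parametric.

#' Vessel, plaque and balloon dimensions
#'
#' Container for the geometric parameters of the post-dilation configuration.
#' The defaults are coronary-scale fixture values (lumen radius 1.5 mm, wall
#' thickness 1.0 mm, vessel length 20 mm, plaque half-length 5 mm, balloon
#' length 15 mm); the balloon shell thickness default of 0.10 mm is the
#' standard uniform shell thickness for a medical nylon balloon.
#'
#' @param lumen_radius Healthy lumen radius (m).
#' @param wall_thickness Vessel wall thickness (m).
#' @param vessel_length Axial length of the modelled segment (m).
#' @param plaque_half_length Axial half-length of the plaque (m); the plaque
#'   tapers smoothly to zero thickness at both ends.
#' @param balloon_thickness Balloon shell thickness (m).
#' @param balloon_length Axial length of the balloon (m), centred in the
#'   segment; must not exceed `vessel_length`.
#' @return An object of class `vessel_dims`.
#' @export
#' @examples
#' vessel_dims()
vessel_dims <- function(lumen_radius = 1.5e-3,
                        wall_thickness = 1.0e-3,
                        vessel_length = 20e-3,
                        plaque_half_length = 5e-3,
                        balloon_thickness = 0.10e-3,
                        balloon_length = 15e-3) {
  stopifnot_positive(lumen_radius, "lumen_radius")
  stopifnot_positive(wall_thickness, "wall_thickness")
  stopifnot_positive(vessel_length, "vessel_length")
  stopifnot_positive(plaque_half_length, "plaque_half_length")
  stopifnot_positive(balloon_thickness, "balloon_thickness")
  stopifnot_positive(balloon_length, "balloon_length")
  if (plaque_half_length >= vessel_length / 2) {
    dcb_abort("'plaque_half_length' must be smaller than vessel_length/2",
              "dcb_validation_error")
  }
  if (balloon_length > vessel_length) {
    dcb_abort("'balloon_length' must not exceed 'vessel_length'",
              "dcb_validation_error")
  }
  structure(
    list(lumen_radius = lumen_radius, wall_thickness = wall_thickness,
         vessel_length = vessel_length, plaque_half_length = plaque_half_length,
         balloon_thickness = balloon_thickness, balloon_length = balloon_length),
    class = "vessel_dims")
}

#' Build a post-dilation stenotic vessel geometry
#'
#' Constructs the axisymmetric configuration of lumen, wall, annular plaque
#' and inflated balloon shell for a given stenosis rate. The stenosis rate
#' follows the clinical diameter-reduction convention: at the plaque throat,
#' `(lumen_radius - plaque_inner_radius) / lumen_radius == stenosis_rate`.
#' The plaque shoulder follows a cosine taper to zero thickness at its axial
#' ends, centred at mid-vessel. `stenosis_rate = 0` yields a plain tube (the
#' ex vivo test-vessel configuration, no plaque).
#'
#' @param stenosis_rate Fractional diameter reduction at the throat, in
#'   `[0, 1)`.
#' @param dims A [vessel_dims()] object.
#' @return An object of class `stenosis_geometry` with elements `dims`,
#'   `stenosis_rate`, and `r_plaque(z)`, the plaque inner radius (m) as a
#'   function of axial position (m).
#' @export
#' @examples
#' geom <- build_geometry(0.5)
#' geom$r_plaque(geom$dims$vessel_length / 2)  # throat radius: 0.75 mm
build_geometry <- function(stenosis_rate, dims = vessel_dims()) {
  if (!is.numeric(stenosis_rate) || length(stenosis_rate) != 1L ||
      !is.finite(stenosis_rate) || stenosis_rate < 0 || stenosis_rate >= 1) {
    dcb_abort("'stenosis_rate' must lie in [0, 1)", "dcb_domain_error")
  }
  if (!inherits(dims, "vessel_dims")) {
    dims <- do.call(vessel_dims, as.list(dims))
  }
  R <- dims$lumen_radius
  zc <- dims$vessel_length / 2
  Lp <- dims$plaque_half_length
  s <- stenosis_rate
  depth_fun <- function(z) {
    d <- numeric(length(z))
    inside <- abs(z - zc) <= Lp
    d[inside] <- s * R * 0.5 * (1 + cos(pi * (z[inside] - zc) / Lp))
    d
  }
  structure(
    list(dims = dims,
         stenosis_rate = s,
         plaque_depth = depth_fun,
         r_plaque = function(z) R - depth_fun(z)),
    class = "stenosis_geometry")
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<stenosis_geometry> stenosis %.0f%%, lumen R %.2f mm, wall %.2f mm, length %.1f mm\n",
    100 * x$stenosis_rate, 1e3 * d$lumen_radius, 1e3 * d$wall_thickness,
    1e3 * d$vessel_length))
  invisible(x)
}

# region codes used in the mesh label matrix
REGION_CODES <- c(balloon = 1L, plaque = 2L, wall = 3L)
REGION_NAMES <- names(REGION_CODES)

# Subdivide [a, b] into cells of width as close to `spacing` as possible,
# always at least `nmin` cells, returning interior+boundary edges.
seg_edges <- function(a, b, spacing, nmin = 1L) {
  n <- max(nmin, round((b - a) / spacing))
  seq(a, b, length.out = n + 1L)
}

#' Discretise a geometry into a structured axisymmetric mesh
#'
#' Builds a cell-centred finite-volume mesh in `(r, z)` with per-cell region
#' labels (`balloon`, `plaque`, `wall`; unlabelled cells are void and excluded
#' from transport), axisymmetric cell volumes `2*pi*rbar*dr*dz`, interior face
#' conductance geometry, and the named boundary/interface surfaces used by the
#' transfer and retention stages (`vessel`, `vessel_in`, `vessel_out`,
#' `balloon_inner`, `plaque_balloon`, `vessel_balloon`, `vessel_plaque`).
#'
#' Radial cell edges are snapped to the lumen radius and (for the plain tube)
#' to the balloon inner radius, so annular region volumes are exact; the
#' tapered plaque and the balloon band under it are labelled by cell centre.
#'
#' @param geom A [build_geometry()] result.
#' @param target_spacing Target cell size (m) in both directions. Must resolve
#'   the thinnest region with at least 2 cells.
#' @return An object of class `axi_mesh`.
#' @export
mesh_geometry <- function(geom, target_spacing) {
  if (!inherits(geom, "stenosis_geometry")) {
    dcb_abort("'geom' must be a 'stenosis_geometry'", "dcb_validation_error")
  }
  stopifnot_positive(target_spacing, "target_spacing")
  d <- geom$dims
  s <- geom$stenosis_rate
  R <- d$lumen_radius
  tb <- d$balloon_thickness
  tw <- d$wall_thickness

  # resolution check: >= 2 cells across each region thickness
  thinnest <- c(balloon = tb, wall = tw)
  if (s > 0) thinnest <- c(thinnest, plaque = s * R)
  bad <- names(thinnest)[2 * target_spacing > thinnest + 1e-15]
  if (length(bad)) {
    dcb_abort(sprintf(
      "target_spacing %.3g m too coarse to resolve region(s): %s (need <= half the region thickness)",
      target_spacing, paste(bad, collapse = ", ")), "dcb_resolution_error")
  }

  # radial edges: piecewise-uniform between snapped breakpoints
  r_min <- R * (1 - s) - tb
  brk <- if (s > 0) c(r_min, R - tb, R, R + tw) else c(r_min, R, R + tw)
  r_edges <- brk[1]
  for (k in seq_len(length(brk) - 1L)) {
    e <- seg_edges(brk[k], brk[k + 1L], target_spacing)
    r_edges <- c(r_edges, e[-1L])
  }
  z_edges <- seg_edges(0, d$vessel_length, target_spacing)

  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  r_mid <- (r_edges[-1L] + r_edges[-(nr + 1L)]) / 2
  z_mid <- (z_edges[-1L] + z_edges[-(nz + 1L)]) / 2
  dr <- diff(r_edges)
  dz <- diff(z_edges)

  # label cells by centre
  zc <- d$vessel_length / 2
  depth <- geom$plaque_depth(z_mid)          # per column
  r_in <- R - depth                          # tissue inner surface
  in_balloon_z <- abs(z_mid - zc) <= d$balloon_length / 2 + 1e-12

  region <- matrix(0L, nr, nz)
  for (j in seq_len(nz)) {
    rc <- r_mid
    lab <- integer(nr)
    lab[rc > R] <- REGION_CODES[["wall"]]
    if (depth[j] > 1e-12) {
      lab[rc > r_in[j] & rc <= R] <- REGION_CODES[["plaque"]]
    }
    if (in_balloon_z[j]) {
      lab[rc > r_in[j] - tb & rc <= r_in[j]] <- REGION_CODES[["balloon"]]
    }
    region[, j] <- lab
  }

  mesh <- build_axi_mesh(r_edges, z_edges, region)
  mesh$geom <- geom
  mesh$target_spacing <- target_spacing
  mesh
}

# Assemble an axi_mesh from edge coordinates and a label matrix. Also used
# directly by tests to craft bespoke configurations (e.g. planar two-slab
# problems along z), and by the retention stage to drop the balloon region.
build_axi_mesh <- function(r_edges, z_edges, region) {
  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  stopifnot(nrow(region) == nr, ncol(region) == nz)
  r_mid <- (r_edges[-1L] + r_edges[-(nr + 1L)]) / 2
  z_mid <- (z_edges[-1L] + z_edges[-(nz + 1L)]) / 2
  dr <- diff(r_edges)
  dz <- diff(z_edges)

  active <- matrix(NA_integer_, nr, nz)
  act <- which(region > 0L)
  active[act] <- seq_along(act)
  n <- length(act)
  ij <- arrayInd(act, c(nr, nz))
  cell_i <- ij[, 1L]
  cell_j <- ij[, 2L]
  cell_region <- region[act]
  cell_r <- r_mid[cell_i]
  cell_z <- z_mid[cell_j]
  vol <- 2 * pi * cell_r * dr[cell_i] * dz[cell_j]

  # interior faces between active cells ------------------------------------
  # radial: (i, j) - (i+1, j)
  a_idx <- integer(0); b_idx <- integer(0); area <- numeric(0); dist <- numeric(0)
  if (nr > 1L) {
    A <- active[-nr, , drop = FALSE]; B <- active[-1L, , drop = FALSE]
    ok <- which(!is.na(A) & !is.na(B))
    if (length(ok)) {
      ijf <- arrayInd(ok, c(nr - 1L, nz))
      i <- ijf[, 1L]; j <- ijf[, 2L]
      a_idx <- c(a_idx, A[ok]); b_idx <- c(b_idx, B[ok])
      area <- c(area, 2 * pi * r_edges[i + 1L] * dz[j])
      dist <- c(dist, r_mid[i + 1L] - r_mid[i])
    }
  }
  # axial: (i, j) - (i, j+1)
  if (nz > 1L) {
    A <- active[, -nz, drop = FALSE]; B <- active[, -1L, drop = FALSE]
    ok <- which(!is.na(A) & !is.na(B))
    if (length(ok)) {
      ijf <- arrayInd(ok, c(nr, nz - 1L))
      i <- ijf[, 1L]; j <- ijf[, 2L]
      a_idx <- c(a_idx, A[ok]); b_idx <- c(b_idx, B[ok])
      area <- c(area, 2 * pi * r_mid[i] * dr[i])
      dist <- c(dist, z_mid[j + 1L] - z_mid[j])
    }
  }
  faces <- data.frame(a = a_idx, b = b_idx, area = area, dist = dist)
  faces$region_a <- cell_region[faces$a]
  faces$region_b <- cell_region[faces$b]

  # named surfaces ----------------------------------------------------------
  surf <- list()
  # exterior: outer vessel surface (outermost active cell per column at i = nr)
  top <- active[nr, ]
  ok <- which(!is.na(top))
  surf$vessel <- data.frame(cell = top[ok], area = 2 * pi * r_edges[nr + 1L] * dz[ok])
  inlet <- active[, 1L]; ok <- which(!is.na(inlet))
  surf$vessel_in <- data.frame(cell = inlet[ok], area = 2 * pi * r_mid[ok] * dr[ok])
  outlet <- active[, nz]; ok <- which(!is.na(outlet))
  surf$vessel_out <- data.frame(cell = outlet[ok], area = 2 * pi * r_mid[ok] * dr[ok])

  # balloon inner surface: balloon cells whose inward radial neighbour is void
  bal <- REGION_CODES[["balloon"]]
  is_bal <- region == bal
  inner <- which(is_bal & rbind(rep(TRUE, nz), region[-nr, , drop = FALSE] == 0L))
  if (length(inner)) {
    ijb <- arrayInd(inner, c(nr, nz))
    surf$balloon_inner <- data.frame(
      cell = active[inner],
      area = 2 * pi * r_edges[ijb[, 1L]] * dz[ijb[, 2L]])
  } else {
    surf$balloon_inner <- data.frame(cell = integer(0), area = numeric(0))
  }

  # interface surfaces from interior faces, keyed by unordered region pair
  pair_surface <- function(code_a, code_b) {
    sel <- (faces$region_a == code_a & faces$region_b == code_b) |
           (faces$region_a == code_b & faces$region_b == code_a)
    f <- faces[sel, , drop = FALSE]
    # orient: 'a' cell carries code_a
    swap <- f$region_a != code_a
    tmp <- f$a[swap]; f$a[swap] <- f$b[swap]; f$b[swap] <- tmp
    data.frame(a = f$a, b = f$b, area = f$area)
  }
  surf$plaque_balloon <- pair_surface(REGION_CODES[["balloon"]], REGION_CODES[["plaque"]])
  surf$vessel_balloon <- pair_surface(REGION_CODES[["balloon"]], REGION_CODES[["wall"]])
  surf$vessel_plaque <- pair_surface(REGION_CODES[["plaque"]], REGION_CODES[["wall"]])

  structure(
    list(r_edges = r_edges, z_edges = z_edges, nr = nr, nz = nz,
         region = region, active = active, n = n,
         cell_i = cell_i, cell_j = cell_j, cell_region = cell_region,
         cell_r = cell_r, cell_z = cell_z, vol = vol,
         faces = faces, surfaces = surf),
    class = "axi_mesh")
}

#' @export
print.axi_mesh <- function(x, ...) {
  counts <- table(factor(REGION_NAMES[x$cell_region], levels = REGION_NAMES))
  cat(sprintf("<axi_mesh> %d x %d grid, %d active cells (%s)\n",
              x$nr, x$nz, x$n,
              paste(sprintf("%s %d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' Total meshed volume of each region
#'
#' @param mesh An `axi_mesh`.
#' @return Named numeric vector of region volumes (m^3).
#' @export
region_volumes <- function(mesh) {
  v <- vapply(REGION_CODES, function(code) {
    sum(mesh$vol[mesh$cell_region == code])
  }, numeric(1))
  names(v) <- REGION_NAMES
  v
}

# Drop the balloon region (post-withdrawal configuration). Returns
# list(mesh, map, loss_layers): `map[old_index] -> new_index` over the
# surviving cells; `loss_layers[[k]]` holds the new indices of the k-th
# tissue cell outward from the luminal surface in every column — the
# depth-ordered layers over which luminal wash-off removal cascades
# (layer 1 is the blood-contacted surface itself).
drop_balloon <- function(mesh) {
  region <- mesh$region
  region[region == REGION_CODES[["balloon"]]] <- 0L
  new_mesh <- build_axi_mesh(mesh$r_edges, mesh$z_edges, region)
  new_mesh$geom <- mesh$geom
  new_mesh$target_spacing <- mesh$target_spacing
  # old active index -> new active index
  map <- rep(NA_integer_, mesh$n)
  keep <- which(mesh$cell_region != REGION_CODES[["balloon"]])
  lin <- cbind(mesh$cell_i[keep], mesh$cell_j[keep])
  map[keep] <- new_mesh$active[lin]
  # depth-ordered luminal layers: per column, active cells sorted radially
  depth_rank <- matrix(NA_integer_, new_mesh$nr, new_mesh$nz)
  nlayer <- 0L
  for (j in seq_len(new_mesh$nz)) {
    ii <- which(!is.na(new_mesh$active[, j]))
    if (length(ii)) {
      depth_rank[ii, j] <- seq_along(ii)
      nlayer <- max(nlayer, length(ii))
    }
  }
  loss_layers <- lapply(seq_len(nlayer), function(k) {
    sel <- which(depth_rank == k)
    as.integer(new_mesh$active[sel])
  })
  list(mesh = new_mesh, map = map, loss_layers = loss_layers)
}
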