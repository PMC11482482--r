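#' Grid resolution policy
#'
#' Controls the graded axisymmetric grid: finest cells at the needle wall, the
#' slot and the tip (default 0.1 mm), growing geometrically away from those
#' features up to a cap (default 1 mm).
#'
#' @param min_cell finest cell size (m).
#' @param max_cell coarsest cell size (m).
#' @param growth geometric growth factor between neighbouring cells.
#' @param grade_rate target cell size increase per metre of distance from the
#'   nearest refinement feature (dimensionless slope).
#' @param pml_cells number of absorbing-layer cells padded onto the open EM
#'   boundaries.
#' @return an object of class `resolution_policy`.
#' @export
resolution_policy <- function(min_cell = 1e-4, max_cell = 1e-3, growth = 1.3,
                              grade_rate = 0.4, pml_cells = 16L) {
  stopifnot(min_cell > 0, max_cell >= min_cell, growth > 1, grade_rate > 0,
            pml_cells >= 4)
  structure(list(min_cell = min_cell, max_cell = max_cell, growth = growth,
                 grade_rate = grade_rate, pml_cells = as.integer(pml_cells)),
            class = "resolution_policy")
}

# steps filling [0, len], growing geometrically inward from whichever end has
# the smaller target size; the step list is rescaled to fit exactly
graded_steps <- function(len, h0, h1, growth, h_max) {
  h0 <- min(h0, h_max); h1 <- min(h1, h_max)
  if (len <= min(h0, h1) * 1.0000001) return(len)
  a <- numeric(0); b <- numeric(0)
  ha <- h0; hb <- h1; sa <- 0; sb <- 0
  while (sa + sb < len) {
    if (ha <= hb) { a <- c(a, ha); sa <- sa + ha; ha <- min(ha * growth, h_max) }
    else          { b <- c(b, hb); sb <- sb + hb; hb <- min(hb * growth, h_max) }
  }
  steps <- c(a, rev(b))
  steps * (len / sum(steps))
}

# target cell size from distance to the nearest refinement feature
feature_size <- function(x, features, pol) {
  d <- vapply(x, function(xx) min(abs(xx - features)), numeric(1))
  pmin(pol$max_cell, pol$min_cell + pol$grade_rate * d)
}

# 1D grid lines honouring mandatory breakpoints and the mesh-size policy
axis_lines <- function(breaks, features, pol) {
  breaks <- sort(unique(breaks))
  out <- breaks[1]
  for (k in seq_len(length(breaks) - 1L)) {
    p <- breaks[k]; q <- breaks[k + 1L]
    if (q - p < 1e-12) next
    st <- graded_steps(q - p, feature_size(p, features, pol),
                       feature_size(q, features, pol), pol$growth, pol$max_cell)
    out <- c(out, p + cumsum(st))
    out[length(out)] <- q  # guard against accumulation error
  }
  out
}

#' Construct an axisymmetric cell grid directly
#'
#' Low-level constructor used by [rasterize()] and by tests that need simple
#' homogeneous blocks. Cell material is taken at cell centres.
#'
#' @param r_edges radial cell edges (m), increasing, starting at 0.
#' @param z_edges axial cell edges (m), increasing.
#' @param material either a character matrix of dim
#'   `(length(r_edges)-1, length(z_edges)-1)` or a single label.
#' @param geometry optional [build_geometry()] the grid was rasterized from.
#' @param policy optional [resolution_policy()].
#' @return an object of class `domain_grid` with cell-centre coordinates,
#'   material labels and revolved cell volumes (m^3).
#' @export
domain_grid <- function(r_edges, z_edges, material, geometry = NULL,
                        policy = NULL) {
  r_edges <- as.numeric(r_edges); z_edges <- as.numeric(z_edges)
  if (abs(r_edges[1]) > 1e-15) stop("first radial edge must be at r = 0", call. = FALSE)
  r_edges[1] <- 0
  if (any(diff(r_edges) <= 0) || any(diff(z_edges) <= 0))
    stop("grid edges must be strictly increasing", call. = FALSE)
  nr <- length(r_edges) - 1L; nz <- length(z_edges) - 1L
  if (is.character(material) && length(material) == 1L)
    material <- matrix(material, nr, nz)
  if (!is.matrix(material) || !identical(dim(material), c(nr, nz)))
    stop("material must be a (nr x nz) matrix of labels", call. = FALSE)
  r <- (r_edges[-1] + r_edges[-(nr + 1L)]) / 2
  z <- (z_edges[-1] + z_edges[-(nz + 1L)]) / 2
  dr <- diff(r_edges); dz <- diff(z_edges)
  vol <- outer(pi * (r_edges[-1]^2 - r_edges[-(nr + 1L)]^2), dz)
  g <- list(r_edges = r_edges, z_edges = z_edges, r = r, z = z,
            dr = dr, dz = dz, nr = nr, nz = nz,
            material = material, cell_volumes = vol,
            geometry = geometry, policy = policy)
  class(g) <- "domain_grid"
  g
}

#' Rasterize a geometry onto a graded axisymmetric grid
#'
#' Grid lines are forced onto every material interface (needle layer radii,
#' tip and slot heights, tumor extent), so each applicator layer is resolved by
#' at least one cell column; between interfaces the spacing grows geometrically
#' from the policy's finest size near the needle features to the cap. Each
#' cell takes the material of the region containing its centre.
#'
#' @param geometry a [build_geometry()] result.
#' @param policy a [resolution_policy()].
#' @return a [domain_grid()].
#' @export
rasterize <- function(geometry, policy = resolution_policy()) {
  stopifnot(inherits(geometry, "em_geometry"))
  n <- geometry$needle; d <- geometry$domain
  if (policy$min_cell > n$slot_width / 2)
    stop("minimum cell size must be <= half the slot width", call. = FALSE)
  layers <- c(inner_conductor = n$inner_conductor_radius,
              dielectric = n$dielectric_outer_radius - n$inner_conductor_radius,
              outer_conductor = n$outer_conductor_outer_radius - n$dielectric_outer_radius,
              catheter = n$catheter_outer_radius - n$outer_conductor_outer_radius)
  too_thin <- layers < policy$min_cell / 2 * (1 - 1e-9)
  if (any(too_thin))
    stop("resolution too coarse to resolve needle layer(s): ",
         paste(names(layers)[too_thin], collapse = ", "), call. = FALSE)
  r_breaks <- c(0, n$inner_conductor_radius, n$dielectric_outer_radius,
                n$outer_conductor_outer_radius, n$catheter_outer_radius,
                d$domain_radius)
  r_feats <- r_breaks[2:5]
  zc <- n$slot_center_offset_from_tip; w2 <- n$slot_width / 2
  z_breaks <- c(d$z_min, 0, n$tip_length, zc - w2, zc + w2, d$z_max)
  if (d$case_kind == "clinical")
    z_breaks <- c(z_breaks, d$tumor_center_z - d$tumor_half_length,
                  d$tumor_center_z + d$tumor_half_length)
  z_breaks <- z_breaks[z_breaks >= d$z_min & z_breaks <= d$z_max]
  z_feats <- c(0, n$tip_length, zc - w2, zc + w2)
  r_edges <- axis_lines(r_breaks, r_feats, policy)
  z_edges <- axis_lines(z_breaks, z_feats, policy)
  nr <- length(r_edges) - 1L; nz <- length(z_edges) - 1L
  rc <- (r_edges[-1] + r_edges[-(nr + 1L)]) / 2
  zcn <- (z_edges[-1] + z_edges[-(nz + 1L)]) / 2
  mat <- matrix(material_at(geometry, rep(rc, nz), rep(zcn, each = nr)), nr, nz)
  domain_grid(r_edges, z_edges, mat, geometry = geometry, policy = policy)
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("<domain_grid> %d x %d cells (r x z), %d total\n",
              x$nr, x$nz, x$nr * x$nz))
  cat(sprintf("  r in [0, %.2f] mm, z in [%.2f, %.2f] mm\n",
              1e3 * max(x$r_edges), 1e3 * min(x$z_edges), 1e3 * max(x$z_edges)))
  cat(sprintf("  cell sizes: dr %.3g..%.3g mm, dz %.3g..%.3g mm\n",
              1e3 * min(x$dr), 1e3 * max(x$dr), 1e3 * min(x$dz), 1e3 * max(x$dz)))
  cat("  materials:", paste(sort(unique(as.vector(x$material))), collapse = ", "), "\n")
  invisible(x)
}

# logical matrix helpers over grids
grid_material_flag <- function(grid, materials, field) {
  vals <- vapply(materials, `[[`, logical(1), field)
  matrix(vals[grid$material], grid$nr, grid$nz)
}

grid_material_value <- function(grid, materials, field) {
  vals <- vapply(materials, `[[`, numeric(1), field)
  matrix(vals[grid$material], grid$nr, grid$nz)
}
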