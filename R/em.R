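#' EM solver configuration
#'
#' @param frequency operating microwave frequency (Hz).
#' @param input_power power delivered at the applicator (W); used by
#'   [normalize_to_input_power()].
#' @param absorbing_boundary_thickness number of stretched-coordinate absorbing
#'   cells padded beyond the outer radial and bottom axial boundaries.
#' @param excitation excitation type; only the impressed coax-port TEM profile
#'   is implemented.
#' @return an object of class `em_config`.
#' @export
em_config <- function(frequency = 2.45e9, input_power = 35,
                      absorbing_boundary_thickness = 16L,
                      excitation = "coax_port") {
  stopifnot(frequency > 0, input_power >= 0)
  excitation <- match.arg(excitation, "coax_port")
  structure(list(frequency = frequency, input_power = input_power,
                 absorbing_boundary_thickness = as.integer(absorbing_boundary_thickness),
                 excitation = excitation),
            class = "em_config")
}

# complex relative permittivity eps_r - i sigma / (omega eps0)
complex_permittivity <- function(eps_r, sigma, omega) {
  eps_r - 1i * sigma / (omega * .eps0)
}

# polynomial stretched-coordinate profile: s = 1 - i smax d^3 over the layer
pml_stretch <- function(depth_frac, smax = 5, m = 3) {
  1 - 1i * smax * pmax(depth_frac, 0)^m
}

# pad a grid for the EM solve: replicate edge materials outward in +r and -z
.pad_em_grid <- function(grid, n_pml) {
  dr_last <- grid$dr[grid$nr]
  dz_first <- grid$dz[1]
  r_edges <- c(grid$r_edges, max(grid$r_edges) + dr_last * seq_len(n_pml))
  z_edges <- c(min(grid$z_edges) - dz_first * rev(seq_len(n_pml)), grid$z_edges)
  mat <- grid$material
  mat <- rbind(mat, matrix(rep(mat[grid$nr, ], each = n_pml), n_pml, grid$nz))
  mat <- cbind(matrix(rep(mat[, 1], times = n_pml), nrow(mat), n_pml), mat)
  list(r_edges = r_edges, z_edges = z_edges, material = mat,
       nr = grid$nr + n_pml, nz = grid$nz + n_pml,
       phys_r = seq_len(grid$nr), phys_z = n_pml + seq_len(grid$nz))
}

#' Solve the axisymmetric frequency-domain EM problem
#'
#' Solves for the azimuthal magnetic field H_phi(r, z) of the coaxial monopole
#' (the axisymmetric TM mode) with cell-centred finite volumes:
#' d/dr\[a (1/r) d(r H)/dr\] + d/dz\[a dH/dz\] + k0^2 H = 0 with
#' a = 1 / eps_r_complex. Copper is a perfect electric conductor (a = 0, which
#' enforces zero tangential E on its faces and H = 0 inside). A unit-amplitude
#' transverse-electromagnetic 1/r profile is impressed across the coax
#' dielectric at the top boundary; the outer radial and bottom boundaries carry
#' stretched-coordinate absorbing layers. The absolute power scale is set
#' afterwards by [normalize_to_input_power()].
#'
#' @param grid a [rasterize()]d `domain_grid` resolving all needle layers.
#' @param materials a [build_material_table()].
#' @param config an [em_config()].
#' @return an object of class `em_field` with complex `H`, `Er`, `Ez` (V/m per
#'   unit port amplitude) and `Emag2 = |E|^2` on the physical grid.
#' @export
solve_em <- function(grid, materials, config = em_config()) {
  stopifnot(inherits(grid, "domain_grid"), inherits(materials, "material_table"))
  omega <- 2 * pi * config$frequency
  k0 <- omega / .c0
  # wavelength sampling check: >= 10 cells per wavelength in the densest
  # medium actually present on the grid
  present <- unique(as.vector(grid$material))
  eps_max <- max(vapply(materials[present], function(m)
    if (m$is_pec) 1 else m$relative_permittivity, numeric(1)))
  lam_min <- .c0 / (config$frequency * sqrt(eps_max))
  h_max <- max(grid$dr, grid$dz)
  if (h_max > lam_min / 10)
    stop(sprintf(paste0("resolution error: max cell %.3g mm exceeds lambda/10 = ",
                        "%.3g mm in the highest-permittivity material"),
                 1e3 * h_max, 1e3 * lam_min / 10), call. = FALSE)

  n_pml <- config$absorbing_boundary_thickness
  pg <- .pad_em_grid(grid, n_pml)
  nr <- pg$nr; nz <- pg$nz
  r_edges <- pg$r_edges; z_edges <- pg$z_edges
  rc <- (r_edges[-1] + r_edges[-(nr + 1L)]) / 2
  zc <- (z_edges[-1] + z_edges[-(nz + 1L)]) / 2
  dr <- diff(r_edges); dz <- diff(z_edges)

  eps_r <- vapply(materials, `[[`, numeric(1), "relative_permittivity")
  sig <- vapply(materials, `[[`, numeric(1), "electric_conductivity")
  pec <- vapply(materials, `[[`, logical(1), "is_pec")
  epsc <- complex_permittivity(eps_r, sig, omega)
  a_mat <- ifelse(pec, 0 + 0i, 1 / epsc)
  a <- matrix(a_mat[pg$material], nr, nz)

  # stretch factors: radial layer over the outer n_pml columns, axial layer
  # over the bottom n_pml rows; needle columns are never inside a layer
  r0 <- r_edges[nr + 1L - n_pml]; rL <- r_edges[nr + 1L] - r0
  z0 <- z_edges[n_pml + 1L]; zL <- z0 - z_edges[1]
  sr_c <- pml_stretch((rc - r0) / rL)
  sz_c <- pml_stretch((z0 - zc) / zL)
  sr_f <- pml_stretch((r_edges - r0) / rL)   # at r faces (nr+1)
  sz_f <- pml_stretch((z0 - z_edges) / zL)   # at z faces (nz+1)

  hmean <- function(x, y) {
    s <- x + y
    out <- 2 * x * y
    out[Mod(s) > 0] <- out[Mod(s) > 0] / s[Mod(s) > 0]
    out[Mod(s) == 0] <- 0
    out
  }

  N <- nr * nz
  idx <- function(i, j) i + (j - 1L) * nr
  ii <- integer(0); jj <- integer(0); xx <- complex(0)
  rhs <- complex(N)
  add <- function(p, q, v) {
    ii <<- c(ii, p); jj <<- c(jj, q); xx <<- c(xx, v)
  }

  I <- rep(seq_len(nr), nz)
  J <- rep(seq_len(nz), each = nr)
  P <- idx(I, J)

  # ---- radial fluxes ----------------------------------------------------
  # interior faces between columns i and i+1 (face index i+1 in r_edges)
  fi <- seq_len(nr - 1L)
  a_f <- hmean(a[fi, , drop = FALSE], a[fi + 1L, , drop = FALSE])
  rf <- r_edges[fi + 1L]
  denom <- rf * (rc[fi + 1L] - rc[fi])
  # flux F = a_f/sr_f * (r_{i+1} u_{i+1} - r_i u_i) / (r_f dr_c)
  cf_hi <- sweep(a_f, 1, rc[fi + 1L] / denom / sr_f[fi + 1L], `*`)
  cf_lo <- sweep(a_f, 1, rc[fi] / denom / sr_f[fi + 1L], `*`)
  # contribution to cell (i, j): +(F_e) * dz / sr_c(i); to cell (i+1, j): -(F_w)...
  for (j in seq_len(nz)) {
    p_lo <- idx(fi, j); p_hi <- idx(fi + 1L, j)
    w_lo <- dz[j] / sr_c[fi]
    w_hi <- dz[j] / sr_c[fi + 1L]
    # cell i gains F_e * dz / sr_c(i)
    add(p_lo, p_hi, cf_hi[, j] * w_lo)
    add(p_lo, p_lo, -cf_lo[, j] * w_lo)
    # cell i+1 loses F_w * dz / sr_c(i+1)
    add(p_hi, p_hi, -cf_hi[, j] * w_hi)
    add(p_hi, p_lo, cf_lo[, j] * w_hi)
  }
  # axis face of column 1: F_w = a * 2 u_1 / r_1 (regularity, H ~ r)
  for (j in seq_len(nz)) {
    p <- idx(1L, j)
    add(p, p, -a[1L, j] * (2 / rc[1L]) * dz[j] / sr_c[1L])
  }
  # outer face of column nr: Dirichlet u = 0 beyond the absorbing layer
  rfN <- r_edges[nr + 1L]
  for (j in seq_len(nz)) {
    p <- idx(nr, j)
    cf <- a[nr, j] / sr_f[nr + 1L] * rc[nr] / (rfN * (rfN - rc[nr]))
    add(p, p, -cf * dz[j] / sr_c[nr])
  }

  # ---- axial fluxes -----------------------------------------------------
  fj <- seq_len(nz - 1L)
  a_fz <- hmean(a[, fj, drop = FALSE], a[, fj + 1L, drop = FALSE])
  dcz <- zc[fj + 1L] - zc[fj]
  for (j in fj) {
    p_lo <- idx(seq_len(nr), j); p_hi <- idx(seq_len(nr), j + 1L)
    cf <- a_fz[, j] / sz_f[j + 1L] / dcz[j]
    add(p_lo, p_hi, cf * dr / sz_c[j])
    add(p_lo, p_lo, -cf * dr / sz_c[j])
    add(p_hi, p_hi, -cf * dr / sz_c[j + 1L])
    add(p_hi, p_lo, cf * dr / sz_c[j + 1L])
  }
  # bottom face (j = 1): Dirichlet 0 beyond the absorbing layer
  cf <- a[, 1L] / sz_f[1L] / (zc[1L] - z_edges[1L])
  add(idx(seq_len(nr), 1L), idx(seq_len(nr), 1L), -cf * dr / sz_c[1L])
  # top face (j = nz): impressed port profile across the coax dielectric,
  # zero elsewhere (the shaft metal caps most of the needle cross-section)
  needle <- if (!is.null(grid$geometry)) grid$geometry$needle else NULL
  u_top <- complex(nr)
  if (!is.null(needle)) {
    in_port <- rc > needle$inner_conductor_radius &
      rc < needle$dielectric_outer_radius
    r_ref <- sqrt(needle$inner_conductor_radius * needle$dielectric_outer_radius)
    u_top[in_port] <- r_ref / rc[in_port]
  }
  cf <- a[, nz] / sz_f[nz + 1L] / (z_edges[nz + 1L] - zc[nz])
  pN <- idx(seq_len(nr), nz)
  add(pN, pN, -cf * dr / sz_c[nz])
  rhs[pN] <- rhs[pN] - cf * dr / sz_c[nz] * u_top

  # ---- Helmholtz term ---------------------------------------------------
  add(P, P, k0^2 * rep(dr, nz) * rep(dz, each = nr) + 0i)

  u <- .solve_complex_sparse(ii, jj, xx, rhs, N)
  if (any(!is.finite(Mod(u))))
    stop("solver error: non-finite EM solution", call. = FALSE)
  H <- matrix(u, nr, nz)

  # derived E components at cell centres: E = (a / (i omega eps0)) curl H
  fac <- a / (1i * omega * .eps0)
  dudz <- .central_diff(H, zc, along = 2L)
  v <- sweep(H, 1, rc, `*`)
  drv <- .central_diff(v, rc, along = 1L)
  Ez <- fac * sweep(drv, 1, rc, `/`)
  Er <- -fac * dudz
  pr <- pg$phys_r; pz <- pg$phys_z
  H <- H[pr, pz]; Er <- Er[pr, pz]; Ez <- Ez[pr, pz]
  Emag2 <- Mod(Er)^2 + Mod(Ez)^2
  structure(list(H = H, Er = Er, Ez = Ez, Emag2 = Emag2,
                 frequency = config$frequency, grid = grid,
                 port_amplitude = 1),
            class = "em_field")
}

# central differences on a nonuniform axis, one-sided at the ends
.central_diff <- function(M, x, along = 1L) {
  if (along == 2L) return(t(.central_diff(t(M), x, along = 1L)))
  n <- nrow(M)
  out <- M * 0
  if (n == 1L) return(out)
  out[1, ] <- (M[2, ] - M[1, ]) / (x[2] - x[1])
  out[n, ] <- (M[n, ] - M[n - 1, ]) / (x[n] - x[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1L)
    out[i, ] <- (M[i + 1L, ] - M[i - 1L, ]) / (x[i + 1L] - x[i - 1L])
  }
  out
}

# solve a complex sparse system through the equivalent 2N real system
.solve_complex_sparse <- function(ii, jj, xx, rhs, N) {
  re <- Re(xx); im <- Im(xx)
  A <- Matrix::sparseMatrix(
    i = c(ii, ii, ii + N, ii + N),
    j = c(jj, jj + N, jj, jj + N),
    x = c(re, -im, im, re),
    dims = c(2L * N, 2L * N))
  b <- c(Re(rhs), Im(rhs))
  sol <- Matrix::solve(A, b)
  sol <- as.numeric(sol)
  complex(real = sol[seq_len(N)], imaginary = sol[N + seq_len(N)])
}

#' @export
print.em_field <- function(x, ...) {
  cat(sprintf("<em_field> %.3g GHz, %d x %d cells, max |E| = %.3g (per unit port amplitude)\n",
              x$frequency / 1e9, nrow(x$H), ncol(x$H), sqrt(max(x$Emag2))))
  invisible(x)
}

#' Volumetric heat source (SAR) from the EM field
#'
#' Dielectric heating Qext = sigma |E|^2 / 2 per cell, with sigma taken from
#' each cell's material.
#'
#' @param field an [solve_em()] result.
#' @param grid the same `domain_grid` the field was solved on.
#' @param materials the [build_material_table()] used.
#' @return an object of class `sar_field` with the cell-wise source `Q`
#'   (W/m^3) and the revolved-volume integral `total_power` (W).
#' @export
compute_sar <- function(field, grid, materials) {
  stopifnot(inherits(field, "em_field"))
  if (!identical(dim(field$Emag2), dim(grid$material)))
    stop("field and grid are not congruent", call. = FALSE)
  sig <- grid_material_value(grid, materials, "electric_conductivity")
  Q <- sig * field$Emag2 / 2
  structure(list(Q = Q, total_power = sum(Q * grid$cell_volumes), grid = grid),
            class = "sar_field")
}

#' Rescale a SAR field to a prescribed delivered power
#'
#' Multiplies the heat source so that its revolved volume integral equals the
#' power delivered at the applicator (e.g. 35 W for the phantom case, 42 W for
#' the clinical case). This power-conservation contract replaces an explicit
#' port-impedance calibration.
#'
#' @param sar a [compute_sar()] result.
#' @param grid the matching `domain_grid`.
#' @param Pin delivered power (W, > 0).
#' @return the rescaled `sar_field` (with a `scale` attribute).
#' @export
normalize_to_input_power <- function(sar, grid, Pin) {
  stopifnot(inherits(sar, "sar_field"), Pin > 0)
  tot <- sum(sar$Q * grid$cell_volumes)
  if (!is.finite(tot) || tot <= 0)
    stop("normalization error: zero absorbed power (sigma = 0 everywhere or EM failure)",
         call. = FALSE)
  s <- Pin / tot
  out <- sar
  out$Q <- sar$Q * s
  out$total_power <- Pin
  attr(out, "scale") <- s
  out
}

#' @export
print.sar_field <- function(x, ...) {
  cat(sprintf("<sar_field> total absorbed power %.6g W, max Q = %.3g W/m^3\n",
              x$total_power, max(x$Q)))
  invisible(x)
}

#' One-dimensional lossy-slab verification harness
#'
#' Solves the 1D layered-slab Helmholtz problem
#' d/dx\[(1/eps_c) dH/dx\] + k0^2 H = 0 with the same complex-permittivity and
#' stretched-boundary machinery as the axisymmetric kernel: unit Dirichlet
#' excitation on the left, absorbing layer on the right. Used to verify the
#' numerical attenuation in a homogeneous lossy medium against the closed-form
#' plane-wave attenuation constant.
#'
#' @param eps_r,sigma relative permittivity and conductivity per layer;
#'   recycled across `layers` equal slabs.
#' @param frequency frequency (Hz).
#' @param length total slab length (m).
#' @param dx cell size (m).
#' @param pml_cells absorbing cells appended on the right.
#' @return list with `x` (cell centres), complex `H`, and `alpha_fit`
#'   (Np/m, from a log-amplitude fit over the central portion).
#' @export
plane_wave_slab <- function(eps_r, sigma, frequency = 2.45e9, length = 0.08,
                            dx = 5e-4, pml_cells = 32L) {
  omega <- 2 * pi * frequency
  k0 <- omega / .c0
  n <- as.integer(round(length / dx))
  layer <- rep(seq_along(eps_r), each = ceiling(n / max(1L, base::length(eps_r))))[seq_len(n)]
  epsc <- complex_permittivity(eps_r[layer], sigma[layer], omega)
  ntot <- n + pml_cells
  epsc <- c(epsc, rep(epsc[n], pml_cells))
  a <- 1 / epsc
  s_c <- c(rep(1 + 0i, n), pml_stretch(seq_len(pml_cells) / pml_cells))
  s_f <- c(rep(1 + 0i, n + 1L),
           pml_stretch(seq_len(pml_cells) / pml_cells))
  ii <- integer(0); jj <- integer(0); xx <- complex(0)
  add <- function(p, q, v) { ii <<- c(ii, p); jj <<- c(jj, q); xx <<- c(xx, v) }
  rhs <- complex(ntot)
  hm <- function(x, y) ifelse(Mod(x + y) > 0, 2 * x * y / (x + y), 0)
  for (f in seq_len(ntot - 1L)) {  # face between cells f, f+1
    cf <- hm(a[f], a[f + 1L]) / (dx * s_f[f + 1L])
    add(f, f + 1L, cf / s_c[f]); add(f, f, -cf / s_c[f])
    add(f + 1L, f + 1L, -cf / s_c[f + 1L]); add(f + 1L, f, cf / s_c[f + 1L])
  }
  cf <- a[1L] / (dx / 2)  # left Dirichlet u = 1
  add(1L, 1L, -cf); rhs[1L] <- -cf
  cf <- a[ntot] / (dx / 2 * s_f[ntot + 1L]) / s_c[ntot]  # right Dirichlet 0
  add(ntot, ntot, -cf)
  add(seq_len(ntot), seq_len(ntot), rep(k0^2 * dx + 0i, ntot))
  u <- .solve_complex_sparse(ii, jj, xx, rhs, ntot)
  x <- (seq_len(ntot) - 0.5) * dx
  keep <- seq_len(n)
  fit_lo <- which(x >= 0.15 * length)[1]
  fit_hi <- max(which(x <= 0.6 * length))
  sel <- fit_lo:fit_hi
  alpha <- -coef(lm(log(Mod(u[sel])) ~ x[sel]))[[2]]
  list(x = x[keep], H = u[keep], alpha_fit = alpha)
}

#' Closed-form plane-wave attenuation constant in a lossy medium
#'
#' alpha = omega * sqrt(mu eps/2 * (sqrt(1 + (sigma/(omega eps))^2) - 1)),
#' in Np/m.
#'
#' @param eps_r relative permittivity.
#' @param sigma conductivity (S/m).
#' @param frequency frequency (Hz).
#' @return attenuation constant (Np/m).
#' @export
plane_wave_attenuation <- function(eps_r, sigma, frequency = 2.45e9) {
  omega <- 2 * pi * frequency
  eps <- eps_r * .eps0
  omega * sqrt(.mu0 * eps / 2 * (sqrt(1 + (sigma / (omega * eps))^2) - 1))
}
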