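# shared fixtures and independent oracles for the test suite

# reduced phantom domain: same needle, smaller tank, coarser cap -- keeps EM
# and bioheat solves fast while still resolving every applicator layer
small_domain <- function(case = "phantom", ...) {
  domain_spec(case, domain_radius = 20e-3, domain_height = 55e-3,
              tip_clearance = 12e-3, ...)
}

small_policy <- function(min_cell = 2e-4, max_cell = 1.2e-3, pml = 10L) {
  resolution_policy(min_cell = min_cell, max_cell = max_cell, pml_cells = pml)
}

# memoized expensive fixtures
.fix <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

small_phantom_grid <- function() memo("grid", {
  rasterize(build_geometry(needle_spec(), small_domain()), small_policy())
})

small_phantom_sar <- function() memo("sar", {
  g <- small_phantom_grid()
  mat <- build_material_table("phantom")
  f <- solve_em(g, mat, em_config(absorbing_boundary_thickness = 10L))
  normalize_to_input_power(compute_sar(f, g, mat), g, 35)
})

# homogeneous liver block on a uniform grid (no needle)
block_grid <- function(nr = 25L, nz = 25L, h = 1e-3) {
  domain_grid(r_edges = seq(0, nr * h, by = h),
              z_edges = seq(0, nz * h, by = h), material = "liver")
}

# craft a temperature history without running the solver
make_history <- function(times, field_fun, grid) {
  fields <- lapply(times, function(t)
    matrix(field_fun(t), grid$nr, grid$nz))
  structure(list(times = times, fields = fields,
                 max_field = Reduce(pmax, fields), grid = grid,
                 config = NULL, energy_residuals = numeric(0)),
            class = "temperature_history")
}

# closed-form Arrhenius quantities (independent of the integrator)
omega_closed_form <- function(T_celsius, t_seconds,
                              A = 7.39e39, Ea = 2.577e5, R = 8.3145) {
  A * t_seconds * exp(-Ea / (R * (T_celsius + 273.15)))
}

# brute-force all-pairs surface-distance + overlap oracle for small masks
oracle_metrics <- function(A, B, spacing) {
  surf <- function(m) {
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (k in seq_len(nrow(idx))) {
      p <- idx[k, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + s
        if (any(q < 1) || any(q > d) || !m[q[1], q[2], q[3]]) keep[k] <- TRUE
      }
    }
    idx[keep, , drop = FALSE]
  }
  sA <- surf(A); sB <- surf(B)
  dmat <- matrix(0, nrow(sA), nrow(sB))
  for (k in seq_len(nrow(sA)))
    dmat[k, ] <- sqrt(colSums((t(sB) - sA[k, ])^2))
  dAB <- apply(dmat, 1, min)
  dBA <- apply(dmat, 2, min)
  list(dice = 2 * sum(A & B) / (sum(A) + sum(B)),
       hausdorff_mm = 1e3 * spacing * max(max(dAB), max(dBA)),
       mean_euclidean_mm = 1e3 * spacing * mean(c(dAB, dBA)))
}

# wrap a logical matrix as a zone_mask
zone_mask_for_test <- function(m, g) {
  structure(list(mask = m, grid = g, model = "test"), class = "zone_mask")
}

# 4-connected flood fill on a logical matrix; TRUE if mask is one component
single_component <- function(m) {
  if (!any(m)) return(FALSE)
  lab <- matrix(0L, nrow(m), ncol(m))
  start <- which(m, arr.ind = TRUE)[1, ]
  stack <- list(start)
  lab[start[1], start[2]] <- 1L
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
          m[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
        lab[q[1], q[2]] <- 1L
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  sum(lab == 1L) == sum(m)
}
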