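#' Thermal transient configuration
#'
#' @param duration simulated ablation time (s).
#' @param time_step implicit time step (s).
#' @param snapshot_interval cadence at which temperature fields are stored (s);
#'   also the cadence the damage integral is evaluated on.
#' @param initial_temperature initial (and far-boundary) temperature (K),
#'   either a scalar or a full (nr x nz) field; `NULL` takes the value from
#'   the domain spec when available.
#' @param blood a [blood_properties()]; `NULL` takes the material-table record.
#' @param coolant_temperature circulating-water temperature (degrees C);
#'   `NULL` takes the needle spec value.
#' @param coolant_heat_transfer_coefficient Robin coefficient at the needle
#'   wall (W/(m^2 K)); `NULL` takes the needle spec value.
#' @param include_perfusion,include_metabolic switch the Pennes perfusion sink
#'   and metabolic source on (clinical) or off (phantom).
#' @param outer_boundary `"dirichlet"` holds the outer domain walls at the
#'   initial temperature; `"insulated"` makes them adiabatic (verification).
#' @param conduction test hook: set `FALSE` to suppress heat conduction and
#'   isolate the perfusion relaxation.
#' @return an object of class `thermal_config`.
#' @export
thermal_config <- function(duration = 600, time_step = 0.5,
                           snapshot_interval = 1,
                           initial_temperature = NULL,
                           blood = NULL,
                           coolant_temperature = NULL,
                           coolant_heat_transfer_coefficient = NULL,
                           include_perfusion = FALSE,
                           include_metabolic = FALSE,
                           outer_boundary = c("dirichlet", "insulated"),
                           conduction = TRUE) {
  stopifnot(duration >= 0, time_step > 0, snapshot_interval > 0)
  structure(list(duration = duration, time_step = time_step,
                 snapshot_interval = snapshot_interval,
                 initial_temperature = initial_temperature,
                 blood = blood,
                 coolant_temperature = coolant_temperature,
                 coolant_heat_transfer_coefficient = coolant_heat_transfer_coefficient,
                 include_perfusion = isTRUE(include_perfusion),
                 include_metabolic = isTRUE(include_metabolic),
                 outer_boundary = match.arg(outer_boundary),
                 conduction = isTRUE(conduction)),
            class = "thermal_config")
}

#' Probe locations in the (r, z) half-plane
#'
#' @param r,z probe coordinates (m).
#' @param labels probe names.
#' @return an object of class `probe_set` (a data frame).
#' @export
probe_set <- function(r, z, labels = NULL) {
  stopifnot(length(r) == length(z), all(r >= 0))
  if (is.null(labels)) labels <- paste0("probe", seq_along(r))
  structure(data.frame(label = labels, r = r, z = z),
            class = c("probe_set", "data.frame"))
}

#' Default probe sets
#'
#' Phantom probes mirror the fiber-optic sensors (10 mm and 20 mm from the
#' axis, 18 mm above the tip) plus the evaluation point 5 mm from the axis,
#' 20 mm above the tip.
#'
#' @param case_kind `"phantom"` or `"clinical"`.
#' @return a [probe_set()].
#' @export
default_probe_set <- function(case_kind = c("phantom", "clinical")) {
  case_kind <- match.arg(case_kind)
  probe_set(r = c(10e-3, 20e-3, 5e-3),
            z = c(18e-3, 18e-3, 20e-3),
            labels = c("sensor_10mm", "sensor_20mm", "eval_5mm"))
}

#' Integrate Pennes' bioheat equation on the axisymmetric grid
#'
#' Solves rho_T C_T dT/dt = k_T lap(T) + rho_b C_b omega_b (T_b - T) + Qm +
#' Qext on the tissue cells of the grid with an unconditionally stable implicit
#' (backward Euler) finite-volume scheme. Needle-interior cells are excluded;
#' tissue faces adjoining them carry the convective coolant condition
#' h (T_cool - T). Outer domain walls are held at the initial temperature by
#' default. Vaporization enthalpy and temperature-dependent properties are not
#' modelled.
#'
#' @param grid a `domain_grid`.
#' @param materials a [build_material_table()].
#' @param source a normalized [compute_sar()] field, or `NULL` for no heating.
#' @param config a [thermal_config()].
#' @return an object of class `temperature_history`: snapshot `times` (s),
#'   `fields` (list of (nr x nz) matrices, K; `NA` inside the needle), the
#'   running maximum field `max_field`, the per-step energy-balance residual
#'   and the grid.
#' @export
run_transient <- function(grid, materials, source = NULL,
                          config = thermal_config()) {
  stopifnot(inherits(grid, "domain_grid"), inherits(materials, "material_table"))
  nr <- grid$nr; nz <- grid$nz
  geom <- grid$geometry
  T0 <- config$initial_temperature
  if (is.null(T0)) {
    T0 <- if (!is.null(geom)) geom$domain$initial_temperature else
      stop("initial temperature required when the grid has no geometry", call. = FALSE)
  }
  # scalar or full (nr x nz) field; outer Dirichlet walls hold the local value
  T0m <- if (is.matrix(T0)) {
    if (!identical(dim(T0), c(nr, nz)))
      stop("initial temperature field must match the grid", call. = FALSE)
    T0
  } else matrix(T0, nr, nz)
  blood <- config$blood
  if (is.null(blood)) blood <- attr(materials, "blood")
  if (config$include_perfusion && is.null(blood))
    stop("configuration error: blood properties required when perfusion is on",
         call. = FALSE)
  h_cool <- config$coolant_heat_transfer_coefficient
  T_cool <- config$coolant_temperature
  if (!is.null(geom)) {
    if (is.null(h_cool)) h_cool <- geom$needle$coolant_heat_transfer_coefficient
    if (is.null(T_cool)) T_cool <- geom$needle$coolant_temperature
  }
  if (is.null(h_cool)) h_cool <- 0
  if (is.null(T_cool)) T_cool <- 20
  T_cool_K <- T_cool + 273.15

  in_needle <- grid_material_flag(grid, materials, "in_needle")
  tissue <- !in_needle
  M <- sum(tissue)
  map <- matrix(NA_integer_, nr, nz)
  map[tissue] <- seq_len(M)

  rho <- grid_material_value(grid, materials, "density")
  Cp <- grid_material_value(grid, materials, "specific_heat")
  kT <- grid_material_value(grid, materials, "thermal_conductivity")
  omg <- grid_material_value(grid, materials, "perfusion_rate")
  Qm <- grid_material_value(grid, materials, "metabolic_heat")
  V <- grid$cell_volumes
  dt <- config$time_step

  # heat capacity per cell and constant source terms
  Cvol <- rho * Cp * V
  perf <- if (config$include_perfusion)
    blood$density * blood$specific_heat * omg * V else matrix(0, nr, nz)
  b0 <- matrix(0, nr, nz)
  if (config$include_perfusion) b0 <- b0 + perf * blood$temperature
  if (config$include_metabolic) b0 <- b0 + Qm * V
  if (!is.null(source)) {
    stopifnot(inherits(source, "sar_field"))
    if (!identical(dim(source$Q), dim(grid$material)))
      stop("source and grid are not congruent", call. = FALSE)
    b0 <- b0 + source$Q * V
  }

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_extra <- numeric(M)
  b_fixed <- b0[tissue]
  hmean <- function(x, y) ifelse(x + y > 0, 2 * x * y / (x + y), 0)

  if (config$conduction) {
    r_edges <- grid$r_edges; dz <- grid$dz; dr <- grid$dr
    rc <- grid$r; zc <- grid$z
    # radial faces
    for (i in seq_len(nr - 1L)) {
      A_f <- 2 * pi * r_edges[i + 1L] * dz
      kf <- hmean(kT[i, ], kT[i + 1L, ])
      G <- kf * A_f / (rc[i + 1L] - rc[i])
      both <- tissue[i, ] & tissue[i + 1L, ]
      if (any(both)) {
        p <- map[i, both]; q <- map[i + 1L, both]; g <- G[both]
        ii <- c(ii, p, q, p, q); jj <- c(jj, p, q, q, p)
        xx <- c(xx, g, g, -g, -g)
      }
      # tissue face against a needle cell -> Robin coolant coupling
      rob_lo <- tissue[i, ] & in_needle[i + 1L, ]
      rob_hi <- in_needle[i, ] & tissue[i + 1L, ]
      if (any(rob_lo)) {
        p <- map[i, rob_lo]; g <- h_cool * A_f[rob_lo]
        diag_extra[p] <- diag_extra[p] + g
        b_fixed[p] <- b_fixed[p] + g * T_cool_K
      }
      if (any(rob_hi)) {
        p <- map[i + 1L, rob_hi]; g <- h_cool * A_f[rob_hi]
        diag_extra[p] <- diag_extra[p] + g
        b_fixed[p] <- b_fixed[p] + g * T_cool_K
      }
    }
    # axial faces
    ring <- pi * (r_edges[-1]^2 - r_edges[-(nr + 1L)]^2)
    for (j in seq_len(nz - 1L)) {
      kf <- hmean(kT[, j], kT[, j + 1L])
      G <- kf * ring / (zc[j + 1L] - zc[j])
      both <- tissue[, j] & tissue[, j + 1L]
      if (any(both)) {
        p <- map[both, j]; q <- map[both, j + 1L]; g <- G[both]
        ii <- c(ii, p, q, p, q); jj <- c(jj, p, q, q, p)
        xx <- c(xx, g, g, -g, -g)
      }
      rob_lo <- tissue[, j] & in_needle[, j + 1L]
      rob_hi <- in_needle[, j] & tissue[, j + 1L]
      if (any(rob_lo)) {
        p <- map[rob_lo, j]; g <- h_cool * ring[rob_lo]
        diag_extra[p] <- diag_extra[p] + g
        b_fixed[p] <- b_fixed[p] + g * T_cool_K
      }
      if (any(rob_hi)) {
        p <- map[rob_hi, j + 1L]; g <- h_cool * ring[rob_hi]
        diag_extra[p] <- diag_extra[p] + g
        b_fixed[p] <- b_fixed[p] + g * T_cool_K
      }
    }
    # outer walls (r = R, z = z_min, z = z_max) at the initial temperature
    if (config$outer_boundary == "dirichlet") {
      A_out <- 2 * pi * r_edges[nr + 1L] * dz
      sel <- which(tissue[nr, ])
      if (length(sel)) {
        g <- kT[nr, sel] * A_out[sel] / (r_edges[nr + 1L] - rc[nr])
        p <- map[nr, sel]
        diag_extra[p] <- diag_extra[p] + g
        b_fixed[p] <- b_fixed[p] + g * T0m[nr, sel]
      }
      for (jb in c(1L, nz)) {
        sel <- which(tissue[, jb])
        if (length(sel)) {
          dzb <- if (jb == 1L) zc[1] - grid$z_edges[1] else
            grid$z_edges[nz + 1L] - zc[nz]
          g <- kT[sel, jb] * ring[sel] / dzb
          p <- map[sel, jb]
          diag_extra[p] <- diag_extra[p] + g
          b_fixed[p] <- b_fixed[p] + g * T0m[sel, jb]
        }
      }
    }
  }

  Cv <- Cvol[tissue]
  pf <- perf[tissue]
  diag_all <- Cv / dt + pf + diag_extra
  ii <- c(ii, seq_len(M)); jj <- c(jj, seq_len(M)); xx <- c(xx, diag_all)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M, M))
  A <- Matrix::forceSymmetric(A)
  ch <- Matrix::Cholesky(A, LDL = FALSE)

  n_steps <- if (config$duration == 0) 0L else
    as.integer(ceiling(config$duration / dt - 1e-9))
  every <- max(1L, as.integer(round(config$snapshot_interval / dt)))

  Tn <- T0m[tissue]
  full <- function(v) { m <- matrix(NA_real_, nr, nz); m[tissue] <- v; m }
  times <- 0
  fields <- list(full(Tn))
  Tmax <- Tn
  ebal <- numeric(0)
  for (s in seq_len(n_steps)) {
    b <- Cv / dt * Tn + b_fixed
    Tn1 <- as.numeric(Matrix::solve(ch, b))
    if (any(!is.finite(Tn1)))
      stop("divergence error at step ", s, ": non-finite temperatures", call. = FALSE)
    # discrete energy balance residual (relative): dH - dt * net power
    dH <- sum(Cv * (Tn1 - Tn))
    Pnet <- sum(b_fixed - (pf + diag_extra) * Tn1)
    ebal <- c(ebal, (dH - dt * Pnet) / max(abs(dH), 1e-12))
    Tn <- Tn1
    Tmax <- pmax(Tmax, Tn)
    if (s %% every == 0L || s == n_steps) {
      times <- c(times, s * dt)
      fields[[length(fields) + 1L]] <- full(Tn)
    }
  }
  structure(list(times = times, fields = fields, max_field = full(Tmax),
                 grid = grid, config = config,
                 energy_residuals = ebal),
            class = "temperature_history")
}

#' @export
print.temperature_history <- function(x, ...) {
  cat(sprintf("<temperature_history> %d snapshots over %.1f s, peak %.2f degC\n",
              length(x$times), max(x$times),
              max(x$max_field, na.rm = TRUE) - 273.15))
  invisible(x)
}

#' Sample a temperature history at probe locations
#'
#' Bilinear interpolation of every stored snapshot at the probe coordinates.
#'
#' @param history a [run_transient()] result.
#' @param probes a [probe_set()].
#' @return data frame with `time_s` and one column per probe (degrees C).
#' @export
sample_probes <- function(history, probes) {
  stopifnot(inherits(history, "temperature_history"),
            inherits(probes, "probe_set"))
  g <- history$grid
  out <- data.frame(time_s = history$times)
  for (k in seq_len(nrow(probes))) {
    pr <- probes$r[k]; pz <- probes$z[k]
    if (pr < min(g$r) - 1e-12 || pr > max(g$r) + 1e-12 ||
        pz < min(g$z) - 1e-12 || pz > max(g$z) + 1e-12)
      stop("probe '", probes$label[k], "' lies outside the grid", call. = FALSE)
    i <- findInterval(pr, g$r, rightmost.closed = TRUE)
    j <- findInterval(pz, g$z, rightmost.closed = TRUE)
    i <- min(max(i, 1L), g$nr - 1L); j <- min(max(j, 1L), g$nz - 1L)
    tr <- (pr - g$r[i]) / (g$r[i + 1L] - g$r[i])
    tz <- (pz - g$z[j]) / (g$z[j + 1L] - g$z[j])
    tr <- min(max(tr, 0), 1); tz <- min(max(tz, 0), 1)
    vals <- vapply(history$fields, function(f) {
      v <- (1 - tr) * (1 - tz) * f[i, j] + tr * (1 - tz) * f[i + 1L, j] +
        (1 - tr) * tz * f[i, j + 1L] + tr * tz * f[i + 1L, j + 1L]
      v
    }, numeric(1))
    if (anyNA(vals))
      stop("probe '", probes$label[k], "' touches needle-interior cells", call. = FALSE)
    out[[probes$label[k]]] <- vals - 273.15
  }
  out
}
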