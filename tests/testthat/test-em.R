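test_that("1D slab harness reproduces the closed-form attenuation in liver", {
  alpha_cf <- plane_wave_attenuation(43.03, 1.69, 2.45e9)
  res <- plane_wave_slab(43.03, 1.69, frequency = 2.45e9)
  expect_lt(abs(res$alpha_fit - alpha_cf) / alpha_cf, 0.02)
  # the published tissue constants put the attenuation near 48 Np/m
  expect_equal(alpha_cf, 48, tolerance = 0.01)
})

test_that("lossless medium absorbs zero power", {
  mat <- build_material_table("phantom", list(sigma_phantom = 0))
  g <- small_phantom_grid()
  f <- solve_em(g, mat, em_config(absorbing_boundary_thickness = 10L))
  s <- compute_sar(f, g, mat)
  expect_identical(s$total_power, 0)
  expect_true(all(s$Q == 0))
})

test_that("a fully shielded coax leaks no field into the tissue", {
  geo <- build_geometry(needle_spec(), small_domain())
  # close the radiating structure: gap, monopole coating and tip become copper
  geo$regions <- lapply(geo$regions, function(r) {
    if (r$label %in% c("dielectric", "tip") &&
        !(r$r0 == needle_spec()$inner_conductor_radius))  # keep the coax fill
      r$label <- "copper"
    r
  })
  g <- rasterize(geo, small_policy())
  mat <- build_material_table("phantom")
  f <- solve_em(g, mat, em_config(absorbing_boundary_thickness = 10L))
  outside <- matrix(g$r, g$nr, g$nz) > needle_spec()$catheter_outer_radius
  port_amp <- max(Mod(f$H))
  expect_lt(max(Mod(f$H[outside])) / port_amp, 1e-6)
})

test_that("SAR follows sigma |E|^2 / 2 and scales quadratically", {
  g <- domain_grid(c(0, 1e-3, 2e-3), c(0, 1e-3, 2e-3), "tumor")
  mat <- build_material_table("clinical")
  E <- matrix(100, 2, 2)
  f <- structure(list(H = E * 0i, Er = E + 0i, Ez = E * 0,
                      Emag2 = E^2, frequency = 2.45e9, grid = g),
                 class = "em_field")
  s <- compute_sar(f, g, mat)
  expect_equal(unique(as.vector(s$Q)), 2 * 100^2 / 2)  # 10 000 W/m^3
  f2 <- f; f2$Emag2 <- (2 * E)^2
  s2 <- compute_sar(f2, g, mat)
  expect_equal(s2$Q, 4 * s$Q)
  # sigma = 0 cell gives zero source
  g0 <- domain_grid(c(0, 1e-3, 2e-3), c(0, 1e-3, 2e-3), "dielectric")
  expect_true(all(compute_sar(f, g0, mat)$Q == 0))
  # shape mismatch is an error
  gbad <- domain_grid(c(0, 1e-3), c(0, 1e-3), "tumor")
  expect_error(compute_sar(f, gbad, mat), "congruent")
})

test_that("power normalization hits the delivered power to 1e-9 relative", {
  g <- small_phantom_grid()
  s <- small_phantom_sar()
  expect_lt(abs(sum(s$Q * g$cell_volumes) - 35) / 35, 1e-9)
  mat <- build_material_table("clinical")
  s42 <- normalize_to_input_power(s, g, 42)
  expect_lt(abs(sum(s42$Q * g$cell_volumes) - 42) / 42, 1e-9)
  # already-normalized field is returned unchanged
  s35 <- normalize_to_input_power(s, g, 35)
  expect_equal(s35$Q, s$Q, tolerance = 1e-12)
  # zero absorbed power cannot be normalized
  szero <- s; szero$Q <- s$Q * 0
  expect_error(normalize_to_input_power(szero, g, 35), "zero absorbed power")
})

test_that("normalized SAR at probe points is grid-converged", {
  geo <- build_geometry(needle_spec(), small_domain())
  mat <- build_material_table("phantom")
  qprobe <- function(pol) {
    g <- rasterize(geo, pol)
    f <- solve_em(g, mat, em_config(absorbing_boundary_thickness = 10L))
    s <- normalize_to_input_power(compute_sar(f, g, mat), g, 35)
    pts <- rbind(c(3e-3, 25e-3), c(5e-3, 20e-3), c(4e-3, 15e-3))
    # bilinear interpolation so both grids are probed at identical locations
    apply(pts, 1, function(p) {
      i <- findInterval(p[1], g$r); j <- findInterval(p[2], g$z)
      tr <- (p[1] - g$r[i]) / (g$r[i + 1] - g$r[i])
      tz <- (p[2] - g$z[j]) / (g$z[j + 1] - g$z[j])
      (1 - tr) * (1 - tz) * s$Q[i, j] + tr * (1 - tz) * s$Q[i + 1, j] +
        (1 - tr) * tz * s$Q[i, j + 1] + tr * tz * s$Q[i + 1, j + 1]
    })
  }
  q1 <- qprobe(small_policy(min_cell = 2e-4, max_cell = 1.2e-3))
  q2 <- qprobe(small_policy(min_cell = 1e-4, max_cell = 0.6e-3))
  expect_true(all(abs(q1 - q2) / q2 < 0.05))
})

test_that("wavelength sampling and config preconditions are enforced", {
  geo <- build_geometry(needle_spec(), small_domain())
  g <- rasterize(geo, resolution_policy(min_cell = 2e-4, max_cell = 2.5e-3))
  expect_error(solve_em(g, build_material_table("phantom"), em_config()),
               "resolution error")
  expect_error(em_config(frequency = -1))
  expect_error(em_config(input_power = -5))
})
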