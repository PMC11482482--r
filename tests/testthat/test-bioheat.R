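test_that("insulated no-source run stays at the initial temperature", {
  g <- block_grid()
  mat <- build_material_table("clinical")
  h <- run_transient(g, mat, NULL,
                     thermal_config(duration = 20, time_step = 1,
                                    initial_temperature = 310.15,
                                    outer_boundary = "insulated"))
  for (f in h$fields)
    expect_equal(max(abs(f - 310.15)), 0, tolerance = 1e-10)
})

test_that("perfusion-only relaxation follows the closed-form exponential", {
  g <- block_grid(10L, 10L)
  mat <- build_material_table("clinical")
  blood <- attr(mat, "blood")
  # conduction suppressed; T0 = 47 C, Tb = 37 C
  h <- run_transient(g, mat, NULL,
                     thermal_config(duration = 600, time_step = 0.5,
                                    initial_temperature = 320.15,
                                    include_perfusion = TRUE,
                                    conduction = FALSE,
                                    outer_boundary = "insulated"))
  tau_cf <- (1069 * 3600) / (1000 * 3639 * 0.00361)  # ~293 s from the tables
  expect_equal(tau_cf, 293, tolerance = 0.001)
  Tc <- vapply(h$fields, function(f) f[5, 5], numeric(1))
  # fitted time constant within 0.5% of the closed form
  t_end <- max(h$times)
  tau_fit <- -t_end / log((Tc[length(Tc)] - 310.15) / 10)
  expect_lt(abs(tau_fit - tau_cf) / tau_cf, 0.005)
  # trajectory matches 37 + 10 exp(-t/tau) pointwise
  expect_equal(Tc, 310.15 + 10 * exp(-h$times / tau_cf), tolerance = 0.002)
})

test_that("discrete energy balance closes every step under insulation", {
  g <- block_grid(15L, 15L)
  mat <- build_material_table("clinical")
  Q <- matrix(5e5, g$nr, g$nz)  # uniform 0.5 W/cm^3 source
  src <- structure(list(Q = Q, total_power = sum(Q * g$cell_volumes), grid = g),
                   class = "sar_field")
  h <- run_transient(g, mat, src,
                     thermal_config(duration = 30, time_step = 0.5,
                                    initial_temperature = 310.15,
                                    outer_boundary = "insulated"))
  expect_true(all(abs(h$energy_residuals) < 1e-3))
  # heating is monotone under a constant positive source
  Tc <- vapply(h$fields, function(f) f[8, 8], numeric(1))
  expect_true(all(diff(Tc) > 0))
})

test_that("zero-source temperatures respect the maximum principle", {
  g <- block_grid(20L, 20L)
  mat <- build_material_table("clinical")
  set.seed(7)
  T0 <- matrix(300 + 20 * runif(g$nr * g$nz), g$nr, g$nz)
  h <- run_transient(g, mat, NULL,
                     thermal_config(duration = 50, time_step = 1,
                                    initial_temperature = T0))
  lo <- min(T0); hi <- max(T0)
  for (f in h$fields) {
    expect_gte(min(f), lo - 1e-9)
    expect_lte(max(f), hi + 1e-9)
  }
  # running maximum dominates every snapshot pointwise
  for (f in h$fields)
    expect_true(all(h$max_field - f >= -1e-12))
})

test_that("probe temperatures are time-step converged", {
  g <- small_phantom_grid()
  mat <- build_material_table("phantom")
  s <- small_phantom_sar()
  run_dt <- function(dt) {
    h <- run_transient(g, mat, s, thermal_config(duration = 120, time_step = dt))
    tail(sample_probes(h, probe_set(5e-3, 20e-3, "p"))$p, 1)
  }
  T1 <- run_dt(1); T2 <- run_dt(0.5)
  expect_lt(abs(T1 - T2) / abs(T2), 0.005)
})

test_that("probe sampling interpolates bilinearly and validates locations", {
  g <- block_grid(3L, 3L, 1e-3)  # centres at 0.5, 1.5, 2.5 mm
  vals <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3, 3) + 273.15
  h <- make_history(0, function(t) vals, g)
  # exactly at a node
  expect_equal(sample_probes(h, probe_set(g$r[2], g$z[2], "n"))$n, vals[2, 2] - 273.15)
  # midpoint of four nodes with 10/20/40/50 -> 30
  p <- sample_probes(h, probe_set(1e-3, 1e-3, "m"))$m
  expect_equal(p, mean(c(10, 20, 40, 50)))
  expect_error(sample_probes(h, probe_set(9e-3, 1e-3, "out")), "out")
})

test_that("default phantom probes mirror the sensor layout", {
  ps <- default_probe_set("phantom")
  expect_true(all(c("sensor_10mm", "sensor_20mm") %in% ps$label))
  expect_equal(ps$r[ps$label == "sensor_10mm"], 10e-3)
  expect_equal(ps$z[ps$label == "sensor_10mm"], 18e-3)
  expect_equal(ps$r[ps$label == "sensor_20mm"], 20e-3)
  expect_equal(ps$z[ps$label == "sensor_20mm"], 18e-3)
})

test_that("perfusion without blood properties is a configuration error", {
  g <- block_grid(5L, 5L)
  mat <- build_material_table("clinical")
  attr(mat, "blood") <- NULL
  expect_error(run_transient(g, mat, NULL,
                             thermal_config(duration = 1, time_step = 1,
                                            initial_temperature = 310,
                                            include_perfusion = TRUE)),
               "blood properties")
})
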