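test_that("constant-temperature histories match the Arrhenius closed form", {
  g <- block_grid(3L, 3L)
  for (Tc in c(50, 60, 70, 90)) {
    hold <- 10
    h <- make_history(seq(0, hold, by = 0.5), function(t) Tc + 273.15, g)
    d <- arrhenius_integral(h)
    cf <- omega_closed_form(Tc, hold)
    expect_lt(abs(d$omega[1, 1] - cf) / cf, 0.001)
  }
})

test_that("time to unit damage at 60 C is ~3.42 s", {
  g <- block_grid(2L, 2L)
  h <- make_history(seq(0, 6, by = 0.01), function(t) 60 + 273.15, g)
  d <- arrhenius_integral(h)
  rate <- d$omega[1, 1] / 6            # constant integrand: Omega linear in t
  t_star <- 1 / rate
  t_cf <- exp(2.577e5 / (8.3145 * 333.15)) / 7.39e39
  expect_lt(abs(t_star - t_cf) / t_cf, 0.005)
  expect_equal(t_star, 3.42, tolerance = 0.01)
  # 37 C held 10 s accumulates ~2.9e-3
  h37 <- make_history(c(0, 10), function(t) 37 + 273.15, g)
  om37 <- arrhenius_integral(h37)$omega[1, 1]
  expect_equal(om37, omega_closed_form(37, 10))
  expect_equal(om37, 2.9e-3, tolerance = 0.05)
})

test_that("degenerate and malformed histories are handled", {
  g <- block_grid(2L, 2L)
  h0 <- make_history(0, function(t) 373.15, g)
  expect_true(all(arrhenius_integral(h0)$omega == 0))
  hbad <- make_history(c(0, 2, 1), function(t) 373.15, g)
  expect_error(arrhenius_integral(hbad), "increasing")
})

test_that("damage fraction is 1 - exp(-Omega)", {
  expect_equal(round(100 * damage_fraction(1)), 63)
  expect_identical(damage_fraction(0), 0)
  expect_equal(damage_fraction(2), 1 - exp(-2))
  expect_error(damage_fraction(-0.1), ">= 0")
  om <- seq(0, 20, by = 0.5)
  fr <- damage_fraction(om)
  expect_true(all(fr >= 0 & fr < 1))
  expect_true(all(diff(fr) > 0))  # monotone in Omega
})

test_that("Arrhenius mask thresholds strictly and stays connected for monotone fields", {
  g <- block_grid(30L, 30L)
  d <- structure(list(omega = matrix(1.0, g$nr, g$nz), fraction = NULL, grid = g,
                      params = damage_params()), class = "damage_field")
  expect_false(any(arrhenius_mask(d)$mask))  # Omega exactly 1 is not necrotic
  d$omega <- matrix(0, g$nr, g$nz)
  expect_false(any(arrhenius_mask(d)$mask))
  # radially decreasing field: brute-force threshold equals the mask and the
  # necrotic region is a single connected blob containing the peak
  rr <- outer(g$r, g$z, function(r, z) sqrt(r^2 + (z - 0.015)^2))
  d$omega <- 5 * exp(-(rr / 8e-3)^2)
  m <- arrhenius_mask(d)
  expect_identical(m$mask, d$omega > 1)
  expect_true(single_component(m$mask))
  expect_true(m$mask[which.max(d$omega)])
})

test_that("critical-temperature mask distinguishes running-max from final-time", {
  g <- block_grid(4L, 4L)
  # one cell reaches 61 C at mid-run then cools to 50 C
  fields <- list(matrix(310, 4, 4), matrix(310, 4, 4), matrix(310, 4, 4))
  fields[[2]][2, 2] <- 61 + 273.15
  fields[[3]][2, 2] <- 50 + 273.15
  h <- structure(list(times = c(0, 300, 600), fields = fields,
                      max_field = Reduce(pmax, fields), grid = g),
                 class = "temperature_history")
  m_max <- critical_temp_mask(h, damage_params(critical_mode = "max_over_time"))
  m_fin <- critical_temp_mask(h, damage_params(critical_mode = "final_time"))
  expect_true(m_max$mask[2, 2])
  expect_false(m_fin$mask[2, 2])
  expect_equal(sum(m_max$mask), 1)
  # all below 60 C -> empty mask
  hcold <- make_history(c(0, 600), function(t) 59 + 273.15, g)
  expect_false(any(critical_temp_mask(hcold)$mask))
})

test_that("Omega is additive in time and monotone in temperature", {
  g <- block_grid(2L, 2L)
  ramp <- function(t) 37 + 30 * (1 - exp(-t / 120)) + 273.15
  h_short <- make_history(seq(0, 300, by = 1), ramp, g)
  h_long <- make_history(seq(0, 600, by = 1), ramp, g)
  expect_true(all(arrhenius_integral(h_long)$omega >=
                    arrhenius_integral(h_short)$omega))
  hotter <- make_history(seq(0, 300, by = 1), function(t) ramp(t) + 5, g)
  expect_true(all(arrhenius_integral(hotter)$omega >
                    arrhenius_integral(h_short)$omega))
})

test_that("snapshot-cadence integration agrees with a 10x oversampled reference", {
  g <- block_grid(2L, 2L)
  # smooth saturating heating curve that lands near Omega ~ 1
  curve <- function(t) 37 + 23 * (1 - exp(-t / 150)) + 273.15
  om <- function(dt) arrhenius_integral(
    make_history(seq(0, 600, by = dt), curve, g))$omega[1, 1]
  o1 <- om(1); o01 <- om(0.1)
  expect_gt(o1, 0.1)  # the scenario exercises the steep part of the kinetics
  expect_lt(abs(o1 - o01) / o01, 0.005)
})
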