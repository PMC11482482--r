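test_that("synthetic reference zones are deterministic voxelized ellipsoids", {
  z <- generate_reference_zone(c(10e-3, 10e-3, 10e-3), voxel_spacing = 0.5e-3)
  vol_cf <- 4 / 3 * pi * (10e-3)^3
  expect_lt(abs(z$volume - vol_cf) / vol_cf, 0.02)
  z2 <- generate_reference_zone(c(10e-3, 10e-3, 10e-3), voxel_spacing = 0.5e-3)
  expect_identical(z$mask, z2$mask)
  # jittered zones are seed-deterministic and differ between seeds
  j1 <- generate_reference_zone(jitter = 1e-3, seed = 7)
  j2 <- generate_reference_zone(jitter = 1e-3, seed = 7)
  j3 <- generate_reference_zone(jitter = 1e-3, seed = 8)
  expect_identical(j1$mask, j2$mask)
  expect_false(identical(j1$mask, j3$mask))
  expect_error(generate_reference_zone(c(2e-3, 9e-3, 9e-3), voxel_spacing = 3e-3),
               "spacing")
})

test_that("a vessel defect cuts a through-hole along its axis", {
  z <- generate_reference_zone(
    c(10e-3, 10e-3, 10e-3), voxel_spacing = 0.5e-3,
    vessel_defect = list(radius = 1.5e-3, axis = c(0, 0, 1), offset = c(0, 0, 0)))
  full <- generate_reference_zone(c(10e-3, 10e-3, 10e-3), voxel_spacing = 0.5e-3)
  expect_lt(z$voxel_count, full$voxel_count)
  # no mask voxel lies within the defect radius of the axis line
  pts <- which(z$mask, arr.ind = TRUE)
  xyz <- sweep((pts - 1) * z$spacing, 2, z$origin, `+`)
  d_axis <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  expect_true(all(d_axis >= 1.5e-3 * (1 - 1e-9)))
  # in particular the axis line itself contains no voxels
  expect_false(any(d_axis < z$spacing / 2))
})

test_that("synthetic sensor curves follow the saturating-rise closed form", {
  s <- generate_sensor_series(asymptotic_temperature = 80,
                              initial_temperature = 17,
                              time_constant = 150, noise_sd = 0, duration = 600)
  expect_identical(s$temp_C[1], 17)
  at_tau <- s$temp_C[s$time_s == 150]
  expect_equal(at_tau, 17 + (80 - 17) * (1 - exp(-1)))
  expect_true(all(diff(s$temp_C) > 0))
  n1 <- generate_sensor_series(noise_sd = 0.5, seed = 3)
  n2 <- generate_sensor_series(noise_sd = 0.5, seed = 3)
  expect_identical(n1, n2)
  expect_false(identical(n1$temp_C,
                         generate_sensor_series(noise_sd = 0.5, seed = 4)$temp_C))
})

# coarse, short case used for the pipeline tests
mini_config <- function(case = "phantom", duration = 60, ...) {
  case_config(case,
              duration = duration,
              domain = list(domain_radius = 25e-3, domain_height = 55e-3,
                            tip_clearance = 12e-3),
              resolution = small_policy(),
              thermal = list(time_step = 1, snapshot_interval = 2),
              voxel_spacing = 1e-3, ...)
}

test_that("the phantom pipeline produces both damage models and is deterministic", {
  b1 <- run_case(mini_config())
  expect_s3_class(b1$masks$arrhenius, "zone_mask")
  expect_s3_class(b1$masks$critical_temp, "zone_mask")
  expect_s3_class(b1$volumes$arrhenius, "zone_volume")
  expect_s3_class(b1$volumes$critical_temp, "zone_volume")
  expect_true(all(c("sensor_10mm", "sensor_20mm") %in% names(b1$probes)))
  b2 <- run_case(mini_config())
  expect_identical(b1$probes, b2$probes)
  expect_identical(b1$damage$omega, b2$damage$omega)
  expect_identical(b1$volumes$arrhenius$mask, b2$volumes$arrhenius$mask)
})

test_that("the clinical case activates perfusion, metabolism and warm coolant", {
  b <- run_case(mini_config("clinical", duration = 20))
  expect_true(b$manifest$thermal$include_perfusion)
  expect_true(b$manifest$thermal$include_metabolic)
  expect_equal(b$manifest$thermal$coolant_temperature_C, 20)
  expect_true("tumor" %in% names(b$materials))
  expect_true(any(b$grid$material == "tumor"))
})

test_that("a zero-duration run degrades gracefully", {
  b <- run_case(mini_config(duration = 0))
  expect_true(all(b$damage$omega == 0, na.rm = TRUE))
  expect_false(any(b$masks$arrhenius$mask))
  expect_equal(b$volumes$arrhenius$voxel_count, 0)
  expect_null(b$metrics)
})

test_that("metrics close the loop against a lattice-shifted copy of the zone", {
  b <- run_case(mini_config(duration = 120))
  expect_gt(b$volumes$arrhenius$voxel_count, 0)
  # same contour revolved on a sub-voxel-shifted lattice: only voxelization
  # error remains
  v <- revolve(b$contours$arrhenius, 0.5e-3)
  v2 <- revolve(b$contours$arrhenius, 0.5e-3, pad = 0.75e-3)
  m <- compute_metrics(v, v2)
  expect_gte(m$dice, 0.98)
  expect_lte(m$hausdorff_mm, 2 * 1e3 * v$spacing)
})

test_that("bundles serialize every artifact with a manifest", {
  dir <- withr::local_tempdir()
  b <- run_case(mini_config(duration = 40,
                            reference = generate_reference_zone(
                              c(8e-3, 8e-3, 10e-3), center = c(0, 0, 20e-3),
                              voxel_spacing = 1e-3)),
                out_dir = dir)
  expect_true(file.exists(file.path(dir, "probes.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "mask_arrhenius.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$case, "phantom")
  expect_equal(man$input_power_W, 35)
  expect_true(man$grid$cells > 0)
  if (b$volumes$arrhenius$voxel_count > 0) {
    expect_true(file.exists(file.path(dir, "zone_arrhenius.nii.gz")))
    expect_true(file.exists(file.path(dir, "metrics_arrhenius.json")))
    rep <- jsonlite::read_json(file.path(dir, "metrics_arrhenius.json"))
    expect_true(rep$dice >= 0 && rep$dice <= 1)
  }
})

test_that("YAML case configs map Table-style keys onto the pipeline", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(case = "phantom", P_in = 30, duration = 10,
                        overrides = list(sigma_phantom = 1.5),
                        resolution = list(min_cell = 2e-4, max_cell = 1.2e-3,
                                          pml_cells = 10)),
                   path)
  cfg <- read_case_config(path)
  expect_equal(cfg$input_power, 30)
  expect_equal(cfg$duration, 10)
  expect_equal(cfg$material_overrides$sigma_phantom, 1.5)
  expect_equal(cfg$resolution$min_cell, 2e-4)
})
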