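test_that("identical, half-overlapping and disjoint masks give the expected metrics", {
  mk <- function(xr) {
    a <- array(FALSE, c(20, 12, 12)); a[xr, 2:11, 2:11] <- TRUE
    zone_volume(a, 1e-3)
  }
  A <- mk(2:11); B <- mk(7:16); C <- mk(14:19)
  self <- compute_metrics(A, A)
  expect_equal(self$dice, 1)
  expect_equal(self$hausdorff_mm, 0)
  expect_equal(self$mean_euclidean_mm, 0)
  half <- compute_metrics(A, B)   # two 10x10x10 cubes sharing a 5x10x10 block
  expect_equal(half$dice, 0.5)
  expect_equal(compute_metrics(A, C)$dice, 0)
  expect_error(compute_metrics(mk(integer(0)), mk(integer(0))), "empty")
})

test_that("metrics equal the brute-force all-pairs oracle on small masks", {
  set.seed(11)
  for (rep in 1:3) {
    A <- array(FALSE, c(12, 12, 12)); B <- array(FALSE, c(12, 12, 12))
    # random blobs: balls at random centres
    ball <- function() {
      c0 <- runif(3, 4, 9); rad <- runif(1, 2, 4)
      idx <- as.matrix(expand.grid(1:12, 1:12, 1:12))
      d <- sqrt(rowSums(sweep(idx, 2, c0)^2))
      array(d <= rad, c(12, 12, 12))
    }
    A <- ball(); B <- ball()
    if (!any(A) || !any(B)) next
    got <- compute_metrics(zone_volume(A, 1e-3), zone_volume(B, 1e-3))
    ref <- oracle_metrics(A, B, 1e-3)
    expect_equal(got$dice, ref$dice)
    expect_equal(got$hausdorff_mm, ref$hausdorff_mm)
    expect_equal(got$mean_euclidean_mm, ref$mean_euclidean_mm)
  }
})

test_that("dice is symmetric and bounded", {
  set.seed(3)
  for (rep in 1:3) {
    A <- array(runif(10^3) > 0.6, c(10, 10, 10))
    B <- array(runif(10^3) > 0.6, c(10, 10, 10))
    ab <- compute_metrics(zone_volume(A, 1e-3), zone_volume(B, 1e-3))
    ba <- compute_metrics(zone_volume(B, 1e-3), zone_volume(A, 1e-3))
    expect_equal(ab$dice, ba$dice)
    expect_equal(ab$hausdorff_mm, ba$hausdorff_mm)
    expect_equal(ab$mean_euclidean_mm, ba$mean_euclidean_mm)
    expect_true(ab$dice >= 0 && ab$dice <= 1)
    expect_gte(ab$hausdorff_mm, 0)
  }
})

test_that("self-registration and known displacements are recovered", {
  z1 <- generate_reference_zone(c(8e-3, 6e-3, 10e-3), voxel_spacing = 1e-3)
  tr <- register_zones(z1, z1)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tr$translation)), 0.01 * z1$spacing)
  expect_equal(tr$provenance, "icp")
  # volume vs itself translated by (5, 0, 0) mm -> recovered (-5, 0, 0)
  z2 <- zone_volume(z1$mask, z1$spacing, z1$origin + c(5e-3, 0, 0))
  tr2 <- register_zones(z2, z1)
  expect_equal(1e3 * tr2$translation, c(-5, 0, 0), tolerance = 0.2 / 5)
})

test_that("supplied transforms are validated and passed through", {
  z1 <- generate_reference_zone(c(6e-3, 6e-3, 6e-3), voxel_spacing = 1e-3)
  id <- rigid_transform()
  out <- register_zones(z1, z1, transform = id)
  expect_identical(out$rotation, id$rotation)
  expect_equal(out$provenance, "supplied")
  expect_error(rigid_transform(rotation = diag(3) * 2), "rigid")
  expect_error(rigid_transform(rotation = diag(c(1, 1, -1))), "rigid")
  empty <- zone_volume(array(FALSE, c(2, 2, 2)), 1e-3)
  expect_error(register_zones(empty, z1), "empty")
})

test_that("metrics are invariant when the lattice shift is carried by the transform", {
  z1 <- generate_reference_zone(c(8e-3, 5e-3, 7e-3), voxel_spacing = 1e-3)
  z2 <- generate_reference_zone(c(6e-3, 6e-3, 6e-3), center = c(3e-3, 0, 0),
                                voxel_spacing = 1e-3)
  base <- compute_metrics(z1, z2)
  # shift z1's frame by a whole-voxel offset and compensate in the transform
  d <- c(4e-3, -2e-3, 3e-3)
  z1s <- zone_volume(z1$mask, z1$spacing, z1$origin + d)
  comp <- compute_metrics(z1s, z2, rigid_transform(translation = -d))
  expect_equal(comp$dice, base$dice)
  expect_equal(comp$hausdorff_mm, base$hausdorff_mm)
  expect_equal(comp$mean_euclidean_mm, base$mean_euclidean_mm)
})

test_that("transforms and reports round-trip through their file formats", {
  ang <- 0.3
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  tr <- rigid_transform(R, c(1e-3, -2e-3, 0.5e-3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$rotation, tr$rotation)
  expect_equal(back$translation, tr$translation)
  # zone volume NIfTI round trip
  z <- generate_reference_zone(c(5e-3, 5e-3, 5e-3), voxel_spacing = 1e-3)
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_zone_nifti(z, nii)
  zz <- read_zone_nifti(nii)
  expect_identical(zz$mask, z$mask)
  expect_equal(zz$spacing, z$spacing)
  expect_equal(zz$origin, z$origin, tolerance = 1e-6)
})
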