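# run a block with a private, seeded RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic segmented reference ablation zone
#'
#' Stands in for a radiologist's segmentation: a voxelized ellipsoid with an
#' optional cylindrical defect subtracted (emulating a blood vessel piercing
#' the ablation zone, i.e. a heat-sink artefact) and optional smooth boundary
#' jitter. Deterministic for a fixed seed.
#'
#' @param half_axes ellipsoid half-axes (m), length 3 (x, y, z).
#' @param center ellipsoid centre (m).
#' @param voxel_spacing isotropic voxel size (m).
#' @param vessel_defect optional list with `radius` (m), `axis` (direction
#'   vector) and `offset` (m, a point on the cylinder axis relative to the
#'   ellipsoid centre); the infinite cylinder is subtracted.
#' @param jitter boundary jitter amplitude (m); realised as a smooth random
#'   perturbation of the implicit ellipsoid boundary.
#' @param seed RNG seed for the jitter.
#' @return a [zone_volume()].
#' @export
generate_reference_zone <- function(half_axes = c(10e-3, 10e-3, 10e-3),
                                    center = c(0, 0, 0),
                                    voxel_spacing = 0.5e-3,
                                    vessel_defect = NULL,
                                    jitter = 0, seed = 1L) {
  stopifnot(length(half_axes) == 3, all(half_axes > 0), voxel_spacing > 0)
  if (voxel_spacing > min(half_axes))
    stop("voxel spacing larger than the smallest half-axis", call. = FALSE)
  pad <- 2 * voxel_spacing + jitter
  ax <- lapply(1:3, function(k)
    seq(center[k] - half_axes[k] - pad, center[k] + half_axes[k] + pad,
        by = voxel_spacing))
  dims <- vapply(ax, length, 1L)
  X <- (rep(ax[[1]], times = dims[2] * dims[3]) - center[1]) / half_axes[1]
  Y <- (rep(rep(ax[[2]], each = dims[1]), times = dims[3]) - center[2]) / half_axes[2]
  Z <- (rep(ax[[3]], each = dims[1] * dims[2]) - center[3]) / half_axes[3]
  q <- sqrt(X^2 + Y^2 + Z^2)  # normalised radius; boundary at 1
  thr <- 1
  if (jitter > 0) {
    # smooth noise: random coefficients on a coarse lattice, trilinear interp
    ngrid <- 5L
    noise <- with_seed(seed, array(rnorm(ngrid^3), c(ngrid, ngrid, ngrid)))
    u <- pmin(pmax((X + 1) / 2, 0), 1) * (ngrid - 1) + 1
    v <- pmin(pmax((Y + 1) / 2, 0), 1) * (ngrid - 1) + 1
    w <- pmin(pmax((Z + 1) / 2, 0), 1) * (ngrid - 1) + 1
    tri <- function(u, v, w) {
      i0 <- pmin(floor(u), ngrid - 1); j0 <- pmin(floor(v), ngrid - 1)
      k0 <- pmin(floor(w), ngrid - 1)
      fu <- u - i0; fv <- v - j0; fw <- w - k0
      g <- function(i, j, k) noise[cbind(i, j, k)]
      (1 - fu) * (1 - fv) * (1 - fw) * g(i0, j0, k0) +
        fu * (1 - fv) * (1 - fw) * g(i0 + 1, j0, k0) +
        (1 - fu) * fv * (1 - fw) * g(i0, j0 + 1, k0) +
        fu * fv * (1 - fw) * g(i0 + 1, j0 + 1, k0) +
        (1 - fu) * (1 - fv) * fw * g(i0, j0, k0 + 1) +
        fu * (1 - fv) * fw * g(i0 + 1, j0, k0 + 1) +
        (1 - fu) * fv * fw * g(i0, j0 + 1, k0 + 1) +
        fu * fv * fw * g(i0 + 1, j0 + 1, k0 + 1)
    }
    thr <- 1 + (jitter / mean(half_axes)) * tri(u, v, w)
  }
  inside <- q <= thr
  if (!is.null(vessel_defect)) {
    d <- vessel_defect$axis / sqrt(sum(vessel_defect$axis^2))
    p0 <- center + vessel_defect$offset
    px <- rep(ax[[1]], times = dims[2] * dims[3]) - p0[1]
    py <- rep(rep(ax[[2]], each = dims[1]), times = dims[3]) - p0[2]
    pz <- rep(ax[[3]], each = dims[1] * dims[2]) - p0[3]
    proj <- px * d[1] + py * d[2] + pz * d[3]
    dist2 <- px^2 + py^2 + pz^2 - proj^2
    inside <- inside & dist2 > vessel_defect$radius^2
  }
  zone_volume(array(inside, dims), voxel_spacing,
              origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]))
}

#' Generate a synthetic probe temperature series
#'
#' Emulates the saturating temperature rise recorded by a fiber-optic sensor
#' during ablation: T(t) = T_inf - (T_inf - T0) exp(-t / tau) plus seeded
#' Gaussian noise.
#'
#' @param asymptotic_temperature T_inf (degrees C).
#' @param initial_temperature T0 (degrees C).
#' @param time_constant tau (s, > 0).
#' @param noise_sd Gaussian noise standard deviation (degrees C, >= 0).
#' @param duration series length (s).
#' @param sample_interval sampling interval (s).
#' @param seed RNG seed.
#' @return data frame with `time_s` and `temp_C`.
#' @export
generate_sensor_series <- function(asymptotic_temperature = 80,
                                   initial_temperature = 17,
                                   time_constant = 150,
                                   noise_sd = 0.3,
                                   duration = 600, sample_interval = 1,
                                   seed = 1L) {
  stopifnot(time_constant > 0, noise_sd >= 0, duration >= 0)
  t <- seq(0, duration, by = sample_interval)
  temp <- asymptotic_temperature -
    (asymptotic_temperature - initial_temperature) * exp(-t / time_constant)
  if (noise_sd > 0)
    temp <- temp + with_seed(seed, rnorm(length(t), sd = noise_sd))
  data.frame(time_s = t, temp_C = temp)
}
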