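#' Rigid transform (rotation + translation)
#'
#' Maps moving-volume coordinates into fixed-volume coordinates:
#' x_fixed = R x_moving + t.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (m).
#' @param provenance `"supplied"` (e.g. from a manual surface registration) or
#'   `"icp"` (estimated by [register_zones()]).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            provenance = "supplied") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  t <- list(rotation = rotation, translation = translation,
            provenance = provenance)
  class(t) <- "rigid_transform"
  validate_rigid_transform(t)
  t
}

validate_rigid_transform <- function(t, tol = 1e-6) {
  R <- t$rotation
  if (!identical(dim(R), c(3L, 3L)) || length(t$translation) != 3)
    stop("rigid transform needs a 3x3 rotation and length-3 translation", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("supplied matrix is not a rigid rotation (orthonormal, det +1)", call. = FALSE)
  invisible(t)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> (%s) translation [%s] mm\n", x$provenance,
              paste(sprintf("%.2f", 1e3 * x$translation), collapse = ", ")))
  print(round(x$rotation, 6))
  invisible(x)
}

apply_transform <- function(transform, pts) {
  sweep(pts %*% t(transform$rotation), 2, transform$translation, `+`)
}

invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation),
                  provenance = transform$provenance)
}

#' Rigidly register a moving zone volume to a fixed one
#'
#' If a transform is supplied (mirroring a manually derived registration
#' matrix) it is validated and returned unchanged. Otherwise an iterative
#' closest-point (ICP) fit is run on subsampled surface-voxel point clouds,
#' starting from centroid alignment, with a Kabsch (SVD) rigid update per
#' iteration.
#'
#' @param moving,fixed nonempty [zone_volume()] objects.
#' @param transform optional [rigid_transform()] to validate and pass through.
#' @param max_iter,tol ICP iteration cap and convergence tolerance on the mean
#'   correspondence distance (m).
#' @param max_points surfaces are subsampled (deterministic stride) to at most
#'   this many points.
#' @return a [rigid_transform()] mapping `moving` into `fixed` coordinates.
#' @export
register_zones <- function(moving, fixed, transform = NULL,
                           max_iter = 50L, tol = 1e-7, max_points = 3000L) {
  stopifnot(inherits(moving, "zone_volume"), inherits(fixed, "zone_volume"))
  if (moving$voxel_count == 0 || fixed$voxel_count == 0)
    stop("cannot register empty zone volumes", call. = FALSE)
  if (!is.null(transform)) {
    stopifnot(inherits(transform, "rigid_transform"))
    validate_rigid_transform(transform)
    transform$provenance <- "supplied"
    return(transform)
  }
  sub <- function(p) {
    if (nrow(p) > max_points)
      p[seq(1L, nrow(p), length.out = max_points), , drop = FALSE] else p
  }
  P <- sub(surface_points(moving))
  Q <- sub(surface_points(fixed))
  cm <- colMeans(P); cf <- colMeans(Q)
  R <- diag(3); tr <- cf - cm
  prev <- Inf
  for (it in seq_len(max_iter)) {
    Pt <- sweep(P %*% t(R), 2, tr, `+`)
    nn <- nn_brute(Pt, Q)
    corr <- Q[nn$idx, , drop = FALSE]
    md <- mean(sqrt(nn$d2))
    # Kabsch on the correspondences
    mp <- colMeans(P); mq <- colMeans(corr)
    H <- crossprod(sweep(P, 2, mp), sweep(corr, 2, mq))
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    tr <- mq - as.numeric(R %*% mp)
    if (abs(prev - md) < tol) break
    prev <- md
  }
  rigid_transform(R, tr, provenance = "icp")
}

# resample two volumes onto a common voxel lattice (the fixed volume's
# spacing/lattice, extended to the union bounding box); nearest-neighbour so
# binary masks stay binary
.common_frame <- function(a, b, transform) {
  sp <- b$spacing
  corners <- function(v) {
    d <- dim(v$mask)
    ext <- rbind(c(0, 0, 0), t(t(expand.grid(0:1, 0:1, 0:1)) * (d - 1)))
    sweep(as.matrix(ext) * v$spacing, 2, v$origin, `+`)
  }
  ca <- apply_transform(transform, corners(a))
  cb <- corners(b)
  lo <- pmin(apply(ca, 2, min), apply(cb, 2, min)) - sp
  hi <- pmax(apply(ca, 2, max), apply(cb, 2, max)) + sp
  # align the lattice with b's voxel centres
  lo <- b$origin + floor((lo - b$origin) / sp) * sp
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * sp)
  grd <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  lookup <- function(v, pts) {
    idx <- sweep(pts, 2, v$origin, `-`) / v$spacing
    idx <- round(idx) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= dim(v$mask)[1] &
      idx[, 2] >= 1 & idx[, 2] <= dim(v$mask)[2] &
      idx[, 3] >= 1 & idx[, 3] <= dim(v$mask)[3]
    out <- logical(nrow(pts))
    if (any(ok))
      out[ok] <- v$mask[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
    out
  }
  inv <- invert_transform(transform)
  A <- array(lookup(a, apply_transform(inv, grd)), dims)
  B <- array(lookup(b, grd), dims)
  list(A = A, B = B, spacing = sp)
}

#' Overlap and surface-distance metrics between two zone volumes
#'
#' Resamples volume `a` through the rigid transform onto volume `b`'s lattice
#' (nearest neighbour) and reports the Dice coefficient
#' 2|A&B| / (|A| + |B|), the symmetric Hausdorff distance (maximum of the two
#' directed maximum nearest-surface distances) and the mean symmetric
#' nearest-surface (Euclidean) distance. Surface distances are computed with
#' an exact voxel Euclidean distance transform and reported in mm.
#'
#' @param a,b [zone_volume()] objects (simulated and reference zone).
#' @param transform a [rigid_transform()] mapping `a` into `b` coordinates.
#' @return an object of class `metrics_report` with fields `dice`,
#'   `hausdorff_mm`, `mean_euclidean_mm`, `transform`, `voxel_spacing`.
#' @export
compute_metrics <- function(a, b, transform = rigid_transform()) {
  stopifnot(inherits(a, "zone_volume"), inherits(b, "zone_volume"))
  if (a$voxel_count == 0 && b$voxel_count == 0)
    stop("undefined metrics: both volumes are empty", call. = FALSE)
  cf <- .common_frame(a, b, transform)
  A <- cf$A; B <- cf$B
  nA <- sum(A); nB <- sum(B)
  dice <- if (nA + nB == 0) NA_real_ else 2 * sum(A & B) / (nA + nB)
  if (nA == 0 || nB == 0) {
    hd <- Inf; meu <- Inf
  } else {
    sA <- .surface_array(A); sB <- .surface_array(B)
    dB <- sqrt(edt3d_sq(as.logical(sB), dim(sB)))  # distance to B's surface
    dA <- sqrt(edt3d_sq(as.logical(sA), dim(sA)))
    dAB <- dB[which(sA)]  # directed distances A -> B (voxel units)
    dBA <- dA[which(sB)]
    hd <- max(max(dAB), max(dBA)) * cf$spacing
    meu <- mean(c(dAB, dBA)) * cf$spacing
  }
  structure(list(dice = dice, hausdorff_mm = 1e3 * hd,
                 mean_euclidean_mm = 1e3 * meu,
                 transform = transform, voxel_spacing = cf$spacing,
                 n_voxels = c(a = nA, b = nB, overlap = sum(A & B))),
            class = "metrics_report")
}

# 6-connected surface voxels of a 3D logical array
.surface_array <- function(m) {
  d <- dim(m)
  interior <- m
  pad_shift <- function(arr, dim, by) {
    out <- array(FALSE, d)
    n <- d[dim]
    src <- lapply(d, seq_len); dst <- lapply(d, seq_len)
    if (by > 0) { src[[dim]] <- seq_len(n - by); dst[[dim]] <- seq_len(n - by) + by }
    else { src[[dim]] <- seq_len(n + by) - by; dst[[dim]] <- seq_len(n + by) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (dim in 1:3) for (by in c(-1L, 1L))
    interior <- interior & pad_shift(m, dim, by)
  m & !interior
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Dice %.3f | Hausdorff %.3f mm | mean Euclidean %.3f mm\n",
              x$dice, x$hausdorff_mm, x$mean_euclidean_mm))
  cat(sprintf("  voxel %.2f mm, transform: %s\n", 1e3 * x$voxel_spacing,
              x$transform$provenance))
  invisible(x)
}
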