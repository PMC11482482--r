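#' Extract isoline contours from a 2D field or necrosis mask
#'
#' Marching-squares isolines with sub-cell linear interpolation (via
#' `grDevices::contourLines`). Binary masks are contoured at level 0.5 on
#' their 0/1 indicator. Open polylines whose two ends fall on the inner radial
#' data margin are closed through the symmetry axis (r = 0); polylines ending
#' on the same axial margin are closed along that margin.
#'
#' @param x a `zone_mask`, or a numeric matrix.
#' @param level contour level (for matrix input).
#' @param r,z cell-centre coordinates (m) when `x` is a plain matrix.
#' @return an object of class `zone_contour`: a list of closed loops, each a
#'   two-column matrix of (r, z) in metres. Empty region gives an empty list.
#' @export
extract_contour <- function(x, level = NULL, r = NULL, z = NULL) {
  if (inherits(x, "zone_mask")) {
    field <- x$mask * 1
    r <- x$grid$r; z <- x$grid$z
    if (is.null(level)) level <- 0.5
  } else {
    field <- x
    stopifnot(is.matrix(field), !is.null(r), !is.null(z))
    if (any(!is.finite(field))) field[!is.finite(field)] <- min(field, na.rm = TRUE)
    if (is.null(level)) stop("a contour level is required for matrix input", call. = FALSE)
    rng <- range(field)
    if (level < rng[1] || level > rng[2])
      return(structure(list(), class = "zone_contour"))
  }
  if (diff(range(field)) == 0) {
    # constant field: either the whole domain is inside (boundary loop) or
    # nothing is
    if (field[1, 1] < level) return(structure(list(), class = "zone_contour"))
    loop <- cbind(r = c(min(r), max(r), max(r), min(r), min(r)),
                  z = c(min(z), min(z), max(z), max(z), min(z)))
    return(structure(list(loop), class = "zone_contour"))
  }
  cl <- grDevices::contourLines(x = r, y = z, z = field, levels = level)
  loops <- lapply(cl, function(ln) {
    p <- cbind(r = ln$x, z = ln$y)
    n <- nrow(p)
    closed <- sqrt(sum((p[1, ] - p[n, ])^2)) < 1e-12
    if (!closed) {
      tol <- 1e-9
      at_rmin <- abs(p[c(1, n), 1] - min(r)) < tol
      same_z_edge <- abs(p[1, 2] - p[n, 2]) < tol
      if (all(at_rmin)) {
        # close through the symmetry axis
        p <- rbind(p, c(0, p[n, 2]), c(0, p[1, 2]), p[1, ])
      } else if (same_z_edge) {
        p <- rbind(p, p[1, ])
      } else {
        p <- rbind(p, p[1, ])  # generic straight closure
      }
    }
    p
  })
  loops <- loops[vapply(loops, nrow, 1L) >= 4L]
  if (any(vapply(loops, function(p) any(p[, 1] < -1e-12), logical(1))))
    stop("contour with r < 0", call. = FALSE)
  structure(loops, class = "zone_contour")
}

#' @export
print.zone_contour <- function(x, ...) {
  cat(sprintf("<zone_contour> %d loop(s), %s vertices\n", length(x),
              paste(vapply(x, nrow, 1L), collapse = "+")))
  invisible(x)
}

# 3D voxel volume constructor
new_zone_volume <- function(mask, spacing, origin, surface = NULL) {
  vc <- sum(mask)
  structure(list(mask = mask, spacing = spacing, origin = origin,
                 voxel_count = vc, volume = vc * spacing^3,
                 surface = surface),
            class = "zone_volume")
}

#' Construct a 3D zone volume from a voxel mask
#'
#' @param mask 3D logical array (x, y, z), isotropic voxels.
#' @param spacing voxel edge length (m).
#' @param origin physical coordinate of the centre of voxel `[1, 1, 1]` (m).
#' @return an object of class `zone_volume` (`volume = voxel_count * spacing^3`).
#' @export
zone_volume <- function(mask, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, spacing > 0,
            length(origin) == 3)
  new_zone_volume(mask == TRUE, spacing, as.numeric(origin))
}

#' @export
print.zone_volume <- function(x, ...) {
  cat(sprintf("<zone_volume> %s voxels at %.2f mm: %d filled, %.0f mm^3%s\n",
              paste(dim(x$mask), collapse = "x"), 1e3 * x$spacing,
              x$voxel_count, 1e9 * x$volume,
              if (is.null(x$surface)) "" else ", with surface mesh"))
  invisible(x)
}

#' Revolve a planar zone contour into a 3D voxel volume
#'
#' Voxelizes the solid obtained by a 360 degree rotation of the (r, z) region
#' about the z axis, and sweeps the contour into a triangulated surface.
#' Inside/outside is resolved by even-odd point-in-polygon tests on a fine
#' (r, z) raster (spacing / 8 radially), then mapped to voxels through each
#' voxel centre's cylindrical radius.
#'
#' @param contour a [extract_contour()] result.
#' @param voxel_spacing isotropic voxel size (m).
#' @param n_theta angular steps of the swept surface.
#' @param pad margin added around the contour bounding box (m).
#' @return a [zone_volume()] centred on the rotation axis.
#' @export
revolve <- function(contour, voxel_spacing = 0.5e-3, n_theta = 72L,
                    pad = NULL) {
  stopifnot(inherits(contour, "zone_contour"), voxel_spacing > 0)
  if (length(contour) == 0)
    return(new_zone_volume(array(FALSE, c(0L, 0L, 0L)), voxel_spacing,
                           c(0, 0, 0)))
  if (is.null(pad)) pad <- voxel_spacing
  allp <- do.call(rbind, contour)
  if (any(allp[, 1] < -1e-12)) stop("contour with r < 0", call. = FALSE)
  r_max <- max(allp[, 1]) + pad
  z0 <- min(allp[, 2]) - pad; z1 <- max(allp[, 2]) + pad
  nxy <- max(3L, as.integer(ceiling(2 * r_max / voxel_spacing)))
  if (nxy %% 2L == 0L) nxy <- nxy + 1L  # odd: one voxel column on the axis
  xy <- (seq_len(nxy) - (nxy + 1) / 2) * voxel_spacing
  zz <- seq(z0 + voxel_spacing / 2, z1, by = voxel_spacing)
  nz <- length(zz)
  # even-odd polygon test on a fine (r, z) raster
  bnd <- do.call(rbind, lapply(contour, function(p) rbind(p, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  dr_f <- voxel_spacing / 8
  r_samp <- seq(dr_f / 2, r_max + dr_f, by = dr_f)
  pts <- cbind(rep(r_samp, times = nz), rep(zz, each = length(r_samp)))
  inside2d <- matrix(mgcv::in.out(bnd, pts), length(r_samp), nz)
  rr <- sqrt(outer(xy^2, xy^2, `+`))
  ri <- pmin(pmax(as.integer(floor(rr / dr_f)) + 1L, 1L), length(r_samp))
  mask <- array(FALSE, c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    col <- inside2d[, k]
    mask[, , k] <- col[ri]
  }
  surface <- sweep_surface(contour, n_theta)
  new_zone_volume(mask, voxel_spacing,
                  origin = c(xy[1], xy[1], zz[1]), surface = surface)
}

# sweep closed (r, z) loops about the z axis into a triangle mesh
sweep_surface <- function(contour, n_theta = 72L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- NULL; faces <- NULL
  for (loop in contour) {
    p <- loop
    n <- nrow(p)
    if (sqrt(sum((p[1, ] - p[n, ])^2)) < 1e-12) p <- p[-n, , drop = FALSE]
    n <- nrow(p)
    if (n < 3) next
    base <- if (is.null(verts)) 0L else nrow(verts)
    v <- cbind(rep(p[, 1], each = n_theta) * cos(theta),
               rep(p[, 1], each = n_theta) * sin(theta),
               rep(p[, 2], each = n_theta))
    idx <- function(i, k) base + (i - 1L) * n_theta + ((k - 1L) %% n_theta) + 1L
    f <- NULL
    for (i in seq_len(n)) {
      i2 <- if (i == n) 1L else i + 1L
      k <- seq_len(n_theta)
      f <- rbind(f,
                 cbind(idx(i, k), idx(i2, k), idx(i2, k + 1L)),
                 cbind(idx(i, k), idx(i2, k + 1L), idx(i, k + 1L)))
    }
    verts <- rbind(verts, v)
    faces <- rbind(faces, f)
  }
  if (is.null(verts)) return(NULL)
  # drop degenerate triangles (axis points produce coincident vertices)
  a <- verts[faces[, 1], ] - verts[faces[, 2], ]
  b <- verts[faces[, 1], ] - verts[faces[, 3], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  keep <- sqrt(rowSums(cr^2)) > 1e-18
  list(vertices = verts, faces = faces[keep, , drop = FALSE])
}

#' Physical coordinates of the surface voxels of a zone volume
#'
#' A voxel is a surface voxel when it is filled and at least one of its six
#' face neighbours (or the array boundary) is empty.
#'
#' @param vol a `zone_volume`.
#' @return matrix of surface-voxel centre coordinates (m), one row per voxel.
#' @export
surface_points <- function(vol) {
  stopifnot(inherits(vol, "zone_volume"))
  m <- vol$mask
  d <- dim(m)
  if (vol$voxel_count == 0) return(matrix(numeric(0), 0, 3))
  shift <- function(arr, dim, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len); dst <- lapply(d, seq_len)
    if (by > 0) { src[[dim]] <- seq_len(d[dim] - by); dst[[dim]] <- seq_len(d[dim] - by) + by }
    else { src[[dim]] <- seq_len(d[dim] + by) - by; dst[[dim]] <- seq_len(d[dim] + by) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- m
  for (dim in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift(m, dim, by)
  surf <- which(m & !interior, arr.ind = TRUE)
  sweep(sweep((surf - 1), 2, rep(vol$spacing, 3), `*`), 2, vol$origin, `+`)
}
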