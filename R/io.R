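#' Write / read a 3D zone volume as NIfTI
#'
#' The voxel spacing is stored in the NIfTI header (mm); the origin is carried
#' in the affine. Axis convention: the needle axis (z) is the third volume
#' axis.
#'
#' @param vol a [zone_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_zone_nifti` returns `path` invisibly; `read_zone_nifti`
#'   returns a `zone_volume`.
#' @export
write_zone_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "zone_volume"))
  img <- array(as.integer(vol$mask), dim(vol$mask))
  sp_mm <- 1e3 * vol$spacing
  aff <- diag(c(sp_mm, sp_mm, sp_mm, 1))
  aff[1:3, 4] <- 1e3 * vol$origin
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- rep(sp_mm, 3)
  RNifti::qform(nii) <- structure(aff, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_zone_nifti
#' @export
read_zone_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(nii)
  sp <- hdr$pixdim[2:4]
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1])
    stop("zone volumes must have isotropic voxels", call. = FALSE)
  aff <- RNifti::xform(nii)
  origin <- aff[1:3, 4] / 1e3
  zone_volume(array(nii != 0, dim(nii)), sp[1] / 1e3, origin)
}

#' Write a surface mesh as ASCII STL or PLY
#'
#' @param surface list with `vertices` (n x 3, m) and `faces` (m x 3 vertex
#'   indices), e.g. from [revolve()].
#' @param path output path; format chosen by extension (`.stl` or `.ply`).
#' @param name solid name written into the STL header.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, name = "zone") {
  stopifnot(is.list(surface), !is.null(surface$vertices), !is.null(surface$faces))
  v <- surface$vertices; f <- surface$faces
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "stl") {
    writeLines(paste("solid", name), con)
    n1 <- v[f[, 2], ] - v[f[, 1], ]
    n2 <- v[f[, 3], ] - v[f[, 1], ]
    nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
                 n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
                 n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    for (k in seq_len(nrow(f))) {
      writeLines(sprintf(" facet normal %.9g %.9g %.9g", nrm[k, 1], nrm[k, 2], nrm[k, 3]), con)
      writeLines("  outer loop", con)
      for (j in 1:3)
        writeLines(sprintf("   vertex %.9g %.9g %.9g",
                           v[f[k, j], 1], v[f[k, j], 2], v[f[k, j], 3]), con)
      writeLines("  endloop", con)
      writeLines(" endfacet", con)
    }
    writeLines(paste("endsolid", name), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported surface format '", ext, "'", call. = FALSE)
  invisible(path)
}

#' Write / read a rigid transform as a plain-text 4x4 matrix
#'
#' @param transform a [rigid_transform()].
#' @param path text file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- unname(as.matrix(utils::read.table(path)))
  if (!identical(dim(m), c(4L, 4L)))
    stop("transform file must contain a 4x4 matrix", call. = FALSE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4], provenance = "supplied")
}

#' Write a metrics report as JSON
#'
#' @param report a [compute_metrics()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- list(dice = report$dice,
              hausdorff_mm = report$hausdorff_mm,
              mean_euclidean_mm = report$mean_euclidean_mm,
              voxel_spacing_mm = 1e3 * report$voxel_spacing,
              transform = list(rotation = report$transform$rotation,
                               translation_m = report$transform$translation,
                               provenance = report$transform$provenance),
              n_voxels = as.list(report$n_voxels))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
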