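#' Construct a 3D volume
#'
#' A `medbridge_volume` is the package's universal image carrier: a 3D scalar
#' intensity grid together with a 4x4 homogeneous mapping from 0-based voxel
#' indices (voxel centers) to world coordinates in RAS+ millimetres.
#'
#' @param data numeric 3D array of finite intensities.
#' @param voxel_to_world 4x4 invertible matrix; last row `(0,0,0,1)`.
#' @return An object of class `medbridge_volume` with elements `data`,
#'   `voxel_to_world` and `shape`.
#' @export
new_volume <- function(data, voxel_to_world = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume intensities must be finite (no NA/NaN/Inf)")
  voxel_to_world <- check_spatial_matrix(voxel_to_world)
  structure(list(data = data, voxel_to_world = voxel_to_world,
                 shape = dim(data)),
            class = "medbridge_volume")
}

#' Construct a binary mask
#'
#' Same carrier as [new_volume()] but values restricted to exactly 0/1.
#'
#' @param data numeric or logical 3D array with values in `{0, 1}`.
#' @param voxel_to_world 4x4 voxel-to-world matrix (mm).
#' @return An object of class `medbridge_mask` (also a `medbridge_volume`).
#' @export
new_mask <- function(data, voxel_to_world = diag(4)) {
  if (is.logical(data)) {
    d <- dim(data)
    data <- array(as.double(data), dim = d)
  }
  v <- new_volume(data, voxel_to_world)
  if (!all(v$data %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  class(v) <- c("medbridge_mask", "medbridge_volume")
  v
}

check_spatial_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop("spatial mapping must be a 4x4 matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of a spatial mapping must be (0,0,0,1)")
  if (abs(det(m)) < 1e-12) stop("spatial mapping is singular")
  unname(m)
}

#' @export
print.medbridge_volume <- function(x, ...) {
  kind <- if (inherits(x, "medbridge_mask")) "mask" else "volume"
  vox <- sqrt(colSums(x$voxel_to_world[1:3, 1:3]^2))
  cat(sprintf("<medbridge %s> %s voxels, %s mm\n", kind,
              paste(x$shape, collapse = "x"),
              paste(signif(vox, 4), collapse = "x")))
  invisible(x)
}

#' Read a 3D NIfTI-1 volume
#'
#' Loads a `.nii`/`.nii.gz` file into a [new_volume()] object. The
#' voxel-to-world mapping is taken from the file's sform when present,
#' otherwise its qform; intensities are cast to double.
#'
#' @param path path to a 3D single-channel NIfTI-1 file.
#' @return A `medbridge_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D single-channel image, got ", length(d), " dimensions: ", path)
  m <- RNifti::xform(img, useQuaternionFirst = FALSE)
  m <- matrix(as.numeric(m), 4, 4)
  arr <- array(as.double(img), dim = d)
  if (!all(is.finite(arr))) stop("non-finite intensities in ", path)
  new_volume(arr, m)
}

#' Read a binary brain mask from NIfTI
#'
#' @param path path to a NIfTI-1 file whose voxels are (numerically) 0 or 1.
#' @return A `medbridge_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  d <- round(v$data)
  if (max(abs(v$data - d)) > 1e-6 || !all(d %in% c(0, 1)))
    stop("mask file has values other than 0/1: ", path)
  new_mask(array(d, dim = v$shape), v$voxel_to_world)
}

#' Write a volume or mask to NIfTI-1
#'
#' Round-trips exactly through [read_volume()]: the grid is stored as
#' float64 and the mapping in the sform/qform.
#'
#' @param v a `medbridge_volume` or `medbridge_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "medbridge_volume"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  RNifti::sform(img) <- structure(v$voxel_to_world, code = 2L)
  RNifti::qform(img) <- structure(v$voxel_to_world, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# world coordinates (n x 3) of a set of 0-based voxel indices
voxel_to_world_points <- function(vol, idx0) {
  p <- cbind(idx0, 1) %*% t(vol$voxel_to_world)
  p[, 1:3, drop = FALSE]
}

# intensity centroid in world mm
intensity_centroid <- function(vol) {
  w <- as.numeric(vol$data)
  tot <- sum(w)
  if (tot <= 0) stop("volume has no positive intensity")
  d <- vol$shape
  ix <- rep.int(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  cx <- c(sum(w * ix), sum(w * iy), sum(w * iz)) / tot
  as.numeric(vol$voxel_to_world %*% c(cx, 1))[1:3]
}
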