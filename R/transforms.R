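TRANSFORM_CONVENTION <- "pullback-ras-mm"

#' Affine transform between two labelled spaces
#'
#' A 12-parameter affine world-to-world mapping under the pull-back
#' (resampling) convention: a transform labelled `a -> b` takes a world point
#' expressed in space `b` and returns the corresponding world point in space
#' `a`. Resampling an image of space `a` onto the grid of space `b` evaluates
#' it at the pulled-back points, and the chain `a -> b` then `b -> c` is the
#' plain matrix product of the two 4x4 matrices.
#'
#' The 12 parameters are, in order: rotations about x, y, z (degrees,
#' intrinsic Z-Y-X, i.e. `R = Rz %*% Ry %*% Rx`), translations in x, y, z
#' (mm), scales in x, y, z, and shears xy, xz, yz (unit upper-triangular
#' factor). The linear part composes as `R %*% SH %*% S`: scale first, then
#' shear, then rotation, with translation applied last.
#'
#' @param matrix 4x4 homogeneous world-to-world matrix (last row 0,0,0,1).
#' @param params numeric vector of 12 parameters (alternative to `matrix`).
#' @param from_space,to_space space labels.
#' @return An object of class `medbridge_transform` with elements `params`,
#'   `matrix`, `from_space`, `to_space`.
#' @export
affine_transform <- function(matrix = NULL, params = NULL,
                             from_space = "a", to_space = "b") {
  if (is.null(matrix) && is.null(params))
    stop("supply either matrix or params")
  if (is.null(matrix)) {
    params <- check_params(params)
    matrix <- affine_matrix_from_params(params)
  } else {
    matrix <- check_spatial_matrix(matrix)
    if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("transform matrix is singular")
    if (is.null(params)) params <- affine_params_from_matrix(matrix)
    else params <- check_params(params)
  }
  structure(list(params = params, matrix = matrix,
                 from_space = from_space, to_space = to_space),
            class = "medbridge_transform")
}

#' Identity transform between two spaces
#' @param from_space,to_space space labels.
#' @return A `medbridge_transform` with identity matrix.
#' @export
affine_identity <- function(from_space = "a", to_space = "b") {
  affine_transform(params = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0),
                   from_space = from_space, to_space = to_space)
}

check_params <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 12L) stop("affine parameter vector must have length 12")
  if (any(!is.finite(p))) stop("non-finite affine parameters")
  if (any(abs(p[7:9]) < 1e-9)) stop("zero scale parameter")
  p
}

#' Build a 4x4 matrix from 12 affine parameters
#'
#' @param p parameters in the order documented in [affine_transform()].
#' @return 4x4 homogeneous matrix.
#' @export
affine_matrix_from_params <- function(p) {
  p <- check_params(p)
  r <- p[1:3] * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  SH <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% SH %*% diag(p[7:9])
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- p[4:6]
  m
}

#' Decompose a 4x4 affine matrix into 12 parameters
#'
#' Inverse of [affine_matrix_from_params()]; unique (and an exact round-trip)
#' for positive scales and rotations within (-90, 90) degrees.
#'
#' @param m 4x4 homogeneous affine matrix.
#' @return numeric vector of 12 parameters.
#' @export
affine_params_from_matrix <- function(m) {
  m <- check_spatial_matrix(m)
  A <- m[1:3, 1:3]
  qrd <- qr(A)
  Q <- qr.Q(qrd)
  R <- qr.R(qrd)
  sgn <- sign(diag(R))
  sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn)
  R <- diag(sgn) %*% R
  if (det(Q) < 0) {
    # improper rotation: flip the z column into the scale instead
    Q[, 3] <- -Q[, 3]
    R[3, ] <- -R[3, ]
  }
  s <- diag(R)
  h <- c(R[1, 2] / s[2], R[1, 3] / s[3], R[2, 3] / s[3])
  ry <- asin(max(-1, min(1, -Q[3, 1])))
  rx <- atan2(Q[3, 2], Q[3, 3])
  rz <- atan2(Q[2, 1], Q[1, 1])
  c(c(rx, ry, rz) * 180 / pi, m[1:3, 4], s, h)
}

#' Invert an affine transform
#' @param t a `medbridge_transform`.
#' @return The inverse transform, with space labels swapped.
#' @export
invert_affine <- function(t) {
  stopifnot(inherits(t, "medbridge_transform"))
  affine_transform(matrix = solve(t$matrix),
                   from_space = t$to_space, to_space = t$from_space)
}

#' Compose two affine transforms
#'
#' For pull-backs `t_ab: a -> b` and `t_bc: b -> c`, returns the `a -> c`
#' pull-back: a world point `p` in space `c` maps to `t_ab(t_bc(p))`, so the
#' matrix is the plain product `t_ab$matrix %*% t_bc$matrix`. This is the
#' subject-to-mediator-to-template chain used throughout the mediator
#' workflow.
#'
#' @param t_ab transform from `a` to `b` (pull-back).
#' @param t_bc transform from `b` to `c` (pull-back).
#' @return Transform from `a` to `c`.
#' @export
compose_affine <- function(t_ab, t_bc) {
  stopifnot(inherits(t_ab, "medbridge_transform"),
            inherits(t_bc, "medbridge_transform"))
  if (!identical(t_ab$to_space, t_bc$from_space))
    stop(sprintf("space labels do not chain: (%s -> %s) then (%s -> %s)",
                 t_ab$from_space, t_ab$to_space,
                 t_bc$from_space, t_bc$to_space))
  affine_transform(matrix = t_ab$matrix %*% t_bc$matrix,
                   from_space = t_ab$from_space, to_space = t_bc$to_space)
}

#' @export
print.medbridge_transform <- function(x, ...) {
  cat(sprintf("<affine transform> %s -> %s (pull-back)\n",
              x$from_space, x$to_space))
  cat(sprintf("  rot (deg): %s\n", paste(signif(x$params[1:3], 4), collapse = " ")))
  cat(sprintf("  trans (mm): %s\n", paste(signif(x$params[4:6], 4), collapse = " ")))
  cat(sprintf("  scale: %s  shear: %s\n",
              paste(signif(x$params[7:9], 4), collapse = " "),
              paste(signif(x$params[10:12], 4), collapse = " ")))
  invisible(x)
}

#' Read an affine transform from a JSON file
#'
#' The file format is `{"matrix": [16 row-major floats], "from_space": str,
#' "to_space": str, "convention": "pullback-ras-mm"}`. A file carrying any
#' other convention tag is rejected rather than silently reinterpreted.
#'
#' @param path path to a transform JSON file.
#' @return A `medbridge_transform`.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("matrix", "from_space", "to_space", "convention")
  if (!all(need %in% names(j)))
    stop("malformed transform file (need ", paste(need, collapse = ", "), "): ", path)
  if (!identical(j$convention, TRANSFORM_CONVENTION))
    stop("unsupported transform convention '", j$convention,
         "' (expected '", TRANSFORM_CONVENTION, "'): ", path)
  if (length(j$matrix) != 16L) stop("transform matrix must have 16 values: ", path)
  m <- matrix(as.numeric(j$matrix), 4, 4, byrow = TRUE)
  affine_transform(matrix = m, from_space = j$from_space, to_space = j$to_space)
}

#' Write an affine transform to a JSON file
#' @param t a `medbridge_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "medbridge_transform"))
  jsonlite::write_json(
    list(matrix = as.numeric(base::t(t$matrix)),
         from_space = t$from_space, to_space = t$to_space,
         convention = TRANSFORM_CONVENTION),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean displacement between two transforms over a mask
#'
#' Applies both matrices to the world coordinates of every foreground voxel
#' of `mask` and returns the mean Euclidean distance (mm) between the two
#' mapped point sets — the standard registration-error summary when the true
#' transform is known.
#'
#' @param mask a `medbridge_mask` defining the evaluation region.
#' @param t_a,t_b two `medbridge_transform`s (or 4x4 matrices).
#' @return Mean displacement in mm.
#' @export
mean_voxel_displacement <- function(mask, t_a, t_b) {
  ma <- if (inherits(t_a, "medbridge_transform")) t_a$matrix else t_a
  mb <- if (inherits(t_b, "medbridge_transform")) t_b$matrix else t_b
  idx <- which(mask$data > 0, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty mask")
  pts <- cbind(idx, 1) %*% t(mask$voxel_to_world)
  d <- pts %*% t(ma - mb)
  mean(sqrt(rowSums(d[, 1:3, drop = FALSE]^2)))
}
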