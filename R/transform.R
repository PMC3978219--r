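#' 12-parameter affine world-to-world transforms
#'
#' An `affine_transform` is a 4x4 homogeneous matrix mapping world
#' coordinates (RAS mm) of one image onto world coordinates of another. The
#' 12-parameter form is `T %*% R %*% S`: scale/shear first, then rotations
#' about x, y, z (applied in that order), then translation. The parameter
#' vector is `c(tx, ty, tz, rx, ry, rz, sx, sy, sz, hxy, hxz, hyz)` with
#' translations in mm, rotations in radians, scales dimensionless and shears
#' as off-diagonal ratios of the upper-triangular scale/shear factor.
#'
#' @param params Numeric vector of 12 parameters (see Details), or `NULL` if
#'   `matrix` is given.
#' @param matrix 4x4 homogeneous matrix, used directly if supplied.
#' @return An object of class `affine_transform` with elements `matrix` and
#'   `params`.
#' @examples
#' t1 <- affine_transform(c(3, -2, 1, 0, 0, 0.05, 1.02, 1, 1, 0, 0, 0))
#' max(abs(compose(t1, invert(t1))$matrix - diag(4)))
#' @export
affine_transform <- function(params = NULL, matrix = NULL) {
  if (is.null(matrix)) {
    if (length(params) != 12L)
      stop_petsuvr("affine transform needs 12 parameters", "format")
    matrix <- params_to_matrix(params)
  } else {
    matrix <- as_affine_matrix(matrix)
    if (det(matrix[1:3, 1:3]) <= 0)
      stop_petsuvr("affine transform must preserve orientation (positive determinant)", "format")
    params <- matrix_to_params(matrix)
  }
  structure(list(matrix = matrix, params = params), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform(c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0))

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

params_to_matrix <- function(p) {
  tr <- p[1:3]; ang <- p[4:6]; sc <- p[7:9]; sh <- p[10:12]
  if (any(sc <= 0))
    stop_petsuvr("scale parameters must be strictly positive", "format")
  S <- diag(sc) %*% matrix(c(1, 0, 0, sh[1], 1, 0, sh[2], sh[3], 1), 3, 3)
  R <- rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1])
  M <- diag(4)
  M[1:3, 1:3] <- R %*% S
  M[1:3, 4] <- tr
  M
}

# Inverse of params_to_matrix via QR: M3 = Q * U with U upper triangular,
# positive diagonal; Q is the rotation, U carries scale and shear.
matrix_to_params <- function(M) {
  M3 <- M[1:3, 1:3]
  qrd <- qr(M3)
  Q <- qr.Q(qrd); U <- qr.R(qrd)
  s <- sign(diag(U)); s[s == 0] <- 1
  Q <- Q %*% diag(s); U <- diag(s) %*% U
  ry <- asin(max(-1, min(1, -Q[3, 1])))
  rx <- atan2(Q[3, 2], Q[3, 3])
  rz <- atan2(Q[2, 1], Q[1, 1])
  sc <- diag(U)
  c(M[1:3, 4], rx, ry, rz, sc, U[1, 2] / sc[1], U[1, 3] / sc[1], U[2, 3] / sc[2])
}

#' @export
print.affine_transform <- function(x, ...) {
  p <- x$params
  cat("<affine_transform>\n")
  cat(sprintf("  translation %7.3f %7.3f %7.3f mm\n", p[1], p[2], p[3]))
  cat(sprintf("  rotation    %7.3f %7.3f %7.3f deg\n", p[4] * 180 / pi, p[5] * 180 / pi, p[6] * 180 / pi))
  cat(sprintf("  scale       %7.4f %7.4f %7.4f\n", p[7], p[8], p[9]))
  cat(sprintf("  shear       %7.4f %7.4f %7.4f\n", p[10], p[11], p[12]))
  invisible(x)
}

#' Transform algebra
#'
#' `invert()` returns the inverse mapping; `compose(first, second)` returns
#' the transform applying `first` then `second` (matrix product
#' `second %*% first`).
#'
#' @param transform,first,second `affine_transform` objects.
#' @return An `affine_transform`.
#' @export
invert <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  affine_transform(matrix = solve(transform$matrix))
}

#' @rdname invert
#' @export
compose <- function(first, second) {
  stopifnot(inherits(first, "affine_transform"), inherits(second, "affine_transform"))
  affine_transform(matrix = second$matrix %*% first$matrix)
}

#' @rdname invert
#' @param points n x 3 matrix of world coordinates.
#' @export
apply_transform <- function(transform, points) {
  points <- rbind(t(points), 1)
  t(transform$matrix %*% points)[, 1:3, drop = FALSE]
}

#' Read / write transforms as plain-text 4x4 matrices
#'
#' One matrix row per line, whitespace-separated, for audit trails and the
#' command line's `--save-transform` / `--apply-transform`.
#'
#' @param transform An `affine_transform`.
#' @param path File path.
#' @export
write_transform <- function(transform, path) {
  m <- format(transform$matrix, digits = 17)
  writeLines(apply(m, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  affine_transform(matrix = unname(m))
}

#' Resample a volume onto a target grid
#'
#' Back-projects every target voxel through `transform` (a world-to-world map
#' from source space to target space) into the source grid and interpolates.
#' Locations outside the source field of view receive `fill` (0 by default,
#' the PET background).
#'
#' @param source `pet_volume` to resample.
#' @param transform `affine_transform` mapping source world space onto target
#'   world space.
#' @param target `grid_spec` (or `pet_volume`) defining the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill Value for out-of-field voxels (default 0; `NA` marks them).
#' @return A `pet_volume` on the target grid.
#' @export
resample <- function(source, transform = identity_transform(), target = grid_of(source),
                     interpolation = c("trilinear", "nearest"), fill = 0) {
  interpolation <- tryCatch(match.arg(interpolation),
                            error = function(e) stop_petsuvr(
                              sprintf("unknown interpolation mode '%s'", interpolation[1]), "usage"))
  if (inherits(target, "pet_volume")) target <- grid_of(target)
  stopifnot(inherits(source, "pet_volume"), inherits(target, "grid_spec"),
            inherits(transform, "affine_transform"))
  # target voxel -> target world -> source world -> source voxel
  map <- solve(source$affine) %*% solve(transform$matrix) %*% target$affine
  out <- resample_affine_cpp(source$data, dim(source$data), target$shape, map,
                             if (interpolation == "nearest") 1L else 0L, fill)
  v <- structure(list(data = out, affine = target$affine), class = "pet_volume")
  v
}

#' Gaussian smoothing
#'
#' Separable Gaussian filter specified by full-width-at-half-maximum in mm
#' (converted per axis using the volume's voxel sizes).
#'
#' @param vol A `pet_volume`.
#' @param fwhm_mm Scalar FWHM in millimetres (0 is a no-op).
#' @return Smoothed `pet_volume`.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "pet_volume"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_sizes(vol)
  out <- gaussian_blur_cpp(vol$data, dim(vol$data), sigma_vox)
  structure(list(data = out, affine = vol$affine), class = "pet_volume")
}
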