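#' Volumetric image with a voxel-to-world affine
#'
#' A `pet_volume` bundles a 3-D numeric array with the 4x4 affine matrix that
#' maps 0-based voxel indices to world coordinates in RAS millimetres. It is
#' the container every pipeline stage (registration, masking, quantification)
#' operates on, and holds PET, CT, T1, probability-map and label data alike.
#'
#' @param data 3-D numeric array of voxel intensities.
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @param nonfinite How to treat non-finite voxel values: `"error"` rejects
#'   the array, `"zero"` replaces them with 0 (the count is reported via a
#'   message).
#'
#' @return An object of class `pet_volume` with elements `data` and `affine`.
#' @examples
#' v <- volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), diag(4))
#' voxel_sizes(v)
#' @export
volume <- function(data, affine = diag(4), nonfinite = c("error", "zero")) {
  nonfinite <- match.arg(nonfinite)
  if (length(dim(data)) != 3L)
    stop_petsuvr(sprintf("volume data must be a 3-D array, got %d dimension(s); 4-D multi-frame images are not supported",
                         length(dim(data))), "dimension")
  affine <- as_affine_matrix(affine)
  storage.mode(data) <- "double"
  bad <- !is.finite(data)
  if (any(bad)) {
    if (nonfinite == "error")
      stop_petsuvr(sprintf("volume contains %d non-finite voxel(s)", sum(bad)), "format")
    message(sprintf("replacing %d non-finite voxel(s) with 0", sum(bad)))
    data[bad] <- 0
  }
  structure(list(data = data, affine = affine), class = "pet_volume")
}

as_affine_matrix <- function(affine) {
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop_petsuvr("affine must be a 4x4 matrix", "format")
  d <- abs(det(affine))
  if (!is.finite(d) || d < 1e-12)
    stop_petsuvr("affine matrix is not invertible", "format")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0))
    stop_petsuvr("voxel sizes derived from affine must be strictly positive", "format")
  affine
}

#' @rdname volume
#' @param x A `pet_volume` or `grid_spec`.
#' @export
voxel_sizes <- function(x) {
  aff <- if (inherits(x, c("pet_volume", "grid_spec"))) x$affine else as_affine_matrix(x)
  sqrt(colSums(aff[1:3, 1:3]^2))
}

#' @export
print.pet_volume <- function(x, ...) {
  vs <- voxel_sizes(x)
  cat(sprintf("<pet_volume> %s voxels, %.3g x %.3g x %.3g mm\n",
              paste(dim(x$data), collapse = " x "), vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

#' Target sampling grid
#'
#' A `grid_spec` describes a voxel grid (shape plus voxel-to-world affine)
#' without carrying data; it is the target argument of [resample()] and
#' [transform_labels()].
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_petsuvr("grid shape must be three integers >= 1", "format")
  structure(list(shape = shape, affine = as_affine_matrix(affine)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param volume A `pet_volume` whose grid is extracted.
#' @export
grid_of <- function(volume) grid_spec(dim(volume$data), volume$affine)

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "grid_spec")) a else grid_of(a)
  gb <- if (inherits(b, "grid_spec")) b else grid_of(b)
  all(ga$shape == gb$shape) && max(abs(ga$affine - gb$affine)) <= tol
}

#' Read / write NIfTI-1 volumes
#'
#' `read_volume()` loads a single-frame NIfTI-1 file into a [volume()],
#' applying the header intensity scaling and taking the world mapping from
#' the sform (falling back to the qform). `write_volume()` stores a volume
#' losslessly as 32-bit float (or a chosen datatype).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param nonfinite Passed on to [volume()].
#' @return `read_volume()` returns a `pet_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, nonfinite = "error") {
  if (!file.exists(path))
    stop_petsuvr(sprintf("file not found: %s", path), "io")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_petsuvr(
                    sprintf("cannot read '%s' as NIfTI: %s", path, conditionMessage(e)), "format"))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
  } else if (length(d) != 3L) {
    stop_petsuvr(sprintf("'%s' has %d dimensions (%s frames); only static 3-D volumes are supported",
                         path, length(d), if (length(d) >= 4) d[4] else "?"), "dimension")
  } else {
    img2 <- array(as.numeric(img), d)
  }
  aff <- structure(RNifti::xform(img), code = NULL)
  volume(img2, unname(aff[, , drop = FALSE]), nonfinite = nonfinite)
}

#' @rdname read_volume
#' @param vol A `pet_volume`.
#' @param datatype NIfTI on-disk datatype (default `"float"`, lossless for
#'   single-precision data).
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "pet_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_petsuvr(sprintf("directory does not exist: %s", dir), "io")
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, voxel_sizes(vol))  # before sform: scales stick
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# world coordinates (rows of an n x 3 matrix) of all voxels, 0-based indexing
voxel_world_coords <- function(grid) {
  shape <- grid$shape
  aff <- grid$affine
  i <- seq_len(shape[1]) - 1
  j <- seq_len(shape[2]) - 1
  k <- seq_len(shape[3]) - 1
  ijk <- cbind(rep(i, times = shape[2] * shape[3]),
               rep(rep(j, each = shape[1]), times = shape[3]),
               rep(k, each = shape[1] * shape[2]))
  sweep(ijk %*% t(aff[1:3, 1:3]), 2, aff[1:3, 4], `+`)
}
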