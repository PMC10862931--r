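#' Construct an image volume
#'
#' A minimal container for a 3D scalar CT volume on a regular anisotropic
#' lattice: a numeric array of Hounsfield units plus physical voxel spacing
#' (mm) and the physical coordinate of voxel `(1,1,1)`. The third array axis
#' is the axial (slice) axis, with slice index increasing toward the head.
#'
#' @param data 3D numeric array of HU values; must be finite everywhere.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, physical coordinate (mm) of the first
#'   voxel's centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values (NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm), got: ",
         paste(spacing, collapse = ", "))
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a mask volume
#'
#' A binary or labelled integer volume on the same lattice convention as
#' [image_volume()]: 0 is background, positive integers are foreground or
#' region labels.
#'
#' @param data 3D array of non-negative integers.
#' @inheritParams image_volume
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  d <- as.integer(data)
  if (anyNA(d) || any(d < 0L))
    stop("mask values must be integers in {0..K}")
  dim(d) <- dim(data)
  vol <- image_volume(array(0, dim(data)), spacing, origin)
  vol$data <- d
  class(vol) <- c("mask_volume", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  if (inherits(x, "mask_volume"))
    cat(sprintf("  foreground voxels: %d\n", sum(x$data != 0L)))
  invisible(x)
}

#' Check that two volumes share the same lattice
#'
#' Shapes must match exactly; spacings must agree within `tol` mm.
#' Resampling is out of scope, so a mismatch is treated as a user error.
#'
#' @param a,b `image_volume` / `mask_volume` objects.
#' @param tol spacing tolerance in mm.
#' @return Invisibly `TRUE`; stops with a message naming both grids otherwise.
#' @export
check_congruent <- function(a, b, tol = 1e-3) {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("grids are not congruent: shapes %s vs %s",
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (any(abs(a$spacing - b$spacing) > tol))
    stop(sprintf("grids are not congruent: spacings (%s) vs (%s) mm",
                 paste(format(a$spacing), collapse = ", "),
                 paste(format(b$spacing), collapse = ", ")))
  invisible(TRUE)
}

#' Read a 3D volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file, returning HU values unmodified with voxel
#' spacing taken from the header. Where the header carries complete
#' orientation metadata the volume is reoriented so the third axis is axial
#' with slice index increasing superiorly (RAS).
#'
#' @param path file path.
#' @param mask if `TRUE`, return a [mask_volume()] (values coerced to
#'   integer labels).
#' @return An `image_volume` or `mask_volume`.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  # best-effort reorientation; headers without a complete xform are used
  # as stored
  suppressWarnings(try(RNifti::orientation(img) <- "RAS", silent = TRUE))
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D volume, got a ", nd, "D payload in ", path)
  spacing <- RNifti::pixdim(img)
  if (any(spacing <= 0))
    stop("non-positive voxel spacing in header of ", path, ": ",
         paste(spacing, collapse = ", "))
  origin <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]),
                     error = function(e) c(0, 0, 0))
  arr <- array(as.numeric(img), dim = dim(img))
  if (mask) mask_volume(arr, spacing, origin)
  else image_volume(arr, spacing, origin)
}

#' Write a volume to NIfTI
#'
#' @param vol an `image_volume` or `mask_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Threshold EAT within the pericardial sac
#'
#' Epicardial adipose tissue is defined as the voxels inside the pericardium
#' ("sac") mask whose attenuation falls in the fat window, by default the
#' closed interval \[-190, -30\] HU.
#'
#' @param ct an `image_volume` of HU values.
#' @param sac a `mask_volume` congruent with `ct`.
#' @param hu_window closed HU interval `c(lo, hi)`, `lo < hi`.
#' @return A binary `mask_volume` congruent with `ct`.
#' @export
derive_eat_mask <- function(ct, sac, hu_window = c(-190, -30)) {
  check_congruent(ct, sac)
  if (length(hu_window) != 2L || hu_window[1] >= hu_window[2])
    stop("`hu_window` must be c(lo, hi) with lo < hi")
  fat <- (sac$data != 0L) & ct$data >= hu_window[1] & ct$data <= hu_window[2]
  out <- array(0L, dim(ct$data))
  out[fat] <- 1L
  mask_volume(out, ct$spacing, ct$origin)
}

# physical centre coordinates (mm) of voxels given 1-based index matrix n x 3
voxel_coords <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

voxel_volume_mm3 <- function(vol) prod(vol$spacing)
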