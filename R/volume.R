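#' Volume image container
#'
#' A minimal 3-D image: an (x, y, z) array of Hounsfield units plus voxel
#' spacing and the position of the first voxel center, both in mm. All
#' geometry in the package is voxel-center based and 1-indexed.
#'
#' @param values numeric 3-D array, dimensions (nx, ny, nz).
#' @param spacing numeric length-3 vector of voxel sizes (x, y, z) in mm.
#' @param origin numeric length-3 vector, mm position of voxel (1, 1, 1).
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

# voxel-center coordinates along one axis
axis_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Write a volume as NIfTI-1
#'
#' Spacing is carried in the NIfTI pixdim; values are written as-is.
#'
#' @param vol a `volume_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return a `volume_image` with spacing from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  volume_image(vals, spacing = RNifti::pixdim(img)[1:3],
               origin = RNifti::xform(img)[1:3, 4])
}
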