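#' Spherical region of interest
#'
#' Builds a voxel mask of all voxels whose centers lie within `radius` mm of
#' `center` on the volume's grid.
#'
#' @param volume a `volume_image`.
#' @param center mm triple (x, y, z).
#' @param radius sphere radius, mm.
#' @param label ROI label.
#' @return an object of class `roi_mask`: logical grid plus geometry.
#' @export
make_sphere_roi <- function(volume, center, radius, label = "roi") {
  stopifnot(radius > 0)
  xc <- axis_centers(volume, 1); yc <- axis_centers(volume, 2)
  zc <- axis_centers(volume, 3)
  dx2 <- (xc - center[1])^2
  dy2 <- (yc - center[2])^2
  dz2 <- (zc - center[3])^2
  d <- dim(volume$values)
  grid <- array(
    outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2,
    dim = d
  )
  if (!any(grid))
    stop("sphere ROI '", label, "' does not intersect the volume grid")
  structure(
    list(label = label, center = as.numeric(center), radius = radius,
         grid = grid, spacing = volume$spacing, origin = volume$origin),
    class = "roi_mask"
  )
}

#' Select the 2-D analysis plane of an ROI
#'
#' Finds the orientation (axial = fixed z, coronal = fixed y, sagittal =
#' fixed x) and slice whose in-plane mask diameter — the maximum pairwise
#' distance between in-mask voxel centers, in mm — is largest. Ties are
#' broken axial > coronal > sagittal, then lowest slice index.
#'
#' @param mask an `roi_mask`.
#' @return list with `plane` (`"axial"`, `"coronal"`, `"sagittal"`),
#'   `slice` (index along the fixed axis), and `diameter` (mm).
#' @export
select_2d_plane <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!any(mask$grid)) stop("empty ROI mask")
  sp <- mask$spacing
  planes <- list(axial = 3L, coronal = 2L, sagittal = 1L)
  best <- NULL
  for (pn in names(planes)) {
    ax <- planes[[pn]]
    inplane <- setdiff(1:3, ax)
    n <- dim(mask$grid)[ax]
    for (s in seq_len(n)) {
      sl <- switch(ax, mask$grid[s, , ], mask$grid[, s, ], mask$grid[, , s])
      w <- which(sl, arr.ind = TRUE)
      if (nrow(w) == 0) next
      pts <- cbind(w[, 1] * sp[inplane[1]], w[, 2] * sp[inplane[2]])
      dia <- if (nrow(pts) == 1) 0 else max(stats::dist(pts))
      if (is.null(best) || dia > best$diameter + 1e-9) {
        best <- list(plane = pn, slice = s, diameter = dia)
      }
    }
  }
  best
}

# 2-D logical/level slice of an array in a named orientation
plane_slice_of <- function(arr, plane, slice) {
  switch(plane,
    axial = arr[, , slice],
    coronal = arr[, slice, ],
    sagittal = arr[slice, , ]
  )
}

#' Quantize an ROI sample to gray-level bins
#'
#' Extracts the HU values under the mask, optionally drops air-bubble
#' voxels below `hu_floor`, clips to the 12-bit CT window \[-1024, 3071\],
#' and maps values to `n_bins` equal-width bins over the ROI's own
#' \[min, max\] range (the maximum maps to bin `n_bins`; a constant sample
#' maps to bin 1). Also selects the largest-diameter 2-D analysis plane.
#'
#' @param volume a `volume_image`.
#' @param mask an `roi_mask` on the same grid.
#' @param n_bins number of gray-level bins (default 20).
#' @param hu_floor drop voxels below this HU before quantization (emulating
#'   exclusion of air bubbles); `NULL` disables.
#' @return an object of class `quantized_roi`: `hu` (raw values), `bins`
#'   (bin levels, same order), `index` (voxel indices), `bin_array` (bin
#'   levels on the mask bounding box, NA outside the mask), `n_bins`,
#'   `spacing`, `plane`, `plane_slice_index`, `plane_slice` (2-D bin grid of
#'   the selected slice, NA outside the mask).
#' @export
quantize <- function(volume, mask, n_bins = 20, hu_floor = -200) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "roi_mask"),
            all(dim(volume$values) == dim(mask$grid)), n_bins >= 2)
  grid <- mask$grid
  hu <- volume$values[grid]
  if (anyNA(hu)) stop("NaN/NA values inside the ROI")
  if (!is.null(hu_floor)) {
    keep <- hu >= hu_floor
    if (!all(keep)) {
      grid <- grid & (volume$values >= hu_floor)
      hu <- volume$values[grid]
    }
  }
  if (length(hu) < 1) stop("ROI empty after air-bubble exclusion")
  hu <- pmin(pmax(hu, -1024), 3071)

  rng <- range(hu)
  if (rng[2] > rng[1]) {
    w <- (rng[2] - rng[1]) / n_bins
    bins <- pmin(n_bins, floor((hu - rng[1]) / w) + 1L)
  } else {
    bins <- rep(1L, length(hu))
  }

  idx <- which(grid, arr.ind = TRUE)
  # bounding-box bin array, NA outside the mask
  rng_i <- apply(idx, 2, range)
  bb <- array(NA_integer_, dim = rng_i[2, ] - rng_i[1, ] + 1)
  bb[cbind(idx[, 1] - rng_i[1, 1] + 1,
           idx[, 2] - rng_i[1, 2] + 1,
           idx[, 3] - rng_i[1, 3] + 1)] <- bins

  msk <- mask
  msk$grid <- grid
  pl <- select_2d_plane(msk)
  full_bins <- array(NA_integer_, dim = dim(grid))
  full_bins[grid] <- bins
  pslice <- plane_slice_of(full_bins, pl$plane, pl$slice)

  structure(
    list(hu = hu, bins = as.integer(bins), index = idx, bin_array = bb,
         n_bins = as.integer(n_bins), spacing = volume$spacing,
         plane = pl$plane, plane_slice_index = pl$slice,
         plane_slice = pslice),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d voxels, %d bins, plane %s slice %d\n",
              length(x$hu), x$n_bins, x$plane, x$plane_slice_index))
  invisible(x)
}

#' Write an ROI mask as a 0/1 NIfTI volume
#'
#' @param mask an `roi_mask`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  vol <- volume_image(array(as.numeric(mask$grid), dim = dim(mask$grid)),
                      spacing = mask$spacing, origin = mask$origin)
  write_volume(vol, path)
}
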