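#' Digital texture-phantom specification
#'
#' Describes a short cylinder of homogeneous background material containing
#' square texture regions, each filled with a deterministic periodic binary
#' lattice of insert material at a prescribed volume fraction. The default
#' geometry is a 15 cm cylinder with three 5 x 5 cm patterns at 10%, 20% and
#' 40% fill, the texture span of soft-tissue tumors on CT.
#'
#' @param cylinder_diameter cylinder diameter, mm.
#' @param cylinder_length cylinder length, mm.
#' @param pattern_regions list of regions, each
#'   `list(center = c(x, y, z) mm, extent = mm, fill_fraction = [0, 1])`.
#'   Regions are `extent` x `extent` boxes in-plane (and at most `extent`
#'   along z, clipped to the cylinder).
#' @param background_hu background material attenuation, HU.
#' @param insert_hu insert (lattice) material attenuation, HU.
#' @param lattice_period texture lattice period, mm.
#' @param supersample_factor integer >= 1; the ground-truth grid resolves
#'   each lattice period into `supersample_factor` voxels per axis, so the
#'   truth voxel size is `lattice_period / supersample_factor` mm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_diameter = 150,
                         cylinder_length = 40,
                         pattern_regions = default_pattern_regions(),
                         background_hu = 40,
                         insert_hu = -40,
                         lattice_period = 2,
                         supersample_factor = 2) {
  stopifnot(cylinder_diameter > 0, cylinder_length > 0, lattice_period > 0)
  if (supersample_factor < 1 || supersample_factor != round(supersample_factor))
    stop("supersample_factor must be a positive integer")
  r <- cylinder_diameter / 2
  for (reg in pattern_regions) {
    f <- reg$fill_fraction
    if (!is.finite(f) || f < 0 || f > 1)
      stop("fill fractions must lie in [0, 1]")
    # all four in-plane corners strictly inside the cylinder
    h <- reg$extent / 2
    cx <- reg$center[1]; cy <- reg$center[2]
    corners <- rbind(
      c(cx - h, cy - h), c(cx - h, cy + h),
      c(cx + h, cy - h), c(cx + h, cy + h)
    )
    if (any(rowSums(corners^2) >= r^2))
      stop("pattern region extends outside the cylinder")
  }
  if (length(pattern_regions) > 1) {
    for (i in seq_along(pattern_regions)[-1]) for (j in seq_len(i - 1)) {
      a <- pattern_regions[[i]]; b <- pattern_regions[[j]]
      sep <- abs(a$center[1:2] - b$center[1:2]) >= (a$extent + b$extent) / 2
      if (!any(sep))
        stop("pattern regions overlap: regions ", j, " and ", i)
    }
  }
  structure(
    list(
      cylinder_diameter = cylinder_diameter,
      cylinder_length = cylinder_length,
      pattern_regions = pattern_regions,
      background_hu = background_hu,
      insert_hu = insert_hu,
      lattice_period = lattice_period,
      supersample_factor = as.integer(supersample_factor)
    ),
    class = "phantom_spec"
  )
}

#' Default texture-pattern layout
#'
#' Three 5 x 5 cm regions at 10/20/40% fill, centered 38 mm off-axis at
#' 120-degree spacing so each fits strictly inside a 15 cm cylinder.
#'
#' @param fill_fractions fill fractions of the three regions.
#' @param extent region edge length, mm.
#' @param offset radial offset of region centers, mm.
#' @param z_center z position of region centers, mm.
#' @return list of region definitions for [phantom_spec()].
#' @export
default_pattern_regions <- function(fill_fractions = c(0.10, 0.20, 0.40),
                                    extent = 50, offset = 38, z_center = 20) {
  angles <- c(90, 210, 330) * pi / 180
  lapply(seq_along(fill_fractions), function(i) {
    list(
      center = c(offset * cos(angles[i]), offset * sin(angles[i]), z_center),
      extent = extent,
      fill_fraction = fill_fractions[i]
    )
  })
}

# Deterministic threshold lattice for one period cell: ranks the S^3 subcells
# by an integer hash so that a fraction-f threshold selects round-to-rank
# (f * S^3) subcells. Periodic, binary, occupancy error <= 1/(2 S^3).
lattice_thresholds <- function(s) {
  idx <- expand.grid(i = 0:(s - 1), j = 0:(s - 1), k = 0:(s - 1))
  key <- bitwXor(
    bitwXor(as.integer(idx$i * 73856093L %% 2147483647),
            as.integer(idx$j * 19349663L %% 2147483647)),
    as.integer(idx$k * 83492791L %% 2147483647)
  )
  rk <- order(order(key, seq_along(key)))  # ranks 1..S^3, ties by index
  array((rk - 0.5) / s^3, dim = c(s, s, s))
}

#' Build the ground-truth phantom volume
#'
#' Rasterizes the phantom on an isotropic grid with voxel size
#' `lattice_period / supersample_factor`. Outside the cylinder the volume is
#' air (-1000 HU); inside, background material; within each pattern region a
#' periodic binary lattice places insert material at the region's fill
#' fraction.
#'
#' @param spec a [phantom_spec()].
#' @return a `volume_image` with the spec attached as attribute `"spec"`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$lattice_period / spec$supersample_factor
  r <- spec$cylinder_diameter / 2
  nx <- ceiling(spec$cylinder_diameter / sp)
  nz <- ceiling(spec$cylinder_length / sp)
  ox <- -((nx - 1) / 2) * sp
  xc <- ox + (seq_len(nx) - 1) * sp
  zc <- (seq_len(nz) - 0.5) * sp

  in_cyl <- outer(xc^2, xc^2, `+`) <= r^2
  slice <- matrix(-1000, nx, nx)
  slice[in_cyl] <- spec$background_hu
  vals <- array(slice, dim = c(nx, nx, nz))

  s <- spec$supersample_factor
  thr <- lattice_thresholds(s)
  for (reg in spec$pattern_regions) {
    h <- reg$extent / 2
    ix <- which(abs(xc - reg$center[1]) <= h)
    iy <- which(abs(xc - reg$center[2]) <= h)
    iz <- which(abs(zc - reg$center[3]) <= h)
    if (!length(ix) || !length(iy) || !length(iz)) next
    thr_sub <- thr[(ix - 1) %% s + 1, (iy - 1) %% s + 1, (iz - 1) %% s + 1,
                   drop = FALSE]
    sub <- vals[ix, iy, iz, drop = FALSE]
    sub[thr_sub <= reg$fill_fraction] <- spec$insert_hu
    vals[ix, iy, iz] <- sub
  }

  out <- volume_image(vals, spacing = c(sp, sp, sp), origin = c(ox, ox, sp / 2))
  attr(out, "spec") <- spec
  out
}

#' Measured lattice occupancy of a pattern region
#'
#' Fraction of ground-truth voxels inside a pattern region that hold insert
#' material; converges to the requested fill fraction as the supersampling
#' factor grows.
#'
#' @param truth output of [build_phantom()].
#' @param region_index which pattern region.
#' @return occupancy fraction in \[0, 1\].
#' @export
region_occupancy <- function(truth, region_index) {
  spec <- attr(truth, "spec")
  reg <- spec$pattern_regions[[region_index]]
  xc <- axis_centers(truth, 1); yc <- axis_centers(truth, 2)
  zc <- axis_centers(truth, 3)
  h <- reg$extent / 2
  ix <- which(abs(xc - reg$center[1]) <= h)
  iy <- which(abs(yc - reg$center[2]) <= h)
  iz <- which(abs(zc - reg$center[3]) <= h)
  sub <- truth$values[ix, iy, iz]
  mean(sub == spec$insert_hu)
}
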