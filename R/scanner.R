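#' Virtual scanner profile
#'
#' Parametric model of one CT scanner: HU calibration offset, reference
#' noise level, tube-voltage contrast scaling, the exposed edge-preserving
#' filter strengths, and the value lists of the one-factor-at-a-time
#' acquisition matrix.
#'
#' @param scanner_id identifier, e.g. `"A"`.
#' @param hu_offset additive HU calibration offset of this scanner.
#' @param noise_sigma_ref noise standard deviation (HU) at `reference_ma`.
#' @param reference_ma tube current (mA) at which `noise_sigma_ref` applies;
#'   noise scales as `sqrt(reference_ma / ma)`.
#' @param kvp_values tube voltages (kVp) supported by the scanner; the
#'   contrast factor is linear in kVp: 1 at 100 kVp, +5% per 20 kVp decrease.
#' @param filter_levels integer strengths of the exposed reconstruction
#'   filter settings (6 levels on scanner A, 2 on scanner B).
#' @param filter_range_sigma range sigma of the edge-preserving filter per
#'   strength level, HU (0 disables filtering entirely).
#' @param settings_matrix named list of value vectors varied one at a time:
#'   `slice_thickness` (mm), `fov` (mm), `filter`, `kvp`, `ma`.
#' @param baseline named list of the baseline acquisition
#'   (`slice_thickness`, `fov`, `kvp`, `ma`, `filter`).
#' @param matrix_size in-plane reconstruction matrix (pixels per axis);
#'   pixel size is `fov / matrix_size`.
#' @return an object of class `scanner_profile`.
#' @export
scanner_profile <- function(scanner_id,
                            hu_offset = 0,
                            noise_sigma_ref = 12,
                            reference_ma = 100,
                            kvp_values = c(80, 100, 140),
                            filter_levels = 1:6,
                            filter_range_sigma = 20,
                            settings_matrix = list(
                              slice_thickness = 1:5,
                              fov = c(125, 500),
                              filter = filter_levels,
                              kvp = kvp_values,
                              ma = c(40, 60, 80, 100)
                            ),
                            baseline = list(slice_thickness = 3, fov = 500,
                                            kvp = 100, ma = 100, filter = 0),
                            matrix_size = 512) {
  stopifnot(noise_sigma_ref >= 0, reference_ma > 0, matrix_size >= 8)
  contrast <- stats::setNames(1 - 0.05 * (kvp_values - 100) / 20,
                              as.character(kvp_values))
  structure(
    list(
      scanner_id = scanner_id,
      hu_offset = hu_offset,
      noise_sigma_ref = noise_sigma_ref,
      reference_ma = reference_ma,
      kvp_contrast_scale = contrast,
      filter_levels = filter_levels,
      filter_range_sigma = filter_range_sigma,
      settings_matrix = settings_matrix,
      baseline = baseline,
      matrix_size = matrix_size
    ),
    class = "scanner_profile"
  )
}

#' Default two-scanner study profiles
#'
#' Scanner A: 6 filter levels, 3 tube voltages, reference noise 12 HU, no HU
#' offset. Scanner B: 2 filter levels ("Mild"/"Strong", strengths 2 and 5),
#' 2 tube voltages, reference noise 18 HU, +4 HU offset. Together with the
#' shared slice-thickness, FOV and mA lists these give 21 and 16 settings.
#'
#' @param matrix_size reconstruction matrix for both scanners.
#' @param fast if `TRUE`, trim to 2 filter levels and 2 mA values per
#'   scanner (a reduced profile for quick replicate studies).
#' @return named list with profiles `A` and `B`.
#' @export
default_scanner_profiles <- function(matrix_size = 512, fast = FALSE) {
  fa <- if (fast) c(3L, 6L) else 1:6
  ma <- if (fast) c(40, 100) else c(40, 60, 80, 100)
  a <- scanner_profile(
    "A", hu_offset = 0, noise_sigma_ref = 12,
    kvp_values = c(80, 100, 140), filter_levels = fa,
    settings_matrix = list(slice_thickness = 1:5, fov = c(125, 500),
                           filter = fa, kvp = c(80, 100, 140), ma = ma),
    matrix_size = matrix_size
  )
  fb <- c(2L, 5L)  # "Mild" and "Strong"
  b <- scanner_profile(
    "B", hu_offset = 4, noise_sigma_ref = 18,
    kvp_values = c(100, 135), filter_levels = fb,
    settings_matrix = list(slice_thickness = 1:5, fov = c(125, 500),
                           filter = fb, kvp = c(100, 135), ma = ma),
    matrix_size = matrix_size
  )
  list(A = a, B = b)
}

#' One acquisition setting
#'
#' @param scanner_id scanner identifier.
#' @param slice_thickness slice thickness, mm.
#' @param fov field of view, mm.
#' @param kvp tube voltage, kVp.
#' @param ma tube current, mA.
#' @param filter_level reconstruction filter strength (0 = none).
#' @param varied_parameter which parameter differs from baseline, one of
#'   `"baseline"`, `"slice_thickness"`, `"fov"`, `"filter"`, `"kvp"`, `"ma"`.
#' @param repeat_index 0 for the initial scan, 1 for the 15-min re-scan.
#' @param seed noise seed for this volume.
#' @param setting_id identifier of the setting (shared by both repeats).
#' @return an object of class `acquisition_setting`.
#' @export
acquisition_setting <- function(scanner_id, slice_thickness, fov, kvp, ma,
                                filter_level = 0,
                                varied_parameter = "baseline",
                                repeat_index = 0L, seed = 1L,
                                setting_id = NA_character_) {
  stopifnot(slice_thickness > 0, fov > 0, ma > 0, filter_level >= 0,
            repeat_index %in% c(0L, 1L))
  varied_parameter <- match.arg(
    varied_parameter,
    c("baseline", "slice_thickness", "fov", "filter", "kvp", "ma")
  )
  structure(
    list(scanner_id = scanner_id, slice_thickness = slice_thickness,
         fov = fov, kvp = kvp, ma = ma, filter_level = filter_level,
         varied_parameter = varied_parameter,
         repeat_index = as.integer(repeat_index), seed = as.integer(seed),
         setting_id = setting_id),
    class = "acquisition_setting"
  )
}

# shift a matrix by (di, dj), NA outside
shift_mat <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(NA_real_, n1, n2)
  si <- max(1, 1 - di):min(n1, n1 - di)
  sj <- max(1, 1 - dj):min(n2, n2 - dj)
  out[si, sj] <- m[si + di, sj + dj]
  out
}

# edge-preserving (bilateral) smoothing of one slice: 5x5 window,
# spatial sigma in pixels, range sigma in HU
bilateral2d <- function(m, sigma_s = 1, sigma_r = 20) {
  acc <- m * 0
  wsum <- acc
  for (di in -2:2) for (dj in -2:2) {
    ws <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
    ms <- shift_mat(m, di, dj)
    w <- ws * exp(-(ms - m)^2 / (2 * sigma_r^2))
    w[is.na(ms)] <- 0
    ms[is.na(ms)] <- 0
    acc <- acc + w * ms
    wsum <- wsum + w
  }
  acc / wsum
}

#' Apply the edge-preserving reconstruction filter to a volume
#'
#' Slice-wise bilateral smoothing (5 x 5 window, spatial sigma 1 pixel)
#' with range sigma `range_sigma * level` HU; level 0 is the identity.
#'
#' @param vol a `volume_image`.
#' @param level filter strength level (integer >= 0).
#' @param range_sigma range sigma per level, HU.
#' @return the filtered `volume_image`.
#' @export
apply_filter <- function(vol, level, range_sigma = 20) {
  if (level <= 0 || range_sigma <= 0) return(vol)
  for (k in seq_len(dim(vol$values)[3]))
    vol$values[, , k] <- bilateral2d(vol$values[, , k], 1, range_sigma * level)
  vol
}

# cache of truth-voxel -> target-voxel partial-volume mappings
.pv_cache <- new.env(parent = emptyenv())

pv_mapping <- function(truth, n, fov, st, nz) {
  key <- paste(c(dim(truth$values), truth$spacing, truth$origin,
                 n, fov, st, nz), collapse = "|")
  hit <- .pv_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- fov / n
  xc <- axis_centers(truth, 1); yc <- axis_centers(truth, 2)
  zc <- axis_centers(truth, 3)
  ix <- floor((xc + fov / 2) / p) + 1
  iy <- floor((yc + fov / 2) / p) + 1
  iz <- floor(zc / st) + 1
  ix[ix < 1 | ix > n] <- NA; iy[iy < 1 | iy > n] <- NA
  iz[iz < 1 | iz > nz] <- NA
  d <- dim(truth$values)
  lin <- rep(ix, times = d[2] * d[3]) +
    n * (rep(rep(iy - 1, each = d[1]), times = d[3])) +
    n * n * (rep(iz - 1, each = d[1] * d[2]))
  keep <- which(!is.na(lin))
  lin <- lin[keep]
  counts <- tabulate(lin, n * n * nz)
  map <- list(keep = keep, lin = lin, counts = counts)
  .pv_cache[[key]] <- map
  map
}

#' Simulate one CT acquisition of the phantom
#'
#' Produces a reconstructed volume on a `matrix_size` x `matrix_size`
#' in-plane grid (pixel size `fov / matrix_size`) at the setting's slice
#' thickness by, in order: partial-volume averaging of the ground truth into
#' target voxels; kVp-dependent contrast scaling of (HU - background);
#' additive zero-mean Gaussian noise with sigma
#' `noise_sigma_ref * sqrt(reference_ma / ma)` seeded by `setting$seed`;
#' edge-preserving smoothing at the setting's filter level (0 = none); and
#' the scanner's HU offset.
#'
#' @param truth ground-truth volume from [build_phantom()].
#' @param setting an [acquisition_setting()].
#' @param profile a [scanner_profile()].
#' @return a `volume_image`.
#' @export
simulate_acquisition <- function(truth, setting, profile) {
  n <- profile$matrix_size
  fov <- setting$fov
  st <- setting$slice_thickness
  p <- fov / n
  kc <- profile$kvp_contrast_scale[as.character(setting$kvp)]
  if (is.na(kc))
    stop("kVp ", setting$kvp, " not supported by scanner ", profile$scanner_id)
  spec <- attr(truth, "spec")
  ext <- dim(truth$values) * truth$spacing
  if (p > ext[1] || p > ext[2] || st > ext[3])
    stop("target voxel larger than the phantom extent")
  if (any(truth$spacing > c(p, p, st) + 1e-9))
    stop("ground truth must be at least as fine as the target grid ",
         sprintf("(truth %.3g/%.3g mm vs target %.3g/%.3g mm)",
                 max(truth$spacing[1:2]), truth$spacing[3], p, st))
  nz <- max(1L, floor(ext[3] / st + 1e-9))

  map <- pv_mapping(truth, n, fov, st, nz)
  sums <- numeric(n * n * nz)
  rs <- rowsum(truth$values[map$keep], map$lin)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  vals <- rep(-1000, n * n * nz)          # uncovered target voxels are air
  cov <- map$counts > 0
  vals[cov] <- sums[cov] / map$counts[cov]

  bg <- if (!is.null(spec)) spec$background_hu else 0
  vals <- bg + (vals - bg) * kc

  sigma <- profile$noise_sigma_ref * sqrt(profile$reference_ma / setting$ma)
  if (sigma > 0)
    vals <- vals + with_seed(setting$seed, stats::rnorm(length(vals), 0, sigma))

  out <- volume_image(array(vals, dim = c(n, n, nz)),
                      spacing = c(p, p, st),
                      origin = c(-fov / 2 + p / 2, -fov / 2 + p / 2, st / 2))
  out <- apply_filter(out, setting$filter_level, profile$filter_range_sigma)
  out$values <- out$values + profile$hu_offset
  out
}

#' Simulate a test-retest pair
#'
#' Two acquisitions at identical parameters with independent noise seeds,
#' emulating scans taken 15 minutes apart.
#'
#' @inheritParams simulate_acquisition
#' @param reseed noise seed of the re-scan; defaults to a seed derived from
#'   the setting's own. Forcing `reseed = setting$seed` yields voxelwise
#'   identical volumes.
#' @return list of two `volume_image`s.
#' @export
test_retest_pair <- function(truth, setting, profile,
                             reseed = derive_seed(setting$seed, 1, 1, 1)) {
  first <- simulate_acquisition(truth, setting, profile)
  s2 <- setting
  s2$seed <- as.integer(reseed)
  s2$repeat_index <- 1L
  list(first, simulate_acquisition(truth, s2, profile))
}

# enumerate the one-factor-at-a-time settings of one scanner
scanner_settings <- function(profile, scanner_idx, master_seed) {
  bl <- profile$baseline
  rows <- list(list(varied = "baseline", slice = bl$slice_thickness,
                    fov = bl$fov, kvp = bl$kvp, ma = bl$ma,
                    filter = bl$filter))
  sm <- profile$settings_matrix
  add <- function(rows, family, values, field) {
    for (v in values) {
      r <- rows[[1]]
      r$varied <- family
      r[[field]] <- v
      rows[[length(rows) + 1]] <- r
    }
    rows
  }
  rows <- add(rows, "slice_thickness", sm$slice_thickness, "slice")
  rows <- add(rows, "fov", sm$fov, "fov")
  rows <- add(rows, "filter", sm$filter, "filter")
  rows <- add(rows, "kvp", sm$kvp, "kvp")
  rows <- add(rows, "ma", sm$ma, "ma")

  out <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    sid <- sprintf("%s%02d", profile$scanner_id, i)
    for (rep_i in 0:1) {
      out[[length(out) + 1]] <- acquisition_setting(
        scanner_id = profile$scanner_id,
        slice_thickness = r$slice, fov = r$fov, kvp = r$kvp, ma = r$ma,
        filter_level = r$filter, varied_parameter = r$varied,
        repeat_index = rep_i,
        seed = derive_seed(master_seed, scanner_idx, i, rep_i),
        setting_id = sid
      )
    }
  }
  out
}

#' Generate a full two-scanner phantom study
#'
#' Enumerates, for each scanner, the baseline setting plus one setting per
#' value in each parameter family (one factor at a time), each acquired
#' twice (test-retest with independent noise seeds), and simulates every
#' volume. With the default profiles this yields 21 settings on scanner A
#' and 16 on scanner B, 74 volumes in total.
#'
#' @param spec a [phantom_spec()].
#' @param profiles named list of two [scanner_profile()]s.
#' @param master_seed integer; every per-volume seed derives from it.
#' @param simulate if `FALSE`, return only the manifest and settings.
#' @return an object of class `ctta_study`: list with `manifest`
#'   (data.frame), `settings` (list of [acquisition_setting()]), `volumes`
#'   (named list of `volume_image`, key `<setting_id>_r<repeat>`), `spec`,
#'   `profiles`, `master_seed`.
#' @export
generate_study <- function(spec, profiles, master_seed = 1L,
                           simulate = TRUE) {
  stopifnot(length(profiles) == 2)
  truth <- build_phantom(spec)
  settings <- list()
  for (si in seq_along(profiles))
    settings <- c(settings, scanner_settings(profiles[[si]], si, master_seed))

  manifest <- do.call(rbind, lapply(settings, function(s) {
    data.frame(
      scanner_id = s$scanner_id, setting_id = s$setting_id,
      varied_parameter = s$varied_parameter,
      slice_thickness = s$slice_thickness, fov = s$fov, kvp = s$kvp,
      ma = s$ma, filter_level = s$filter_level,
      repeat_index = s$repeat_index, seed = s$seed,
      volume_key = sprintf("%s_r%d", s$setting_id, s$repeat_index),
      stringsAsFactors = FALSE
    )
  }))

  volumes <- NULL
  if (simulate) {
    prof_by_id <- stats::setNames(profiles,
                                  vapply(profiles, `[[`, "", "scanner_id"))
    volumes <- stats::setNames(
      lapply(settings, function(s)
        simulate_acquisition(truth, s, prof_by_id[[s$scanner_id]])),
      manifest$volume_key
    )
  }

  structure(
    list(manifest = manifest, settings = settings, volumes = volumes,
         truth = truth, spec = spec, profiles = profiles,
         master_seed = master_seed),
    class = "ctta_study"
  )
}

#' @export
print.ctta_study <- function(x, ...) {
  m <- x$manifest
  per <- table(m$scanner_id[m$repeat_index == 0])
  cat(sprintf("<ctta_study> %d volumes; settings per scanner: %s\n",
              nrow(m), paste(sprintf("%s=%d", names(per), per),
                             collapse = ", ")))
  invisible(x)
}
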