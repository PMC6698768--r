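#' Load a pipeline configuration
#'
#' Reads a YAML configuration describing the phantom, the two scanner
#' profiles, the ROI and analysis parameters, and the master seed, and
#' resolves it into package objects. The shipped default
#' (`system.file("extdata", "default_config.yaml", package =
#' "cttaphantom")`) reproduces the full two-scanner acquisition matrix.
#'
#' @param path YAML file path, or `NULL` for the shipped default.
#' @return list with `spec` ([phantom_spec()]), `profiles` (two
#'   [scanner_profile()]s), `rois`, `analysis` (n_bins, tally_cutoff,
#'   reliable_band, clip_max), `master_seed`, and the `raw` YAML list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml",
                        package = "cttaphantom")
  raw <- yaml::read_yaml(path)
  ph <- raw$phantom
  spec <- phantom_spec(
    cylinder_diameter = ph$cylinder_diameter,
    cylinder_length = ph$cylinder_length,
    pattern_regions = default_pattern_regions(
      fill_fractions = as.numeric(ph$fill_fractions),
      z_center = ph$cylinder_length / 2
    ),
    background_hu = ph$background_hu, insert_hu = ph$insert_hu,
    lattice_period = ph$lattice_period,
    supersample_factor = ph$supersample_factor
  )
  mk_profile <- function(id, s) {
    scanner_profile(
      scanner_id = id,
      hu_offset = s$hu_offset, noise_sigma_ref = s$noise_sigma_ref,
      reference_ma = s$reference_ma,
      kvp_values = as.numeric(s$kvp),
      filter_levels = as.integer(s$filter_levels),
      filter_range_sigma = s$filter_range_sigma,
      settings_matrix = list(
        slice_thickness = as.numeric(s$slice_thickness),
        fov = as.numeric(s$fov), filter = as.integer(s$filter_levels),
        kvp = as.numeric(s$kvp), ma = as.numeric(s$ma)
      ),
      baseline = s$baseline,
      matrix_size = raw$scanners$matrix_size
    )
  }
  profiles <- list(A = mk_profile("A", raw$scanners$A),
                   B = mk_profile("B", raw$scanners$B))
  rois <- default_rois(spec, radius = raw$rois$radius)
  list(spec = spec, profiles = profiles, rois = rois,
       analysis = raw$analysis, master_seed = raw$master_seed, raw = raw)
}

#' Simulate a study and write it to disk
#'
#' Writes one NIfTI volume per (scanner, setting, repeat), a CSV manifest,
#' and an echo of the resolved configuration.
#'
#' @param config list from [load_config()].
#' @param out_dir output directory.
#' @param force overwrite a directory holding a previous (possibly partial)
#'   study.
#' @param seed master seed override (defaults to the config's).
#' @return the study manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir, force = FALSE, seed = NULL) {
  if (file.exists(file.path(out_dir, "manifest.csv")) && !force)
    stop("output directory already holds a study; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ms <- if (is.null(seed)) config$master_seed else seed
  study <- generate_study(config$spec, config$profiles, master_seed = ms)
  man <- study$manifest
  man$filename <- paste0(man$volume_key, ".nii.gz")
  for (i in seq_len(nrow(man)))
    write_volume(study$volumes[[man$volume_key[i]]],
                 file.path(out_dir, man$filename[i]))
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config$raw, file.path(out_dir, "config_resolved.yaml"))
  invisible(man)
}

#' Extract the texture panel from a study on disk
#'
#' @param study_dir directory written by [run_simulate()].
#' @param config list from [load_config()].
#' @return the long feature table; also written to
#'   `<study_dir>/features.csv`.
#' @export
run_extract <- function(study_dir, config) {
  man_path <- file.path(study_dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", study_dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  volumes <- stats::setNames(
    lapply(file.path(study_dir, man$filename), read_volume),
    man$volume_key
  )
  study <- structure(
    list(manifest = man, volumes = volumes, spec = config$spec),
    class = "ctta_study"
  )
  feats <- extract_features(study, rois = config$rois,
                            n_bins = config$analysis$n_bins)
  utils::write.csv(feats, file.path(study_dir, "features.csv"),
                   row.names = FALSE)
  feats
}

#' Reliability assessment of a feature table
#'
#' Runs the repeatability, robustness, reliability and filter-effect
#' analyses and writes comparisons, the per-feature report, family tallies
#' and heatmaps.
#'
#' @param features long feature table.
#' @param config list from [load_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param manifest study manifest (for the filter-effect contrast); `NULL`
#'   skips that analysis.
#' @return list with `repeatability`, `robustness`, `report`,
#'   `filter_effect`.
#' @export
run_assess <- function(features, config, out_dir = NULL, manifest = NULL) {
  if (nrow(features) == 0) stop("empty feature table")
  cutoff <- config$analysis$tally_cutoff
  band <- config$analysis$reliable_band
  rep_t <- repeatability_table(features, cutoff = cutoff)
  rob_t <- robustness_table(features, cutoff = cutoff)
  report <- reliable_set(rep_t, rob_t, band = band)
  fe <- if (!is.null(manifest)) filter_effect_contrast(rob_t, manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rec <- rbind(rep_t$records, rob_t$records)
    utils::write.csv(rec, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(report$features,
                     file.path(out_dir, "reliability_report.csv"),
                     row.names = FALSE)
    utils::write.csv(rob_t$family_tally,
                     file.path(out_dir, "family_tally.csv"),
                     row.names = FALSE)
    heatmap_export(rec, out_dir, clip_max = config$analysis$clip_max,
                   band = band)
  }
  list(repeatability = rep_t, robustness = rob_t, report = report,
       filter_effect = fe)
}

#' Run a full study in memory
#'
#' Convenience wrapper: simulate, extract and assess without touching disk.
#'
#' @param config list from [load_config()].
#' @param seed master seed override.
#' @return list with `study`, `features` and the [run_assess()] results.
#' @export
run_study <- function(config, seed = NULL) {
  ms <- if (is.null(seed)) config$master_seed else seed
  study <- generate_study(config$spec, config$profiles, master_seed = ms)
  features <- extract_features(study, rois = config$rois,
                               n_bins = config$analysis$n_bins)
  assess <- run_assess(features, config, out_dir = NULL,
                       manifest = study$manifest)
  c(list(study = study, features = features), assess)
}

#' Monte-Carlo trend of texture-metric change with filter strength
#'
#' Measures how far each reconstruction-filter level moves the texture
#' panel from the unfiltered image. Per replicate, one noisy unfiltered
#' acquisition is simulated at the baseline setting and every filter level
#' is applied to that same acquisition (paired design: the noise
#' realization is shared across levels, so the curve isolates the filter
#' effect); the summary per level is the mean finite PAD of the
#' second-order (noise-sensitive) feature families against the unfiltered
#' panel, averaged over ROIs and replicates.
#'
#' @param spec a [phantom_spec()].
#' @param profile a [scanner_profile()] (its baseline and
#'   `filter_range_sigma` are used).
#' @param levels filter levels to assess.
#' @param n_rep number of noise replicates.
#' @param seed master seed.
#' @param rois ROI definitions (default: the phantom's three).
#' @param families feature families summarized (default: the second-order
#'   GLCM/GLDM/GLRLM blocks).
#' @return named numeric vector: replicate-mean of mean PAD per level.
#' @export
filter_level_trend <- function(spec, profile, levels = 1:6, n_rep = 10,
                               seed = 1, rois = NULL,
                               families = c("glcm2d", "gldm2d", "glcm3d",
                                            "gldm3d", "glrlm2d", "glrlm3d")) {
  truth <- build_phantom(spec)
  if (is.null(rois)) rois <- default_rois(spec)
  sel <- feature_manifest()$family %in% families
  bl <- profile$baseline
  res <- matrix(NA_real_, n_rep, length(levels))
  for (r in seq_len(n_rep)) {
    s0 <- acquisition_setting(
      profile$scanner_id, bl$slice_thickness, bl$fov, bl$kvp, bl$ma,
      filter_level = 0, varied_parameter = "baseline",
      seed = derive_seed(seed, 1, r, 0)
    )
    v0 <- simulate_acquisition(truth, s0, profile)
    base_panels <- lapply(rois, function(rd)
      extract_panel(quantize(v0, make_sphere_roi(v0, rd$center, rd$radius))))
    for (li in seq_along(levels)) {
      v <- apply_filter(v0, levels[li], profile$filter_range_sigma)
      per_roi <- vapply(seq_along(rois), function(i) {
        rd <- rois[[i]]
        fv <- extract_panel(quantize(v, make_sphere_roi(v, rd$center,
                                                        rd$radius)))
        p <- pad(as.numeric(fv), as.numeric(base_panels[[i]]))[sel]
        mean(p[is.finite(p)])
      }, 0)
      res[r, li] <- mean(per_roi)
    }
  }
  stats::setNames(colMeans(res), paste0("level", levels))
}

#' Noise level of a homogeneous volume region
#'
#' Standard deviation of the voxel values in a small corner block of the
#' first slice (air outside the phantom cylinder, uniform ground truth), a
#' direct probe of the simulated quantum noise.
#'
#' @param vol a `volume_image`.
#' @param block block edge length in voxels; the default (1/8 of the
#'   in-plane matrix) stays outside the default cylinder at every FOV.
#' @return standard deviation, HU.
#' @export
background_noise_sd <- function(vol, block = max(2, dim(vol$values)[1] %/% 8)) {
  stats::sd(vol$values[seq_len(block), seq_len(block), 1])
}

#' Reduced-size configuration for quick studies
#'
#' The shipped default acquisition matrix on a coarse reconstruction grid
#' (64 x 64) with a supersample factor of 2, for test and replicate runs.
#' Optionally trims to the reduced ("fast") profile: 2 filter levels and
#' 2 mA values per scanner.
#'
#' @param matrix_size reconstruction matrix.
#' @param fast use the reduced variation lists.
#' @param rois which default ROIs to keep (indices).
#' @return config list as from [load_config()].
#' @export
small_config <- function(matrix_size = 64, fast = FALSE, rois = 1:3) {
  cfg <- load_config()
  cfg$raw$scanners$matrix_size <- matrix_size
  cfg$profiles <- default_scanner_profiles(matrix_size = matrix_size,
                                           fast = fast)
  cfg$rois <- cfg$rois[rois]
  cfg
}
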