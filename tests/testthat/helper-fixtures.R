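# Small fixtures built in code.

# miniature phantom: 6 cm cylinder, one central 2 cm pattern region
tiny_spec <- function(fill = 0.4, supersample = 2) {
  phantom_spec(
    cylinder_diameter = 60, cylinder_length = 16,
    pattern_regions = list(
      list(center = c(0, 0, 8), extent = 20, fill_fraction = fill)
    ),
    supersample_factor = supersample
  )
}

# scanner with no variation lists (baseline only) on a coarse grid
tiny_profile <- function(id = "A", noise_sigma_ref = 0, matrix_size = 32,
                         fov = 64, ...) {
  scanner_profile(
    id, noise_sigma_ref = noise_sigma_ref,
    settings_matrix = list(slice_thickness = numeric(0), fov = numeric(0),
                           filter = integer(0), kvp = numeric(0),
                           ma = numeric(0)),
    baseline = list(slice_thickness = 2, fov = fov, kvp = 100, ma = 100,
                    filter = 0),
    matrix_size = matrix_size, ...
  )
}

tiny_setting <- function(profile, seed = 1, filter_level = 0, ma = 100,
                         repeat_index = 0, varied = "baseline") {
  bl <- profile$baseline
  acquisition_setting(
    profile$scanner_id, bl$slice_thickness, bl$fov, bl$kvp, ma,
    filter_level = filter_level, varied_parameter = varied,
    repeat_index = repeat_index, seed = seed, setting_id = "S01"
  )
}

# degenerate study config: all variation lists pinned to the baseline
# values, zero noise, filtering disabled -- the full-pipeline determinism
# conditions (every PAD exactly 0)
frozen_config <- function(matrix_size = 48) {
  cfg <- load_config()
  cfg$raw$scanners$matrix_size <- matrix_size
  mk <- function(id, hu_offset) scanner_profile(
    id, hu_offset = hu_offset, noise_sigma_ref = 0,
    kvp_values = 100, filter_levels = 0L, filter_range_sigma = 0,
    settings_matrix = list(slice_thickness = 3, fov = 500, filter = 0L,
                           kvp = 100, ma = 100),
    matrix_size = matrix_size
  )
  cfg$profiles <- list(A = mk("A", 0), B = mk("B", 4))
  cfg$rois <- cfg$rois[3]
  cfg
}

# synthetic long-format feature table for reliability-module unit tests:
# `values` is a named list scanner -> matrix [features x settings incl.
# baseline], repeats identical unless jitter supplied
synth_features <- function(n_feat = 4, settings = list(
                             A = c("baseline", "slice_thickness",
                                   "slice_thickness", "fov"),
                             B = c("baseline", "fov")),
                           value_fun = function(sc, set, f) f,
                           rois = "roi1") {
  rows <- list()
  for (sc in names(settings)) {
    fams <- settings[[sc]]
    for (si in seq_along(fams)) for (rep_i in 0:1) for (roi in rois) {
      for (f in seq_len(n_feat)) {
        rows[[length(rows) + 1]] <- data.frame(
          scanner_id = sc, setting_id = sprintf("%s%02d", sc, si),
          varied_parameter = fams[si], repeat_index = rep_i,
          roi_label = roi, feature_index = f,
          feature_name = paste0("f", f), family = "synthetic",
          value = value_fun(sc, si, f) + 0 * rep_i,
          degenerate_flag = FALSE, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
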