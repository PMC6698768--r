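#' Canonical 235-feature manifest
#'
#' The fixed ordering of the texture panel: histogram (1-13), 2-D GLCM+GLDM
#' (14-93), 3-D GLCM+GLDM (94-173), 2-D GLRLM (174-206), 3-D GLRLM
#' (207-217), FFT (218-235).
#'
#' @return data.frame with `feature_index`, `feature_name`, `family`.
#' @export
feature_manifest <- function() {
  hist_names <- paste0("hist_", c("mean", "variance", "skewness", "kurtosis",
                                  "median", "min", "max", "range", "p10",
                                  "p90", "mad", "energy", "entropy"))
  ang <- c("0", "45", "90", "135")
  agg4 <- c("mean", "range", "min", "max")
  n2 <- c(
    as.vector(sapply(ang, function(a) sprintf("glcm2d_%s_%s",
                                              glcm_stat_names, a))),
    as.vector(sapply(ang, function(a) sprintf("gldm2d_%s_%s",
                                              gldm_stat_names, a)))
  )
  n3 <- c(
    as.vector(sapply(agg4, function(a) sprintf("glcm3d_%s_%s",
                                               glcm_stat_names, a))),
    as.vector(sapply(agg4, function(a) sprintf("gldm3d_%s_%s",
                                               gldm_stat_names, a)))
  )
  rl2 <- as.vector(sapply(c("mean", "min", "max"), function(a)
    sprintf("glrlm2d_%s_%s", glrlm_stat_names, a)))
  rl3 <- sprintf("glrlm3d_%s_mean", glrlm_stat_names)
  fft_names <- c(paste0("fft_mag_", c("mean", "sd", "skewness", "kurtosis",
                                      "energy", "entropy", "max",
                                      "rcentroid", "rspread")),
                 paste0("fft_phase_", c("mean", "sd", "skewness", "kurtosis",
                                        "energy", "entropy", "max",
                                        "rcentroid", "rspread")))
  fam2 <- c(rep("glcm2d", 60), rep("gldm2d", 20))
  fam3 <- c(rep("glcm3d", 60), rep("gldm3d", 20))
  data.frame(
    feature_index = seq_len(235),
    feature_name = c(hist_names, n2, n3, rl2, rl3, fft_names),
    family = c(rep("histogram", 13), fam2, fam3,
               rep("glrlm2d", 33), rep("glrlm3d", 11), rep("fft", 18)),
    stringsAsFactors = FALSE
  )
}

#' Extract the full 235-feature texture panel
#'
#' Concatenates the family blocks in canonical order. Family-level failures
#' are converted to NA values with the degenerate flag set rather than
#' aborting the whole panel.
#'
#' @param roi a `quantized_roi`.
#' @return a `feature_vector`: named numeric vector of 235 values with
#'   attributes `"family"` and `"degenerate"`.
#' @export
extract_panel <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  man <- feature_manifest()
  blocks <- list(
    function() histogram_features(roi),
    function() second_order_block(roi, "2D"),
    function() second_order_block(roi, "3D"),
    function() glrlm_block(roi),
    function() {
      # crop to the mask bounding box so the embedding (and hence the
      # spectrum phase) does not depend on where the ROI sits in the grid
      pl <- roi$plane_slice
      keep_r <- which(rowSums(!is.na(pl)) > 0)
      keep_c <- which(colSums(!is.na(pl)) > 0)
      s <- fft_spectrum(pl[keep_r, keep_c, drop = FALSE])
      fft_features(s)
    }
  )
  sizes <- c(13, 80, 80, 44, 18)
  vals <- numeric(0); degen <- logical(0)
  for (b in seq_along(blocks)) {
    res <- tryCatch(blocks[[b]](), error = function(e) e)
    if (inherits(res, "error")) {
      v <- rep(NA_real_, sizes[b])
      d <- rep(TRUE, sizes[b])
    } else {
      v <- as.numeric(res)
      d <- attr(res, "degenerate")
      if (is.null(d)) d <- rep(FALSE, length(v))
    }
    vals <- c(vals, v); degen <- c(degen, d)
  }
  stopifnot(length(vals) == 235)
  names(vals) <- man$feature_name
  attr(vals, "family") <- man$family
  attr(vals, "degenerate") <- degen
  class(vals) <- "feature_vector"
  vals
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features (%d flagged degenerate)\n",
              length(x), sum(attr(x, "degenerate"))))
  invisible(x)
}

#' Extract features for every volume and ROI of a study
#'
#' @param study a `ctta_study` from [generate_study()] (with volumes).
#' @param rois list of ROI definitions:
#'   `list(label =, center = c(x, y, z), radius =)`. Defaults to spheres at
#'   the phantom's three pattern-region centers.
#' @param n_bins gray-level bins for quantization.
#' @param roi_radius radius of the default ROIs, mm.
#' @return long-format data.frame: one row per (volume, roi, feature) with
#'   columns scanner_id, setting_id, varied_parameter, repeat_index,
#'   roi_label, feature_index, feature_name, family, value, degenerate_flag.
#' @export
extract_features <- function(study, rois = NULL, n_bins = 20,
                             roi_radius = 16) {
  stopifnot(inherits(study, "ctta_study"), !is.null(study$volumes))
  if (is.null(rois)) rois <- default_rois(study$spec, roi_radius)
  man <- feature_manifest()
  out <- vector("list", nrow(study$manifest) * length(rois))
  k <- 0
  for (i in seq_len(nrow(study$manifest))) {
    row <- study$manifest[i, ]
    vol <- study$volumes[[row$volume_key]]
    for (r in rois) {
      mask <- make_sphere_roi(vol, r$center, r$radius, r$label)
      q <- quantize(vol, mask, n_bins = n_bins)
      fv <- extract_panel(q)
      k <- k + 1
      out[[k]] <- data.frame(
        scanner_id = row$scanner_id, setting_id = row$setting_id,
        varied_parameter = row$varied_parameter,
        repeat_index = row$repeat_index, roi_label = r$label,
        feature_index = man$feature_index, feature_name = man$feature_name,
        family = man$family, value = as.numeric(fv),
        degenerate_flag = attr(fv, "degenerate"),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Default spherical ROIs at the pattern-region centers
#'
#' @param spec a [phantom_spec()].
#' @param radius sphere radius, mm.
#' @return list of ROI definitions for [extract_features()].
#' @export
default_rois <- function(spec, radius = 16) {
  lapply(seq_along(spec$pattern_regions), function(i) {
    list(label = paste0("roi", i),
         center = spec$pattern_regions[[i]]$center,
         radius = radius)
  })
}
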