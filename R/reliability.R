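#' Percent absolute difference
#'
#' The instability measure `|test - baseline| / |baseline|`, vectorized.
#' Zero-baseline guard: if `|baseline| < 1e-12` the PAD is 0 when `|test|`
#' is also below 1e-12 (no signal, no instability) and `Inf` otherwise.
#'
#' @param test feature value(s) under the changed condition.
#' @param baseline reference feature value(s).
#' @return non-negative fraction(s); `Inf` marks a zero-baseline blow-up.
#' @export
pad <- function(test, baseline) {
  if (any(is.nan(test)) || any(is.nan(baseline)))
    stop("NaN input to pad()")
  out <- abs(test - baseline) / abs(baseline)
  zero_b <- abs(baseline) < 1e-12
  out[zero_b & abs(test) < 1e-12] <- 0
  out[zero_b & abs(test) >= 1e-12] <- Inf
  out
}

# long feature table -> one comparison per matched key
compare_tables <- function(base_df, test_df, keys) {
  m <- merge(base_df, test_df, by = keys, suffixes = c("_base", "_test"))
  miss_b <- nrow(test_df) - nrow(m)
  if (miss_b > 0) {
    stop("unmatched comparison rows: ", miss_b,
         " test rows have no baseline counterpart")
  }
  m$baseline_value <- m$value_base
  m$test_value <- m$value_test
  m$pad <- pad(m$test_value, m$baseline_value)
  m
}

#' Test-retest (repeatability) comparisons
#'
#' Pairs the repeat-0 and repeat-1 feature values of every
#' (scanner, setting, ROI, feature) and computes their PAD. The tally is
#' the fraction of comparisons with PAD at or below the cutoff, per scanner
#' (pooled over ROIs) and per (scanner, ROI).
#'
#' @param features long feature table from [extract_features()].
#' @param cutoff tally cutoff on PAD (default 0.15).
#' @return list with `records` (one row per comparison, with
#'   `comparison_kind = "repeatability"`), `tally` (named by scanner) and
#'   `tally_by_roi` (data.frame).
#' @export
repeatability_table <- function(features, cutoff = 0.15) {
  keys <- c("scanner_id", "setting_id", "roi_label", "feature_index",
            "feature_name", "family", "varied_parameter")
  r0 <- features[features$repeat_index == 0,
                 c(keys, "value"), drop = FALSE]
  r1 <- features[features$repeat_index == 1,
                 c(keys, "value"), drop = FALSE]
  if (nrow(r1) == 0) stop("no repeat-1 rows in the feature table")
  m <- compare_tables(r0, r1, keys)
  rec <- data.frame(
    scanner_id = m$scanner_id, setting_id = m$setting_id,
    roi_label = m$roi_label, feature_index = m$feature_index,
    feature_name = m$feature_name, family = m$family,
    comparison_kind = "repeatability", parameter_family = "none",
    baseline_value = m$baseline_value, test_value = m$test_value,
    pad = m$pad, stringsAsFactors = FALSE
  )
  tally <- tapply(rec$pad <= cutoff, rec$scanner_id, mean)
  tb <- stats::aggregate(ok ~ scanner_id + roi_label,
                         data = transform(rec, ok = pad <= cutoff), FUN = mean)
  names(tb)[names(tb) == "ok"] <- "tally"
  list(records = rec, tally = c(tally), tally_by_roi = tb, cutoff = cutoff)
}

#' Baseline-versus-varied (robustness) comparisons
#'
#' Pairs every varied setting's repeat-0 feature values with the baseline
#' setting's, per scanner and ROI, and groups PADs by the varied parameter
#' family. Family tallies use the cutoff.
#'
#' @param features long feature table from [extract_features()].
#' @param cutoff tally cutoff on PAD (default 0.15).
#' @return list with `records` (`comparison_kind = "robustness"`,
#'   `parameter_family` set), `family_tally` (data.frame scanner x family
#'   with n and tally) and `cutoff`.
#' @export
robustness_table <- function(features, cutoff = 0.15) {
  f0 <- features[features$repeat_index == 0, , drop = FALSE]
  base <- f0[f0$varied_parameter == "baseline", , drop = FALSE]
  if (nrow(base) == 0) stop("baseline setting missing from the feature table")
  varied <- f0[f0$varied_parameter != "baseline", , drop = FALSE]
  keys <- c("scanner_id", "roi_label", "feature_index", "feature_name",
            "family")
  m <- merge(
    base[, c(keys, "value")],
    varied[, c(keys, "setting_id", "varied_parameter", "value")],
    by = keys, suffixes = c("_base", "_test")
  )
  if (nrow(m) != nrow(varied))
    stop("unmatched robustness rows: baseline misses ",
         nrow(varied) - nrow(m), " keys")
  rec <- data.frame(
    scanner_id = m$scanner_id, setting_id = m$setting_id,
    roi_label = m$roi_label, feature_index = m$feature_index,
    feature_name = m$feature_name, family = m$family,
    comparison_kind = rep("robustness", nrow(m)),
    parameter_family = m$varied_parameter,
    baseline_value = m$value_base, test_value = m$value_test,
    pad = pad(m$value_test, m$value_base), stringsAsFactors = FALSE
  )
  if (nrow(rec) == 0) {
    ft <- data.frame(scanner_id = character(0),
                     parameter_family = character(0),
                     tally = numeric(0), n = integer(0))
    return(list(records = rec, family_tally = ft, cutoff = cutoff))
  }
  ft <- stats::aggregate(ok ~ scanner_id + parameter_family,
                         data = transform(rec, ok = pad <= cutoff),
                         FUN = mean)
  names(ft)[names(ft) == "ok"] <- "tally"
  cnt <- stats::aggregate(ok ~ scanner_id + parameter_family,
                          data = transform(rec, ok = pad <= cutoff),
                          FUN = length)
  ft$n <- cnt$ok
  list(records = rec, family_tally = ft, cutoff = cutoff)
}

#' Identify reliable features across two scanners
#'
#' A feature is repeatable (robust) on a scanner when all its repeatability
#' (robustness) PADs are at or below the band; it is reliable when it is
#' repeatable and robust on both scanners — the cross-scanner
#' reproducibility conjunction.
#'
#' @param repeatability output of [repeatability_table()].
#' @param robustness output of [robustness_table()].
#' @param band reliable band on PAD (default 0.05).
#' @return an object of class `reliability_report`: list with `features`
#'   (per-feature flags and per-scanner max PADs), `reliable`
#'   (character vector of reliable feature names), `band`,
#'   `family_tally` (carried from robustness).
#' @export
reliable_set <- function(repeatability, robustness, band = 0.05) {
  rec <- rbind(repeatability$records, robustness$records)
  scanners <- sort(unique(rec$scanner_id))
  if (length(scanners) < 2)
    stop("reliable_set needs records from both scanners")
  man <- unique(rec[, c("feature_index", "feature_name", "family")])
  man <- man[order(man$feature_index), ]
  out <- man
  for (sc in scanners) {
    for (kind in c("repeatability", "robustness")) {
      sub <- rec[rec$scanner_id == sc & rec$comparison_kind == kind, ]
      mx <- tapply(sub$pad, sub$feature_index, max)
      col_m <- mx[as.character(man$feature_index)]
      out[[paste0("max_pad_", kind, "_", sc)]] <- as.numeric(col_m)
      out[[paste0(ifelse(kind == "repeatability", "repeatable_", "robust_"),
                  sc)]] <- !is.na(col_m) & col_m <= band
    }
  }
  rep_cols <- paste0("repeatable_", scanners)
  rob_cols <- paste0("robust_", scanners)
  out$reproducible <- Reduce(`&`, lapply(c(rep_cols), function(cn) out[[cn]])) &
    Reduce(`&`, lapply(c(rob_cols), function(cn) out[[cn]]))
  out$reliable <- out$reproducible
  structure(
    list(features = out,
         reliable = out$feature_name[out$reliable],
         band = band,
         family_tally = robustness$family_tally),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d/%d features reliable at band %.2f\n",
              length(x$reliable), nrow(x$features), x$band))
  invisible(x)
}

#' Effect of reconstruction-filter strength on robustness
#'
#' Summarizes the robustness PADs of the filter parameter family per filter
#' level: mean PAD across features and ROIs, a sign-test p-value against
#' zero change, and a rank-based monotone trend statistic of mean PAD
#' across levels per scanner.
#'
#' @param robustness output of [robustness_table()].
#' @param manifest study manifest (to map settings to filter levels).
#' @return list with `by_level` (scanner, filter_level, n, mean_pad,
#'   p_sign) and `trend` (per scanner, Spearman correlation of level vs
#'   mean PAD; NA with fewer than 2 levels).
#' @export
filter_effect_contrast <- function(robustness, manifest) {
  rec <- robustness$records
  rec <- rec[rec$parameter_family == "filter", , drop = FALSE]
  if (nrow(rec) == 0)
    return(list(by_level = data.frame(), trend = numeric(0)))
  key <- unique(manifest[, c("scanner_id", "setting_id", "filter_level")])
  rec <- merge(rec, key, by = c("scanner_id", "setting_id"))
  fin <- rec[is.finite(rec$pad), , drop = FALSE]
  by_level <- do.call(rbind, lapply(
    split(fin, list(fin$scanner_id, fin$filter_level), drop = TRUE),
    function(d) {
      pos <- sum(d$pad > 0)
      p <- stats::binom.test(pos, nrow(d), 0.5,
                             alternative = "greater")$p.value
      data.frame(scanner_id = d$scanner_id[1],
                 filter_level = d$filter_level[1], n = nrow(d),
                 mean_pad = mean(d$pad), p_sign = p,
                 stringsAsFactors = FALSE)
    }
  ))
  rownames(by_level) <- NULL
  by_level <- by_level[order(by_level$scanner_id, by_level$filter_level), ]
  trend <- vapply(split(by_level, by_level$scanner_id), function(d) {
    if (nrow(d) < 2) return(NA_real_)
    if (stats::sd(d$mean_pad) == 0) return(0)   # flat: no trend
    stats::cor(d$filter_level, d$mean_pad, method = "spearman")
  }, 0)
  list(by_level = by_level, trend = trend)
}

#' Export PAD heatmaps
#'
#' For each (scanner, comparison kind) in the records, writes a matrix of
#' PAD values — rows the 235 features in canonical order, columns the
#' settings grouped by parameter family, averaged over ROIs — as a CSV
#' (unclipped) and a PNG rendered on a blue-to-red scale clipped to
#' `[0, clip_max]`, with the reliable band marked on the color legend.
#'
#' @param records comparison records (repeatability and/or robustness).
#' @param dir output directory.
#' @param clip_max color-scale ceiling on PAD (default 0.20).
#' @param band reliable band to mark (default 0.05).
#' @param png also render PNG images (CSV is always written).
#' @return character vector of written file paths, invisibly.
#' @export
heatmap_export <- function(records, dir, clip_max = 0.20, band = 0.05,
                           png = TRUE) {
  stopifnot(nrow(records) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- feature_manifest()
  paths <- character(0)
  for (sc in unique(records$scanner_id)) {
    for (kind in unique(records$comparison_kind)) {
      rec <- records[records$scanner_id == sc &
                       records$comparison_kind == kind, , drop = FALSE]
      if (nrow(rec) == 0) next
      rec <- rec[order(rec$parameter_family, rec$setting_id), ]
      setts <- unique(rec$setting_id)
      mat <- matrix(NA_real_, nrow = 235, ncol = length(setts),
                    dimnames = list(man$feature_name, setts))
      agg <- stats::aggregate(pad ~ feature_index + setting_id, data = rec,
                              FUN = mean)
      mat[cbind(agg$feature_index,
                match(agg$setting_id, setts))] <- agg$pad
      csv <- file.path(dir, sprintf("heatmap_%s_%s.csv", sc, kind))
      utils::write.csv(as.data.frame(mat), csv, row.names = TRUE)
      paths <- c(paths, csv)
      if (png) {
        png_path <- file.path(dir, sprintf("heatmap_%s_%s.png", sc, kind))
        grDevices::png(png_path, width = 900, height = 1200)
        clipped <- pmin(pmax(mat, 0), clip_max)
        cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
        graphics::par(mar = c(6, 4, 3, 6))
        graphics::image(
          x = seq_len(ncol(mat)), y = seq_len(nrow(mat)), z = t(clipped),
          zlim = c(0, clip_max), col = cols, xaxt = "n", xlab = "",
          ylab = "feature index (canonical order)",
          main = sprintf("PAD %s, scanner %s (band %.0f%% marked)",
                         kind, sc, band * 100)
        )
        graphics::axis(1, at = seq_len(ncol(mat)), labels = setts, las = 2,
                       cex.axis = 0.7)
        # outline the cells inside the reliable band
        if (ncol(mat) > 1 && nrow(mat) > 1)
          graphics::contour(x = seq_len(ncol(mat)), y = seq_len(nrow(mat)),
                            z = t(clipped), levels = band, add = TRUE,
                            drawlabels = FALSE, col = "black", lwd = 0.5)
        grDevices::dev.off()
        paths <- c(paths, png_path)
      }
    }
  }
  invisible(paths)
}
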