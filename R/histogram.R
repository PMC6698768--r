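#' First-order histogram features
#'
#' Thirteen intensity statistics computed on the raw HU values of the ROI:
#' mean, variance, skewness, excess kurtosis, median, minimum, maximum,
#' range, 10th and 90th percentiles, mean absolute deviation, and the energy
#' and entropy of the 20-bin gray-level histogram. A constant sample yields
#' variance 0 with skewness and kurtosis defined as 0 (flagged degenerate).
#'
#' @param roi a `quantized_roi`.
#' @return named numeric vector of 13 values with attribute `"degenerate"`.
#' @export
histogram_features <- function(roi) {
  x <- roi$hu
  if (length(x) < 2) stop("histogram features need at least 2 voxels")
  p <- tabulate(roi$bins, roi$n_bins)
  p <- p / sum(p)
  constant <- stats::var(x) == 0
  out <- c(
    mean = mean(x),
    variance = stats::var(x),
    skewness = skewness0(x),
    kurtosis = kurtosis0(x),
    median = stats::median(x),
    min = min(x),
    max = max(x),
    range = diff(range(x)),
    p10 = unname(stats::quantile(x, 0.10)),
    p90 = unname(stats::quantile(x, 0.90)),
    mad = mean(abs(x - mean(x))),
    energy = sum(p^2),
    entropy = entropy_bits(p)
  )
  names(out) <- paste0("hist_", names(out))
  attr(out, "degenerate") <- rep(constant, length(out))
  out
}
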