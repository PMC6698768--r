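#' Band-limited 2-D spectrum of the analysis plane
#'
#' Embeds the ROI's 2-D bin-level slice (NA outside the mask set to 0) in
#' the center of an `n` x `n` zero frame (center-cropping if larger), takes
#' the 2-D discrete Fourier transform, and restricts to the annulus between
#' 10% and 90% of the Nyquist frequency, which excludes the DC component and
#' the highest-frequency corners.
#'
#' @param plane numeric/integer matrix (NA treated as 0).
#' @param n transform size (default 512).
#' @param band lower/upper band edges as fractions of the Nyquist frequency.
#' @return an object of class `spectrum_sample`: list with `fourier`
#'   (complex n x n), `radial_freq` (cycles/sample, n x n), `in_band`
#'   (logical n x n), `image_energy` (sum of squared embedded image), `n`.
#' @export
fft_spectrum <- function(plane, n = 512, band = c(0.10, 0.90)) {
  m <- plane
  m[is.na(m)] <- 0
  m <- as.matrix(m) * 1.0
  if (nrow(m) > n) {
    i0 <- floor((nrow(m) - n) / 2)
    m <- m[i0 + seq_len(n), , drop = FALSE]
  }
  if (ncol(m) > n) {
    j0 <- floor((ncol(m) - n) / 2)
    m <- m[, j0 + seq_len(n), drop = FALSE]
  }
  frame <- matrix(0, n, n)
  i0 <- floor((n - nrow(m)) / 2)
  j0 <- floor((n - ncol(m)) / 2)
  frame[i0 + seq_len(nrow(m)), j0 + seq_len(ncol(m))] <- m

  ft <- stats::fft(frame)
  fr <- c(0:(n / 2), seq(n / 2 - 1, 1)) / n   # |frequency| per axis
  rad <- sqrt(outer(fr^2, fr^2, `+`))
  nyq <- 0.5
  in_band <- rad >= band[1] * nyq & rad <= band[2] * nyq
  structure(
    list(fourier = ft, radial_freq = rad, in_band = in_band,
         image_energy = sum(frame^2), n = n),
    class = "spectrum_sample"
  )
}

fft_channel_stats <- function(x, r, weights = abs(x)) {
  m2 <- mean((x - mean(x))^2)
  wsum <- sum(weights)
  cen <- if (wsum > 0) sum(r * weights) / wsum else 0
  spr <- if (wsum > 0) sqrt(sum((r - cen)^2 * weights) / wsum) else 0
  c(mean = mean(x), sd = sqrt(m2), skewness = skewness0(x),
    kurtosis = kurtosis0(x), energy = mean(x^2), entropy = NA_real_,
    max = max(x), rcentroid = cen, rspread = spr)
}

#' Fourier spectral features
#'
#' Nine statistics each for the in-band magnitude and phase of the 2-D
#' spectrum: mean, standard deviation, skewness, kurtosis, energy (mean
#' square), entropy, maximum, radial spectral centroid and radial spectral
#' spread (amplitude-weighted). Magnitude entropy treats the normalized
#' magnitudes as probabilities; phase entropy uses a 64-bin histogram over
#' (-pi, pi]. A constant slice leaves no in-band signal and is flagged
#' degenerate (magnitude entropy 0).
#'
#' @param s a `spectrum_sample` from [fft_spectrum()].
#' @return named numeric vector of 18 values with attribute `"degenerate"`.
#' @export
fft_features <- function(s) {
  stopifnot(inherits(s, "spectrum_sample"))
  mag <- Mod(s$fourier[s$in_band])
  phs <- Arg(s$fourier[s$in_band])
  r <- s$radial_freq[s$in_band]

  degenerate <- sum(mag) <= 1e-9 * s$n
  mstats <- fft_channel_stats(mag, r, weights = mag)
  mstats["entropy"] <- if (degenerate) 0 else entropy_bits(mag / sum(mag))

  pstats <- fft_channel_stats(phs, r, weights = abs(phs))
  br <- seq(-pi, pi, length.out = 65)
  ph <- pmin(pmax(phs, -pi + 1e-12), pi)
  hcnt <- tabulate(findInterval(ph, br, rightmost.closed = TRUE), 64)
  pstats["entropy"] <- entropy_bits(hcnt / sum(hcnt))

  out <- c(
    stats::setNames(mstats, paste0("fft_mag_", names(mstats))),
    stats::setNames(pstats, paste0("fft_phase_", names(pstats)))
  )
  attr(out, "degenerate") <- rep(degenerate, length(out))
  out
}
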