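#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring bin-level pairs at a fixed voxel offset (distance 1),
#' symmetrizes, and normalizes to probabilities. `levels` may be a 2-D
#' matrix or 3-D array of bin levels with NA outside the region; only pairs
#' with both voxels inside are counted.
#'
#' @param levels integer matrix/array of bin levels in `1..n_bins`, NA
#'   outside the region.
#' @param offset integer offset, length 2 (matrix) or 3 (array).
#' @param n_bins number of gray levels.
#' @return an object of class `cooc_matrix`: list with `p` (n_bins x n_bins
#'   probability matrix), `counts`, `offset`, `n_pairs`.
#' @export
glcm <- function(levels, offset, n_bins) {
  pr <- offset_pairs(levels, offset)
  if (nrow(pr) == 0)
    stop("no valid voxel pairs at offset (",
         paste(offset, collapse = ","), ")")
  counts <- matrix(tabulate((pr[, 2] - 1) * n_bins + pr[, 1], n_bins * n_bins),
                   n_bins, n_bins)
  counts <- counts + t(counts)       # symmetrize
  structure(
    list(p = counts / sum(counts), counts = counts, offset = offset,
         n_pairs = nrow(pr)),
    class = "cooc_matrix"
  )
}

# all (value, neighbor-value) pairs at an offset; NA-aware
offset_pairs <- function(levels, offset) {
  d <- dim(levels)
  stopifnot(length(offset) == length(d))
  rng <- lapply(seq_along(d), function(a) {
    o <- offset[a]
    lo <- max(1, 1 - o)
    hi <- min(d[a], d[a] - o)
    if (hi < lo) integer(0) else lo:hi
  })
  if (any(vapply(rng, length, 1L) == 0))
    return(matrix(integer(0), 0, 2))
  a <- if (length(d) == 2) levels[rng[[1]], rng[[2]], drop = FALSE]
       else levels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  rng2 <- lapply(seq_along(d), function(ax) rng[[ax]] + offset[ax])
  b <- if (length(d) == 2) levels[rng2[[1]], rng2[[2]], drop = FALSE]
       else levels[rng2[[1]], rng2[[2]], rng2[[3]], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' Haralick-type statistics of a co-occurrence matrix
#'
#' The 13 Haralick measures plus autocorrelation and maximum probability.
#' Degenerate marginals (zero variance) define correlation and both
#' information measures of correlation as 0, flagged via attribute
#' `"degenerate"`.
#'
#' @param m a `cooc_matrix` (or a normalized probability matrix).
#' @return named numeric vector of 15 statistics.
#' @export
glcm_stats <- function(m) {
  p <- if (inherits(m, "cooc_matrix")) m$p else m
  n <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(n) * px); mu_y <- sum(seq_len(n) * py)
  var_x <- sum((seq_len(n) - mu_x)^2 * px)
  var_y <- sum((seq_len(n) - mu_y)^2 * py)

  # p_{x+y}(k), k = 2..2n  and  p_{x-y}(k), k = 0..n-1
  psum <- vapply(2:(2 * n), function(k) sum(p[i + j == k]), 0)
  pdiff <- vapply(0:(n - 1), function(k) sum(p[abs(i - j) == k]), 0)

  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  degenerate <- var_x <= 0 || var_y <= 0
  correlation <- if (degenerate) 0 else
    (sum(i * j * p) - mu_x * mu_y) / sqrt(var_x * var_y)
  variance <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_average <- sum((2:(2 * n)) * psum)
  sum_entropy <- entropy_bits(psum)
  sum_variance <- sum(((2:(2 * n)) - sum_average)^2 * psum)
  entropy <- entropy_bits(p)
  diff_mean <- sum((0:(n - 1)) * pdiff)
  diff_variance <- sum(((0:(n - 1)) - diff_mean)^2 * pdiff)
  diff_entropy <- entropy_bits(pdiff)

  hx <- entropy_bits(px); hy <- entropy_bits(py)
  pxy <- outer(px, py)
  ok <- p > 0 & pxy > 0
  hxy1 <- -sum(p[ok] * log2(pxy[ok]))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (degenerate || max(hx, hy) <= 0) 0 else
    (entropy - hxy1) / max(hx, hy)
  imc2 <- if (degenerate) 0 else
    sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  autocorrelation <- sum(i * j * p)
  max_prob <- max(p)

  out <- c(
    energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2,
    autocorrelation = autocorrelation, max_prob = max_prob
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Gray-level difference histogram
#'
#' Distribution of absolute bin-level differences `k = 0..n_bins-1` at a
#' fixed offset.
#'
#' @inheritParams glcm
#' @return an object of class `diff_histogram`: list with `p` (probability
#'   over k = 0..n_bins-1) and `offset`.
#' @export
gldm <- function(levels, offset, n_bins) {
  pr <- offset_pairs(levels, offset)
  if (nrow(pr) == 0)
    stop("no valid voxel pairs at offset (",
         paste(offset, collapse = ","), ")")
  k <- abs(pr[, 1] - pr[, 2])
  counts <- tabulate(k + 1L, n_bins)
  structure(list(p = counts / sum(counts), offset = offset),
            class = "diff_histogram")
}

#' Statistics of a gray-level difference histogram
#'
#' @param h a `diff_histogram` (or a probability vector over k = 0..K).
#' @return named numeric vector: contrast, angular second moment, entropy,
#'   mean, inverse difference moment.
#' @export
gldm_stats <- function(h) {
  p <- if (inherits(h, "diff_histogram")) h$p else h
  k <- seq_along(p) - 1
  c(
    contrast = sum(k^2 * p),
    asm = sum(p^2),
    entropy = entropy_bits(p),
    mean = sum(k * p),
    idm = sum(p / (1 + k^2))
  )
}

# in-plane offsets at 0, 45, 90, 135 degrees (row, col)
offsets_2d <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

# the 13 unique 3-D directions (x, y, z), one per +/- pair
offsets_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  g <- g[keep, ]
  lapply(seq_len(nrow(g)), function(i) c(g$dx[i], g$dy[i], g$dz[i]))
}

glcm_stat_names <- c("energy", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "diff_variance", "diff_entropy", "imc1", "imc2",
                     "autocorrelation", "max_prob")
gldm_stat_names <- c("contrast", "asm", "entropy", "mean", "idm")

#' Second-order (GLCM + GLDM) feature block
#'
#' 2-D mode: 15 co-occurrence statistics and 5 difference statistics at each
#' of the four in-plane directions (0/45/90/135 degrees, distance 1) on the
#' selected analysis plane: 80 features. 3-D mode: the same statistics
#' computed per direction over the 13 unique 3-D directions, then aggregated
#' by mean, range, min and max: 80 features. Directions with no valid pairs
#' (region thinner than 2 voxels along an axis) are skipped from the
#' aggregation and recorded in the `"skipped_directions"` attribute.
#'
#' @param roi a `quantized_roi`.
#' @param mode `"2D"` or `"3D"`.
#' @return named numeric vector of 80 values with attribute `"degenerate"`.
#' @export
second_order_block <- function(roi, mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  n <- roi$n_bins
  if (mode == "2D") {
    lv <- roi$plane_slice
    offs <- offsets_2d()
    vals <- c(); degen <- c()
    for (a in names(offs)) {
      g <- glcm_stats(glcm(lv, offs[[a]], n))
      names(g) <- sprintf("glcm2d_%s_%s", glcm_stat_names, a)
      vals <- c(vals, g)
      degen <- c(degen, rep(attr(g, "degenerate"), length(g)))
    }
    for (a in names(offs)) {
      g <- gldm_stats(gldm(lv, offs[[a]], n))
      names(g) <- sprintf("gldm2d_%s_%s", gldm_stat_names, a)
      vals <- c(vals, g)
      degen <- c(degen, rep(FALSE, length(g)))
    }
    attr(vals, "degenerate") <- degen
    return(vals)
  }

  lv <- roi$bin_array
  offs <- offsets_3d()
  per_dir_glcm <- NULL; per_dir_gldm <- NULL
  degen_any <- FALSE; skipped <- 0L
  for (o in offs) {
    if (nrow(offset_pairs(lv, o)) == 0) { skipped <- skipped + 1L; next }
    g <- glcm_stats(glcm(lv, o, n))
    degen_any <- degen_any || attr(g, "degenerate")
    d <- gldm_stats(gldm(lv, o, n))
    per_dir_glcm <- rbind(per_dir_glcm, g)
    per_dir_gldm <- rbind(per_dir_gldm, d)
  }
  if (is.null(per_dir_glcm))
    stop("no 3-D direction has valid voxel pairs in this ROI")
  aggs <- list(mean = colMeans,
               range = function(m) apply(m, 2, function(v) diff(range(v))),
               min = function(m) apply(m, 2, min),
               max = function(m) apply(m, 2, max))
  vals <- c()
  for (an in names(aggs)) {
    v <- aggs[[an]](per_dir_glcm)
    names(v) <- sprintf("glcm3d_%s_%s", glcm_stat_names, an)
    vals <- c(vals, v)
  }
  for (an in names(aggs)) {
    v <- aggs[[an]](per_dir_gldm)
    names(v) <- sprintf("gldm3d_%s_%s", gldm_stat_names, an)
    vals <- c(vals, v)
  }
  attr(vals, "degenerate") <- rep(degen_any, length(vals))
  attr(vals, "skipped_directions") <- skipped
  vals
}
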