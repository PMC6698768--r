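#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal bin level along one direction. Runs break at
#' the region boundary (NA voxels) and at level changes. The matrix is
#' indexed by (gray level, run length).
#'
#' @param levels integer matrix/array of bin levels, NA outside the region.
#' @param offset direction, length 2 (matrix) or 3 (array), entries in
#'   \{-1, 0, 1\}.
#' @param n_bins number of gray levels.
#' @return an object of class `run_length_matrix`: list with `counts`
#'   (n_bins x L_max), `n_runs`, `n_voxels` (non-NA voxels scanned),
#'   `offset`.
#' @export
glrlm <- function(levels, offset, n_bins) {
  d <- dim(levels)
  stopifnot(length(offset) == length(d), any(offset != 0))
  coords <- arrayInd(seq_along(levels), d)
  k <- sum(offset^2)
  t_raw <- as.numeric(coords %*% offset)
  # line label: k * position - t_raw * offset is constant along a line
  lid_mat <- k * coords - outer(t_raw, as.numeric(offset))
  big <- max(d) * max(abs(offset)) * (k + 1) * 4 + 10
  lid <- as.numeric(lid_mat %*% (big^(seq_along(d) - 1)))

  ord <- order(lid, t_raw)
  v <- as.vector(levels)[ord]
  line_no <- cumsum(c(TRUE, diff(lid[ord]) != 0))
  # unique encoding per (line, level); NA cells get unique negatives so rle
  # breaks runs at region boundaries
  enc <- line_no * (n_bins + 2) + as.numeric(v)
  nas <- is.na(enc)
  enc[nas] <- -seq_len(sum(nas))
  r <- rle(enc)
  lev <- r$values %% (n_bins + 2)
  keep <- r$values > 0
  lev <- as.integer(round(lev[keep]))
  len <- r$lengths[keep]
  lmax <- max(len)
  counts <- matrix(tabulate((len - 1) * n_bins + lev, n_bins * lmax),
                   n_bins, lmax)
  structure(
    list(counts = counts, n_runs = sum(counts), n_voxels = sum(!is.na(v)),
         offset = offset),
    class = "run_length_matrix"
  )
}

glrlm_stat_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                      "srlge", "srhge", "lrlge", "lrhge")

#' Run-length statistics
#'
#' The 11 classical run-emphasis measures: short/long run emphasis,
#' gray-level and run-length non-uniformity, run percentage, low/high
#' gray-level run emphasis, and the four joint emphases.
#'
#' @param m a `run_length_matrix`.
#' @return named numeric vector of 11 statistics.
#' @export
glrlm_stats <- function(m) {
  cnt <- m$counts
  nr <- m$n_runs
  i <- seq_len(nrow(cnt))          # gray level
  j <- seq_len(ncol(cnt))          # run length
  gi <- rowSums(cnt)
  rj <- colSums(cnt)
  ij2 <- outer(i^2, j^2)
  c(
    sre = sum(sweep(cnt, 2, j^2, `/`)) / nr,
    lre = sum(sweep(cnt, 2, j^2, `*`)) / nr,
    gln = sum(gi^2) / nr,
    rln = sum(rj^2) / nr,
    rp = nr / m$n_voxels,
    lgre = sum(cnt / i^2) / nr,
    hgre = sum(cnt * i^2) / nr,
    srlge = sum(cnt / ij2) / nr,
    srhge = sum(sweep(cnt, 2, j^2, `/`) * i^2) / nr,
    lrlge = sum(sweep(cnt, 2, j^2, `*`) / i^2) / nr,
    lrhge = sum(cnt * ij2) / nr
  )
}

#' Run-length feature block
#'
#' 2-D: the 11 run statistics per in-plane direction (0/45/90/135 degrees)
#' on the analysis plane, aggregated by mean, min and max over directions:
#' 33 features. 3-D: the 11 statistics averaged over the 13 unique 3-D
#' directions: 11 features. 44 in total.
#'
#' @param roi a `quantized_roi`.
#' @return named numeric vector of 44 values with attribute `"degenerate"`.
#' @export
glrlm_block <- function(roi) {
  n <- roi$n_bins
  per2 <- t(vapply(
    offsets_2d(),
    function(o) glrlm_stats(glrlm(roi$plane_slice, o, n)),
    numeric(11)
  ))
  vals <- c()
  for (an in c("mean", "min", "max")) {
    v <- switch(an, mean = colMeans(per2),
                min = apply(per2, 2, min), max = apply(per2, 2, max))
    names(v) <- sprintf("glrlm2d_%s_%s", glrlm_stat_names, an)
    vals <- c(vals, v)
  }
  per3 <- t(vapply(
    offsets_3d(),
    function(o) glrlm_stats(glrlm(roi$bin_array, o, n)),
    numeric(11)
  ))
  v <- colMeans(per3)
  names(v) <- sprintf("glrlm3d_%s_mean", glrlm_stat_names)
  vals <- c(vals, v)
  attr(vals, "degenerate") <- rep(FALSE, length(vals))
  vals
}
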