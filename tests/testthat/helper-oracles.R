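# Independent brute-force oracles for the matrix-based texture families.
# These deliberately use naive nested loops / exhaustive enumeration and
# share no code with the package implementations.

oracle_glcm <- function(levels, offset, n_bins) {
  d <- dim(levels)
  cnt <- matrix(0, n_bins, n_bins)
  it <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (r in seq_len(nrow(it))) {
    p <- it[r, ]
    q <- p + offset
    if (any(q < 1) || any(q > d)) next
    a <- if (length(d) == 2) levels[p[1], p[2]] else levels[p[1], p[2], p[3]]
    b <- if (length(d) == 2) levels[q[1], q[2]] else levels[q[1], q[2], q[3]]
    if (is.na(a) || is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1
  }
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

oracle_gldm <- function(levels, offset, n_bins) {
  d <- dim(levels)
  cnt <- numeric(n_bins)
  it <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (r in seq_len(nrow(it))) {
    p <- it[r, ]
    q <- p + offset
    if (any(q < 1) || any(q > d)) next
    a <- if (length(d) == 2) levels[p[1], p[2]] else levels[p[1], p[2], p[3]]
    b <- if (length(d) == 2) levels[q[1], q[2]] else levels[q[1], q[2], q[3]]
    if (is.na(a) || is.na(b)) next
    k <- abs(a - b)
    cnt[k + 1] <- cnt[k + 1] + 1
  }
  cnt / sum(cnt)
}

# direct-summation Haralick statistics from a normalized symmetric matrix
oracle_glcm_stats <- function(p) {
  n <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:n) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:n) { vx <- vx + (i - mux)^2 * px[i]; vy <- vy + (i - muy)^2 * py[i] }
  ene <- 0; con <- 0; cor <- 0; vrr <- 0; idm <- 0; ent <- 0; aut <- 0
  for (i in 1:n) for (j in 1:n) {
    v <- p[i, j]
    ene <- ene + v^2
    con <- con + (i - j)^2 * v
    aut <- aut + i * j * v
    vrr <- vrr + (i - mux)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    if (v > 0) ent <- ent - v * log2(v)
  }
  cor <- if (vx > 0 && vy > 0) (aut - mux * muy) / sqrt(vx * vy) else 0
  ps <- numeric(2 * n); pd <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    ps[i + j] <- ps[i + j] + p[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((1:(2 * n)) * ps)
  sv <- sum(((1:(2 * n)) - sa)^2 * ps)
  se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  dm <- sum((0:(n - 1)) * pd)
  dv <- sum(((0:(n - 1)) - dm)^2 * pd)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:n) for (j in 1:n) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(pp)
      hxy2 <- hxy2 - pp * log2(pp)
    }
  }
  imc1 <- if (vx > 0 && vy > 0 && max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- if (vx > 0 && vy > 0) sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))) else 0
  c(energy = ene, contrast = con, correlation = cor, variance = vrr,
    idm = idm, sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, diff_variance = dv, diff_entropy = de, imc1 = imc1,
    imc2 = imc2, autocorrelation = aut, max_prob = max(p))
}

# run-length counts by explicitly walking every line of the grid
oracle_rlm <- function(levels, offset, n_bins) {
  d <- dim(levels)
  runs <- list()
  it <- as.matrix(expand.grid(lapply(d, seq_len)))
  getv <- function(p) {
    if (any(p < 1) || any(p > d)) return(NULL)
    if (length(d) == 2) levels[p[1], p[2]] else levels[p[1], p[2], p[3]]
  }
  for (r in seq_len(nrow(it))) {
    p <- it[r, ]
    v <- getv(p)
    if (is.na(v)) next
    prev <- getv(p - offset)
    is_start <- is.null(prev) || is.na(prev) || prev != v
    if (!is_start) next
    len <- 1
    q <- p + offset
    repeat {
      w <- getv(q)
      if (is.null(w) || is.na(w) || w != v) break
      len <- len + 1
      q <- q + offset
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  runs <- do.call(rbind, runs)
  lmax <- max(runs[, 2])
  cnt <- matrix(0, n_bins, lmax)
  for (r in seq_len(nrow(runs)))
    cnt[runs[r, 1], runs[r, 2]] <- cnt[runs[r, 1], runs[r, 2]] + 1
  cnt
}

# exhaustive largest-diameter plane search over all orientations and slices
oracle_plane <- function(grid, spacing) {
  best <- NULL
  for (pn in c("axial", "coronal", "sagittal")) {
    ax <- switch(pn, sagittal = 1L, coronal = 2L, axial = 3L)
    inplane <- setdiff(1:3, ax)
    for (s in seq_len(dim(grid)[ax])) {
      sl <- switch(ax, grid[s, , ], grid[, s, ], grid[, , s])
      w <- which(sl, arr.ind = TRUE)
      if (nrow(w) == 0) next
      dia <- 0
      if (nrow(w) > 1) {
        for (a in 1:(nrow(w) - 1)) for (b in (a + 1):nrow(w)) {
          dd <- sqrt(((w[a, 1] - w[b, 1]) * spacing[inplane[1]])^2 +
                       ((w[a, 2] - w[b, 2]) * spacing[inplane[2]])^2)
          dia <- max(dia, dd)
        }
      }
      if (is.null(best) || dia > best$diameter + 1e-9)
        best <- list(plane = pn, slice = s, diameter = dia)
    }
  }
  best
}

# canonical direction sets, restated independently of the package
offsets_2d_for_test <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
offsets_3d_for_test <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  g <- g[g$dz > 0 | (g$dz == 0 & g$dy > 0) |
           (g$dz == 0 & g$dy == 0 & g$dx > 0), ]
  lapply(seq_len(nrow(g)), function(i) c(g$dx[i], g$dy[i], g$dz[i]))
})

# random bin-level image with optional NA holes
rand_levels <- function(dims, n_bins = 4, na_frac = 0) {
  a <- array(sample.int(n_bins, prod(dims), replace = TRUE), dim = dims)
  if (na_frac > 0) {
    idx <- sample(length(a), round(na_frac * length(a)))
    a[idx] <- NA_integer_
  }
  a
}

# quantized_roi wrapper around a plain level array (bounding box = array)
fake_roi <- function(bins3d, n_bins = max(bins3d, na.rm = TRUE),
                     spacing = c(1, 1, 1)) {
  pl <- bins3d[, , ceiling(dim(bins3d)[3] / 2)]
  structure(
    list(hu = as.numeric(bins3d[!is.na(bins3d)]),
         bins = as.integer(bins3d[!is.na(bins3d)]),
         index = which(!is.na(bins3d), arr.ind = TRUE),
         bin_array = bins3d, n_bins = as.integer(n_bins), spacing = spacing,
         plane = "axial", plane_slice_index = ceiling(dim(bins3d)[3] / 2),
         plane_slice = pl),
    class = "quantized_roi"
  )
}
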