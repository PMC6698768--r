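test_that("GLCM matches brute-force pair enumeration on random images", {
  set.seed(101)
  n_cases_2d <- 60
  for (case in seq_len(n_cases_2d)) {
    dims <- sample(3:8, 2, replace = TRUE)
    nb <- sample(2:6, 1)
    lv <- rand_levels(dims, nb, na_frac = ifelse(case %% 3 == 0, 0.2, 0))
    off <- offsets_2d_for_test[[sample(4, 1)]]
    want <- try(oracle_glcm(lv, off, nb), silent = TRUE)
    if (inherits(want, "try-error") || any(!is.finite(want))) next
    got <- glcm(lv, off, nb)
    expect_equal(got$p, want, tolerance = 1e-12)
    expect_equal(sum(got$p), 1, tolerance = 1e-9)
    expect_equal(got$p, t(got$p))          # symmetric
  }
  for (case in 1:50) {
    dims <- sample(3:6, 3, replace = TRUE)
    nb <- sample(2:5, 1)
    lv <- rand_levels(dims, nb)
    off <- offsets_3d_for_test[[sample(13, 1)]]
    want <- oracle_glcm(lv, off, nb)
    got <- glcm(lv, off, nb)
    expect_equal(got$p, want, tolerance = 1e-12)
  }
})

test_that("GLCM degenerate and closed-form cases", {
  lv <- matrix(1L, 4, 4)
  g <- glcm(lv, c(0, 1), 3)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p != 0), 1)
  st <- glcm_stats(g)
  expect_equal(unname(st["energy"]), 1)
  expect_equal(unname(st["entropy"]), 0)
  expect_equal(unname(st["contrast"]), 0)
  expect_equal(unname(st["max_prob"]), 1)
  expect_true(attr(st, "degenerate"))

  # 2-level checkerboard, horizontal: all mass off-diagonal
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  gcb <- glcm(cb, c(0, 1), 2)
  expect_equal(gcb$p[1, 1], 0)
  expect_equal(gcb$p[2, 2], 0)
  stcb <- glcm_stats(gcb)
  expect_equal(unname(stcb["correlation"]), -1)
  expect_equal(unname(stcb["contrast"]), 1)  # (delta level)^2 = 1

  # no valid pairs in a direction errors with the direction named
  expect_error(glcm(matrix(1L, 1, 3), c(1, 0), 2), "offset")
})

test_that("all 15 GLCM statistics match the direct-summation oracle", {
  set.seed(202)
  for (case in 1:25) {
    lv <- rand_levels(c(6, 6), sample(3:6, 1))
    g <- glcm(lv, c(0, 1), max(lv))
    got <- glcm_stats(g)
    want <- oracle_glcm_stats(g$p)
    expect_equal(unclass(got)[names(want)], want, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("GLDM histogram and statistics match oracles and closed forms", {
  set.seed(303)
  for (case in 1:30) {
    dims <- if (case %% 2) c(6, 6) else c(4, 5, 3)
    nb <- sample(3:6, 1)
    lv <- rand_levels(dims, nb)
    off <- if (length(dims) == 2) c(0, 1) else c(1, 0, 0)
    got <- gldm(lv, off, nb)
    expect_equal(got$p, oracle_gldm(lv, off, nb), tolerance = 1e-12)
    # stats against direct formulas
    st <- gldm_stats(got)
    k <- seq_along(got$p) - 1
    expect_equal(unname(st["contrast"]), sum(k^2 * got$p), tolerance = 1e-10)
    expect_equal(unname(st["mean"]), sum(k * got$p), tolerance = 1e-10)
  }

  # constant image: all mass at difference 0
  st0 <- gldm_stats(gldm(matrix(2L, 4, 4), c(0, 1), 4))
  expect_equal(unname(st0), c(0, 1, 0, 0, 1))

  # horizontal ramp 1..n per row: all horizontal differences are 1
  ramp <- matrix(rep(1:5, each = 5), 5, 5)   # ramp[i, j] = j
  str <- gldm_stats(gldm(ramp, c(0, 1), 5))
  expect_equal(unname(str["mean"]), 1)
  expect_equal(unname(str["contrast"]), 1)
  expect_equal(unname(str["idm"]), 0.5)
})

test_that("entropy measures are invariant under bin relabeling", {
  set.seed(404)
  for (case in 1:20) {
    nb <- 5
    lv <- rand_levels(c(6, 6), nb)
    perm <- sample(nb)
    lv2 <- array(perm[lv], dim = dim(lv))
    e1 <- glcm_stats(glcm(lv, c(0, 1), nb))["entropy"]
    e2 <- glcm_stats(glcm(lv2, c(0, 1), nb))["entropy"]
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})

test_that("second-order blocks have 80 features each (160 total)", {
  set.seed(11)
  roi <- fake_roi(rand_levels(c(7, 7, 7), 5))
  b2 <- second_order_block(roi, "2D")
  b3 <- second_order_block(roi, "3D")
  expect_length(b2, 80)
  expect_length(b3, 80)
  expect_length(unique(c(names(b2), names(b3))), 160)

  # constant ROI: energy-type 1, entropy/contrast 0
  croi <- fake_roi(array(1L, c(5, 5, 5)), n_bins = 3)
  c2 <- second_order_block(croi, "2D")
  expect_true(all(c2[grep("glcm2d_energy", names(c2))] == 1))
  expect_true(all(c2[grep("entropy", names(c2))] == 0))
  expect_true(all(c2[grep("contrast", names(c2))] == 0))
})

test_that("direction-isotropic texture has small range aggregation", {
  set.seed(21)
  # iid noise is isotropic in distribution: the spread across the 13
  # directions is small next to the mean for entropy
  roi <- fake_roi(rand_levels(c(14, 14, 14), 4))
  b3 <- second_order_block(roi, "3D")
  expect_lt(abs(b3[["glcm3d_entropy_range"]]),
            0.05 * abs(b3[["glcm3d_entropy_mean"]]))
  expect_lt(abs(b3[["glcm3d_energy_range"]]),
            0.1 * abs(b3[["glcm3d_energy_mean"]]))
})
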