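mk_vol <- function(dims = c(24, 24, 24), spacing = c(1, 1, 1),
                   values = NULL) {
  if (is.null(values)) values <- array(0, dim = dims)
  volume_image(values, spacing = spacing)
}

test_that("sphere ROI voxel count approaches the analytic volume", {
  vol <- mk_vol(c(24, 24, 24))
  mask <- make_sphere_roi(vol, center = c(11.5, 11.5, 11.5), radius = 10)
  expect_equal(sum(mask$grid), 4 / 3 * pi * 10^3, tolerance = 0.02)
})

test_that("degenerate and failing spheres behave as specified", {
  vol <- mk_vol(c(9, 9, 9))
  # radius under half a voxel centered on a voxel center -> single voxel
  m <- make_sphere_roi(vol, center = c(4, 4, 4), radius = 0.4)
  expect_equal(sum(m$grid), 1)
  # no intersection -> error
  expect_error(make_sphere_roi(vol, center = c(100, 100, 100), radius = 2),
               "intersect")
})

test_that("plane selection: symmetric sphere ties to axial", {
  vol <- mk_vol(c(17, 17, 17))
  m <- make_sphere_roi(vol, center = c(8, 8, 8), radius = 5)
  pl <- select_2d_plane(m)
  expect_equal(pl$plane, "axial")
  expect_equal(pl$slice, 9)   # central slice (1-based grid, center at 8 mm)
})

test_that("plane selection: ellipsoid picks the two longest axes", {
  # semi-axes (x, y, z) = (12, 8, 4) mm -> axial plane holds x and y
  dims <- c(31, 31, 31)
  cx <- 15
  g <- array(FALSE, dims)
  for (k in 1:31) for (j in 1:31) for (i in 1:31) {
    g[i, j, k] <- ((i - cx) / 12)^2 + ((j - cx) / 8)^2 +
      ((k - cx) / 4)^2 <= 1
  }
  m <- structure(list(label = "e", center = c(cx, cx, cx), radius = NA,
                      grid = g, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                 class = "roi_mask")
  pl <- select_2d_plane(m)
  expect_equal(pl$plane, "axial")
  expect_equal(pl$slice, 15)
  expect_equal(pl$diameter, 24)

  # single-voxel mask -> axial, that voxel's slice
  g1 <- array(FALSE, c(5, 5, 5)); g1[2, 3, 4] <- TRUE
  m1 <- m; m1$grid <- g1
  pl1 <- select_2d_plane(m1)
  expect_equal(pl1$plane, "axial")
  expect_equal(pl1$slice, 4)
})

test_that("plane selection agrees with exhaustive search on random masks", {
  set.seed(42)
  for (rep in 1:12) {
    dims <- sample(4:9, 3, replace = TRUE)
    sp <- runif(3, 0.5, 3)
    g <- array(runif(prod(dims)) < 0.3, dim = dims)
    if (!any(g)) g[1, 1, 1] <- TRUE
    m <- structure(list(label = "r", center = c(0, 0, 0), radius = NA,
                        grid = g, spacing = sp, origin = c(0, 0, 0)),
                   class = "roi_mask")
    got <- select_2d_plane(m)
    want <- oracle_plane(g, sp)
    expect_equal(got$diameter, want$diameter, tolerance = 1e-9)
    expect_equal(got$plane, want$plane)
    expect_equal(got$slice, want$slice)
  }
})

test_that("equal-width quantization matches the closed form", {
  vals <- array(rep(1:100, length.out = 5 * 5 * 5), dim = c(5, 5, 5))
  vol <- mk_vol(c(5, 5, 5), values = vals)
  mask <- make_sphere_roi(vol, center = c(2, 2, 2), radius = 50)
  expect_equal(sum(mask$grid), 125)
  q <- quantize(vol, mask, n_bins = 20, hu_floor = NULL)
  # width (100 - 1)/20 = 4.95; 1 -> bin 1, 100 -> bin 20, 5.96 -> bin 2
  expect_equal(q$bins[q$hu == 1][1], 1L)
  expect_equal(q$bins[q$hu == 100][1], 20L)
  expect_equal(q$bins[q$hu == 6][1], 2L)
  expect_true(all(q$bins >= 1 & q$bins <= 20))
  # monotone in value
  ord <- order(q$hu)
  expect_true(all(diff(q$bins[ord]) >= 0))
})

test_that("constant ROI maps to bin 1 and NaN is rejected", {
  vol <- mk_vol(c(4, 4, 4), values = array(7, c(4, 4, 4)))
  mask <- make_sphere_roi(vol, center = c(1.5, 1.5, 1.5), radius = 10)
  q <- quantize(vol, mask)
  expect_true(all(q$bins == 1L))
  vol$values[2, 2, 2] <- NaN
  expect_error(quantize(vol, mask), "NaN")
})

test_that("air-bubble floor drops low-HU voxels from the sample", {
  vals <- array(50, c(6, 6, 6))
  vals[3, 3, 3] <- -900    # air bubble
  vol <- mk_vol(c(6, 6, 6), values = vals)
  mask <- make_sphere_roi(vol, center = c(2.5, 2.5, 2.5), radius = 20)
  q <- quantize(vol, mask, hu_floor = -200)
  expect_equal(length(q$hu), sum(mask$grid) - 1)
  expect_true(all(q$hu == 50))
})

test_that("NIfTI round-trip preserves values and spacing", {
  set.seed(9)
  vol <- mk_vol(c(7, 6, 5), spacing = c(0.9766, 0.9766, 3),
                values = array(rnorm(210), c(7, 6, 5)))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$values, vol$values, tolerance = 1e-12)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  unlink(path)
  expect_error(read_volume(path), "not found")
})
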