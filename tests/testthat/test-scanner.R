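test_that("no-noise acquisition equals partial-volume-averaged truth", {
  spec <- tiny_spec(fill = 0.4)
  truth <- build_phantom(spec)
  prof <- tiny_profile(matrix_size = 16, fov = 64)
  vol <- simulate_acquisition(truth, tiny_setting(prof), prof)
  # naive partial-volume oracle: loop over target voxels, average the truth
  # voxels whose centers fall inside
  n <- 16; p <- 64 / n; st <- 2
  d <- dim(truth$values)
  xc <- truth$origin[1] + (seq_len(d[1]) - 1) * truth$spacing[1]
  zc <- truth$origin[3] + (seq_len(d[3]) - 1) * truth$spacing[3]
  nz <- dim(vol$values)[3]
  for (ti in c(1, 8, 9)) for (tj in c(4, 8)) for (tk in c(1, nz)) {
    x0 <- -32 + (ti - 1) * p; x1 <- x0 + p
    y0 <- -32 + (tj - 1) * p; y1 <- y0 + p
    z0 <- (tk - 1) * st; z1 <- z0 + st
    sel_x <- xc >= x0 & xc < x1
    sel_y <- xc >= y0 & xc < y1
    sel_z <- zc >= z0 & zc < z1
    expected <- mean(truth$values[sel_x, sel_y, sel_z])
    expect_equal(vol$values[ti, tj, tk], expected, tolerance = 1e-12)
  }
})

test_that("acquisition is bit-reproducible for a fixed seed", {
  spec <- tiny_spec()
  truth <- build_phantom(spec)
  prof <- tiny_profile(noise_sigma_ref = 10)
  s <- tiny_setting(prof, seed = 99)
  v1 <- simulate_acquisition(truth, s, prof)
  v2 <- simulate_acquisition(truth, s, prof)
  expect_identical(v1$values, v2$values)
})

test_that("noise sd scales as 1/sqrt(mA), ratio 2 between 40 and 160 mA", {
  spec <- tiny_spec()
  truth <- build_phantom(spec)
  prof <- tiny_profile(noise_sigma_ref = 12)
  sds <- sapply(1:12, function(r) {
    v40 <- simulate_acquisition(truth, tiny_setting(prof, seed = 100 + r,
                                                    ma = 40), prof)
    v160 <- simulate_acquisition(truth, tiny_setting(prof, seed = 500 + r,
                                                     ma = 160), prof)
    c(background_noise_sd(v40), background_noise_sd(v160))
  })
  ratio <- mean(sds[1, ]) / mean(sds[2, ])
  expect_equal(ratio, 2.0, tolerance = 0.10)
})

test_that("noise sd is non-increasing in tube current and in filter level", {
  spec <- tiny_spec()
  truth <- build_phantom(spec)
  prof <- tiny_profile(noise_sigma_ref = 12)
  # paired noise realizations across conditions (same seed per replicate)
  ma_sd <- sapply(c(40, 60, 80, 100), function(ma)
    mean(sapply(1:10, function(r) background_noise_sd(
      simulate_acquisition(truth, tiny_setting(prof, seed = r * 31,
                                               ma = ma), prof)))))
  expect_true(all(diff(ma_sd) <= 0))
  lev_sd <- sapply(0:4, function(lv)
    mean(sapply(1:10, function(r) background_noise_sd(
      simulate_acquisition(truth, tiny_setting(prof, seed = r * 17,
                                               filter_level = lv), prof)))))
  expect_true(all(diff(lev_sd) <= 0))
})

test_that("contrast scaling and HU offset act as configured", {
  spec <- tiny_spec(fill = 0.4, supersample = 4)
  truth <- build_phantom(spec)
  prof <- scanner_profile(
    "X", hu_offset = 7, noise_sigma_ref = 0, kvp_values = c(80, 100),
    settings_matrix = list(slice_thickness = numeric(0), fov = numeric(0),
                           filter = integer(0), kvp = numeric(0),
                           ma = numeric(0)),
    baseline = list(slice_thickness = 2, fov = 64, kvp = 100, ma = 100,
                    filter = 0),
    matrix_size = 32
  )
  bl <- prof$baseline
  s100 <- acquisition_setting("X", 2, 64, 100, 100, seed = 1)
  s80 <- acquisition_setting("X", 2, 64, 80, 100, seed = 1)
  v100 <- simulate_acquisition(truth, s100, prof)
  v80 <- simulate_acquisition(truth, s80, prof)
  # 80 kVp boosts contrast about background by 5%
  c100 <- v100$values - 7 - spec$background_hu
  c80 <- v80$values - 7 - spec$background_hu
  expect_equal(c80, c100 * 1.05, tolerance = 1e-12)
  # unsupported kVp errors
  expect_error(simulate_acquisition(
    truth, acquisition_setting("X", 2, 64, 120, 100, seed = 1), prof),
    "kVp")
})

test_that("coarser truth than target grid is rejected", {
  spec <- tiny_spec(supersample = 1)   # 2 mm truth voxels
  truth <- build_phantom(spec)
  prof <- tiny_profile(matrix_size = 64, fov = 64)  # 1 mm target pixels
  expect_error(simulate_acquisition(truth, tiny_setting(prof), prof),
               "fine")
})

test_that("test-retest pairs: shared seed identical, fresh seed differs", {
  spec <- tiny_spec()
  truth <- build_phantom(spec)
  prof <- tiny_profile(noise_sigma_ref = 15)
  s <- tiny_setting(prof, seed = 7)
  pr <- test_retest_pair(truth, s, prof, reseed = s$seed)
  expect_identical(pr[[1]]$values, pr[[2]]$values)

  pr <- test_retest_pair(truth, s, prof)
  expect_false(identical(pr[[1]]$values, pr[[2]]$values))
  # difference of two independent acquisitions: mean ~ 0, sd ~ sigma*sqrt(2)
  diffs <- unlist(lapply(1:10, function(r) {
    s2 <- tiny_setting(prof, seed = 1000 + r)
    pp <- test_retest_pair(truth, s2, prof)
    (pp[[1]]$values - pp[[2]]$values)[1:8, 1:8, 1]
  }))
  expect_lt(abs(mean(diffs)), 1.5)
  expect_equal(sd(diffs), 15 * sqrt(2), tolerance = 0.10)

  # zero noise: identical regardless of seeds
  prof0 <- tiny_profile(noise_sigma_ref = 0)
  pr0 <- test_retest_pair(truth, tiny_setting(prof0, seed = 3), prof0)
  expect_identical(pr0[[1]]$values, pr0[[2]]$values)
})

test_that("study enumeration yields 21 + 16 settings and is deterministic", {
  profs <- default_scanner_profiles(matrix_size = 64)
  expect_equal(profs$A$settings_matrix$slice_thickness, 1:5)
  st <- generate_study(phantom_spec(), profs, master_seed = 5,
                       simulate = FALSE)
  m <- st$manifest
  expect_equal(length(unique(m$setting_id[m$scanner_id == "A"])), 21)
  expect_equal(length(unique(m$setting_id[m$scanner_id == "B"])), 16)
  expect_equal(nrow(m), 2 * (21 + 16))
  expect_equal(sort(unique(m$repeat_index)), c(0, 1))
  # repeats share the setting but not the seed
  sp <- split(m, m$setting_id)
  expect_true(all(vapply(sp, function(d) d$seed[1] != d$seed[2], TRUE)))
  # deterministic manifest for a fixed master seed
  st2 <- generate_study(phantom_spec(), profs, master_seed = 5,
                        simulate = FALSE)
  expect_identical(st$manifest, st2$manifest)

  # empty variation lists -> baseline only
  stb <- generate_study(tiny_spec(),
                        list(tiny_profile("A"), tiny_profile("B", fov = 64)),
                        simulate = FALSE)
  expect_equal(sum(stb$manifest$repeat_index == 0), 2)
  expect_true(all(stb$manifest$varied_parameter == "baseline"))
})
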