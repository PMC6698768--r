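test_that("pad: identity, cutoff arithmetic, zero guard, scale invariance", {
  expect_equal(pad(5.5, 5.5), 0)
  expect_equal(pad(-3, -3), 0)
  expect_equal(pad(1.15, 1.0), 0.15)
  expect_equal(pad(0, 0), 0)
  expect_equal(pad(2, 0), Inf)
  expect_error(pad(NaN, 1), "NaN")
  set.seed(12)
  for (i in 1:50) {
    a <- runif(1, -5, 5); x <- rnorm(1); x0 <- rnorm(1)
    if (abs(a) < 1e-3 || abs(x0) < 1e-3) next
    expect_equal(pad(a * x, a * x0), pad(x, x0), tolerance = 1e-12)
  }
})

test_that("repeatability: identical repeats tally 1, one perturbation counted", {
  ft <- synth_features()
  rt <- repeatability_table(ft)
  expect_true(all(rt$records$pad == 0))
  expect_equal(unname(rt$tally["A"]), 1)
  expect_equal(unname(rt$tally["B"]), 1)
  # records: one per (setting, roi, feature)
  expect_equal(nrow(rt$records), (4 + 2) * 4)

  # perturb one feature in one setting's re-scan by x1.5
  ft2 <- ft
  hit <- ft2$scanner_id == "A" & ft2$setting_id == "A02" &
    ft2$repeat_index == 1 & ft2$feature_index == 2
  expect_equal(sum(hit), 1)
  ft2$value[hit] <- ft2$value[hit] * 1.5
  rt2 <- repeatability_table(ft2)
  nA <- sum(rt2$records$scanner_id == "A")
  expect_equal(unname(rt2$tally["A"]), 1 - 1 / nA)

  # unmatched pairs error
  expect_error(repeatability_table(ft[ft$repeat_index == 0, ]), "repeat")
})

test_that("robustness: per-family grouping, counts and zero-noise tally", {
  ft <- synth_features()
  rb <- robustness_table(ft)
  expect_true(all(rb$records$pad == 0))
  expect_true(all(rb$family_tally$tally == 1))
  # scanner A: 2 slice-thickness settings + 1 fov, 4 features each
  fams <- rb$family_tally
  expect_equal(fams$n[fams$scanner_id == "A" &
                        fams$parameter_family == "slice_thickness"], 8)
  expect_equal(fams$n[fams$scanner_id == "A" &
                        fams$parameter_family == "fov"], 4)
  # missing baseline errors
  expect_error(robustness_table(ft[ft$varied_parameter != "baseline", ]),
               "baseline")
})

test_that("tally is monotone in the cutoff", {
  set.seed(33)
  ft <- synth_features(value_fun = function(sc, set, f)
    1 + 0.2 * set + 0.3 * f)
  # add jitter between repeats
  ft$value <- ft$value * ifelse(ft$repeat_index == 1,
                                exp(rnorm(nrow(ft), 0, 0.1)), 1)
  cuts <- c(0.01, 0.05, 0.15, 0.5)
  tallies <- sapply(cuts, function(ct)
    mean(repeatability_table(ft, cutoff = ct)$records$pad <= ct))
  expect_true(all(diff(tallies) >= 0))
})

test_that("reliable_set: conjunction across scanners, band monotonicity", {
  ft <- synth_features()
  rt <- repeatability_table(ft)
  rb <- robustness_table(ft)
  rep0 <- reliable_set(rt, rb, band = 0.05)
  expect_setequal(rep0$reliable, paste0("f", 1:4))

  # a single PAD of 0.06 on one scanner excludes a feature at band 0.05
  ft2 <- ft
  hit <- ft2$scanner_id == "B" & ft2$setting_id == "B02" &
    ft2$repeat_index == 1 & ft2$feature_index == 3
  ft2$value[hit] <- ft2$value[hit] * 1.06
  rep2 <- reliable_set(repeatability_table(ft2), robustness_table(ft2),
                       band = 0.05)
  expect_false("f3" %in% rep2$reliable)
  expect_true("f2" %in% rep2$reliable)
  # ... but is admitted at a wider band
  rep3 <- reliable_set(repeatability_table(ft2), robustness_table(ft2),
                       band = 0.10)
  expect_true("f3" %in% rep3$reliable)
  expect_true(all(rep2$reliable %in% rep3$reliable))
})

test_that("filter contrast: empty family, zero-noise zero means", {
  ft <- synth_features()   # no filter family present
  rb <- robustness_table(ft)
  fe <- filter_effect_contrast(rb, data.frame(
    scanner_id = "A", setting_id = "A02", filter_level = 1
  ))
  expect_equal(nrow(fe$by_level), 0)

  # filter family with zero PADs -> zero means
  ft2 <- synth_features(settings = list(A = c("baseline", "filter",
                                              "filter")))
  man <- data.frame(scanner_id = "A",
                    setting_id = c("A01", "A02", "A03"),
                    filter_level = c(0, 1, 2))
  fe2 <- filter_effect_contrast(robustness_table(ft2), man)
  expect_equal(fe2$by_level$mean_pad, c(0, 0))
})

test_that("heatmap export: dimensions, clipping, CSV fidelity", {
  ft <- synth_features(n_feat = 235)
  ft$feature_name <- feature_manifest()$feature_name[ft$feature_index]
  ft$family <- feature_manifest()$family[ft$feature_index]
  # inject one large PAD: repeat-1 value of feature 1 in A02 x1.5
  hit <- ft$scanner_id == "A" & ft$setting_id == "A02" &
    ft$repeat_index == 1 & ft$feature_index == 1
  ft$value[hit] <- ft$value[hit] * 1.5
  rt <- repeatability_table(ft)
  dir <- tempfile()
  paths <- heatmap_export(rt$records, dir, png = FALSE)
  csv <- grep("heatmap_A_repeatability.csv", paths, value = TRUE)
  expect_true(file.exists(csv))
  m <- as.matrix(read.csv(csv, row.names = 1, check.names = FALSE))
  expect_equal(dim(m), c(235, 4))      # 235 features x 4 settings
  expect_equal(m["hist_mean", "A02"], 0.5)   # unclipped in the CSV
  expect_true(all(m[-1, ] == 0))
  unlink(dir, recursive = TRUE)
})
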