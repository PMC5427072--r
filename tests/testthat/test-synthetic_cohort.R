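test_that("cohort sampling respects the configured age range and determinism", {
  coh <- sample_cohort(72, cohort_config(), seed = 21)
  expect_equal(nrow(coh), 72)
  expect_true(all(coh$age_years >= 40 & coh$age_years <= 77))
  expect_true(all(is.finite(coh$ssrt_ms)))
  coh2 <- sample_cohort(72, cohort_config(), seed = 21)
  expect_identical(coh, coh2)
  expect_error(sample_cohort(2, cohort_config(), seed = 1), "n_subjects >= 3")

  # minimal cohort with no age-SSRT coupling still yields a defined correlation
  coh3 <- sample_cohort(3, cohort_config(age_ssrt_r = 0), seed = 5)
  expect_true(is.finite(cor(coh3$age_years, coh3$ssrt_ms)))
})

test_that("configured population age-SSRT correlation is recovered", {
  coh <- sample_cohort(200, cohort_config(age_ssrt_r = 0.22), seed = 31)
  expect_lt(abs(cor(coh$age_years, coh$ssrt_ms) - 0.22), 0.1)
})

test_that("volumes realize the scene: masked-out zeros, finite values, effects", {
  scene <- scene_spec(grid_shape = c(14, 14, 14), n_timepoints = 96,
                      effect_regions = list())
  coh <- sample_cohort(3, cohort_config(), seed = 2)
  vol <- generate_subject_volume(coh[1, ], scene, seed = 41)
  expect_true(all(is.finite(vol$data)))
  expect_true(all(vol$data[rep(!scene$mask, scene$n_timepoints)] == 0))
  expect_identical(generate_subject_volume(coh[1, ], scene, seed = 41)$data,
                   vol$data)

  # a strong synchrony region pushes KCC far above the white-noise background
  ctr <- c(7.5, 7.5, 7.5)
  strong <- scene_spec(grid_shape = c(14, 14, 14), n_timepoints = 96,
                       effect_regions = list(
                         effect_region("hot", "synchrony",
                                       sphere_region(c(14, 14, 14), ctr, 3.5),
                                       base = 0.95, slope = 0, noise_sd = 0)))
  vol2 <- generate_subject_volume(coh[1, ], strong, seed = 43)
  rh <- reho_map(bandpass(vol2, 0.01, 0.08))
  reg_big <- strong$effect_regions[[1]]$region
  reg <- sphere_region(c(14, 14, 14), ctr, 2.5)
  bg <- strong$mask & !reg_big
  # evaluate on the region interior: neighbourhoods at the region border mix
  # in background voxels and dilute the concordance by construction
  core <- erode27(reg_big)
  expect_gt(mean(rh$values[core]), 0.5)
  expect_gt(mean(rh$values[core]), mean(rh$values[bg], na.rm = TRUE) + 0.3)

  # a zero-coupling region is indistinguishable from background
  null_reg <- scene_spec(grid_shape = c(14, 14, 14), n_timepoints = 96,
                         effect_regions = list(
                           effect_region("cold", "synchrony",
                                         sphere_region(c(14, 14, 14), ctr, 2.5),
                                         base = 0, slope = 0, noise_sd = 0,
                                         lo = 0)))
  vol3 <- generate_subject_volume(coh[1, ], null_reg, seed = 44)
  rh3 <- reho_map(bandpass(vol3, 0.01, 0.08))
  m_reg <- mean(rh3$values[reg])
  bg_vals <- rh3$values[null_reg$mask & !reg]
  se <- sd(bg_vals, na.rm = TRUE) / sqrt(sum(reg))
  expect_lt(abs(m_reg - mean(bg_vals, na.rm = TRUE)), 2 * se + 0.02)

  # amplitude gain 0 leaves the fALFF distribution at background level
  null_amp <- scene_spec(grid_shape = c(14, 14, 14), n_timepoints = 96,
                         effect_regions = list(
                           effect_region("amp0", "amplitude",
                                         sphere_region(c(14, 14, 14), ctr, 2.5),
                                         base = 0, slope = 0, noise_sd = 0,
                                         lo = 0)))
  vol4 <- generate_subject_volume(coh[1, ], null_amp, seed = 45)
  fa <- falff_map(detrend(vol4))
  expect_lt(abs(mean(fa$values[reg]) -
                mean(fa$values[null_amp$mask & !reg], na.rm = TRUE)), 0.02)

  # region voxels outside the mask are rejected
  bad_mask <- array(FALSE, c(14, 14, 14))
  bad_mask[4:11, 4:11, 4:11] <- TRUE
  expect_error(
    scene_spec(grid_shape = c(14, 14, 14), n_timepoints = 96, mask = bad_mask,
               effect_regions = list(
                 effect_region("out", "synchrony",
                               sphere_region(c(14, 14, 14), c(2, 2, 2), 1.5)))),
    "outside the mask")
})

test_that("amplitude regions raise fALFF without raising local synchrony", {
  dims <- c(14, 14, 14)
  ctr <- c(7.5, 7.5, 7.5)
  reg <- sphere_region(dims, ctr, 2.5)
  sc <- scene_spec(grid_shape = dims, n_timepoints = 240,
                   effect_regions = list(
                     effect_region("amp", "amplitude", reg,
                                   base = 1.5, slope = 0, noise_sd = 0)))
  coh <- sample_cohort(3, cohort_config(), seed = 3)
  vol <- generate_subject_volume(coh[1, ], sc, seed = 51)
  fa <- falff_map(detrend(vol))
  rh <- reho_map(bandpass(vol, 0.01, 0.08))
  bg <- sc$mask & !reg
  expect_gt(mean(fa$values[reg]), mean(fa$values[bg], na.rm = TRUE) + 0.1)
  expect_lt(abs(mean(rh$values[reg]) - mean(rh$values[bg], na.rm = TRUE)), 0.05)
})

test_that("cohorts round-trip through disk losslessly", {
  scene <- scene_spec(grid_shape = c(10, 10, 10), n_timepoints = 64,
                      effect_regions = list(
                        effect_region("core", "both",
                                      sphere_region(c(10, 10, 10),
                                                    c(5.5, 5.5, 5.5), 1.6))))
  coh <- sample_cohort(3, cohort_config(), seed = 61)
  vols <- lapply(1:3, function(i)
    generate_subject_volume(coh[i, ], scene, seed = coh$volume_seed[i]))
  out <- file.path(tempdir(), "cohort_rt")
  unlink(out, recursive = TRUE)
  paths <- write_cohort(coh, vols, out, scene)
  expect_true(file.exists(file.path(out, "cohort.tsv")))
  expect_true(file.exists(file.path(out, "mask.nii.gz")))
  expect_true(file.exists(file.path(out, "truth_labels.nii.gz")))

  back <- read_volume_series(file.path(out, "sub-001_bold.nii.gz"),
                             mask = file.path(out, "mask.nii.gz"))
  expect_equal(back$tr_s, scene$tr_s)
  expect_equal(back$voxel_mm, scene$voxel_mm)
  expect_equal(back$data, vols[[1]]$data, tolerance = 1e-6)

  # overwrite protection
  expect_error(write_cohort(coh, vols, out, scene), "overwrite")
  expect_silent(write_cohort(coh, vols, out, scene, overwrite = TRUE))

  # same seed regenerates a byte-identical cohort table
  tab1 <- readLines(file.path(out, "cohort.tsv"))
  coh2 <- sample_cohort(3, cohort_config(), seed = 61)
  vols2 <- lapply(1:3, function(i)
    generate_subject_volume(coh2[i, ], scene, seed = coh2$volume_seed[i]))
  out2 <- file.path(tempdir(), "cohort_rt2")
  unlink(out2, recursive = TRUE)
  write_cohort(coh2, vols2, out2, scene)
  expect_identical(tab1, readLines(file.path(out2, "cohort.tsv")))
  expect_identical(vols2[[2]]$data, vols[[2]]$data)
})
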