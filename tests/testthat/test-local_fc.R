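test_that("kcc reproduces hand-computed and analytic cases", {
  # 27 identical copies of a strictly monotone series: perfect concordance
  m <- matrix(rep(1:10, 27), nrow = 27, byrow = TRUE)
  expect_equal(kcc(m), 1)

  # two perfectly anti-concordant series: rank sums constant, W = 0
  expect_equal(kcc(rbind(1:4, 4:1)), 0)

  # hand-computed rank-sum example: rank sums (6, 7, 8, 9) -> W = 5/45
  m3 <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(kcc(m3), 5 / 45)

  expect_error(kcc(rbind(rep(1, 5), 1:5)), "constant")
  expect_error(kcc(matrix(1:4, 1)), "K >= 2")
})

test_that("kcc agrees with a first-principles implementation and is rank-invariant", {
  set.seed(42)
  for (i in 1:300) {
    K <- sample(2:30, 1)
    n <- sample(2:50, 1)
    m <- matrix(rnorm(K * n), K, n)
    expect_equal(kcc(m), kcc_bruteforce(m), tolerance = 1e-12)
  }
  # invariance under strictly monotone transform of a single series
  m <- matrix(rnorm(5 * 20), 5, 20)
  m2 <- m
  m2[3, ] <- exp(2 * m2[3, ]) + 5
  expect_equal(kcc(m2), kcc(m), tolerance = 1e-12)
})

test_that("reho_map matches voxelwise kcc and behaves at the mask edge", {
  s <- noise_series(dims = c(7, 7, 7), nt = 48, seed = 14)
  rh <- reho_map(s, 27)
  # interior voxel: full 27-neighbourhood, compare against kcc directly
  nb <- as.matrix(expand.grid(3:5, 3:5, 3:5))
  series <- t(apply(nb, 1, function(p) s$data[p[1], p[2], p[3], ]))
  expect_equal(rh$values[4, 4, 4], kcc(series), tolerance = 1e-12)
  # corner voxel: neighbourhood truncated to the 8 in-grid members
  nb2 <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  series2 <- t(apply(nb2, 1, function(p) s$data[p[1], p[2], p[3], ]))
  expect_equal(rh$values[1, 1, 1], kcc(series2), tolerance = 1e-12)
  # smaller neighbourhoods are accepted, others rejected
  expect_s3_class(reho_map(s, 7), "brain_map")
  expect_s3_class(reho_map(s, 19), "brain_map")
  expect_error(reho_map(s, 11), "neighborhood")
})

test_that("reho_map hits its analytic extremes", {
  # every voxel shares one series: W = 1 everywhere
  dims <- c(5, 5, 5)
  w <- rnorm(40)
  arr <- array(rep(w, each = prod(dims)), c(dims, 40))
  s <- volume_series(arr, array(TRUE, dims), tr_s = 2)
  rh <- reho_map(s)
  expect_true(all(abs(rh$values - 1) < 1e-12))

  # independent white noise: map mean near the small-sample null of W
  s2 <- noise_series(dims = c(10, 10, 10), nt = 240, seed = 15)
  rh2 <- reho_map(s2)
  expect_lt(mean(rh2$values), 0.1)

  # a synchrony region stands out from a null background
  dims3 <- c(12, 12, 12)
  reg <- sphere_region(dims3, c(6.5, 6.5, 6.5), 2.5)
  sc <- scene_spec(grid_shape = dims3, n_timepoints = 120,
                   effect_regions = list(
                     effect_region("hot", "synchrony", reg,
                                   base = 0.9, slope = 0, noise_sd = 0)))
  coh <- sample_cohort(3, cohort_config(), seed = 4)
  vol <- generate_subject_volume(coh[1, ], sc, seed = 71)
  rh3 <- reho_map(bandpass(vol, 0.01, 0.08))
  reg_v <- rh3$values[reg]
  bg_v <- rh3$values[sc$mask & !reg]
  expect_lt(t.test(bg_v, reg_v, alternative = "less")$p.value, 1e-3)
})

test_that("falff matches the spectral-ratio definition on analytic inputs", {
  tr <- 2
  nt <- 250   # 0.04 and 0.20 Hz sit exactly on the FFT grid (1/500 Hz steps)
  t_s <- (seq_len(nt) - 1) * tr
  mk <- function(x) {
    arr <- array(rep(x, each = 8), c(2, 2, 2, nt))
    volume_series(arr, array(TRUE, c(2, 2, 2)), tr_s = tr)
  }
  # all amplitude inside the numerator band
  x1 <- sin(2 * pi * 0.04 * t_s)
  f1 <- falff_map(mk(x1))
  expect_lt(abs(f1$values[1, 1, 1] - 1), 0.02)
  expect_lt(abs(f1$values[1, 1, 1] - falff_oracle(x1, tr)), 0.02)
  # all amplitude outside the numerator band
  x2 <- sin(2 * pi * 0.20 * t_s)
  f2 <- falff_map(mk(x2))
  expect_lt(abs(f2$values[1, 1, 1] - 0), 0.02)
  # equal mix: ratio one half
  x3 <- x1 + x2
  f3 <- falff_map(mk(x3))
  expect_lt(abs(f3$values[1, 1, 1] - 0.5), 0.02)
  expect_lt(abs(f3$values[1, 1, 1] - falff_oracle(x3, tr)), 0.02)
  # scale invariance
  f4 <- falff_map(mk(7.3 * x3))
  expect_equal(f4$values[1, 1, 1], f3$values[1, 1, 1], tolerance = 1e-12)
  # values bounded in [0, 1] on noise
  s <- noise_series(dims = c(4, 4, 4), nt = 100, seed = 16)
  fv <- falff_map(s)$values
  expect_true(all(fv >= 0 & fv <= 1))
})

test_that("map standardization divides by the within-mask mean", {
  dims <- c(4, 4, 4)
  cmap <- brain_map(array(3, dims), array(TRUE, dims), kind = "reho")
  expect_true(all(standardize_map(cmap)$values == 1))

  set.seed(17)
  m <- brain_map(array(runif(64, 0.2, 1), dims), array(TRUE, dims),
                 kind = "falff")
  sm <- standardize_map(m)
  expect_equal(mean(sm$values), 1, tolerance = 1e-12)
  # scale invariance of the standardized map
  m2 <- m
  m2$values <- 2 * m2$values
  expect_equal(standardize_map(m2)$values, sm$values, tolerance = 1e-12)
  # non-positive mean rejected
  neg <- brain_map(array(-1, dims), array(TRUE, dims), kind = "r")
  expect_error(standardize_map(neg), "positive")
})

test_that("array path and NIfTI file path agree bit for bit", {
  scene <- scene_spec(grid_shape = c(10, 10, 10), n_timepoints = 64,
                      effect_regions = list())
  coh <- sample_cohort(3, cohort_config(), seed = 6)
  vol <- generate_subject_volume(coh[1, ], scene, seed = 81)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume_series(f, mask = scene$mask)
  rh_mem <- reho_map(bandpass(vol, 0.01, 0.08))
  rh_file <- reho_map(bandpass(back, 0.01, 0.08))
  expect_identical(rh_mem$values, rh_file$values)
  fa_mem <- falff_map(detrend(vol))
  fa_file <- falff_map(detrend(back))
  expect_identical(fa_mem$values, fa_file$values)
})
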