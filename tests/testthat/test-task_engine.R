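test_that("trial sequences honor block composition and are deterministic", {
  plan <- build_trial_sequence(5, 140, 40, seed = 11)
  expect_equal(nrow(plan$trials), 700)
  expect_equal(sum(plan$trials$type == "stop"), 200)
  counts <- tapply(plan$trials$type == "stop", plan$trials$block, sum)
  expect_true(all(counts == 40))
  expect_true(all(plan$trials$isi_ms >= 1300 & plan$trials$isi_ms <= 4800))

  # degenerate single-trial block
  tiny <- build_trial_sequence(1, 1, 0, seed = 1)
  expect_equal(tiny$trials$type, "go")

  # per-block counts verified by exhaustive count on a small design
  p2 <- build_trial_sequence(2, 10, 3, seed = 5)
  expect_equal(as.vector(tapply(p2$trials$type == "stop", p2$trials$block, sum)),
               c(3L, 3L))

  expect_identical(build_trial_sequence(3, 20, 5, seed = 9)$trials,
                   build_trial_sequence(3, 20, 5, seed = 9)$trials)
  expect_error(build_trial_sequence(2, 5, 6, seed = 1), "exceed")
})

test_that("staircase steps by 50 ms and clamps to [0, 800]", {
  expect_equal(staircase_update(350, TRUE), 400)
  expect_equal(staircase_update(350, FALSE), 300)
  expect_equal(staircase_update(0, FALSE), 0)
  expect_equal(staircase_update(800, TRUE), 800)
  expect_equal(staircase_update(25, FALSE, step_ms = 50), 0)
})

test_that("SSD trajectories stay on the 50-ms lattice of their start values", {
  plan <- build_trial_sequence(2, 100, 40, seed = 3)
  beh <- simulate_subject(race_model_params(), plan, seed = 3)
  st <- beh[beh$type == "stop", ]
  for (s in 1:2) {
    ssd <- st$ssd_ms[st$staircase == s]
    start <- c(150, 350)[s]
    # until the first clamp at 0 or 800 the lattice offset is preserved
    first_clamp <- which(ssd %in% c(0, 800))[1]
    upto <- if (is.na(first_clamp)) length(ssd) else first_clamp
    expect_true(all((ssd[seq_len(upto)] - start) %% 50 == 0))
    expect_true(all(ssd >= 0 & ssd <= 800))
  }
  # strict alternation between the two staircases
  expect_true(all(st$staircase == rep_len(c(1L, 2L), nrow(st))))
})

test_that("race outcomes follow the independent-race rule at pinned SSDs", {
  params <- race_model_params(mu_ms = 500, sigma_ms = 50, tau_ms = 100,
                              true_ssrt_ms = 250, omission_rate = 0,
                              choice_error_rate = 0)
  plan <- build_trial_sequence(1, 400, 400, seed = 2)

  # stop latency far below any plausible go RT at ssd 0: all stops succeed
  fast_stop <- race_model_params(mu_ms = 800, sigma_ms = 20, tau_ms = 50,
                                 true_ssrt_ms = 1, omission_rate = 0,
                                 choice_error_rate = 0)
  beh <- simulate_subject(fast_stop, plan, seed = 1, start_ms = c(0, 0),
                          lower_ms = 0, upper_ms = 0)
  expect_true(all(!beh$responded[beh$type == "stop"]))

  # SSD pinned at 800 with go RTs virtually all far below 800 + ssrt: all fail
  slow_stop <- race_model_params(mu_ms = 300, sigma_ms = 20, tau_ms = 30,
                                 true_ssrt_ms = 300, omission_rate = 0,
                                 choice_error_rate = 0)
  beh2 <- simulate_subject(slow_stop, plan, seed = 1, start_ms = c(800, 800),
                           lower_ms = 800, upper_ms = 800)
  expect_true(all(beh2$responded[beh2$type == "stop"]))

  # P(respond | ssd) matches the analytic ex-Gaussian CDF at ssd + ssrt
  big <- build_trial_sequence(1, 10000, 10000, seed = 4)
  for (ssd in c(200, 350)) {
    beh3 <- simulate_subject(params, big, seed = ssd,
                             start_ms = c(ssd, ssd),
                             lower_ms = ssd, upper_ms = ssd)
    p_emp <- mean(beh3$responded[beh3$type == "stop"])
    p_th <- pexgauss(ssd + 250, 500, 50, 100)
    expect_lt(abs(p_emp - p_th), 0.01)
  }
})

test_that("SSRT estimation implements median go RT minus median SSD", {
  beh <- data.frame(
    trial = 1:6, block = 1,
    type = c("go", "go", "go", "stop", "stop", "stop"),
    staircase = c(NA, NA, NA, 1, 2, 1),
    ssd_ms = c(NA, NA, NA, 200, 300, 400),
    responded = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    rt_ms = c(500, 600, 700, NA, NA, 650),
    correct = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  s <- estimate_ssrt(beh)
  expect_equal(s$ssrt_ms, 300)
  expect_equal(s$median_go_rt_ms, 600)
  expect_equal(s$median_ssd_ms, 300)

  # all go trials omitted -> undefined median -> error
  beh$responded[1:3] <- FALSE
  beh$rt_ms[1:3] <- NA
  expect_error(estimate_ssrt(beh), "insufficient")
})

test_that("SSRT recovery is accurate and nearly unbiased for a race subject", {
  plan <- build_trial_sequence(1, 600, 200, seed = 6)  # 200 stop trials
  params <- race_model_params(true_ssrt_ms = 250)
  est <- vapply(1:8, function(s) {
    estimate_ssrt(simulate_subject(params, plan, seed = s))$ssrt_ms
  }, numeric(1))
  expect_lt(abs(mean(est) - 250), 20)
  expect_lt(abs(mean(est) - 250) / 250, 0.10)  # bias < 10% of true SSRT
})

test_that("go RT and SSRT estimates are uncorrelated across independent subjects", {
  plan <- build_trial_sequence(2, 140, 40, seed = 10)
  set.seed(77)
  mu <- rnorm(200, 550, 40)
  ssrt_true <- rnorm(200, 300, 50)
  out <- t(vapply(1:200, function(i) {
    p <- race_model_params(mu_ms = mu[i], true_ssrt_ms = max(ssrt_true[i], 100))
    s <- estimate_ssrt(simulate_subject(p, plan, seed = 1000 + i))
    c(s$median_go_rt_ms, s$ssrt_ms)
  }, numeric(2)))
  # mu and true ssrt were generated independently; estimates must not couple
  expect_lt(abs(cor(out[, 1], out[, 2])), 0.1)
})
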