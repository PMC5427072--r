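#' Build a stop-signal task trial sequence
#'
#' Lays out a block-structured stop-signal experiment: each block contains
#' `trials_per_block` trials of which exactly `stop_per_block` are stop trials,
#' with the stop positions shuffled uniformly within each block. Inter-stimulus
#' intervals are drawn uniformly from 1300--4800 ms. The defaults reproduce the
#' standard design of five blocks of 140 trials with 40 stop trials each.
#'
#' @param blocks Number of blocks.
#' @param trials_per_block Trials in each block.
#' @param stop_per_block Stop trials in each block; must not exceed
#'   `trials_per_block`.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return An object of class `trial_plan`: a list with the design counts and a
#'   `trials` data frame (columns `trial`, `block`, `type`, `isi_ms`).
#' @export
build_trial_sequence <- function(blocks = 5L, trials_per_block = 140L,
                                 stop_per_block = 40L, seed = 1L) {
  blocks <- as.integer(blocks)
  trials_per_block <- as.integer(trials_per_block)
  stop_per_block <- as.integer(stop_per_block)
  if (blocks < 1L || trials_per_block < 1L || stop_per_block < 0L)
    stop("blocks and trials_per_block must be >= 1, stop_per_block >= 0")
  if (stop_per_block > trials_per_block)
    stop("stop_per_block must not exceed trials_per_block")
  n <- blocks * trials_per_block
  set.seed(seed)
  type <- character(n)
  for (b in seq_len(blocks)) {
    idx <- (b - 1L) * trials_per_block + seq_len(trials_per_block)
    lab <- rep("go", trials_per_block)
    if (stop_per_block > 0L)
      lab[sample.int(trials_per_block, stop_per_block)] <- "stop"
    type[idx] <- lab
  }
  plan <- list(
    blocks = blocks,
    trials_per_block = trials_per_block,
    stop_per_block = stop_per_block,
    trials = data.frame(
      trial = seq_len(n),
      block = rep(seq_len(blocks), each = trials_per_block),
      type = type,
      isi_ms = stats::runif(n, 1300, 4800),
      stringsAsFactors = FALSE
    )
  )
  class(plan) <- "trial_plan"
  plan
}

#' One step of the 50-ms staircase tracking rule
#'
#' A successful stop raises the stop-signal delay by `step_ms` (making the next
#' stop harder); a failed stop lowers it. The delay is clamped to
#' `[lower_ms, upper_ms]` (0--800 ms by default).
#'
#' @param ssd_ms Current stop-signal delay (ms).
#' @param stop_succeeded Logical: was the stop successful?
#' @param step_ms Step size (default 50 ms).
#' @param lower_ms,upper_ms Clamp bounds (default 0 and 800 ms).
#' @return Updated SSD in ms.
#' @export
staircase_update <- function(ssd_ms, stop_succeeded, step_ms = 50,
                             lower_ms = 0, upper_ms = 800) {
  stopifnot(is.numeric(ssd_ms), length(ssd_ms) == 1L, is.finite(ssd_ms))
  ssd <- ssd_ms + if (isTRUE(stop_succeeded)) step_ms else -step_ms
  min(max(ssd, lower_ms), upper_ms)
}

#' Race-model subject parameters
#'
#' Go reaction times follow an ex-Gaussian distribution (Gaussian with mean
#' `mu_ms` and sd `sigma_ms`, plus an independent exponential with mean
#' `tau_ms`), the standard parametric family for RT data. The stop process has
#' a fixed latency `true_ssrt_ms`; go and stop finish times race independently.
#'
#' @param mu_ms,sigma_ms,tau_ms Ex-Gaussian parameters of the go RT (ms).
#' @param true_ssrt_ms Stop-process latency (ms), constant within subject.
#' @param omission_rate Probability a go trial receives no response.
#' @param choice_error_rate Probability a responded go trial presses the wrong
#'   key (such trials keep their RT).
#' @return A `race_model_params` list.
#' @export
race_model_params <- function(mu_ms = 550, sigma_ms = 60, tau_ms = 127,
                              true_ssrt_ms = 300, omission_rate = 0.0207,
                              choice_error_rate = 0.1124) {
  p <- list(mu_ms = mu_ms, sigma_ms = sigma_ms, tau_ms = tau_ms,
            true_ssrt_ms = true_ssrt_ms, omission_rate = omission_rate,
            choice_error_rate = choice_error_rate)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1L))))
    stop("race-model parameters must be finite numeric scalars")
  if (p$sigma_ms <= 0 || p$tau_ms <= 0) stop("sigma_ms and tau_ms must be > 0")
  if (p$true_ssrt_ms <= 0) stop("true_ssrt_ms must be > 0")
  if (p$omission_rate < 0 || p$omission_rate >= 1 ||
      p$choice_error_rate < 0 || p$choice_error_rate >= 1)
    stop("rates must lie in [0, 1)")
  class(p) <- "race_model_params"
  p
}

#' Simulate one subject performing the stop-signal task
#'
#' Runs the horse-race model through a trial plan. Stop trials alternate
#' strictly between two interleaved staircases (starting SSDs 150 and 350 ms,
#' 50-ms steps, clamped to 0--800 ms). On a stop trial the response is emitted
#' iff the sampled go finishing time is at most `ssd + true_ssrt_ms` (and the
#' trial is not an omission); the staircase in force is then updated by the
#' outcome.
#'
#' @param params A [race_model_params()] object.
#' @param plan A [build_trial_sequence()] plan.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @param start_ms Length-2 starting SSDs of the two staircases.
#' @param step_ms,lower_ms,upper_ms Staircase step and clamp bounds. Setting
#'   `lower_ms = upper_ms` pins the SSD, which is useful for probing the race
#'   model at a fixed delay.
#' @return A `subject_behavior` data frame with one row per trial: `trial`,
#'   `block`, `type`, `staircase` (NA on go trials), `ssd_ms` (NA on go
#'   trials), `responded`, `rt_ms` (NA on omissions and successful stops),
#'   `correct`.
#' @export
simulate_subject <- function(params, plan, seed = 1L,
                             start_ms = c(150, 350), step_ms = 50,
                             lower_ms = 0, upper_ms = 800) {
  stopifnot(inherits(params, "race_model_params"), inherits(plan, "trial_plan"))
  trials <- plan$trials
  n <- nrow(trials)
  if (n < 1L) stop("plan is empty")
  stopifnot(length(start_ms) == 2L)
  set.seed(seed)
  go_time <- params$mu_ms + stats::rnorm(n, 0, params$sigma_ms) +
    stats::rexp(n, rate = 1 / params$tau_ms)
  omit <- stats::runif(n) < params$omission_rate
  wrong <- stats::runif(n) < params$choice_error_rate

  ssd_state <- c(min(max(start_ms[1], lower_ms), upper_ms),
                 min(max(start_ms[2], lower_ms), upper_ms))
  stair_id <- rep(NA_integer_, n)
  ssd_ms <- rep(NA_real_, n)
  responded <- logical(n)
  rt_ms <- rep(NA_real_, n)
  correct <- logical(n)
  next_stair <- 1L
  for (i in seq_len(n)) {
    if (trials$type[i] == "go") {
      if (omit[i]) {
        responded[i] <- FALSE
        correct[i] <- FALSE
      } else {
        responded[i] <- TRUE
        rt_ms[i] <- go_time[i]
        correct[i] <- !wrong[i]
      }
    } else {
      s <- next_stair
      next_stair <- 3L - next_stair
      stair_id[i] <- s
      ssd_ms[i] <- ssd_state[s]
      respond <- !omit[i] && go_time[i] <= ssd_state[s] + params$true_ssrt_ms
      responded[i] <- respond
      if (respond) rt_ms[i] <- go_time[i]
      correct[i] <- !respond  # a stop trial is correct iff inhibited
      ssd_state[s] <- staircase_update(ssd_state[s], !respond, step_ms,
                                       lower_ms, upper_ms)
    }
  }
  out <- data.frame(
    trial = trials$trial, block = trials$block, type = trials$type,
    staircase = stair_id, ssd_ms = ssd_ms, responded = responded,
    rt_ms = rt_ms, correct = correct, stringsAsFactors = FALSE
  )
  class(out) <- c("subject_behavior", "data.frame")
  out
}

#' Summarize behavior and estimate SSRT
#'
#' SSRT is estimated by the median method: the median SSD over all stop trials
#' is subtracted from the median RT of correct, responded go trials. Omitted go
#' trials are excluded from the RT median; choice errors are excluded as
#' incorrect.
#'
#' @param behavior A `subject_behavior` data frame from [simulate_subject()]
#'   (or any data frame with the same columns).
#' @return A one-row `data.frame`: `median_go_rt_ms`, `median_ssd_ms`,
#'   `stop_success_rate` (percent), `ssrt_ms`, `go_accuracy_pct`,
#'   `omission_pct`.
#' @export
estimate_ssrt <- function(behavior) {
  stopifnot(is.data.frame(behavior))
  go <- behavior[behavior$type == "go", , drop = FALSE]
  stops <- behavior[behavior$type == "stop", , drop = FALSE]
  go_rts <- go$rt_ms[go$responded & go$correct & !is.na(go$rt_ms)]
  if (length(go_rts) < 1L || nrow(stops) < 1L)
    stop("insufficient trials: need >= 1 correct go RT and >= 1 stop trial")
  med_go <- stats::median(go_rts)
  med_ssd <- stats::median(stops$ssd_ms)
  data.frame(
    median_go_rt_ms = med_go,
    median_ssd_ms = med_ssd,
    stop_success_rate = 100 * mean(!stops$responded),
    ssrt_ms = med_go - med_ssd,
    go_accuracy_pct = 100 * mean(go$responded & go$correct),
    omission_pct = 100 * mean(!go$responded)
  )
}

#' Cumulative distribution of the ex-Gaussian go RT
#'
#' Closed-form CDF of the ex-Gaussian family; used for analytic predictions of
#' the probability of responding on a stop trial, P(go finishing time <= ssd +
#' ssrt).
#'
#' @param q Quantiles (ms).
#' @param mu_ms,sigma_ms,tau_ms Ex-Gaussian parameters.
#' @return P(RT <= q).
#' @export
pexgauss <- function(q, mu_ms, sigma_ms, tau_ms) {
  z <- (q - mu_ms) / sigma_ms
  u <- sigma_ms / tau_ms
  # guard the exp term against overflow where the CDF is effectively Phi(z)
  lg <- sigma_ms^2 / (2 * tau_ms^2) - (q - mu_ms) / tau_ms +
    stats::pnorm(z - u, log.p = TRUE)
  stats::pnorm(z) - exp(pmin(lg, 700))
}
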