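#' Spherical region on a voxel grid
#'
#' @param grid_shape 3-D voxel counts.
#' @param center Voxel coordinates of the centre (may be fractional).
#' @param radius_vox Radius in voxels.
#' @return 3-D logical array.
#' @export
sphere_region <- function(grid_shape, center, radius_vox) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius_vox^2, grid_shape)
}

#' Effect region specification
#'
#' Describes one region of the synthetic brain and how its signal couples to
#' behavior. Kinds: `"synchrony"` injects a region-shared broadband component
#' (raises regional homogeneity, leaves the spectrum untouched);
#' `"amplitude"` injects voxel-private low-frequency components (raises fALFF,
#' leaves local synchrony untouched); `"both"` injects a region-shared
#' low-frequency component (raises both); `"age_only"` is the `"both"`
#' construction driven by the subject's age instead of SSRT.
#'
#' @param name Region label.
#' @param kind One of `"synchrony"`, `"amplitude"`, `"both"`, `"age_only"`.
#' @param region 3-D logical array of member voxels.
#' @param sign Coupling direction relative to the driving score (-1: higher
#'   score, weaker signal — the negative brain-behavior coupling).
#' @param base,slope,lo,hi,noise_sd Affine link for the latent effect scalar:
#'   `latent = clip(base + slope * sign * z + noise_sd * eps, lo, hi)` with
#'   `z` the within-cohort standardized driving score and `eps` a per-subject
#'   standard-normal deviate modelling biological variability unrelated to
#'   behavior. Because the local-connectivity metrics are nearly noise-free
#'   at 240 time points, `noise_sd` is what sets the population correlation:
#'   `|r| = slope / sqrt(slope^2 + noise_sd^2)`. The per-kind defaults use
#'   `noise_sd = slope * sqrt(3)`, i.e. population |r| of about 0.5.
#' @return An `effect_region` list.
#' @export
effect_region <- function(name, kind, region, sign = -1,
                          base = NULL, slope = NULL, lo = NULL, hi = NULL,
                          noise_sd = NULL) {
  kind <- match.arg(kind, c("synchrony", "amplitude", "both", "age_only"))
  defaults <- switch(kind,
    synchrony = list(base = 0.40, slope = 0.10, noise_sd = 0.150,
                     lo = 0.02, hi = 0.90),
    amplitude = list(base = 1.00, slope = 0.25, noise_sd = 0.375,
                     lo = 0.05, hi = 2.50),
    both      = list(base = 0.32, slope = 0.12, noise_sd = 0.132,
                     lo = 0.02, hi = 0.90),
    age_only  = list(base = 0.32, slope = 0.12, noise_sd = 0.132,
                     lo = 0.02, hi = 0.90))
  structure(list(
    name = name, kind = kind, region = region, sign = sign,
    base = if (is.null(base)) defaults$base else base,
    slope = if (is.null(slope)) defaults$slope else slope,
    lo = if (is.null(lo)) defaults$lo else lo,
    hi = if (is.null(hi)) defaults$hi else hi,
    noise_sd = if (is.null(noise_sd)) defaults$noise_sd else noise_sd
  ), class = "effect_region")
}

#' Scene specification for synthetic volumes
#'
#' Geometry, timing and ground-truth effect layout of the synthetic brain.
#' Defaults: a 24x24x24 grid of 2-mm voxels, TR 2 s, 240 time points, a
#' spherical in-brain mask, and four disjoint spherical effect regions (one
#' per kind).
#'
#' @param grid_shape 3-D voxel counts.
#' @param voxel_mm Voxel edge length (mm).
#' @param tr_s Repetition time (s).
#' @param n_timepoints Retained samples (>= 64).
#' @param mask 3-D logical array; default: sphere of radius
#'   `min(grid_shape)/2 - 1.5` voxels at the grid centre.
#' @param effect_regions List of [effect_region()]s; regions must be disjoint
#'   subsets of the mask. `NULL` gives the default four-region layout;
#'   `list()` gives a null scene with no effects.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(grid_shape = c(24L, 24L, 24L), voxel_mm = 2, tr_s = 2,
                       n_timepoints = 240L, mask = NULL,
                       effect_regions = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  if (n_timepoints < 64L) stop("need n_timepoints >= 64")
  ctr <- (grid_shape + 1) / 2
  if (is.null(mask))
    mask <- sphere_region(grid_shape, ctr, min(grid_shape) / 2 - 1.5)
  mask <- array(as.logical(mask), grid_shape)
  if (is.null(effect_regions)) {
    r <- 3
    off <- 4.5
    effect_regions <- list(
      effect_region("synchrony_only", "synchrony",
                    sphere_region(grid_shape, ctr + c(-off, -off, 0), r)),
      effect_region("amplitude_only", "amplitude",
                    sphere_region(grid_shape, ctr + c(off, -off, 0), r)),
      effect_region("both_effects", "both",
                    sphere_region(grid_shape, ctr + c(-off, off, 0), r)),
      effect_region("age_related", "age_only",
                    sphere_region(grid_shape, ctr + c(off, off, 0), r))
    )
  }
  seen <- array(FALSE, grid_shape)
  for (er in effect_regions) {
    stopifnot(inherits(er, "effect_region"))
    if (any(er$region & !mask))
      stop("effect region '", er$name, "' has voxels outside the mask")
    if (any(er$region & seen))
      stop("effect regions must be disjoint ('", er$name, "' overlaps)")
    seen <- seen | er$region
  }
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm, tr_s = tr_s,
                 n_timepoints = as.integer(n_timepoints), mask = mask,
                 effect_regions = effect_regions),
            class = "scene_spec")
}

#' Cohort-level generator configuration
#'
#' Population parameters of the simulated participants. Defaults emulate a
#' healthy middle-aged-to-elderly sample: ages 40--77 (mean 59.38), a weak
#' positive age-SSRT coupling (population r 0.22), go RTs around 677 ms and
#' stop latencies around 300 ms.
#'
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param ssrt_mean,ssrt_sd Population mean and between-subject sd of the true
#'   stop latency (ms).
#' @param age_ssrt_r Population correlation between age and true SSRT.
#' @param mu_mean,mu_sd,sigma_ms,tau_ms Ex-Gaussian go-RT population
#'   parameters; `mu` varies across subjects.
#' @param omission_rate,choice_error_rate Go-trial lapse rates.
#' @param blocks,trials_per_block,stop_per_block Task design counts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(age_mean = 59.38, age_sd = 9.8,
                          age_range = c(40, 77), ssrt_mean = 300,
                          ssrt_sd = 80, age_ssrt_r = 0.22,
                          mu_mean = 550, mu_sd = 40, sigma_ms = 60,
                          tau_ms = 127, omission_rate = 0.0207,
                          choice_error_rate = 0.1124, blocks = 5L,
                          trials_per_block = 140L, stop_per_block = 40L) {
  stopifnot(abs(age_ssrt_r) <= 1, ssrt_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample a cohort of simulated subjects
#'
#' Draws ages and race-model parameters, runs every subject through the
#' stop-signal task engine, and returns one row per subject with the true and
#' estimated quantities. The columns `z_ssrt` and `z_age` are within-cohort
#' standardized scores used to drive region couplings.
#'
#' @param n_subjects Number of subjects (>= 3; a correlation is undefined
#'   below that).
#' @param config A [cohort_config()].
#' @param seed Integer seed; deterministic given the seed.
#' @return A `data.frame` with id, age, race parameters and behavioral
#'   summaries (including `ssrt_ms`, the estimated SSRT).
#' @export
sample_cohort <- function(n_subjects, config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 3L) stop("need n_subjects >= 3")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects + 1L)
  # truncated-normal ages by rejection
  age <- numeric(n_subjects)
  z_age_pop <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    repeat {
      a <- stats::rnorm(1, config$age_mean, config$age_sd)
      if (a >= config$age_range[1] && a <= config$age_range[2]) break
    }
    age[i] <- a
    z_age_pop[i] <- (a - config$age_mean) / config$age_sd
  }
  # orthogonalize the noise against age so the sample age-SSRT correlation
  # equals the configured population value (up to the floor clip below)
  z_age_s <- as.vector(scale(age))
  eps <- stats::rnorm(n_subjects)
  eps <- stats::residuals(stats::lm(eps ~ z_age_s))
  eps <- if (stats::sd(eps) > 0) eps / stats::sd(eps) else eps
  rho <- config$age_ssrt_r
  true_ssrt <- config$ssrt_mean +
    config$ssrt_sd * (rho * z_age_s + sqrt(1 - rho^2) * eps)
  true_ssrt <- pmax(true_ssrt, 80)
  mu <- stats::rnorm(n_subjects, config$mu_mean, config$mu_sd)

  plan <- build_trial_sequence(config$blocks, config$trials_per_block,
                               config$stop_per_block,
                               seed = sub_seeds[n_subjects + 1L])
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    params <- race_model_params(mu_ms = mu[i], sigma_ms = config$sigma_ms,
                                tau_ms = config$tau_ms,
                                true_ssrt_ms = true_ssrt[i],
                                omission_rate = config$omission_rate,
                                choice_error_rate = config$choice_error_rate)
    beh <- simulate_subject(params, plan, seed = sub_seeds[i])
    rows[[i]] <- cbind(
      data.frame(id = sprintf("sub-%03d", i), age_years = age[i],
                 mu_ms = mu[i], sigma_ms = config$sigma_ms,
                 tau_ms = config$tau_ms, true_ssrt_ms = true_ssrt[i],
                 volume_seed = sub_seeds[i]),
      estimate_ssrt(beh)
    )
  }
  cohort <- do.call(rbind, rows)
  cohort$z_ssrt <- as.vector(scale(cohort$ssrt_ms))
  cohort$z_age <- as.vector(scale(cohort$age_years))
  cohort
}

# latent effect scalar for one region and subject; eps ~ N(0,1) is the
# subject's behavior-unrelated biological variability for this region
region_latent <- function(er, z_ssrt, z_age, eps = 0) {
  z <- if (er$kind == "age_only") z_age else z_ssrt
  min(max(er$base + er$slope * er$sign * z + er$noise_sd * eps, er$lo), er$hi)
}

# unit-variance band-limited noise matrix (nt x k), hard passband on the FFT grid
band_limited_noise <- function(nt, k, tr_s, low_hz = 0.01, high_hz = 0.08) {
  Y <- matrix(stats::rnorm(nt * k), nt, k)
  f <- fft_freqs(nt, tr_s)
  keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12 & seq_len(nt) != 1L
  Fy <- stats::mvfft(Y)
  Fy[!keep, ] <- 0
  Yf <- Re(stats::mvfft(Fy, inverse = TRUE)) / nt
  sweep(Yf, 2, apply(Yf, 2, stats::sd), "/")
}

#' Generate one subject's 4-D volume
#'
#' Background in-mask voxels are unit-variance white noise. Effect regions
#' modify the series according to their kind and the subject's latent scalar
#' (see [effect_region()]); masked-out voxels are exactly zero. Every series
#' keeps unit variance in expectation, so amplitude effects act on the
#' spectral composition, not the overall scale.
#'
#' @param subject One row of a [sample_cohort()] data frame (needs `z_ssrt`
#'   and `z_age`).
#' @param scene A [scene_spec()].
#' @param seed Integer seed; deterministic given the seed.
#' @return A [volume_series()].
#' @export
generate_subject_volume <- function(subject, scene, seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  if (!all(c("z_ssrt", "z_age") %in% names(subject)))
    stop("subject row must carry z_ssrt and z_age")
  d <- c(scene$grid_shape, scene$n_timepoints)
  nt <- scene$n_timepoints
  vox <- which(scene$mask)
  set.seed(seed)
  M <- matrix(0, prod(scene$grid_shape), nt)
  M[vox, ] <- stats::rnorm(length(vox) * nt)
  for (er in scene$effect_regions) {
    rvox <- which(er$region)
    if (any(!scene$mask[rvox])) stop("region voxels outside the mask")
    lat <- region_latent(er, subject$z_ssrt, subject$z_age, stats::rnorm(1))
    k <- length(rvox)
    if (er$kind == "synchrony") {
      shared <- stats::rnorm(nt)              # broadband: spectrum unchanged
      M[rvox, ] <- sqrt(lat) * matrix(shared, k, nt, byrow = TRUE) +
        sqrt(1 - lat) * M[rvox, ]
    } else if (er$kind == "amplitude") {
      l <- band_limited_noise(nt, k, scene$tr_s)  # private low-frequency
      M[rvox, ] <- (M[rvox, ] + lat * t(l)) / sqrt(1 + lat^2)
    } else {                                   # both / age_only: shared low-freq
      shared <- band_limited_noise(nt, 1L, scene$tr_s)
      M[rvox, ] <- sqrt(lat) * matrix(shared, k, nt, byrow = TRUE) +
        sqrt(1 - lat) * M[rvox, ]
    }
  }
  volume_series(array(M, d), scene$mask, tr_s = scene$tr_s,
                voxel_mm = scene$voxel_mm)
}

#' Ground-truth region label map
#'
#' @param scene A [scene_spec()].
#' @return 3-D integer array: 0 background, `i` for the i-th effect region.
#' @export
truth_labels <- function(scene) {
  lab <- array(0L, scene$grid_shape)
  for (i in seq_along(scene$effect_regions))
    lab[scene$effect_regions[[i]]$region] <- i
  lab
}

#' Write a cohort to disk
#'
#' Writes one 4-D NIfTI per subject (grid geometry and TR in the header), the
#' cohort table as TSV, the mask and the ground-truth region labels as NIfTI.
#'
#' @param cohort A [sample_cohort()] data frame.
#' @param volumes List of [volume_series()], one per cohort row.
#' @param out_dir Output directory.
#' @param scene The [scene_spec()] used (for mask and truth labels).
#' @param overwrite Refuse to overwrite an existing directory unless TRUE.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, volumes, out_dir, scene, overwrite = FALSE) {
  if (length(volumes) != nrow(cohort))
    stop("one volume per cohort row required")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (i in seq_len(nrow(cohort))) {
    f <- file.path(out_dir, paste0(cohort$id[i], "_bold.nii.gz"))
    write_volume(volumes[[i]], f)
    paths[[cohort$id[i]]] <- f
  }
  tsv <- file.path(out_dir, "cohort.tsv")
  utils::write.table(cohort, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  mask_f <- file.path(out_dir, "mask.nii.gz")
  write_volume(array(as.numeric(scene$mask), scene$grid_shape), mask_f)
  lab_f <- file.path(out_dir, "truth_labels.nii.gz")
  write_volume(array(as.numeric(truth_labels(scene)), scene$grid_shape), lab_f)
  invisible(c(paths, list(cohort = tsv, mask = mask_f, truth = lab_f)))
}
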