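#' Maximum-r conjunction of two correlation maps
#'
#' Minimum-statistic conjunction adapted to negative correlations: at each
#' voxel the conjunction value is the maximum of the two raw (unthresholded)
#' r values, i.e. the weaker negative evidence. A voxel can only pass a
#' negative threshold if both parents pass it. Undefined where either parent
#' is undefined.
#'
#' @param map1,map2 Two `corr_map`s on the same grid, mask, subject count and
#'   covariate set.
#' @return A `corr_map` of kind `"conjunction_r"`.
#' @export
conjunction_max_r <- function(map1, map2) {
  stopifnot(inherits(map1, "corr_map"), inherits(map2, "corr_map"))
  if (!identical(dim(map1$values), dim(map2$values)) ||
      !identical(map1$mask, map2$mask))
    stop("conjunction parents must share grid and mask")
  if (!identical(map1$n_subjects, map2$n_subjects) ||
      !identical(map1$n_covariates, map2$n_covariates) ||
      !identical(map1$df, map2$df))
    stop("conjunction parents must share subjects, covariates and df")
  v <- pmax(map1$values, map2$values)   # NA wherever either parent is NA
  out <- brain_map(v, map1$mask, map1$affine, kind = "conjunction_r",
                   voxel_mm = map1$voxel_mm)
  out$analysis <- paste(map1$analysis, map2$analysis, sep = "&")
  out$n_subjects <- map1$n_subjects
  out$n_covariates <- map1$n_covariates
  out$df <- map1$df
  class(out) <- c("corr_map", class(out))
  out
}

#' Threshold a conjunction map with cluster-extent correction
#'
#' Applies the negative voxel threshold `-r_crit` and the Monte-Carlo minimum
#' cluster extent to a max-r conjunction map, and reports the surviving
#' clusters. Survivors are necessarily a subset of the intersection of the
#' parents' survivors at the same thresholds.
#'
#' @param conj A conjunction `corr_map` from [conjunction_max_r()].
#' @param r_crit Voxel-level critical |r|.
#' @param mc An `mc_threshold` from [alphasim_kmin()] computed on the same
#'   mask and FWHM.
#' @return List with `map` and `table` as in [apply_threshold()].
#' @export
conjunction_inference <- function(conj, r_crit, mc) {
  stopifnot(inherits(conj, "corr_map"), identical(conj$kind, "conjunction_r"),
            inherits(mc, "mc_threshold"))
  apply_threshold(conj, r_crit, mc$k_min, sign = "negative",
                  connectivity = mc$connectivity)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: cohort and scene
#' parameters, preprocessing (smoothing FWHM, band edges), statistical levels
#' (voxel alpha, corrected alpha), connectivity, Monte-Carlo size and seeds.
#'
#' @param n_subjects Cohort size.
#' @param cohort A [cohort_config()].
#' @param scene A [scene_spec()].
#' @param fwhm_mm Spatial smoothing FWHM in mm.
#' @param band_low_hz,band_high_hz Temporal band-pass edges in Hz.
#' @param bands [spectral_bands()] for fALFF.
#' @param voxel_alpha Voxel-level alpha for both the critical r and the
#'   Monte-Carlo null.
#' @param corrected_alpha Cluster-level (family-wise) alpha.
#' @param tails 1 or 2 for the critical r.
#' @param connectivity Cluster connectivity rule (6/18/26).
#' @param n_iterations Monte-Carlo iterations for [alphasim_kmin()].
#' @param standardize Divide maps by their within-mask mean before
#'   correlation.
#' @param reho_on_smoothed If TRUE (default) regional homogeneity is computed
#'   on smoothed, band-passed data (smooth, filter, then ReHo/fALFF); if
#'   FALSE, ReHo is computed on unsmoothed band-passed data and the map is
#'   smoothed afterwards — the common alternative that avoids inflating
#'   neighbourhood concordance.
#' @param seed Master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 40L, cohort = cohort_config(),
                            scene = scene_spec(), fwhm_mm = 6,
                            band_low_hz = 0.01, band_high_hz = 0.08,
                            bands = spectral_bands(), voxel_alpha = 0.005,
                            corrected_alpha = 0.05, tails = 2,
                            connectivity = 26L, n_iterations = 1000L,
                            standardize = TRUE, reho_on_smoothed = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# per-subject maps: smooth -> band-pass -> ReHo; fALFF on smoothed,
# detrended, unfiltered data
subject_maps <- function(vol, config) {
  sm <- smooth_volume(vol, config$fwhm_mm)
  if (config$reho_on_smoothed) {
    reho <- reho_map(bandpass(sm, config$band_low_hz, config$band_high_hz))
  } else {
    raw <- reho_map(bandpass(vol, config$band_low_hz, config$band_high_hz))
    sig <- config$fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_mm
    v <- raw$values
    v[is.na(v)] <- 0
    reho <- brain_map(smooth_array(v, sig), raw$mask, raw$affine,
                      kind = "reho", voxel_mm = raw$voxel_mm)
  }
  falff <- falff_map(detrend(sm), config$bands)
  if (config$standardize) {
    reho <- standardize_map(reho)
    falff <- standardize_map(falff)
  }
  list(reho = reho, falff = falff)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort generation (task simulation included), volume
#' synthesis, preprocessing, regional homogeneity and fALFF maps, voxelwise
#' full and age-partialled correlation with SSRT, the Monte-Carlo cluster
#' extent, cluster-corrected tables for the four parent analyses, and the two
#' max-r conjunctions (full and age-partialled, each re-thresholded with the
#' Monte-Carlo extent). Subjects are processed one at a time so only the maps
#' stay in memory.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: maps as NIfTI, cluster tables as
#'   TSV, plus a JSON run log with every seed and threshold.
#' @param mc Optional precomputed `mc_threshold` (same mask/FWHM); if `NULL`
#'   it is computed with a seed derived from the master seed.
#' @param cohort Optional precomputed cohort data frame (must match
#'   `config$n_subjects`).
#' @return A list: `cohort`, `maps` (the six correlation/conjunction maps),
#'   `mc`, `r_crit` (full and partial), `tables` (six cluster tables),
#'   `thresholded` (the six cluster-corrected survivor maps), `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, mc = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  scene <- config$scene
  if (is.null(cohort))
    cohort <- stage("cohort", sample_cohort(config$n_subjects, config$cohort,
                                            seed = config$seed))
  if (nrow(cohort) != config$n_subjects)
    stop("pipeline stage 'cohort': cohort size does not match config")

  reho_maps <- vector("list", nrow(cohort))
  falff_maps <- vector("list", nrow(cohort))
  stage("maps", for (i in seq_len(nrow(cohort))) {
    vol <- generate_subject_volume(cohort[i, ], scene,
                                   seed = cohort$volume_seed[i])
    m <- subject_maps(vol, config)
    reho_maps[[i]] <- m$reho
    falff_maps[[i]] <- m$falff
  })

  ssrt <- cohort$ssrt_ms
  age <- cohort$age_years
  n <- nrow(cohort)
  maps <- stage("correlate", list(
    reho_full = voxelwise_correlation(reho_maps, ssrt, kind = "reho_ssrt"),
    reho_partial = voxelwise_partial_correlation(reho_maps, ssrt, age,
                                                 kind = "reho_ssrt"),
    falff_full = voxelwise_correlation(falff_maps, ssrt, kind = "falff_ssrt"),
    falff_partial = voxelwise_partial_correlation(falff_maps, ssrt, age,
                                                  kind = "falff_ssrt")
  ))
  r_crit <- list(full = critical_r(config$voxel_alpha, n - 2, config$tails),
                 partial = critical_r(config$voxel_alpha, n - 3, config$tails))

  if (is.null(mc)) {
    mc_seed <- config$seed + 104729L   # derived, distinct from cohort seed
    mc <- stage("alphasim", alphasim_kmin(
      scene$mask, config$fwhm_mm, config$voxel_alpha, config$corrected_alpha,
      config$connectivity, config$n_iterations, seed = mc_seed,
      voxel_mm = scene$voxel_mm))
  }

  thr <- stage("threshold", list(
    reho_full = apply_threshold(maps$reho_full, r_crit$full, mc$k_min,
                                "negative", config$connectivity),
    reho_partial = apply_threshold(maps$reho_partial, r_crit$partial,
                                   mc$k_min, "negative", config$connectivity),
    falff_full = apply_threshold(maps$falff_full, r_crit$full, mc$k_min,
                                 "negative", config$connectivity),
    falff_partial = apply_threshold(maps$falff_partial, r_crit$partial,
                                    mc$k_min, "negative", config$connectivity)
  ))
  conj <- stage("conjunction", list(
    full = conjunction_max_r(maps$reho_full, maps$falff_full),
    partial = conjunction_max_r(maps$reho_partial, maps$falff_partial)
  ))
  conj_thr <- stage("conjunction", list(
    full = conjunction_inference(conj$full, r_crit$full, mc),
    partial = conjunction_inference(conj$partial, r_crit$partial, mc)
  ))

  maps$conjunction_full <- conj$full
  maps$conjunction_partial <- conj$partial
  tables <- list(
    reho_ssrt_full = thr$reho_full$table,
    reho_ssrt_partial = thr$reho_partial$table,
    falff_ssrt_full = thr$falff_full$table,
    falff_ssrt_partial = thr$falff_partial$table,
    conjunction_full = conj_thr$full$table,
    conjunction_partial = conj_thr$partial$table
  )
  log <- list(
    package_version = as.character(utils::packageVersion("restingstop")),
    n_subjects = n, df_full = n - 2L, df_partial = n - 3L,
    voxel_alpha = config$voxel_alpha, corrected_alpha = config$corrected_alpha,
    tails = config$tails, r_crit_full = r_crit$full,
    r_crit_partial = r_crit$partial, fwhm_mm = config$fwhm_mm,
    band_hz = c(config$band_low_hz, config$band_high_hz),
    connectivity = config$connectivity, k_min = mc$k_min,
    mc_iterations = mc$n_iterations, mc_seed = mc$seed,
    master_seed = config$seed, standardize = config$standardize,
    reho_on_smoothed = config$reho_on_smoothed,
    conjunction_extent = "recomputed on the same mask/FWHM (same Monte-Carlo null)",
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  thresholded <- list(
    reho_ssrt_full = thr$reho_full$map,
    reho_ssrt_partial = thr$reho_partial$map,
    falff_ssrt_full = thr$falff_full$map,
    falff_ssrt_partial = thr$falff_partial$map,
    conjunction_full = conj_thr$full$map,
    conjunction_partial = conj_thr$partial$map
  )
  bundle <- list(cohort = cohort, maps = maps, mc = mc, r_crit = r_crit,
                 tables = tables, thresholded = thresholded, log = log)
  if (!is.null(out_dir)) write_bundle(bundle, thr, conj_thr, out_dir)
  bundle
}

# write maps, tables and the run log of a pipeline bundle
write_bundle <- function(bundle, thr, conj_thr, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$tables)) {
    utils::write.table(bundle$tables[[nm]],
                       file.path(out_dir, paste0(nm, "_clusters.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(bundle$maps))
    write_volume(bundle$maps[[nm]], file.path(out_dir, paste0(nm, "_rmap.nii.gz")))
  for (nm in names(thr))
    write_volume(thr[[nm]]$map,
                 file.path(out_dir, paste0(nm, "_thresholded.nii.gz")))
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
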