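#' Label connected components of a binary map
#'
#' Maximal connected components of a 3-D binary array under a 6- (faces), 18-
#' (faces + edges) or 26-neighbour (faces + edges + corners) rule. Labels are
#' dense from 1 in scan order of first encounter.
#'
#' @param binary_map 3-D logical (or 0/1 numeric) array.
#' @param connectivity 6, 18 or 26 (default 26, the convention for
#'   cluster-extent correction of correlation maps).
#' @return List with `labels` (3-D integer array, 0 = background) and `sizes`
#'   (voxel count of cluster `i` at position `i`).
#' @export
label_clusters <- function(binary_map, connectivity = 26L) {
  stopifnot(is.array(binary_map), length(dim(binary_map)) == 3L)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  bin <- array(as.logical(binary_map), dim(binary_map))
  bin[is.na(bin)] <- FALSE
  res <- .label_clusters_cpp(as.logical(bin), as.integer(dim(bin)),
                             connectivity)
  list(labels = array(res$labels, dim(bin)), sizes = res$sizes)
}

#' Monte-Carlo minimum cluster extent (AlphaSim-style)
#'
#' Estimates the smallest cluster size `k_min` such that, under a smooth
#' Gaussian null field, the probability of observing any supra-threshold
#' cluster of at least `k_min` voxels is at most `corrected_alpha`. Each
#' iteration draws white Gaussian noise on the in-mask voxels, smooths the
#' field with the analysis FWHM, standardizes within the mask, applies a
#' two-tailed voxel threshold at `voxel_alpha`, labels the supra-threshold
#' voxels, and records the maximum cluster size. `k_min` is the smallest `k`
#' whose exceedance fraction over iterations does not exceed
#' `corrected_alpha`; if even the full mask size fails (e.g. `voxel_alpha =
#' 1`), `k_min` is `NA` with `attainable = FALSE`.
#'
#' @param mask 3-D logical array.
#' @param fwhm_mm Smoothing FWHM of the null field in mm.
#' @param voxel_alpha Two-tailed voxel-level threshold probability.
#' @param corrected_alpha Desired family-wise (cluster-level) alpha.
#' @param connectivity Cluster connectivity rule (6/18/26).
#' @param n_iterations Monte-Carlo iterations (>= 100).
#' @param seed Integer seed.
#' @param voxel_mm Voxel size in mm (converts `fwhm_mm` to voxels).
#' @return An `mc_threshold` list: `k_min`, `attainable`, `voxel_alpha`,
#'   `corrected_alpha`, `n_iterations`, `fwhm_mm`, `connectivity`,
#'   `max_cluster_null` (length `n_iterations`), `seed`.
#' @export
alphasim_kmin <- function(mask, fwhm_mm = 6, voxel_alpha = 0.005,
                          corrected_alpha = 0.05, connectivity = 26L,
                          n_iterations = 1000L, seed = 1L, voxel_mm = 2) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim(mask))
  if (n_iterations < 100L) stop("need n_iterations >= 100")
  if (!(voxel_alpha > 0 && voxel_alpha <= 1)) stop("voxel_alpha must be in (0, 1]")
  vox <- which(mask)
  nmask <- length(vox)
  if (nmask < 1L) stop("empty mask")
  zthr <- stats::qnorm(1 - voxel_alpha / 2)
  sigma_vox <- if (fwhm_mm > 0) fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm else 0
  set.seed(seed)
  max_sizes <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    field <- array(0, dim(mask))
    field[vox] <- stats::rnorm(nmask)
    if (sigma_vox > 0) field <- smooth_array(field, sigma_vox)
    v <- field[vox]
    z <- (v - mean(v)) / stats::sd(v)
    bin <- array(FALSE, dim(mask))
    bin[vox] <- abs(z) > zthr
    if (!any(bin)) { max_sizes[it] <- 0L; next }
    max_sizes[it] <- max(label_clusters(bin, connectivity)$sizes)
  }
  k_min <- NA_integer_
  attainable <- FALSE
  for (k in seq_len(max(max_sizes) + 1L)) {
    if (mean(max_sizes >= k) <= corrected_alpha) {
      k_min <- k
      attainable <- TRUE
      break
    }
  }
  if (attainable && k_min > nmask) { k_min <- NA_integer_; attainable <- FALSE }
  structure(list(k_min = k_min, attainable = attainable,
                 voxel_alpha = voxel_alpha, corrected_alpha = corrected_alpha,
                 n_iterations = n_iterations, fwhm_mm = fwhm_mm,
                 connectivity = connectivity, max_cluster_null = max_sizes,
                 seed = seed),
            class = "mc_threshold")
}

#' @export
print.mc_threshold <- function(x, ...) {
  cat(sprintf("<mc_threshold> k_min = %s (voxel alpha %g, corrected alpha %g, fwhm %g mm, %d iterations, %d-connectivity)\n",
              if (x$attainable) x$k_min else "unattainable",
              x$voxel_alpha, x$corrected_alpha, x$fwhm_mm, x$n_iterations,
              x$connectivity))
  invisible(x)
}

#' Apply voxel and cluster-extent thresholds to a correlation map
#'
#' Keeps voxels whose r exceeds `r_crit` in the requested direction
#' (`"negative"`: r <= -r_crit; `"positive"`: r >= r_crit; `"both"`: |r| >=
#' r_crit), removes clusters smaller than `k_min`, and summarizes the
#' survivors: one row per cluster with its size, the peak (most extreme r)
#' voxel converted to world mm via the affine, and the peak r, sorted by size
#' descending.
#'
#' @param corr_map A `corr_map` or any `brain_map` holding r values.
#' @param r_crit Voxel-level critical |r|.
#' @param k_min Minimum cluster extent in voxels (from [alphasim_kmin()]).
#' @param sign `"negative"`, `"positive"` or `"both"`.
#' @param connectivity Cluster connectivity rule.
#' @return List with `map` (a `brain_map`, NA outside surviving clusters) and
#'   `table` (data frame: `cluster_id`, `size_voxels`, `peak_x_mm`,
#'   `peak_y_mm`, `peak_z_mm`, `peak_r`).
#' @export
apply_threshold <- function(corr_map, r_crit, k_min, sign = "negative",
                            connectivity = 26L) {
  stopifnot(inherits(corr_map, "brain_map"))
  sign <- match.arg(sign, c("negative", "positive", "both"))
  if (is.na(k_min)) k_min <- Inf  # unattainable extent: nothing survives
  v <- corr_map$values
  supra <- switch(sign,
                  negative = !is.na(v) & v <= -r_crit,
                  positive = !is.na(v) & v >= r_crit,
                  both = !is.na(v) & abs(v) >= r_crit)
  lab <- label_clusters(supra, connectivity)
  keep_ids <- which(lab$sizes >= k_min)
  rows <- lapply(keep_ids, function(id) {
    idx <- which(lab$labels == id)
    peak <- idx[which.max(abs(v[idx]))]
    ijk <- arrayInd(peak, dim(v))
    xyz <- voxel_to_world(ijk, corr_map$affine)
    data.frame(cluster_id = id, size_voxels = lab$sizes[id],
               peak_x_mm = xyz[1], peak_y_mm = xyz[2], peak_z_mm = xyz[3],
               peak_r = v[peak])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), size_voxels = integer(),
               peak_x_mm = numeric(), peak_y_mm = numeric(),
               peak_z_mm = numeric(), peak_r = numeric())
  tab <- tab[order(-tab$size_voxels), , drop = FALSE]
  rownames(tab) <- NULL
  out_vals <- array(NA_real_, dim(v))
  keep_vox <- lab$labels %in% keep_ids & lab$labels > 0L
  out_vals[keep_vox] <- v[keep_vox]
  out_map <- brain_map(out_vals, corr_map$mask, corr_map$affine,
                       kind = if (identical(corr_map$kind, "conjunction_r"))
                         "conjunction_r" else "r",
                       voxel_mm = corr_map$voxel_mm)
  list(map = out_map, table = tab)
}
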