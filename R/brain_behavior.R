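#' Stack per-subject maps into a voxel-by-subject matrix
#'
#' @param map_stack List of `brain_map`s sharing grid and mask.
#' @return List with the matrix `X` (in-mask voxels x subjects), the common
#'   mask, affine, voxel indices, and voxel size.
#' @keywords internal
stack_maps <- function(map_stack) {
  stopifnot(is.list(map_stack), length(map_stack) >= 1L)
  m1 <- map_stack[[1]]
  for (m in map_stack) {
    stopifnot(inherits(m, "brain_map"))
    if (!identical(dim(m$values), dim(m1$values)) ||
        !identical(m$mask, m1$mask))
      stop("all maps must share grid and mask")
  }
  vox <- which(m1$mask)
  X <- vapply(map_stack, function(m) m$values[vox],
              numeric(length(vox)))
  X <- matrix(X, nrow = length(vox))   # guard the single-voxel case
  list(X = X, mask = m1$mask, affine = m1$affine, vox = vox,
       voxel_mm = m1$voxel_mm)
}

# rowwise Pearson correlation of X (voxels x subjects) with a score vector
row_cor <- function(X, y) {
  n <- length(y)
  Xc <- X - rowMeans(X)
  sx <- sqrt(rowSums(Xc^2))
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  r <- as.vector(Xc %*% yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' Voxelwise Pearson correlation with a behavioral score
#'
#' Correlates, at each in-mask voxel, the across-subject vector of map values
#' with a per-subject score (e.g. SSRT in ms). Voxels with zero variance
#' across subjects are undefined.
#'
#' @param map_stack List of per-subject `brain_map`s on a common grid.
#' @param scores Numeric vector, one score per subject, in the same order.
#' @param kind Label for the resulting map, e.g. `"reho_ssrt"`.
#' @return A `corr_map`: a `brain_map` of kind `"r"` carrying `n_subjects`,
#'   `n_covariates = 0` and `df = n - 2`.
#' @export
voxelwise_correlation <- function(map_stack, scores, kind = "r") {
  s <- stack_maps(map_stack)
  n <- length(scores)
  if (ncol(s$X) != n) stop("number of maps and scores must match")
  if (n < 3L) stop("need at least 3 subjects")
  if (anyNA(scores)) stop("scores must not contain missing values")
  if (max(scores) == min(scores)) stop("scores are constant")
  r <- row_cor(s$X, scores)
  vals <- array(NA_real_, dim(s$mask))
  vals[s$vox] <- r
  out <- brain_map(vals, s$mask, s$affine, kind = "r", voxel_mm = s$voxel_mm)
  out$analysis <- kind
  out$n_subjects <- n
  out$n_covariates <- 0L
  out$df <- n - 2L
  class(out) <- c("corr_map", class(out))
  out
}

#' Voxelwise partial correlation controlling for one covariate
#'
#' First-order partial correlation of map values with the score, controlling
#' for a covariate such as age:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with `df = n - 3`. Voxels collinear with the covariate (`|r_xz| = 1`) are
#' undefined.
#'
#' @param map_stack List of per-subject `brain_map`s on a common grid.
#' @param scores Per-subject score vector.
#' @param covariate Per-subject covariate vector (non-constant).
#' @param kind Label for the resulting map.
#' @return A `corr_map` with `n_covariates = 1` and `df = n - 3`.
#' @export
voxelwise_partial_correlation <- function(map_stack, scores, covariate,
                                          kind = "r") {
  s <- stack_maps(map_stack)
  n <- length(scores)
  if (ncol(s$X) != n || length(covariate) != n)
    stop("number of maps, scores and covariate values must match")
  if (n < 4L) stop("need at least 4 subjects for a partial correlation")
  if (anyNA(scores) || anyNA(covariate)) stop("missing values not allowed")
  if (max(covariate) == min(covariate)) stop("covariate is constant")
  r_yz <- stats::cor(scores, covariate)
  if (abs(r_yz) >= 1) stop("scores and covariate are collinear")
  r_xy <- row_cor(s$X, scores)
  r_xz <- row_cor(s$X, covariate)
  denom <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- (r_xy - r_xz * r_yz) / denom
  bad <- !is.na(r_xz) & abs(r_xz) >= 1 - 1e-12
  r[bad] <- NA_real_
  if (any(bad))
    warning(sum(bad), " voxel(s) collinear with the covariate are undefined")
  vals <- array(NA_real_, dim(s$mask))
  vals[s$vox] <- pmin(pmax(r, -1), 1)
  out <- brain_map(vals, s$mask, s$affine, kind = "r", voxel_mm = s$voxel_mm)
  out$analysis <- kind
  out$n_subjects <- n
  out$n_covariates <- 1L
  out$df <- n - 3L
  class(out) <- c("corr_map", class(out))
  out
}

#' Critical correlation threshold
#'
#' The smallest |r| significant at level `alpha` with `df` degrees of freedom,
#' via the t transform: `r_crit = t / sqrt(t^2 + df)` with `t` the upper-tail
#' Student quantile at `alpha` (halved for two-tailed tests). With alpha =
#' 0.005 and df = 70 (72 subjects, full correlation) the two-tailed value is
#' about 0.327.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (n - 2 for a full correlation, n - 3 with one
#'   covariate).
#' @param tails 1 or 2.
#' @return The critical r in (0, 1).
#' @export
critical_r <- function(alpha = 0.005, df = 70, tails = 2) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  t_crit <- stats::qt(1 - alpha / tails, df)
  t_crit / sqrt(t_crit^2 + df)
}
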