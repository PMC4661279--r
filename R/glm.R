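#' Convert a time series to percent signal change
#'
#' `100 * (y - mean) / mean`, computed per run and per voxel. Accepts a
#' vector (one voxel, one run) or a matrix with voxels in rows and volumes
#' in columns.
#'
#' @param ts Numeric vector or voxels-by-volumes matrix of raw intensities.
#' @return Same shape as the input, in percent signal change units.
#' @export
to_percent_signal_change <- function(ts) {
  if (is.matrix(ts)) {
    m <- rowMeans(ts)
    if (any(m <= 0)) stopf("non-positive run mean; cannot convert to PSC")
    100 * (ts - m) / m
  } else {
    m <- mean(ts)
    if (m <= 0) stopf("non-positive run mean; cannot convert to PSC")
    100 * (ts - m) / m
  }
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares of each voxel's percent-signal-change time course
#' on a first-level design matrix. With `ar1 = TRUE` the residual lag-1
#' autocorrelation is estimated per voxel, pooled (median across voxels),
#' and a single Cochrane-Orcutt prewhitening pass with the pooled coefficient
#' is applied within runs before refitting.
#'
#' @param Y Numeric vector (one voxel) or volumes-by-voxels matrix, in PSC.
#' @param design An `ambicon_design`.
#' @param ar1 Apply one Cochrane-Orcutt prewhitening pass.
#' @return Object of class `ambicon_glm`: list with `pe`
#'   (regressors-by-voxels matrix of parameter estimates), `resid_var`,
#'   `ar1_rho` (pooled estimate, 0 if `ar1 = FALSE`), `df_residual`, and the
#'   design column names.
#' @export
fit_glm <- function(Y, design, ar1 = FALSE) {
  if (!inherits(design, "ambicon_design")) stopf("design must be an ambicon_design")
  X <- design$X
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(X)) stopf("time series length (%d) does not match design (%d rows)",
                                nrow(Y), nrow(X))
  if (design$rank_deficient) stopf("design matrix is rank deficient")
  qx <- qr(X)
  B <- qr.coef(qx, Y)
  rho <- 0
  if (ar1) {
    E <- Y - X %*% B
    # lag-1 within runs, pooled over voxels
    keep <- design$run[-1] == design$run[-length(design$run)]
    E1 <- E[-1, , drop = FALSE][keep, , drop = FALSE]
    E0 <- E[-nrow(E), , drop = FALSE][keep, , drop = FALSE]
    num <- colSums(E0 * E1)
    den <- colSums(E0 * E0)
    rho <- median(num / pmax(den, .Machine$double.eps))
    rho <- max(min(rho, 0.99), -0.99)
    W <- prewhiten_rows(design$run, rho)
    Xw <- W$scale_first(X, design$run, rho)
    Yw <- W$scale_first(Y, design$run, rho)
    qx <- qr(Xw)
    B <- qr.coef(qx, Yw)
    X <- Xw
    Y <- Yw
  }
  E <- Y - X %*% B
  dfres <- nrow(X) - ncol(X)
  structure(list(pe = B, resid_var = colSums(E^2) / dfres, ar1_rho = rho,
                 df_residual = dfres, regressors = colnames(design$X)),
            class = "ambicon_glm")
}

# quasi-differencing y_t - rho*y_{t-1} within runs; first volume of each run
# scaled by sqrt(1 - rho^2)
prewhiten_rows <- function(run, rho) {
  list(scale_first = function(M, run, rho) {
    out <- M
    first <- !duplicated(run)
    out[!first, ] <- M[!first, , drop = FALSE] -
      rho * M[which(!first) - 1L, , drop = FALSE]
    out[first, ] <- sqrt(1 - rho^2) * M[first, , drop = FALSE]
    out
  })
}

#' Group random-effects t map
#'
#' Voxelwise one-sample t test of per-subject parameter estimates against
#' zero (subjects are the random unit).
#'
#' @param pes Subjects-by-voxels matrix of parameter estimates for one
#'   regressor.
#' @return List of class `ambicon_map`: `stat` (t values), `p` (two-sided),
#'   `df`, `n`, `type = "t"`. Zero-variance voxels get `NA` and are flagged
#'   in `undefined`.
#' @export
group_ttest_map <- function(pes) {
  n <- nrow(pes)
  if (n < 3L) stopf("need at least 3 subjects")
  m <- colMeans(pes)
  s <- sqrt(colSums((pes - rep(m, each = n))^2) / (n - 1))
  undefined <- s == 0
  tval <- m / (s / sqrt(n))
  tval[undefined] <- NA_real_
  p <- 2 * pt(-abs(tval), df = n - 1)
  structure(list(stat = tval, p = p, df = n - 1L, n = n, type = "t",
                 undefined = undefined),
            class = "ambicon_map")
}

#' Brain-behaviour correlation map
#'
#' Voxelwise Pearson correlation between per-subject parameter estimates and
#' a behavioural attitude (use `ln gamma_A` for ambiguity attitudes, raw
#' `gamma_C` for conflict).
#'
#' @param pes Subjects-by-voxels matrix of parameter estimates.
#' @param attitudes Per-subject scalar attitude.
#' @return List of class `ambicon_map`: `stat` (r values), `p` (two-sided),
#'   `df`, `n`, `type = "r"`, `undefined` for constant-PE voxels.
#' @export
brain_behavior_map <- function(pes, attitudes) {
  n <- nrow(pes)
  if (n < 4L) stopf("need at least 4 subjects")
  if (length(attitudes) != n) stopf("attitudes must have one value per subject")
  if (sd(attitudes) == 0) stopf("zero-variance attitude")
  zc <- scale(pes)
  undefined <- !is.finite(zc[1, ]) | apply(pes, 2, sd) == 0
  za <- as.vector(scale(attitudes))
  r <- as.vector(crossprod(zc, za)) / (n - 1)
  r[undefined] <- NA_real_
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  structure(list(stat = r, p = p, df = n - 2L, n = n, type = "r",
                 undefined = undefined),
            class = "ambicon_map")
}

#' Paired contrast map between two regressors
#'
#' Voxelwise paired t test of the difference `pes_a - pes_b` across subjects
#' (e.g. conflict-level minus ambiguity-level parameter estimates).
#'
#' @param pes_a,pes_b Subjects-by-voxels matrices over the same subjects.
#' @return `ambicon_map` of paired t values for `a - b`.
#' @export
contrast_map <- function(pes_a, pes_b) {
  if (!all(dim(pes_a) == dim(pes_b))) stopf("PE matrices must match")
  group_ttest_map(pes_a - pes_b)
}

#' Minimum-statistic conjunction mask
#'
#' Voxels at which both maps are individually significant at `alpha` with
#' the same sign.
#'
#' @param map_a,map_b `ambicon_map` objects on the same grid.
#' @param alpha Per-map significance level.
#' @return Logical mask vector.
#' @export
conjunction_map <- function(map_a, map_b, alpha = 0.05) {
  if (length(map_a$stat) != length(map_b$stat)) stopf("maps must be aligned")
  ok <- !is.na(map_a$stat) & !is.na(map_b$stat)
  ok & map_a$p < alpha & map_b$p < alpha &
    sign(map_a$stat) == sign(map_b$stat)
}
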