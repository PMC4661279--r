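#' @importFrom stats setNames var
NULL

#' Flag outliers by distance from the mean
#'
#' Single-pass rule: a value is flagged when it lies more than `k` sample
#' standard deviations from the sample mean, both computed over the full
#' vector including the candidate point (no iteration, no leave-one-out).
#' A zero-dispersion vector yields no flags.
#'
#' @param values Numeric vector, length at least 3.
#' @param k Threshold in standard-deviation multiples (default 3).
#' @return Logical exclusion mask, `TRUE` for flagged values.
#' @export
flag_outliers <- function(values, k = 3) {
  if (length(values) < 3L) stopf("need at least 3 values")
  if (anyNA(values)) stopf("values must not contain NA")
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > k * s
}

#' Cohen's d from a one-sample or paired t statistic
#'
#' The reporting convention `d = t / sqrt(n)`, i.e. the standardised mean
#' (difference) implied by the t statistic and sample size.
#'
#' @param t t statistic.
#' @param n Sample size (pairs for a paired test).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

test_result <- function(ht, n) {
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, d = cohens_d_from_t(unname(ht$statistic), n),
                 n = n, mean = unname(ht$estimate), se = unname(ht$stderr)),
            class = "ambicon_test")
}

#' @export
print.ambicon_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$d, x$n))
  invisible(x)
}

#' One-sample t test with Cohen's d
#'
#' Two-sided one-sample t test of `values` against `mu0`, reporting
#' `d = t/sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2, positive dispersion.
#' @param mu0 Null mean.
#' @return Object of class `ambicon_test`: list with `t`, `df`, `p`, `d`,
#'   `n`, `mean`, `se`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L) stopf("need at least 2 values")
  if (sd(values) == 0) stopf("zero standard deviation: degenerate input")
  test_result(t.test(values, mu = mu0), length(values))
}

#' Paired t test with Cohen's d
#'
#' One-sample t test on the paired differences `a - b`; `d = t/sqrt(n)` with
#' `n` the number of pairs.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Object of class `ambicon_test`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  one_sample_t(a - b, 0)
}

#' Pearson correlation with two-sided p value
#'
#' @param a,b Numeric vectors of equal length, n >= 3, both with positive
#'   dispersion.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors must have equal length")
  if (length(a) < 3L) stopf("need at least 3 pairs")
  if (sd(a) == 0 || sd(b) == 0) stopf("zero variance input")
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Group-level attitude summary
#'
#' Applies the 3-SD outlier rule to the model-free ambiguity and conflict
#' attitudes, drops flagged subjects from all analyses, and reports:
#' one-sample tests of RA, AA and CA against 0; tests of the
#' probability-weighting attitudes against neutrality (`ln gamma_A` vs 0 —
#' ambiguity attitudes are log-normally distributed, so the ambiguity test is
#' run on the log scale — and raw `gamma_C` vs 1); and pairwise Pearson
#' correlations among RA, AA, CA, `ln gamma_A` and `gamma_C`.
#'
#' @param subjects Data frame with one row per subject and columns `ra`,
#'   `aa`, `ca`, `gamma_a`, `gamma_c` (extra columns are ignored).
#' @param k Outlier threshold in SD multiples.
#' @return List: `tests` (data frame: test, n, mean, se, t, df, p, d),
#'   `correlations` (r matrix), `correlation_p` (p matrix), `excluded`
#'   (row indices of excluded subjects), `n` (subjects analysed).
#' @export
attitude_summary <- function(subjects, k = 3) {
  need <- c("ra", "aa", "ca", "gamma_a", "gamma_c")
  if (!all(need %in% names(subjects)))
    stopf("subjects need columns %s", paste(need, collapse = ", "))
  if (nrow(subjects) < 3L) stopf("need at least 3 subjects")
  excl <- flag_outliers(subjects$aa, k) | flag_outliers(subjects$ca, k)
  kept <- subjects[!excl, , drop = FALSE]
  if (nrow(kept) < 3L) stopf("fewer than 3 subjects remain after exclusion")

  vars <- list(RA = list(x = kept$ra, mu = 0),
               AA = list(x = kept$aa, mu = 0),
               CA = list(x = kept$ca, mu = 0),
               ln_gamma_a = list(x = log(kept$gamma_a), mu = 0),
               gamma_c = list(x = kept$gamma_c, mu = 1))
  tests <- do.call(rbind, lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    tt <- one_sample_t(v$x, v$mu)
    data.frame(test = nm, n = tt$n, mean = tt$mean, se = tt$se,
               t = tt$t, df = tt$df, p = tt$p, d = tt$d,
               stringsAsFactors = FALSE)
  }))

  mat <- cbind(ra = kept$ra, aa = kept$aa, ca = kept$ca,
               ln_gamma_a = log(kept$gamma_a), gamma_c = kept$gamma_c)
  r <- cor(mat)
  pmat <- matrix(NA_real_, ncol(mat), ncol(mat),
                 dimnames = dimnames(r))
  for (i in seq_len(ncol(mat) - 1)) for (j in (i + 1):ncol(mat)) {
    pr <- pearson_r(mat[, i], mat[, j])
    pmat[i, j] <- pmat[j, i] <- pr$p
  }
  list(tests = tests, correlations = r, correlation_p = pmat,
       excluded = which(excl), n = nrow(kept))
}
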