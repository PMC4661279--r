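#' Double-gamma haemodynamic response function
#'
#' Canonical two-gamma HRF: a gamma-density peak minus a scaled gamma-density
#' undershoot, normalised to unit peak. With the default unit scales the peak
#' sits at `(peak_shape - 1)` seconds (5 s) and the undershoot bottoms out
#' near `(under_shape - 1)` seconds (15 s). Other conventions (e.g. a 5 s
#' time-to-peak with different dispersions) are reachable through the shape /
#' scale arguments.
#'
#' @param t Time grid in seconds, non-negative and increasing.
#' @param peak_shape,peak_scale Gamma shape/scale of the positive lobe.
#' @param under_shape,under_scale Gamma shape/scale of the undershoot.
#' @param under_ratio Undershoot amplitude relative to the peak lobe.
#' @return Amplitude at each `t`, max 1.
#' @export
double_gamma_hrf <- function(t, peak_shape = 6, peak_scale = 1,
                             under_shape = 16, under_scale = 1,
                             under_ratio = 1 / 6) {
  if (any(t < 0)) stopf("t must be non-negative")
  if (is.unsorted(t)) stopf("t must be increasing")
  if (any(c(peak_shape, peak_scale, under_shape, under_scale) <= 0) ||
      peak_shape <= 1 || under_shape <= 1)
    stopf("gamma shapes must exceed 1 and scales be positive")
  h <- dgamma(t, shape = peak_shape, scale = peak_scale) -
    under_ratio * dgamma(t, shape = under_shape, scale = under_scale)
  h / max(h)
}

# convolve a stimulus function sampled at dt with the HRF, returning the
# same-length leading segment (causal convolution), scaled by dt so boxcar
# responses are on the HRF amplitude scale
convolve_hrf <- function(stim, hrf_kernel, dt) {
  n <- length(stim)
  out <- convolve(stim, rev(hrf_kernel), type = "open")[seq_len(n)]
  out * dt
}

# events of one run for one regressor -> stimulus vector on the dt grid
boxcar <- function(onsets, durations, amplitudes, n_hires, dt) {
  s <- numeric(n_hires)
  for (i in seq_along(onsets)) {
    from <- floor(onsets[i] / dt) + 1L
    to <- min(n_hires, ceiling((onsets[i] + durations[i]) / dt))
    if (from <= n_hires) s[from:to] <- s[from:to] + amplitudes[i]
  }
  s
}

new_design <- function(X, tr, run, task_cols) {
  structure(list(X = X, tr = tr, run = run, task_cols = task_cols,
                 rank_deficient = qr(X)$rank < ncol(X)),
            class = "ambicon_design")
}

#' @export
print.ambicon_design <- function(x, ...) {
  cat(sprintf("ambicon design: %d volumes x %d regressors (TR %.2f s)%s\n",
              nrow(x$X), ncol(x$X), x$tr,
              if (x$rank_deficient) " [RANK DEFICIENT]" else ""))
  cat("columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

build_design_core <- function(session, events, n_vols, tr, hrf_fun, dt,
                              parametric, par_names) {
  n_runs <- session$n_runs
  hrf_t <- seq(0, 32, by = dt)
  kern <- hrf_fun(hrf_t)
  conds <- intersect(ALL_CONDITIONS, unique(events$condition))
  run_blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ev <- events[events$run == r, , drop = FALSE]
    n_hires <- ceiling(n_vols * tr / dt)
    cols <- list()
    for (cond in conds) {
      e <- ev[ev$condition == cond, , drop = FALSE]
      dummy <- boxcar(e$onset, rep(6.5, nrow(e)), rep(1, nrow(e)), n_hires, dt)
      cols[[cond]] <- convolve_hrf(dummy, kern, dt)
      for (pn in names(parametric)) {
        vals <- parametric[[pn]](e)
        mod <- boxcar(e$onset, rep(6.5, nrow(e)), vals - mean(vals), n_hires, dt)
        cols[[paste0(cond, par_names[pn])]] <- convolve_hrf(mod, kern, dt)
      }
    }
    if ("rt_ms" %in% names(ev)) {
      resp <- ev[!is.na(ev$rt_ms), , drop = FALSE]
      rt_s <- resp$rt_ms / 1000
      imp <- numeric(n_hires)
      idx <- pmin(n_hires, floor(resp$onset / dt) + 1L)
      imp[idx] <- imp[idx] + (rt_s - mean(rt_s)) / dt
      cols[["RT"]] <- convolve_hrf(imp, kern, dt)
    }
    sample_idx <- floor((seq_len(n_vols) - 1) * tr / dt) + 1L
    M <- vapply(cols, function(cl) cl[sample_idx], numeric(n_vols))
    # exact per-run mean-centering of parametric and RT columns; the per-run
    # intercept absorbs the dummy means
    par_cols <- setdiff(colnames(M), conds)
    M[, par_cols] <- scale(M[, par_cols, drop = FALSE], center = TRUE, scale = FALSE)
    run_blocks[[r]] <- M
  }
  X <- do.call(rbind, run_blocks)
  run <- rep(seq_len(n_runs), each = n_vols)
  task_cols <- colnames(X)
  for (r in seq_len(n_runs)) X <- cbind(X, as.numeric(run == r))
  colnames(X) <- c(task_cols, paste0("run", seq_len(n_runs)))
  new_design(X, tr, run, task_cols)
}

#' First-level design matrix of the main model
#'
#' Per run: one convolved boxcar dummy per condition present; one parametric
#' regressor per condition carrying the trial uncertainty level (mean-centred
#' within the run before convolution, and re-centred exactly after
#' sampling); and one response-time regressor (onset impulses with amplitude
#' equal to the trial RT in seconds, mean-centred per run, convolved). A
#' per-run intercept column closes the model. With the four default
#' conditions this yields 9 task regressors plus intercepts.
#'
#' @param session A [build_session()] schedule.
#' @param choices Trial records carrying `run`, `onset`, `condition`,
#'   `level` and `rt_ms` (e.g. [simulate_choices()] output).
#' @param n_vols Volumes per run (defaults to the session's).
#' @param tr Repetition time in seconds (defaults to the session's).
#' @param hrf_fun HRF evaluated on a seconds grid; default
#'   [double_gamma_hrf()].
#' @param dt Oversampling resolution in seconds for convolution.
#' @return Object of class `ambicon_design` (fields `X`, `tr`, `run`,
#'   `task_cols`, `rank_deficient`). Level columns are named
#'   `<condition>_level`.
#' @export
build_design_matrix <- function(session, choices, n_vols = session$volumes_per_run,
                                tr = session$tr, hrf_fun = double_gamma_hrf,
                                dt = 0.1) {
  build_design_core(session, choices, n_vols, tr, hrf_fun, dt,
                    parametric = list(level = function(e) e$level),
                    par_names = c(level = "_level"))
}

#' Subjective-value confound design matrix
#'
#' Alternative first-level model: one dummy per condition plus one parametric
#' regressor per condition carrying the subjective value of the chosen option
#' ([subjective_value()] under the subject's fitted parameters), mean-centred
#' per run — 8 regressors plus intercepts for the default four conditions.
#' A subject who always took the sure gain yields constant value modulators,
#' which centre to zero; the design is then flagged rank-deficient.
#'
#' @inheritParams build_design_matrix
#' @param params Fitted subject parameters (list with `theta`, `gamma_a`,
#'   `gamma_c`, `gamma_i`).
#' @return Object of class `ambicon_design`; value columns are named
#'   `<condition>_sv`.
#' @export
build_sv_design_matrix <- function(session, choices, params,
                                   n_vols = session$volumes_per_run,
                                   tr = session$tr, hrf_fun = double_gamma_hrf,
                                   dt = 0.1) {
  choices <- choices[!is.na(choices$choice), , drop = FALSE]
  sv <- vapply(seq_len(nrow(choices)), function(i) {
    g <- list(condition = choices$condition[i], level = choices$level[i])
    subjective_value(g, choices$choice[i], params)
  }, numeric(1))
  choices$sv <- sv
  choices$rt_ms <- NULL  # the confound model has no RT regressor
  build_design_core(session, choices, n_vols, tr, hrf_fun, dt,
                    parametric = list(sv = function(e) e$sv),
                    par_names = c(sv = "_sv"))
}
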