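#' Negative log-likelihood of a choice sequence
#'
#' Sum over trials of minus the log softmax probability of the chosen option
#' under the multinomial logit model ([choice_probabilities()]). Trials with
#' a missing choice (no recorded response) are dropped. Probabilities are
#' floored at `1e-300` so the value stays finite (optimiser-safe) even for
#' degenerate parameter values.
#'
#' @param params Subject parameters (list with `theta`, `gamma_a`, `gamma_c`,
#'   `gamma_i`).
#' @param choices Data frame of trial records with columns `condition`,
#'   `level`, `choice` (or a `gamble_id` column resolved through `gambles`).
#' @param gambles Optional gamble table ([generate_gamble_set()]) used to
#'   look up `condition`/`level` from `gamble_id`.
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(params, choices, gambles = NULL) {
  choices <- resolve_choices(choices, gambles)
  choices <- choices[!is.na(choices$choice), , drop = FALSE]
  if (nrow(choices) == 0L) stopf("no responded trials in choices")
  pm <- choice_prob_matrix(choices$condition, choices$level, params)
  idx <- match(choices$choice, CHOICE_OPTIONS)
  if (anyNA(idx)) stopf("unknown choice label")
  p <- pm[cbind(seq_len(nrow(pm)), idx)]
  -sum(log(pmax(p, 1e-300)))
}

resolve_choices <- function(choices, gambles = NULL) {
  if (!is.null(gambles) && (!"level" %in% names(choices) || !"condition" %in% names(choices))) {
    m <- match(choices$gamble_id, gambles$gamble_id)
    if (anyNA(m)) stopf("choices reference unknown gamble ids")
    choices$condition <- gambles$condition[m]
    choices$level <- gambles$level[m]
  }
  if (!all(c("condition", "level", "choice") %in% names(choices)))
    stopf("choices need columns condition, level, choice")
  choices
}

#' Fit options for per-subject maximum likelihood
#'
#' @param theta_bounds,gamma_bounds Box bounds on the natural scale;
#'   optimisation runs on log parameters.
#' @param n_starts Number of seeded multi-starts (first start is the neutral
#'   point `theta = gamma = 1`).
#' @param seed Seed for the start jitter.
#' @return List of options for [fit_subject()].
#' @export
fit_options <- function(theta_bounds = c(0.05, 5),
                        gamma_bounds = c(0.05, 10),
                        n_starts = 5L, seed = 1L) {
  list(theta_bounds = theta_bounds, gamma_bounds = gamma_bounds,
       n_starts = as.integer(n_starts), seed = as.integer(seed))
}

param_vector_to_list <- function(par, free) {
  full <- c(theta = 1, gamma_a = 1, gamma_c = 1, gamma_i = 1)
  full[free] <- exp(par)
  as.list(full)
}

#' Per-subject maximum-likelihood estimation
#'
#' Maximises the trial-level likelihood over `(ln theta, ln gamma_A,
#' ln gamma_C, ln gamma_I)` with box bounds, using L-BFGS-B from multiple
#' seeded starts. Probability-weighting parameters are only estimated for
#' conditions present in the data; a subject who never gambles is flagged
#' unidentifiable and returned at the neutral defaults.
#'
#' @inheritParams negative_log_likelihood
#' @param options Output of [fit_options()].
#' @return Object of class `ambicon_fit`: list with `params` (fitted subject
#'   parameters), `nll`, `converged`, `at_bound` (named logical), `n_trials`,
#'   `identifiable`.
#' @export
fit_subject <- function(choices, gambles = NULL, options = fit_options()) {
  choices <- resolve_choices(choices, gambles)
  choices <- choices[!is.na(choices$choice), , drop = FALSE]
  n_trials <- nrow(choices)
  free <- c("theta",
            c(ambiguity = "gamma_a", conflict = "gamma_c",
              ignorance = "gamma_i")[intersect(UNCERTAIN_CONDITIONS,
                                               unique(choices$condition))])
  free <- unname(free[!is.na(free)])

  if (all(choices$choice == "sure")) {
    params <- param_vector_to_list(numeric(0), character(0))
    return(structure(list(params = params,
                          nll = negative_log_likelihood(params, choices),
                          converged = FALSE,
                          at_bound = setNames(rep(TRUE, length(free)), free),
                          n_trials = n_trials, identifiable = FALSE),
                     class = "ambicon_fit"))
  }

  lb <- log(c(theta = options$theta_bounds[1], gamma_a = options$gamma_bounds[1],
              gamma_c = options$gamma_bounds[1], gamma_i = options$gamma_bounds[1]))[free]
  ub <- log(c(theta = options$theta_bounds[2], gamma_a = options$gamma_bounds[2],
              gamma_c = options$gamma_bounds[2], gamma_i = options$gamma_bounds[2]))[free]
  obj <- function(par) negative_log_likelihood(param_vector_to_list(par, free), choices)

  starts <- with_seed(options$seed, {
    s <- matrix(0, options$n_starts, length(free))
    if (options$n_starts > 1)
      s[-1, ] <- matrix(rnorm((options$n_starts - 1) * length(free), 0, 0.7),
                        options$n_starts - 1, length(free))
    s
  })
  starts <- pmin(pmax(starts, matrix(lb, nrow(starts), length(free), byrow = TRUE)),
                 matrix(ub, nrow(starts), length(free), byrow = TRUE))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("all optimisation starts failed")

  at_bound <- setNames(abs(best$par - lb) < 1e-6 | abs(best$par - ub) < 1e-6, free)
  structure(list(params = param_vector_to_list(best$par, free),
                 nll = best$value,
                 converged = best$convergence == 0,
                 at_bound = at_bound,
                 n_trials = n_trials,
                 identifiable = TRUE),
            class = "ambicon_fit")
}

#' @export
print.ambicon_fit <- function(x, ...) {
  cat(sprintf("ambicon fit (%d trials): nll = %.3f%s\n", x$n_trials, x$nll,
              if (x$identifiable) "" else " [unidentifiable]"))
  print(round(unlist(x$params), 4))
  invisible(x)
}

#' Exhaustive grid search oracle
#'
#' Evaluates the negative log-likelihood at every point of a finite parameter
#' grid and returns the argmin; ties are broken by the lexicographically
#' smallest parameter vector. Intended as an independent brute-force check on
#' [fit_subject()].
#'
#' @inheritParams negative_log_likelihood
#' @param grid Named list of candidate values per parameter (subset of
#'   `theta`, `gamma_a`, `gamma_c`, `gamma_i`; omitted parameters are held
#'   at 1).
#' @return List: `params` at the grid optimum, `nll`, and the full `table` of
#'   grid evaluations.
#' @export
grid_oracle <- function(choices, gambles = NULL, grid) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) stopf("empty grid")
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  nll <- vapply(seq_len(nrow(tab)), function(i) {
    negative_log_likelihood(as.list(tab[i, , drop = FALSE]), choices, gambles)
  }, numeric(1))
  ord <- do.call(order, c(list(nll), as.list(tab)))
  best <- ord[1]
  list(params = as.list(tab[best, , drop = FALSE]),
       nll = nll[best],
       table = cbind(tab, nll = nll))
}
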