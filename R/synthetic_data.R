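# lognormal parameters from an arithmetic mean and SD
lognormal_from_mean_sd <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Population specification for synthetic cohorts
#'
#' Defaults emulate the study cohort: 32 subjects, half male, age 25.2 +/-
#' 5.6 years. Probability-weighting attitudes are log-normal with arithmetic
#' mean 0.85 (ambiguity) and 1.69 (conflict); their SDs are the printed
#' standard errors scaled to n = 30 (0.20 * sqrt(30) and 0.16 * sqrt(30)).
#' The utility exponent theta and the ignorance weight are unit-median
#' log-normals with log-SD 0.3 (between-subject spread unreported; a free
#' modelling choice documented in the methods vignette). Response times are
#' log-normal in milliseconds with condition offsets making risk faster than
#' ambiguity and conflict, and a per-subject-by-condition jitter.
#'
#' @param n_subjects Cohort size.
#' @param prop_male Proportion male (exact count, not sampled).
#' @param age_mean,age_sd Age distribution in years.
#' @param theta_median,theta_sdlog Utility exponent log-normal.
#' @param gamma_a_mean,gamma_a_sd Ambiguity attitude arithmetic mean / SD.
#' @param gamma_c_mean,gamma_c_sd Conflict attitude arithmetic mean / SD.
#' @param gamma_i_median,gamma_i_sdlog Ignorance attitude log-normal.
#' @param rt_base_meanlog Baseline log response time (log ms).
#' @param rt_offsets Named per-condition additive offsets on the log scale.
#' @param rt_subject_sdlog SD of the subject-by-condition log RT jitter.
#' @param rt_trial_sdlog Trial-level log RT noise.
#' @param rt_max_ms Response window ceiling in ms.
#' @return List of class `ambicon_population_spec`.
#' @export
population_spec <- function(n_subjects = 32L,
                            prop_male = 0.5,
                            age_mean = 25.2, age_sd = 5.6,
                            theta_median = 1, theta_sdlog = 0.3,
                            gamma_a_mean = 0.85, gamma_a_sd = 0.20 * sqrt(30),
                            gamma_c_mean = 1.69, gamma_c_sd = 0.16 * sqrt(30),
                            gamma_i_median = 1, gamma_i_sdlog = 0.3,
                            rt_base_meanlog = log(1600),
                            rt_offsets = c(risk = 0, ambiguity = 0.07,
                                           conflict = 0.10, ignorance = 0.08),
                            rt_subject_sdlog = 0.085,
                            rt_trial_sdlog = 0.25,
                            rt_max_ms = 6400) {
  if (n_subjects < 2L) stopf("n_subjects must be at least 2")
  if (any(c(age_sd, theta_sdlog, gamma_a_sd, gamma_c_sd, gamma_i_sdlog,
            rt_subject_sdlog, rt_trial_sdlog) <= 0))
    stopf("scale parameters must be positive")
  if (any(c(gamma_a_mean, gamma_c_mean, theta_median, gamma_i_median) <= 0))
    stopf("location parameters must be positive")
  structure(as.list(environment()), class = "ambicon_population_spec")
}

#' Sample a synthetic cohort with known ground truth
#'
#' Draws per-subject demographics, generative model parameters and
#' subject-by-condition response-time shifts from a [population_spec()].
#' Reproducible given the seed.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return Data frame with one row per subject: `subject_id`, `sex`, `age`,
#'   `theta`, `gamma_a`, `gamma_c`, `gamma_i`, `ln_gamma_a`, and RT shift
#'   columns `rt_shift_<condition>`.
#' @export
sample_population <- function(spec = population_spec(), seed = 1L) {
  if (!inherits(spec, "ambicon_population_spec")) stopf("spec must be a population_spec()")
  n <- spec$n_subjects
  with_seed(seed, {
    n_male <- round(n * spec$prop_male)
    sex <- c(rep("M", n_male), rep("F", n - n_male))
    age <- round(pmax(18, rnorm(n, spec$age_mean, spec$age_sd)), 1)
    ga <- lognormal_from_mean_sd(spec$gamma_a_mean, spec$gamma_a_sd)
    gc <- lognormal_from_mean_sd(spec$gamma_c_mean, spec$gamma_c_sd)
    cohort <- data.frame(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      sex = sex,
      age = age,
      theta = rlnorm(n, log(spec$theta_median), spec$theta_sdlog),
      gamma_a = rlnorm(n, ga$meanlog, ga$sdlog),
      gamma_c = rlnorm(n, gc$meanlog, gc$sdlog),
      gamma_i = rlnorm(n, log(spec$gamma_i_median), spec$gamma_i_sdlog),
      stringsAsFactors = FALSE
    )
    cohort$ln_gamma_a <- log(cohort$gamma_a)
    for (cond in names(spec$rt_offsets))
      cohort[[paste0("rt_shift_", cond)]] <- rnorm(n, 0, spec$rt_subject_sdlog)
    attr(cohort, "spec") <- spec
    attr(cohort, "seed") <- seed
    cohort
  })
}

#' Simulate one subject's choices and response times
#'
#' Choices on gamble trials are drawn from the multinomial logit model
#' ([choice_probabilities()]) under the subject's generative parameters.
#' Response times are log-normal with per-condition offsets (risk faster
#' than ambiguity and conflict in expectation) plus the subject's
#' condition-specific shift, truncated at the response window.
#'
#' @param subject One cohort row ([sample_population()]), or any list with
#'   `theta`, `gamma_a`, `gamma_c`, `gamma_i` (RT shifts default to 0).
#' @param session A [build_session()] schedule.
#' @param seed Integer seed.
#' @param spec A [population_spec()] providing the RT distribution (defaults
#'   to the cohort spec attached to `subject`, else `population_spec()`).
#' @return Data frame of trial records: `subject_id`, `run`, `trial`,
#'   `onset`, `condition`, `level`, `gamble_id`, `choice`, `rt_ms`.
#' @export
simulate_choices <- function(subject, session, seed = 1L, spec = NULL) {
  spec <- spec %||% attr(subject, "spec") %||% population_spec()
  trials <- session$trials[session$trials$trial_type != "fixation", , drop = FALSE]
  params <- as_subject_parameters(subject)
  pm <- choice_prob_matrix(trials$trial_type, trials$level, params,
                           sure_gain = trials$sure_gain[1],
                           win_payoff = trials$win_payoff[1])
  with_seed(seed, {
    k <- nrow(trials)
    u <- runif(k)
    cum <- pm %*% upper.tri(diag(4), diag = TRUE)
    choice_idx <- rowSums(u > cbind(0, cum[, -4])) # in 1..4
    shift <- vapply(trials$trial_type, function(cond) {
      s <- subject[[paste0("rt_shift_", cond)]]
      if (is.null(s) || is.na(s)) 0 else s
    }, numeric(1))
    mu <- spec$rt_base_meanlog + unname(spec$rt_offsets[trials$trial_type]) + shift
    rt <- pmin(exp(rnorm(k, mu, spec$rt_trial_sdlog)), spec$rt_max_ms)
    data.frame(
      subject_id = subject$subject_id %||% "sub-01",
      run = trials$run,
      trial = trials$position,
      onset = trials$onset,
      condition = trials$trial_type,
      level = trials$level,
      gamble_id = trials$gamble_id,
      choice = CHOICE_OPTIONS[choice_idx],
      rt_ms = round(rt),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate choices for an arbitrary trial list
#'
#' Session-free generative sampler: draws one choice per row of `trials`
#' from the multinomial logit model under `params`. Useful for scaling the
#' number of trials per condition beyond one scanner session (e.g.
#' consistency and bias studies).
#'
#' @param params Subject parameters (list with `theta`, `gamma_a`,
#'   `gamma_c`, `gamma_i`).
#' @param trials Data frame with columns `condition` and `level`.
#' @param seed Integer seed.
#' @return `trials` with a `choice` column appended.
#' @export
simulate_trials <- function(params, trials, seed = 1L) {
  pm <- choice_prob_matrix(trials$condition, trials$level, params)
  with_seed(seed, {
    u <- runif(nrow(trials))
    cum <- pm %*% upper.tri(diag(4), diag = TRUE)
    trials$choice <- CHOICE_OPTIONS[rowSums(u > cbind(0, cum[, -4])) ]
    trials
  })
}

#' Simulate an entire cohort's choices
#'
#' Convenience wrapper calling [simulate_choices()] per subject with derived
#' seeds; sessions are rebuilt per subject (seeded) so trial orders differ
#' across subjects as in the scanner task.
#'
#' @param cohort Output of [sample_population()].
#' @param gambles Gamble table ([generate_gamble_set()]).
#' @param seed Integer master seed.
#' @param ... Passed to [build_session()] (e.g. `n_runs`, `volumes_per_run`).
#' @return List with `sessions` (per subject) and `choices` (per subject).
#' @export
simulate_cohort_choices <- function(cohort, gambles, seed = 1L, ...) {
  sessions <- lapply(seq_len(nrow(cohort)), function(i)
    build_session(gambles, seed = child_seed(seed, i), ...))
  choices <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, , drop = FALSE]
    attr(subj, "spec") <- attr(cohort, "spec")
    simulate_choices(subj, sessions[[i]], seed = child_seed(seed, 100000 + i))
  })
  names(sessions) <- names(choices) <- cohort$subject_id
  list(sessions = sessions, choices = choices)
}

#' Fit every subject of a simulated cohort
#'
#' @param choices_list List of per-subject choice data frames.
#' @param options [fit_options()].
#' @return Data frame of fitted parameters (one row per subject) with
#'   columns `theta`, `gamma_a`, `gamma_c`, `gamma_i`, `nll`, `converged`.
#' @export
fit_cohort <- function(choices_list, options = fit_options()) {
  rows <- lapply(seq_along(choices_list), function(i) {
    f <- fit_subject(choices_list[[i]], options = options)
    data.frame(subject_id = choices_list[[i]]$subject_id[1],
               theta = f$params$theta, gamma_a = f$params$gamma_a,
               gamma_c = f$params$gamma_c, gamma_i = f$params$gamma_i,
               nll = f$nll, converged = f$converged,
               identifiable = f$identifiable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
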