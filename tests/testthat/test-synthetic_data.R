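test_that("cohort sampling reproduces the population structure", {
  cohort <- sample_population(seed = 5)
  expect_equal(nrow(cohort), 32L)
  expect_equal(sum(cohort$sex == "M"), 16L)
  expect_true(all(cohort$theta > 0 & cohort$gamma_a > 0 & cohort$gamma_c > 0))
  expect_equal(cohort$ln_gamma_a, log(cohort$gamma_a))
  expect_identical(cohort, sample_population(seed = 5))
  expect_false(identical(cohort$gamma_c, sample_population(seed = 6)$gamma_c))
})

test_that("large-sample attitude means match the specified moments", {
  big <- sample_population(population_spec(n_subjects = 10000), seed = 8)
  se_c <- 0.16 * sqrt(30) / sqrt(10000)
  expect_lt(abs(mean(big$gamma_c) - 1.69), 3 * se_c)
  se_a <- 0.20 * sqrt(30) / sqrt(10000)
  expect_lt(abs(mean(big$gamma_a) - 0.85), 4 * se_a)
  expect_lt(abs(mean(big$age) - 25.2), 0.5)
})

test_that("simulated choices follow the generative logit model", {
  g <- generate_gamble_set()
  s <- build_session(g, seed = 2, n_runs = 2, volumes_per_run = 120)
  cohort <- sample_population(population_spec(n_subjects = 2), seed = 3)
  subj <- cohort[1, , drop = FALSE]
  ch1 <- simulate_choices(subj, s, seed = 10)
  expect_identical(ch1, simulate_choices(subj, s, seed = 10))
  expect_equal(nrow(ch1), 64L)   # 4 conditions x 8 trials x 2 runs
  expect_true(all(ch1$rt_ms > 0 & ch1$rt_ms <= 6400))

  # extreme conflict aversion: essentially no conflict bets
  averse <- list(subject_id = "x", theta = 1, gamma_a = 1, gamma_c = 10, gamma_i = 1)
  ch2 <- simulate_choices(averse, s, seed = 11)
  bets_c <- sum(ch2$condition == "conflict" & ch2$choice %in% c("type2", "type3"))
  expect_lte(bets_c, 1L)
})

test_that("neutral weighting equalises expected bet rates across conditions", {
  # Monte-Carlo against matched probabilities: many trials per condition
  trials <- trial_grid(reps = 60)    # 1800 per condition
  ch <- simulate_trials(neutral_params(), trials, seed = 4)
  bet <- ch$choice %in% c("type2", "type3")
  rates <- tapply(bet, ch$condition, mean)
  expect_lt(diff(range(rates)), 0.035)
})

test_that("response times are slower under uncertainty than risk", {
  g <- generate_gamble_set()
  cohort <- sample_population(population_spec(n_subjects = 16), seed = 6)
  sim <- simulate_cohort_choices(cohort, g, seed = 7, n_runs = 2,
                                 volumes_per_run = 120)
  mean_rt <- function(cond) vapply(sim$choices, function(ch)
    mean(ch$rt_ms[ch$condition == cond]), numeric(1))
  d_conf <- paired_t(mean_rt("risk"), mean_rt("conflict"))$d
  d_amb <- paired_t(mean_rt("risk"), mean_rt("ambiguity"))$d
  expect_lt(d_conf, 0)
  expect_lt(d_amb, 0)
})

test_that("the BOLD generator honours its noise and reproducibility contract", {
  ds <- small_planted_dataset(seed = 9, n_subjects = 4,
                              planted = default_planted_effects(c(12, 12, 12))[0, ])
  ds2 <- small_planted_dataset(seed = 9, n_subjects = 4,
                               planted = default_planted_effects(c(12, 12, 12))[0, ])
  expect_identical(ds$subjects[[1]]$runs[[1]], ds2$subjects[[1]]$runs[[1]])

  # noise-only voxels: lag-1 autocorrelation of the PSC residual field
  run <- to_percent_signal_change(ds$subjects[[1]]$runs[[1]])
  run <- run - rowMeans(run)
  ac1 <- mean(vapply(sample(nrow(run), 200), function(v) {
    x <- run[v, ]
    cor(x[-1], x[-length(x)])
  }, numeric(1)))
  expect_lt(abs(ac1 - ds$noise$ar1), 0.05)
})

test_that("planted regions must lie inside the grid", {
  pl <- default_planted_effects(c(12, 12, 12))
  pl$x[1] <- 40
  cohort <- sample_population(population_spec(n_subjects = 2), seed = 1)
  g <- generate_gamble_set()
  sim <- simulate_cohort_choices(cohort, g, seed = 2, n_runs = 2,
                                 volumes_per_run = 80, trials_per_type = 5)
  expect_error(simulate_bold(cohort, sim$sessions, sim$choices, planted = pl,
                             grid_dim = c(12, 12, 12)),
               "outside the grid")
})

test_that("attitude-coupled amplitudes realise their target correlation", {
  ds <- small_planted_dataset(seed = 12, n_subjects = 16)
  pl <- ds$planted
  for (i in which(!is.na(pl$couple_to))) {
    r_obs <- cor(ds$amplitudes[, pl$name[i]], ds$cohort[[pl$couple_to[i]]])
    expect_equal(r_obs, pl$couple_r[i], tolerance = 1e-10)
  }
})

test_that("end-to-end recovery improves with trials per condition", {
  cohort <- sample_population(population_spec(n_subjects = 12), seed = 14)
  fit_at <- function(reps) {
    est <- t(vapply(seq_len(nrow(cohort)), function(i) {
      tr <- simulate_trials(as.list(cohort[i, c("theta", "gamma_a", "gamma_c", "gamma_i")]),
                            trial_grid(reps = reps), seed = 500 + i)
      f <- fit_subject(tr, options = fit_options(n_starts = 2))
      c(a = log(f$params$gamma_a), c = log(f$params$gamma_c))
    }, numeric(2)))
    est
  }
  e1 <- fit_at(1)    # 120 trials
  e4 <- fit_at(4)    # 480 trials
  rmse <- function(est) sqrt(mean((est[, "a"] - cohort$ln_gamma_a)^2 +
                                    (est[, "c"] - log(cohort$gamma_c))^2))
  expect_lt(rmse(e4), rmse(e1))
  expect_gt(cor(e4[, "a"], cohort$ln_gamma_a), cor(e1[, "a"], cohort$ln_gamma_a) - 0.05)
})
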