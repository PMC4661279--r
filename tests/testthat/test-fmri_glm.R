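test_that("the double-gamma HRF has the canonical shape", {
  t <- seq(0, 32, 0.01)
  h <- double_gamma_hrf(t)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_equal(t[which.max(h)], 5, tolerance = 0.05)   # mode (shape-1)*scale
  expect_lt(min(h), 0)                                  # undershoot exists
  expect_equal(t[which.min(h)], 15, tolerance = 1)      # near second mode
  expect_error(double_gamma_hrf(c(1, 0.5)), "increasing")
  expect_error(double_gamma_hrf(t, peak_shape = 0.5), "exceed 1")
})

test_that("the main design matrix has the contracted structure", {
  g <- generate_gamble_set()
  s <- build_session(g, seed = 3, n_runs = 2, volumes_per_run = 120)
  cohort <- sample_population(population_spec(n_subjects = 2), seed = 4)
  ch <- simulate_choices(cohort[1, , drop = FALSE], s, seed = 5)
  X <- build_design_matrix(s, ch)
  expect_equal(length(X$task_cols), 9L)     # 4 dummies + 4 levels + RT
  expect_equal(ncol(X$X), 11L)              # + 2 run intercepts
  expect_false(X$rank_deficient)
  # dummies are convolved nonnegative boxcars: positive response lobe,
  # bounded undershoot
  for (cn in c("risk", "ambiguity", "conflict", "ignorance")) {
    expect_gt(max(X$X[, cn]), 0.5)
    expect_gt(min(X$X[, cn]), -1)
  }
  # parametric and RT columns centred exactly within each run
  for (cn in c("risk_level", "ambiguity_level", "conflict_level",
               "ignorance_level", "RT"))
    expect_equal(as.vector(tapply(X$X[, cn], X$run, sum)), c(0, 0), tolerance = 1e-9)
  # reproducible bit-exactly
  expect_identical(X$X, build_design_matrix(s, ch)$X)
})

test_that("convolved columns match a brute-force convolution oracle", {
  # two-trial toy run, dummy regressor only
  s <- structure(list(trials = data.frame(run = 1L, position = 1:2,
                                          onset = c(10, 40), duration = 6.5,
                                          trial_type = "risk", level = c(20, 80),
                                          gamble_id = c("r_20", "r_80"),
                                          sure_gain = 3, win_payoff = 10),
                      n_runs = 1L, tr = 2.5, volumes_per_run = 40L),
                 class = "ambicon_session")
  ch <- data.frame(run = 1L, onset = c(10, 40), condition = "risk",
                   level = c(20, 80), rt_ms = c(1500, 2000))
  X <- build_design_matrix(s, ch, dt = 0.1)
  # oracle: explicit discrete convolution on the fine grid
  dt <- 0.1
  fine <- seq(0, 40 * 2.5 - dt, by = dt)
  stim <- as.numeric((fine >= 10 & fine < 16.5) | (fine >= 40 & fine < 46.5))
  hrf <- double_gamma_hrf(seq(0, 32, dt))
  conv <- numeric(length(fine))
  for (i in seq_along(fine)) {
    jmax <- min(i, length(hrf))
    conv[i] <- sum(stim[i - seq_len(jmax) + 1] * hrf[seq_len(jmax)]) * dt
  }
  oracle <- conv[floor((seq_len(40) - 1) * 2.5 / dt) + 1]
  expect_equal(unname(X$X[, "risk"]), oracle, tolerance = 1e-8)
})

test_that("the subjective-value model has 8 regressors with matching values", {
  g <- generate_gamble_set()
  s <- build_session(g, seed = 6, n_runs = 2, volumes_per_run = 120)
  cohort <- sample_population(population_spec(n_subjects = 2), seed = 7)
  ch <- simulate_choices(cohort[1, , drop = FALSE], s, seed = 8)
  pars <- as.list(cohort[1, c("theta", "gamma_a", "gamma_c", "gamma_i")])
  X <- build_sv_design_matrix(s, ch, pars)
  expect_equal(length(X$task_cols), 8L)
  expect_equal(sum(grepl("_sv$", X$task_cols)), 4L)
  for (cn in X$task_cols[grepl("_sv$", X$task_cols)])
    expect_equal(as.vector(tapply(X$X[, cn], X$run, sum)), c(0, 0), tolerance = 1e-9)
  # modulator values are the subjective values of the chosen options:
  # cross-check one condition by rebuilding with hand-computed values
  sv_hand <- vapply(which(ch$condition == "ambiguity"), function(i)
    subjective_value(list(condition = "ambiguity", level = ch$level[i]),
                     ch$choice[i], pars), numeric(1))
  expect_true(sd(sv_hand) > 0)
})

test_that("percent signal change conversion is exact and scale-free", {
  expect_equal(to_percent_signal_change(c(90, 110)), c(-10, 10))
  expect_equal(to_percent_signal_change(rep(5, 10)), rep(0, 10))
  y <- c(95, 100, 105, 102)
  expect_equal(to_percent_signal_change(7 * y), to_percent_signal_change(y))
  m <- rbind(c(90, 110), c(50, 150))
  expect_equal(to_percent_signal_change(m), rbind(c(-10, 10), c(-50, 50)))
  expect_error(to_percent_signal_change(c(-1, 1)), "non-positive")
})

test_that("the GLM matches the normal-equations oracle and recovers noiselessly", {
  g <- generate_gamble_set()
  s <- build_session(g, seed = 9, n_runs = 2, volumes_per_run = 60, trials_per_type = 3)
  cohort <- sample_population(population_spec(n_subjects = 2), seed = 10)
  ch <- simulate_choices(cohort[1, , drop = FALSE], s, seed = 11)
  des <- build_design_matrix(s, ch)
  beta <- seq(-0.5, 0.5, length.out = ncol(des$X))
  y <- des$X %*% beta
  f <- fit_glm(y, des)
  expect_equal(unname(f$pe[, 1]), beta, tolerance = 1e-10)

  set.seed(12)
  Y <- y %*% t(rep(1, 5)) + matrix(rnorm(nrow(des$X) * 5), ncol = 5)
  f2 <- fit_glm(Y, des)
  oracle <- solve(crossprod(des$X)) %*% crossprod(des$X, Y)
  expect_equal(unname(f2$pe), unname(oracle), tolerance = 1e-8)
})

test_that("AR(1) noise leaves the prewhitened estimates unbiased", {
  g <- generate_gamble_set()
  s <- build_session(g, seed = 13, n_runs = 2, volumes_per_run = 60, trials_per_type = 3)
  cohort <- sample_population(population_spec(n_subjects = 2), seed = 14)
  ch <- simulate_choices(cohort[1, , drop = FALSE], s, seed = 15)
  des <- build_design_matrix(s, ch)
  beta <- rep(0.2, ncol(des$X))
  nvox <- 500
  set.seed(16)
  rho <- 0.4
  innov <- matrix(rnorm(nrow(des$X) * nvox), nrow(des$X), nvox)
  E <- innov
  for (t in 2:nrow(E)) E[t, ] <- rho * E[t - 1, ] + innov[t, ]
  Y <- as.vector(des$X %*% beta) + E
  f <- fit_glm(Y, des, ar1 = TRUE)
  expect_lt(abs(f$ar1_rho - rho), 0.12)
  bias <- rowMeans(f$pe) - beta
  expect_lt(max(abs(bias[seq_len(9)])), 0.02)
})

test_that("group maps are calibrated and antisymmetric", {
  set.seed(17)
  pes <- matrix(rnorm(16 * 4000), 16, 4000)
  m <- group_ttest_map(pes)
  expect_lt(abs(mean(m$p < 0.05) - 0.05), 0.015)
  m2 <- group_ttest_map(-pes)
  expect_equal(m2$stat, -m$stat)
  # zero-variance voxels flagged
  pes[, 1] <- 1
  m3 <- group_ttest_map(pes)
  expect_true(m3$undefined[1] && is.na(m3$stat[1]))
})

test_that("brain-behaviour maps detect coupling and pass a permutation control", {
  set.seed(18)
  n <- 24
  att <- rnorm(n)
  pes <- matrix(rnorm(n * 800, sd = 1), n, 800)
  pes[, 1:5] <- pes[, 1:5] * 0.6 + att    # strongly coupled voxels
  m <- brain_behavior_map(pes, att)
  expect_true(all(m$p[1:5] < 0.01))
  expect_lt(abs(mean(m$p[6:800] < 0.05) - 0.05), 0.03)
  perm <- sample(n)
  mp <- brain_behavior_map(pes[perm, ], att)
  expect_gt(mean(mp$p[1:5] > 0.05), 0.5)
  expect_error(brain_behavior_map(pes, rep(1, n)), "zero-variance")
})

test_that("contrast and conjunction maps behave under sign symmetry", {
  set.seed(19)
  a <- matrix(rnorm(10 * 50), 10, 50)
  b <- a + 0.5
  expect_true(all(abs(contrast_map(a, a)$stat) < 1e-12 | is.na(contrast_map(a, a)$stat)))
  cf <- contrast_map(a, b)
  cr <- contrast_map(b, a)
  expect_equal(cf$stat, -cr$stat)

  strong <- group_ttest_map(matrix(rnorm(10 * 50, mean = 2), 10, 50))
  expect_equal(conjunction_map(strong, strong, 0.05), strong$p < 0.05)
  neg <- group_ttest_map(matrix(rnorm(10 * 50, mean = -2), 10, 50))
  expect_false(any(conjunction_map(strong, neg, 0.05)))
})

test_that("Monte-Carlo cluster thresholds are small unsmoothed and grow with smoothing", {
  k0 <- cluster_threshold(c(14, 14, 14), voxel_p = 0.005, n_sims = 100,
                          smooth_sigma = 0, seed = 20)
  expect_lte(as.integer(k0), 3L)
  k1 <- cluster_threshold(c(14, 14, 14), voxel_p = 0.005, n_sims = 100,
                          smooth_sigma = 1.5, seed = 20)
  expect_gte(as.integer(k1), as.integer(k0))
  # held-out calibration: fresh null maps, family-wise rate <= alpha band
  set.seed(21)
  grid_dim <- c(14, 14, 14)
  hits <- vapply(1:100, function(i) {
    e <- matrix(rnorm(prod(grid_dim)), ncol = 1)
    sz <- ambicon:::cluster_sizes(abs(e) > -qnorm(0.0025), grid_dim)
    length(sz) > 0 && max(sz) >= as.integer(k0)
  }, logical(1))
  expect_lte(mean(hits), 0.12)   # 0.05 within binomial slack at 100 sims
})

test_that("cluster labelling agrees with an independent flood-fill oracle", {
  set.seed(22)
  grid_dim <- c(8, 8, 8)
  mask <- runif(prod(grid_dim)) < 0.2
  sizes <- sort(ambicon:::cluster_sizes(mask, grid_dim))
  # oracle: queue-based flood fill over 6-neighbourhoods
  oracle_sizes <- local({
    arr <- array(mask, grid_dim)
    seen <- array(FALSE, grid_dim)
    out <- integer(0)
    for (x in 1:8) for (y in 1:8) for (z in 1:8) {
      if (!arr[x, y, z] || seen[x, y, z]) next
      queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; n <- 0
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]; n <- n + 1
        for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
          w <- v + d
          if (all(w >= 1 & w <= 8) && arr[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
            seen[w[1], w[2], w[3]] <- TRUE
            queue[[length(queue) + 1]] <- w
          }
        }
      }
      out <- c(out, n)
    }
    sort(out)
  })
  expect_equal(sizes, oracle_sizes)
})
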