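# shared small fixtures, built in code

toy_gambles <- function(levels = c(6L, 50L, 94L)) {
  generate_gamble_set(levels = levels, seed = 1)
}

# a risk-only pseudo-session for bet-count checks (only $trials is consulted)
risk_only_session <- function(levels) {
  structure(list(trials = data.frame(run = 1L, position = seq_along(levels),
                                     onset = 0, duration = 6.5,
                                     trial_type = "risk", level = levels,
                                     gamble_id = paste0("r_", levels),
                                     sure_gain = 3, win_payoff = 10),
                 n_runs = 1L, tr = 2.5, volumes_per_run = 200L),
            class = "ambicon_session")
}

neutral_params <- function() list(theta = 1, gamma_a = 1, gamma_c = 1, gamma_i = 1)

# balanced trial list over conditions x levels (for session-free simulation)
trial_grid <- function(levels = default_levels(), reps = 1L,
                       conditions = c("risk", "ambiguity", "conflict", "ignorance")) {
  expand.grid(condition = conditions, level = rep(levels, reps),
              stringsAsFactors = FALSE)
}

# small planted dataset for pipeline tests: 12 subjects, 12^3 grid, 2x80 vols
small_planted_dataset <- function(seed = 5, n_subjects = 12L,
                                  planted = NULL, grid_dim = c(12, 12, 12)) {
  if (is.null(planted)) planted <- default_planted_effects(grid_dim, radius = 2)
  simulate_study(spec = population_spec(n_subjects = n_subjects),
                 n_runs = 2L, volumes_per_run = 80L, grid_dim = grid_dim,
                 planted = planted, seed = seed, trials_per_type = 5L)
}
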