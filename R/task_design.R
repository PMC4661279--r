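#' @importFrom stats rnorm rlnorm runif rmultinom dgamma qt pt sd cor median
#' @importFrom stats t.test cor.test optim rbinom quantile complete.cases
NULL

# Conditions in which the Type 2 / Type 3 composition is uncertain.
UNCERTAIN_CONDITIONS <- c("ambiguity", "conflict", "ignorance")
ALL_CONDITIONS <- c("risk", UNCERTAIN_CONDITIONS)

#' Default uncertainty levels of the gamble set
#'
#' Thirty distinct even levels (total count of Type 2 + Type 3 cards in the
#' 100-card deck) spanning 6 to 94. Twenty levels lie at or below 66 and ten
#' lie strictly above 200/3, so that a risk-neutral decision maker facing the
#' default 32-trial risk session (repeats are drawn from the low-level subset)
#' bets on the uncertain card types exactly ten times.
#'
#' @return Integer vector of 30 even levels in `[6, 94]`.
#' @export
default_levels <- function() {
  c(6L, 8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L, 40L,
    44L, 46L, 50L, 52L, 56L, 58L, 60L, 62L, 64L, 66L,
    68L, 72L, 76L, 78L, 82L, 84L, 88L, 90L, 92L, 94L)
}

validate_levels <- function(levels) {
  if (length(levels) < 1L) stopf("level list is empty")
  if (anyNA(levels) || !is.numeric(levels)) stopf("levels must be numeric and non-missing")
  if (any(levels != round(levels))) stopf("levels must be integers")
  if (any(levels %% 2 != 0)) stopf("levels must be even (equal-split risk decks need level/2 integral)")
  if (any(levels < 6 | levels > 94)) stopf("levels must lie in [6, 94]")
  if (anyDuplicated(levels)) stopf("levels must be distinct")
  invisible(as.integer(levels))
}

# Conflict messages: source A asserts (round(L/3), L - round(L/3)) cards of
# Type 2 / Type 3; source B asserts the swapped pair. The message mean is
# L/2 for both types, so the information-neutral winning probability matches
# the risk and ambiguity conditions.
conflict_messages <- function(level) {
  a2 <- round(level / 3)
  cbind(msg_a_type2 = a2, msg_a_type3 = level - a2,
        msg_b_type2 = level - a2, msg_b_type3 = a2)
}

#' Generate the matched gamble set
#'
#' Builds one gamble per level and condition. Decks always hold 100 cards;
#' the known Type 1 count is `100 - level`. Risk decks split the remaining
#' cards evenly, ambiguity decks reveal only the total, and conflict decks
#' carry two disagreeing messages whose pairwise mean equals the even split.
#' All conditions are therefore matched on expected value at every level.
#'
#' Two seeded repeat levels per condition (drawn from the levels at or below
#' 66) extend the 30 unique gambles to 32 trials per condition.
#'
#' @param levels Integer vector of distinct even levels in `[6, 94]`.
#' @param conditions Conditions to generate. Default: risk, ambiguity,
#'   conflict, ignorance.
#' @param n_repeats Number of repeated gamble selections per condition.
#' @param seed Integer seed controlling the repeat draw.
#' @param sure_gain,win_payoff Payoffs in dollars.
#' @return A data frame of gambles (one row per unique gamble per condition)
#'   with attribute `"repeat_levels"`, a named list of the repeated levels per
#'   condition, and attribute `"trial_levels"`, the full per-condition trial
#'   level vectors (unique levels plus repeats).
#' @export
generate_gamble_set <- function(levels = default_levels(),
                                conditions = ALL_CONDITIONS,
                                n_repeats = 2L,
                                seed = 1L,
                                sure_gain = 3,
                                win_payoff = 10) {
  levels <- validate_levels(levels)
  conditions <- match.arg(conditions, ALL_CONDITIONS, several.ok = TRUE)
  rows <- lapply(conditions, function(cond) {
    msg <- if (cond == "conflict") conflict_messages(levels) else
      matrix(NA_integer_, length(levels), 4,
             dimnames = list(NULL, c("msg_a_type2", "msg_a_type3",
                                     "msg_b_type2", "msg_b_type3")))
    data.frame(
      gamble_id = paste0(substr(cond, 1, 1), "_", levels),
      condition = cond,
      level = levels,
      type1_count = 100L - levels,
      msg,
      sure_gain = sure_gain,
      win_payoff = win_payoff,
      stringsAsFactors = FALSE
    )
  })
  gambles <- do.call(rbind, rows)

  low <- levels[levels <= 66]
  if (length(low) == 0L) low <- levels   # degenerate custom sets
  repeat_levels <- with_seed(seed, {
    out <- lapply(conditions, function(cond)
      if (n_repeats > 0) sample(low, n_repeats, replace = n_repeats > length(low))
      else integer(0))
    names(out) <- conditions
    out
  })
  trial_levels <- lapply(conditions, function(cond)
    c(levels, repeat_levels[[cond]]))
  names(trial_levels) <- conditions

  attr(gambles, "repeat_levels") <- repeat_levels
  attr(gambles, "trial_levels") <- trial_levels
  gambles
}

#' Winning probability of a choice option
#'
#' The sure option pays with certainty. Betting on Type 1 wins with the known
#' probability `(100 - level)/100`. Betting on Type 2 or Type 3 wins with
#' probability `level/200` under the information-neutral convention: the known
#' even split under risk, the midpoint of the `[0, level]` interval under
#' ambiguity, and the mean of the two messages under conflict.
#'
#' @param gamble A single gamble (one row of [generate_gamble_set()] output,
#'   or any list with a `level` element).
#' @param option One of `"sure"`, `"type1"`, `"type2"`, `"type3"`.
#' @return Probability in `[0, 1]`.
#' @export
winning_probability <- function(gamble, option = c("sure", "type1", "type2", "type3")) {
  option <- match.arg(option)
  level <- gamble$level
  if (is.null(level) || length(level) != 1L) stopf("gamble must have a single level")
  switch(option,
         sure  = 1,
         type1 = (100 - level) / 100,
         type2 = level / 200,
         type3 = level / 200)
}

#' Risk-neutral bet count of a session
#'
#' Number of risk trials in which a risk-neutral (expected-value maximising)
#' decision maker bets on the uncertain card types: the lottery on Type 2 or
#' Type 3 must beat both the sure gain and the Type 1 bet, i.e.
#' `win_payoff * level/200` must exceed `sure_gain` and
#' `win_payoff * (100 - level)/100`. With $3 / $10 payoffs this reduces to
#' `level > 200/3`.
#'
#' @param session A session built by [build_session()].
#' @return Integer count.
#' @export
risk_neutral_bet_count <- function(session) {
  trials <- session$trials
  risk <- trials[trials$trial_type == "risk", , drop = FALSE]
  if (nrow(risk) == 0L) stopf("session contains no risk trials")
  ev_bet23 <- risk$win_payoff * risk$level / 200
  ev_bet1 <- risk$win_payoff * (100 - risk$level) / 100
  sum(ev_bet23 > risk$sure_gain & ev_bet23 > ev_bet1)
}

#' Build the pseudorandom session schedule
#'
#' Distributes the per-condition trial lists over `n_runs` runs with exactly
#' eight trials of each of the five trial types (four gamble conditions plus
#' fixation) per run. Every gamble trial occupies 6.5 s followed by 1.0 s of
#' fixation; fixation-only trials occupy 7.5 s. Time left over up to
#' `volumes_per_run * tr` is distributed as seeded inter-trial baseline gaps
#' (multiples of 0.5 s).
#'
#' When `8 * n_runs` is smaller than the number of available trials per
#' condition, a seeded subsample of the trial levels is scheduled (desk-scale
#' sessions); the full 4-run default schedules all 32 trials per condition.
#'
#' @param gambles Output of [generate_gamble_set()].
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @param n_runs Number of runs.
#' @param volumes_per_run EPI volumes acquired per run.
#' @param tr Repetition time in seconds.
#' @param trials_per_type Gamble trials of each condition per run.
#' @return An object of class `ambicon_session`: a list with elements
#'   `trials` (data frame: run, position, onset, duration, trial_type, level,
#'   gamble_id, sure_gain, win_payoff), `n_runs`, `tr`, `volumes_per_run`.
#' @export
build_session <- function(gambles, seed = 1L, n_runs = 4L,
                          volumes_per_run = 200L, tr = 2.5,
                          trials_per_type = 8L) {
  conditions <- unique(gambles$condition)
  trial_levels <- attr(gambles, "trial_levels")
  if (is.null(trial_levels))
    trial_levels <- split(gambles$level, gambles$condition)[conditions]
  needed <- trials_per_type * n_runs
  for (cond in conditions) {
    if (length(trial_levels[[cond]]) < needed)
      stopf("condition %s has %d trials, fewer than the %d needed for %d runs",
            cond, length(trial_levels[[cond]]), needed, n_runs)
  }
  trial_dur <- 6.5
  fix_after <- 1.0
  slot <- trial_dur + fix_after      # 7.5 s per trial slot, fixation trials alike
  n_types <- length(conditions) + 1L # + fixation-only
  run_secs <- volumes_per_run * tr
  per_run_secs <- n_types * trials_per_type * slot
  if (per_run_secs > run_secs)
    stopf("%d trials of %.1f s do not fit in %d x %.2f s volumes",
          n_types * trials_per_type, slot, volumes_per_run, tr)

  with_seed(seed, {
    sel <- lapply(conditions, function(cond) {
      lv <- trial_levels[[cond]]
      if (length(lv) > needed) sort(sample(lv, needed)) else lv
    })
    names(sel) <- conditions
    # per condition, permute trials and deal them 8 per run
    dealt <- lapply(sel, function(lv) {
      perm <- sample(lv)
      split(perm, rep(seq_len(n_runs), each = trials_per_type))
    })
    gap_units_total <- round((run_secs - per_run_secs) / 0.5)
    runs <- lapply(seq_len(n_runs), function(r) {
      types <- sample(rep(c(conditions, "fixation"), each = trials_per_type))
      lev <- integer(length(types)); lev[] <- NA_integer_
      for (cond in conditions) lev[types == cond] <- dealt[[cond]][[r]]
      n_slots <- length(types)
      gaps <- as.vector(rmultinom(1, gap_units_total, rep(1, n_slots + 1L))) * 0.5
      onset <- cumsum(c(gaps[1], rep(slot, n_slots - 1L) + gaps[2:n_slots]))
      data.frame(run = r, position = seq_len(n_slots), onset = onset,
                 duration = trial_dur, trial_type = types, level = lev,
                 stringsAsFactors = FALSE)
    })
    trials <- do.call(rbind, runs)
    trials$gamble_id <- ifelse(trials$trial_type == "fixation", NA_character_,
                               paste0(substr(trials$trial_type, 1, 1), "_", trials$level))
    trials$sure_gain <- ifelse(trials$trial_type == "fixation", NA_real_,
                               gambles$sure_gain[1])
    trials$win_payoff <- ifelse(trials$trial_type == "fixation", NA_real_,
                                gambles$win_payoff[1])
    structure(list(trials = trials, n_runs = n_runs, tr = tr,
                   volumes_per_run = as.integer(volumes_per_run)),
              class = "ambicon_session")
  })
}

#' @export
print.ambicon_session <- function(x, ...) {
  cat(sprintf("ambicon session: %d runs x %d volumes (TR %.2f s), %d trials\n",
              x$n_runs, x$volumes_per_run, x$tr, nrow(x$trials)))
  print(table(x$trials$run, x$trials$trial_type))
  invisible(x)
}
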