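CHOICE_OPTIONS <- c("sure", "type1", "type2", "type3")

#' Subjective decision weight of one option
#'
#' The weight of an option paying `x` dollars with probability `pi` is
#' `x^theta * pi^gamma`, where `theta` is the decision maker's monetary
#' utility exponent and `gamma` the probability-weighting parameter applied
#' to that option. `gamma > 1` downweights uncertain probabilities
#' (aversion), `gamma < 1` upweights them (seeking), and `gamma = 1` is
#' neutral.
#'
#' @param x Payoff in dollars, positive.
#' @param pi Winning probability in `(0, 1]` (0 returns weight 0 by
#'   continuity).
#' @param gamma Probability-weighting parameter, positive.
#' @param theta Utility exponent, positive.
#' @return Dimensionless weight.
#' @export
option_weight <- function(x, pi, gamma = 1, theta = 1) {
  if (any(x <= 0)) stopf("payoff x must be positive")
  if (any(pi < 0 | pi > 1)) stopf("pi must lie in [0, 1]")
  if (any(gamma <= 0) || any(theta <= 0)) stopf("gamma and theta must be positive")
  ifelse(pi == 0, 0, x^theta * pi^gamma)
}

as_subject_parameters <- function(params) {
  p <- list(theta = params$theta %||% 1,
            gamma_a = params$gamma_a %||% 1,
            gamma_c = params$gamma_c %||% 1,
            gamma_i = params$gamma_i %||% 1)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("subject parameters must be strictly positive and finite")
  p
}

# gamma applied to the uncertain options (type2/type3) of each trial:
# 1 under risk by identification, the condition's gamma otherwise.
condition_gamma <- function(condition, params) {
  g <- rep(1, length(condition))
  g[condition == "ambiguity"] <- params$gamma_a
  g[condition == "conflict"] <- params$gamma_c
  g[condition == "ignorance"] <- params$gamma_i
  g
}

# Vectorised core: n trials -> n x 4 matrix of choice probabilities.
# Weights: sure = s^theta, type1 = w^theta * p1 (known probability, gamma 1),
# type2 = type3 = w^theta * p2^gamma_cond. Utilities equal weights; the
# softmax is computed with a row-max shift so it is finite whenever the
# weights are.
choice_prob_matrix <- function(condition, level, params,
                               sure_gain = 3, win_payoff = 10) {
  params <- as_subject_parameters(params)
  p1 <- (100 - level) / 100
  p2 <- level / 200
  g <- condition_gamma(condition, params)
  U <- cbind(sure = sure_gain^params$theta + numeric(length(level)),
             type1 = win_payoff^params$theta * p1,
             type2 = win_payoff^params$theta * p2^g,
             type3 = win_payoff^params$theta * p2^g)
  U <- U - apply(U, 1, max)
  E <- exp(U)
  E / rowSums(E)
}

#' Choice probabilities of the multinomial logit model
#'
#' Each option's subjective expected utility equals its decision weight
#' ([option_weight()]); choice probabilities are the softmax of the four
#' utilities. The condition's probability-weighting parameter applies only to
#' the options with uncertain winning probability (Type 2 / Type 3 bets); the
#' sure gain and the Type 1 bet have precisely known probabilities and always
#' use `gamma = 1`, so risk trials reduce to the `gamma = 1` special case.
#'
#' @param gamble A single gamble (row of [generate_gamble_set()] output).
#' @param params Subject parameters: list with `theta`, `gamma_a`, `gamma_c`,
#'   `gamma_i` (missing entries default to 1).
#' @return Named probability vector over sure, type1, type2, type3; sums
#'   to 1.
#' @export
choice_probabilities <- function(gamble, params) {
  pm <- choice_prob_matrix(gamble$condition, gamble$level, params,
                           sure_gain = gamble$sure_gain %||% 3,
                           win_payoff = gamble$win_payoff %||% 10)
  p <- pm[1, ]
  names(p) <- CHOICE_OPTIONS
  p
}

#' Model-free uncertainty attitudes
#'
#' Bet counts are choices of the uncertain card types (Type 2 or Type 3).
#' Risk attitude is the shortfall from the risk-neutral benchmark of ten
#' bets; ambiguity and conflict attitudes are the drop in betting relative to
#' risk. Positive values indicate aversion, negative values seeking.
#'
#' @param choices Data frame of trial records with columns `condition` and
#'   `choice` covering risk, ambiguity and conflict.
#' @return List with integer elements `ra`, `aa`, `ca` and the per-condition
#'   bet counts (`bets`).
#' @export
model_free_attitudes <- function(choices) {
  need <- c("risk", "ambiguity", "conflict")
  missing_cond <- setdiff(need, unique(choices$condition))
  if (length(missing_cond) > 0)
    stopf("choices lack condition(s): %s", paste(missing_cond, collapse = ", "))
  is_bet <- choices$choice %in% c("type2", "type3")
  bets <- vapply(need, function(cond)
    sum(is_bet & choices$condition == cond), integer(1))
  list(ra = 10L - bets[["risk"]],
       aa = bets[["risk"]] - bets[["ambiguity"]],
       ca = bets[["risk"]] - bets[["conflict"]],
       bets = bets)
}

#' Subjective value of the chosen option
#'
#' The decision weight of the option actually chosen on a trial, with the
#' trial condition's probability-weighting parameter applied to uncertain
#' options. Used as the parametric modulator of the subjective-value confound
#' model ([build_sv_design_matrix()]).
#'
#' @inheritParams choice_probabilities
#' @param choice The chosen option.
#' @return Scalar weight.
#' @export
subjective_value <- function(gamble, choice = CHOICE_OPTIONS, params) {
  choice <- match.arg(choice)
  params <- as_subject_parameters(params)
  pi <- winning_probability(gamble, choice)
  x <- if (choice == "sure") gamble$sure_gain %||% 3 else gamble$win_payoff %||% 10
  g <- if (choice %in% c("type2", "type3"))
    condition_gamma(gamble$condition, params) else 1
  option_weight(x, pi, gamma = g, theta = params$theta)
}

#' Second-order variance of the Type 2 winning probability
#'
#' Variance of the winning probability of a Type 2 bet under the decision
#' maker's information: zero under risk (composition known), the variance of
#' `k/100` with `k` uniform on `{0, ..., level}` under ambiguity, and the
#' variance of the equal-weight two-point distribution over the two message
#' probabilities under conflict. For every admissible level the ambiguity
#' variance strictly exceeds the conflict variance while the mean winning
#' probability (`level/200`) is identical, which is the design's variance
#' ordering.
#'
#' @inheritParams choice_probabilities
#' @return Variance (probability squared).
#' @export
second_order_variance <- function(gamble) {
  cond <- gamble$condition
  L <- gamble$level
  if (!cond %in% c("risk", "ambiguity", "conflict"))
    stopf("second_order_variance is defined for risk, ambiguity and conflict")
  switch(cond,
         risk = 0,
         # k uniform on {0..L}: Var(k) = ((L+1)^2 - 1)/12 = L(L+2)/12
         ambiguity = L * (L + 2) / 12 / 100^2,
         conflict = {
           p_a <- (gamble$msg_a_type2 %||% round(L / 3)) / 100
           p_b <- (gamble$msg_b_type2 %||% (L - round(L / 3))) / 100
           ((p_a - p_b) / 2)^2
         })
}
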