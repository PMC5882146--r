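#' Agent parameters
#'
#' Describes a reinforcement-learning agent for the two-stage task. Three
#' classes are available:
#'
#' * `"model_free"` — SARSA(lambda) temporal-difference learner. The
#'   initial-stage value of the chosen action is updated toward a mixture of
#'   the chosen final-state action's value and the obtained reward,
#'   `Q(s_i, a_i) <- (1 - alpha) Q(s_i, a_i) + alpha [(1 - lambda) Q(s_f, a_f) + lambda r]`,
#'   and the final-stage value toward the reward,
#'   `Q(s_f, a_f) <- (1 - alpha) Q(s_f, a_f) + alpha r`.
#' * `"model_based"` — plans over the (known, true) transition structure:
#'   initial-stage values are transition-probability-weighted maxima of the
#'   final-state values, which are themselves learned by the same
#'   reward-driven rule.
#' * `"hybrid"` — initial-stage values are the mixture
#'   `w * Q_MB + (1 - w) * Q_MF`; `w = 0` reproduces the model-free agent
#'   and `w = 1` the model-based one.
#'
#' All choices use a softmax with inverse temperature `beta`. Defaults
#' (`alpha = 0.5`, `beta = 5`, `lambda` 1 or 0.6) are typical median
#' estimates from human two-step data.
#'
#' @param class Agent class.
#' @param alpha Learning rate, in (0, 1].
#' @param lambda Eligibility-trace parameter, in \[0, 1\] (model-free and
#'   hybrid agents). `lambda = 0` is allowed but emits a warning: with no
#'   trace the final-stage reward has no direct reinforcing effect on the
#'   initial-stage choice, and the usual stay-probability logic breaks down.
#' @param beta Softmax inverse temperature, >= 0.
#' @param w Hybrid model-based weight, in \[0, 1\] (hybrid agents only).
#' @return An `agent_params` object.
#' @examples
#' agent_params("model_free", lambda = 0.6)
#' agent_params("hybrid", w = 0.5)
#' @export
agent_params <- function(class = c("model_free", "model_based", "hybrid"),
                         alpha = 0.5, lambda = 1, beta = 5, w = NULL) {
  class <- match.arg(class)
  stopifnot(alpha > 0, alpha <= 1, beta >= 0,
            lambda >= 0, lambda <= 1)
  if (class == "hybrid") {
    if (is.null(w)) stop("hybrid agents require a model-based weight `w`")
    stopifnot(w >= 0, w <= 1)
  } else if (!is.null(w)) {
    stop("`w` is only meaningful for hybrid agents")
  }
  if (class != "model_based" && lambda == 0)
    warning("lambda = 0: final-stage rewards have no direct reinforcing ",
            "effect on the initial-stage choice")
  structure(
    list(class = class, alpha = alpha, lambda = lambda, beta = beta, w = w),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Agent:", x$class, "\n")
  cat("  alpha =", x$alpha, " beta =", x$beta)
  if (x$class != "model_based") cat("  lambda =", x$lambda)
  if (x$class == "hybrid") cat("  w =", x$w)
  cat("\n")
  invisible(x)
}

#' Create an empty Q table
#'
#' All values start at 0: `initial` holds one value per initial action
#' (left, right) and `final` one value per (final state, final action).
#' With binary rewards and zero initialization every entry remains in
#' \[0, 1\] under the update rules.
#'
#' @param n_final_actions Number of actions per final state.
#' @return A list with elements `initial` (named numeric of length 2) and
#'   `final` (2 x `n_final_actions` matrix, rows pink/blue).
#' @export
q_table <- function(n_final_actions = 2L) {
  list(initial = c(left = 0, right = 0),
       final = matrix(0, nrow = 2L, ncol = n_final_actions,
                      dimnames = list(c("pink", "blue"), NULL)))
}

#' Softmax choice probabilities
#'
#' `P(a) = exp(beta * v_a) / sum_a' exp(beta * v_a')`, computed with the
#' usual max-subtraction for numerical stability. `beta = 0` gives the
#' uniform distribution; large `beta` approaches the greedy choice.
#'
#' @param values Numeric vector of action values (at least one).
#' @param beta Inverse temperature, >= 0.
#' @return Probability vector of the same length, summing to 1.
#' @examples
#' softmax_prob(c(1, 0), beta = 5)
#' @export
softmax_prob <- function(values, beta) {
  if (length(values) == 0L) stop("`values` must contain at least one action")
  z <- beta * values
  e <- exp(z - max(z))
  e / sum(e)
}

#' SARSA final-stage update
#'
#' Moves the chosen final-state action's value toward the obtained reward:
#' `Q(s_f, a_f) <- (1 - alpha) Q(s_f, a_f) + alpha r`.
#'
#' @param q A [q_table()].
#' @param final_state `"pink"` or `"blue"`.
#' @param final_action Final-action index.
#' @param reward 0 or 1.
#' @param alpha Learning rate.
#' @return The updated Q table.
#' @export
mf_final_update <- function(q, final_state, final_action, reward, alpha) {
  old <- q$final[final_state, final_action]
  q$final[final_state, final_action] <- (1 - alpha) * old + alpha * reward
  q
}

#' Model-based final-stage update
#'
#' The model-based learner updates its final-state values with the same
#' reward-driven rule as the SARSA final-stage update; see
#' [mf_final_update()].
#'
#' @inheritParams mf_final_update
#' @return The updated Q table.
#' @export
mb_update <- mf_final_update

#' SARSA(lambda) initial-stage update
#'
#' Updates the chosen initial action's value using the final-state action
#' value *before* the final-stage update of the same trial:
#' `Q(s_i, a_i) <- (1 - alpha) Q(s_i, a_i) + alpha [(1 - lambda) Q(s_f, a_f) + lambda r]`.
#' At `lambda = 1` this reduces to a pure reward-driven update.
#'
#' @inheritParams mf_final_update
#' @param initial_action `"left"` or `"right"`.
#' @param lambda Eligibility-trace parameter.
#' @return The updated Q table.
#' @export
mf_initial_update <- function(q, initial_action, final_state, final_action,
                              reward, alpha, lambda) {
  target <- (1 - lambda) * q$final[final_state, final_action] + lambda * reward
  q$initial[initial_action] <-
    (1 - alpha) * q$initial[initial_action] + alpha * target
  q
}

#' Model-based initial-stage values
#'
#' The value of each initial action is the transition-probability-weighted
#' sum of the best final-state values: with `p` the best pink value and `b`
#' the best blue value, `Q(left) = c * p + (1 - c) * b` and
#' `Q(right) = (1 - c) * p + c * b`, where `c` is the common-transition
#' probability. The agent uses the true transition probabilities.
#'
#' @param q A [q_table()] whose `final` matrix holds the learned values.
#' @param task A [two_stage_task()].
#' @return Named numeric vector `c(left = , right = )`.
#' @export
mb_initial_values <- function(q, task) {
  p <- max(q$final["pink", ])
  b <- max(q$final["blue", ])
  cp <- task$common_prob
  c(left = cp * p + (1 - cp) * b, right = (1 - cp) * p + cp * b)
}

#' Model-based probability of choosing left
#'
#' Closed form of the softmax over the model-based initial values under the
#' symmetric transition structure:
#' `P(left) = 1 / (1 + exp(-beta * (2c - 1) * (p - b)))`,
#' so the probability of choosing left increases with `p - b`, equals 0.5
#' when `p = b`, and is 0.5 for `beta = 0`.
#'
#' @inheritParams mb_initial_values
#' @param beta Inverse temperature.
#' @return Probability of choosing left.
#' @export
mb_initial_choice_prob <- function(q, task, beta) {
  p <- max(q$final["pink", ])
  b <- max(q$final["blue", ])
  gap <- 2 * task$common_prob - 1
  stats::plogis(beta * gap * (p - b))
}

#' Hybrid initial-stage values
#'
#' Value-level mixture `w * Q_MB + (1 - w) * Q_MF` of the model-based and
#' model-free initial-stage values.
#'
#' @param v_mf,v_mb Numeric vectors of model-free and model-based initial
#'   values (same length).
#' @param w Model-based weight in \[0, 1\].
#' @return Numeric vector of mixed values.
#' @export
hybrid_initial_values <- function(v_mf, v_mb, w) {
  stopifnot(length(v_mf) == length(v_mb), w >= 0, w <= 1)
  w * v_mb + (1 - w) * v_mf
}
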