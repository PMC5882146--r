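#' Post-update value gaps of a model-based agent
#'
#' Let `p` and `b` be the values of the best actions at the pink and blue
#' final states. A model-based agent's initial-stage preference is driven
#' by the gap `p - b`. After a single trial, the gap becomes
#' `[(1 - alpha) p + alpha] - b` if the agent took the common transition to
#' pink and was rewarded, and `p - (1 - alpha) b` if it took the rare
#' transition to blue and was unrewarded. The two post-update gaps differ
#' by `alpha (1 - p - b)`, which vanishes exactly when `p + b = 1` (for
#' `alpha > 0`): this is the condition under which model-based behavior
#' shows no main effect of transition.
#'
#' @param p,b Values of the best pink and blue actions, in \[0, 1\].
#' @param alpha Learning rate in \[0, 1\].
#' @return A numeric value (vectorized over the inputs).
#' @examples
#' gap_after_common_rewarded(0.6, 0.4, 0.5)   # 0.4
#' gap_after_rare_unrewarded(0.6, 0.4, 0.5)   # 0.4 (p + b = 1)
#' gap_update_difference(0.8, 0.8, 0.5)       # -0.3
#' @export
gap_after_common_rewarded <- function(p, b, alpha) {
  ((1 - alpha) * p + alpha) - b
}

#' @rdname gap_after_common_rewarded
#' @export
gap_after_rare_unrewarded <- function(p, b, alpha) {
  p - (1 - alpha) * b
}

#' @rdname gap_after_common_rewarded
#' @export
gap_update_difference <- function(p, b, alpha) {
  alpha * (1 - p - b)
}

#' Analytic stay probabilities of a model-based agent after one trial
#'
#' Starting from converged value estimates `p` (best pink action) and `b`
#' (best blue action), applies the model-based reward update to the visited
#' state's best value for each of the four outcome types (reward x
#' transition) and evaluates the probability of repeating the initial
#' choice under the closed-form choice rule
#' `P(left) = 1 / (1 + exp(-beta (2c - 1) (p - b)))`. By the task's
#' left/right symmetry the choice of initial action is irrelevant; the
#' computation conditions on "left".
#'
#' @param p,b Pre-trial value estimates in \[0, 1\].
#' @param alpha Learning rate in (0, 1\].
#' @param beta Softmax inverse temperature.
#' @param common_prob Common-transition probability.
#' @return Named numeric vector with the four stay probabilities `P_rc`,
#'   `P_uc`, `P_rr`, `P_ur` (rewarded/unrewarded x common/rare).
#' @export
mb_stay_probabilities <- function(p, b, alpha, beta = 2.5,
                                  common_prob = 0.7) {
  gap <- 2 * common_prob - 1
  stay <- function(pp, bb) stats::plogis(beta * gap * (pp - bb))
  c(P_rc = stay((1 - alpha) * p + alpha, b),  # common -> pink, rewarded
    P_uc = stay((1 - alpha) * p, b),          # common -> pink, unrewarded
    P_rr = stay(p, (1 - alpha) * b + alpha),  # rare -> blue, rewarded
    P_ur = stay(p, (1 - alpha) * b))          # rare -> blue, unrewarded
}

#' Analytic common-minus-rare stay-probability difference
#'
#' Computes `(P_rc + P_uc) - (P_rr + P_ur)` from
#' [mb_stay_probabilities()] under the symmetric-value assumption
#' `p = b = p_plus_b / 2`. The difference is positive for `p_plus_b < 1`,
#' zero at `p_plus_b = 1` and negative for `p_plus_b > 1`: a model-based
#' agent shows a main effect of transition whenever the final-state values
#' do not sum to one.
#'
#' @param p_plus_b Sum of the two final-state values, in \[0, 2\].
#'   Vectorized.
#' @param alpha Learning rate; `alpha = 0` is degenerate (no update ever
#'   happens) and returns 0 with a warning.
#' @param beta Softmax inverse temperature (default 2.5).
#' @param common_prob Common-transition probability (default 0.7).
#' @return Numeric vector of stay-probability differences.
#' @examples
#' analytic_stay_difference(c(0.4, 1, 1.6), alpha = 0.5)
#' @export
analytic_stay_difference <- function(p_plus_b, alpha, beta = 2.5,
                                     common_prob = 0.7) {
  if (alpha == 0) {
    warning("alpha = 0: values never update, the difference is identically 0")
    return(rep(0, length(p_plus_b)))
  }
  vapply(p_plus_b, function(s) {
    pr <- mb_stay_probabilities(s / 2, s / 2, alpha, beta, common_prob)
    (pr[["P_rc"]] + pr[["P_uc"]]) - (pr[["P_rr"]] + pr[["P_ur"]])
  }, numeric(1))
}

#' Root of the analytic transition effect in p + b
#'
#' Locates where [analytic_stay_difference()] crosses zero as a function of
#' `p_plus_b`, by bisection-based root search. The difference is strictly
#' decreasing in `p_plus_b`, so the root is unique; it sits at
#' `p_plus_b = 1`.
#'
#' @inheritParams analytic_stay_difference
#' @param interval Search interval inside (0, 2).
#' @param tol Root tolerance (default 1e-9).
#' @return The value of `p_plus_b` at the zero crossing.
#' @export
transition_effect_root <- function(alpha = 0.5, beta = 2.5,
                                   common_prob = 0.7,
                                   interval = c(1e-6, 2 - 1e-6),
                                   tol = 1e-9) {
  stats::uniroot(function(s) analytic_stay_difference(s, alpha, beta,
                                                      common_prob),
                 interval = interval, tol = tol)$root
}

#' Grid of analytic transition effects (heatmap table)
#'
#' Evaluates [analytic_stay_difference()] over a grid of `p_plus_b` and
#' `alpha` values, producing a long table suitable for heatmap rendering.
#'
#' @param p_plus_b Grid of value sums (default 0.02..1.98).
#' @param alpha Grid of learning rates (default 0.05..1).
#' @inheritParams analytic_stay_difference
#' @return A data.frame with columns `p_plus_b`, `alpha`, `diff`.
#' @export
transition_effect_grid <- function(p_plus_b = seq(0.02, 1.98, by = 0.02),
                                   alpha = seq(0.05, 1, by = 0.05),
                                   beta = 2.5, common_prob = 0.7) {
  grid <- expand.grid(p_plus_b = p_plus_b, alpha = alpha,
                      KEEP.OUT.ATTRS = FALSE)
  grid$diff <- unlist(Map(function(s, a)
    analytic_stay_difference(s, a, beta, common_prob),
    grid$p_plus_b, grid$alpha))
  grid
}
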