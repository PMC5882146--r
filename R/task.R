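#' Define a two-stage decision task
#'
#' A two-stage task has an initial state with two actions ("left", "right"),
#' two final states ("pink", "blue") reached probabilistically from the
#' initial choice, one or more actions at each final state, and a binary
#' reward whose probability is governed by a reward schedule.
#'
#' Choosing left leads to pink with probability `common_prob` (the "common"
#' transition) and to blue otherwise (the "rare" transition); right is the
#' mirror image. `common_prob` must exceed 0.5 so that "common" is
#' meaningful.
#'
#' @param common_prob Probability of the common transition (default 0.7).
#' @param n_final_actions Number of actions available at each final state
#'   (default 2).
#' @param n_trials Number of trials in a session (default 250).
#' @param schedule A reward schedule created by [drifting_schedule()],
#'   [fixed_schedule()] or [swap_schedule()].
#' @return An object of class `two_stage_task`.
#' @examples
#' task <- two_stage_task(schedule = fixed_schedule(pink = 0.8, blue = 0.2))
#' @seealso [drifting_schedule()], [run_session()]
#' @export
two_stage_task <- function(common_prob = 0.7, n_final_actions = 2L,
                           n_trials = 250L, schedule = drifting_schedule()) {
  stopifnot(is.numeric(common_prob), length(common_prob) == 1L)
  if (!(common_prob > 0.5 && common_prob <= 1))
    stop("`common_prob` must lie in (0.5, 1] so the common transition is the more likely one")
  n_final_actions <- as.integer(n_final_actions)
  n_trials <- as.integer(n_trials)
  if (n_final_actions < 1L) stop("`n_final_actions` must be >= 1")
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  if (!inherits(schedule, "reward_schedule"))
    stop("`schedule` must be a reward schedule object")
  structure(
    list(common_prob = common_prob,
         n_final_actions = n_final_actions,
         n_trials = n_trials,
         schedule = schedule),
    class = "two_stage_task"
  )
}

#' @export
print.two_stage_task <- function(x, ...) {
  cat("Two-stage task\n")
  cat("  common transition probability:", x$common_prob, "\n")
  cat("  final actions per state:      ", x$n_final_actions, "\n")
  cat("  trials per session:           ", x$n_trials, "\n")
  cat("  reward schedule:              ", x$schedule$kind, "\n")
  invisible(x)
}

# Internal state/action codes used by the simulator: states 1 = pink,
# 2 = blue; initial actions 1 = left, 2 = right.  Labels are attached only
# when building user-facing trial records.
.final_states <- c("pink", "blue")
.initial_actions <- c("left", "right")

#' Sample final states for initial actions
#'
#' Draws the probabilistic transition of the two-stage task: left goes to
#' pink with the common-transition probability and to blue otherwise;
#' right is the mirror image. Vectorized over `action`.
#'
#' @param action Character vector of initial actions, `"left"` or `"right"`.
#' @param task A [two_stage_task()].
#' @return A data.frame with columns `final_state` (`"pink"`/`"blue"`) and
#'   `transition` (`"common"`/`"rare"`), one row per element of `action`.
#' @examples
#' task <- two_stage_task()
#' set.seed(1)
#' sample_transition(c("left", "right"), task)
#' @export
sample_transition <- function(action, task) {
  a <- match(action, .initial_actions)
  if (anyNA(a)) stop("`action` must be \"left\" or \"right\"")
  common <- stats::runif(length(a)) < task$common_prob
  # common: left -> pink (1), right -> blue (2); rare: the other state
  state <- ifelse(common, a, 3L - a)
  data.frame(
    final_state = .final_states[state],
    transition = ifelse(common, "common", "rare"),
    stringsAsFactors = FALSE
  )
}

#' Sample binary rewards from the current schedule state
#'
#' Bernoulli rewards with the probability the schedule currently assigns to
#' each (final state, final action) pair. Vectorized over `final_state` and
#' `action`.
#'
#' @param final_state Character vector, `"pink"` or `"blue"`.
#' @param action Integer vector of final-action indices.
#' @param state Schedule state from [init_schedule_state()] /
#'   [advance_schedule()].
#' @return Integer vector of 0/1 rewards.
#' @export
sample_reward <- function(final_state, action, state) {
  s <- match(final_state, .final_states)
  if (anyNA(s)) stop("`final_state` must be \"pink\" or \"blue\"")
  action <- as.integer(action)
  if (any(action < 1L) || any(action > ncol(state$reward_prob)))
    stop("unknown final action index for this schedule state")
  p <- state$reward_prob[cbind(s, action)]
  as.integer(stats::runif(length(p)) < p)
}
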