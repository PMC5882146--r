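#' Reward schedules for the two-stage task
#'
#' Three families of reward schedule are supported:
#'
#' * **drifting** — every (final state, action) reward probability starts at
#'   an independent uniform draw from `[init_low, init_high]` and performs a
#'   Gaussian random walk (step s.d. `step_sd`) with reflecting bounds at
#'   `bound_low`/`bound_high`, so the long-run mean is the interval
#'   midpoint. This is the classic continuously-drifting task.
#' * **fixed** — constant probabilities, one per final state (shared by all
#'   actions at that state).
#' * **swap** — one final state holds the `high` probability and the other
#'   the `low` one; on each trial the assignment is exchanged with
#'   probability `swap_prob`, except during a refractory period of
#'   `refractory` trials after a swap.
#'
#' @param init_low,init_high Bounds of the uniform initialization interval.
#' @param step_sd Standard deviation of the Gaussian drift step.
#' @param bound_low,bound_high Reflecting bounds of the random walk.
#' @return A `reward_schedule` object.
#' @examples
#' drifting_schedule()
#' fixed_schedule(pink = 0.8, blue = 0.2)
#' swap_schedule(swap_prob = 0.02)
#' @name reward_schedules
NULL

#' @rdname reward_schedules
#' @export
drifting_schedule <- function(init_low = 0.25, init_high = 0.75,
                              step_sd = 0.025,
                              bound_low = 0.25, bound_high = 0.75) {
  stopifnot(step_sd > 0, bound_low < bound_high,
            bound_low >= 0, bound_high <= 1,
            init_low >= bound_low, init_high <= bound_high)
  structure(
    list(kind = "drifting", init_low = init_low, init_high = init_high,
         step_sd = step_sd, bound_low = bound_low, bound_high = bound_high),
    class = c("drifting_schedule", "reward_schedule")
  )
}

#' @rdname reward_schedules
#' @param pink,blue Fixed reward probability of the actions at each state.
#' @export
fixed_schedule <- function(pink, blue = pink) {
  stopifnot(pink >= 0, pink <= 1, blue >= 0, blue <= 1)
  structure(
    list(kind = "fixed", pink = pink, blue = blue),
    class = c("fixed_schedule", "reward_schedule")
  )
}

#' @rdname reward_schedules
#' @param high,low The two reward probabilities exchanged between states.
#' @param swap_prob Per-trial probability of a swap (outside the refractory
#'   period).
#' @param refractory Number of trials after a swap during which no further
#'   swap can occur.
#' @export
swap_schedule <- function(high = 0.8, low = 0.2, swap_prob = 0.02,
                          refractory = 10L) {
  stopifnot(high >= 0, high <= 1, low >= 0, low <= 1, low < high,
            swap_prob >= 0, swap_prob <= 1, refractory >= 0)
  structure(
    list(kind = "swap", high = high, low = low, swap_prob = swap_prob,
         refractory = as.integer(refractory)),
    class = c("swap_schedule", "reward_schedule")
  )
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat("Reward schedule:", x$kind, "\n")
  utils::str(unclass(x)[-1], give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Initialize the per-trial state of a reward schedule
#'
#' The state holds the current `reward_prob` matrix (rows `pink`/`blue`,
#' one column per final action) and, for swap schedules, the number of
#' trials since the last swap. Drifting schedules draw their initial values
#' at random; swap schedules assign high/low to a random state.
#'
#' @param schedule A `reward_schedule`.
#' @param n_actions Number of actions per final state.
#' @return A `schedule_state` list.
#' @export
init_schedule_state <- function(schedule, n_actions = 2L) {
  UseMethod("init_schedule_state")
}

.new_schedule_state <- function(reward_prob, trials_since_swap = NULL) {
  dimnames(reward_prob) <- list(c("pink", "blue"), NULL)
  structure(list(reward_prob = reward_prob,
                 trials_since_swap = trials_since_swap),
            class = "schedule_state")
}

#' @export
init_schedule_state.drifting_schedule <- function(schedule, n_actions = 2L) {
  p <- matrix(stats::runif(2L * n_actions, schedule$init_low, schedule$init_high),
              nrow = 2L)
  .new_schedule_state(p)
}

#' @export
init_schedule_state.fixed_schedule <- function(schedule, n_actions = 2L) {
  p <- matrix(rep(c(schedule$pink, schedule$blue), n_actions), nrow = 2L)
  .new_schedule_state(p)
}

#' @export
init_schedule_state.swap_schedule <- function(schedule, n_actions = 2L) {
  hi_state <- sample.int(2L, 1L)
  vals <- if (hi_state == 1L) c(schedule$high, schedule$low) else
    c(schedule$low, schedule$high)
  p <- matrix(rep(vals, n_actions), nrow = 2L)
  # start outside the refractory period so an early swap is possible
  .new_schedule_state(p, trials_since_swap = schedule$refractory)
}

# Reflect x into [lo, hi] by mirroring about the violated bound,
# iterating until inside (handles steps larger than the interval).
reflect_into_bounds <- function(x, lo, hi) {
  width <- hi - lo
  out <- x < lo | x > hi
  while (any(out)) {
    x[x > hi] <- 2 * hi - x[x > hi]
    x[x < lo] <- 2 * lo - x[x < lo]
    out <- x < lo | x > hi
  }
  x
}

#' Advance a reward schedule by one trial
#'
#' Fixed schedules are unchanged. Drifting schedules add an independent
#' Gaussian step to each reward probability and reflect it back into the
#' bounds. Swap schedules exchange the high/low assignment with probability
#' `swap_prob` provided at least `refractory` trials have passed since the
#' previous swap.
#'
#' @param state A `schedule_state`.
#' @param schedule The `reward_schedule` that produced it.
#' @return The updated `schedule_state`.
#' @export
advance_schedule <- function(state, schedule) {
  UseMethod("advance_schedule", schedule)
}

#' @export
advance_schedule.fixed_schedule <- function(state, schedule) state

#' @export
advance_schedule.drifting_schedule <- function(state, schedule) {
  p <- state$reward_prob +
    stats::rnorm(length(state$reward_prob), 0, schedule$step_sd)
  state$reward_prob[] <- reflect_into_bounds(p, schedule$bound_low,
                                             schedule$bound_high)
  state
}

#' @export
advance_schedule.swap_schedule <- function(state, schedule) {
  if (state$trials_since_swap >= schedule$refractory &&
      stats::runif(1L) < schedule$swap_prob) {
    state$reward_prob <- state$reward_prob[c(2L, 1L), , drop = FALSE]
    rownames(state$reward_prob) <- c("pink", "blue")
    state$trials_since_swap <- 0L
  } else {
    state$trials_since_swap <- state$trials_since_swap + 1L
  }
  state
}
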