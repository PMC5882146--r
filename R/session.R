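#' Simulate one agent performing a two-stage task session
#'
#' Runs `task$n_trials` trials. On each trial the agent chooses an initial
#' action by softmax over its class-specific initial-stage values, a final
#' state is sampled from the transition structure, the agent chooses a
#' final action by softmax over its learned final-state values, a binary
#' reward is drawn from the current reward schedule, the agent's values are
#' updated, and the schedule advances by one trial.
#'
#' The output is deterministic given `seed`.
#'
#' @param agent An [agent_params()] object.
#' @param task A [two_stage_task()].
#' @param seed Optional integer seed set before the session.
#' @return A data.frame with one row per trial and columns `trial`,
#'   `choice` ("left"/"right"), `final_state` ("pink"/"blue"),
#'   `transition` ("common"/"rare"), `final_action` (integer index) and
#'   `reward` (0/1).
#' @examples
#' trials <- run_session(agent_params("model_based"), two_stage_task(), seed = 1)
#' head(trials)
#' @export
run_session <- function(agent, task, seed = NULL) {
  if (!inherits(agent, "agent_params")) stop("`agent` must be agent_params()")
  if (!inherits(task, "two_stage_task")) stop("`task` must be two_stage_task()")
  if (!is.null(seed)) set.seed(seed)

  n <- task$n_trials
  na <- task$n_final_actions
  beta <- agent$beta
  alpha <- agent$alpha
  lambda <- agent$lambda
  cls <- agent$class

  q <- q_table(na)
  sched_state <- init_schedule_state(task$schedule, na)

  choice <- integer(n)
  fstate <- integer(n)
  common <- logical(n)
  faction <- integer(n)
  reward <- integer(n)

  for (t in seq_len(n)) {
    v <- switch(cls,
      model_free = q$initial,
      model_based = mb_initial_values(q, task),
      hybrid = hybrid_initial_values(q$initial, mb_initial_values(q, task),
                                     agent$w))
    p_left <- softmax_prob(v, beta)[1L]
    a_i <- if (stats::runif(1L) < p_left) 1L else 2L

    is_common <- stats::runif(1L) < task$common_prob
    s_f <- if (is_common) a_i else 3L - a_i  # 1 = pink, 2 = blue

    pf <- softmax_prob(q$final[s_f, ], beta)
    a_f <- if (na == 1L) 1L else
      sample.int(na, 1L, prob = pf)

    r <- as.integer(stats::runif(1L) < sched_state$reward_prob[s_f, a_f])

    sname <- .final_states[s_f]
    aname <- .initial_actions[a_i]
    if (cls == "model_based") {
      q <- mb_update(q, sname, a_f, r, alpha)
    } else {
      # initial-stage update uses the final value before its own update
      q <- mf_initial_update(q, aname, sname, a_f, r, alpha, lambda)
      q <- mf_final_update(q, sname, a_f, r, alpha)
    }

    sched_state <- advance_schedule(sched_state, task$schedule)

    choice[t] <- a_i
    fstate[t] <- s_f
    common[t] <- is_common
    faction[t] <- a_f
    reward[t] <- r
  }

  data.frame(
    trial = seq_len(n),
    choice = .initial_actions[choice],
    final_state = .final_states[fstate],
    transition = ifelse(common, "common", "rare"),
    final_action = faction,
    reward = reward,
    stringsAsFactors = FALSE
  )
}

#' Simulate a population of identical agents
#'
#' Runs [run_session()] for `n_agents` agents. A master seed generates one
#' sub-seed per agent, so increasing `n_agents` extends the population
#' without perturbing the trajectories of earlier agents.
#'
#' @inheritParams run_session
#' @param n_agents Number of agents to simulate.
#' @param seed Master seed (required for reproducibility; optional).
#' @return A data.frame as in [run_session()] with an additional leading
#'   `agent_id` column (1..n_agents).
#' @export
run_agents <- function(agent, task, n_agents, seed = NULL) {
  n_agents <- as.integer(n_agents)
  stopifnot(n_agents >= 1L)
  if (!is.null(seed)) set.seed(seed)
  agent_seeds <- sample.int(.Machine$integer.max, n_agents)
  out <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    trials <- run_session(agent, task, seed = agent_seeds[i])
    out[[i]] <- cbind(agent_id = i, trials)
  }
  do.call(rbind, out)
}
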