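# Shared fixtures for the test suite: all data are generated in code.

# Design rows drawn from the stay-regression generative model itself:
# predictors are iid +1/-1, stay ~ Bernoulli(plogis(linear predictor)).
# `beta` is a named vector over (Intercept), reward, transition,
# reward_x_transition and optionally choice, final_state.
simulate_design <- function(beta, n, n_agents = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_r <- sample(c(-1, 1), n, replace = TRUE)
  x_t <- sample(c(-1, 1), n, replace = TRUE)
  x_c <- sample(c(-1, 1), n, replace = TRUE)
  x_f <- sample(c(-1, 1), n, replace = TRUE)
  eta <- beta[["(Intercept)"]] + beta[["reward"]] * x_r +
    beta[["transition"]] * x_t +
    beta[["reward_x_transition"]] * x_r * x_t
  if ("choice" %in% names(beta)) eta <- eta + beta[["choice"]] * x_c
  if ("final_state" %in% names(beta)) eta <- eta + beta[["final_state"]] * x_f
  data.frame(
    agent_id = rep_len(seq_len(n_agents), n),
    stay = as.integer(runif(n) < plogis(eta)),
    x_r = x_r, x_t = x_t, x_c = x_c, x_f = x_f
  )
}

# Hand-built trial log for encoding tests.
make_trials <- function(choice, final_state, transition, reward,
                        agent_id = 1L) {
  data.frame(
    agent_id = agent_id,
    trial = seq_along(choice),
    choice = choice,
    final_state = final_state,
    transition = transition,
    final_action = 1L,
    reward = reward
  )
}

# A stay_fit skeleton with given coefficients, for exercising stay_table()
# and relation checks without a real fit.
mock_stay_fit <- function(coefs, boot = NULL, model = "basic") {
  nms <- names(coefs)
  ci <- matrix(NA_real_, length(coefs), 2L,
               dimnames = list(nms, c("low", "high")))
  structure(
    list(model = model, coefficients = coefs, ci = ci, boot = boot,
         n_rows = NA_integer_, n_agents = NA_integer_,
         lambda = 1e-4, conf_level = 0.95),
    class = "stay_fit"
  )
}

# Empirical four-cell stay table straight from trial frequencies (no
# regression), used as an independent check of the analytic results.
empirical_stay_probs <- function(trials) {
  d <- encode_trials(trials)
  cell <- function(r, t) mean(d$stay[d$x_r == r & d$x_t == t])
  c(P_rc = cell(1, 1), P_uc = cell(-1, 1),
    P_rr = cell(1, -1), P_ur = cell(-1, -1))
}
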