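#' Encode trials into the stay-probability regression design
#'
#' For each trial after the first within an agent's session, codes whether
#' the initial choice repeated the previous trial's choice (`stay`), and
#' four +1/-1 indicators derived from the *previous* trial: `x_r` (+1
#' rewarded), `x_t` (+1 common transition), `x_c` (+1 chose left) and
#' `x_f` (+1 reached pink). The first trial of every session is dropped.
#'
#' @param trials A data.frame from [run_session()] or [run_agents()] (if
#'   there is no `agent_id` column, a single session is assumed). Rows must
#'   be ordered by trial within agent.
#' @return A data.frame with columns `agent_id`, `stay` (0/1), `x_r`,
#'   `x_t`, `x_c`, `x_f` (each +1/-1); one row per trial after the first.
#' @examples
#' trials <- run_session(agent_params("model_free"), two_stage_task(), seed = 1)
#' design <- encode_trials(trials)
#' nrow(design)  # n_trials - 1
#' @export
encode_trials <- function(trials) {
  need <- c("trial", "choice", "final_state", "transition", "reward")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    stop("`trials` is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(trials$agent_id)) trials$agent_id <- 1L

  n <- nrow(trials)
  if (n == 0L) {
    warning("no trials to encode")
    return(data.frame(agent_id = integer(), stay = integer(),
                      x_r = numeric(), x_t = numeric(),
                      x_c = numeric(), x_f = numeric()))
  }
  same_agent <- c(FALSE, trials$agent_id[-1L] == trials$agent_id[-n])
  if (!any(same_agent)) {
    warning("every session has fewer than 2 trials; no design rows produced")
    return(data.frame(agent_id = integer(), stay = integer(),
                      x_r = numeric(), x_t = numeric(),
                      x_c = numeric(), x_f = numeric()))
  }
  cur <- which(same_agent)
  prev <- cur - 1L
  data.frame(
    agent_id = trials$agent_id[cur],
    stay = as.integer(trials$choice[cur] == trials$choice[prev]),
    x_r = ifelse(trials$reward[prev] == 1, 1, -1),
    x_t = ifelse(trials$transition[prev] == "common", 1, -1),
    x_c = ifelse(trials$choice[prev] == "left", 1, -1),
    x_f = ifelse(trials$final_state[prev] == "pink", 1, -1)
  )
}

# Cell-level aggregation of the design: one row per agent x predictor cell
# with stay counts. Fitting on counts is exactly equivalent to row-level
# logistic regression and makes agent-resampling bootstraps cheap.
.aggregate_design <- function(design, vars) {
  key <- do.call(paste, c(design[c("agent_id", vars)], sep = "/"))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  data.frame(
    agent_id = design$agent_id[first],
    design[first, vars, drop = FALSE],
    n_stay = as.vector(rowsum(design$stay, idx)[order(unique(idx)), ]),
    n_tot = as.vector(tabulate(idx)),
    row.names = NULL
  )
}

.model_vars <- function(model) {
  switch(model,
         basic = c("x_r", "x_t"),
         extended = c("x_r", "x_t", "x_c", "x_f"))
}

.coef_names <- function(model) {
  base <- c("(Intercept)", "reward", "transition", "reward_x_transition")
  if (model == "extended") c(base, "choice", "final_state") else base
}

# Ridge logistic fit on aggregated stay counts per predictor cell.
.fit_cells <- function(cells, vars, lambda) {
  x <- as.matrix(cells[, vars, drop = FALSE])
  x <- cbind(x, reward_x_transition = x[, "x_r"] * x[, "x_t"])
  ord <- c("x_r", "x_t", "reward_x_transition",
           intersect(c("x_c", "x_f"), vars))
  x <- x[, ord, drop = FALSE]
  y <- cbind(cells$n_tot - cells$n_stay, cells$n_stay)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-12)
  as.vector(stats::coef(fit))
}

#' Fit the stay-probability logistic regression
#'
#' Fits `logit P(stay) = b0 + b_r x_r + b_t x_t + b_rxt x_r x_t`
#' (basic model), optionally extended with the previous-choice and
#' previous-final-state controls `b_c x_c + b_f x_f`. Rows from all agents
#' are pooled into one regression. A weak ridge penalty keeps the
#' coefficients finite even under complete separation; its fixed default
#' strength introduces negligible bias (see the package vignette).
#' Coefficient uncertainty comes from a nonparametric bootstrap that
#' resamples agents (not rows).
#'
#' @param design A design data.frame from [encode_trials()].
#' @param model `"basic"` or `"extended"`.
#' @param lambda Ridge penalty passed to glmnet (default 1e-4).
#' @param n_boot Number of bootstrap resamples of agents (default 200; 0
#'   disables the bootstrap and the intervals are `NA`).
#' @param conf_level Bootstrap percentile interval coverage (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `stay_fit` with elements `model`,
#'   `coefficients` (named vector: `(Intercept)`, `reward`, `transition`,
#'   `reward_x_transition`, and for the extended model `choice`,
#'   `final_state`), `ci` (matrix with columns `low`, `high`), `boot`
#'   (replicate coefficients), `n_rows`, `n_agents`, `lambda`.
#' @examples
#' trials <- run_agents(agent_params("model_free"), two_stage_task(),
#'                      n_agents = 20, seed = 1)
#' fit <- fit_stay_regression(encode_trials(trials), n_boot = 50, seed = 2)
#' coef(fit)
#' @export
fit_stay_regression <- function(design, model = c("basic", "extended"),
                                lambda = 1e-4, n_boot = 200L,
                                conf_level = 0.95, seed = NULL) {
  model <- match.arg(model)
  if (nrow(design) == 0L) stop("empty design: nothing to fit")
  if (length(unique(design$stay)) < 2L)
    stop("`stay` takes a single value; the regression is not identified")
  vars <- .model_vars(model)
  cells <- .aggregate_design(design, vars)
  nms <- .coef_names(model)

  pool <- function(w) {
    # collapse agent x cell counts (weighted by agent multiplicity) to cells
    key <- do.call(paste, c(cells[vars], sep = "/"))
    s <- rowsum(cells$n_stay * w, key)
    ntot <- rowsum(cells$n_tot * w, key)
    keep <- ntot[, 1L] > 0
    out <- cells[match(rownames(s)[keep], key), vars, drop = FALSE]
    out$n_stay <- s[keep, 1L]
    out$n_tot <- ntot[keep, 1L]
    out
  }

  agents <- unique(cells$agent_id)
  w1 <- rep(1, nrow(cells))
  est <- .fit_cells(pool(w1), vars, lambda)
  names(est) <- nms

  boot <- NULL
  ci <- matrix(NA_real_, length(nms), 2L,
               dimnames = list(nms, c("low", "high")))
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, length(nms), dimnames = list(NULL, nms))
    for (b in seq_len(n_boot)) {
      draw <- sample(agents, length(agents), replace = TRUE)
      mult <- table(factor(draw, levels = agents))
      w <- as.numeric(mult[match(cells$agent_id, agents)])
      boot[b, ] <- .fit_cells(pool(w), vars, lambda)
    }
    a <- (1 - conf_level) / 2
    ci[] <- t(apply(boot, 2L, stats::quantile, probs = c(a, 1 - a)))
  }

  structure(
    list(model = model, coefficients = est, ci = ci, boot = boot,
         n_rows = nrow(design), n_agents = length(agents),
         lambda = lambda, conf_level = conf_level),
    class = "stay_fit"
  )
}

#' @export
coef.stay_fit <- function(object, ...) object$coefficients

#' @export
print.stay_fit <- function(x, ...) {
  cat("Stay-probability logistic regression (", x$model, " model)\n", sep = "")
  cat("  rows:", x$n_rows, " agents:", x$n_agents,
      " ridge lambda:", x$lambda, "\n\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Tidy a stay-probability fit into a coefficient table
#'
#' @param x A `stay_fit`.
#' @param ... Unused.
#' @return A data.frame with columns `model`, `coefficient`, `estimate`,
#'   `ci_low`, `ci_high`, `n_rows`.
#' @export
as.data.frame.stay_fit <- function(x, ...) {
  data.frame(
    model = x$model,
    coefficient = names(x$coefficients),
    estimate = unname(x$coefficients),
    ci_low = unname(x$ci[, "low"]),
    ci_high = unname(x$ci[, "high"]),
    n_rows = x$n_rows,
    row.names = NULL
  )
}

#' Four-cell stay-probability table implied by a fit
#'
#' Evaluates the inverse-logit of the fitted linear predictor at the four
#' (previous reward, previous transition) combinations, with the control
#' variables (extended model) set to 0. Cells follow the standard naming:
#' `P_rc` (rewarded, common), `P_uc` (unrewarded, common), `P_rr`
#' (rewarded, rare), `P_ur` (unrewarded, rare).
#'
#' @param fit A `stay_fit`.
#' @return A data.frame with columns `cell`, `prev_outcome`,
#'   `prev_transition`, `stay_prob`.
#' @export
stay_table <- function(fit) {
  b <- fit$coefficients
  grid <- data.frame(
    cell = c("P_rc", "P_uc", "P_rr", "P_ur"),
    prev_outcome = c("rewarded", "unrewarded", "rewarded", "unrewarded"),
    prev_transition = c("common", "common", "rare", "rare"),
    x_r = c(1, -1, 1, -1),
    x_t = c(1, 1, -1, -1)
  )
  eta <- b[["(Intercept)"]] + b[["reward"]] * grid$x_r +
    b[["transition"]] * grid$x_t +
    b[["reward_x_transition"]] * grid$x_r * grid$x_t
  data.frame(grid[c("cell", "prev_outcome", "prev_transition")],
             stay_prob = stats::plogis(eta))
}

#' Check the transition/interaction coefficient relation
#'
#' For purely model-based agents on a task with fixed final-state reward
#' probabilities `p` (pink) and `b` (blue), the transition and
#' reward-by-transition coefficients of the basic stay regression satisfy
#' `b_t = (1 - p - b) * b_rxt`. This function measures the residual
#' `b_t - (1 - p - b) * b_rxt` on a fitted model and judges it against the
#' bootstrap distribution of the same quantity.
#'
#' If the interaction coefficient's own interval covers 0 the relation is
#' reported as untestable (both sides are indistinguishable from 0).
#'
#' @param fit A `stay_fit` fitted with a bootstrap (`n_boot > 0`).
#' @param p,b True reward probabilities of the pink and blue final states.
#' @param conf_level Interval coverage for the residual (default 0.95).
#' @return A list with `residual`, `ci` (bootstrap interval of the
#'   residual), `ratio` (`b_t / b_rxt`), `expected_ratio` (`1 - p - b`),
#'   `testable` and `pass`.
#' @export
coefficient_relation_check <- function(fit, p, b, conf_level = 0.95) {
  if (is.null(fit$boot)) stop("fit has no bootstrap replicates; refit with n_boot > 0")
  k <- 1 - p - b
  bt <- fit$coefficients[["transition"]]
  brt <- fit$coefficients[["reward_x_transition"]]
  res <- bt - k * brt
  a <- (1 - conf_level) / 2
  boot_res <- fit$boot[, "transition"] - k * fit$boot[, "reward_x_transition"]
  ci <- stats::quantile(boot_res, c(a, 1 - a), names = FALSE)
  brt_ci <- stats::quantile(fit$boot[, "reward_x_transition"],
                            c(a, 1 - a), names = FALSE)
  testable <- brt_ci[1] > 0 || brt_ci[2] < 0
  list(residual = res, ci = ci, ratio = bt / brt, expected_ratio = k,
       testable = testable, pass = testable && ci[1] <= 0 && ci[2] >= 0)
}
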