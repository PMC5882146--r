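test_that("trial encoding codes stay and previous-trial indicators correctly", {
  tr <- make_trials(choice = c("left", "left"),
                    final_state = c("pink", "blue"),
                    transition = c("common", "rare"),
                    reward = c(1L, 0L))
  d <- encode_trials(tr)
  expect_equal(nrow(d), 1L)
  expect_equal(d$stay, 1L)
  expect_equal(unlist(d[1, c("x_r", "x_t", "x_c", "x_f")]),
               c(x_r = 1, x_t = 1, x_c = 1, x_f = 1))

  tr2 <- make_trials(choice = c("left", "right"),
                     final_state = c("blue", "pink"),
                     transition = c("rare", "common"),
                     reward = c(0L, 1L))
  d2 <- encode_trials(tr2)
  expect_equal(d2$stay, 0L)
  expect_equal(unlist(d2[1, c("x_r", "x_t", "x_c", "x_f")]),
               c(x_r = -1, x_t = -1, x_c = 1, x_f = -1))
})

test_that("encoding drops the first trial of every session", {
  trials <- run_session(agent_params("model_free"), two_stage_task(), seed = 1)
  expect_equal(nrow(encode_trials(trials)), 249L)

  two <- rbind(make_trials(rep("left", 5), rep("pink", 5), rep("common", 5),
                           rep(1L, 5), agent_id = 1L),
               make_trials(rep("right", 5), rep("blue", 5), rep("common", 5),
                           rep(0L, 5), agent_id = 2L))
  d <- encode_trials(two)
  expect_equal(nrow(d), 8L)
  expect_equal(sum(d$agent_id == 1L), 4L)

  short <- make_trials("left", "pink", "common", 1L)
  expect_warning(d0 <- encode_trials(short), "fewer than 2")
  expect_equal(nrow(d0), 0L)
})

test_that("regression recovers generating coefficients and matches an unpenalized fit", {
  truth <- c("(Intercept)" = 0, reward = 1, transition = 0,
             reward_x_transition = 0)
  d <- simulate_design(truth, n = 100000L, seed = 21)
  fit <- fit_stay_regression(d, "basic", n_boot = 0)
  expect_equal(coef(fit), truth, tolerance = 0.05)

  # independent route: unpenalized maximum likelihood via glm
  d2 <- simulate_design(c("(Intercept)" = 0.3, reward = 0.8,
                          transition = -0.4, reward_x_transition = 0.5),
                        n = 20000L, seed = 22)
  ours <- coef(fit_stay_regression(d2, "basic", n_boot = 0))
  ml <- coef(glm(stay ~ x_r * x_t, binomial, d2))
  expect_equal(unname(ours),
               unname(ml[c("(Intercept)", "x_r", "x_t", "x_r:x_t")]),
               tolerance = 0.01)
})

test_that("null data yield near-zero slopes and separation stays finite", {
  set.seed(31)
  d <- simulate_design(c("(Intercept)" = 0.4, reward = 0, transition = 0,
                         reward_x_transition = 0), n = 30000L)
  fit <- fit_stay_regression(d, "basic", n_boot = 0)
  expect_lt(max(abs(coef(fit)[-1])), 0.05)

  # perfectly separated data: ridge keeps the estimate finite
  sep <- data.frame(agent_id = rep(1:10, each = 40),
                    x_r = rep(c(1, -1), 200),
                    x_t = rep(c(1, 1, -1, -1), 100),
                    x_c = 1, x_f = 1)
  sep$stay <- as.integer(sep$x_r == 1)
  fit_sep <- fit_stay_regression(sep, "basic", n_boot = 0)
  expect_true(all(is.finite(coef(fit_sep))))
  expect_gt(coef(fit_sep)[["reward"]], 2)

  expect_error(fit_stay_regression(sep[sep$stay == 1, ], "basic"),
               "single value")
})

test_that("extended model nests the basic model", {
  truth <- c("(Intercept)" = 0.2, reward = 0.7, transition = 0.1,
             reward_x_transition = 0.4)
  d <- simulate_design(truth, n = 60000L, seed = 41)
  basic <- fit_stay_regression(d, "basic", n_boot = 0)
  ext <- fit_stay_regression(d, "extended", n_boot = 0)
  expect_equal(names(coef(ext)),
               c(names(coef(basic)), "choice", "final_state"))
  # controls carry no signal here and shared coefficients agree
  expect_lt(max(abs(coef(ext)[c("choice", "final_state")])), 0.05)
  expect_equal(coef(ext)[names(coef(basic))], coef(basic), tolerance = 0.05)
})

test_that("permuting stay labels destroys all effects", {
  truth <- c("(Intercept)" = 0, reward = 1, transition = 0.5,
             reward_x_transition = 0.5)
  d <- simulate_design(truth, n = 40000L, seed = 51)
  d$stay <- sample(d$stay)
  fit <- fit_stay_regression(d, "extended", n_boot = 0)
  expect_lt(max(abs(coef(fit)[-1])), 0.05)
})

test_that("relabeling left/right and pink/blue flips only the control coefficients", {
  task <- two_stage_task(schedule = fixed_schedule(pink = 0.8, blue = 0.2))
  trials <- run_agents(agent_params("model_free", lambda = 0.6), task,
                       n_agents = 100, seed = 61)
  flipped <- trials
  flipped$choice <- c(left = "right", right = "left")[trials$choice]
  flipped$final_state <- c(pink = "blue", blue = "pink")[trials$final_state]
  f1 <- fit_stay_regression(encode_trials(trials), "extended", n_boot = 0)
  f2 <- fit_stay_regression(encode_trials(flipped), "extended", n_boot = 0)
  keep <- c("(Intercept)", "reward", "transition", "reward_x_transition")
  expect_equal(coef(f1)[keep], coef(f2)[keep], tolerance = 1e-6)
  expect_equal(coef(f1)[c("choice", "final_state")],
               -coef(f2)[c("choice", "final_state")], tolerance = 1e-6)
})

test_that("bootstrap intervals bracket the point estimate and cover the truth", {
  truth <- c("(Intercept)" = 0.3, reward = 0.8, transition = 0,
             reward_x_transition = 0.2)
  d <- simulate_design(truth, n = 30000L, n_agents = 60, seed = 71)
  fit <- fit_stay_regression(d, "basic", n_boot = 100, seed = 72)
  expect_true(all(fit$ci[, "low"] <= coef(fit)))
  expect_true(all(fit$ci[, "high"] >= coef(fit)))
  expect_true(all(fit$ci[, "low"] <= truth & truth <= fit$ci[, "high"]))
  expect_equal(dim(fit$boot), c(100L, 4L))
})

test_that("stay tables are the inverse-logit of the linear predictor", {
  all0 <- mock_stay_fit(c("(Intercept)" = 0, reward = 0, transition = 0,
                          reward_x_transition = 0))
  expect_equal(stay_table(all0)$stay_prob, rep(0.5, 4))

  rew <- mock_stay_fit(c("(Intercept)" = 0, reward = 1, transition = 0,
                         reward_x_transition = 0))
  tab <- stay_table(rew)
  expect_equal(tab$stay_prob[tab$cell %in% c("P_rc", "P_rr")],
               rep(plogis(1), 2))
  expect_equal(tab$stay_prob[tab$cell %in% c("P_uc", "P_ur")],
               rep(plogis(-1), 2))

  inter <- mock_stay_fit(c("(Intercept)" = 0, reward = 0, transition = 0,
                           reward_x_transition = 1))
  tab2 <- stay_table(inter)
  outer_cells <- tab2$cell %in% c("P_rc", "P_ur")
  expect_equal(tab2$stay_prob[outer_cells], rep(plogis(1), 2))
  expect_equal(tab2$stay_prob[!outer_cells], rep(plogis(-1), 2))
})

test_that("stay table cells increase with their generating coefficients", {
  base <- c("(Intercept)" = 0.2, reward = 0.5, transition = 0.1,
            reward_x_transition = 0.3)
  up <- base + c(0, 0.3, 0, 0)
  t1 <- stay_table(mock_stay_fit(base))
  t2 <- stay_table(mock_stay_fit(up))
  rewarded <- t1$prev_outcome == "rewarded"
  expect_true(all(t2$stay_prob[rewarded] >= t1$stay_prob[rewarded]))
  expect_true(all(t2$stay_prob[!rewarded] <= t1$stay_prob[!rewarded]))
})

test_that("coefficient relation check judges the residual against its bootstrap", {
  set.seed(81)
  boot <- cbind("(Intercept)" = rnorm(200, 0, 0.01),
                reward = rnorm(200, 0, 0.01),
                transition = rnorm(200, -0.3, 0.02),
                reward_x_transition = rnorm(200, 0.5, 0.02))
  fit <- mock_stay_fit(c("(Intercept)" = 0, reward = 0, transition = -0.3,
                         reward_x_transition = 0.5), boot = boot)
  chk <- coefficient_relation_check(fit, p = 0.8, b = 0.8)
  expect_true(chk$testable)
  expect_true(chk$pass)
  expect_equal(chk$expected_ratio, -0.6)
  expect_lt(abs(chk$residual), 0.05)

  # interaction indistinguishable from zero -> untestable
  boot2 <- boot
  boot2[, "reward_x_transition"] <- rnorm(200, 0, 0.1)
  fit2 <- mock_stay_fit(c("(Intercept)" = 0, reward = 0, transition = 0,
                          reward_x_transition = 0), boot = boot2)
  chk2 <- coefficient_relation_check(fit2, 0.8, 0.8)
  expect_false(chk2$testable)
  expect_false(chk2$pass)
})
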