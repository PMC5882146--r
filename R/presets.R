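#' Read a task configuration from a YAML/JSON file
#'
#' The file holds `common_transition_prob`, `n_final_actions`, `n_trials`
#' and a `schedule` block with a `kind` of `drifting`, `fixed` or `swap`
#' plus that kind's parameters. The shipped presets under
#' `system.file("extdata", "presets", package = "twostagesim")` are the
#' reference for the format.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A [two_stage_task()].
#' @export
read_task_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  task_from_list(cfg)
}

task_from_list <- function(cfg) {
  sc <- cfg$schedule
  if (is.null(sc$kind)) stop("task config: schedule$kind is required")
  schedule <- switch(sc$kind,
    drifting = drifting_schedule(
      init_low = sc$init_low %||% 0.25, init_high = sc$init_high %||% 0.75,
      step_sd = sc$step_sd %||% 0.025,
      bound_low = sc$bound_low %||% 0.25, bound_high = sc$bound_high %||% 0.75),
    fixed = fixed_schedule(pink = sc$pink, blue = sc$blue %||% sc$pink),
    swap = swap_schedule(high = sc$high %||% 0.8, low = sc$low %||% 0.2,
                         swap_prob = sc$swap_prob %||% 0.02,
                         refractory = sc$refractory %||% 10L),
    stop("unknown schedule kind: ", sc$kind)
  )
  two_stage_task(
    common_prob = cfg$common_transition_prob %||% 0.7,
    n_final_actions = cfg$n_final_actions %||% 2L,
    n_trials = cfg$n_trials %||% 250L,
    schedule = schedule
  )
}

#' Read agent parameters from a YAML/JSON file
#'
#' @param path Path to a file with fields `class`, `alpha`, `lambda`,
#'   `beta` and (for hybrids) `w`.
#' @return An [agent_params()].
#' @export
read_agent_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  agent_params(class = cfg$class, alpha = cfg$alpha %||% 0.5,
               lambda = cfg$lambda %||% 1, beta = cfg$beta %||% 5,
               w = cfg$w)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.preset_path <- function(name, what) {
  f <- system.file("extdata", "presets", paste0(what, "_", name, ".yaml"),
                   package = "twostagesim")
  if (f == "") stop("no ", what, " preset named \"", name, "\"")
  f
}

#' Shipped task presets
#'
#' Named task configurations for the six standard experiment panels plus
#' the probability-swap variants:
#' * `panel_a`, `panel_c_drift` alias — classic task, drifting rewards.
#' * `panel_b`, `panel_d`, `panel_e` — fixed rewards 0.8 (pink) / 0.2 (blue).
#' * `panel_c` — fixed rewards 0.5 / 0.5.
#' * `panel_f` — fixed rewards 0.8 / 0.8.
#' * `swap_slow`, `swap_fast` — one action per final state, 0.8/0.2
#'   probabilities swapped between states with probability 0.02 / 0.2
#'   (10-trial refractory).
#'
#' @param name Preset name.
#' @return A [two_stage_task()].
#' @examples
#' task_preset("panel_f")
#' @export
task_preset <- function(name) read_task_config(.preset_path(name, "task"))

#' Shipped agent presets
#'
#' `model_free` (alpha 0.5, lambda 1, beta 5), `model_free_trace`
#' (lambda 0.6), `model_based` and `hybrid` (w 0.5).
#'
#' @param name Preset name.
#' @return An [agent_params()].
#' @export
agent_preset <- function(name) read_agent_params(.preset_path(name, "agent"))
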