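#' Preset experiment specifications
#'
#' Bundles a task preset, the agent populations to simulate, and the
#' regression model to apply:
#'
#' | name      | task                  | agents                  | analysis |
#' |-----------|-----------------------|-------------------------|----------|
#' | `panel_a` | drifting rewards      | MF (lambda 1), MB       | basic    |
#' | `panel_b` | fixed 0.8 / 0.2       | MF (lambda 1), MB       | basic    |
#' | `panel_c` | fixed 0.5 / 0.5       | MF (lambda 1), MB       | basic    |
#' | `panel_d` | fixed 0.8 / 0.2       | MF (lambda 0.6), MB     | basic    |
#' | `panel_e` | fixed 0.8 / 0.2       | MF (lambda 1), MB       | extended |
#' | `panel_f` | fixed 0.8 / 0.8       | MF (lambda 1), MB       | basic    |
#' | `swap_slow`/`swap_fast` | swap 0.02 / 0.2 | MF (lambda 1)     | basic    |
#' | `analytic_grid`    | analytic grid only    | —                       | —        |
#'
#' @param name Experiment name.
#' @param n_agents Agents per population (default 1000).
#' @return An `experiment_spec` list with elements `name`, `task`,
#'   `agents` (named list of `agent_params`), `n_agents`, `analysis`.
#' @export
experiment_preset <- function(name, n_agents = 1000L) {
  panels <- c("panel_a", "panel_b", "panel_c", "panel_d", "panel_e",
              "panel_f", "swap_slow", "swap_fast", "analytic_grid")
  name <- match.arg(name, panels)
  if (name == "analytic_grid") {
    return(structure(list(name = "analytic_grid", task = NULL, agents = NULL,
                          n_agents = 0L, analysis = NULL),
                     class = "experiment_spec"))
  }
  mf <- if (name == "panel_d") agent_preset("model_free_trace") else
    agent_preset("model_free")
  agents <- if (name %in% c("swap_slow", "swap_fast"))
    list(model_free = mf)
  else
    list(model_free = mf, model_based = agent_preset("model_based"))
  structure(
    list(name = name, task = task_preset(name), agents = agents,
         n_agents = as.integer(n_agents),
         analysis = if (name == "panel_e") "extended" else "basic"),
    class = "experiment_spec"
  )
}

#' Run a full simulation-and-analysis experiment
#'
#' Simulates every agent population of the spec, encodes the trials, fits
#' the stay regression, and (optionally) writes all tables plus a JSON
#' manifest to `out_dir`. Re-running with the same seed reproduces the
#' outputs exactly. For the `analytic_grid` spec it evaluates the analytic grid
#' instead.
#'
#' Written files: `trials.csv` (columns `agent_class`, `agent_id`, `trial`,
#' `choice`, `final_state`, `transition`, `final_action`, `reward`),
#' `coefficients.csv`, `stay_tables.csv`, `manifest.json`.
#'
#' @param spec An `experiment_spec` from [experiment_preset()], or a preset
#'   name.
#' @param seed Master seed; one sub-seed per population and one for each
#'   bootstrap are derived from it.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param n_agents Optional override of the spec's population size.
#' @param n_boot Bootstrap resamples for the coefficient intervals.
#' @return Invisibly, a list with `trials`, `fits` (per agent class),
#'   `stay_tables`, `coefficients` (or `grid` for the analytic grid).
#' @examples
#' res <- run_experiment("panel_c", seed = 1, n_agents = 5, n_boot = 20)
#' res$coefficients
#' @export
run_experiment <- function(spec, seed, out_dir = NULL, n_agents = NULL,
                           n_boot = 200L) {
  if (is.character(spec)) spec <- experiment_preset(spec)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (spec$name == "analytic_grid") {
    grid <- transition_effect_grid()
    if (!is.null(out_dir)) {
      utils::write.csv(grid, file.path(out_dir, "transition_effect.csv"),
                       row.names = FALSE)
      .write_manifest(out_dir, spec, seed, n_boot = NA)
    }
    return(invisible(list(grid = grid)))
  }

  if (!is.null(n_agents)) spec$n_agents <- as.integer(n_agents)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2L * length(spec$agents))

  trials_all <- list()
  fits <- list()
  tables <- list()
  for (k in seq_along(spec$agents)) {
    cls <- names(spec$agents)[k]
    trials <- run_agents(spec$agents[[k]], spec$task, spec$n_agents,
                         seed = sub_seeds[2L * k - 1L])
    design <- encode_trials(trials)
    fit <- fit_stay_regression(design, model = spec$analysis,
                               n_boot = n_boot,
                               seed = sub_seeds[2L * k])
    trials_all[[cls]] <- cbind(agent_class = cls, trials)
    fits[[cls]] <- fit
    tables[[cls]] <- cbind(agent_class = cls, stay_table(fit))
  }

  trials_df <- do.call(rbind, trials_all)
  coefs <- do.call(rbind, Map(function(cls, f)
    cbind(agent_class = cls, as.data.frame(f)), names(fits), fits))
  stay_df <- do.call(rbind, tables)
  rownames(trials_df) <- rownames(coefs) <- rownames(stay_df) <- NULL

  if (!is.null(out_dir)) {
    utils::write.csv(trials_df, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(coefs, file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(stay_df, file.path(out_dir, "stay_tables.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, spec, seed, n_boot)
  }
  invisible(list(trials = trials_df, fits = fits, stay_tables = stay_df,
                 coefficients = coefs))
}

.write_manifest <- function(out_dir, spec, seed, n_boot) {
  manifest <- list(
    experiment = spec$name,
    seed = seed,
    n_agents = spec$n_agents,
    n_boot = n_boot,
    analysis = spec$analysis,
    task = if (!is.null(spec$task)) unclass_deep(spec$task),
    agents = if (!is.null(spec$agents)) lapply(spec$agents, unclass_deep),
    package_version = as.character(utils::packageVersion("twostagesim"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Compare the basic and extended regressions on the same rows
#'
#' Fits both stay-regression specifications to an identical design and
#' returns the paired coefficient table, the contrast that shows how the
#' extended model's controls absorb the spurious reward-by-transition
#' interaction of model-free agents on unequal-reward tasks.
#'
#' @param design A design data.frame from [encode_trials()].
#' @inheritParams fit_stay_regression
#' @return A data.frame of both models' coefficient tables (columns as in
#'   [as.data.frame.stay_fit()]).
#' @export
compare_specifications <- function(design, n_boot = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  basic <- fit_stay_regression(design, "basic", n_boot = n_boot,
                               seed = seeds[1])
  extended <- fit_stay_regression(design, "extended", n_boot = n_boot,
                                  seed = seeds[2])
  out <- rbind(as.data.frame(basic), as.data.frame(extended))
  rownames(out) <- NULL
  out
}
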