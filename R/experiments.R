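#' Run the preset experiments over multiple seeds
#'
#' Each `run_simN()` runs its preset task ([task_presets]) with one agent per
#' seed and returns the pooled per-trial trace together with a per-seed
#' summary tibble computed by the matching `summarize_simN()` function. The
#' summaries are pure functions of the trace, so any statistic can be
#' recomputed from an exported trace CSV.
#'
#' * sim 1 — goal-directed acquisition, arbitration disabled (`gd_only`).
#'   Summary: asymptotic action values and Pavlovian value per cue.
#' * sim 2 — Pavlovian interference with both controllers active. Summary:
#'   mean arbitration probability per quintile of each cue's trials.
#' * sim 3 — specific controllability. Summary: asymptotic controllability
#'   and arbitration probability per cue.
#' * sim 4 — learned helplessness: a short-trained (500 uncontrollable
#'   trials) and a long-trained (7000) agent per seed, yoked to the same
#'   environment draws. Summary: generalised controllability at the end of
#'   the uncontrollable block and mean arbitration probability in the novel
#'   controllable block, per agent.
#' * sim 5 — threat distance. Summary: mean arbitration probability per cue
#'   and delay level.
#'
#' "Asymptotic" always means the mean over the last quintile of a cue's
#' trials.
#'
#' @param seeds integer vector of master seeds (one agent per seed).
#' @param config an [agent_config()]; `run_sim1()` forces `gd_only`.
#' @param n_per_cue trials per cue for sims 1-3 and 5.
#' @param n_short,n_long uncontrollable-block lengths of the two sim-4 agents.
#' @param n_test length of the sim-4 controllable test block.
#' @param preserve_gc sim-4 ablation switch: `FALSE` resets generalised
#'   controllability at the context switch like every other learned quantity.
#' @param variant sim-5 contingency variant, see [task_sim5()].
#' @return An object of class `aversim_sim`: list with `sim`, `trace`
#'   (pooled tibble with a `seed` column, plus `agent` for sim 4), `summary`,
#'   `task` (or `tasks`), `config`, `seeds`.
#' @examples
#' s1 <- run_sim1(seeds = 1:2, n_per_cue = 100)
#' s1$summary
#' @name experiments
NULL

.run_seeds <- function(task, config, seeds) {
  purrr::map(seeds, function(s) {
    run_agent(task, config, seed = s)$trace |>
      dplyr::mutate(seed = as.integer(s), .before = 1)
  }) |>
    purrr::list_rbind()
}

.new_sim <- function(sim, trace, summary, task, config, seeds) {
  structure(
    list(
      sim = sim, trace = trace, summary = summary, task = task,
      config = config, seeds = seeds
    ),
    class = "aversim_sim"
  )
}

#' @rdname experiments
#' @export
run_sim1 <- function(seeds = 1:20, config = agent_config(), n_per_cue = 1000) {
  config$arbitration$gd_only <- TRUE
  task <- task_sim1(n_per_cue)
  trace <- .run_seeds(task, config, seeds)
  .new_sim("sim1", trace, summarize_sim1(trace), task, config, seeds)
}

#' @rdname experiments
#' @export
run_sim2 <- function(seeds = 1:20, config = agent_config(), n_per_cue = 1000) {
  task <- task_sim2(n_per_cue)
  trace <- .run_seeds(task, config, seeds)
  .new_sim("sim2", trace, summarize_sim2(trace), task, config, seeds)
}

#' @rdname experiments
#' @export
run_sim3 <- function(seeds = 1:20, config = agent_config(), n_per_cue = 1000) {
  task <- task_sim3(n_per_cue)
  trace <- .run_seeds(task, config, seeds)
  .new_sim("sim3", trace, summarize_sim3(trace), task, config, seeds)
}

#' @rdname experiments
#' @export
run_sim4 <- function(seeds = 1:20, config = agent_config(),
                     n_short = 500, n_long = 7000, n_test = 500,
                     preserve_gc = TRUE) {
  config$preserve_gc <- isTRUE(preserve_gc)
  tasks <- list(
    short = task_sim4(n_uncontrollable = n_short, n_test = n_test),
    long = task_sim4(n_uncontrollable = n_long, n_test = n_test)
  )
  trace <- purrr::imap(tasks, function(task, label) {
    .run_seeds(task, config, seeds) |>
      dplyr::mutate(agent = label, .before = 1)
  }) |>
    purrr::list_rbind()
  .new_sim("sim4", trace, summarize_sim4(trace), tasks, config, seeds)
}

#' @rdname experiments
#' @export
run_sim5 <- function(seeds = 1:20, config = agent_config(), n_per_cue = 1000,
                     variant = c("figure", "text")) {
  task <- task_sim5(n_per_cue, variant = variant)
  trace <- .run_seeds(task, config, seeds)
  .new_sim(task$name, trace, summarize_sim5(trace), task, config, seeds)
}

#' Per-seed summaries of experiment traces
#'
#' Pure functions of a per-trial trace tibble (as produced by [run_agent()],
#' with a `seed` column and, for sim 4, an `agent` column), so every reported
#' statistic can be recomputed from an exported CSV. Trials are split into
#' quintiles within each seed x cue (x agent) group by trial order;
#' "asymptotic" statistics are last-quintile means.
#'
#' @param trace a trace tibble.
#' @return A tibble of per-seed summary statistics (see [experiments]).
#' @name summaries
NULL

.with_quintile <- function(trace, ...) {
  trace |>
    dplyr::group_by(...) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(quintile = ceiling(5 * dplyr::row_number() / dplyr::n())) |>
    dplyr::ungroup()
}

#' @rdname summaries
#' @export
summarize_sim1 <- function(trace) {
  qcols <- grep("^q_", names(trace), value = TRUE)
  trace |>
    .with_quintile(.data$seed, .data$cue) |>
    dplyr::filter(.data$quintile == 5) |>
    dplyr::group_by(.data$seed, .data$cue) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(qcols), mean),
      pv = mean(.data$pv_post),
      .groups = "drop"
    )
}

#' @rdname summaries
#' @export
summarize_sim2 <- function(trace) {
  trace |>
    .with_quintile(.data$seed, .data$cue) |>
    dplyr::group_by(.data$seed, .data$cue, .data$quintile) |>
    dplyr::summarise(
      p_goal_directed = mean(.data$p_goal_directed),
      f_goal_directed = mean(.data$controller == "goal_directed"),
      pv = mean(.data$pv_post),
      .groups = "drop"
    )
}

#' @rdname summaries
#' @export
summarize_sim3 <- function(trace) {
  trace |>
    .with_quintile(.data$seed, .data$cue) |>
    dplyr::filter(.data$quintile == 5) |>
    dplyr::group_by(.data$seed, .data$cue) |>
    dplyr::summarise(
      sc = mean(.data$sc),
      p_goal_directed = mean(.data$p_goal_directed),
      f_goal_directed = mean(.data$controller == "goal_directed"),
      .groups = "drop"
    )
}

#' @rdname summaries
#' @export
summarize_sim4 <- function(trace) {
  gc_end <- trace |>
    dplyr::filter(.data$block == 1) |>
    dplyr::group_by(.data$agent, .data$seed) |>
    dplyr::slice_max(.data$trial, n = 1) |>
    dplyr::summarise(gc_end_block1 = .data$gc_post, .groups = "drop")
  block2 <- trace |>
    dplyr::filter(.data$block == 2) |>
    dplyr::group_by(.data$agent, .data$seed) |>
    dplyr::summarise(
      p_goal_directed_block2 = mean(.data$p_goal_directed),
      f_goal_directed_block2 = mean(.data$controller == "goal_directed"),
      .groups = "drop"
    )
  dplyr::left_join(gc_end, block2, by = c("agent", "seed"))
}

#' @rdname summaries
#' @export
summarize_sim5 <- function(trace) {
  trace |>
    dplyr::group_by(.data$seed, .data$cue, .data$delay_s) |>
    dplyr::summarise(
      p_goal_directed = mean(.data$p_goal_directed),
      f_goal_directed = mean(.data$controller == "goal_directed"),
      .groups = "drop"
    )
}

#' Run a preset experiment by name
#'
#' Thin dispatcher used by the command-line interface.
#'
#' @param sim one of `"sim1"` ... `"sim5"`.
#' @param ... passed to the matching runner.
#' @return An `aversim_sim` object.
#' @export
run_sim <- function(sim, ...) {
  runner <- switch(sim,
    sim1 = run_sim1, sim2 = run_sim2, sim3 = run_sim3,
    sim4 = run_sim4, sim5 = run_sim5,
    stop("unknown simulation: ", sim, call. = FALSE)
  )
  runner(...)
}

#' Sweep agent parameters over a grid
#'
#' Runs one preset experiment once per row of a parameter grid and stacks the
#' per-seed summaries, labelled by the grid values. Grid columns must be
#' names of [agent_config()] arguments (e.g. `temperature`, `alpha_gc`) or of
#' [arbitration_params()] weights (e.g. `w_tstd`).
#'
#' @param sim experiment name, as in [run_sim()].
#' @param grid data frame of parameter values, one sweep point per row.
#' @param seeds master seeds used at every sweep point.
#' @param ... passed on to the runner.
#' @return A tibble: the grid columns joined to each point's summary rows.
#' @export
run_sweep <- function(sim, grid, seeds = 1:5, ...) {
  grid <- tibble::as_tibble(grid)
  arb_names <- setdiff(names(formals(arbitration_params)), "gd_only")
  purrr::map(seq_len(nrow(grid)), function(i) {
    cfg_args <- as.list(grid[i, , drop = FALSE])
    arb_args <- cfg_args[names(cfg_args) %in% arb_names]
    cfg_args <- cfg_args[!names(cfg_args) %in% arb_names]
    cfg_args$arbitration <- do.call(arbitration_params, arb_args)
    config <- do.call(agent_config, cfg_args)
    res <- run_sim(sim, seeds = seeds, config = config, ...)
    dplyr::bind_cols(grid[rep(i, nrow(res$summary)), , drop = FALSE], res$summary)
  }) |>
    purrr::list_rbind()
}
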