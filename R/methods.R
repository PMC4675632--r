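#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Tidiers for runs and experiments
#'
#' `tidy()` on a single run returns its per-trial trace; on an experiment it
#' returns the per-seed summary (`type = "summary"`, default) or the pooled
#' trace (`type = "trace"`). `glance()` returns a one-row overview.
#'
#' @param x an `aversim_run` or `aversim_sim`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.aversim_run <- function(x, ...) {
  x$trace
}

#' @rdname tidy.aversim_run
#' @param type which tibble to return for an experiment.
#' @export
tidy.aversim_sim <- function(x, type = c("summary", "trace"), ...) {
  switch(match.arg(type),
    summary = x$summary,
    trace = x$trace
  )
}

#' @rdname tidy.aversim_run
#' @export
glance.aversim_run <- function(x, ...) {
  tibble::tibble(
    task = x$task$name,
    seed = x$seed,
    n_trials = nrow(x$trace),
    shock_rate = mean(x$trace$shock),
    p_goal_directed = mean(x$trace$p_goal_directed),
    f_goal_directed = mean(x$trace$controller == "goal_directed"),
    gc_final = x$agent$gc
  )
}

#' @rdname tidy.aversim_run
#' @export
glance.aversim_sim <- function(x, ...) {
  tibble::tibble(
    sim = x$sim,
    n_seeds = length(x$seeds),
    n_trials = nrow(x$trace),
    shock_rate = mean(x$trace$shock),
    p_goal_directed = mean(x$trace$p_goal_directed),
    f_goal_directed = mean(x$trace$controller == "goal_directed")
  )
}

#' @export
print.aversim_run <- function(x, ...) {
  cat("<aversim_run> task ", x$task$name, ", seed ", x$seed, ", ",
    nrow(x$trace), " trials\n",
    sep = ""
  )
  print(glance(x))
  invisible(x)
}

#' @export
print.aversim_sim <- function(x, ...) {
  cat("<aversim_sim> ", x$sim, ": ", length(x$seeds), " seeds, ",
    nrow(x$trace), " trials total\n",
    sep = ""
  )
  print(x$summary, n = 10)
  invisible(x)
}
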