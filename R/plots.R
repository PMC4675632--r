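#' Trailing moving average
#'
#' Mean of the current value and up to `window - 1` preceding ones; used to
#' smooth per-trial trajectories for plotting. Raw values are always kept in
#' the trace.
#'
#' @param x numeric vector.
#' @param window positive integer window length.
#' @return numeric vector of the same length as `x`.
#' @export
trailing_mean <- function(x, window = 25L) {
  stopifnot(window >= 1)
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - window, 0L)
  (cs[i + 1L] - cs[lo + 1L]) / (i - lo)
}

#' Plot learning trajectories from a trace
#'
#' Seed-averaged, trailing-moving-average trajectories of one or more trace
#' variables, split by cue. Trials are counted within each cue (trial rank),
#' since cues are interleaved randomly in most tasks.
#'
#' @param trace a trace tibble (with a `seed` column if multi-seed).
#' @param vars character vector of trace columns to plot (e.g. `"pv"`,
#'   `"p_goal_directed"`, `"sc"`, or `q_` columns).
#' @param window trailing-average window ([trailing_mean()]).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trace, vars = "p_goal_directed", window = 25L) {
  if (!"seed" %in% names(trace)) trace$seed <- 1L
  grouping <- intersect(c("agent", "seed", "cue"), names(trace))
  long <- trace |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(cue_trial = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(vars),
      names_to = "variable", values_to = "value"
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grouping, "seed"))),
      .data$variable, .data$cue_trial
    ) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop_last") |>
    dplyr::mutate(value = trailing_mean(.data$value, window)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cue_trial, y = .data$value, colour = .data$cue
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(red = "#c0392b", black = "#2c3e50")) +
    ggplot2::labs(x = "trial (within cue)", y = NULL, colour = "cue") +
    ggplot2::theme_minimal()
  facets <- intersect(c("variable", "agent"), names(long))
  if (length(vars) > 1 || "agent" %in% facets) {
    p <- p + ggplot2::facet_grid(
      rows = if ("variable" %in% facets && length(vars) > 1) ggplot2::vars(.data$variable) else NULL,
      cols = if ("agent" %in% facets) ggplot2::vars(.data$agent) else NULL,
      scales = "free_y"
    )
  }
  p
}

#' @export
autoplot.aversim_run <- function(object, vars = "p_goal_directed",
                                 window = 25L, ...) {
  plot_trajectories(object$trace, vars = vars, window = window)
}

#' Default plots for the preset experiments
#'
#' sim 1: action and Pavlovian values by cue; sim 2: arbitration probability
#' and Pavlovian value; sim 3: arbitration probability and specific
#' controllability; sim 4: generalised controllability and arbitration
#' probability per agent; sim 5: arbitration probability by cue and delay.
#'
#' @param object an `aversim_sim`.
#' @param window trailing-average window.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.aversim_sim <- function(object, window = 25L, ...) {
  trace <- object$trace
  qcols <- grep("^q_", names(trace), value = TRUE)
  sim <- sub("_.*$", "", object$sim)
  if (sim == "sim5") {
    means <- trace |>
      dplyr::group_by(.data$cue, .data$delay_s, .data$seed) |>
      dplyr::summarise(p = mean(.data$p_goal_directed), .groups = "drop")
    return(
      ggplot2::ggplot(means, ggplot2::aes(
        x = factor(.data$delay_s), y = .data$p, fill = .data$cue
      )) +
        ggplot2::geom_boxplot() +
        ggplot2::scale_fill_manual(values = c(red = "#c0392b", black = "#7f8c8d")) +
        ggplot2::labs(
          x = "signalled delay to shock (s)",
          y = "P(goal-directed control)", fill = "cue"
        ) +
        ggplot2::theme_minimal()
    )
  }
  vars <- switch(sim,
    sim1 = c(qcols, "pv"),
    sim2 = c("p_goal_directed", "pv"),
    sim3 = c("p_goal_directed", "sc"),
    sim4 = c("p_goal_directed", "gc"),
    c("p_goal_directed")
  )
  plot_trajectories(trace, vars = vars, window = window)
}
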