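#' Preset avoidance experiments
#'
#' Five contingency presets for the simulated-rat avoidance task: a red or
#' black visual cue is followed by a high tone plus shock (value -1) or a low
#' tone and no shock, depending on whether the rat presses a lever, pulls a
#' chain, or does nothing.
#'
#' * `task_sim1()` / `task_sim2()` — acquisition contingencies: with the red
#'   cue lever pressing always avoids shock; with the black cue chain pulling
#'   avoids shock 20% of the time; every other action is always punished.
#'   The two presets are identical; sim 1 is run with arbitration disabled
#'   (goal-directed control only) and sim 2 with both controllers active.
#' * `task_sim3()` — specific-controllability contrast: the red cue avoids
#'   shock 20% of the time whatever the action (uncontrollable); the black
#'   cue avoids 20% of the time with chain pulling only (controllable). Best
#'   attainable shock probability is 0.8 for both cues.
#' * `task_sim4()` — learned-helplessness design: an uncontrollable first
#'   block (red cue, shock 90% regardless of action) of `n_uncontrollable`
#'   trials, then a novel controllable context (black cue, chain pulling
#'   avoids shock 90% of the time, other actions 10%). Compare agents with
#'   500 vs 7000 uncontrollable trials.
#' * `task_sim5()` — threat-distance manipulation: the cue signals a shock
#'   delay of 3 or 30 s, sampled per trial. With `variant = "figure"` lever
#'   pressing under the red cue is punished 20% of the time and chain pulling
#'   under the black cue 40% of the time; `variant = "text"` makes red-cue
#'   lever pressing perfectly safe. The two published descriptions disagree;
#'   both are provided and never merged.
#'
#' @param n_per_cue expected trials per cue (total trials = 2 * `n_per_cue`;
#'   cues are sampled uniformly per trial).
#' @param n_uncontrollable trials in the uncontrollable first block of the
#'   helplessness design.
#' @param n_test trials in its controllable test block.
#' @param variant which published sim-5 contingency to use.
#' @return A [task_spec()].
#' @examples
#' task_sim1()
#' task_sim4(n_uncontrollable = 7000)
#' @name task_presets
NULL

.rat_cues <- c("red", "black")
.rat_actions <- c("lever_press", "chain_pull", "no_action")

.rat_p <- function(red, black) {
  rbind(red = red, black = black) |>
    `colnames<-`(.rat_actions)
}

.random_blocks <- function(n_total) {
  tibble::tibble(rule = "random", n_trials = as.integer(n_total))
}

#' @rdname task_presets
#' @export
task_sim1 <- function(n_per_cue = 1000) {
  task_spec(
    cues = .rat_cues, actions = .rat_actions,
    p_shock = .rat_p(red = c(0, 1, 1), black = c(1, 0.8, 1)),
    blocks = .random_blocks(2 * n_per_cue), name = "sim1"
  )
}

#' @rdname task_presets
#' @export
task_sim2 <- function(n_per_cue = 1000) {
  t <- task_sim1(n_per_cue)
  t$name <- "sim2"
  t
}

#' @rdname task_presets
#' @export
task_sim3 <- function(n_per_cue = 1000) {
  task_spec(
    cues = .rat_cues, actions = .rat_actions,
    p_shock = .rat_p(red = c(0.8, 0.8, 0.8), black = c(1, 0.8, 1)),
    blocks = .random_blocks(2 * n_per_cue), name = "sim3"
  )
}

#' @rdname task_presets
#' @export
task_sim4 <- function(n_uncontrollable = 500, n_test = 500) {
  task_spec(
    cues = .rat_cues, actions = .rat_actions,
    p_shock = .rat_p(red = c(0.9, 0.9, 0.9), black = c(0.9, 0.1, 0.9)),
    blocks = tibble::tibble(
      rule = c("red", "black"),
      n_trials = as.integer(c(n_uncontrollable, n_test)),
      novel_context = c(FALSE, TRUE)
    ),
    name = sprintf("sim4_block1_%d", n_uncontrollable)
  )
}

#' @rdname task_presets
#' @export
task_sim5 <- function(n_per_cue = 1000, variant = c("figure", "text")) {
  variant <- match.arg(variant)
  p_lp_red <- switch(variant, figure = 0.2, text = 0)
  task_spec(
    cues = .rat_cues, actions = .rat_actions,
    p_shock = .rat_p(red = c(p_lp_red, 1, 1), black = c(1, 0.4, 1)),
    delay_levels = c(3, 30),
    blocks = .random_blocks(2 * n_per_cue),
    name = if (variant == "figure") "sim5" else "sim5_textvariant"
  )
}
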