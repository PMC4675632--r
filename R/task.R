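#' Define a signalled-avoidance task
#'
#' Describes the contingencies of a cued avoidance experiment: on each trial a
#' visual cue is presented (optionally with a signalled delay to threat), the
#' agent emits one action, and a high or low auditory tone follows. The high
#' tone is perfectly coupled with delivery of an electric shock of value
#' `shock_value`; the low tone signals omission (value 0). Which tone occurs
#' is a single Bernoulli draw with probability `p_shock[cue, action]`.
#'
#' @param cues character vector of cue identifiers.
#' @param actions character vector of action identifiers.
#' @param p_shock data frame with columns `cue`, `action`, `p_shock` giving
#'   the probability of the shock tone for every (cue, action) pair, or a
#'   numeric matrix with cues as rows and actions as columns.
#' @param outcomes length-2 character vector; the first element is the tone
#'   coupled with shock, the second the safe tone.
#' @param shock_value scalar reinforcer for the shock outcome; must be
#'   negative. The safe outcome is always worth 0.
#' @param delay_levels numeric vector of threat delays in seconds sampled
#'   uniformly per trial, or `numeric(0)` when delay is not manipulated.
#' @param blocks data frame with columns `rule` (a cue identifier for a fixed
#'   cue, or `"random"` for uniform cue sampling), `n_trials`, and optionally
#'   `novel_context` (logical; a novel context triggers an agent reset at the
#'   block boundary, sparing only generalised controllability). Defaults to a
#'   single 1000-trial random-cue block.
#' @param name optional label for the task.
#' @return An object of class `task_spec`.
#' @examples
#' task <- task_spec(
#'   cues = c("red", "black"),
#'   actions = c("lever_press", "chain_pull", "no_action"),
#'   p_shock = expand.grid(
#'     cue = c("red", "black"), action = c("lever_press", "chain_pull", "no_action"),
#'     stringsAsFactors = FALSE
#'   ) |> transform(p_shock = c(0, 1, 1, 0.8, 1, 1))
#' )
#' task
#' @export
task_spec <- function(cues, actions, p_shock,
                      outcomes = c("high_tone", "low_tone"),
                      shock_value = -1,
                      delay_levels = numeric(0),
                      blocks = NULL,
                      name = "custom") {
  cues <- as.character(cues)
  actions <- as.character(actions)
  outcomes <- as.character(outcomes)
  if (length(outcomes) != 2) {
    stop("exactly two outcomes are required: the shock tone and the safe tone",
      call. = FALSE
    )
  }
  if (!is.numeric(shock_value) || length(shock_value) != 1 || shock_value >= 0) {
    stop("`shock_value` must be a single negative number", call. = FALSE)
  }
  if (any(delay_levels < 0)) {
    stop("`delay_levels` must be non-negative seconds", call. = FALSE)
  }

  pmat <- .as_p_shock_matrix(p_shock, cues, actions)
  if (any(is.na(pmat))) {
    stop("`p_shock` must cover every (cue, action) pair", call. = FALSE)
  }
  if (any(pmat < 0 | pmat > 1)) {
    stop("every `p_shock` entry must lie in [0, 1]", call. = FALSE)
  }

  if (is.null(blocks)) {
    blocks <- tibble::tibble(rule = "random", n_trials = 1000L)
  }
  blocks <- tibble::as_tibble(blocks)
  if (!all(c("rule", "n_trials") %in% names(blocks))) {
    stop("`blocks` needs columns `rule` and `n_trials`", call. = FALSE)
  }
  if (!"novel_context" %in% names(blocks)) {
    blocks$novel_context <- FALSE
  }
  bad <- setdiff(blocks$rule, c("random", cues))
  if (length(bad) > 0) {
    stop(
      "unknown block rule(s): ", paste(bad, collapse = ", "),
      " (must be \"random\" or a cue identifier)",
      call. = FALSE
    )
  }
  if (any(blocks$n_trials < 1)) stop("block trial counts must be >= 1", call. = FALSE)
  blocks$n_trials <- as.integer(blocks$n_trials)

  structure(
    list(
      cues = cues, actions = actions, outcomes = outcomes,
      p_shock = pmat, shock_value = shock_value,
      delay_levels = as.numeric(delay_levels),
      blocks = blocks, name = name
    ),
    class = "task_spec"
  )
}

.as_p_shock_matrix <- function(p_shock, cues, actions) {
  if (is.matrix(p_shock)) {
    pmat <- p_shock[cues, actions, drop = FALSE]
    dimnames(pmat) <- list(cues, actions)
    return(pmat)
  }
  df <- as.data.frame(p_shock)
  stopifnot(all(c("cue", "action", "p_shock") %in% names(df)))
  pmat <- matrix(NA_real_, length(cues), length(actions),
    dimnames = list(cues, actions)
  )
  for (i in seq_len(nrow(df))) {
    pmat[as.character(df$cue[i]), as.character(df$action[i])] <- df$p_shock[i]
  }
  pmat
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", x$name, "\n", sep = "")
  cat("  cues:    ", paste(x$cues, collapse = ", "), "\n", sep = "")
  cat("  actions: ", paste(x$actions, collapse = ", "), "\n", sep = "")
  cat(
    "  shock tone \"", x$outcomes[1], "\" worth ", x$shock_value,
    "; safe tone \"", x$outcomes[2], "\" worth 0\n",
    sep = ""
  )
  cat("  P(shock | cue, action):\n")
  print(x$p_shock)
  if (length(x$delay_levels) > 0) {
    cat("  delays (s): ", paste(x$delay_levels, collapse = ", "), "\n", sep = "")
  }
  cat(
    "  blocks: ", paste(sprintf("%s x %d", x$blocks$rule, x$blocks$n_trials),
      collapse = " | "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Total number of trials in a task
#' @param spec a [task_spec()].
#' @return integer trial count.
#' @export
n_trials <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  sum(spec$blocks$n_trials)
}

.block_of_trial <- function(spec, trial) {
  ends <- cumsum(spec$blocks$n_trials)
  which(trial <= ends)[1]
}

#' Present the stimulus for a trial
#'
#' Returns the cue dictated by the task's block schedule (fixed-cue blocks are
#' deterministic; `"random"` blocks sample uniformly over cues) and, when the
#' task manipulates threat delay, a delay sampled uniformly from
#' `delay_levels`.
#'
#' @param spec a [task_spec()].
#' @param trial 1-based trial number within the run.
#' @param rng an [rng_stream()] supplying the environment's randomness.
#' @return A list of class `trial_stimulus` with fields `cue`, `delay_s`
#'   (`NA` when delay is not manipulated), and `trial`.
#' @export
present_stimulus <- function(spec, trial, rng) {
  stopifnot(inherits(spec, "task_spec"))
  total <- n_trials(spec)
  if (trial < 1 || trial > total) {
    stop("`trial` must be in [1, ", total, "], got ", trial, call. = FALSE)
  }
  b <- .block_of_trial(spec, trial)
  rule <- spec$blocks$rule[b]
  cue <- if (rule == "random") {
    spec$cues[ceiling(stream_runif(rng) * length(spec$cues))]
  } else {
    rule
  }
  delay <- if (length(spec$delay_levels) > 0) {
    spec$delay_levels[ceiling(stream_runif(rng) * length(spec$delay_levels))]
  } else {
    NA_real_
  }
  structure(
    list(cue = cue, delay_s = delay, trial = as.integer(trial), block = b),
    class = "trial_stimulus"
  )
}

#' Resolve a trial: action in, tone and shock out
#'
#' Draws the shock tone with probability `p_shock[cue, action]`; tone and
#' shock are perfectly coupled, so a single Bernoulli draw decides both.
#'
#' @param spec a [task_spec()].
#' @param stimulus a `trial_stimulus` from [present_stimulus()], or a cue
#'   identifier.
#' @param action action identifier; must be one of `spec$actions`.
#' @param rng an [rng_stream()].
#' @return A list of class `trial_outcome` with fields `tone`, `shock`
#'   (logical), and `reinforcer` (`shock_value` or 0).
#' @export
environment_step <- function(spec, stimulus, action, rng) {
  stopifnot(inherits(spec, "task_spec"))
  cue <- if (inherits(stimulus, "trial_stimulus")) stimulus$cue else as.character(stimulus)
  if (!cue %in% spec$cues) {
    stop("unknown cue: ", cue, call. = FALSE)
  }
  if (!action %in% spec$actions) {
    stop("unknown action: ", action, call. = FALSE)
  }
  p <- spec$p_shock[cue, action]
  shock <- stream_runif(rng) < p
  structure(
    list(
      tone = spec$outcomes[if (shock) 1L else 2L],
      shock = shock,
      reinforcer = if (shock) spec$shock_value else 0
    ),
    class = "trial_outcome"
  )
}

#' Read or write a task specification as YAML
#'
#' Tasks serialise to a plain YAML file so experiment contingencies can be
#' versioned and edited outside R. The five preset experiments ship as YAML
#' under `system.file("extdata", package = "aversim")`.
#'
#' @param path file path.
#' @return `read_task_spec()` returns a [task_spec()]; `write_task_spec()`
#'   returns `path` invisibly.
#' @export
read_task_spec <- function(path) {
  y <- yaml::read_yaml(path)
  p <- do.call(rbind, lapply(y$p_shock, function(row) {
    data.frame(
      cue = row$cue, action = row$action, p_shock = row$p_shock,
      stringsAsFactors = FALSE
    )
  }))
  blocks <- do.call(rbind, lapply(y$blocks, function(b) {
    data.frame(
      rule = b$rule, n_trials = b$n_trials,
      novel_context = isTRUE(b$novel_context),
      stringsAsFactors = FALSE
    )
  }))
  task_spec(
    cues = unlist(y$cues), actions = unlist(y$actions), p_shock = p,
    outcomes = unlist(y$outcomes), shock_value = y$shock_value,
    delay_levels = if (is.null(y$delay_levels)) numeric(0) else unlist(y$delay_levels),
    blocks = blocks, name = if (is.null(y$name)) "custom" else y$name
  )
}

#' @rdname read_task_spec
#' @param spec a [task_spec()].
#' @export
write_task_spec <- function(spec, path) {
  stopifnot(inherits(spec, "task_spec"))
  grid <- expand.grid(
    cue = spec$cues, action = spec$actions,
    stringsAsFactors = FALSE
  )
  y <- list(
    name = spec$name,
    cues = as.list(spec$cues),
    actions = as.list(spec$actions),
    outcomes = as.list(spec$outcomes),
    shock_value = spec$shock_value,
    delay_levels = as.list(spec$delay_levels),
    p_shock = lapply(seq_len(nrow(grid)), function(i) {
      list(
        cue = grid$cue[i], action = grid$action[i],
        p_shock = as.numeric(spec$p_shock[grid$cue[i], grid$action[i]])
      )
    }),
    blocks = lapply(seq_len(nrow(spec$blocks)), function(i) {
      list(
        rule = spec$blocks$rule[i],
        n_trials = spec$blocks$n_trials[i],
        novel_context = spec$blocks$novel_context[i]
      )
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
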