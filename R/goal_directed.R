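#' Stimulus-action-outcome transition model
#'
#' The goal-directed controller's world model: a Hebbian count for every
#' (cue, action, outcome) triple, initialised at a pseudocount so that
#' conditional outcome probabilities are defined (and uniform) before any
#' experience. The outcome probability is the count normalised by the total
#' input for that (cue, action):
#' `P(o | c, a) = counts[c, a, o] / sum_o' counts[c, a, o']`.
#'
#' @param cues,actions,outcomes identifier vectors.
#' @param pseudocount positive initial count per triple.
#' @return An object of class `transition_model`.
#' @examples
#' m <- transition_model(c("red", "black"), c("lp", "cp", "dn"))
#' transition_probs(m)
#' @export
transition_model <- function(cues, actions,
                             outcomes = c("high_tone", "low_tone"),
                             pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be positive so probabilities stay defined", call. = FALSE)
  }
  counts <- array(
    pseudocount,
    dim = c(length(cues), length(actions), length(outcomes)),
    dimnames = list(cues, actions, outcomes)
  )
  structure(
    list(counts = counts, cues = cues, actions = actions, outcomes = outcomes),
    class = "transition_model"
  )
}

#' @rdname transition_model
#' @param model a `transition_model`.
#' @return `transition_probs()` returns a tibble with columns `cue`, `action`,
#'   `outcome`, `prob`; probabilities sum to 1 within each (cue, action).
#' @export
transition_probs <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  totals <- apply(model$counts, c(1, 2), sum)
  grid <- expand.grid(
    cue = model$cues, action = model$actions, outcome = model$outcomes,
    stringsAsFactors = FALSE
  )
  grid$prob <- mapply(
    function(c, a, o) model$counts[c, a, o] / totals[c, a],
    grid$cue, grid$action, grid$outcome
  )
  tibble::as_tibble(grid)
}

#' Strengthen one experienced transition
#'
#' Hebbian update: only the count of the triple actually experienced this
#' trial grows; derived probabilities renormalise automatically.
#'
#' @param model a [transition_model()].
#' @param cue,action,tone the experienced triple.
#' @param increment positive count increment (default 1).
#' @return The updated model.
#' @export
update_transition <- function(model, cue, action, tone, increment = 1) {
  stopifnot(inherits(model, "transition_model"))
  .check_id(cue, model$cues, "cue")
  .check_id(action, model$actions, "action")
  .check_id(tone, model$outcomes, "outcome")
  if (!is.numeric(increment) || increment <= 0) {
    stop("`increment` must be positive", call. = FALSE)
  }
  model$counts[cue, action, tone] <- model$counts[cue, action, tone] + increment
  model
}

.check_id <- function(x, pool, what) {
  if (length(x) != 1 || !x %in% pool) {
    stop("unknown ", what, ": ", paste(x, collapse = ","), call. = FALSE)
  }
  invisible(x)
}

#' Learned outcome values
#'
#' Expected value attached to each outcome (tone), learned by a single-step
#' temporal-difference rule on the reinforcer actually received. Values start
#' at 0 (no expectation before experience).
#'
#' @param outcomes outcome identifiers.
#' @return Named numeric vector of class `outcome_values`.
#' @export
outcome_values <- function(outcomes = c("high_tone", "low_tone")) {
  v <- stats::setNames(rep(0, length(outcomes)), outcomes)
  class(v) <- "outcome_values"
  v
}

#' Temporal-difference update of an outcome's value
#'
#' `v(tone) <- v(tone) + alpha_v * (reinforcer - v(tone))`. Outcomes are
#' terminal within a trial, so there is no bootstrapped successor term and the
#' rule coincides with a Rescorla-Wagner delta rule whose fixed point is the
#' mean reinforcer that follows the tone.
#'
#' @param values an [outcome_values()] vector.
#' @param tone the outcome experienced this trial.
#' @param reinforcer scalar reinforcer received.
#' @param alpha_v learning rate in (0, 1].
#' @return Updated `outcome_values`.
#' @export
update_outcome_value <- function(values, tone, reinforcer, alpha_v) {
  .check_rate(alpha_v, "alpha_v")
  .check_id(tone, names(values), "outcome")
  values[tone] <- values[tone] + alpha_v * (reinforcer - values[tone])
  values
}

.check_rate <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x > 1) {
    stop("`", what, "` must be a learning rate in (0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Fill the working-memory buffer with one expected value per action
#'
#' The planner simulates each candidate action in turn: the current action's
#' expected-outcome activations are read from the transition model, their
#' value-weighted sum is stored in the working-memory buffer, and the action
#' is inhibited so the next one can be simulated. After the serial sweep the
#' buffer holds `q(a) = sum_o P(o | cue, a) * v(o)` for every action.
#'
#' @param model a [transition_model()].
#' @param values an [outcome_values()] vector.
#' @param cue the presented cue; must be known to the model.
#' @return An object of class `action_value_buffer`: list with `q` (named
#'   numeric), `best_action`, `best_value`. Ties in the maximum are broken by
#'   action-list order.
#' @examples
#' m <- transition_model(c("red"), c("lp", "cp"))
#' v <- outcome_values()
#' v["high_tone"] <- -1
#' plan_values(m, v, "red")
#' @export
plan_values <- function(model, values, cue) {
  stopifnot(inherits(model, "transition_model"))
  .check_id(cue, model$cues, "cue")
  if (!identical(names(values), model$outcomes)) {
    stop("`values` must be defined over the model's outcomes", call. = FALSE)
  }
  q <- stats::setNames(numeric(length(model$actions)), model$actions)
  for (a in model$actions) { # serial simulate-inhibit-next sweep
    input <- model$counts[cue, a, ]
    out_activation <- input / sum(input)
    q[a] <- sum(out_activation * unclass(values))
  }
  best <- which.max(q) # first index wins ties: action-list order
  structure(
    list(q = q, best_action = names(q)[best], best_value = unname(q[best])),
    class = "action_value_buffer"
  )
}

#' Softmax plan selection
#'
#' Samples an action from the working-memory buffer with probabilities
#' proportional to `exp(q / temperature)`. The plan node's activation is the
#' buffer's maximum value even when the sampled action is not the best one.
#' Uses max-subtraction for numerical stability; identical to the naive
#' formula within 1e-12.
#'
#' @param buffer an [plan_values()] buffer.
#' @param temperature positive softmax temperature; lower is greedier.
#' @param rng an [rng_stream()].
#' @return An object of class `goal_directed_plan`: list with `action`,
#'   `activation` (= buffer maximum), and `choice_probs`.
#' @export
choose_plan <- function(buffer, temperature, rng) {
  stopifnot(inherits(buffer, "action_value_buffer"))
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("`temperature` must be a positive scalar", call. = FALSE)
  }
  p <- softmax_probs(buffer$q, temperature)
  u <- stream_runif(rng)
  idx <- min(findInterval(u, cumsum(p), left.open = TRUE) + 1L, length(p))
  structure(
    list(
      action = names(p)[idx],
      activation = buffer$best_value,
      choice_probs = p
    ),
    class = "goal_directed_plan"
  )
}

#' @rdname choose_plan
#' @param q named numeric vector of action values.
#' @return `softmax_probs()` returns the named probability vector.
#' @export
softmax_probs <- function(q, temperature) {
  z <- q / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
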