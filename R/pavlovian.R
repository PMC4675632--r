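#' Pavlovian controller state
#'
#' The Pavlovian subsystem attaches a learned value to each cue and triggers a
#' fixed innate response whose activation is proportional to that value
#' (proportionality constant 1, so the response activation is the signed cue
#' value itself — negative under threat). In the shipped experiments the
#' innate response to every cue is `"no_action"`, modelling freezing.
#'
#' @param cues cue identifiers.
#' @param innate_response single action identifier used for every cue, or a
#'   named character vector mapping each cue to its innate response. The map
#'   is fixed for the lifetime of a run; only values are learned.
#' @return An object of class `pavlovian_state` with fields `pv` (named
#'   numeric, initialised at 0) and `innate_response` (named character).
#' @examples
#' ps <- pavlovian_state(c("red", "black"))
#' pavlovian_react(ps, "red")
#' @export
pavlovian_state <- function(cues, innate_response = "no_action") {
  cues <- as.character(cues)
  if (length(innate_response) == 1 && is.null(names(innate_response))) {
    innate_response <- stats::setNames(rep(innate_response, length(cues)), cues)
  }
  if (!setequal(names(innate_response), cues)) {
    stop("`innate_response` must map every cue to an action", call. = FALSE)
  }
  structure(
    list(
      pv = stats::setNames(rep(0, length(cues)), cues),
      innate_response = innate_response[cues]
    ),
    class = "pavlovian_state"
  )
}

#' Innate reaction to a cue
#'
#' @param state a [pavlovian_state()].
#' @param cue the presented cue.
#' @return List with `action` (the cue's fixed innate response) and
#'   `activation` (the cue's current Pavlovian value; 0 for a neutral cue,
#'   negative for a threatening one).
#' @export
pavlovian_react <- function(state, cue) {
  stopifnot(inherits(state, "pavlovian_state"))
  .check_id(cue, names(state$pv), "cue")
  list(
    action = unname(state$innate_response[cue]),
    activation = unname(state$pv[cue])
  )
}

#' Update a cue's Pavlovian value
#'
#' Delta rule on the reinforcer actually received under the agent's own
#' behaviour: `pv(cue) <- pv(cue) + alpha_p * (reinforcer - pv(cue))`. The
#' fixed point is minus the realised shock frequency times the shock
#' magnitude under whatever policy the agent is actually emitting — not the
#' optimal policy's — which is what lets freezing feed the very value that
#' sustains it.
#'
#' @param state a [pavlovian_state()].
#' @param cue the presented cue.
#' @param reinforcer scalar reinforcer received this trial.
#' @param alpha_p learning rate in (0, 1].
#' @return Updated `pavlovian_state`.
#' @export
update_pv <- function(state, cue, reinforcer, alpha_p) {
  stopifnot(inherits(state, "pavlovian_state"))
  .check_id(cue, names(state$pv), "cue")
  .check_rate(alpha_p, "alpha_p")
  state$pv[cue] <- state$pv[cue] + alpha_p * (reinforcer - state$pv[cue])
  state
}
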