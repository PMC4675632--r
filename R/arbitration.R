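#' Arbitration parameters
#'
#' Coefficients of the instrumental-ability node. Instrumental ability is a
#' weighted sum of the goal-directed plan's activation, specific
#' controllability, the (signed) Pavlovian response activation, generalised
#' controllability, and threat distance; the probability that behaviour is
#' goal-directed rather than Pavlovian is the logistic of that sum.
#'
#' All five coefficients must be non-negative: each input is positively
#' related to instrumental ability, and the Pavlovian input carries its own
#' sign (it is the cue's Pavlovian value, at most 0 under purely aversive
#' reinforcement), so a stronger expected punishment lowers instrumental
#' ability through a positive coefficient.
#'
#' The defaults are the calibrated values under which the five preset
#' experiments jointly reproduce their expected qualitative patterns with one
#' shared configuration: unit weights on the plan value, Pavlovian input,
#' generalised controllability and threat distance, a raised weight on
#' specific controllability (2.5), and a positive intercept (2) that keeps an
#' untrained agent predominantly goal-directed.
#'
#' @param w_gdp,w_sc,w_pr,w_gc,w_tstd non-negative weights.
#' @param bias intercept of the logistic.
#' @param gd_only when `TRUE`, arbitration is bypassed and behaviour is always
#'   the goal-directed plan (used to study the planner in isolation).
#' @return An object of class `arbitration_params`.
#' @export
arbitration_params <- function(w_gdp = 1, w_sc = 2.5, w_pr = 1, w_gc = 1,
                               w_tstd = 1, bias = 2, gd_only = FALSE) {
  w <- c(w_gdp = w_gdp, w_sc = w_sc, w_pr = w_pr, w_gc = w_gc, w_tstd = w_tstd)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("all arbitration weights must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(
      w_gdp = w_gdp, w_sc = w_sc, w_pr = w_pr, w_gc = w_gc,
      w_tstd = w_tstd, bias = bias, gd_only = isTRUE(gd_only)
    ),
    class = "arbitration_params"
  )
}

#' Instrumental ability
#'
#' @param plan_activation the plan node's activation (the working-memory
#'   buffer's maximum value).
#' @param sc specific controllability ([compute_sc()]).
#' @param pr_activation signed Pavlovian response activation (the cue's
#'   Pavlovian value; \eqn{\le 0} under threat).
#' @param gc generalised controllability.
#' @param tstd threat-distance activation ([compute_tstd()]).
#' @param params an [arbitration_params()].
#' @return Scalar instrumental ability
#'   `bias + w_gdp*plan_activation + w_sc*sc + w_pr*pr_activation +
#'   w_gc*gc + w_tstd*tstd`.
#' @examples
#' compute_ia(-0.2, 1, -0.2, 0.5, 1.5, arbitration_params())
#' @export
compute_ia <- function(plan_activation, sc, pr_activation, gc, tstd, params) {
  stopifnot(inherits(params, "arbitration_params"))
  params$bias +
    params$w_gdp * plan_activation +
    params$w_sc * sc +
    params$w_pr * pr_activation +
    params$w_gc * gc +
    params$w_tstd * tstd
}

#' Select the emitted behaviour
#'
#' The probability that behaviour follows the goal-directed plan is
#' `plogis(ia)`; otherwise the innate Pavlovian reaction is emitted. A
#' literal "directly/inversely proportional" reading would not yield a
#' probability, so the logistic is used. With `params$gd_only` the plan is
#' emitted deterministically (no controller draw is consumed).
#'
#' @param ia instrumental ability ([compute_ia()]).
#' @param plan a [choose_plan()] result.
#' @param pav_action the innate Pavlovian action.
#' @param params an [arbitration_params()].
#' @param rng an [rng_stream()].
#' @return An object of class `behaviour_decision`: list with `ia`,
#'   `p_goal_directed`, `controller` (`"goal_directed"` or `"pavlovian"`),
#'   and `emitted_action`.
#' @export
select_behaviour <- function(ia, plan, pav_action, params, rng) {
  stopifnot(inherits(params, "arbitration_params"))
  p_gd <- stats::plogis(ia)
  if (params$gd_only) {
    goal_directed <- TRUE
  } else {
    goal_directed <- stream_runif(rng) < p_gd
  }
  structure(
    list(
      ia = ia,
      p_goal_directed = p_gd,
      controller = if (goal_directed) "goal_directed" else "pavlovian",
      emitted_action = if (goal_directed) plan$action else pav_action
    ),
    class = "behaviour_decision"
  )
}
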