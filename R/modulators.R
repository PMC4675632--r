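#' Specific controllability of the current stimulus
#'
#' The spread of the working-memory buffer: `max(q) - min(q)`. When one action
#' is clearly better than the others the stimulus is controllable and the
#' spread is large; when all actions are equally (in)effective the spread
#' collapses to zero.
#'
#' @param buffer an [plan_values()] buffer (or any named numeric vector of
#'   action values).
#' @return Non-negative scalar.
#' @examples
#' compute_sc(list(q = c(lp = 0, cp = -1, dn = -1)))
#' @export
compute_sc <- function(buffer) {
  q <- if (is.list(buffer)) buffer$q else buffer
  if (length(q) == 0) stop("empty action-value buffer", call. = FALSE)
  max(q) - min(q)
}

#' Generalised controllability
#'
#' A slow, stimulus-independent delta rule over the specific-controllability
#' signal: `gc <- gc + alpha_gc * (sc - gc)`. The result is an exponentially
#' weighted average of the agent's entire controllability history, which
#' persists across context switches; its depletion after long uncontrollable
#' experience is the model's account of learned helplessness.
#'
#' @param gc current generalised-controllability belief.
#' @param sc_observed this trial's specific controllability.
#' @param alpha_gc learning rate in (0, 1]; much slower than value learning so
#'   that the amount of uncontrollable training matters.
#' @return Updated scalar `gc`, always within the convex hull of its initial
#'   value and the observed `sc` history.
#' @export
update_gc <- function(gc, sc_observed, alpha_gc) {
  .check_rate(alpha_gc, "alpha_gc")
  gc + alpha_gc * (sc_observed - gc)
}

#' Threat-distance activation
#'
#' Converts the signalled temporal (or spatial) distance to threat into a
#' scalar activation. The default is linear, `tstd = scale * delay_s`, the
#' minimal reading of "activation corresponds to the distance"; an optional
#' saturating form `scale * delay / (1 + scale * delay)` bounds the channel
#' at 1 for very distal threats.
#'
#' @param delay_s non-negative seconds (or distance units) to threat.
#' @param scale positive conversion factor (activation per second).
#' @param saturating use the bounded form instead of the linear one.
#' @return Non-negative scalar activation; 0 means contact with the threat.
#' @examples
#' compute_tstd(30, scale = 0.05)
#' @export
compute_tstd <- function(delay_s, scale = 0.05, saturating = FALSE) {
  if (!is.numeric(delay_s) || length(delay_s) != 1 || is.na(delay_s) || delay_s < 0) {
    stop("`delay_s` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(scale) || scale <= 0) {
    stop("`scale` must be positive", call. = FALSE)
  }
  x <- scale * delay_s
  if (saturating) x / (1 + x) else x
}
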