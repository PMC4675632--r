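# Shared fixtures and independent oracles. Oracles are written as explicit
# elementwise arithmetic, independent of the package's vectorised paths.

# minimal one-cue task: deterministic safety for action "a", certain shock
# for "b"
tiny_task <- function(p_a = 0, p_b = 1, n = 10) {
  task_spec(
    cues = "cue",
    actions = c("a", "b"),
    p_shock = data.frame(
      cue = "cue", action = c("a", "b"), p_shock = c(p_a, p_b)
    ),
    blocks = data.frame(rule = "cue", n_trials = n)
  )
}

# brute-force expected value per action: explicit loop over outcomes using
# raw counts, no shared code with plan_values()
oracle_expectations <- function(counts, v, cue) {
  actions <- dimnames(counts)[[2]]
  outcomes <- dimnames(counts)[[3]]
  q <- setNames(numeric(length(actions)), actions)
  for (a in actions) {
    total <- 0
    for (o in outcomes) total <- total + counts[cue, a, o]
    s <- 0
    for (o in outcomes) s <- s + (counts[cue, a, o] / total) * v[o]
    q[a] <- s
  }
  q
}

# naive softmax, no max-subtraction
oracle_softmax <- function(q, temperature) {
  e <- exp(q / temperature)
  e / sum(e)
}

# exponentially weighted average of an sc history from a given prior
oracle_gc_trajectory <- function(prior, sc_history, alpha) {
  gc <- prior
  out <- numeric(length(sc_history))
  for (i in seq_along(sc_history)) {
    gc <- (1 - alpha) * gc + alpha * sc_history[i]
    out[i] <- gc
  }
  out
}

# default preset config used by the experiment checks
default_config <- function(...) agent_config(...)
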