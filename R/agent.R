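#' Agent configuration
#'
#' All tunable parameters of the simulated agent. Learning rates are per-trial
#' delta-rule steps; `temperature` controls softmax exploration (lower is
#' greedier); `gc_prior` is the optimistic initial generalised-controllability
#' belief (a zero prior would start agents helpless); `tstd_scale` converts
#' signalled seconds-to-threat into activation; `pseudocount` initialises the
#' transition model.
#'
#' @param alpha_v outcome-value learning rate in (0, 1].
#' @param alpha_p Pavlovian-value learning rate in (0, 1].
#' @param alpha_gc generalised-controllability learning rate in (0, 1]; kept
#'   far below the value-learning rates so that the *amount* of uncontrollable
#'   experience, not just its presence, determines helplessness.
#' @param temperature softmax temperature (> 0).
#' @param gc_prior initial generalised controllability.
#' @param tstd_scale threat-distance activation per second.
#' @param tstd_saturating use the saturating threat-distance form.
#' @param pseudocount initial transition count per (cue, action, outcome).
#' @param increment Hebbian count increment per experienced transition.
#' @param innate_response innate Pavlovian action (single id or named map per
#'   cue); the default models freezing.
#' @param arbitration an [arbitration_params()].
#' @param preserve_gc keep generalised controllability across novel-context
#'   resets (the model's default); `FALSE` is an ablation that makes a
#'   context switch equivalent to a brand-new agent.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(alpha_v = 0.1, alpha_p = 0.01, alpha_gc = 0.002,
                         temperature = 0.25, gc_prior = 0.6,
                         tstd_scale = 0.05, tstd_saturating = FALSE,
                         pseudocount = 1, increment = 1,
                         innate_response = "no_action",
                         arbitration = arbitration_params(),
                         preserve_gc = TRUE) {
  .check_rate(alpha_v, "alpha_v")
  .check_rate(alpha_p, "alpha_p")
  .check_rate(alpha_gc, "alpha_gc")
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("`temperature` must be positive", call. = FALSE)
  }
  stopifnot(inherits(arbitration, "arbitration_params"))
  structure(
    list(
      alpha_v = alpha_v, alpha_p = alpha_p, alpha_gc = alpha_gc,
      temperature = temperature, gc_prior = gc_prior,
      tstd_scale = tstd_scale, tstd_saturating = isTRUE(tstd_saturating),
      pseudocount = pseudocount, increment = increment,
      innate_response = innate_response, arbitration = arbitration,
      preserve_gc = isTRUE(preserve_gc)
    ),
    class = "agent_config"
  )
}

#' Create a fresh agent for a task
#'
#' @param task a [task_spec()].
#' @param config an [agent_config()].
#' @param seed master seed; environment and agent substreams are derived from
#'   it deterministically (and re-derived at each block boundary, so agents
#'   sharing a seed are yoked to the same environment draws within a block).
#' @return An object of class `aversion_agent`.
#' @export
new_agent <- function(task, config = agent_config(), seed = 1L) {
  stopifnot(inherits(task, "task_spec"), inherits(config, "agent_config"))
  structure(
    list(
      task = task, config = config, seed = as.integer(seed),
      model = transition_model(task$cues, task$actions, task$outcomes,
        pseudocount = config$pseudocount
      ),
      values = outcome_values(task$outcomes),
      pav = pavlovian_state(task$cues, config$innate_response),
      gc = config$gc_prior,
      trial = 0L, block = 0L,
      env_stream = NULL, agent_stream = NULL
    ),
    class = "aversion_agent"
  )
}

.enter_block <- function(agent, b) {
  agent$env_stream <- rng_stream(derive_seed(agent$seed, 11L, b))
  agent$agent_stream <- rng_stream(derive_seed(agent$seed, 23L, b))
  if (agent$block > 0L && isTRUE(agent$task$blocks$novel_context[b])) {
    agent <- context_switch_reset(agent, preserve_gc = agent$config$preserve_gc)
  }
  agent$block <- b
  agent
}

#' Reset an agent's knowledge at a context switch
#'
#' Entering a novel context resets everything the agent has learned —
#' transition counts, outcome values, Pavlovian values — to initial values.
#' Generalised controllability, being a context-independent belief, survives
#' the switch unless `preserve_gc = FALSE`, in which case the knowledge state
#' equals a freshly constructed agent's. The reset is idempotent.
#'
#' @param agent an [new_agent()] object.
#' @param preserve_gc keep the generalised-controllability belief.
#' @return The reset agent.
#' @export
context_switch_reset <- function(agent, preserve_gc = TRUE) {
  stopifnot(inherits(agent, "aversion_agent"))
  agent$model <- transition_model(
    agent$task$cues, agent$task$actions, agent$task$outcomes,
    pseudocount = agent$config$pseudocount
  )
  agent$values <- outcome_values(agent$task$outcomes)
  agent$pav <- pavlovian_state(agent$task$cues, agent$config$innate_response)
  if (!preserve_gc) agent$gc <- agent$config$gc_prior
  agent
}

#' Run one trial end-to-end
#'
#' Executes, in order: stimulus presentation, goal-directed planning and plan
#' selection, the Pavlovian reaction, the three modulators, arbitration,
#' action execution in the environment, and finally all learning updates.
#' Every update uses the pre-update state's predictions; nothing learned this
#' trial leaks into this trial's decisions.
#'
#' @param agent an [new_agent()] object (or one returned by a previous call).
#' @return A list with `agent` (updated) and `record`, a one-row tibble with
#'   the full trial trace (see [run_agent()] for the column schema).
#' @examples
#' ag <- new_agent(task_sim1(), seed = 7)
#' step <- run_trial(ag)
#' step$record
#' @export
run_trial <- function(agent) {
  stopifnot(inherits(agent, "aversion_agent"))
  task <- agent$task
  cfg <- agent$config
  t <- agent$trial + 1L
  if (t > n_trials(task)) {
    stop("task is exhausted after ", n_trials(task), " trials", call. = FALSE)
  }
  b <- .block_of_trial(task, t)
  if (b != agent$block) agent <- .enter_block(agent, b)

  stim <- present_stimulus(task, t, agent$env_stream)
  buffer <- plan_values(agent$model, agent$values, stim$cue)
  plan <- choose_plan(buffer, cfg$temperature, agent$agent_stream)
  pav <- pavlovian_react(agent$pav, stim$cue)
  sc <- compute_sc(buffer)
  tstd <- if (is.na(stim$delay_s)) {
    0
  } else {
    compute_tstd(stim$delay_s, cfg$tstd_scale, cfg$tstd_saturating)
  }
  ia <- compute_ia(plan$activation, sc, pav$activation, agent$gc, tstd, cfg$arbitration)
  decision <- select_behaviour(ia, plan, pav$action, cfg$arbitration, agent$agent_stream)
  outcome <- environment_step(task, stim, decision$emitted_action, agent$env_stream)

  gc_pre <- agent$gc
  pv_pre <- agent$pav$pv[stim$cue]
  agent$model <- update_transition(
    agent$model, stim$cue, decision$emitted_action, outcome$tone, cfg$increment
  )
  agent$values <- update_outcome_value(
    agent$values, outcome$tone, outcome$reinforcer, cfg$alpha_v
  )
  agent$pav <- update_pv(agent$pav, stim$cue, outcome$reinforcer, cfg$alpha_p)
  agent$gc <- update_gc(agent$gc, sc, cfg$alpha_gc)
  agent$trial <- t

  q <- as.list(buffer$q)
  names(q) <- paste0("q_", names(buffer$q))
  record <- tibble::tibble(
    trial = t, block = b, cue = stim$cue, delay_s = stim$delay_s,
    !!!q,
    plan_action = plan$action, plan_activation = plan$activation,
    pv = unname(pv_pre), sc = sc, gc = gc_pre, tstd = tstd,
    ia = ia, p_goal_directed = decision$p_goal_directed,
    controller = decision$controller, action = decision$emitted_action,
    tone = outcome$tone, shock = outcome$shock, reinforcer = outcome$reinforcer,
    pv_post = unname(agent$pav$pv[stim$cue]), gc_post = agent$gc,
    v_shock_post = unname(agent$values[task$outcomes[1]]),
    v_safe_post = unname(agent$values[task$outcomes[2]])
  )
  list(agent = agent, record = record)
}

#' Run an agent through a whole task
#'
#' Runs every trial of the task's block schedule and returns the complete
#' per-trial trace. The computation is identical, draw for draw, to iterating
#' [run_trial()]; this entry point just assembles the trace efficiently.
#'
#' The trace schema, one row per trial: `trial`, `block`, `cue`, `delay_s`,
#' one `q_<action>` column per action (pre-update action values), the chosen
#' plan (`plan_action`, `plan_activation`), the pre-update modulators (`pv`,
#' `sc`, `gc`, `tstd`), arbitration (`ia`, `p_goal_directed`, `controller`),
#' the emitted `action`, the outcome (`tone`, `shock`, `reinforcer`), and
#' post-update values (`pv_post`, `gc_post`, `v_shock_post`, `v_safe_post`).
#' `p_goal_directed` is the logistic arbitration probability; the realised
#' controller frequency can be taken from `controller`.
#'
#' @param task a [task_spec()].
#' @param config an [agent_config()].
#' @param seed master seed for the run.
#' @return An object of class `aversim_run`: list with `trace` (tibble),
#'   `agent` (final state), `task`, `config`, `seed`. [generics::tidy()]
#'   returns the trace, [generics::glance()] a one-row summary.
#' @examples
#' run <- run_agent(task_sim1(n_per_cue = 50), seed = 1)
#' dplyr::glimpse(run$trace)
#' @export
run_agent <- function(task, config = agent_config(), seed = 1L) {
  stopifnot(inherits(task, "task_spec"), inherits(config, "agent_config"))
  seed <- as.integer(seed)
  nC <- length(task$cues)
  nA <- length(task$actions)
  n <- n_trials(task)
  arb <- config$arbitration

  cnt <- array(config$pseudocount, dim = c(nC, nA, 2L))
  v <- c(0, 0) # outcome values: 1 = shock tone, 2 = safe tone
  pv <- rep(0, nC)
  gc <- config$gc_prior
  pmat <- task$p_shock # [cue, action]
  innate <- pavlovian_state(task$cues, config$innate_response)$innate_response
  innate_i <- match(unname(innate), task$actions)
  has_delay <- length(task$delay_levels) > 0
  nD <- length(task$delay_levels)
  block_end <- cumsum(task$blocks$n_trials)
  rule_i <- match(task$blocks$rule, task$cues) # NA means "random"
  temp <- config$temperature
  inc <- config$increment

  rec <- matrix(NA_real_, nrow = n, ncol = 21L + nA)
  b <- 0L
  block_start <- 0L
  eu <- au <- NULL # per-block batches of uniform draws, one row per trial
  for (t in seq_len(n)) {
    if (b == 0L || t > block_end[b]) {
      b <- b + 1L
      while (t > block_end[b]) b <- b + 1L
      block_start <- t - 1L
      nb <- block_end[b] - block_start
      # batch the block's draws; within-stream order (cue, delay, shock per
      # trial) is identical to drawing one uniform at a time
      env_per <- as.integer(is.na(rule_i[b])) + as.integer(has_delay) + 1L
      eu <- matrix(
        stream_runif(rng_stream(derive_seed(seed, 11L, b)), env_per * nb),
        nrow = nb, byrow = TRUE
      )
      agent_per <- 1L + as.integer(!arb$gd_only)
      au <- matrix(
        stream_runif(rng_stream(derive_seed(seed, 23L, b)), agent_per * nb),
        nrow = nb, byrow = TRUE
      )
      if (t > 1L && isTRUE(task$blocks$novel_context[b])) {
        cnt[] <- config$pseudocount
        v[] <- 0
        pv[] <- 0
        if (!config$preserve_gc) gc <- config$gc_prior
      }
    }
    tb <- t - block_start
    ecol <- 1L
    if (is.na(rule_i[b])) {
      ci <- ceiling(eu[tb, ecol] * nC)
      ecol <- ecol + 1L
    } else {
      ci <- rule_i[b]
    }
    if (has_delay) {
      delay <- task$delay_levels[ceiling(eu[tb, ecol] * nD)]
      ecol <- ecol + 1L
    } else {
      delay <- NA_real_
    }

    m1 <- cnt[ci, , 1L]
    m2 <- cnt[ci, , 2L]
    q <- (m1 * v[1L] + m2 * v[2L]) / (m1 + m2)
    best_i <- which.max(q)
    best_q <- q[best_i]

    z <- q / temp
    e <- exp(z - max(z))
    p <- e / sum(e)
    plan_i <- min(findInterval(au[tb, 1L], cumsum(p), left.open = TRUE) + 1L, nA)

    pr_act <- pv[ci]
    sc <- best_q - min(q)
    tstd <- if (is.na(delay)) {
      0
    } else {
      x <- config$tstd_scale * delay
      if (config$tstd_saturating) x / (1 + x) else x
    }
    ia <- arb$bias + arb$w_gdp * best_q + arb$w_sc * sc + arb$w_pr * pr_act +
      arb$w_gc * gc + arb$w_tstd * tstd
    p_gd <- stats::plogis(ia)
    goal_directed <- if (arb$gd_only) TRUE else au[tb, 2L] < p_gd
    act_i <- if (goal_directed) plan_i else innate_i[ci]

    shock <- eu[tb, ecol] < pmat[ci, act_i]
    tone_i <- if (shock) 1L else 2L
    r <- if (shock) task$shock_value else 0

    gc_pre <- gc
    pv_pre <- pv[ci]
    cnt[ci, act_i, tone_i] <- cnt[ci, act_i, tone_i] + inc
    v[tone_i] <- v[tone_i] + config$alpha_v * (r - v[tone_i])
    pv[ci] <- pv[ci] + config$alpha_p * (r - pv[ci])
    gc <- gc + config$alpha_gc * (sc - gc)

    rec[t, ] <- c(
      t, b, ci, delay, q, plan_i, best_q, pv_pre, sc, gc_pre, tstd, ia, p_gd,
      if (goal_directed) 1 else 2, act_i, tone_i, as.numeric(shock), r,
      pv[ci], gc, v[1L], v[2L]
    )
  }

  trace <- .trace_tibble(rec, task)
  agent <- new_agent(task, config, seed)
  agent$model$counts[] <- cnt
  agent$values[] <- v
  agent$pav$pv[] <- pv
  agent$gc <- gc
  agent$trial <- n
  agent$block <- b
  # reposition streams to where sequential consumption would have left them
  consumed <- n - block_start
  agent$env_stream <- rng_stream(derive_seed(seed, 11L, b))
  stream_runif(agent$env_stream, ncol(eu) * consumed)
  agent$agent_stream <- rng_stream(derive_seed(seed, 23L, b))
  stream_runif(agent$agent_stream, ncol(au) * consumed)
  structure(
    list(trace = trace, agent = agent, task = task, config = config, seed = seed),
    class = "aversim_run"
  )
}

.trace_tibble <- function(rec, task) {
  nA <- length(task$actions)
  qcols <- 5L:(4L + nA)
  k <- 4L + nA
  tibble::tibble(
    trial = as.integer(rec[, 1L]),
    block = as.integer(rec[, 2L]),
    cue = task$cues[rec[, 3L]],
    delay_s = rec[, 4L],
    !!!stats::setNames(
      lapply(qcols, function(j) rec[, j]),
      paste0("q_", task$actions)
    ),
    plan_action = task$actions[rec[, k + 1L]],
    plan_activation = rec[, k + 2L],
    pv = rec[, k + 3L],
    sc = rec[, k + 4L],
    gc = rec[, k + 5L],
    tstd = rec[, k + 6L],
    ia = rec[, k + 7L],
    p_goal_directed = rec[, k + 8L],
    controller = c("goal_directed", "pavlovian")[rec[, k + 9L]],
    action = task$actions[rec[, k + 10L]],
    tone = task$outcomes[rec[, k + 11L]],
    shock = rec[, k + 12L] > 0,
    reinforcer = rec[, k + 13L],
    pv_post = rec[, k + 14L],
    gc_post = rec[, k + 15L],
    v_shock_post = rec[, k + 16L],
    v_safe_post = rec[, k + 17L]
  )
}

#' Write a run's trace and metadata to disk
#'
#' The per-trial trace goes to `<path>.csv` with the documented column schema;
#' the full configuration, task, and seed go to a `<path>.json` sidecar so any
#' trace can be regenerated exactly.
#'
#' @param run an [run_agent()] result.
#' @param path output path without extension.
#' @return Invisibly, a character vector of the two files written.
#' @export
write_trace <- function(run, path) {
  stopifnot(inherits(run, "aversim_run"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(run$trace, csv, row.names = FALSE)
  meta <- list(
    package = "aversim",
    version = as.character(utils::packageVersion("aversim")),
    seed = run$seed,
    config = unclass(run$config)[setdiff(names(run$config), "arbitration")],
    arbitration = unclass(run$config$arbitration),
    task = list(
      name = run$task$name,
      cues = run$task$cues, actions = run$task$actions,
      outcomes = run$task$outcomes, shock_value = run$task$shock_value,
      delay_levels = run$task$delay_levels,
      p_shock = as.data.frame.table(run$task$p_shock,
        responseName = "p_shock", stringsAsFactors = FALSE
      ),
      blocks = as.data.frame(run$task$blocks)
    )
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, json))
}

#' Snapshot or restore an agent's learned state as JSON
#'
#' Serialises the knowledge state (transition counts, outcome values,
#' Pavlovian values, generalised controllability, trial counter) — not the
#' random-stream positions, so a restored agent is a checkpoint of what was
#' learned, not a resumable replay.
#'
#' @param agent an [new_agent()] object.
#' @param path JSON file path.
#' @return `write_agent_state()` returns `path` invisibly;
#'   `read_agent_state()` returns `agent` with the stored state applied.
#' @export
write_agent_state <- function(agent, path) {
  stopifnot(inherits(agent, "aversion_agent"))
  jsonlite::write_json(
    list(
      counts = agent$model$counts,
      values = as.numeric(agent$values),
      pv = as.numeric(agent$pav$pv),
      gc = agent$gc,
      trial = agent$trial
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_agent_state
#' @export
read_agent_state <- function(agent, path) {
  stopifnot(inherits(agent, "aversion_agent"))
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  agent$model$counts[] <- s$counts
  agent$values[] <- s$values
  agent$pav$pv[] <- s$pv
  agent$gc <- s$gc
  agent$trial <- as.integer(s$trial)
  agent
}
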