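test_that("agent_config validates its parameters", {
  expect_error(agent_config(alpha_v = 0), "learning rate")
  expect_error(agent_config(alpha_p = 2), "learning rate")
  expect_error(agent_config(alpha_gc = -0.1), "learning rate")
  expect_error(agent_config(temperature = 0), "positive")
})

test_that("a fresh agent starts symmetric and uninformed", {
  ag <- new_agent(task_sim1(n_per_cue = 10), seed = 5)
  step <- run_trial(ag)
  rec <- step$record
  qcols <- grep("^q_", names(rec), value = TRUE)
  expect_true(all(rec[qcols] == 0))
  expect_identical(rec$sc, 0)
  expect_identical(rec$pv, 0)
  expect_identical(rec$gc, ag$config$gc_prior)
  # with all q equal, plan choice is uniform across many fresh agents
  picks <- vapply(1:300, function(s) {
    run_trial(new_agent(task_sim1(n_per_cue = 10), seed = s))$record$plan_action
  }, character(1))
  freqs <- table(picks) / length(picks)
  expect_true(all(abs(freqs - 1 / 3) < 0.1))
})

test_that("recorded arbitration is internally consistent", {
  run <- run_agent(task_sim5(n_per_cue = 100), seed = 2)
  tr <- run$trace
  expect_equal(tr$p_goal_directed, plogis(tr$ia), tolerance = 1e-12)
  arb <- run$config$arbitration
  ia <- arb$bias + arb$w_gdp * tr$plan_activation + arb$w_sc * tr$sc +
    arb$w_pr * tr$pv + arb$w_gc * tr$gc + arb$w_tstd * tr$tstd
  expect_equal(tr$ia, ia, tolerance = 1e-12)
  expect_identical(
    tr$action,
    ifelse(tr$controller == "goal_directed", tr$plan_action, "no_action")
  )
  expect_identical(tr$shock, tr$tone == "high_tone")
  expect_identical(tr$reinforcer, ifelse(tr$shock, -1, 0))
})

test_that("run_agent reproduces trial-by-trial execution exactly", {
  task <- task_sim5(n_per_cue = 100)
  ag <- new_agent(task, agent_config(), seed = 3)
  recs <- vector("list", 200)
  for (i in 1:200) {
    step <- run_trial(ag)
    ag <- step$agent
    recs[[i]] <- step$record
  }
  stepwise <- dplyr::bind_rows(recs)
  batch <- run_agent(task, agent_config(), seed = 3)
  expect_equal(as.data.frame(stepwise), as.data.frame(batch$trace))
  # final learned state agrees too
  expect_equal(ag$model$counts, batch$agent$model$counts)
  expect_equal(ag$gc, batch$agent$gc)
  expect_equal(unclass(ag$values), unclass(batch$agent$values))
})

test_that("every decision uses pre-update knowledge only", {
  # two-phase oracle: recompute each trial's decision quantities from the
  # captured pre-trial state, then check the committed updates
  task <- task_sim2(n_per_cue = 50)
  ag <- new_agent(task, agent_config(), seed = 17)
  arb <- ag$config$arbitration
  for (i in 1:100) {
    pre <- ag
    step <- run_trial(ag)
    ag <- step$agent
    rec <- step$record
    q <- oracle_expectations(pre$model$counts, unclass(pre$values), rec$cue)
    expect_equal(unname(unlist(rec[paste0("q_", names(q))])), unname(q),
      tolerance = 1e-12
    )
    sc <- max(q) - min(q)
    ia <- arb$bias + arb$w_gdp * max(q) + arb$w_sc * sc +
      arb$w_pr * pre$pav$pv[rec$cue] + arb$w_gc * pre$gc
    expect_equal(rec$ia, unname(ia), tolerance = 1e-12)
    # commits: one count incremented, delta rules applied to pre-values
    expect_equal(
      ag$model$counts[rec$cue, rec$action, rec$tone],
      pre$model$counts[rec$cue, rec$action, rec$tone] + 1
    )
    expect_equal(sum(ag$model$counts), sum(pre$model$counts) + 1)
    expect_equal(
      unname(ag$pav$pv[rec$cue]),
      unname(pre$pav$pv[rec$cue] +
        ag$config$alpha_p * (rec$reinforcer - pre$pav$pv[rec$cue]))
    )
    expect_equal(ag$gc, pre$gc + ag$config$alpha_gc * (sc - pre$gc))
    expect_equal(
      unname(unclass(ag$values)[rec$tone]),
      unname(unclass(pre$values)[rec$tone] +
        ag$config$alpha_v * (rec$reinforcer - unclass(pre$values)[rec$tone]))
    )
  }
})

test_that("context switches reset knowledge but spare generalised controllability", {
  task <- task_sim4(n_uncontrollable = 50, n_test = 50)
  run <- run_agent(task, seed = 6)
  ag <- run$agent
  expect_gt(sum(ag$model$counts), length(ag$model$counts)) # learned something
  gc_before <- ag$gc
  reset <- context_switch_reset(ag)
  expect_identical(reset$gc, gc_before)
  expect_true(all(reset$model$counts == ag$config$pseudocount))
  expect_true(all(unclass(reset$values) == 0))
  expect_true(all(reset$pav$pv == 0))
  # idempotent
  expect_identical(
    context_switch_reset(reset)[c("model", "values", "pav", "gc")],
    reset[c("model", "values", "pav", "gc")]
  )
  # full reset equals a fresh agent's knowledge
  full <- context_switch_reset(ag, preserve_gc = FALSE)
  fresh <- new_agent(task, ag$config, seed = 1)
  expect_identical(
    full[c("model", "values", "pav", "gc")],
    fresh[c("model", "values", "pav", "gc")]
  )
  # the reset actually happened at the block-2 boundary during the run
  first_block2 <- dplyr::filter(run$trace, block == 2, trial == 51)
  expect_identical(first_block2$pv, 0)
  expect_true(all(first_block2[grep("^q_", names(first_block2))] == 0))
  expect_identical(first_block2$gc, run$trace$gc_post[50])
})

test_that("identical (config, seed) replays are bit-identical", {
  a <- run_agent(task_sim5(n_per_cue = 50), seed = 31)
  b <- run_agent(task_sim5(n_per_cue = 50), seed = 31)
  expect_identical(a$trace, b$trace)
  c <- run_agent(task_sim5(n_per_cue = 50), seed = 32)
  expect_false(identical(a$trace, c$trace))
})

test_that("traces and state snapshots round-trip through disk", {
  run <- run_agent(task_sim1(n_per_cue = 20), seed = 1)
  path <- withr::local_tempfile()
  files <- write_trace(run, path)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(files[1])
  expect_equal(nrow(back), nrow(run$trace))
  meta <- jsonlite::read_json(files[2])
  expect_identical(meta$seed, 1L)
  expect_identical(meta$task$name, "sim1")

  snap <- withr::local_tempfile(fileext = ".json")
  write_agent_state(run$agent, snap)
  blank <- new_agent(run$task, run$config, seed = 99)
  restored <- read_agent_state(blank, snap)
  expect_equal(restored$model$counts, run$agent$model$counts)
  expect_equal(unclass(restored$values), unclass(run$agent$values))
  expect_equal(restored$gc, run$agent$gc)
})
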