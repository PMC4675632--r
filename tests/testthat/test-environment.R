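test_that("task_spec validates its contingency table", {
  expect_error(tiny_task(p_a = 1.2), "\\[0, 1\\]")
  expect_error(
    task_spec("c", c("a", "b"),
      p_shock = data.frame(cue = "c", action = "a", p_shock = 0.5)
    ),
    "every \\(cue, action\\) pair"
  )
  expect_error(
    task_spec("c", "a",
      p_shock = data.frame(cue = "c", action = "a", p_shock = 0.5),
      shock_value = 1
    ),
    "negative"
  )
  expect_error(
    task_spec("c", "a",
      p_shock = data.frame(cue = "c", action = "a", p_shock = 0.5),
      outcomes = c("x", "y", "z")
    ),
    "two outcomes"
  )
  expect_error(
    task_spec("c", "a",
      p_shock = data.frame(cue = "c", action = "a", p_shock = 0.5),
      blocks = data.frame(rule = "nope", n_trials = 10)
    ),
    "unknown block rule"
  )
})

test_that("block schedule dictates the cue deterministically", {
  short <- task_sim4(n_uncontrollable = 500, n_test = 500)
  rng <- rng_stream(1)
  expect_identical(present_stimulus(short, 1, rng)$cue, "red")
  expect_identical(present_stimulus(short, 500, rng)$cue, "red")
  expect_identical(present_stimulus(short, 501, rng)$cue, "black")
  expect_identical(present_stimulus(short, 1000, rng)$cue, "black")
  expect_error(present_stimulus(short, 1001, rng), "must be in")
  expect_error(present_stimulus(short, 0, rng), "must be in")

  one <- tiny_task()
  stim <- present_stimulus(one, 1, rng)
  expect_identical(stim$cue, "cue")
  expect_true(is.na(stim$delay_s))
})

test_that("delays are sampled from the configured levels only", {
  task <- task_sim5(n_per_cue = 10)
  rng <- rng_stream(5)
  delays <- vapply(1:20, function(i) present_stimulus(task, i, rng)$delay_s, 1)
  expect_true(all(delays %in% c(3, 30)))
  expect_length(unique(delays), 2)
})

test_that("outcome, tone and reinforcer are perfectly coupled", {
  task <- task_sim1()
  rng <- rng_stream(2)
  for (i in 1:25) {
    out <- environment_step(task, "red", "lever_press", rng)
    expect_false(out$shock)
    expect_identical(out$tone, "low_tone")
    expect_identical(out$reinforcer, 0)
  }
  certain <- tiny_task(p_b = 1)
  for (i in 1:25) {
    out <- environment_step(certain, "cue", "b", rng)
    expect_true(out$shock)
    expect_identical(out$tone, "high_tone")
    expect_identical(out$reinforcer, -1)
  }
  expect_error(environment_step(task, "red", "jump", rng), "unknown action")
  expect_error(environment_step(task, "green", "lever_press", rng), "unknown cue")
})

test_that("empirical shock frequency concentrates at p_shock", {
  task <- task_sim1()
  rng <- rng_stream(11)
  n <- 10000
  p <- 0.8
  hits <- sum(vapply(
    seq_len(n),
    function(i) environment_step(task, "black", "chain_pull", rng)$shock,
    logical(1)
  ))
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("identical seeds give bit-identical environment sequences", {
  task <- task_sim5(n_per_cue = 25)
  draw_seq <- function(seed) {
    rng <- rng_stream(seed)
    lapply(1:50, function(i) {
      s <- present_stimulus(task, i, rng)
      o <- environment_step(task, s, "chain_pull", rng)
      list(s$cue, s$delay_s, o$shock)
    })
  }
  expect_identical(draw_seq(99), draw_seq(99))
  expect_false(identical(draw_seq(99), draw_seq(100)))
})

test_that("shipped YAML presets parse and match the constructors", {
  presets <- list(
    sim1.yaml = task_sim1(), sim2.yaml = task_sim2(), sim3.yaml = task_sim3(),
    sim4_short.yaml = task_sim4(500), sim4_long.yaml = task_sim4(7000),
    sim5.yaml = task_sim5(), sim5_textvariant.yaml = task_sim5(variant = "text")
  )
  for (file in names(presets)) {
    path <- system.file("extdata", file, package = "aversim")
    expect_true(nzchar(path), label = paste("preset shipped:", file))
    got <- read_task_spec(path)
    want <- presets[[file]]
    expect_identical(got$p_shock, want$p_shock, label = file)
    expect_identical(got$delay_levels, want$delay_levels, label = file)
    expect_identical(
      as.data.frame(got$blocks), as.data.frame(want$blocks),
      label = file
    )
  }
  # the two published sim-5 contingencies stay distinct
  fig <- read_task_spec(system.file("extdata", "sim5.yaml", package = "aversim"))
  txt <- read_task_spec(
    system.file("extdata", "sim5_textvariant.yaml", package = "aversim")
  )
  expect_identical(fig$p_shock["red", "lever_press"], 0.2)
  expect_identical(txt$p_shock["red", "lever_press"], 0)
})

test_that("task specs survive a YAML round trip", {
  task <- task_sim4(123, 45)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_task_spec(task, path)
  back <- read_task_spec(path)
  expect_identical(back$p_shock, task$p_shock)
  expect_identical(back$blocks$novel_context, task$blocks$novel_context)
  expect_identical(back$shock_value, task$shock_value)
})
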