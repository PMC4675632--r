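test_that("transition counts turn into normalised conditional probabilities", {
  m <- transition_model(c("red", "black"), c("lp", "cp", "dn"))
  probs <- transition_probs(m)
  expect_true(all(probs$prob == 0.5)) # uniform before any experience
  m <- update_transition(m, "red", "lp", "low_tone")
  probs <- transition_probs(m)
  p_low <- probs$prob[probs$cue == "red" & probs$action == "lp" &
    probs$outcome == "low_tone"]
  expect_equal(p_low, 2 / 3) # (1 + 1) / (1 + 2) with unit pseudocount
  # only the experienced row changed
  other <- probs[!(probs$cue == "red" & probs$action == "lp"), ]
  expect_true(all(other$prob == 0.5))
  # rows always renormalise
  sums <- tapply(probs$prob, paste(probs$cue, probs$action), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(update_transition(m, "red", "lp", "low_tone", increment = -1), "positive")
  expect_error(update_transition(m, "red", "nope", "low_tone"), "unknown action")
  expect_error(transition_model("c", "a", pseudocount = 0), "positive")
})

test_that("learned transition probabilities concentrate at the true rate", {
  task <- tiny_task(p_b = 0.8)
  m <- transition_model(task$cues, task$actions)
  rng <- rng_stream(4)
  for (i in 1:10000) {
    out <- environment_step(task, "cue", "b", rng)
    m <- update_transition(m, "cue", "b", out$tone)
  }
  p_hat <- m$counts["cue", "b", "high_tone"] / sum(m$counts["cue", "b", ])
  expect_lt(abs(p_hat - 0.8), 0.02)
})

test_that("plan_values equals the expectation sum", {
  m <- transition_model(c("red", "black"), c("lp", "cp", "dn"))
  v <- outcome_values()
  v["high_tone"] <- -1
  # certain safety: P(shock | red, lp) driven to ~0
  m$counts["red", "lp", ] <- c(1e-9, 1)
  buf <- plan_values(m, v, "red")
  expect_equal(unname(buf$q["lp"]), 0, tolerance = 1e-8)
  # hand-computed expectation: P(shock) = 0.8 against v = -1
  m$counts["black", "cp", ] <- c(8, 2)
  buf <- plan_values(m, v, "black")
  expect_equal(unname(buf$q["cp"]), -0.8)
  expect_error(plan_values(m, v, "green"), "unknown cue")
})

test_that("plan_values matches brute-force enumeration on random instances", {
  set.seed(42)
  for (i in 1:300) {
    nA <- sample(2:4, 1)
    m <- transition_model("c", paste0("a", seq_len(nA)))
    m$counts[] <- runif(length(m$counts), 0.01, 5)
    v <- outcome_values()
    v[] <- runif(2, -1, 0)
    buf <- plan_values(m, v, "c")
    want <- oracle_expectations(m$counts, unclass(v), "c")
    expect_equal(buf$q, want, tolerance = 1e-12)
    expect_identical(buf$best_action, names(want)[which.max(want)])
    expect_equal(buf$best_value, max(want))
  }
})

test_that("buffer ties break by action-list order and activation is the max", {
  m <- transition_model("c", c("a1", "a2"))
  v <- outcome_values() # all zero: every q ties at 0
  buf <- plan_values(m, v, "c")
  expect_identical(buf$best_action, "a1")
  expect_identical(buf$best_value, 0)
  plan <- choose_plan(buf, temperature = 1, rng_stream(1))
  expect_identical(plan$activation, 0) # buffer max, not the sampled action's q
})

test_that("softmax selection has the closed-form probabilities", {
  m <- transition_model("c", c("a1", "a2", "a3"))
  v <- outcome_values()
  buf <- plan_values(m, v, "c") # all equal
  plan <- choose_plan(buf, temperature = 0.25, rng_stream(1))
  expect_equal(unname(plan$choice_probs), rep(1 / 3, 3))

  buf$q <- c(a1 = 0, a2 = -1)
  expect_equal(
    unname(softmax_probs(buf$q, 1)["a1"]),
    exp(0) / (exp(0) + exp(-1))
  )
  # stability trick agrees with the naive formula
  set.seed(7)
  for (i in 1:50) {
    q <- runif(3, -2, 0)
    temp <- runif(1, 0.05, 2)
    expect_equal(softmax_probs(q, temp), oracle_softmax(q, temp),
      tolerance = 1e-12
    )
  }
  # greedy limit
  buf$q <- c(a1 = 0, a2 = -1, a3 = -1)
  picks <- vapply(
    1:200,
    function(i) choose_plan(buf, 1e-3, rng_stream(i))$action,
    character(1)
  )
  expect_true(all(picks == "a1"))
  expect_error(choose_plan(buf, 0, rng_stream(1)), "positive")
  expect_error(choose_plan(buf, -1, rng_stream(1)), "positive")
})

test_that("outcome values follow the one-step delta rule", {
  v <- outcome_values()
  v2 <- update_outcome_value(v, "high_tone", -1, alpha_v = 0.2)
  expect_equal(unname(v2["high_tone"]), -0.2)
  expect_equal(unname(v2["low_tone"]), 0) # untouched
  # zero prediction error
  v3 <- update_outcome_value(v2, "high_tone", -0.2, alpha_v = 0.2)
  expect_equal(unname(v3["high_tone"]), -0.2)
  # fixed point under repeated shocks
  v4 <- v
  for (i in 1:200) v4 <- update_outcome_value(v4, "high_tone", -1, 0.1)
  expect_equal(unname(v4["high_tone"]), -1, tolerance = 1e-6)
  expect_error(update_outcome_value(v, "high_tone", -1, 0), "learning rate")
  expect_error(update_outcome_value(v, "high_tone", -1, 1.5), "learning rate")
})
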