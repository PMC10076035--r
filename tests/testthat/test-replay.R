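track_memory <- function(length = 5, gamma = 0.5, strength = 0) {
  env <- build_linear_track(length)
  make_memory(env, similarity_dr(env, gamma), init_strength = strength)
}

test_that("visit strengthening increments exactly one experience by one", {
  mem <- track_memory()
  e <- exp_index(mem, 2L, "E")
  mem1 <- strengthen_on_visit(mem, e)
  expect_equal(mem1$C[e], 1)
  expect_equal(mem1$C[-e], mem$C[-e])
  for (i in 1:30) mem <- strengthen_on_visit(mem, e)
  expect_equal(mem$C[e], 30)
})

test_that("reward strengthening spreads by similarity to the rewarded state", {
  mem <- track_memory(strength = 1)
  e_r <- exp_index(mem, 4L, "E")  # lands on the rewarded terminal state
  expect_equal(strengthen_on_reward(mem, e_r, 0)$C, mem$C)

  m1 <- strengthen_on_reward(mem, e_r, 1)
  D <- mem$sim$D
  land <- mem$dst[e_r]
  expect_equal(m1$C - mem$C, D[, land][mem$src])
  ## experiences at the rewarded state receive the largest increment
  expect_equal(which.max(m1$C - mem$C) %in% exp_index(mem, land, 1:4), TRUE)

  ## modulation scales increments exactly
  m10 <- strengthen_on_reward(mem, e_r, 1, reward_modulation = 10)
  expect_equal(m10$C - mem$C, 10 * (m1$C - mem$C))
})

test_that("priority ratings combine strength, similarity and inhibition", {
  mem <- track_memory(strength = 1)
  e_t <- exp_index(mem, 3L, "E")
  ## uniform C, no inhibition: ratings equal the similarity column
  expect_equal(priority_ratings(mem, e_t, "default"),
               experience_similarity(mem$sim, mem, e_t, "default"))
  ## full inhibition and zero strength both null a rating
  mem$I[1] <- 1
  mem$C[2] <- 0
  R <- priority_ratings(mem, e_t, "default")
  expect_equal(R[1], 0)
  expect_equal(R[2], 0)
  expect_true(all(R >= 0))
})

test_that("customized softmax zeroes zero ratings and matches direct evaluation", {
  expect_equal(reactivation_probabilities(c(2, 2), 9), c(0.5, 0.5))
  expect_equal(reactivation_probabilities(c(3, 0), 9), c(1, 0))
  p <- reactivation_probabilities(c(1, 0.5), 9)
  expect_equal(p, c(expm1(9), expm1(4.5)) / (expm1(9) + expm1(4.5)))
  expect_equal(round(p, 4), c(0.9891, 0.0109))
  expect_equal(sum(p), 1)
  expect_error(reactivation_probabilities(c(0, 0), 9), "stop")
})

test_that("inhibition is keyed to the source state and decays geometrically", {
  env <- build_open_field(5, 5)
  mem <- make_memory(env, similarity_dr(env, 0.1), init_strength = 1)
  interior <- state_at(env, 2, 2)
  corner <- state_at(env, 0, 0)
  m1 <- inhibit(mem, exp_index(mem, interior, "N"))
  expect_equal(sum(m1$I == 1), 4L)
  expect_true(all(which(m1$I == 1) %in% exp_index(mem, interior, 1:4)))
  m2 <- inhibit(m1, exp_index(m1, corner, "S"))
  expect_equal(sum(m2$I == 1), 8L)
  ## decay
  for (k in 1:3) m2 <- decay_inhibition(m2, 0.9)
  expect_equal(max(m2$I), 0.9^3)
  expect_equal(min(m2$I), 0)
  expect_equal(max(decay_inhibition(m2, 0)$I), 0)
  expect_equal(max(reset_inhibition(m2)$I), 0)
})

test_that("online initiation samples proportional to strength at the state", {
  mem <- track_memory(10)
  mem$C[exp_index(mem, 5L, "N")] <- 3
  mem$C[exp_index(mem, 5L, "E")] <- 1
  set.seed(1)
  draws <- replicate(4000, init_online(mem, 5L))
  frac_n <- mean(draws == exp_index(mem, 5L, "N"))
  expect_equal(frac_n, 0.75, tolerance = 0.05)
  expect_true(all(draws %in% exp_index(mem, 5L, c("N", "E"))))
  expect_error(init_online(mem, 6L), "init-failure")
})

test_that("offline initiation samples proportional to global strength", {
  mem <- track_memory(3)
  e1 <- exp_index(mem, 1L, "E")
  e2 <- exp_index(mem, 2L, "E")
  mem$C[e1] <- 1
  mem$C[e2] <- 3
  set.seed(2)
  draws <- replicate(4000, init_offline(mem))
  expect_equal(mean(draws == e2), 0.75, tolerance = 0.05)
  mem$C[e2] <- 0
  expect_equal(unique(replicate(50, init_offline(mem))), e1)
  mem$C[e1] <- 0
  expect_error(init_offline(mem), "init-failure")
})

test_that("replay epochs respect length, determinism and the stop rule", {
  mem <- track_memory(10, strength = 1)
  cfg1 <- replay_config("default", max_steps = 1)
  tr <- generate_replay(mem, cfg1, exp_index(mem, 5L, "E"))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$s, 5L)

  cfg <- replay_config("default", max_steps = 20)
  set.seed(7)
  a <- generate_replay(mem, cfg, exp_index(mem, 5L, "E"))
  set.seed(7)
  b <- generate_replay(mem, cfg, exp_index(mem, 5L, "E"))
  expect_identical(a$exp, b$exp)

  ## an isolated strengthened experience stops replay immediately after
  ## its source state is inhibited
  mem0 <- track_memory(10, strength = 0)
  mem0$C[exp_index(mem0, 4L, "E")] <- 1
  tr0 <- generate_replay(mem0, cfg, exp_index(mem0, 4L, "E"))
  expect_equal(nrow(tr0), 1L)
  expect_equal(attr(tr0, "stop_reason"), "below_threshold")
})

test_that("a replay never repeats a source state on consecutive steps", {
  env <- build_open_field(8, 8)
  mem <- make_memory(env, similarity_dr(env, 0.5), init_strength = 1)
  cfg <- replay_config("default", lambda_decay = 0.9, max_steps = 60)
  set.seed(3)
  for (i in 1:5) {
    tr <- generate_replay(mem, cfg, init_online(mem, state_at(env, 4, 4)))
    expect_true(all(diff(tr$s) != 0))
  }
})

test_that("reverse-mode replay on a track is almost entirely reverse-ordered", {
  env <- build_linear_track(20)
  mem <- make_memory(env, similarity_dr(env, 0.1), init_strength = 1)
  cfg <- replay_config("reverse", max_steps = 10)
  set.seed(4)
  traces <- sfma:::generate_replays(mem, cfg, 30, init_states = rep(10L, 30))
  d <- directionality(traces)
  expect_gte(sum(d$reverse) / sum(d$forward + d$reverse + d$unordered), 0.9)
})

test_that("dynamic-mode switch follows the TD-error sigmoid", {
  expect_equal(p_reverse(0), 1 / (1 + exp(2)))
  expect_equal(round(p_reverse(0), 4), 0.1192)
  expect_equal(p_reverse(0.4), 0.5)
  expect_gt(p_reverse(100), 1 - 1e-10)
  expect_true(all(diff(p_reverse(seq(0, 2, 0.1))) > 0))

  cfg <- replay_config("dynamic")
  expect_error(choose_mode(replay_config("default"), 1), "dynamic")
  set.seed(5)
  frac <- mean(replicate(4000, choose_mode(cfg, 0)) == "reverse")
  expect_lt(abs(frac - p_reverse(0)), 0.02)
  set.seed(5)
  expect_equal(mean(replicate(200, choose_mode(cfg, 10)) == "reverse"), 1)
})

test_that("slower inhibition decay pushes the diffusion exponent above 1/2", {
  env <- build_open_field(30, 30)
  sim <- cached_dr(env, 0.5, "of30_05")
  center <- state_at(env, 15, 15)
  alpha_at <- function(lambda) {
    mem <- make_memory(env, sim, init_strength = 1)
    cfg <- replay_config("default", lambda_decay = lambda, max_steps = 300)
    traces <- sfma:::generate_replays(mem, cfg, 25, init_states = rep(center, 25))
    fit_power_law(traces, env, 1:30)$alpha
  }
  set.seed(6)
  a0 <- alpha_at(0)
  a5 <- alpha_at(0.5)
  a9 <- alpha_at(0.9)
  expect_lt(a0, a9)
  expect_lt(a0, a5 + 0.03)
  expect_lt(a5, a9 + 0.03)
  expect_equal(a0, 0.5, tolerance = 0.08)
})
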