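ballistic_traces <- function(env, n = 3, len = 20) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(trace = i, step = 1:len,
                   s = vapply(0:(len - 1), function(c) state_at(env, i, c),
                              integer(1)))
  }))
}

test_that("mean displacement: ballistic limit and empty intervals", {
  env <- build_open_field(30, 10)
  tr <- ballistic_traces(env)
  for (dt in c(1, 5, 10)) expect_equal(mean_displacement(tr, env, dt), dt)
  expect_error(mean_displacement(tr, env, 50), "empty-result")
})

test_that("power-law fit recovers ballistic and Brownian exponents", {
  env <- build_open_field(30, 10)
  fit <- fit_power_law(ballistic_traces(env), env, 1:10)
  expect_equal(fit$alpha, 1, tolerance = 1e-9)
  expect_equal(fit$G, 1, tolerance = 1e-9)

  ## independent lattice random-walk oracle, on an arena large enough that
  ## the walks never feel the borders
  big <- build_open_field(150, 150)
  set.seed(10)
  rw <- oracle_random_walk(big, n_traces = 30, n_steps = 1000,
                           start = state_at(big, 75, 75))
  fit_rw <- fit_power_law(rw, big, 1:40)
  expect_lt(abs(fit_rw$alpha - 0.5), 0.02)

  td <- tidy(fit_rw)
  expect_equal(td$term, c("alpha", "G"))
  gl <- glance(fit_rw)
  expect_equal(gl$n_traces, 30)
  expect_gt(gl$r.squared, 0.98)
})

test_that("displacement distributions normalize and spread with time", {
  big <- open_field_50()
  set.seed(11)
  rw <- oracle_random_walk(big, n_traces = 150, n_steps = 6,
                           start = state_at(big, 25, 25))
  dd <- displacement_distribution(rw, big, dt_set = 1:4, window = 25)
  sums <- tapply(dd$p, dd$dt, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  ## dt = 1 concentrates on the four adjacent offsets
  d1 <- dd[dd$dt == 1 & dd$p > 0, ]
  expect_true(all(abs(d1$drow) + abs(d1$dcol) == 1))
  ## second moment non-decreasing in dt
  m2 <- tapply(dd$p * (dd$drow^2 + dd$dcol^2), dd$dt, sum)
  expect_true(all(diff(m2) > -1e-12))
})

test_that("start and direction statistics behave for degenerate and uniform input", {
  env <- build_open_field(30, 10)
  east <- ballistic_traces(env, n = 5, len = 6)
  res <- start_and_direction_distributions(east, env, spatial_bin = 10)
  expect_true(all(res$directions$sector == 0))

  ## homogeneous strengths: replay starts uniformly, no preferred direction
  big <- open_field_50()
  sim <- cached_dr(big, 0.9, "of50_09")
  mem <- make_memory(big, sim, init_strength = 1)
  cfg <- replay_config("default", lambda_decay = 0.9, max_steps = 5)
  set.seed(12)
  traces <- sfma:::generate_replays(mem, cfg, 1000, init_states = NULL)
  res2 <- start_and_direction_distributions(traces, big, spatial_bin = 25)
  ## 4 spatial bins over a 50x50 field
  expect_gt(stats::chisq.test(res2$starts$n)$p.value, 0.01)
  ## directions: no preferred sector away from the borders (border starts are
  ## necessarily deflected inward)
  first_states <- vapply(split(traces$s, traces$trace), `[`, integer(1), 1L)
  central_ids <- which(big$coords[first_states, 1] %in% 5:44 &
                         big$coords[first_states, 2] %in% 5:44)
  central <- traces[traces$trace %in% central_ids, ]
  dirs <- start_and_direction_distributions(central, big, spatial_bin = 50)
  expect_gt(stats::chisq.test(dirs$directions$n)$p.value, 0.01)
})

test_that("directionality counts partition consecutive pairs", {
  env <- build_linear_track(10)
  mem <- make_memory(env, similarity_dr(env, 0.1), init_strength = 1)
  fwd <- sfma:::trace_from_steps(exp_index(mem, 1:5, "E"), mem, "default",
                                 "online", "max_steps")
  d <- directionality(fwd)
  expect_equal(d$forward, 4L)
  expect_equal(d$reverse, 0L)
  rev_tr <- fwd[5:1, ]
  rev_tr$step <- 1:5
  d2 <- directionality(rev_tr)
  expect_equal(d2$reverse, 4L)
  expect_equal(d2$score, -4L)
  ## partition property on random experience sequences
  set.seed(13)
  for (i in 1:20) {
    steps <- sample(mem$n_exp, 12)
    tr <- sfma:::trace_from_steps(steps, mem, "default", "online", "max_steps")
    d3 <- directionality(tr)
    expect_equal(d3$forward + d3$reverse + d3$unordered, 11L)
  }
})

test_that("template matching counts mismatches at the best offset", {
  tpl <- c(3L, 4L, 5L, 6L, 7L)
  expect_equal(match_template(c(1:10), tpl)$mismatches, 0L)
  expect_true(match_template(c(1:10), tpl)$match)
  seq2 <- c(3L, 9L, 5L, 9L, 7L)        # 2 substitutions
  expect_true(match_template(seq2, tpl)$match)
  seq3 <- c(9L, 9L, 5L, 9L, 7L)        # 3 substitutions
  expect_false(match_template(seq3, tpl)$match)
  expect_false(match_template(1:3, tpl)$match)  # template longer than sequence
})

test_that("shortcut detection finds the enumerated corner-pair patterns", {
  env <- build_figure_eight()
  tpls <- shortcut_templates(env)
  ## synthetic top-row crossing: up the left rail, across, down the right rail
  left_up <- vapply(2:0, function(r) state_at(env, r, 0), integer(1))
  top <- vapply(1:9, function(c) state_at(env, 0, c), integer(1))
  right_down <- vapply(0:2, function(r) state_at(env, r, 10), integer(1))
  crossing <- c(left_up, top, right_down)
  ev <- detect_shortcuts(crossing, env, tpls)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$first, "TL_backward")
  expect_equal(ev$second, "TR_forward")
  expect_equal(ev$separation, 9L)

  ## a pure right lap contains no shortcut
  lap <- sfma:::figure_eight_lap(env, env$start, "right")
  expect_equal(nrow(detect_shortcuts(lap, env, tpls)), 0L)

  ## stretching the crossing beyond 8 +/- 2 intervening states kills the event
  padded <- c(left_up, top[1:4], rep(top[4:5], 2), top[4:9], right_down)
  ev2 <- detect_shortcuts(padded, env, tpls)
  expect_true(nrow(ev2) == 0L || all(ev2$separation <= 10))
})

test_that("preplay classification assigns template families", {
  env <- build_t_maze(5, 3, TRUE)
  tpls <- preplay_templates(env, cued = "right")
  cued_path <- vapply(4:6, function(c) state_at(env, 0, c), integer(1))
  expect_equal(detect_preplay(c(cued_path, rev(cued_path)), tpls), "cued_arm")
  stem_path <- vapply(0:4, function(r) state_at(env, r, 3), integer(1))
  expect_equal(detect_preplay(c(stem_path, stem_path[4]), tpls), "stem")
  uncued <- vapply(2:0, function(c) state_at(env, 0, c), integer(1))
  expect_equal(detect_preplay(c(uncued, rev(uncued)), tpls), "uncued_arm")
})

test_that("reactivation maps are normalized occupancy fractions", {
  env <- build_open_field(4, 4)
  tr <- tibble::tibble(trace = 1L, step = 1:5, s = c(1L, 2L, 6L, 7L, 11L))
  m <- reactivation_map(tr, env)
  expect_equal(sum(m$fraction), 1)
  expect_equal(m$fraction[c(1, 2, 6, 7, 11)], rep(0.2, 5))
  expect_equal(sum(m$fraction > 0), 5L)
})

test_that("invalid transitions are consecutive reactivations across a barrier", {
  env <- build_open_field(4, 4)
  a <- state_at(env, 1, 1)
  b <- state_at(env, 1, 2)
  env2 <- gw_add_barriers(env, cbind(a, b))
  cross <- tibble::tibble(trace = 1L, step = 1:4, s = c(1L, a, b, a))
  expect_equal(invalid_transition_fraction(cross, env2), 2 / 3)
  stay <- tibble::tibble(trace = 1L, step = 1:3, s = c(1L, 2L, 3L))
  expect_equal(invalid_transition_fraction(stay, env2), 0)
  expect_equal(invalid_transition_fraction(cross, env), 0)  # no barriers
})

test_that("optimal-update scoring matches a brute-force gain oracle", {
  env <- build_linear_track(6)
  mem <- make_memory(env, similarity_dr(env, 0.1), init_strength = 1)
  q <- make_q(env)

  ## all-zero Q, no rewards: every gain is zero, all ties, all optimal
  mem0 <- mem
  mem0$rew[] <- 0
  tr0 <- sfma:::trace_from_steps(exp_index(mem0, c(2L, 3L), "E"), mem0,
                                 "default", "online", "max_steps")
  expect_true(all(optimal_update_fraction(tr0, mem0, q)$optimal))

  ## one rewarded transition: it is the unique gain maximizer (oracle check)
  gains <- vapply(seq_len(mem$n_exp), function(e) {
    oracle_gain(q$values, mem$src[e], mem$act[e], mem$rew[e], mem$dst[e],
                q$gamma, q$eta)
  }, numeric(1))
  rewarded <- exp_index(mem, 5L, "E")
  expect_gt(gains[rewarded], 0)
  expect_true(rewarded %in% which(gains == max(gains)))
  expect_equal(gains[exp_index(mem, 2L, "E")], 0)
  tr1 <- sfma:::trace_from_steps(rewarded, mem, "default", "online",
                                 "max_steps")
  expect_true(optimal_update_fraction(tr1, mem, q)$optimal[1])
  tr2 <- sfma:::trace_from_steps(exp_index(mem, 2L, "E"), mem, "default",
                                 "online", "max_steps")
  expect_false(optimal_update_fraction(tr2, mem, q)$optimal[1])
})
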