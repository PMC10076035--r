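## Protocol runners. Each runner is deterministic given the R RNG state; set
## a seed before calling (the CLI does this from --seed).

#' Heterogeneous experience-strength profile
#'
#' Strength 1 at the environment's center cell, decreasing linearly with
#' Euclidean distance to half the maximum at the farthest border cell.
#'
#' @param env a grid world.
#' @return Numeric vector over states.
#' @export
heterogeneous_strengths <- function(env) {
  center <- state_at(env, env$height %/% 2L, env$width %/% 2L)
  d <- sqrt((env$coords[, 1] - env$coords[center, 1])^2 +
              (env$coords[, 2] - env$coords[center, 2])^2)
  1 - 0.5 * d / max(d)
}

#' Random-walk replay protocol
#'
#' Generates default-mode replays from the center of an open field for every
#' cell of a (gamma_dr, lambda) grid and fits the diffusion power law per
#' cell. Strengths are homogeneous (C = 1) or heterogeneous (peaked at the
#' center, halved at the borders).
#'
#' @param size side length of the square open field.
#' @param gammas,lambdas parameter grids.
#' @param n_replays,replay_length epochs and epoch length.
#' @param strengths "homogeneous" or "heterogeneous".
#' @param beta_m softmax inverse temperature.
#' @param dt_range time intervals for the power-law fit.
#' @return Tibble: strengths, gamma_dr, lambda, alpha, G.
#' @export
run_random_walk <- function(size = 50L,
                            gammas = c(0.01, 0.5, 0.9),
                            lambdas = c(0.0, 0.5, 0.9),
                            n_replays = 50L, replay_length = 500L,
                            strengths = c("homogeneous", "heterogeneous"),
                            beta_m = 9, dt_range = 1:50) {
  strengths <- match.arg(strengths)
  env <- build_open_field(size, size)
  center <- state_at(env, size %/% 2L, size %/% 2L)
  C <- if (strengths == "homogeneous") rep(1, env$n_states) else heterogeneous_strengths(env)
  out <- list()
  for (g in gammas) {
    sim <- similarity_dr(env, g)
    memory <- make_memory(env, sim)
    memory$C <- C[memory$src]
    for (l in lambdas) {
      config <- replay_config("default", beta_m = beta_m, lambda_decay = l,
                              max_steps = replay_length)
      traces <- generate_replays(memory, config, n_replays,
                                 init_states = rep(center, n_replays))
      fit <- fit_power_law(traces, env, dt_range)
      out[[length(out) + 1L]] <- tibble::tibble(
        strengths = strengths, gamma_dr = g, lambda = l,
        alpha = fit$alpha, G = fit$G
      )
    }
  }
  dplyr::bind_rows(out)
}

## ---- figure-eight scripted running ----------------------------------------

## Coordinate path between two cells along a straight rail.
straight_path <- function(env, r1, c1, r2, c2) {
  if (r1 == r2) {
    cols <- if (c2 >= c1) c1:c2 else c1:c2
    vapply(cols, function(c) state_at(env, r1, c), integer(1))
  } else {
    rows <- r1:r2
    vapply(rows, function(r) state_at(env, r, c1), integer(1))
  }
}

## State path of one lap ending at `side`'s reward, starting from the given
## bottom-row state (S or either reward site).
figure_eight_lap <- function(env, from_state, side) {
  h <- env$height - 1L
  w <- env$width - 1L
  mid <- w %/% 2L
  from_col <- env$coords[from_state, 2]
  p <- straight_path(env, h, from_col, h, mid)                # bottom to S
  p <- c(p, straight_path(env, h, mid, 0L, mid)[-1])          # up the stem
  if (side == "right") {
    p <- c(p, straight_path(env, 0L, mid, 0L, w)[-1])         # top east
    p <- c(p, straight_path(env, 0L, w, h, w)[-1])            # right rail down
    p <- c(p, straight_path(env, h, w, h, w - 2L)[-1])        # to right reward
  } else {
    p <- c(p, straight_path(env, 0L, mid, 0L, 0L)[-1])
    p <- c(p, straight_path(env, 0L, 0L, h, 0L)[-1])
    p <- c(p, straight_path(env, h, 0L, h, 2L)[-1])
  }
  p
}

## Walk a scripted state path: visit strengthening plus a reward event when
## a rewarded state is entered.
script_path <- function(memory, path, reward_modulation = 1) {
  env <- memory$env
  for (i in seq_len(length(path) - 1L)) {
    s <- path[i]
    sn <- path[i + 1L]
    a <- which(env$trans[s, ] == sn)[1]
    e <- (s - 1L) * 4L + a
    memory <- strengthen_on_visit(memory, e)
    r <- env$rewards[sn]
    if (r != 0) memory <- strengthen_on_reward(memory, e, r, reward_modulation)
  }
  memory
}

#' Shortcut replay protocol
#'
#' Scripted lap running on the figure-eight maze (20 trials per session:
#' 10 trials of the first pattern, 10 of the second), with replays generated
#' at the just-visited reward site after every trial and screened for
#' shortcut events.
#'
#' @param condition "right-left", "right-alternating", "alternating-left" or
#'   "alternating-alternating".
#' @param betas softmax inverse temperatures to sweep.
#' @param trials trials per session.
#' @param replays_per_trial replays generated after each trial.
#' @param replay_length epoch length.
#' @param mode replay mode.
#' @param gamma_dr,lambda_decay similarity and inhibition parameters.
#' @return Tibble: condition, beta_m, trial, side, shortcuts.
#' @export
run_shortcut <- function(condition = "right-left",
                         betas = c(5, 9, 15), trials = 20L,
                         replays_per_trial = 200L, replay_length = 50L,
                         mode = "default", gamma_dr = 0.1,
                         lambda_decay = 0.9) {
  env <- build_figure_eight()
  sides <- condition_sides(condition, trials)
  sim <- similarity_dr(env, gamma_dr)
  templates <- shortcut_templates(env)
  out <- list()
  for (beta in betas) {
    memory <- make_memory(env, sim)
    config <- replay_config(mode, beta_m = beta, lambda_decay = lambda_decay,
                            max_steps = replay_length)
    pos <- env$start
    for (tr in seq_len(trials)) {
      path <- figure_eight_lap(env, pos, sides[tr])
      memory <- script_path(memory, path)
      pos <- path[length(path)]
      traces <- generate_replays(memory, config, replays_per_trial,
                                 init_states = rep(pos, replays_per_trial))
      n_sc <- sum(vapply(split(traces$s, traces$trace), function(v) {
        nrow(detect_shortcuts(v, env, templates))
      }, numeric(1)))
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = condition, beta_m = beta, trial = tr,
        side = sides[tr], shortcuts = n_sc
      )
    }
  }
  dplyr::bind_rows(out)
}

condition_sides <- function(condition, trials) {
  half <- trials %/% 2L
  first <- switch(substr(condition, 1, 5),
                  "right" = rep("right", half),
                  "alter" = rep(c("right", "left"), length.out = half))
  second_kind <- sub(".*-", "", condition)
  second <- switch(second_kind,
                   "left" = rep("left", trials - half),
                   "alternating" = {
                     start <- if (first[half] == "right") "left" else "right"
                     if (start == "left") {
                       rep(c("left", "right"), length.out = trials - half)
                     } else {
                       rep(c("right", "left"), length.out = trials - half)
                     }
                   })
  if (is.null(first) || is.null(second)) stop("unknown condition", call. = FALSE)
  c(first, second)
}

#' Adaptive replay protocol
#'
#' Three structurally different 10 x 10 environments are presented in
#' sequence; the DR is carried over by low-rank barrier updates rather than
#' recomputed. Replays are generated from a fixed agent location with uniform
#' strengths, for the DR and for the Euclidean (structure-blind) control, and
#' screened for barrier-crossing reactivations.
#'
#' @param n_replays,replay_length epochs per environment and epoch length.
#' @param gamma_dr DR discount.
#' @param beta_m,lambda_decay replay parameters.
#' @return list(summary = tibble(environment, similarity, invalid_fraction),
#'   maps = tibble of reactivation maps, envs = the three grid worlds).
#' @export
run_adaptive <- function(n_replays = 50L, replay_length = 50L,
                         gamma_dr = 0.1, beta_m = 9, lambda_decay = 0.9) {
  base <- build_open_field(10L, 10L)
  walls <- adaptive_barrier_sets(base)
  agent <- state_at(base, 5L, 1L)
  dr <- similarity_dr(base, gamma_dr)
  euc <- similarity_euclidean(base)
  config <- replay_config("default", beta_m = beta_m,
                          lambda_decay = lambda_decay,
                          max_steps = replay_length)
  summary <- list()
  maps <- list()
  envs <- list()
  for (i in seq_along(walls)) {
    env_i <- gw_add_barriers(base, walls[[i]])
    dr <- apply_barrier_update(dr, transition_matrix(env_i))
    envs[[i]] <- env_i
    for (kind in c("dr", "euclidean")) {
      model <- if (kind == "dr") dr else euc
      memory <- make_memory(env_i, model, init_strength = 1)
      traces <- generate_replays(memory, config, n_replays,
                                 init_states = rep(agent, n_replays))
      summary[[length(summary) + 1L]] <- tibble::tibble(
        environment = i, similarity = kind,
        invalid_fraction = invalid_transition_fraction(traces, env_i)
      )
      maps[[length(maps) + 1L]] <- dplyr::mutate(
        reactivation_map(traces, env_i),
        environment = i, similarity = kind
      )
    }
  }
  list(summary = dplyr::bind_rows(summary), maps = dplyr::bind_rows(maps),
       envs = envs)
}

adaptive_barrier_sets <- function(env) {
  vwall <- function(col, rows) {
    cbind(state_at(env, rows, col), state_at(env, rows, col + 1L))
  }
  hwall <- function(row, cols) {
    cbind(state_at(env, row, cols), state_at(env, row + 1L, cols))
  }
  list(
    vwall(4L, 0:6),
    rbind(hwall(4L, 3:9)),
    rbind(vwall(6L, 3:9), hwall(2L, 0:5))
  )
}

#' Preplay protocol (blocked T-maze)
#'
#' Run phase: ten scripted stem laps with rewards at both stem ends. Cue
#' phase: arm experience strengths are raised by attention — the increase a
#' matching amount of physical arm running would have produced, scaled by
#' attention_strength x asymmetry for the cued (right) arm and
#' attention_strength x (1 - asymmetry) for the uncued arm. Preplays of
#' length six are then generated offline and classified by template
#' matching; optionally the preplays train a Q-function whose choice at the
#' junction is evaluated by a softmax before and after.
#'
#' @param attention_strength strength of visual relative to physical
#'   exploration.
#' @param asymmetry fraction of attention allocated to the cued arm.
#' @param n_preplays,preplay_length number and length of preplay epochs.
#' @param n_run_laps stem laps in the run phase.
#' @param gamma_dr,beta_m,lambda_decay replay parameters.
#' @param choice_phase train Q from the preplays and evaluate the junction
#'   choice?
#' @param choice_beta softmax inverse temperature of the choice evaluation.
#' @return list(counts, pct_cued, choice).
#' @export
run_preplay <- function(attention_strength = 0.14, asymmetry = 0.75,
                        n_preplays = 5000L, preplay_length = 6L,
                        n_run_laps = 10L, gamma_dr = 0.1, beta_m = 9,
                        lambda_decay = 0.9, choice_phase = TRUE,
                        choice_beta = 20) {
  blocked <- build_t_maze(5L, 3L, arms_blocked = TRUE)
  open <- build_t_maze(5L, 3L, arms_blocked = FALSE)
  arm <- 3L
  top <- state_at(open, 0L, arm)
  bottom <- state_at(open, 4L, arm)
  cued_end <- state_at(open, 0L, open$width - 1L)
  open$rewards[c(top, bottom, cued_end)] <- 1
  sim <- similarity_dr(blocked, gamma_dr)
  memory <- make_memory(open, sim)

  stem_up <- vapply(4:0, function(r) state_at(open, r, arm), integer(1))
  for (lap in seq_len(n_run_laps)) {
    memory <- script_path(memory, stem_up)
    memory <- script_path(memory, rev(stem_up))
  }

  ## Hypothetical arm-traversal increments, computed on scratch memories.
  ## The only reward in the hypothetical is the visible one at the cued arm's
  ## end; the stem-end rewards belong to the run phase and must not be
  ## re-collected on the scripted return into the junction.
  arm_delta <- function(side) {
    cols <- if (side == "right") (arm + 1L):(open$width - 1L) else (arm - 1L):0
    path <- c(top, vapply(cols, function(c) state_at(open, 0L, c), integer(1)))
    arm_env <- open
    arm_env$rewards[] <- 0
    if (side == "right") arm_env$rewards[cued_end] <- 1
    scratch <- make_memory(arm_env, sim)
    for (lap in seq_len(n_run_laps)) {
      scratch <- script_path(scratch, path)       # cue reward spreads on entry
      scratch <- script_path(scratch, rev(path))
    }
    scratch$C
  }
  memory$C <- memory$C +
    attention_strength * asymmetry * arm_delta("right") +
    attention_strength * (1 - asymmetry) * arm_delta("left")

  ## From here on the reward information available to preplay is the visible
  ## cued-arm reward; the run-phase stem rewards only shaped the strengths.
  memory$rew <- as.numeric(memory$dst == cued_end)

  config <- replay_config("default", beta_m = beta_m,
                          lambda_decay = lambda_decay,
                          max_steps = preplay_length)
  traces <- generate_replays(memory, config, n_preplays, init_states = NULL)
  templates <- preplay_templates(blocked, cued = "right")

  ## Replay cannot cross the stem/arm barrier (cross-barrier DR entries are
  ## exactly zero), so each trace lives in one maze component. Stem-component
  ## traces are stem replays; arm-component traces count as preplay of their
  ## arm when they match an arm template, and are discarded otherwise (no
  ## sequential content).
  first_states <- vapply(split(traces$s, traces$trace), `[`, integer(1), 1L)
  comp_of <- function(s) {
    col <- open$coords[s, 2]
    ifelse(col == arm, "stem", ifelse(col > arm, "right", "left"))
  }
  comp <- comp_of(first_states)
  fams <- vapply(split(traces$s, traces$trace), detect_preplay, character(1),
                 templates = templates)
  cls <- ifelse(comp == "stem", "stem",
                ifelse(fams %in% c("cued_arm", "uncued_arm"), fams, "none"))
  counts <- dplyr::count(tibble::tibble(family = cls), .data$family,
                         name = "n")
  n_of <- function(f) sum(cls == f)
  denom <- n_of("cued_arm") + n_of("uncued_arm") + n_of("stem")
  pct_cued <- if (denom > 0) 100 * n_of("cued_arm") / denom else NA_real_

  choice <- NULL
  if (choice_phase) {
    q <- make_q(open)
    p_choice <- function(q) {
      v <- q$values[top, c("E", "W")]
      w <- exp(choice_beta * (v - max(v)))
      unname(w[1] / sum(w))
    }
    before <- p_choice(q)
    ids <- unique(traces$trace)
    for (id in ids) {
      q <- q_learn_trace(q, traces[traces$trace == id, ])$q
    }
    choice <- tibble::tibble(phase = c("before", "after"),
                             p_cued = c(before, p_choice(q)))
  }
  list(counts = counts, pct_cued = pct_cued, choice = choice)
}

#' Reward-modulation protocol
#'
#' Goal-directed training with online replays of length 10 at the beginning
#' and end of every trial plus offline replays, of which only the end-of-trial
#' replays train the agent. Reactivation maps are pooled per replay timing.
#'
#' @param env_kind "open_field" (10 x 10) or "t_maze".
#' @param reward_modulation 1 or 10.
#' @param trials,steps_per_trial trial schedule.
#' @param replay_length replayed experiences per epoch.
#' @param reps independent repetitions pooled into the maps.
#' @param mode replay mode.
#' @param gamma_dr,beta_m,lambda_decay,epsilon remaining parameters.
#' @return list(maps = tibble(timing, state, row, col, fraction), env).
#' @export
run_reward_modulation <- function(env_kind = c("open_field", "t_maze"),
                                  reward_modulation = 1, trials = 100L,
                                  steps_per_trial = 100L, replay_length = 10L,
                                  reps = 10L, mode = "default",
                                  gamma_dr = 0.1, beta_m = 9,
                                  lambda_decay = 0.9, epsilon = 0.1) {
  env_kind <- match.arg(env_kind)
  env <- if (env_kind == "open_field") {
    e <- build_open_field(10L, 10L)
    e <- gw_set_start(e, state_at(e, 9L, 9L))
    gw_set_goal(e, state_at(e, 0L, 0L), reward = 1)
  } else {
    e <- build_t_maze(5L, 3L)
    e <- gw_set_start(e, state_at(e, 4L, 3L))
    gw_set_goal(e, state_at(e, 0L, e$width - 1L), reward = 1)
  }
  config <- replay_config(mode, beta_m = beta_m, lambda_decay = lambda_decay,
                          max_steps = replay_length,
                          reward_modulation = reward_modulation)
  sim <- similarity_dr(env, gamma_dr)
  pooled <- list(begin = list(), end = list(), offline = list())
  for (rep_i in seq_len(reps)) {
    memory <- make_memory(env, sim)
    q <- make_q(env)
    for (tr in seq_len(trials)) {
      tryCatch({
        init <- init_online(memory, env$start)
        pooled$begin[[length(pooled$begin) + 1L]] <-
          generate_replay(memory, config, init)$s
      }, error = function(e) NULL)
      state <- env$start
      for (st in seq_len(steps_per_trial)) {
        res <- behave_step(state, q, memory, env, epsilon, reward_modulation)
        q <- res$q
        memory <- res$memory
        state <- res$state
        if (state == env$goal) break
      }
      tryCatch({
        init <- init_online(memory, state)
        trace <- generate_replay(memory, config, init)
        pooled$end[[length(pooled$end) + 1L]] <- trace$s
        q <- q_learn_trace(q, trace)$q
      }, error = function(e) NULL)
      pooled$offline[[length(pooled$offline) + 1L]] <-
        generate_replay(memory, config, init_offline(memory),
                        init_kind = "offline")$s
    }
  }
  maps <- dplyr::bind_rows(lapply(names(pooled), function(tm) {
    ss <- unlist(pooled[[tm]], use.names = FALSE)
    dplyr::mutate(
      reactivation_map(tibble::tibble(trace = 1L, step = seq_along(ss), s = ss),
                       env),
      timing = tm
    )
  }))
  list(maps = maps, env = env)
}

#' Aversive shock-zone protocol
#'
#' A 20-state linear track whose two leftmost states form a shock zone (dark
#' zone = left half, light zone = right half). After 30 scripted laps the
#' strengths are weighted by the reported zone occupancies (74% / 26%). One
#' shock trial (shock of magnitude 1, replays generated at the shock site)
#' is followed by nine light-zone lap trials with replays generated in front
#' of the dark zone. A punishment Q-function is trained from the replays
#' only.
#'
#' @param reps independent repetitions.
#' @param n_laps pre-shock laps.
#' @param post_trials light-zone trials after the shock trial.
#' @param replays_per_trial,replay_length replay schedule.
#' @param mode replay mode.
#' @param gamma_dr,beta_m,lambda_decay replay parameters.
#' @return list(map, avoidance = tibble(state, phase, p_avoid), env).
#' @export
run_aversive <- function(reps = 30L, n_laps = 30L, post_trials = 9L,
                         replays_per_trial = 20L, replay_length = 10L,
                         mode = "default", gamma_dr = 0.1, beta_m = 9,
                         lambda_decay = 0.9) {
  env <- build_linear_track(20L, shock_zone = 2L)
  dark <- 1:10
  light <- 11:20
  sim <- similarity_dr(env, gamma_dr)
  config <- replay_config(mode, beta_m = beta_m, lambda_decay = lambda_decay,
                          max_steps = replay_length)
  all_states <- list()
  avoid_early <- matrix(0, reps, env$n_states)
  avoid_late <- matrix(0, reps, env$n_states)
  for (rp in seq_len(reps)) {
    memory <- make_memory(env, sim)
    for (lap in seq_len(n_laps)) {
      memory <- script_path_visits_only(memory, 20:1)
      memory <- script_path_visits_only(memory, 1:20)
    }
    memory$C[memory$src %in% dark] <- memory$C[memory$src %in% dark] * 0.74
    memory$C[memory$src %in% light] <- memory$C[memory$src %in% light] * 0.26
    q <- make_q(env)
    do_replays <- function(at_state) {
      for (i in seq_len(replays_per_trial)) {
        trace <- generate_replay(memory, config, init_online(memory, at_state))
        all_states[[length(all_states) + 1L]] <<- trace$s
        q <<- q_learn_trace(q, trace)$q
      }
    }
    ## shock trial: run from the right end into the shock zone
    memory <- script_path_visits_only(memory, 20:2)
    e_shock <- exp_index(memory, 3L, "W")
    memory <- strengthen_on_reward(memory, e_shock, 1)
    do_replays(2L)
    for (tr in seq_len(post_trials)) {
      memory <- script_path_visits_only(memory, c(11:20, 19:11))
      do_replays(11L)
      if (tr == 5L) {
        avoid_early[rp, ] <- q$values[, "E"] < q$values[, "W"]
      }
    }
    avoid_late[rp, ] <- q$values[, "E"] < q$values[, "W"]
  }
  ss <- unlist(all_states, use.names = FALSE)
  map <- reactivation_map(
    tibble::tibble(trace = 1L, step = seq_along(ss), s = ss), env
  )
  avoidance <- dplyr::bind_rows(
    tibble::tibble(state = 1:env$n_states, phase = "early",
                   p_avoid = colMeans(avoid_early)),
    tibble::tibble(state = 1:env$n_states, phase = "late",
                   p_avoid = colMeans(avoid_late))
  )
  list(map = map, avoidance = avoidance, env = env, dark = dark, light = light)
}

script_path_visits_only <- function(memory, path) {
  env <- memory$env
  for (i in seq_len(length(path) - 1L)) {
    s <- path[i]
    sn <- path[i + 1L]
    a <- which(env$trans[s, ] == sn)[1]
    memory <- strengthen_on_visit(memory, (s - 1L) * 4L + a)
  }
  memory
}

#' Navigation presets
#'
#' The three navigation tasks with their trial schedules: linear track
#' (20 trials, 100 steps, replay length 10), open field (100/100/10) and
#' labyrinth (100/300/50; ASCII fixture shipped with the package).
#'
#' @param env_kind "linear_track", "open_field" or "labyrinth".
#' @return list(env, trials, steps_per_trial, replay_length).
#' @export
navigation_preset <- function(env_kind = c("linear_track", "open_field",
                                           "labyrinth")) {
  env_kind <- match.arg(env_kind)
  switch(env_kind,
    linear_track = list(env = build_linear_track(10L), trials = 20L,
                        steps_per_trial = 100L, replay_length = 10L),
    open_field = {
      e <- build_open_field(10L, 10L)
      e <- gw_set_start(e, state_at(e, 9L, 0L))
      e <- gw_set_goal(e, state_at(e, 0L, 9L), reward = 1)
      list(env = e, trials = 100L, steps_per_trial = 100L, replay_length = 10L)
    },
    labyrinth = {
      path <- system.file("extdata", "labyrinth.txt", package = "sfma",
                          mustWork = TRUE)
      list(env = load_layout_file(path), trials = 100L,
           steps_per_trial = 300L, replay_length = 50L)
    }
  )
}
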