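#' Create a tabular Q-table
#'
#' @param env a grid world.
#' @param gamma discount factor of the learning problem.
#' @param eta learning rate of the Bellman backup.
#' @return An `sfma_q` object (|S| x 4 value matrix plus parameters).
#' @export
make_q <- function(env, gamma = 0.99, eta = 0.9) {
  structure(
    list(values = matrix(0, env$n_states, 4L,
                         dimnames = list(NULL, names(ACTIONS))),
         gamma = gamma, eta = eta),
    class = "sfma_q"
  )
}

#' One Q-learning backup
#'
#' Q(s,a) <- Q(s,a) + eta * [r + gamma * max_a' Q(s',a') - Q(s,a)].
#'
#' @param q an `sfma_q`.
#' @param s,a,r,s_next the experience tuple (action as "N".."W" or 1:4).
#' @return list(q = updated table, td = signed TD error).
#' @export
q_update <- function(q, s, a, r, s_next) {
  a <- action_id(a)
  td <- unname(r + q$gamma * max(q$values[s_next, ]) - q$values[s, a])
  q$values[s, a] <- q$values[s, a] + q$eta * td
  list(q = q, td = td)
}

#' Train a Q-table from a replay trace
#'
#' Applies [q_update()] to each replayed experience in reactivation order.
#'
#' @param q an `sfma_q`.
#' @param trace an `sfma_trace` tibble (columns s, a, r, s_next).
#' @return list(q = updated table, td = vector of signed TD errors).
#' @export
q_learn_trace <- function(q, trace) {
  n <- nrow(trace)
  tds <- numeric(n)
  val <- q$values
  g <- q$gamma
  eta <- q$eta
  s <- trace$s
  a <- action_id(trace$a)
  r <- trace$r
  sn <- trace$s_next
  for (i in seq_len(n)) {
    td <- r[i] + g * max(val[sn[i], ]) - val[s[i], a[i]]
    val[s[i], a[i]] <- val[s[i], a[i]] + eta * td
    tds[i] <- td
  }
  q$values <- val
  list(q = q, td = tds)
}

#' Behavioral action selection with self-transition masking
#'
#' Actions that would leave the agent in the same state (wall or barrier
#' bumps) are masked out. Among the remaining actions, either epsilon-greedy
#' (training) or softmax with inverse temperature beta (evaluation) selection
#' is applied; greedy ties are broken uniformly at random.
#'
#' @param q an `sfma_q`.
#' @param state current state.
#' @param env the grid world (provides the masking information).
#' @param policy "egreedy" or "softmax".
#' @param epsilon exploration rate for "egreedy".
#' @param beta inverse temperature for "softmax".
#' @param allowed optional integer subset of actions to consider.
#' @return An action id (1:4).
#' @export
select_action <- function(q, state, env, policy = c("egreedy", "softmax"),
                          epsilon = 0.1, beta = 20, allowed = NULL) {
  policy <- match.arg(policy)
  cand <- if (is.null(allowed)) 1:4 else action_id(allowed)
  cand <- cand[env$trans[state, cand] != state]
  if (!length(cand)) stop("policy-error: all actions masked", call. = FALSE)
  if (length(cand) == 1L) return(cand)
  v <- q$values[state, cand]
  if (policy == "egreedy") {
    if (stats::runif(1) < epsilon) {
      cand[sample.int(length(cand), 1L)]
    } else {
      best <- which(v == max(v))
      cand[best[sample.int(length(best), 1L)]]
    }
  } else {
    w <- exp(beta * (v - max(v)))
    cand[sample.int(length(cand), 1L, prob = w)]
  }
}

## One behavioral step: act, store, strengthen, learn online. Used by the
## runners; returns the updated pieces plus the absolute TD error.
behave_step <- function(state, q, memory, env, epsilon, reward_modulation,
                        learn = TRUE) {
  a <- select_action(q, state, env, "egreedy", epsilon = epsilon)
  e <- (state - 1L) * 4L + a
  s_next <- memory$dst[e]
  r <- memory$rew[e]
  memory <- strengthen_on_visit(memory, e)
  if (r != 0) memory <- strengthen_on_reward(memory, e, r, reward_modulation)
  td <- 0
  if (learn) {
    up <- q_update(q, state, a, r, s_next)
    q <- up$q
    td <- up$td
  }
  list(state = s_next, q = q, memory = memory, td = td, e = e)
}

#' Run a goal-directed navigation experiment
#'
#' Per trial the agent behaves epsilon-greedily (with self-transition
#' masking and per-step online Q-learning) until it reaches the goal or the
#' step cap; at the end of the trial, replays of the configured length are
#' generated online at the agent's position and used for additional Q
#' backups. Variants: "sfma" (prioritized replay in the configured mode),
#' "random_replay" (uniform draws from experienced transitions), "no_replay".
#'
#' @param env grid world with start and goal set.
#' @param variant "sfma", "random_replay" or "no_replay".
#' @param mode replay mode for the sfma variant.
#' @param trials number of trials.
#' @param steps_per_trial step cap per trial.
#' @param replay_length replayed experiences per end-of-trial epoch.
#' @param gamma_dr DR discount used for the similarity model.
#' @param epsilon exploration rate.
#' @param gamma,eta Q-learning discount and learning rate.
#' @param beta_m,lambda_decay replay softmax temperature and inhibition decay.
#' @param reward_modulation reward modulation of experience strength.
#' @return A tibble with one row per trial: trial, latency (steps to goal,
#'   capped), delta (cumulative |TD| during behavior).
#' @export
run_navigation <- function(env, variant = c("sfma", "random_replay", "no_replay"),
                           mode = "reverse", trials = 100L,
                           steps_per_trial = 100L, replay_length = 10L,
                           gamma_dr = 0.1, epsilon = 0.1,
                           gamma = 0.99, eta = 0.9,
                           beta_m = 9, lambda_decay = 0.9,
                           reward_modulation = 1) {
  variant <- match.arg(variant)
  stopifnot(!is.na(env$start), !is.na(env$goal))
  sim <- similarity_dr(env, gamma_dr)
  memory <- make_memory(env, sim)
  q <- make_q(env, gamma = gamma, eta = eta)
  config <- replay_config(mode = mode, beta_m = beta_m,
                          lambda_decay = lambda_decay,
                          max_steps = replay_length,
                          reward_modulation = reward_modulation)
  out <- tibble::tibble(trial = seq_len(trials), latency = NA_integer_,
                        delta = NA_real_)
  for (tr in seq_len(trials)) {
    state <- env$start
    delta <- 0
    latency <- steps_per_trial
    for (st in seq_len(steps_per_trial)) {
      stepres <- behave_step(state, q, memory, env, epsilon, reward_modulation)
      q <- stepres$q
      memory <- stepres$memory
      delta <- delta + abs(stepres$td)
      state <- stepres$state
      if (state == env$goal) {
        latency <- st
        break
      }
    }
    if (variant == "sfma") {
      tryCatch({
        init <- init_online(memory, state)
        trace <- generate_replay(memory, config, init,
                                 init_kind = "online", delta = delta)
        q <- q_learn_trace(q, trace)$q
      }, error = function(e) NULL)
    } else if (variant == "random_replay") {
      seen <- which(memory$C > 0)
      draws <- seen[sample.int(length(seen), replay_length, replace = TRUE)]
      for (e in draws) {
        q <- q_update(q, memory$src[e], memory$act[e],
                      memory$rew[e], memory$dst[e])$q
      }
    }
    out$latency[tr] <- latency
    out$delta[tr] <- delta
  }
  out
}

#' Train a punishment Q-function from replay traces only
#'
#' The Q-table is repurposed to represent positive-valued discounted
#' cumulative punishment: replayed shock experiences carry their shock
#' magnitude as reward and are backed up with the ordinary update; behavior
#' itself does not update the table.
#'
#' @param q_punish an `sfma_q`.
#' @param traces a list of `sfma_trace` tibbles (or one combined tibble).
#' @return The updated `sfma_q`.
#' @export
run_punishment_phase <- function(q_punish, traces) {
  if (is.data.frame(traces)) traces <- list(traces)
  for (tr in traces) q_punish <- q_learn_trace(q_punish, tr)$q
  q_punish
}
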