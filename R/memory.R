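#' Create the experience memory for an environment
#'
#' One experience tuple (s, a, r, s') is stored for every (state, action)
#' pair, in state-major order: experience index (s - 1) * 4 + a. The reward
#' field is the reward of the landing state. Each experience carries a
#' strength C (how often / how rewardingly it was experienced) and an
#' inhibition value I in [0, 1].
#'
#' @param env a grid world (defines the stored transitions).
#' @param similarity an `sfma_similarity` used for prioritization.
#' @param init_strength initial strength for every experience (0 for learning
#'   simulations; 1 emulates a uniformly familiar environment).
#' @return An `sfma_memory` object.
#' @export
make_memory <- function(env, similarity, init_strength = 0) {
  S <- env$n_states
  src <- rep(seq_len(S), each = 4L)
  act <- rep(1:4, S)
  dst <- as.integer(t(env$trans))
  structure(
    list(
      env = env, sim = similarity,
      src = src, act = act, dst = dst,
      rew = env$rewards[dst],
      C = rep(as.numeric(init_strength), 4L * S),
      I = numeric(4L * S),
      n_exp = 4L * S
    ),
    class = "sfma_memory"
  )
}

#' Experience index of a (state, action) pair
#' @param memory an `sfma_memory`.
#' @param state state index.
#' @param action action ("N","E","S","W" or 1:4).
#' @export
exp_index <- function(memory, state, action) {
  (as.integer(state) - 1L) * 4L + action_id(action)
}

#' Strength and inhibition updates
#'
#' `strengthen_on_visit()` increments the visited experience's strength by 1.
#' `strengthen_on_reward()` spreads a reward r encountered at experience `e_r`
#' to every experience e, C(e) <- C(e) + reward_modulation * r * D(e | e_r),
#' where each experience's current state is compared to the rewarded
#' (landing) state of `e_r` — the spread is centered on the reward location,
#' which is what lets rewarded locations become over-represented in replay.
#' `inhibit()` sets I = 1 for all experiences
#' sharing the source state of `e`; `decay_inhibition()` multiplies every I
#' by lambda.
#'
#' @param memory an `sfma_memory`.
#' @param e experience index.
#' @return The updated memory.
#' @export
strengthen_on_visit <- function(memory, e) {
  memory$C[e] <- memory$C[e] + 1
  memory
}

#' @rdname strengthen_on_visit
#' @param e_r the experience whose transition delivered the reward.
#' @param r scalar reward magnitude.
#' @param reward_modulation multiplier on the reward-driven increment.
#' @export
strengthen_on_reward <- function(memory, e_r, r, reward_modulation = 1) {
  stopifnot(is.finite(r))
  if (r == 0 || reward_modulation == 0) return(memory)
  sim <- memory$sim$D[, memory$dst[e_r]][memory$src]
  memory$C <- memory$C + reward_modulation * r * sim
  memory
}

#' @rdname strengthen_on_visit
#' @export
inhibit <- function(memory, e) {
  s <- memory$src[e]
  memory$I[(s - 1L) * 4L + 1:4] <- 1
  memory
}

#' @rdname strengthen_on_visit
#' @param lambda_decay decay factor in [0, 1).
#' @export
decay_inhibition <- function(memory, lambda_decay) {
  stopifnot(lambda_decay >= 0, lambda_decay < 1)
  memory$I <- memory$I * lambda_decay
  memory
}

#' @rdname strengthen_on_visit
#' @export
reset_inhibition <- function(memory) {
  memory$I[] <- 0
  memory
}

#' Replay initiation
#'
#' Online (awake) replay starts at the agent's current position: an experience
#' with that source state is drawn proportional to strength. Offline (sleep)
#' replay draws any experience with probability C(e) / sum(C).
#'
#' @param memory an `sfma_memory`.
#' @param current_state the agent's position.
#' @return An experience index.
#' @export
init_online <- function(memory, current_state) {
  idx <- (as.integer(current_state) - 1L) * 4L + 1:4
  w <- memory$C[idx]
  if (sum(w) <= 0) {
    stop("init-failure: no experienced transition at this state", call. = FALSE)
  }
  idx[sample.int(4L, 1L, prob = w)]
}

#' @rdname init_online
#' @export
init_offline <- function(memory) {
  if (sum(memory$C) <= 0) {
    stop("init-failure: all experience strengths are zero", call. = FALSE)
  }
  sample.int(memory$n_exp, 1L, prob = memory$C)
}

#' @export
print.sfma_memory <- function(x, ...) {
  cat(sprintf("<sfma_memory> %d experiences (%d states), sum C = %.3g\n",
              x$n_exp, x$env$n_states, sum(x$C)))
  invisible(x)
}

#' @export
as_tibble.sfma_memory <- function(x, ...) {
  tibble::tibble(
    exp = seq_len(x$n_exp),
    s = x$src, a = names(ACTIONS)[x$act], r = x$rew, s_next = x$dst,
    C = x$C, I = x$I
  )
}
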