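#' Replay configuration
#'
#' @param mode replay mode: "default" compares current states, "reverse"
#'   compares stored next states to the current state, "dynamic" picks one of
#'   the two per epoch with reverse probability [p_reverse(delta)].
#' @param beta_m inverse temperature of the customized softmax.
#' @param lambda_decay per-step inhibition decay in [0, 1).
#' @param theta stop threshold on the maximum priority rating.
#' @param max_steps maximum number of reactivated experiences per epoch
#'   (the initiating experience counts as step 1).
#' @param reward_modulation multiplier on reward-driven strength increments.
#' @param normalization how ratings are normalized before the softmax:
#'   divide by the maximum (default) or by the sum.
#' @return An `sfma_replay_config` list.
#' @export
replay_config <- function(mode = c("default", "reverse", "dynamic"),
                          beta_m = 9, lambda_decay = 0.9, theta = 1e-6,
                          max_steps = 10L, reward_modulation = 1,
                          normalization = c("max", "sum")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(beta_m > 0, lambda_decay >= 0, lambda_decay < 1,
            theta > 0, max_steps >= 1)
  structure(
    list(mode = mode, beta_m = beta_m, lambda_decay = lambda_decay,
         theta = theta, max_steps = as.integer(max_steps),
         reward_modulation = reward_modulation,
         normalization = normalization),
    class = "sfma_replay_config"
  )
}

#' Priority ratings R(e | e_t) = C(e) D(e | e_t) [1 - I(e)]
#'
#' @param memory an `sfma_memory`.
#' @param e_t index of the most recently reactivated experience.
#' @param mode "default" or "reverse".
#' @return Non-negative numeric vector over experiences.
#' @export
priority_ratings <- function(memory, e_t, mode = c("default", "reverse")) {
  sim <- experience_similarity(memory$sim, memory, e_t, mode)
  memory$C * sim * (1 - memory$I)
}

#' Customized softmax over priority ratings
#'
#' Ratings are normalized (division by their maximum by default), then
#' P_i = (exp(beta_m * R_i) - 1) / sum_j (exp(beta_m * R_j) - 1). Subtracting
#' one from each exponential assigns exactly zero probability to zero-rated
#' experiences.
#'
#' @param R non-negative priority ratings with max(R) > 0.
#' @param beta_m inverse temperature.
#' @param normalization "max" or "sum".
#' @return Probability vector summing to 1.
#' @export
reactivation_probabilities <- function(R, beta_m = 9, normalization = c("max", "sum")) {
  normalization <- match.arg(normalization)
  m <- max(R)
  if (m <= 0) stop("all priority ratings are zero; replay must stop", call. = FALSE)
  Rn <- R / if (normalization == "max") m else sum(R)
  w <- expm1(beta_m * Rn)
  w / sum(w)
}

#' Probability of generating a replay epoch in the reverse mode
#'
#' Increasing sigmoid of the cumulative absolute TD error since the last
#' trial: p = 1 / (1 + exp(-(5 * delta - 2))).
#'
#' @param delta cumulative absolute TD error (>= 0).
#' @export
p_reverse <- function(delta) {
  stopifnot(all(delta >= 0))
  1 / (1 + exp(-(5 * delta - 2)))
}

#' Draw the mode for one dynamic-mode epoch
#'
#' @param config a replay config with mode "dynamic".
#' @param delta cumulative absolute TD error since the last trial.
#' @return "reverse" with probability [p_reverse(delta)], else "default".
#' @export
choose_mode <- function(config, delta) {
  if (config$mode != "dynamic") {
    stop("choose_mode only applies to the dynamic mode", call. = FALSE)
  }
  if (stats::runif(1) < p_reverse(delta)) "reverse" else "default"
}

## Hot loop shared by all simulations: returns the integer sequence of
## reactivated experiences. Operates on the subset of experiences with C > 0
## (zero-strength experiences can never be rated above zero).
replay_core <- function(memory, config, init, mode_used, delta = 0) {
  C <- memory$C
  active <- which(C > 0)
  if (!(init %in% active)) {
    stop("init-failure: initiating experience has zero strength", call. = FALSE)
  }
  D <- memory$sim$D
  src_a <- memory$src[active]
  cmp_a <- if (mode_used == "reverse") memory$dst[active] else src_a
  C_a <- C[active]
  I_a <- numeric(length(active))
  beta <- config$beta_m
  lambda <- config$lambda_decay
  theta <- config$theta
  use_max <- config$normalization == "max"

  steps <- integer(config$max_steps)
  pos <- match(init, active)
  steps[1] <- pos
  I_a[src_a == src_a[pos]] <- 1
  stop_reason <- "max_steps"
  k <- 1L
  while (k < config$max_steps) {
    s_t <- src_a[steps[k]]
    R <- C_a * D[, s_t][cmp_a] * (1 - I_a)
    R[R < 0] <- 0   # guard against roundoff in low-rank-updated similarities
    m <- max(R)
    if (m < theta) {
      stop_reason <- "below_threshold"
      break
    }
    w <- expm1(beta * (R / if (use_max) m else sum(R)))
    ## inverse-CDF draw (sample.int(prob=) re-sorts the weights every call)
    cw <- cumsum(w)
    nxt <- findInterval(stats::runif(1) * cw[length(cw)], cw,
                        left.open = TRUE) + 1L
    k <- k + 1L
    steps[k] <- nxt
    I_a <- I_a * lambda
    I_a[src_a == src_a[nxt]] <- 1
  }
  list(steps = active[steps[seq_len(k)]], stop_reason = stop_reason)
}

#' Generate one replay epoch
#'
#' Implements the epoch loop: score all experiences, stop if the maximum
#' rating falls below theta, convert ratings to reactivation probabilities,
#' sample the next experience, decay inhibition, inhibit the sampled
#' experience's source state. Inhibition starts fresh each epoch, and the
#' initiating experience's source state is inhibited at initiation.
#'
#' @param memory an `sfma_memory`.
#' @param config an `sfma_replay_config`.
#' @param init experience index to initiate from (see [init_online()] /
#'   [init_offline()]).
#' @param init_kind "online" or "offline" (recorded on the trace).
#' @param delta cumulative absolute TD error, used when mode is "dynamic".
#' @return A tibble of class `sfma_trace` with one row per reactivated
#'   experience (columns step, exp, s, a, r, s_next) and attributes
#'   `mode_used`, `init_kind`, `stop_reason`.
#' @export
generate_replay <- function(memory, config, init, init_kind = "online", delta = 0) {
  mode_used <- if (config$mode == "dynamic") choose_mode(config, delta) else config$mode
  res <- replay_core(memory, config, init, mode_used)
  trace_from_steps(res$steps, memory,
                   mode_used = mode_used, init_kind = init_kind,
                   stop_reason = res$stop_reason)
}

trace_from_steps <- function(steps, memory, mode_used, init_kind, stop_reason,
                             trace_id = 1L) {
  out <- tibble::tibble(
    trace = trace_id,
    step = seq_along(steps),
    exp = steps,
    s = memory$src[steps],
    a = names(ACTIONS)[memory$act[steps]],
    r = memory$rew[steps],
    s_next = memory$dst[steps]
  )
  attr(out, "mode_used") <- mode_used
  attr(out, "init_kind") <- init_kind
  attr(out, "stop_reason") <- stop_reason
  class(out) <- c("sfma_trace", class(out))
  out
}

## Generate many epochs and return one combined tibble; init_states = NULL
## means offline initiation for every epoch.
generate_replays <- function(memory, config, n, init_states = NULL, delta = 0) {
  traces <- vector("list", n)
  modes <- character(n)
  for (i in seq_len(n)) {
    init <- if (is.null(init_states)) {
      init_offline(memory)
    } else {
      init_online(memory, init_states[[min(i, length(init_states))]])
    }
    mode_used <- if (config$mode == "dynamic") choose_mode(config, delta) else config$mode
    res <- replay_core(memory, config, init, mode_used)
    traces[[i]] <- res$steps
    modes[i] <- mode_used
  }
  lens <- lengths(traces)
  steps <- unlist(traces, use.names = FALSE)
  out <- tibble::tibble(
    trace = rep(seq_len(n), lens),
    step = sequence(lens),
    exp = steps,
    s = memory$src[steps],
    a = names(ACTIONS)[memory$act[steps]],
    r = memory$rew[steps],
    s_next = memory$dst[steps]
  )
  attr(out, "modes") <- modes
  out
}
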