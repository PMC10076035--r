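## Shared fixtures and independent oracles. Expensive similarity models are
## cached per session so several tests can share one dense solve.

.sim_cache <- new.env(parent = emptyenv())

cached_dr <- function(env, gamma_dr, key) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, similarity_dr(env, gamma_dr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

open_field_50 <- function() {
  if (!exists("of50", envir = .sim_cache)) {
    assign("of50", build_open_field(50L, 50L), envir = .sim_cache)
  }
  get("of50", envir = .sim_cache)
}

## Independent oracle: a masked lattice random walk (uniform over the moves
## that stay on the grid), returned as a trace tibble. Deliberately written
## against env$coords only — it never touches the replay machinery.
oracle_random_walk <- function(env, n_traces, n_steps, start) {
  rows <- env$coords[, 1]
  cols <- env$coords[, 2]
  out <- vector("list", n_traces)
  for (tr in seq_len(n_traces)) {
    s <- integer(n_steps)
    s[1] <- start
    for (i in 2:n_steps) {
      r <- rows[s[i - 1L]]
      c <- cols[s[i - 1L]]
      repeat {
        d <- sample(1:4, 1L)
        rr <- r + c(-1L, 0L, 1L, 0L)[d]
        cc <- c + c(0L, 1L, 0L, -1L)[d]
        if (rr >= 0 && rr < env$height && cc >= 0 && cc < env$width) break
      }
      s[i] <- state_at(env, rr, cc)
    }
    out[[tr]] <- tibble::tibble(trace = tr, step = seq_len(n_steps), s = s)
  }
  dplyr::bind_rows(out)
}

## Independent oracle for the gain of one hypothetical backup (greedy-policy
## improvement, uniform need), written directly from the definition.
oracle_gain <- function(qmat, s, a, r, sn, gamma, eta) {
  qs <- qmat[s, ]
  q_new <- qs
  q_new[a] <- qs[a] + eta * (r + gamma * max(qmat[sn, ]) - qs[a])
  greedy <- function(v) {
    p <- as.numeric(v == max(v))
    p / sum(p)
  }
  sum((greedy(q_new) - greedy(qs)) * q_new)
}

## Reachability over the environment's transition table (BFS).
reachable_states <- function(env, from) {
  seen <- logical(env$n_states)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(as.vector(env$trans[frontier, ]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

## Scripted laps that build experience strengths on a track-like path.
scripted_memory <- function(env, sim, path, laps = 30L, rewards = TRUE) {
  memory <- make_memory(env, sim)
  for (i in seq_len(laps)) {
    memory <- if (rewards) {
      sfma:::script_path(memory, path)
    } else {
      sfma:::script_path_visits_only(memory, path)
    }
  }
  memory
}
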