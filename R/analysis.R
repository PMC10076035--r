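## All analyses operate on trace tibbles: columns trace, step, s (and where
## needed a, r, s_next), as produced by generate_replay()/generate_replays().

split_trace_states <- function(traces) {
  split(traces$s, traces$trace)
}

#' Mean replay displacement at a fixed time interval
#'
#' The mean Euclidean distance between the grid coordinates of replayed
#' positions (the current state of each reactivated experience) separated by
#' `dt` steps, pooled over all traces and offsets.
#'
#' @param traces trace tibble (columns trace, step, s).
#' @param env the grid world providing coordinates.
#' @param dt time interval in replay steps (>= 1).
#' @export
mean_displacement <- function(traces, env, dt) {
  stopifnot(dt >= 1)
  per <- split_trace_states(traces)
  tot <- 0
  n <- 0L
  for (v in per) {
    len <- length(v)
    if (len <= dt) next
    i <- seq_len(len - dt)
    dr <- env$coords[v[i], 1] - env$coords[v[i + dt], 1]
    dc <- env$coords[v[i], 2] - env$coords[v[i + dt], 2]
    tot <- tot + sum(sqrt(dr^2 + dc^2))
    n <- n + length(i)
  }
  if (n == 0L) stop("empty-result: no state pairs at this time interval", call. = FALSE)
  tot / n
}

#' Brownian diffusion analysis of replay trajectories
#'
#' Fits the power law dx = G * dt^alpha by ordinary least squares on
#' (log dt, log mean displacement). alpha = 0.5 indicates Brownian diffusion,
#' alpha = 1 ballistic motion.
#'
#' @param traces trace tibble.
#' @param env the grid world.
#' @param dt_range integer vector of time intervals (>= 3 distinct values).
#' @return An `sfma_diffusion_fit` with fields alpha, G, dt_range, n_traces,
#'   displacement (per-dt means) and r_squared.
#' @export
fit_power_law <- function(traces, env, dt_range = 1:50) {
  dt_range <- sort(unique(as.integer(dt_range)))
  stopifnot(length(dt_range) >= 3)
  disp <- vapply(dt_range, function(dt) mean_displacement(traces, env, dt),
                 numeric(1))
  if (any(disp <= 0)) stop("numeric-error: non-positive displacement", call. = FALSE)
  fit <- stats::lm(log(disp) ~ log(dt_range))
  structure(
    list(alpha = unname(stats::coef(fit)[2]),
         G = exp(unname(stats::coef(fit)[1])),
         dt_range = dt_range,
         n_traces = length(unique(traces$trace)),
         displacement = tibble::tibble(dt = dt_range, mean_displacement = disp),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "sfma_diffusion_fit"
  )
}

#' @export
print.sfma_diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion fit> alpha = %.3f, G = %.3f (dt %d..%d, %d traces, R^2 = %.3f)\n",
              x$alpha, x$G, min(x$dt_range), max(x$dt_range), x$n_traces,
              x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sfma_diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "G"), estimate = c(x$alpha, x$G))
}

#' @export
glance.sfma_diffusion_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, G = x$G, r.squared = x$r_squared,
                 n_traces = x$n_traces, dt_min = min(x$dt_range),
                 dt_max = max(x$dt_range))
}

#' Spatial displacement distributions relative to the replay start
#'
#' For each time interval, the normalized histogram of the replayed position
#' relative to the first replayed position, inside a square window.
#'
#' @param traces trace tibble.
#' @param env the grid world.
#' @param dt_set time intervals.
#' @param window window side length in states (centered on the start).
#' @return Tibble with columns dt, drow, dcol, p.
#' @export
displacement_distribution <- function(traces, env, dt_set = 1:4, window = 25L) {
  half <- (window - 1L) %/% 2L
  per <- split_trace_states(traces)
  out <- list()
  for (dt in dt_set) {
    dr <- integer(0)
    dc <- integer(0)
    for (v in per) {
      if (length(v) <= dt) next
      dr <- c(dr, env$coords[v[1 + dt], 1] - env$coords[v[1], 1])
      dc <- c(dc, env$coords[v[1 + dt], 2] - env$coords[v[1], 2])
    }
    keep <- abs(dr) <= half & abs(dc) <= half
    tb <- table(factor(dr[keep], levels = -half:half),
                factor(dc[keep], levels = -half:half))
    out[[length(out) + 1L]] <- tibble::tibble(
      dt = dt,
      drow = rep(-half:half, times = 2L * half + 1L),
      dcol = rep(-half:half, each = 2L * half + 1L),
      p = as.vector(tb) / sum(tb)
    )
  }
  dplyr::bind_rows(out)
}

#' Start-position and initial-direction distributions of replay
#'
#' Start states are counted per spatial bin; the initial replay direction
#' (vector between the first two replayed coordinates) is assigned to one of
#' four 90-degree sectors centered on 0/90/180/270 degrees, counted per
#' spatial bin of the start.
#'
#' @param traces trace tibble (each trace length >= 2 for directions).
#' @param env the grid world.
#' @param spatial_bin side length of the square spatial bins.
#' @return list(starts = tibble(bin_row, bin_col, n),
#'   directions = tibble(bin_row, bin_col, sector, n)).
#' @export
start_and_direction_distributions <- function(traces, env, spatial_bin = 20L) {
  per <- split_trace_states(traces)
  s1 <- vapply(per, `[`, integer(1), 1L)
  rows <- env$coords[s1, 1] %/% spatial_bin
  cols <- env$coords[s1, 2] %/% spatial_bin
  starts <- dplyr::count(tibble::tibble(bin_row = rows, bin_col = cols),
                         .data$bin_row, .data$bin_col, name = "n")
  s2 <- vapply(per, function(v) if (length(v) >= 2L) v[2L] else NA_integer_,
               integer(1))
  ok <- !is.na(s2)
  dy <- -(env$coords[s2[ok], 1] - env$coords[s1[ok], 1]) # north = +y
  dx <- env$coords[s2[ok], 2] - env$coords[s1[ok], 2]
  ang <- atan2(dy, dx) * 180 / pi
  sector <- (round(ang / 90) %% 4) * 90
  directions <- dplyr::count(
    tibble::tibble(bin_row = rows[ok], bin_col = cols[ok], sector = sector),
    .data$bin_row, .data$bin_col, .data$sector, name = "n"
  )
  list(starts = starts, directions = directions)
}

#' Directionality of replay traces
#'
#' A consecutive pair (e_{t-1}, e_t) is forward when the next state of
#' e_{t-1} equals the current state of e_t, reverse when the current state of
#' e_{t-1} equals the next state of e_t, and unordered otherwise (pairs
#' satisfying both conditions — immediate bounces — count as unordered).
#' The score is forward - reverse.
#'
#' @param traces trace tibble with columns trace, s, s_next.
#' @return Tibble with one row per trace: forward, reverse, unordered, score.
#' @export
directionality <- function(traces) {
  per_s <- split(traces$s, traces$trace)
  per_n <- split(traces$s_next, traces$trace)
  out <- lapply(names(per_s), function(id) {
    s <- per_s[[id]]
    sn <- per_n[[id]]
    len <- length(s)
    if (len < 2L) {
      return(tibble::tibble(trace = as.integer(id), forward = 0L,
                            reverse = 0L, unordered = 0L, score = 0L))
    }
    i <- seq_len(len - 1L)
    fwd <- sn[i] == s[i + 1L]
    rev <- s[i] == sn[i + 1L]
    both <- fwd & rev
    tibble::tibble(
      trace = as.integer(id),
      forward = sum(fwd & !both), reverse = sum(rev & !both),
      unordered = sum((!fwd & !rev) | both),
      score = sum(fwd & !both) - sum(rev & !both)
    )
  })
  dplyr::bind_rows(out)
}

#' Sliding-window template match
#'
#' Compares a state-sequence template against every offset of a replayed
#' state sequence and reports the best offset; a match requires at most
#' `max_mismatch` mismatching positions.
#'
#' @param states integer vector of replayed states.
#' @param template integer vector (no longer than `states`).
#' @param max_mismatch allowed substitutions.
#' @return list(match, offset (0-based), mismatches).
#' @export
match_template <- function(states, template, max_mismatch = 2L) {
  m <- length(template)
  n <- length(states)
  if (m > n) return(list(match = FALSE, offset = NA_integer_, mismatches = NA_integer_))
  mis <- vapply(0:(n - m), function(off) {
    sum(states[(off + 1L):(off + m)] != template)
  }, integer(1))
  best <- which.min(mis) - 1L
  list(match = mis[best + 1L] <= max_mismatch, offset = best,
       mismatches = mis[best + 1L])
}

## All offsets at which the template matches, plus the trace index of the
## template's apex position for each.
template_hits <- function(states, template, apex_pos, max_mismatch = 2L) {
  m <- length(template)
  n <- length(states)
  if (m > n) return(integer(0))
  mis <- vapply(0:(n - m), function(off) {
    sum(states[(off + 1L):(off + m)] != template)
  }, integer(1))
  offs <- which(mis <= max_mismatch) - 1L
  offs + apex_pos
}

#' Corner templates of the figure-eight maze
#'
#' Five-cell paths through each corner (TL, TR, BL, BR) in the forward
#' direction of lap running (left laps traverse TL/BL, right laps TR/BR),
#' plus their reversals. The corner cell itself (apex) sits at position 3.
#'
#' @param env the figure-eight grid world.
#' @return Named list of lists(states, apex).
#' @export
shortcut_templates <- function(env) {
  sa <- function(r, c) state_at(env, r, c)
  h <- env$height - 1L
  w <- env$width - 1L
  fwd <- list(
    TL = c(sa(0, 2), sa(0, 1), sa(0, 0), sa(1, 0), sa(2, 0)),
    TR = c(sa(0, w - 2L), sa(0, w - 1L), sa(0, w), sa(1, w), sa(2, w)),
    BL = c(sa(h - 2L, 0), sa(h - 1L, 0), sa(h, 0), sa(h, 1), sa(h, 2)),
    BR = c(sa(h - 2L, w), sa(h - 1L, w), sa(h, w), sa(h, w - 1L), sa(h, w - 2L))
  )
  out <- list()
  for (nm in names(fwd)) {
    out[[paste0(nm, "_forward")]] <- list(states = fwd[[nm]], apex = 3L)
    out[[paste0(nm, "_backward")]] <- list(states = rev(fwd[[nm]]), apex = 3L)
  }
  out
}

#' Detect shortcut replays in the figure-eight maze
#'
#' A shortcut joins two corner traversals that behavior never produced
#' contiguously: TL backward then TR forward, TR backward then TL forward,
#' BL forward then BR backward, or BR forward then BL backward, with the two
#' corner cells separated by 8 +/- 2 replayed states.
#'
#' @param trace one trace tibble (or integer state sequence).
#' @param env the figure-eight grid world.
#' @param templates precomputed [shortcut_templates()] (recomputed if NULL).
#' @param max_mismatch allowed substitutions per template.
#' @param gap allowed separations between the corner cells.
#' @return Tibble of events: first, second, apex_first, apex_second, separation.
#' @export
detect_shortcuts <- function(trace, env, templates = NULL, max_mismatch = 2L,
                             gap = 6:10) {
  states <- if (is.data.frame(trace)) trace$s else as.integer(trace)
  if (is.null(templates)) templates <- shortcut_templates(env)
  hits <- lapply(templates, function(tp) {
    template_hits(states, tp$states, tp$apex, max_mismatch)
  })
  pairs <- list(c("TL_backward", "TR_forward"),
                c("TR_backward", "TL_forward"),
                c("BL_forward", "BR_backward"),
                c("BR_forward", "BL_backward"))
  out <- list()
  for (p in pairs) {
    for (i in hits[[p[1]]]) {
      for (j in hits[[p[2]]]) {
        sep <- j - i - 1L
        if (j > i && sep %in% gap) {
          out[[length(out) + 1L]] <- tibble::tibble(
            first = p[1], second = p[2],
            apex_first = i, apex_second = j, separation = sep
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(first = character(0), second = character(0),
                          apex_first = integer(0), apex_second = integer(0),
                          separation = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Stem / arm templates of the blocked T-maze
#'
#' Forward and reverse state sequences for the stem (junction to bottom) and
#' for each arm (junction side outward), used to classify preplay content.
#'
#' @param env the T-maze grid world.
#' @param cued which arm is cued ("right" or "left").
#' @return Named list of family-tagged templates.
#' @export
preplay_templates <- function(env, cued = "right") {
  arm <- (env$width - 1L) %/% 2L
  stem <- vapply(0:(env$height - 1L), function(r) state_at(env, r, arm),
                 integer(1))
  left <- vapply((arm - 1L):0, function(c) state_at(env, 0L, c), integer(1))
  right <- vapply((arm + 1L):(env$width - 1L), function(c) state_at(env, 0L, c),
                  integer(1))
  cued_states <- if (cued == "right") right else left
  uncued_states <- if (cued == "right") left else right
  list(
    stem_forward = list(family = "stem", states = stem),
    stem_reverse = list(family = "stem", states = rev(stem)),
    cued_forward = list(family = "cued_arm", states = cued_states),
    cued_reverse = list(family = "cued_arm", states = rev(cued_states)),
    uncued_forward = list(family = "uncued_arm", states = uncued_states),
    uncued_reverse = list(family = "uncued_arm", states = rev(uncued_states))
  )
}

#' Classify a preplay trace by template matching
#'
#' The best-matching template (fewest mismatches, at most `max_mismatch`)
#' assigns its family; ties between different families yield "none".
#'
#' @param trace one trace tibble or integer state sequence.
#' @param templates [preplay_templates()] output.
#' @param max_mismatch allowed substitutions.
#' @return One of "cued_arm", "uncued_arm", "stem", "none".
#' @export
detect_preplay <- function(trace, templates, max_mismatch = 2L) {
  states <- if (is.data.frame(trace)) trace$s else as.integer(trace)
  best_mis <- Inf
  best_fams <- character(0)
  for (tp in templates) {
    res <- match_template(states, tp$states, max_mismatch = length(tp$states))
    if (is.na(res$mismatches)) next
    if (res$mismatches < best_mis) {
      best_mis <- res$mismatches
      best_fams <- tp$family
    } else if (res$mismatches == best_mis) {
      best_fams <- union(best_fams, tp$family)
    }
  }
  if (best_mis > max_mismatch || length(best_fams) != 1L) return("none")
  best_fams
}

#' Reactivation map
#'
#' The fraction of reactivations each state receives across a set of replay
#' traces (current states of replayed experiences).
#'
#' @param traces trace tibble.
#' @param env the grid world.
#' @return An `sfma_reactivation_map` tibble: state, row, col, n, fraction.
#' @export
reactivation_map <- function(traces, env) {
  stopifnot(nrow(traces) > 0)
  n <- tabulate(traces$s, nbins = env$n_states)
  out <- tibble::tibble(
    state = seq_len(env$n_states),
    row = env$coords[, 1], col = env$coords[, 2],
    n = n, fraction = n / sum(n)
  )
  class(out) <- c("sfma_reactivation_map", class(out))
  out
}

#' Fraction of barrier-crossing consecutive reactivations
#'
#' A pair of consecutively replayed experiences is invalid when their current
#' states are separated by a barrier.
#'
#' @param traces trace tibble.
#' @param env the grid world defining the barriers.
#' @return Fraction in [0, 1].
#' @export
invalid_transition_fraction <- function(traces, env) {
  if (!nrow(env$barriers)) return(0)
  keys <- pair_key(env$barriers[, 1], env$barriers[, 2], env$n_states)
  per <- split_trace_states(traces)
  bad <- 0L
  tot <- 0L
  for (v in per) {
    len <- length(v)
    if (len < 2L) next
    i <- seq_len(len - 1L)
    bad <- bad + sum(pair_key(v[i], v[i + 1L], env$n_states) %in% keys)
    tot <- tot + len - 1L
  }
  if (tot == 0L) return(0)
  bad / tot
}

## Gain of hypothetically backing up experience e under Q: the greedy-policy
## value improvement at its source state. With uniform need this is the
## expected value of backup up to a constant.
backup_gain <- function(val, s, a, r, sn, gamma, eta) {
  qs <- val[s, ]
  td <- r + gamma * max(val[sn, ]) - qs[a]
  qs_new <- qs
  qs_new[a] <- qs[a] + eta * td
  pi_old <- as.numeric(qs == max(qs))
  pi_old <- pi_old / sum(pi_old)
  pi_new <- as.numeric(qs_new == max(qs_new))
  pi_new <- pi_new / sum(pi_new)
  sum((pi_new - pi_old) * qs_new)
}

#' Optimality of replayed backups (uniform need)
#'
#' For each replay step, each stored experience's utility is its gain — the
#' greedy-policy improvement its hypothetical backup would produce at its
#' source state — and the reactivated experience is optimal when it attains
#' the maximal gain (ties count as optimal). The Q-table is updated along the
#' trace, so each step is scored against the Q snapshot it actually saw.
#'
#' @param trace one trace tibble.
#' @param memory the memory holding all stored experiences.
#' @param q the Q-table as it stood when the replay epoch started.
#' @return Tibble: step, gain, max_gain, optimal.
#' @export
optimal_update_fraction <- function(trace, memory, q) {
  n <- nrow(trace)
  out <- tibble::tibble(step = seq_len(n), gain = NA_real_,
                        max_gain = NA_real_, optimal = NA)
  seen <- which(memory$C > 0)
  for (i in seq_len(n)) {
    gains <- vapply(seen, function(e) {
      backup_gain(q$values, memory$src[e], memory$act[e], memory$rew[e],
                  memory$dst[e], q$gamma, q$eta)
    }, numeric(1))
    g_i <- backup_gain(q$values, trace$s[i], action_id(trace$a[i]),
                       trace$r[i], trace$s_next[i], q$gamma, q$eta)
    mg <- max(gains, g_i)
    out$gain[i] <- g_i
    out$max_gain[i] <- mg
    out$optimal[i] <- g_i >= mg - 1e-12
    q <- q_update(q, trace$s[i], action_id(trace$a[i]), trace$r[i],
                  trace$s_next[i])$q
  }
  out
}
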