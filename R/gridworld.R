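## Cardinal actions, fixed order. Deltas are (row, col) with 0-based coordinates.
ACTIONS <- c(N = 1L, E = 2L, S = 3L, W = 4L)
ACTION_DROW <- c(-1L, 0L, 1L, 0L)
ACTION_DCOL <- c(0L, 1L, 0L, -1L)

action_id <- function(action) {
  if (is.character(action)) {
    id <- unname(ACTIONS[match(action, names(ACTIONS))])
  } else {
    id <- as.integer(action)
  }
  if (any(is.na(id)) || any(id < 1L) || any(id > 4L)) {
    stop("invalid action; use one of N, E, S, W (or 1:4)", call. = FALSE)
  }
  id
}

## Canonical key for an unordered state pair (a < b), used for barrier lookups.
pair_key <- function(a, b, n_states) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  (as.numeric(lo) - 1) * n_states + as.numeric(hi)
}

#' Construct a grid world from a free-cell mask
#'
#' States are the free cells, enumerated row-major with 0-based (row, col)
#' coordinates. Every state has the four cardinal actions; an action whose
#' target lies outside the grid, on an obstacle, or across a barrier resolves
#' to a self-transition.
#'
#' @param free logical matrix (height x width); TRUE marks a free cell.
#' @param barriers integer matrix with two columns of state indices; each row
#'   blocks the transition between two adjacent states (symmetrically).
#' @return An object of class `sfma_gridworld`.
#' @keywords internal
new_gridworld <- function(free, barriers = NULL) {
  h <- nrow(free)
  w <- ncol(free)
  cell <- matrix(NA_integer_, h, w)
  k <- 0L
  coords <- matrix(0L, sum(free), 2L)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (free[r, c]) {
        k <- k + 1L
        cell[r, c] <- k
        coords[k, ] <- c(r - 1L, c - 1L)
      }
    }
  }
  env <- structure(
    list(
      width = w, height = h, n_states = k,
      coords = coords, cell = cell,
      barriers = matrix(integer(0), 0L, 2L),
      rewards = numeric(k),
      start = NA_integer_, goal = NA_integer_,
      labels = character(k)
    ),
    class = "sfma_gridworld"
  )
  env$labels[] <- ""
  if (!is.null(barriers) && nrow(barriers) > 0L) {
    env <- gw_add_barriers(env, barriers)
  } else {
    env$trans <- build_transitions(env)
  }
  env
}

## S x 4 integer matrix of transition targets (self where blocked).
build_transitions <- function(env) {
  S <- env$n_states
  keys <- if (nrow(env$barriers)) {
    pair_key(env$barriers[, 1], env$barriers[, 2], S)
  } else {
    numeric(0)
  }
  trans <- matrix(0L, S, 4L)
  for (a in 1:4) {
    tr <- env$coords[, 1] + ACTION_DROW[a]
    tc <- env$coords[, 2] + ACTION_DCOL[a]
    inside <- tr >= 0L & tr < env$height & tc >= 0L & tc < env$width
    tgt <- rep(NA_integer_, S)
    tgt[inside] <- env$cell[cbind(tr[inside] + 1L, tc[inside] + 1L)]
    tgt[is.na(tgt)] <- seq_len(S)[is.na(tgt)]
    if (length(keys)) {
      blocked <- pair_key(seq_len(S), tgt, S) %in% keys
      tgt[blocked] <- seq_len(S)[blocked]
    }
    trans[, a] <- tgt
  }
  trans
}

#' Add or remove barriers between adjacent states
#'
#' Barriers are stored as unordered state pairs and applied symmetrically:
#' blocking (a, b) also blocks (b, a). Both affected actions then resolve to
#' self-transitions.
#'
#' @param env a grid world.
#' @param pairs two-column matrix of state indices.
#' @return The modified grid world (transition table rebuilt).
#' @export
gw_add_barriers <- function(env, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  stopifnot(all(pairs >= 1L), all(pairs <= env$n_states))
  all_pairs <- rbind(env$barriers, pairs)
  keys <- pair_key(all_pairs[, 1], all_pairs[, 2], env$n_states)
  env$barriers <- all_pairs[!duplicated(keys), , drop = FALSE]
  env$trans <- build_transitions(env)
  env
}

#' @rdname gw_add_barriers
#' @export
gw_remove_barriers <- function(env, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  keys_old <- pair_key(env$barriers[, 1], env$barriers[, 2], env$n_states)
  keys_rm <- pair_key(pairs[, 1], pairs[, 2], env$n_states)
  env$barriers <- env$barriers[!(keys_old %in% keys_rm), , drop = FALSE]
  env$trans <- build_transitions(env)
  env
}

#' Look up the state at grid coordinates
#'
#' @param env a grid world.
#' @param row,col 0-based coordinates.
#' @return State index (integer), or NA for an obstacle cell.
#' @export
state_at <- function(env, row, col) {
  env$cell[cbind(row + 1L, col + 1L)]
}

#' Set the start / goal state of a grid world
#'
#' Setting a goal also assigns its reward magnitude.
#' @param env a grid world.
#' @param state state index.
#' @param reward reward magnitude delivered at the goal.
#' @export
gw_set_start <- function(env, state) {
  stopifnot(state >= 1L, state <= env$n_states)
  env$start <- as.integer(state)
  if (env$labels[state] == "") env$labels[state] <- "S"
  env
}

#' @rdname gw_set_start
#' @export
gw_set_goal <- function(env, state, reward = 1) {
  stopifnot(state >= 1L, state <= env$n_states, is.finite(reward))
  env$goal <- as.integer(state)
  env$rewards[state] <- reward
  if (env$labels[state] == "") env$labels[state] <- "G"
  env
}

#' Build a linear track
#'
#' A 1 x `length` corridor with the start at the left end and a rewarded goal
#' (reward 1) at the right end. Setting `shock_zone > 0` labels that many
#' leftmost states as an aversive shock zone instead and assigns them the
#' shock magnitude as (punishment) reward, with no start/goal.
#'
#' @param length number of states (>= 2).
#' @param shock_zone number of leftmost states forming a shock zone.
#' @param shock_magnitude punishment magnitude associated with the zone.
#' @return An `sfma_gridworld`.
#' @examples
#' track <- build_linear_track(10)
#' track$n_states
#' @export
build_linear_track <- function(length, shock_zone = 0L, shock_magnitude = 1) {
  if (length < 2L) stop("a linear track needs at least 2 states", call. = FALSE)
  env <- new_gridworld(matrix(TRUE, 1L, length))
  if (shock_zone > 0L) {
    zone <- seq_len(shock_zone)
    env$rewards[zone] <- shock_magnitude
    env$labels[zone] <- "shock"
  } else {
    env <- gw_set_start(env, 1L)
    env <- gw_set_goal(env, env$n_states, reward = 1)
  }
  env
}

#' Build a rectangular open field
#'
#' All cells free, no barriers, no rewards.
#' @param width,height positive dimensions.
#' @export
build_open_field <- function(width, height) {
  if (width < 1L || height < 1L) stop("dimensions must be positive", call. = FALSE)
  new_gridworld(matrix(TRUE, height, width))
}

#' Build a T-maze
#'
#' A vertical stem of `stem_length` states topped by a horizontal arm row with
#' `arm_length` states on each side. The junction (top of stem) is part of the
#' stem. With `arms_blocked = TRUE`, barriers sever the junction from both
#' arms, leaving the arms visible but physically unreachable.
#'
#' @param stem_length states in the stem, junction included.
#' @param arm_length states per arm.
#' @param arms_blocked insert the stem/arm barriers?
#' @export
build_t_maze <- function(stem_length = 5L, arm_length = 3L, arms_blocked = FALSE) {
  if (arm_length < 1L || stem_length < 2L) {
    stop("need stem_length >= 2 and arm_length >= 1", call. = FALSE)
  }
  w <- 2L * arm_length + 1L
  free <- matrix(FALSE, stem_length, w)
  free[1L, ] <- TRUE
  free[, arm_length + 1L] <- TRUE
  env <- new_gridworld(free)
  junction <- state_at(env, 0L, arm_length)
  if (arms_blocked) {
    left <- state_at(env, 0L, arm_length - 1L)
    right <- state_at(env, 0L, arm_length + 1L)
    env <- gw_add_barriers(env, rbind(c(junction, left), c(junction, right)))
  }
  env$labels[junction] <- "D"
  env
}

FIGURE_EIGHT_LAYOUT <- paste(
  "...........",
  ".####.####.",
  ".####.####.",
  ".####.####.",
  ".####.####.",
  ".####.####.",
  "..R..S..R..",
  sep = "\n"
)

#' Build the figure-eight maze
#'
#' An 11 x 7 track: outer ring plus a central corridor. Trials start at the
#' bottom of the corridor (S), the decision point D sits at its top, and one
#' reward site (R) lies on each side of the bottom rail.
#' @export
build_figure_eight <- function() {
  env <- load_layout(FIGURE_EIGHT_LAYOUT)
  d <- state_at(env, 0L, 5L)
  env$labels[d] <- "D"
  env
}

#' Parse an ASCII grid layout
#'
#' Characters: `#` obstacle, `.` free, `S` start, `G` goal (reward 1),
#' `R` reward site (reward 1), `D` decision point. Rows must be equal length.
#'
#' @param text layout as a single newline-delimited string or character vector
#'   of rows.
#' @return An `sfma_gridworld`.
#' @examples
#' load_layout("SG")$n_states
#' @export
load_layout <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty layout", call. = FALSE)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged layout: line %d has %d characters, expected %d",
                 bad, widths[bad], widths[1]), call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(lines, "", fixed = TRUE))
  known <- c("#", ".", "S", "G", "R", "D")
  bad <- which(matrix(!(chars %in% known), nrow(chars)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("unknown layout character '%s' at line %d",
                 chars[bad[1, 1], bad[1, 2]], bad[1, 1]), call. = FALSE)
  }
  env <- new_gridworld(chars != "#")
  for (r in seq_len(nrow(chars))) {
    for (c in seq_len(ncol(chars))) {
      ch <- chars[r, c]
      if (ch %in% c("S", "G", "R", "D")) {
        s <- env$cell[r, c]
        if (ch == "S") env <- gw_set_start(env, s)
        if (ch == "G") env <- gw_set_goal(env, s, reward = 1)
        if (ch == "R") {
          env$rewards[s] <- 1
          env$labels[s] <- "R"
        }
        if (ch == "D") env$labels[s] <- "D"
      }
    }
  }
  env
}

#' @rdname load_layout
#' @param path path to a layout file.
#' @export
load_layout_file <- function(path) {
  load_layout(readLines(path))
}

#' Take one environment step
#'
#' @param env a grid world.
#' @param state current state index.
#' @param action one of "N","E","S","W" (or 1:4).
#' @return The successor state (the same state if the move is blocked).
#' @export
gw_step <- function(env, state, action) {
  state <- as.integer(state)
  if (any(state < 1L) || any(state > env$n_states)) {
    stop("invalid state", call. = FALSE)
  }
  env$trans[cbind(state, action_id(action))]
}

#' Transition matrix of the uniform default policy
#'
#' Row-stochastic |S| x |S| matrix with T[s, s'] = (number of actions from s
#' resolving to s') / 4. Wall and barrier bumps contribute to the diagonal.
#'
#' @param env a grid world.
#' @export
transition_matrix <- function(env) {
  S <- env$n_states
  Tm <- matrix(0, S, S)
  for (a in 1:4) {
    idx <- cbind(seq_len(S), env$trans[, a])
    Tm[idx] <- Tm[idx] + 0.25
  }
  Tm
}

#' @export
print.sfma_gridworld <- function(x, ...) {
  cat(sprintf("<sfma_gridworld> %d x %d grid, %d states, %d barrier pairs\n",
              x$width, x$height, x$n_states, nrow(x$barriers)))
  if (!is.na(x$start)) cat("  start:", x$start, "\n")
  if (!is.na(x$goal)) cat("  goal:", x$goal, "reward", x$rewards[x$goal], "\n")
  invisible(x)
}

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.sfma_gridworld <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$n_states),
    row = x$coords[, 1],
    col = x$coords[, 2],
    label = x$labels,
    reward = x$rewards
  )
}

#' Serialize a grid world to JSON
#'
#' Records dimensions, free cells, barrier pairs, rewards and labels so a run
#' can be reproduced from its logs.
#' @param env a grid world.
#' @param path optional file; if NULL the JSON string is returned.
#' @export
gw_to_json <- function(env, path = NULL) {
  obj <- list(
    width = env$width, height = env$height,
    coords = env$coords, barriers = env$barriers,
    rewards = env$rewards, start = env$start, goal = env$goal,
    labels = env$labels
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
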