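#' Compute the Default Representation from a transition matrix
#'
#' The Default Representation (DR) is the discounted expected state occupancy
#' under the uniform default policy, D = (I - gamma_dr * T)^-1. For a
#' row-stochastic T every row of D sums to 1/(1 - gamma_dr). Grid worlds give
#' a symmetric T (one action per direction between adjacent free cells), so D
#' is symmetric as well.
#'
#' @param T row-stochastic |S| x |S| transition matrix.
#' @param gamma_dr discount in [0, 1).
#' @return An `sfma_similarity` object of kind "dr" carrying the dense matrix
#'   `D` and the transition matrix it was built from.
#' @examples
#' compute_dr(matrix(1, 1, 1), 0.1)$D # 1 / 0.9
#' @export
compute_dr <- function(T, gamma_dr) {
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  if (gamma_dr < 0 || gamma_dr >= 1) {
    stop("gamma_dr must lie in [0, 1)", call. = FALSE)
  }
  D <- solve(diag(nrow(T)) - gamma_dr * T)
  structure(
    list(kind = "dr", D = D, gamma_dr = gamma_dr, T = T),
    class = "sfma_similarity"
  )
}

#' @rdname compute_dr
#' @param env a grid world; its default-policy transition matrix is used.
#' @export
similarity_dr <- function(env, gamma_dr = 0.1) {
  compute_dr(transition_matrix(env), gamma_dr)
}

#' Fold barrier changes into a DR by a low-rank (Woodbury) correction
#'
#' Given the DR of one environment and the transition matrix of a modified
#' one (barriers inserted and/or removed), returns the DR of the modified
#' environment without re-inverting the full system. With k affected source
#' states the cost is O(|S|^2 k + k^3): writing the change as Delta T = U V
#' with U the k identity columns, the Woodbury identity gives
#' D' = D + gamma D U (I_k - gamma V D U)^-1 V D.
#'
#' @param model an `sfma_similarity` of kind "dr".
#' @param new_T transition matrix of the modified environment (or pass `env`).
#' @param env alternative to `new_T`: the modified grid world.
#' @return The updated `sfma_similarity`.
#' @export
apply_barrier_update <- function(model, new_T = NULL, env = NULL) {
  if (model$kind != "dr") stop("barrier updates require a DR model", call. = FALSE)
  if (is.null(new_T)) {
    if (is.null(env)) stop("supply new_T or env", call. = FALSE)
    new_T <- transition_matrix(env)
  }
  delta <- new_T - model$T
  rows <- which(rowSums(abs(delta)) > 0)
  if (!length(rows)) return(model)
  g <- model$gamma_dr
  V <- delta[rows, , drop = FALSE]
  VD <- V %*% model$D                       # k x S
  M <- diag(length(rows)) - g * VD[, rows, drop = FALSE]
  model$D <- model$D + g * model$D[, rows, drop = FALSE] %*% solve(M, VD)
  model$T <- new_T
  model
}

#' Euclidean state similarity (structure-blind control)
#'
#' D[i, j] = exp(-||c_i - c_j||) on the grid coordinates. Barriers are
#' ignored: two cells on opposite sides of a wall are as similar as any other
#' pair at the same Euclidean distance.
#'
#' @param env a grid world.
#' @export
similarity_euclidean <- function(env) {
  D <- exp(-as.matrix(stats::dist(env$coords)))
  dimnames(D) <- NULL
  structure(
    list(kind = "euclidean", D = D, gamma_dr = NA_real_, T = NULL),
    class = "sfma_similarity"
  )
}

#' Similarity of every stored experience to the one just reactivated
#'
#' In the default mode the current state of the reactivated experience is
#' compared to the current states of all stored experiences; in the reverse
#' mode it is compared to their next states.
#'
#' @param model an `sfma_similarity`.
#' @param memory an `sfma_memory`.
#' @param e_t index of the most recently reactivated experience.
#' @param mode "default" or "reverse".
#' @return Numeric vector over experiences.
#' @export
experience_similarity <- function(model, memory, e_t, mode = c("default", "reverse")) {
  mode <- match.arg(mode)
  s_t <- memory$src[e_t]
  cmp <- if (mode == "default") memory$src else memory$dst
  model$D[, s_t][cmp]
}

#' @export
print.sfma_similarity <- function(x, ...) {
  cat(sprintf("<sfma_similarity> kind=%s, %d states", x$kind, nrow(x$D)))
  if (x$kind == "dr") cat(sprintf(", gamma_dr=%g", x$gamma_dr))
  cat("\n")
  invisible(x)
}
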