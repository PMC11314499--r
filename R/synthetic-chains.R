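#' Specification of a block-metastable Markov chain
#'
#' Describes a discrete-state chain whose states are partitioned into
#' metastable blocks. Each row of the resulting transition matrix spends
#' probability `1 - p_between` inside the state's own block (spread
#' uniformly over the block, self included) and `p_between` outside it
#' (spread uniformly over all other states), so small `p_between` gives
#' slow inter-block exchange and eigenvalues close to 1.
#'
#' @param n_states number of states (positive integer).
#' @param blocks list of integer vectors partitioning `1:n_states`.
#' @param p_between probability mass per row leaving the block; in `[0, 1)`.
#' @param seed integer seed attached to the spec for downstream sampling.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n_states, blocks = list(seq_len(n_states)),
                       p_between = 0.1, seed = 1L) {
  stopifnot(n_states >= 1, p_between >= 0, p_between < 1)
  all_states <- sort(unlist(blocks))
  if (anyDuplicated(all_states))
    stop("blocks overlap: each state may appear in exactly one block")
  if (!identical(as.integer(all_states), seq_len(n_states)))
    stop("blocks must partition 1:n_states")
  structure(
    list(n_states = as.integer(n_states), blocks = blocks,
         p_within = 1 - p_between, p_between = p_between,
         seed = as.integer(seed)),
    class = "chain_spec")
}

#' Build a row-stochastic transition matrix from a chain spec
#'
#' The construction is symmetric (doubly stochastic), so the chain is
#' reversible with respect to the uniform stationary distribution and has
#' a real spectrum. With a single state per block it reduces to the
#' familiar symmetric two-state matrix, e.g. `p_between = 0.1` on two
#' states gives `[[0.9, 0.1], [0.1, 0.9]]`.
#'
#' @param spec a [chain_spec()].
#' @return An `n x n` row-stochastic matrix.
#' @export
make_transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_states
  T_ <- matrix(0, n, n)
  block_of <- integer(n)
  for (b in seq_along(spec$blocks)) block_of[spec$blocks[[b]]] <- b
  for (i in seq_len(n)) {
    inside <- which(block_of == block_of[i])
    outside <- setdiff(seq_len(n), inside)
    T_[i, inside] <- (1 - spec$p_between) / length(inside)
    if (length(outside) > 0) {
      T_[i, outside] <- spec$p_between / length(outside)
    } else {
      # single block: all mass stays inside
      T_[i, inside] <- 1 / length(inside)
    }
  }
  stopifnot(all(abs(rowSums(T_) - 1) < 1e-12))
  T_
}

check_stochastic <- function(T_, tol = 1e-8) {
  if (!is.matrix(T_) || nrow(T_) != ncol(T_))
    stop("transition matrix must be square")
  if (any(T_ < -tol) || any(abs(rowSums(T_) - 1) > tol))
    stop("matrix is not row-stochastic")
  invisible(TRUE)
}

#' Sample a discrete trajectory from a transition matrix
#'
#' @param T_ row-stochastic transition matrix.
#' @param n_steps trajectory length (>= 1), including the start state.
#' @param seed integer seed; fixed seed implies an identical sequence.
#' @param start starting state (1-based); default drawn uniformly.
#' @return Integer vector of 1-based state indices, length `n_steps`.
#' @export
sample_discrete_chain <- function(T_, n_steps, seed = 1L, start = NULL) {
  check_stochastic(T_)
  stopifnot(n_steps >= 1)
  n <- nrow(T_)
  cum <- t(apply(T_, 1, cumsum))
  set.seed(as.integer(seed))
  s <- integer(n_steps)
  s[1] <- if (is.null(start)) sample.int(n, 1) else as.integer(start)
  if (s[1] < 1 || s[1] > n) stop("start state out of range")
  if (n_steps > 1) {
    u <- stats::runif(n_steps - 1)
    for (t in 2:n_steps) {
      s[t] <- findInterval(u[t - 1], cum[s[t - 1], ]) + 1L
    }
  }
  s
}
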