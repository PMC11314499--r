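as_dtraj_list <- function(dtrajs) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lapply(dtrajs, function(d) {
    d <- as.integer(d)
    if (length(d) < 2) stop("each discrete trajectory needs >= 2 frames")
    if (any(d < 1)) stop("state indices must be 1-based positive integers")
    d
  })
}

#' Transition count matrix at a lag
#'
#' Counts observed jumps `(s_t, s_{t+lag})` within each trajectory; no
#' pairs are formed across trajectory boundaries. Sliding mode uses every
#' starting frame (maximal data, correlated counts); strided mode uses
#' every `lag`-th frame (independent counts).
#'
#' @param dtrajs integer vector of 1-based microstate labels, or a list
#'   of such vectors.
#' @param lag lag time in frames (>= 1, shorter than every trajectory).
#' @param n_states number of states (default: largest label observed).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @return `n_states x n_states` count matrix.
#' @export
count_matrix <- function(dtrajs, lag = 1L, n_states = NULL,
                         mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  dtrajs <- as_dtraj_list(dtrajs)
  stopifnot(lag >= 1)
  if (any(vapply(dtrajs, length, 1L) <= lag))
    stop("lag must be shorter than every trajectory")
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, 1L))
  C <- matrix(0, n_states, n_states)
  for (d in dtrajs) {
    starts <- if (mode == "sliding") seq_len(length(d) - lag)
              else seq(1L, length(d) - lag, by = lag)
    from <- d[starts]; to <- d[starts + lag]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  if (sum(C) == 0) stop("no transition counts observed")
  dimnames(C) <- NULL
  C
}

#' Estimate a Markov state model from a count matrix
#'
#' The model is restricted to the largest strongly connected set of
#' states (an index map back to the original labels is reported; dropped
#' states are never silently renumbered). The reversible estimator
#' (default) row-normalizes the symmetrized counts `(C + C^T)/2`, which
#' satisfies detailed balance exactly with stationary distribution
#' proportional to the symmetrized row sums. The nonreversible estimator
#' row-normalizes `C` directly and takes the stationary distribution from
#' the leading left eigenvector.
#'
#' @param C count matrix from [count_matrix()].
#' @param reversible logical, default TRUE.
#' @param lag lag in frames used for the counts (metadata).
#' @param frame_interval frame spacing (ns), for physical timescales.
#' @return Object of class `msm_model`: `P` (row-stochastic), `pi`
#'   (stationary), `C`, `eigenvalues`, `active_states` (original labels
#'   of the retained states), `lag`, `lag_ns`, `reversible`.
#' @export
estimate_msm <- function(C, reversible = TRUE, lag = 1L,
                         frame_interval = 1) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  keep <- which(comp$membership == which.max(tabulate(comp$membership)))
  cov_counts <- sum(C[keep, keep]) / sum(C)
  if (length(keep) < nrow(C) && cov_counts < 0.5)
    stop(sprintf("largest connected state set covers only %.0f%% of counts",
                 100 * cov_counts))
  Ck <- C[keep, keep, drop = FALSE]
  if (reversible) {
    S <- (Ck + t(Ck)) / 2
    P <- S / rowSums(S)
    pi_ <- rowSums(S) / sum(S)
  } else {
    P <- Ck / rowSums(Ck)
    e <- eigen(t(P))
    v <- Re(e$vectors[, which.max(Re(e$values))])
    if (all(v <= 0)) v <- -v
    pi_ <- v / sum(v)
  }
  ev <- eigen(P)
  ord <- order(Mod(ev$values), decreasing = TRUE)
  structure(
    list(P = P, pi = pi_, C = Ck,
         eigenvalues = ev$values[ord],
         right_eigenvectors = ev$vectors[, ord, drop = FALSE],
         active_states = keep, lag = as.integer(lag),
         lag_ns = lag * frame_interval, frame_interval = frame_interval,
         reversible = reversible),
    class = "msm_model")
}

#' Implied relaxation timescales over a set of lag times
#'
#' For each lag, estimates an MSM and reports
#' `t_i(tau) = -tau / ln |lambda_{i+1}(tau)|` in both frames and ns.
#' Non-positive eigenvalues give no defined timescale and are flagged
#' rather than dropped.
#'
#' @param dtrajs discrete trajectory (or list).
#' @param lags integer vector of lags (frames).
#' @param n_timescales how many timescales per lag (default 3).
#' @param frame_interval frame spacing (ns).
#' @param reversible estimator flag, passed to [estimate_msm()].
#' @return Data frame with columns `lag`, `index`, `eigenvalue`,
#'   `timescale_frames`, `timescale_ns`, `defined`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3L,
                               frame_interval = 1, reversible = TRUE) {
  rows <- list()
  for (lag in lags) {
    m <- estimate_msm(count_matrix(dtrajs, lag), reversible = reversible,
                      lag = lag, frame_interval = frame_interval)
    lam <- Re(m$eigenvalues)
    lam <- lam[-1]                       # drop the stationary eigenvalue
    k <- min(n_timescales, length(lam))
    for (i in seq_len(k)) {
      li <- lam[i]
      defined <- is.finite(li) && li > 0 && li < 1
      ts_f <- if (!defined) {
        if (li >= 1) Inf else NA_real_
      } else -lag / log(li)
      rows[[length(rows) + 1L]] <- data.frame(
        lag = lag, index = i, eigenvalue = li,
        timescale_frames = ts_f,
        timescale_ns = ts_f * frame_interval,
        defined = defined)
    }
  }
  do.call(rbind, rows)
}

#' Select the Markov time from an implied-timescale table
#'
#' Returns the smallest lag whose slowest implied timescale changes by
#' less than `tolerance` (relative) with respect to the next two larger
#' lags -- i.e. where the timescale curve has flattened and the model has
#' become memoryless at that resolution.
#'
#' @param its_table output of [implied_timescales()].
#' @param tolerance relative change threshold (default 0.05).
#' @return The chosen lag (frames).
#' @export
select_markov_time <- function(its_table, tolerance = 0.05) {
  t1 <- its_table[its_table$index == 1, ]
  t1 <- t1[order(t1$lag), ]
  if (nrow(t1) < 3) stop("need at least 3 lags to assess convergence")
  for (i in seq_len(nrow(t1) - 2)) {
    ref <- t1$timescale_frames[i]
    nxt <- t1$timescale_frames[c(i + 1, i + 2)]
    if (!all(is.finite(c(ref, nxt)))) next
    if (all(abs(nxt - ref) / ref < tolerance)) return(t1$lag[i])
  }
  stop("implied timescales do not converge over the supplied lags:\n",
       paste(utils::capture.output(print(t1)), collapse = "\n"))
}

#' Chapman--Kolmogorov test
#'
#' Compares the transition matrix re-estimated at lag `k * tau` with the
#' k-th matrix power of the model estimated at `tau`. The deviation at
#' each k is the maximum row total-variation distance
#' `max_i 0.5 * sum_j |P_est(k tau)_ij - [P(tau)^k]_ij|`, a scale-free
#' number interpretable as misplaced probability mass. The test passes
#' when every deviation is below `threshold` (default 0.05).
#'
#' @param dtrajs discrete trajectory (or list).
#' @param tau base lag (frames).
#' @param k_values integer multiples of `tau` to test.
#' @param threshold pass threshold on the deviation (default 0.05).
#' @param reversible estimator flag.
#' @return Object of class `ck_report`: data frame `deviations` (k,
#'   deviation), `tau`, `threshold`, `pass`.
#' @export
ck_test <- function(dtrajs, tau, k_values = c(2L, 3L, 5L),
                    threshold = 0.05, reversible = TRUE) {
  dtrajs <- as_dtraj_list(dtrajs)
  if (any(vapply(dtrajs, length, 1L) <= max(k_values) * tau))
    stop("trajectories too short for the largest k * tau")
  n_states <- max(vapply(dtrajs, max, 1L))
  m1 <- estimate_msm(count_matrix(dtrajs, tau, n_states), reversible,
                     lag = tau)
  devs <- vapply(k_values, function(k) {
    mk <- estimate_msm(count_matrix(dtrajs, k * tau, n_states), reversible,
                       lag = k * tau)
    common <- intersect(m1$active_states, mk$active_states)
    i1 <- match(common, m1$active_states)
    ik <- match(common, mk$active_states)
    Pk_pred <- matpow(m1$P, k)[i1, i1, drop = FALSE]
    Pk_est <- mk$P[ik, ik, drop = FALSE]
    # renormalize rows after restriction to the common state set
    Pk_pred <- Pk_pred / rowSums(Pk_pred)
    Pk_est <- Pk_est / rowSums(Pk_est)
    max(0.5 * rowSums(abs(Pk_est - Pk_pred)))
  }, numeric(1))
  structure(
    list(deviations = data.frame(k = k_values, deviation = devs),
         tau = tau, threshold = threshold, pass = all(devs < threshold)),
    class = "ck_report")
}

matpow <- function(P, k) {
  R <- diag(nrow(P))
  for (i in seq_len(k)) R <- R %*% P
  R
}

#' @export
print.ck_report <- function(x, ...) {
  cat(sprintf("Chapman-Kolmogorov test at tau = %d frames: %s (threshold %.0f%%)\n",
              x$tau, if (x$pass) "PASS" else "FAIL", 100 * x$threshold))
  print(x$deviations, row.names = FALSE)
  invisible(x)
}
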