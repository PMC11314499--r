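#' Forward and backward committors of an MSM
#'
#' The forward committor `q+_i` is the probability that a trajectory
#' started in microstate i reaches the sink set B before the source set
#' A. It satisfies the boundary-value problem `q+ = 0` on A, `q+ = 1` on
#' B and `q+_i = sum_{j in B} T_ij + sum_{j notin A u B} T_ij q+_j`
#' elsewhere, solved here as a dense linear system. For reversible models
#' the backward committor is `q- = 1 - q+`; otherwise it is computed on
#' the time-reversed chain `T~_ij = pi_j T_ji / pi_i`.
#'
#' @param model an [estimate_msm()] result.
#' @param A,B disjoint non-empty source/sink state sets (1-based indices
#'   into the model's active states).
#' @param method `"solve"` (direct linear solve, default) or
#'   `"iterate"` (fixed-point iteration, available as a cross-check).
#' @param tol,max_iter fixed-point controls when `method = "iterate"`.
#' @return List with `q_plus`, `q_minus`.
#' @export
committors <- function(model, A, B, method = c("solve", "iterate"),
                       tol = 1e-14, max_iter = 100000L) {
  method <- match.arg(method)
  P <- model$P; n <- nrow(P)
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0 || length(B) == 0) stop("A and B must be non-empty")
  if (length(intersect(A, B)) > 0) stop("A and B must be disjoint")
  if (any(c(A, B) < 1) || any(c(A, B) > n)) stop("state index out of range")
  I_ <- setdiff(seq_len(n), union(A, B))
  q <- numeric(n); q[B] <- 1
  if (length(I_) > 0) {
    if (method == "solve") {
      M <- diag(length(I_)) - P[I_, I_, drop = FALSE]
      b <- rowSums(P[I_, B, drop = FALSE])
      qI <- tryCatch(solve(M, b),
                     error = function(e) stop("singular committor system: ", conditionMessage(e)))
      q[I_] <- qI
    } else {
      qI <- rep(0.5, length(I_))
      for (it in seq_len(max_iter)) {
        qn <- rowSums(P[I_, B, drop = FALSE]) +
          P[I_, I_, drop = FALSE] %*% qI
        if (max(abs(qn - qI)) < tol) { qI <- qn; break }
        qI <- qn
      }
      q[I_] <- qI
    }
  }
  q <- pmin(pmax(q, 0), 1)
  if (model$reversible) {
    qm <- 1 - q
  } else {
    Pt <- t(P) * model$pi / rep(model$pi, each = n)  # T~_ij = pi_j P_ji / pi_i
    Pt <- Pt / rowSums(Pt)
    qm <- numeric(n); qm[A] <- 1
    if (length(I_) > 0) {
      M <- diag(length(I_)) - Pt[I_, I_, drop = FALSE]
      b <- rowSums(Pt[I_, A, drop = FALSE])
      qm[I_] <- solve(M, b)
    }
    qm <- pmin(pmax(qm, 0), 1)
  }
  list(q_plus = q, q_minus = qm)
}

#' Reactive flux network between two state sets
#'
#' Gross reactive flux `f_ij = pi_i q-_i P_ij q+_j` (diagonal zeroed) and
#' net flux `f+_ij = max(0, f_ij - f_ji)`. The total A->B flux is the net
#' flux leaving A per lag step; it is also reported as a physical rate
#' using `lag * frame_interval` (ns per step).
#'
#' @param model an [estimate_msm()] result.
#' @param A,B source and sink sets.
#' @param q optional committor list from [committors()] (computed if
#'   missing).
#' @return Object of class `flux_network`: `A`, `B`, `q_plus`, `q_minus`,
#'   `gross`, `net`, `total_flux` (per lag step), `rate_per_s` (s^-1),
#'   `lag_ns`.
#' @export
flux_matrix <- function(model, A, B, q = NULL) {
  if (is.null(q)) q <- committors(model, A, B)
  n <- nrow(model$P)
  if (length(q$q_plus) != n) stop("committor length does not match the model")
  f <- (model$pi * q$q_minus) * model$P * rep(q$q_plus, each = n)
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(net[A, setdiff(seq_len(n), A), drop = FALSE])
  lag_ns <- model$lag_ns
  structure(
    list(A = A, B = B, q_plus = q$q_plus, q_minus = q$q_minus,
         gross = f, net = net, total_flux = total,
         rate_per_s = total / (lag_ns * 1e-9),
         lag_ns = lag_ns),
    class = "flux_network")
}

# widest (maximum-bottleneck) A->B path on a capacity matrix;
# returns list(path, width) or NULL when B is unreachable
widest_path <- function(cap, A, B) {
  n <- nrow(cap)
  width <- rep(-Inf, n); width[A] <- Inf
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & width > 0)
    if (length(cand) == 0) return(NULL)
    u <- cand[which.max(width[cand])]
    if (u %in% B) {
      path <- u
      while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
      return(list(path = path, width = width[u]))
    }
    done[u] <- TRUE
    for (v in which(cap[u, ] > 0 & !done)) {
      w <- min(width[u], cap[u, v])
      if (w > width[v]) { width[v] <- w; prev[v] <- u }
    }
  }
}

#' Decompose a net flux network into ranked pathways
#'
#' Iterative bottleneck decomposition: repeatedly extract the A->B path
#' whose minimum-capacity edge is maximal (widest-path search on the
#' residual net flux), record it with its bottleneck flux, and subtract
#' that flux along the path. Extraction stops when the residual total
#' flux falls below `min_fraction` of the original. Path percentages are
#' each path's share of the summed extracted flux.
#'
#' @param net a [flux_matrix()] result.
#' @param min_fraction stopping fraction of the original total flux
#'   (default 0.01).
#' @return List of pathways, each with `states` (ordered indices, A to
#'   B), `flux` (per lag step), `rate_per_s`, `percentage`.
#' @export
decompose_pathways <- function(net, min_fraction = 0.01) {
  stopifnot(inherits(net, "flux_network"))
  if (net$total_flux <= 0) stop("total flux must be positive")
  cap <- net$net
  A <- net$A; B <- net$B
  out <- list()
  residual <- net$total_flux
  while (residual > min_fraction * net$total_flux) {
    wp <- widest_path(cap, A, B)
    if (is.null(wp)) break
    f <- wp$width
    for (e in seq_len(length(wp$path) - 1))
      cap[wp$path[e], wp$path[e + 1]] <- cap[wp$path[e], wp$path[e + 1]] - f
    if (min(cap) < -1e-8 * net$total_flux)
      stop("numerical leakage in the residual flux network")
    cap[cap < 0] <- 0
    out[[length(out) + 1L]] <- list(states = wp$path, flux = f)
    residual <- residual - f
  }
  if (length(out) == 0) stop("no pathway could be extracted")
  tot <- sum(vapply(out, `[[`, numeric(1), "flux"))
  to_rate <- net$rate_per_s / net$total_flux
  lapply(out, function(p) {
    p$percentage <- 100 * p$flux / tot
    p$rate_per_s <- p$flux * to_rate
    p
  })
}

#' Format pathways as a ranked flux table
#'
#' Produces the standard flux-analysis table: one row per pathway with
#' the route rendered from state labels ("SA -> S1 -> SB"), the path flux
#' in s^-1 and its percentage of the total coarse flux, sorted by flux
#' descending, with a Total row whose percentage is 100. Values are
#' shown at 3 significant figures.
#'
#' @param pathways list of pathways (from [decompose_pathways()]) or a
#'   list of `list(states=, rate_per_s=)` entries; percentages are
#'   recomputed from the fluxes.
#' @param state_labels character labels per state (unique).
#' @return Object of class `pathway_table` (a data frame with attributes).
#' @export
pathway_report <- function(pathways, state_labels) {
  if (length(pathways) == 0) stop("pathway list is empty")
  if (anyDuplicated(state_labels)) stop("state labels must be unique")
  flux <- vapply(pathways, function(p)
    if (!is.null(p$rate_per_s)) p$rate_per_s else p$flux, numeric(1))
  ord <- order(flux, decreasing = TRUE)
  pathways <- pathways[ord]; flux <- flux[ord]
  pct <- 100 * flux / sum(flux)
  routes <- vapply(pathways, function(p)
    paste(state_labels[p$states], collapse = " -> "), character(1))
  df <- data.frame(
    Pathways = c(routes, "Total"),
    `Path Flux (s^-1)` = signif(c(flux, sum(flux)), 3),
    `Percentage of Total Coarse Flux (%)` = c(signif(pct, 3), 100),
    check.names = FALSE)
  structure(df, class = c("pathway_table", "data.frame"))
}

#' Write / read a pathway table as TSV
#' @param table a [pathway_report()] result.
#' @param path file path.
#' @export
write_pathway_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathway_table
#' @export
read_pathway_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  structure(df, class = c("pathway_table", "data.frame"))
}
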