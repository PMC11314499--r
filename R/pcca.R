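#' Coarse-grain microstates into metastable macrostates
#'
#' Spectral (PCCA-style) assignment: the rows of the matrix of the top
#' `n_macrostates` right eigenvectors of the transition matrix embed each
#' microstate in a space where metastable sets separate; clustering those
#' rows with restarted k-means yields the crisp macrostate assignment.
#' Soft memberships are derived from a Gaussian kernel on the spectral
#' distances and row-normalized.
#'
#' @param model an [estimate_msm()] result.
#' @param n_macrostates requested number of macrostates.
#' @param seed seed for the spectral-space k-means.
#' @return Object of class `macrostate_map`: `assignment` (macrostate per
#'   microstate), `n_macrostates`, `memberships` (rows sum to 1),
#'   `populations` (fractions of the stationary distribution).
#' @export
coarse_grain <- function(model, n_macrostates, seed = 1L) {
  stopifnot(inherits(model, "msm_model"), n_macrostates >= 1)
  n <- nrow(model$P)
  if (n_macrostates > n) stop("more macrostates than microstates")
  if (n_macrostates == n) {
    assignment <- seq_len(n)
    memberships <- diag(n)
  } else if (n_macrostates > sum(Re(model$eigenvalues) > 0)) {
    warning("requested macrostates exceed the number of positive eigenvalues; assignment is best-effort")
  }
  if (n_macrostates < n) {
    Evec <- Re(model$right_eigenvectors[, seq_len(n_macrostates), drop = FALSE])
    cm <- cluster_kmeans(Evec, n_macrostates, n_restarts = 10L, seed = seed)
    assignment <- cm$assignment
    D2 <- pmax(dist2_to_centers(Evec, cm$centers), 0)
    h <- max(mean(D2), 1e-12)
    K <- exp(-D2 / h)
    memberships <- K / rowSums(K)
    degen <- !is.finite(rowSums(memberships))
    if (any(degen)) {
      memberships[degen, ] <- 0
      memberships[cbind(which(degen), assignment[degen])] <- 1
    }
  }
  pops <- vapply(seq_len(n_macrostates), function(m)
    sum(model$pi[assignment == m]), numeric(1))
  structure(
    list(assignment = as.integer(assignment),
         n_macrostates = as.integer(n_macrostates),
         memberships = memberships, populations = pops),
    class = "macrostate_map")
}

#' Stationary populations of macrostates
#'
#' `population(M) = sum of pi_i over microstates i assigned to M`; the
#' populations sum to 1.
#'
#' @param model an [estimate_msm()] result.
#' @param map a [coarse_grain()] result (or any integer assignment).
#' @return Numeric vector of macrostate populations.
#' @export
macrostate_populations <- function(model, map) {
  assignment <- if (inherits(map, "macrostate_map")) map$assignment else as.integer(map)
  if (length(assignment) != length(model$pi))
    stop("assignment length does not match the model")
  vapply(sort(unique(assignment)), function(m)
    sum(model$pi[assignment == m]), numeric(1))
}
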