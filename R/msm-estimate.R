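asDtrajList <- function(dtrajs) {
  if (is(dtrajs, "DiscreteTrajectory")) return(list(dtrajs))
  if (is.list(dtrajs) && all(vapply(dtrajs, is, TRUE, "DiscreteTrajectory")))
    return(dtrajs)
  stopf("expected a DiscreteTrajectory or a list of them")
}

lagInFrames <- function(lag, frameInterval) {
  lagF <- as.integer(round(lag / frameInterval))
  if (lagF < 1 || abs(lagF * frameInterval - lag) > 1e-9 * max(lag, 1))
    stopf("lag (%g ns) must be a positive multiple of the frame interval (%g ns)",
          lag, frameInterval)
  lagF
}

#' Transition count matrix at a lag
#'
#' Sliding-window transition counts c_ij = #\{t : s_t = i, s_(t+lag) = j\}
#' pooled over trajectories, together with the largest connected set of the
#' symmetrized count graph (states outside it cannot support a reversible
#' model).
#'
#' @param dtrajs a [DiscreteTrajectory-class] or list of them
#' @param lag ns (positive multiple of the frame interval)
#' @param nStates number of states (default: from the trajectories)
#' @return list with `counts` (nStates x nStates integer matrix),
#'   `activeSet` (indices of the largest connected set), `lag`,
#'   `frameInterval`
#' @export
countMatrix <- function(dtrajs, lag, nStates = NULL) {
  dtrajs <- asDtrajList(dtrajs)
  dt <- dtrajs[[1]]@frameInterval
  lagF <- lagInFrames(lag, dt)
  n <- nStates %||% max(vapply(dtrajs, function(d) d@nStates, 1L))
  idx <- integer(0)
  any_ok <- FALSE
  acc <- integer(n * n)
  for (d in dtrajs) {
    s <- d@states
    len <- length(s)
    if (len <= lagF) next
    any_ok <- TRUE
    from <- s[seq_len(len - lagF)]
    to <- s[(lagF + 1):len]
    acc <- acc + tabulate((from - 1L) * n + to, nbins = n * n)
  }
  if (!any_ok) stopf("lag is not shorter than any trajectory")
  C <- matrix(acc, n, n, byrow = TRUE)
  sym <- (C + t(C)) > 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sym, mode = "undirected"))
  # largest component among states actually observed
  observed <- which(rowSums(C) + colSums(C) > 0)
  sizes <- tabulate(comp$membership[observed], nbins = comp$no)
  active <- observed[comp$membership[observed] == which.max(sizes)]
  list(counts = C, activeSet = as.integer(active), lag = lag,
       frameInterval = dt)
}

#' Reversible maximum-likelihood Markov model
#'
#' Maximum-likelihood transition matrix under detailed balance, via the
#' standard self-consistent fixed-point iteration on the symmetric pair
#' counts x_ij: x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j).  The stationary
#' distribution is pi_i = x_i / sum(x); detailed balance then holds by
#' construction and all eigenvalues are real.
#'
#' @param counts output of [countMatrix()], or a plain count matrix (then
#'   `lag` must be given and the largest connected set is computed here)
#' @param lag ns (taken from the count object when available)
#' @param maxIter,tol fixed-point cap and max-change convergence tolerance
#' @return a [MarkovModel-class] over the active set
#' @export
estimateReversible <- function(counts, lag = NULL, maxIter = 500000L,
                               tol = 1e-10) {
  if (is.matrix(counts))
    counts <- list(counts = counts, activeSet = NULL, lag = lag)
  lag <- counts$lag %||% lag
  if (is.null(lag)) stopf("lag required")
  C <- counts$counts
  active <- counts$activeSet
  if (is.null(active)) {
    sym <- (C + t(C)) > 0
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(sym, mode = "undirected"))
    observed <- which(rowSums(C) + colSums(C) > 0)
    if (length(observed) == 0) stopf("no connected set: empty count matrix")
    sizes <- tabulate(comp$membership[observed], nbins = comp$no)
    active <- observed[comp$membership[observed] == which.max(sizes)]
  }
  if (length(active) == 0) stopf("no connected set")
  C <- C[active, active, drop = FALSE]
  Csym <- C + t(C)
  ci <- rowSums(C)
  if (any(ci == 0)) stopf("active set contains a state with no outgoing counts")
  x <- Csym / 2
  converged <- FALSE
  resid <- NA_real_
  Told <- x / rowSums(x)
  for (it in seq_len(maxIter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    xnew <- Csym / denom
    xnew[Csym == 0] <- 0
    Tnew <- xnew / rowSums(xnew)
    resid <- max(abs(Tnew - Told))
    x <- xnew
    Told <- Tnew
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("reversible estimator did not converge (residual %.3g)", resid)
  x <- (x + t(x)) / 2
  pi <- rowSums(x) / sum(x)
  Tm <- x / rowSums(x)
  S <- diag(sqrt(pi)) %*% Tm %*% diag(1 / sqrt(pi))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  ev[1] <- 1
  new("MarkovModel", transitionMatrix = Tm, lag = lag, stationary = pi,
      eigenvalues = ev, activeSet = as.integer(active))
}

#' Log-likelihood of a transition matrix given counts
#'
#' @param T transition matrix
#' @param counts count matrix of matching dimension
#' @return sum of c_ij * log T_ij over observed transitions
#' @export
transitionLogLik <- function(T, counts) {
  sel <- counts > 0
  if (any(T[sel] <= 0)) return(-Inf)
  sum(counts[sel] * log(T[sel]))
}

#' Implied relaxation timescales across lags
#'
#' For each lag tau, a reversible model is estimated and the implied
#' timescales t_i(tau) = -tau / ln lambda_i(tau) of the top eigenvalues are
#' reported; a levelling-off of t_2 with tau indicates Markovianity at that
#' lag.  Non-positive eigenvalues yield NA timescales rather than an error.
#'
#' @param dtrajs a [DiscreteTrajectory-class] or list of them
#' @param lags vector of lag times, ns
#' @param nTimescales how many timescales (beyond the stationary process)
#' @return data.frame with columns lag, index (2, 3, ...), eigenvalue,
#'   timescale; attribute `plateau` holds the relative change of t_2 between
#'   successive lags
#' @export
impliedTimescales <- function(dtrajs, lags, nTimescales = 3) {
  rows <- lapply(lags, function(tau) {
    mm <- estimateReversible(countMatrix(dtrajs, tau))
    ev <- mm@eigenvalues
    idx <- seq(2, min(nTimescales + 1, length(ev)))
    ts <- rep(NA_real_, length(idx))     # non-positive eigenvalue: undefined
    pos <- ev[idx] > 0
    ts[pos] <- -tau / log(ev[idx][pos])
    data.frame(lag = tau, index = idx, eigenvalue = ev[idx], timescale = ts)
  })
  out <- do.call(rbind, rows)
  t2 <- out$timescale[out$index == 2]
  plateau <- if (length(t2) > 1) abs(diff(t2)) / head(t2, -1) else numeric(0)
  attr(out, "plateau") <- plateau
  out
}
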