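#' PCCA+ spectral memberships
#'
#' Fuzzy assignment of microstates to n metastable sets from the top n
#' eigenvectors of a reversible transition matrix (inner-simplex variant:
#' the n most linearly independent rows of the eigenvector matrix serve as
#' simplex vertices; memberships are the barycentric coordinates, clipped to
#' \[0,1\] and renormalized).
#'
#' @param model a [MarkovModel-class]
#' @param n number of macrostates
#' @return microstates x n membership matrix, rows summing to 1
#' @export
pccaPlus <- function(model, n) {
  Tm <- model@transitionMatrix
  m <- nrow(Tm)
  if (n > m) stopf("more macrostates than microstates")
  if (n == m) return(diag(m))
  pi <- model@stationary
  S <- diag(sqrt(pi)) %*% Tm %*% diag(1 / sqrt(pi))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  X <- diag(1 / sqrt(pi)) %*% e$vectors[, seq_len(n), drop = FALSE]
  X[, 1] <- 1
  # inner simplex: successively pick the row farthest from the span of the
  # vertices found so far
  vertices <- integer(n)
  W <- X
  vertices[1] <- which.max(rowSums(W^2))
  for (k in seq_len(n - 1)) {
    v <- W[vertices[k], ]
    W <- W - outer(as.vector(W %*% v), v) / sum(v^2)
    vertices[k + 1] <- which.max(rowSums(W^2))
  }
  A <- solve(X[vertices, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi / rs
}

projectCoarse <- function(Tm, pi, chi) {
  # pi-weighted coarse projection (chi' D chi)^-1 chi' D T chi
  D <- pi * chi            # column-scaled
  M <- t(chi) %*% (pi * Tm) %*% chi
  N <- t(chi) %*% D
  Tc <- solve(N, M)
  Tc[Tc < 0] <- 0
  Tc / rowSums(Tc)
}

stationaryOf <- function(Tm) {
  e <- eigen(t(Tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Coarse-grain a Markov model into metastable macrostates
#'
#' Memberships are initialized by PCCA+ spectral clustering of the
#' reversible transition matrix and then refined by Baum-Welch estimation of
#' a discrete-emission hidden Markov model at the given lag (each hidden
#' macrostate emits microstate indices with a categorical distribution).
#' Macrostate populations come from the stationary distribution of the
#' refined hidden transition matrix; lifetime_k = lag / (1 - T_kk).
#'
#' @param model a [MarkovModel-class]
#' @param dtrajs the discrete trajectories the model was estimated from
#' @param n number of macrostates (default 4)
#' @param lag ns (default: the model's lag)
#' @param maxIter,tol EM iteration cap and log-likelihood convergence
#'   tolerance
#' @return a [MacrostateModel-class]
#' @export
coarseGrain <- function(model, dtrajs, n = 4, lag = NULL, maxIter = 200L,
                        tol = 1e-8) {
  dtrajs <- asDtrajList(dtrajs)
  lag <- lag %||% model@lag
  dt <- dtrajs[[1]]@frameInterval
  lagF <- lagInFrames(lag, dt)
  ev <- model@eigenvalues
  if (length(ev) < n) stopf("model has fewer than %d eigenvalues", n)
  if (length(ev) > n && abs(ev[n] - ev[n + 1]) < 1e-10)
    warning("degenerate spectral gap between lambda_n and lambda_(n+1)")
  m <- nStates(model)
  active <- model@activeSet
  if (n == m) {
    Tm <- model@transitionMatrix
    return(new("MacrostateModel", memberships = diag(m),
               coarseT = Tm, populations = model@stationary,
               lifetimes = lag / (1 - diag(Tm)), lag = lag,
               activeSet = active))
  }
  chi <- pccaPlus(model, n)
  A0 <- projectCoarse(model@transitionMatrix, model@stationary, chi)
  piC0 <- stationaryOf(A0)
  # emission: P(microstate i | macro k) = chi_ik pi_i / pi~_k
  B0 <- t(chi * model@stationary)
  B0 <- B0 / rowSums(B0)
  B0 <- B0 + 1e-12
  B0 <- B0 / rowSums(B0)
  # strided observation sequences at the HMM lag; microstates mapped to
  # active-set positions, trajectories broken at inactive frames
  posOf <- integer(max(active))
  posOf[active] <- seq_along(active)
  obs <- list()
  for (d in dtrajs) {
    s <- d@states
    for (off in seq_len(lagF)) {
      sub <- s[seq(off, length(s), by = lagF)]
      ok <- sub %in% active
      # split at breaks
      grp <- cumsum(!ok)
      for (piece in split(sub[ok], grp[ok]))
        if (length(piece) >= 2) obs[[length(obs) + 1L]] <- posOf[piece]
    }
  }
  if (length(obs) == 0) stopf("no usable observation sequences at this lag")
  fit <- cpp_hmm_em(unlist(obs), lengths(obs), A0, B0, piC0,
                    as.integer(maxIter), tol)
  ll <- fit$loglik
  if (length(ll) > 1 && any(diff(ll) < -1e-6 * pmax(1, abs(ll[-length(ll)]))))
    stopf("EM log-likelihood decreased: implementation bug guard")
  Ahat <- fit$A
  piC <- stationaryOf(Ahat)
  Bhat <- fit$B
  chiHat <- t(Bhat * piC)           # micro x macro, unnormalized posterior
  rs <- rowSums(chiHat)
  zero <- rs == 0
  if (any(zero)) {
    chiHat[zero, ] <- 1 / n
    rs[zero] <- 1
  }
  chiHat <- chiHat / rowSums(chiHat)
  new("MacrostateModel", memberships = chiHat, coarseT = Ahat,
      populations = piC, lifetimes = lag / (1 - diag(Ahat)), lag = lag,
      activeSet = active)
}
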