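#' Forward committor of a Markov model
#'
#' Probability, per state, of reaching the target set B before the source
#' set A.  Solves the discrete Laplace system T q = q on the complement of
#' A and B with boundary values q = 0 on A and q = 1 on B.
#'
#' @param model a [MarkovModel-class] or [MacrostateModel-class]
#' @param source,target disjoint non-empty state sets (indices)
#' @return committor vector q+ (exact 0/1 on the boundary sets)
#' @export
committorForward <- function(model, source, target) {
  Tm <- transitionMatrix(model)
  n <- nrow(Tm)
  if (length(source) == 0 || length(target) == 0)
    stopf("source and target must be non-empty")
  if (length(intersect(source, target)))
    stopf("source and target must be disjoint")
  q <- numeric(n)
  q[target] <- 1
  interior <- setdiff(seq_len(n), c(source, target))
  if (length(interior)) {
    M <- diag(length(interior)) - Tm[interior, interior, drop = FALSE]
    rhs <- Tm[interior, target, drop = FALSE] %*% rep(1, length(target))
    q[interior] <- tryCatch(solve(M, rhs), error = function(e)
      stopf("singular committor system (disconnected states)"))
  }
  q
}

#' @rdname committorForward
#' @details `committorBackward` gives the probability that the chain came
#'   last from A rather than B, computed on the time-reversed chain
#'   T_rev_ij = pi_j T_ji / pi_i; for reversible models it equals 1 - q+.
#' @export
committorBackward <- function(model, source, target) {
  Tm <- transitionMatrix(model)
  pi <- stationaryDistribution(model)
  Trev <- t(Tm * pi) / pi
  n <- nrow(Tm)
  q <- numeric(n)
  q[source] <- 1
  interior <- setdiff(seq_len(n), c(source, target))
  if (length(interior)) {
    M <- diag(length(interior)) - Trev[interior, interior, drop = FALSE]
    rhs <- Trev[interior, source, drop = FALSE] %*% rep(1, length(source))
    q[interior] <- solve(M, rhs)
  }
  q
}

#' Reactive flux analysis (transition path theory)
#'
#' Gross reactive flux f_ij = pi_i q-_i T_ij q+_j (i != j, diagonal zero),
#' net flux f+_ij = max(f_ij - f_ji, 0), total A-to-B flux
#' F = sum over i in A, j not in A of f_ij, and the TPT rate
#' F / sum_i pi_i q-_i.  Flux conservation is verified at every intermediate
#' state and a residual above 1e-8 (relative) raises an error.
#'
#' @inheritParams committorForward
#' @param decompose run the pathway decomposition (default TRUE)
#' @param residualFraction stop extracting pathways once the remaining flux
#'   falls below this fraction of the total
#' @return a [TPTResult-class]
#' @export
reactiveFlux <- function(model, source, target, decompose = TRUE,
                         residualFraction = 0.01) {
  Tm <- transitionMatrix(model)
  pi <- stationaryDistribution(model)
  n <- nrow(Tm)
  qp <- committorForward(model, source, target)
  qm <- committorBackward(model, source, target)
  f <- (pi * qm) * Tm * rep(qp, each = n)
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  notA <- setdiff(seq_len(n), source)
  total <- sum(f[source, notA, drop = FALSE])
  # conservation at intermediates (net in = net out)
  interior <- setdiff(seq_len(n), c(source, target))
  if (length(interior)) {
    imbalance <- abs(colSums(fnet)[interior] - rowSums(fnet)[interior])
    if (any(imbalance > 1e-8 * max(total, 1e-300)))
      stopf("reactive flux conservation violated (residual %.3g)",
            max(imbalance))
  }
  rate <- total / (sum(pi * qm) * lagTime(model))
  paths <- if (decompose)
    decomposePathways(fnet, source, target, residualFraction, total)
  else data.frame(path = character(0), flux = numeric(0),
                  fraction = numeric(0))
  new("TPTResult", forwardCommittor = qp, backwardCommittor = qm,
      grossFlux = f, netFlux = fnet, totalFlux = total, rate = rate,
      pathways = paths)
}

widestPath <- function(W, source, target) {
  # Dijkstra-style maximum-bottleneck path over non-negative edge weights
  n <- nrow(W)
  width <- rep(-Inf, n)
  prev <- rep(NA_integer_, n)
  width[source] <- Inf
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & width > -Inf)
    if (length(cand) == 0) return(NULL)
    u <- cand[which.max(width[cand])]
    if (u %in% target) break
    visited[u] <- TRUE
    for (v in which(W[u, ] > 0)) {
      w <- min(width[u], W[u, v])
      if (w > width[v]) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
  end <- u
  path <- end
  while (!is.na(prev[end])) {
    end <- prev[end]
    path <- c(end, path)
  }
  if (!(path[1] %in% source)) return(NULL)
  list(path = path, bottleneck = width[u])
}

#' Decompose a net reactive flux into pathways
#'
#' Greedy strongest-path extraction: repeatedly find the A-to-B path whose
#' minimal edge (bottleneck) is maximal, record it with its bottleneck flux,
#' subtract that flux along the path, and stop when the remaining flux falls
#' below `residualFraction` of the total.  Fractions are path flux divided by
#' total flux.  The greedy subtraction order is the common convention; a
#' different extraction order can redistribute flux among overlapping paths.
#'
#' @param netFlux net flux matrix (non-negative, no 2-cycles)
#' @param source,target state sets
#' @param residualFraction stopping residual (default 0.01)
#' @param totalFlux total A-to-B flux (default: summed from `netFlux`)
#' @return data.frame: path (e.g. "1->2->4"), flux, fraction (ranked)
#' @export
decomposePathways <- function(netFlux, source, target,
                              residualFraction = 0.01, totalFlux = NULL) {
  W <- netFlux
  if (any(W < 0)) stopf("net flux must be non-negative")
  if (any(W * t(W) > 0)) stopf("net flux contains a 2-cycle")
  n <- nrow(W)
  if (is.null(totalFlux))
    totalFlux <- sum(W[source, setdiff(seq_len(n), source), drop = FALSE])
  paths <- character(0)
  fluxes <- numeric(0)
  remaining <- totalFlux
  guard <- 0L
  while (remaining > residualFraction * totalFlux && guard < 10000L) {
    guard <- guard + 1L
    bp <- widestPath(W, source, target)
    if (is.null(bp) || bp$bottleneck <= 0) break
    p <- bp$path
    fl <- bp$bottleneck
    for (i in seq_len(length(p) - 1)) W[p[i], p[i + 1]] <- W[p[i], p[i + 1]] - fl
    paths <- c(paths, paste(p, collapse = "->"))
    fluxes <- c(fluxes, fl)
    remaining <- remaining - fl
  }
  ord <- order(fluxes, decreasing = TRUE)
  data.frame(path = paths[ord], flux = fluxes[ord],
             fraction = fluxes[ord] / totalFlux)
}
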