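asFeatureList <- function(features) {
  if (is(features, "FeatureTrajectory")) return(list(features))
  if (is.list(features) && all(vapply(features, is, TRUE, "FeatureTrajectory")))
    return(features)
  stopf("features must be a FeatureTrajectory or a list of them")
}

#' Time-lagged independent component analysis
#'
#' Estimates, over all supplied trajectories, the mean-centred instantaneous
#' covariance C0 and the symmetrized time-lagged covariance Ctau at the given
#' correlation lag, then solves the generalized eigenproblem
#' Ctau v = lambda C0 v.  A diagonal regularization
#' eps = 1e-10 * trace(C0)/dim is added to C0 to handle rank-deficient
#' (e.g. binary contact) features.  Components are ordered by descending
#' eigenvalue; the kinetic variance fraction of component i is
#' lambda_i^2 / sum_j lambda_j^2 over the retained (positive-eigenvalue)
#' spectrum.
#'
#' @param features a [FeatureTrajectory-class] or list of them
#' @param lag correlation lag time, ns (default 20)
#' @return a [TICAModel-class]
#' @export
estimateTICA <- function(features, lag = 20) {
  trajs <- asFeatureList(features)
  if (lag <= 0) stopf("tICA lag must be positive")
  dt <- trajs[[1]]@frameInterval
  lagF <- as.integer(round(lag / dt))
  if (abs(lagF * dt - lag) > 1e-9 * lag)
    stopf("lag must be a multiple of the frame interval")
  if (lagF < 1) stopf("lag shorter than one frame")
  d <- ncol(trajs[[1]]@values)
  usable <- vapply(trajs, function(tr) nrow(tr@values) > lagF, TRUE)
  if (!all(usable))
    warning(sprintf("%d trajectory(ies) shorter than the lag were skipped",
                    sum(!usable)))
  trajs <- trajs[usable]
  if (length(trajs) == 0) stopf("all trajectories shorter than the lag")
  ntot <- 0
  mu <- numeric(d)
  for (tr in trajs) {
    mu <- mu + colSums(tr@values)
    ntot <- ntot + nrow(tr@values)
  }
  mu <- mu / ntot
  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  npair <- 0
  for (tr in trajs) {
    X <- sweep(tr@values, 2, mu)
    n <- nrow(X)
    A <- X[seq_len(n - lagF), , drop = FALSE]
    B <- X[(lagF + 1):n, , drop = FALSE]
    C0 <- C0 + (t(A) %*% A + t(B) %*% B) / 2
    Ct <- Ct + t(A) %*% B
    npair <- npair + (n - lagF)
  }
  C0 <- C0 / npair
  Ct <- (Ct + t(Ct)) / (2 * npair)
  if (!all(is.finite(C0)) || !all(is.finite(Ct)))
    stopf("non-finite covariance estimate")
  eps <- 1e-10 * sum(diag(C0)) / d
  diag(C0) <- diag(C0) + eps
  L <- chol(C0)
  Li <- backsolve(L, diag(d))
  M <- t(Li) %*% Ct %*% Li
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lambda <- pmin(e$values, 1)
  V <- Li %*% e$vectors
  keep <- lambda > 0
  kv <- numeric(length(lambda))
  if (any(keep)) kv[keep] <- lambda[keep]^2 / sum(lambda[keep]^2)
  new("TICAModel", center = mu, lag = lag, eigenvalues = lambda,
      eigenvectors = V, kineticVariance = kv)
}

#' Project features onto tICA components
#'
#' Selection rule: either a fixed number of components `n`, or the smallest
#' number whose cumulative kinetic variance reaches `kineticVarianceCutoff`.
#'
#' @param model a [TICAModel-class]
#' @param features a [FeatureTrajectory-class] or list of them
#' @param n fixed number of components (overrides the variance rule)
#' @param kineticVarianceCutoff cumulative kinetic variance threshold in
#'   (0, 1]
#' @return list of projected matrices (frames x components), with attribute
#'   `nComponents`
#' @export
projectTICA <- function(model, features, n = NULL,
                        kineticVarianceCutoff = 0.95) {
  trajs <- asFeatureList(features)
  if (is.null(n)) {
    if (kineticVarianceCutoff > 1) stopf("kinetic variance threshold > 1")
    cum <- cumsum(model@kineticVariance)
    n <- which(cum >= kineticVarianceCutoff - 1e-12)[1]
    if (is.na(n)) n <- length(model@kineticVariance)
  }
  if (n > ncol(model@eigenvectors))
    stopf("requested %d components but only %d available", n,
          ncol(model@eigenvectors))
  V <- model@eigenvectors[, seq_len(n), drop = FALSE]
  out <- lapply(trajs, function(tr)
    sweep(tr@values, 2, model@center) %*% V)
  attr(out, "nComponents") <- n
  out
}
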