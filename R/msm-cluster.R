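#' k-means discretization of reduced trajectories
#'
#' Lloyd iterations from a seeded k-means++ initialization.  Determinism
#' contract: the same seed yields identical assignments; nearest-center ties
#' break to the lowest center index; empty clusters are re-seeded from the
#' point farthest from its current center.
#'
#' @param reduced matrix or list of matrices (frames x dims), e.g. from
#'   [projectTICA()]
#' @param k number of clusters (default 100); total frames must be >= k
#' @param seed RNG seed
#' @param maxIter,tol Lloyd iteration cap and center-movement tolerance
#' @param frameInterval ns, attached to the returned discrete trajectories
#'   (taken from an attribute of `reduced` when present)
#' @param fitStride fit centers on every `fitStride`-th frame (then assign
#'   all frames); 1 fits on everything
#' @return list with `dtrajs` (list of [DiscreteTrajectory-class]) and
#'   `centers` (k x dims matrix)
#' @export
clusterKMeans <- function(reduced, k = 100, seed = 1L, maxIter = 100L,
                          tol = 1e-8, frameInterval = NULL, fitStride = 1L) {
  if (is.matrix(reduced)) reduced <- list(reduced)
  X <- do.call(rbind, reduced)
  if (nrow(X) < k) stopf("total frames (%d) fewer than clusters (%d)",
                         nrow(X), k)
  if (is.null(frameInterval))
    frameInterval <- attr(reduced, "frameInterval") %||% 1
  set.seed(as.integer(seed))
  fitX <- if (fitStride > 1L)
    X[seq(1, nrow(X), by = fitStride), , drop = FALSE] else X
  if (nrow(fitX) < k) fitX <- X
  fit <- cpp_kmeans(fitX, as.integer(k), as.integer(maxIter), tol)
  assignAll <- cpp_assign_clusters(X, fit$centers)
  lens <- vapply(reduced, nrow, 1L)
  splits <- split(assignAll, rep(seq_along(reduced), lens))
  dtrajs <- lapply(splits, function(s)
    new("DiscreteTrajectory", states = as.integer(s), nStates = as.integer(k),
        frameInterval = frameInterval))
  names(dtrajs) <- NULL
  list(dtrajs = dtrajs, centers = fit$centers)
}

#' Assign points to existing cluster centers
#'
#' @param x points matrix
#' @param centers k x dims center matrix
#' @return 1-based nearest-center indices (ties to the lowest index)
#' @export
assignClusters <- function(x, centers) {
  cpp_assign_clusters(as.matrix(x), as.matrix(centers))
}
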