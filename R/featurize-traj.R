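kabsch <- function(mobile, ref) {
  # least-squares proper rotation mapping centred mobile onto centred ref
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)     # proper rotation maximizing tr(R' H)
  list(rotation = R, mobileCenter = cm, refCenter = cr)
}

#' Superposition RMSD against a reference structure
#'
#' Each frame's selected atoms are first translationally and rotationally
#' aligned onto the corresponding reference atoms by the optimal
#' least-squares rigid-body superposition (SVD construction with the proper
#' rotation enforced), then the root-mean-square deviation over the selection
#' is computed.
#'
#' @param traj a [CoordinateTrajectory-class]
#' @param reference a [StructureModel-class]
#' @param selection atom indices into the trajectory
#' @param refSelection matching indices into the reference (defaults to
#'   `selection`); must map 1:1 with at least 3 non-collinear atoms
#' @return RMSD series in nm, one value per frame
#' @export
superposeRMSD <- function(traj, reference, selection,
                          refSelection = selection) {
  if (length(selection) != length(refSelection))
    stopf("selection must map 1:1 between trajectory and reference")
  if (length(selection) < 3) stopf("need at least 3 atoms to superpose")
  refA <- atomTable(reference)
  ref <- as.matrix(refA[refSelection, c("x", "y", "z")])
  cen <- sweep(ref, 2, colMeans(ref))
  if (qr(cen)$rank < 2) stopf("collinear reference selection")
  nf <- dim(traj@coords)[1]
  vapply(seq_len(nf), function(f) {
    xyz <- frameCoords(traj, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    mob <- xyz[selection, , drop = FALSE]
    fit <- kabsch(mob, ref)
    aligned <- sweep(mob, 2, fit$mobileCenter) %*% fit$rotation
    aligned <- sweep(aligned, 2, fit$refCenter, "+")
    sqrt(mean(rowSums((aligned - ref)^2)))
  }, numeric(1))
}

#' Bound-state labelling with a dwell criterion
#'
#' A frame is labelled bound only when it begins a window of at least
#' `dwellMin` ns during which the RMSD stays at or below `rmsdMax` and the
#' pocket-ligand distance stays at or below `distMax` continuously
#' (thresholds inclusive).  The first-binding time is the start of the first
#' such window.
#'
#' @param rmsd RMSD series, nm
#' @param dist pocket-ligand distance series, nm (same frame grid)
#' @param frameInterval ns
#' @param rmsdMax,distMax thresholds in nm (defaults 0.5 and 0.2)
#' @param dwellMin minimum continuous dwell, ns (default 100)
#' @return list with `bound` (logical per frame) and `firstBindingTime` (ns,
#'   NA when never bound)
#' @export
boundStateLabels <- function(rmsd, dist, frameInterval, rmsdMax = 0.5,
                             distMax = 0.2, dwellMin = 100) {
  if (length(rmsd) != length(dist))
    stopf("rmsd and distance series differ in length")
  ok <- rmsd <= rmsdMax & dist <= distMax
  n <- length(ok)
  needed <- as.integer(ceiling(dwellMin / frameInterval))
  # runLeft[t]: number of consecutive TRUE frames starting at t
  runLeft <- integer(n)
  acc <- 0L
  for (t in n:1) {
    acc <- if (ok[t]) acc + 1L else 0L
    runLeft[t] <- acc
  }
  bound <- runLeft >= needed
  first <- if (any(bound)) (which(bound)[1] - 1L) * frameInterval else NA_real_
  list(bound = bound, firstBindingTime = first)
}

#' Transition path segments of an order-parameter series
#'
#' Extracts transition path times: the durations of the maximal segments
#' during which the order parameter, having just left the origin region,
#' reaches the destination region without re-entering the origin region.  For
#' the binding direction the origin region is "unbound" (series at or above
#' `unboundAbove`) and the destination is "bound" (series at or below
#' `boundBelow`); `direction = "unbinding"` swaps the roles.  A segment's
#' duration runs from the first frame outside the origin region to the first
#' frame inside the destination region; excursions within the intermediate
#' region are absorbed, and re-entry into the origin region aborts the
#' segment.
#'
#' @param series order-parameter time series (e.g. ligand-cavity distance, nm)
#' @param frameInterval ns
#' @param boundBelow bound-region threshold, nm (default 0.38)
#' @param unboundAbove unbound-region threshold, nm (default 0.6)
#' @param direction `"binding"` or `"unbinding"`
#' @return numeric vector of transition path times, ns (possibly empty)
#' @export
transitionPathSegments <- function(series, frameInterval, boundBelow = 0.38,
                                   unboundAbove = 0.6,
                                   direction = c("binding", "unbinding")) {
  direction <- match.arg(direction)
  if (boundBelow >= unboundAbove)
    stopf("thresholds inverted: boundBelow must be < unboundAbove")
  inBound <- series <= boundBelow
  inUnbound <- series >= unboundAbove
  if (direction == "binding") {
    origin <- inUnbound; dest <- inBound
  } else {
    origin <- inBound; dest <- inUnbound
  }
  taus <- numeric(0)
  n <- length(series)
  t <- 1L
  # advance to the first visit of the origin region
  while (t <= n && !origin[t]) t <- t + 1L
  while (t <= n) {
    # skip through origin region
    while (t <= n && origin[t]) t <- t + 1L
    if (t > n) break
    startT <- t                          # first frame outside origin
    while (t <= n && !origin[t] && !dest[t]) t <- t + 1L
    if (t <= n && dest[t])
      taus <- c(taus, (t - startT) * frameInterval)
    # on origin re-entry the segment is dropped; loop continues from t
    if (t <= n && dest[t]) {
      # wait until the series returns to the origin region before looking
      # for the next transition
      while (t <= n && !origin[t]) t <- t + 1L
    }
  }
  taus
}
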