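#' Harvest umbrella sampling windows on an analytic potential
#'
#' Runs one restrained Langevin simulation per window center under
#' U(x) + k/2 (x - c)^2 and collects the sampled collective-variable values.
#' The default force constant is 8000 kJ/mol/nm^2 (converted to kcal/mol
#' internally); window centers are typically spaced 0.05 nm apart.  A window
#' whose sample mean drifts more than 3 standard deviations from its center
#' is reported with a warning.
#'
#' @param potential a 1D [PotentialSpec-class]
#' @param centers sorted restraint centers, nm
#' @param forceConstant kJ/mol/nm^2 (default 8000)
#' @param params a [LangevinParams-class]; the per-window seed is derived
#'   from `params@seed` and the window index
#' @param equilFraction fraction of each run discarded as equilibration
#' @return list of [UmbrellaWindow-class]
#' @export
harvestWindows <- function(potential, centers, forceConstant = 8000,
                           params = langevinParams(), equilFraction = 0.1) {
  if (is.unsorted(centers, strictly = TRUE)) stopf("centers must be sorted")
  kKcal <- kJToKcal(forceConstant)
  lapply(seq_along(centers), function(i) {
    c0 <- centers[i]
    set.seed(derivedSeed(params@seed, i))
    res <- cpp_langevin(.potentialCode[[potential@form]], potential@params,
                        c0, params@dt, params@kT, params@friction,
                        params@nSteps, params@stride,
                        kKcal, c0, 0L, numeric(potential@dim),
                        FALSE, 0L, 0, 1, 6, Inf, 0, 0L)
    cv <- res$positions[, 1]
    cv <- cv[-seq_len(max(1, floor(length(cv) * equilFraction)))]
    if (abs(mean(cv) - c0) > 3 * sd(cv))
      warning(sprintf("window %d mean drifted %.3g nm from its center", i,
                      mean(cv) - c0))
    new("UmbrellaWindow", center = c0, forceConstant = kKcal, samples = cv,
        samplingTime = params@nSteps * params@dt)
  })
}

#' WHAM reconstruction of the potential of mean force
#'
#' Standard weighted-histogram self-consistency: with histogram counts
#' h_wb over shared bins and window biases u_w(x) = k_w/2 (x - c_w)^2, the
#' unbiased probabilities and per-window free-energy shifts f_w solve
#' p_b = sum_w h_wb / sum_w N_w exp(-(u_w(b) - f_w)/kT) and
#' exp(-f_w/kT) = sum_b p_b exp(-u_w(b)/kT), iterated until the maximum
#' relative change in the shifts falls below `tol`.  The profile
#' -kT ln p is pinned so its minimum is 0 and is reported only on bins with
#' non-zero total counts.  Consecutive windows must overlap.
#'
#' @param windows list of [UmbrellaWindow-class]
#' @param nBins number of histogram bins (default: 2 per window spacing)
#' @param kT kcal/mol
#' @param tol max relative shift change at convergence (default 1e-8)
#' @param maxIter iteration cap
#' @return a [PMFProfile-class]
#' @export
whamSolve <- function(windows, nBins = NULL, kT = thermalEnergy(),
                      tol = 1e-8, maxIter = 50000L) {
  if (length(windows) < 1) stopf("need at least one window")
  centers <- vapply(windows, function(w) w@center, 1)
  allS <- unlist(lapply(windows, function(w) w@samples))
  lo <- min(allS)
  hi <- max(allS)
  if (is.null(nBins)) {
    spacing <- if (length(centers) > 1) min(diff(sort(centers))) else (hi - lo)
    nBins <- max(10L, as.integer(ceiling((hi - lo) / (spacing / 2))))
  }
  breaks <- seq(lo, hi, length.out = nBins + 1)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  H <- vapply(windows, function(w) {
    b <- findInterval(w@samples, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    tabulate(b, nbins = nBins)
  }, integer(nBins))
  # overlap check between consecutive windows (by center order)
  ord <- order(centers)
  if (length(windows) > 1) {
    for (i in seq_len(length(windows) - 1)) {
      a <- H[, ord[i]] > 0
      b <- H[, ord[i + 1]] > 0
      if (!any(a & b))
        stopf("windows %d and %d (centers %.3g, %.3g nm) do not overlap",
              ord[i], ord[i + 1], centers[ord[i]], centers[ord[i + 1]])
    }
  }
  N <- colSums(H)
  hTot <- rowSums(H)
  # bias energy of each bin under each window
  U <- vapply(windows, function(w) 0.5 * w@forceConstant * (mids - w@center)^2,
              numeric(nBins))
  expU <- exp(-U / kT)
  f <- numeric(length(windows))        # free-energy shifts, kcal/mol
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    denom <- as.vector(expU %*% (N * exp(f / kT)))
    p <- hTot / denom
    fNew <- -kT * log(colSums(p * expU))
    fNew <- fNew - fNew[1]
    delta <- max(abs(fNew - f) / pmax(abs(fNew), 1e-8))
    f <- fNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("WHAM did not converge (residual %.3g after %d iterations)",
          delta, maxIter)
  p <- as.vector(hTot / (expU %*% (N * exp(f / kT))))
  fe <- rep(NA_real_, nBins)
  okBins <- hTot > 0
  fe[okBins] <- -kT * log(p[okBins])
  fe <- fe - min(fe, na.rm = TRUE)
  new("PMFProfile", binCenters = mids, freeEnergy = fe, counts = H)
}

#' Free-energy difference between two points of a profile
#'
#' Linear interpolation between bin centers; both query points must lie
#' within the populated support of the profile.
#'
#' @param profile a [PMFProfile-class]
#' @param x1,x2 query positions, nm
#' @return G(x2) - G(x1) in kcal/mol
#' @export
dGBetween <- function(profile, x1, x2) {
  ok <- is.finite(profile@freeEnergy)
  xs <- profile@binCenters[ok]
  fs <- profile@freeEnergy[ok]
  for (x in c(x1, x2))
    if (x < min(xs) || x > max(xs))
      stopf("query %.3g nm outside profile support [%.3g, %.3g]",
            x, min(xs), max(xs))
  g <- stats::approx(xs, fs, xout = c(x1, x2))$y
  g[2] - g[1]
}

#' Boltzmann fold change of a free-energy difference
#'
#' exp(dG / RT): the factor by which a conformer population changes when its
#' free energy changes by dG.
#'
#' @param dG kcal/mol
#' @param temperature K
#' @return dimensionless fold change
#' @examples
#' foldChange(2.21, 303)   # ~39
#' @export
foldChange <- function(dG, temperature = defaultTemperature) {
  exp(dG / (kB * temperature))
}
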