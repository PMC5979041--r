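#' Infrequent well-tempered metadynamics with rate rescaling
#'
#' Runs overdamped Langevin dynamics under U + V(s, t) where V is a
#' history-dependent sum of repulsive Gaussians deposited along the
#' collective variable every `pace` ns with starting height `height0`
#' (kJ/mol) tempered by the well-tempered bias factor Gamma:
#' the k-th hill's height is height0 * exp(-V(s_k, t_k) / ((Gamma-1) kT)).
#' The run stops at the first frame where the CV exceeds
#' `escapeThreshold`.  The acceleration factor is the time average
#' alpha = <exp(V(s, t)/kT)>_t with the bias evaluated at the current
#' position before any deposition at that step (keeping transition states
#' relatively bias-free is the point of infrequent deposition), and the
#' rescaled escape time is the simulated escape time multiplied by alpha.
#'
#' @param potential a [PotentialSpec-class]
#' @param params a [LangevinParams-class] (`nSteps` acts as the cap; a run
#'   that never escapes is returned with `escaped = FALSE` and must be
#'   treated as censored)
#' @param start starting position (in the bound basin)
#' @param escapeThreshold CV value whose first crossing ends the run
#' @param cv `"x"` (first coordinate) or `"radius"` (distance from
#'   `cvCenter`)
#' @param cvCenter reference point for the radial CV
#' @param pace deposition period, ns (default 0.01, i.e. every 10 ps)
#' @param height0 starting hill height, kJ/mol (default 1.2)
#' @param width hill Gaussian width sigma, CV units (default 0.025)
#' @param biasFactor well-tempered Gamma > 1 (default 6)
#' @param staticBias constant background bias, kcal/mol (zero-gradient;
#'   enters only the acceleration factor -- mainly for validation)
#' @return list with `record` ([EscapeRecord-class]) and `hills`
#'   ([HillsLog-class])
#' @export
runInfrequentMetadyn <- function(potential, params, start, escapeThreshold,
                                 cv = c("x", "radius"),
                                 cvCenter = numeric(potential@dim),
                                 pace = 0.01, height0 = 1.2, width = 0.025,
                                 biasFactor = 6, staticBias = 0) {
  cv <- match.arg(cv)
  validObject(params)
  if (biasFactor <= 1) stopf("well-tempered bias factor must exceed 1")
  if (width <= 0) stopf("hill width must be positive")
  paceSteps <- as.integer(round(pace / params@dt))
  if (paceSteps < 1) stopf("pace must be at least one time step")
  set.seed(params@seed)
  res <- cpp_langevin(.potentialCode[[potential@form]], potential@params,
                      as.numeric(start), params@dt, params@kT,
                      params@friction, params@nSteps, params@stride,
                      0, 0, if (cv == "x") 0L else 1L, as.numeric(cvCenter),
                      TRUE, paceSteps, kJToKcal(height0), width,
                      biasFactor, escapeThreshold, staticBias, 10000000L)
  simTime <- if (res$escaped) res$escape_time else params@nSteps * params@dt
  record <- new("EscapeRecord", simulatedTime = simTime, alpha = res$alpha,
                rescaledTime = simTime * res$alpha, seed = params@seed,
                escaped = res$escaped)
  hills <- new("HillsLog", times = res$hill_times,
               centers = res$hill_centers, width = width,
               heights = res$hill_heights, biasFactor = biasFactor,
               pace = pace)
  list(record = record, hills = hills)
}

#' Evaluate the accumulated metadynamics bias
#'
#' Sum of all Gaussians deposited strictly before time `t`, evaluated at CV
#' value `s` (kcal/mol).  Superposition holds exactly: the bias of a merged
#' log equals the sum of the biases of its parts.
#'
#' @param hills a [HillsLog-class]
#' @param s CV value(s)
#' @param t time, ns (default: after the last deposition)
#' @return bias in kcal/mol (vectorized over `s`)
#' @export
biasValue <- function(hills, s, t = Inf) {
  active <- hills@times < t
  if (!any(active)) return(rep(0, length(s)))
  ctr <- hills@centers[active]
  h <- hills@heights[active]
  w <- hills@width
  vapply(s, function(si) sum(h * exp(-(si - ctr)^2 / (2 * w^2))), numeric(1))
}

#' Poisson analysis of rescaled escape times
#'
#' Maximum-likelihood exponential fit (mean = sample mean) with a
#' Kolmogorov-Smirnov test of the empirical distribution against
#' 1 - exp(-t/mean).  The p-value comes from the asymptotic Kolmogorov
#' distribution; estimating the mean from the same sample inflates it
#' somewhat, which is the common usage of this reliability check.  A high
#' p-value indicates the escape process behaved as a memoryless (Poisson)
#' barrier crossing, i.e. the biasing did not corrupt the transition state.
#'
#' @param times rescaled escape times, ns (all positive; censored runs must
#'   be excluded by the caller)
#' @param minEvents minimum number of events demanded before fitting
#'   (default 5; the statistic itself is defined for any sample size)
#' @return a [RateFit-class]
#' @export
fitPoissonKS <- function(times, minEvents = 5L) {
  if (length(times) < minEvents)
    stopf("need at least %d escape events", minEvents)
  if (any(times <= 0)) stopf("escape times must be positive")
  mu <- mean(times)
  ks <- suppressWarnings(ks.test(times, "pexp", rate = 1 / mu))
  new("RateFit", nEvents = length(times), meanTime = mu, rate = 1e9 / mu,
      ksStatistic = unname(ks$statistic), pValue = ks$p.value)
}
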