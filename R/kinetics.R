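#' Mean first passage time between state sets of a Markov model
#'
#' Solves (I - T_CC) m = tau * 1 over the complement C of the target set B,
#' then averages m over the source set A with weights proportional to the
#' stationary distribution restricted to A (or uniform weights on request).
#' Indirect routes through intermediate states are automatically included.
#'
#' @param model a [MarkovModel-class] or [MacrostateModel-class]
#' @param source,target disjoint, non-empty state-index sets (1-based within
#'   the model's states)
#' @param weighting `"stationary"` (default) or `"uniform"` source weighting
#' @return MFPT in ns
#' @export
mfpt <- function(model, source, target,
                 weighting = c("stationary", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(source) == 0 || length(target) == 0)
    stopf("source and target must be non-empty")
  if (length(intersect(source, target)))
    return(0)                       # A meets B: passage is immediate
  Tm <- transitionMatrix(model)
  tau <- lagTime(model)
  n <- nrow(Tm)
  C <- setdiff(seq_len(n), target)
  M <- diag(length(C)) - Tm[C, C, drop = FALSE]
  m <- tryCatch(solve(M, rep(tau, length(C))),
                error = function(e) stopf("target unreachable from source"))
  mAll <- numeric(n)
  mAll[C] <- m
  pi <- stationaryDistribution(model)
  w <- if (weighting == "stationary") pi[source] else rep(1, length(source))
  if (sum(w) == 0) w <- rep(1, length(source))
  sum(w * mAll[source]) / sum(w)
}

#' Binding rate constants from mean first passage times
#'
#' k_on = 1/(MFPT_on * C) and k_off = 1/MFPT_off, with MFPTs in ns converted
#' to seconds and the ligand concentration C in mol/L.
#'
#' @param mfptOn,mfptOff ns (positive)
#' @param concentration mol/L (positive)
#' @return list with `kOn` (1/(M s)) and `kOff` (1/s)
#' @examples
#' ratesFromMFPT(5163, 3.2e6, 9.55e-3)
#' @export
ratesFromMFPT <- function(mfptOn, mfptOff, concentration) {
  if (concentration <= 0) stopf("concentration must be positive")
  if (mfptOn <= 0 || mfptOff <= 0) stopf("MFPTs must be positive")
  list(kOn = 1 / (mfptOn * 1e-9 * concentration),
       kOff = 1 / (mfptOff * 1e-9))
}

#' Binding free energy from stationary populations
#'
#' dG_sim = -kB T ln(pi_bound / pi_unbound) at the simulation concentration;
#' the standard-state value is dG0 = dG_sim + R T ln(C / standardState),
#' referencing the free energy to 1 M ligand.
#'
#' @param piBound,piUnbound stationary populations (> 0; any common scale)
#' @param temperature K
#' @param concentration simulation ligand concentration, mol/L
#' @param standardState reference concentration, mol/L (default 1)
#' @return list with `dGsim` and `dG0`, kcal/mol
#' @examples
#' bindingDG(0.9983, 0.0011, 303, 9.55e-3)
#' @export
bindingDG <- function(piBound, piUnbound, temperature = defaultTemperature,
                      concentration, standardState = 1) {
  if (piBound <= 0 || piUnbound <= 0) stopf("populations must be positive")
  if (concentration <= 0) stopf("concentration must be positive")
  RT <- kB * temperature
  dGsim <- -RT * log(piBound / piUnbound)
  list(dGsim = dGsim, dG0 = dGsim + RT * log(concentration / standardState))
}

#' Assemble a kinetics summary
#'
#' @param mfptOn,mfptOff ns
#' @param piBound,piUnbound stationary populations
#' @param concentration mol/L
#' @param temperature K
#' @return a [KineticsSummary-class]
#' @export
kineticsSummary <- function(mfptOn, mfptOff, piBound, piUnbound,
                            concentration, temperature = defaultTemperature) {
  r <- ratesFromMFPT(mfptOn, mfptOff, concentration)
  g <- bindingDG(piBound, piUnbound, temperature, concentration)
  new("KineticsSummary", mfptOn = mfptOn, mfptOff = mfptOff, kOn = r$kOn,
      kOff = r$kOff, concentration = concentration,
      temperature = temperature, dGsim = g$dGsim, dG0 = g$dG0)
}

#' Unbinding activation barrier from the transition path time
#'
#' Inverts k_off = (1/tau_TPT) exp(-dG*_unbinding / RT):
#' dG*_unbinding = -RT ln(tau_TPT * k_off).  The transition path time is the
#' duration of the actual barrier-crossing segment, so tau_TPT * k_off < 1
#' for a positive barrier; a non-positive barrier triggers a warning.
#'
#' @param tauTPT ns (positive)
#' @param kOff 1/s (positive)
#' @param temperature K
#' @return a [BarrierEstimate-class] (binding barrier slots NA until
#'   [barrierBinding()] fills them)
#' @examples
#' barrierUnbinding(7, 0.95e3)   # ~11.9 RT
#' @export
barrierUnbinding <- function(tauTPT, kOff, temperature = defaultTemperature) {
  if (tauTPT <= 0 || kOff <= 0) stopf("tauTPT and kOff must be positive")
  prod <- tauTPT * 1e-9 * kOff
  if (prod >= 1)
    warning("tau_TPT * k_off >= 1: implied barrier is non-positive")
  RT <- kB * temperature
  dgRT <- -log(prod)
  new("BarrierEstimate", tauTPT = tauTPT, dGUnbindingRT = dgRT,
      dGUnbindingKcal = dgRT * RT, dGBindingRT = NA_real_,
      dGBindingKcal = NA_real_, temperature = temperature,
      inputs = list(kOffSource = kOff))
}

#' Binding activation barrier from the thermodynamic cycle
#'
#' dG*_binding = dG_binding + dG*_unbinding (consistent units; the binding
#' free energy enters in kcal/mol and is converted to RT at the stated
#' temperature).
#'
#' @param dGBinding binding free energy, kcal/mol (negative for favourable
#'   binding)
#' @param barrier a [BarrierEstimate-class] from [barrierUnbinding()], or the
#'   unbinding barrier in RT units
#' @param temperature K
#' @return a [BarrierEstimate-class] with the binding barrier filled in
#' @examples
#' barrierBinding(-4.2, barrierUnbinding(7, 0.95e3))   # ~5 RT
#' @export
barrierBinding <- function(dGBinding, barrier,
                           temperature = defaultTemperature) {
  RT <- kB * temperature
  if (is(barrier, "BarrierEstimate")) {
    if (abs(barrier@temperature - temperature) > 1e-9)
      stopf("temperature of the unbinding barrier (%g K) differs from %g K",
            barrier@temperature, temperature)
    dgUnb <- barrier@dGUnbindingRT
    out <- barrier
  } else {
    dgUnb <- barrier
    out <- new("BarrierEstimate", tauTPT = NA_real_, dGUnbindingRT = dgUnb,
               dGUnbindingKcal = dgUnb * RT, dGBindingRT = NA_real_,
               dGBindingKcal = NA_real_, temperature = temperature,
               inputs = list())
  }
  dgBindRT <- dGBinding / RT + dgUnb
  out@dGBindingRT <- dgBindRT
  out@dGBindingKcal <- dgBindRT * RT
  out@inputs$dGBindingSource <- dGBinding
  out
}

#' Trajectory-level bootstrap of an estimator
#'
#' Resamples whole trajectories with replacement and re-runs the estimator
#' on each replicate.  Replicates on which the estimator fails are dropped
#' and counted; more than 20% failures is an error.  Deterministic per seed.
#'
#' @param trajectories list of at least two trajectory objects
#' @param estimator function(list of trajectories) -> numeric (scalar or
#'   fixed-length vector)
#' @param nBoot number of replicates (default 100)
#' @param seed RNG seed
#' @param probs percentile interval probabilities
#' @return list with `mean`, `sd`, `interval` (quantiles), `replicates`
#'   (matrix), `nDropped`
#' @export
bootstrapCI <- function(trajectories, estimator, nBoot = 100L, seed = 1L,
                        probs = c(0.025, 0.975)) {
  if (length(trajectories) < 2) stopf("need at least 2 trajectories")
  set.seed(as.integer(seed))
  reps <- vector("list", nBoot)
  dropped <- 0L
  for (b in seq_len(nBoot)) {
    pick <- sample.int(length(trajectories), replace = TRUE)
    val <- tryCatch(estimator(trajectories[pick]), error = function(e) NULL)
    if (is.null(val) || any(!is.finite(val))) dropped <- dropped + 1L
    else reps[[b]] <- val
  }
  if (dropped > 0.2 * nBoot)
    stopf("estimator failed on %d of %d bootstrap replicates", dropped, nBoot)
  R <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  list(mean = colMeans(R), sd = apply(R, 2, sd),
       interval = apply(R, 2, quantile, probs = probs),
       replicates = R, nDropped = dropped)
}
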