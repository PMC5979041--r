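#' Accessors for ligandMSM model objects
#'
#' Slot access goes through these generics rather than `@`.
#'
#' @param object a ligandMSM S4 object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("stationaryDistribution", function(object) standardGeneric("stationaryDistribution"))
#' @rdname accessors
#' @export
setGeneric("lagTime", function(object) standardGeneric("lagTime"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("stateSequence", function(object) standardGeneric("stateSequence"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("lifetimes", function(object) standardGeneric("lifetimes"))
#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(object) standardGeneric("rateMatrix"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

setMethod("rateMatrix", "KineticNetwork", function(object) object@Q)
setMethod("nStates", "KineticNetwork", function(object) nrow(object@Q))
setMethod("stateSequence", "DiscreteTrajectory", function(object) object@states)
setMethod("nStates", "DiscreteTrajectory", function(object) object@nStates)
setMethod("frameInterval", "DiscreteTrajectory", function(object) object@frameInterval)
setMethod("frameInterval", "FeatureTrajectory", function(object) object@frameInterval)
setMethod("frameInterval", "CoordinateTrajectory", function(object) object@frameInterval)
setMethod("featureMatrix", "FeatureTrajectory", function(object) object@values)
setMethod("transitionMatrix", "MarkovModel", function(object) object@transitionMatrix)
setMethod("transitionMatrix", "MacrostateModel", function(object) object@coarseT)
setMethod("stationaryDistribution", "MarkovModel", function(object) object@stationary)
setMethod("stationaryDistribution", "MacrostateModel", function(object) object@populations)
setMethod("lagTime", "MarkovModel", function(object) object@lag)
setMethod("lagTime", "MacrostateModel", function(object) object@lag)
setMethod("lagTime", "TICAModel", function(object) object@lag)
setMethod("memberships", "MacrostateModel", function(object) object@memberships)
setMethod("populations", "MacrostateModel", function(object) object@populations)
setMethod("lifetimes", "MacrostateModel", function(object) object@lifetimes)
setMethod("nStates", "MarkovModel", function(object) nrow(object@transitionMatrix))
setMethod("nStates", "MacrostateModel", function(object) ncol(object@memberships))
setMethod("atomTable", "StructureModel", function(object) object@atoms)
setMethod("atomTable", "CoordinateTrajectory", function(object) object@atoms)

setMethod("show", "KineticNetwork", function(object) {
  cat(sprintf("KineticNetwork with %d states: %s\n", nStates(object),
              paste(object@stateLabels, collapse = ", ")))
  cat("exit rates (1/ns):", signif(-diag(object@Q), 4), "\n")
})

setMethod("show", "DiscreteTrajectory", function(object) {
  cat(sprintf("DiscreteTrajectory: %d frames, %d states, frame interval %g ns\n",
              length(object@states), object@nStates, object@frameInterval))
})

setMethod("show", "FeatureTrajectory", function(object) {
  cat(sprintf("FeatureTrajectory: %d frames x %d features, frame interval %g ns\n",
              nrow(object@values), ncol(object@values), object@frameInterval))
})

setMethod("show", "MarkovModel", function(object) {
  cat(sprintf("MarkovModel: %d active states, lag %g ns\n",
              nStates(object), object@lag))
  ev <- object@eigenvalues
  cat("leading eigenvalues:", signif(head(ev, 5), 5), "\n")
})

setMethod("show", "MacrostateModel", function(object) {
  cat(sprintf("MacrostateModel: %d macrostates (lag %g ns)\n",
              nStates(object), object@lag))
  cat("populations:", signif(object@populations, 4), "\n")
  cat("lifetimes (ns):", signif(object@lifetimes, 4), "\n")
})

setMethod("show", "TPTResult", function(object) {
  cat(sprintf("TPTResult: total A->B flux %.4g per lag, %d pathways\n",
              object@totalFlux, nrow(object@pathways)))
  if (nrow(object@pathways)) print(object@pathways, digits = 4)
})

setMethod("show", "KineticsSummary", function(object) {
  cat(sprintf("KineticsSummary (C = %g M, T = %g K)\n",
              object@concentration, object@temperature))
  cat(sprintf("  MFPT_on  = %.4g ns  -> k_on  = %.4g /M/s\n",
              object@mfptOn, object@kOn))
  cat(sprintf("  MFPT_off = %.4g ns  -> k_off = %.4g /s\n",
              object@mfptOff, object@kOff))
  cat(sprintf("  dG(sim) = %.3f kcal/mol, dG0(1 M) = %.3f kcal/mol\n",
              object@dGsim, object@dG0))
})

setMethod("show", "BarrierEstimate", function(object) {
  cat(sprintf("BarrierEstimate (T = %g K): tau_TPT = %.4g ns\n",
              object@temperature, object@tauTPT))
  cat(sprintf("  dG*_unbinding = %.3f RT (%.3f kcal/mol)\n",
              object@dGUnbindingRT, object@dGUnbindingKcal))
  if (is.finite(object@dGBindingRT))
    cat(sprintf("  dG*_binding   = %.3f RT (%.3f kcal/mol)\n",
                object@dGBindingRT, object@dGBindingKcal))
})

setMethod("show", "PMFProfile", function(object) {
  ok <- is.finite(object@freeEnergy)
  cat(sprintf("PMFProfile: %d bins (%d populated), range %.3g..%.3g kcal/mol\n",
              length(object@binCenters), sum(ok),
              min(object@freeEnergy[ok]), max(object@freeEnergy[ok])))
})

setMethod("show", "RateFit", function(object) {
  cat(sprintf("RateFit: n = %d, mean = %.4g ns, k = %.4g /s, KS D = %.3f, p = %.3f\n",
              object@nEvents, object@meanTime, object@rate,
              object@ksStatistic, object@pValue))
})
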