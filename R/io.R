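#' Read and write trajectories as delimited text
#'
#' Trajectories travel as CSV with a header row and the first column
#' `time_ns`; feature columns carry the feature labels, discrete
#' trajectories a single `state` column (1-based indices).  Larger runs can
#' be exchanged as RDS via the `binary` flag of the writers.
#'
#' @param x object to write
#' @param file path
#' @param binary write RDS instead of CSV
#' @name trajectory-io
NULL

#' @rdname trajectory-io
#' @export
writeFeatureTrajectory <- function(x, file, binary = FALSE) {
  if (binary) { saveRDS(x, file); return(invisible(file)) }
  df <- data.frame(time_ns = (seq_len(nrow(x@values)) - 1) * x@frameInterval,
                   x@values)
  names(df) <- c("time_ns", x@labels)
  data.table::fwrite(df, file)
  invisible(file)
}

#' @rdname trajectory-io
#' @export
readFeatureTrajectory <- function(file) {
  df <- as.data.frame(data.table::fread(file))
  if (names(df)[1] != "time_ns") stopf("first column must be time_ns")
  dt <- if (nrow(df) > 1) df$time_ns[2] - df$time_ns[1] else 1
  new("FeatureTrajectory", values = as.matrix(df[, -1, drop = FALSE]),
      labels = names(df)[-1], frameInterval = dt)
}

#' @rdname trajectory-io
#' @export
writeDiscreteTrajectory <- function(x, file, binary = FALSE) {
  if (binary) { saveRDS(x, file); return(invisible(file)) }
  df <- data.frame(time_ns = (seq_along(x@states) - 1) * x@frameInterval,
                   state = x@states)
  data.table::fwrite(df, file)
  invisible(file)
}

#' @rdname trajectory-io
#' @param nStates number of states (default: max observed)
#' @export
readDiscreteTrajectory <- function(file, nStates = NULL) {
  df <- as.data.frame(data.table::fread(file))
  dt <- if (nrow(df) > 1) df$time_ns[2] - df$time_ns[1] else 1
  new("DiscreteTrajectory", states = as.integer(df$state),
      nStates = as.integer(nStates %||% max(df$state)), frameInterval = dt)
}

#' Serialize model objects to JSON bundles
#'
#' Markov and macrostate models, TPT results, kinetics summaries and rate
#' fits are written as a single JSON object with matrices in row-major
#' nested-array form.
#'
#' @param object the model object
#' @param file path (`.json`)
#' @export
writeModelJSON <- function(object, file) {
  payload <- if (is(object, "MarkovModel")) {
    list(class = "MarkovModel", transitionMatrix = object@transitionMatrix,
         lag_ns = object@lag, stationary = object@stationary,
         eigenvalues = object@eigenvalues, activeSet = object@activeSet)
  } else if (is(object, "MacrostateModel")) {
    list(class = "MacrostateModel", memberships = object@memberships,
         coarseT = object@coarseT, populations = object@populations,
         lifetimes_ns = object@lifetimes, lag_ns = object@lag,
         activeSet = object@activeSet)
  } else if (is(object, "TPTResult")) {
    list(class = "TPTResult", forwardCommittor = object@forwardCommittor,
         backwardCommittor = object@backwardCommittor,
         totalFlux = object@totalFlux, rate_per_ns = object@rate,
         pathways = object@pathways)
  } else if (is(object, "KineticsSummary")) {
    list(class = "KineticsSummary", mfpt_on_ns = object@mfptOn,
         mfpt_off_ns = object@mfptOff, k_on_per_M_s = object@kOn,
         k_off_per_s = object@kOff, concentration_M = object@concentration,
         temperature_K = object@temperature, dG_sim_kcal_mol = object@dGsim,
         dG0_kcal_mol = object@dG0)
  } else if (is(object, "RateFit")) {
    list(class = "RateFit", n_events = object@nEvents,
         mean_time_ns = object@meanTime, rate_per_s = object@rate,
         ks_statistic = object@ksStatistic, p_value = object@pValue)
  } else if (is(object, "KineticNetwork")) {
    list(class = "KineticNetwork", stateLabels = object@stateLabels,
         Q_per_ns = object@Q)
  } else stopf("no JSON serialization for class %s", class(object))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write a hills log as CSV
#'
#' Columns time_ns, center, sigma, height_kcal_mol, bias_factor -- the same
#' fields common metadynamics HILLS files carry.
#'
#' @param hills a [HillsLog-class]
#' @param file path
#' @export
writeHillsCSV <- function(hills, file) {
  data.table::fwrite(data.frame(
    time_ns = hills@times, center = hills@centers, sigma = hills@width,
    height_kcal_mol = hills@heights, bias_factor = hills@biasFactor), file)
  invisible(file)
}

#' Write a PMF profile as CSV
#'
#' @param profile a [PMFProfile-class]
#' @param file path
#' @export
writePMFCSV <- function(profile, file) {
  data.table::fwrite(data.frame(cv_nm = profile@binCenters,
                                free_energy_kcal_mol = profile@freeEnergy),
                     file)
  invisible(file)
}

#' Write bound/unbound labels as CSV
#'
#' Columns time_ns and bound (0/1).
#'
#' @param labels output of [boundStateLabels()]
#' @param frameInterval ns
#' @param file path
#' @export
writeLabelsCSV <- function(labels, frameInterval, file) {
  data.table::fwrite(data.frame(
    time_ns = (seq_along(labels$bound) - 1) * frameInterval,
    bound = as.integer(labels$bound)), file)
  invisible(file)
}
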