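#' @importFrom methods new validObject is slot setClass setGeneric setMethod setValidity show
#' @importFrom stats ks.test optim pexp quantile rnorm runif sd var integrate
#' @importFrom utils head tail
#' @useDynLib ligandMSM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- synthetic-data containers -------------------------------------------

#' Continuous-time kinetic network with known ground truth
#'
#' A labelled continuous-time Markov chain given by its rate (generator)
#' matrix `Q` in 1/ns.  Off-diagonal entries are transition rates and must be
#' non-negative; each diagonal equals minus the row's off-diagonal sum; the
#' chain must be irreducible (a single communicating class), otherwise
#' construction fails.  Serves as the exactly solvable surrogate for a
#' macrostate kinetic scheme (e.g. a bound state, a bulk unbound state and
#' short-lived gateway intermediates).
#'
#' @slot stateLabels character names of the states
#' @slot Q square rate matrix, units 1/ns
#' @seealso [kineticNetwork()], [ctmcOracle()], [simulateCTMC()]
#' @export
setClass("KineticNetwork",
  representation(stateLabels = "character", Q = "matrix"))

setValidity("KineticNetwork", function(object) {
  Q <- object@Q
  n <- nrow(Q)
  if (n != ncol(Q)) return("Q must be square")
  if (length(object@stateLabels) != n) return("one label per state required")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) return("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-10 * max(1, max(abs(Q)))))
    return("rows of a rate matrix must sum to zero")
  if (n > 1) {
    g <- igraph::graph_from_adjacency_matrix(off > 0, mode = "directed")
    if (igraph::components(g, mode = "strong")$no != 1L)
      return("kinetic network is not irreducible")
  }
  TRUE
})

#' Analytic potential specification
#'
#' Identifies one of the built-in analytic potentials together with its
#' parameters (energies in kcal/mol, lengths in nm).  Supported forms:
#' `"harmonic"` (params `k`, `center`), `"double_well"` (params `height` =
#' barrier height, `a` = minimum position, optional `tilt` for an asymmetric
#' landscape) and `"binding_landscape_2d"` (a confining wall plus Gaussian
#' wells emulating a bulk basin, gateway intermediates and a deep cavity).
#'
#' @slot form identifier of the analytic form
#' @slot params named numeric parameter vector
#' @slot dim dimensionality of the configuration space
#' @seealso [potentialSpec()], [potentialEnergy()], [simulateLangevin()]
#' @export
setClass("PotentialSpec",
  representation(form = "character", params = "numeric", dim = "integer"))

#' Overdamped Langevin integrator parameters
#'
#' @slot dt integration time step, ns
#' @slot kT thermal energy, kcal/mol
#' @slot friction friction coefficient (kcal/mol ns / nm^2)
#' @slot nSteps number of integration steps
#' @slot seed RNG seed
#' @slot stride save a frame every `stride` steps (frame interval = dt * stride)
#' @export
setClass("LangevinParams",
  representation(dt = "numeric", kT = "numeric", friction = "numeric",
                 nSteps = "numeric", seed = "integer", stride = "integer"))

setValidity("LangevinParams", function(object) {
  if (object@dt <= 0) return("dt must be > 0")
  if (object@kT <= 0) return("kT must be > 0")
  if (object@friction <= 0) return("friction must be > 0")
  if (object@nSteps < 1) return("nSteps must be >= 1")
  if (object@stride < 1) return("stride must be >= 1")
  TRUE
})

#' Discrete (state-indexed) trajectory
#'
#' A time-ordered sequence of 1-based state indices on a regular frame grid.
#' These hold both ground-truth state sequences produced by the synthetic
#' module and microstate assignments produced by clustering.
#'
#' @slot states integer state sequence (1-based, in 1..nStates)
#' @slot nStates number of states the indices refer to
#' @slot frameInterval time between frames, ns
#' @export
setClass("DiscreteTrajectory",
  representation(states = "integer", nStates = "integer",
                 frameInterval = "numeric"))

setValidity("DiscreteTrajectory", function(object) {
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (length(object@states) &&
      (min(object@states) < 1L || max(object@states) > object@nStates))
    return("state indices out of range")
  TRUE
})

## ---- featurization containers --------------------------------------------

#' Molecular structure model
#'
#' Minimal atom table parsed from a PDB file: serial, atom name, element,
#' residue name/number, chain, coordinates in nm, plus a flag marking ligand
#' (HETATM) records.
#'
#' @slot atoms data.frame with columns serial, name, element, resname, resno,
#'   chain, x, y, z (nm), ligand (logical)
#' @slot provenance source filename
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", provenance = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z", "ligand")
  if (!all(need %in% names(a))) return("atom table misses required columns")
  if (nrow(a) == 0) return("structure contains zero atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  TRUE
})

#' Coordinate trajectory
#'
#' Atom positions per frame in nm, on a regular time grid, with the same atom
#' metadata layout as [StructureModel-class].
#'
#' @slot coords numeric array (frames x atoms x 3), nm
#' @slot frameInterval ns
#' @slot atoms atom metadata data.frame
#' @export
setClass("CoordinateTrajectory",
  representation(coords = "array", frameInterval = "numeric",
                 atoms = "data.frame"))

setValidity("CoordinateTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3) return("coords must be frames x atoms x 3")
  if (nrow(object@atoms) != d[2]) return("atom metadata does not match coords")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

#' Feature trajectory
#'
#' A frames x features real matrix with named columns on a regular time grid
#' (e.g. ligand-residue contact indicators used as Markov-model input
#' coordinates).
#'
#' @slot values frames x features matrix (finite)
#' @slot labels feature names (length = ncol)
#' @slot frameInterval ns
#' @export
setClass("FeatureTrajectory",
  representation(values = "matrix", labels = "character",
                 frameInterval = "numeric"))

setValidity("FeatureTrajectory", function(object) {
  if (!all(is.finite(object@values))) return("non-finite feature values")
  if (length(object@labels) != ncol(object@values))
    return("label count must equal feature column count")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

## ---- model containers ----------------------------------------------------

#' Time-lagged independent component analysis model
#'
#' Generalized eigendecomposition of the symmetrized time-lagged covariance
#' against the instantaneous covariance at a correlation lag time.  The
#' kinetic variance fraction of component i is lambda_i^2 / sum_j lambda_j^2
#' over the retained (positive) spectrum.
#'
#' @slot center data mean removed before estimation
#' @slot lag correlation lag time, ns
#' @slot eigenvalues autocorrelation eigenvalues, descending
#' @slot eigenvectors projection vectors (columns)
#' @slot kineticVariance per-component kinetic variance fraction
#' @export
setClass("TICAModel",
  representation(center = "numeric", lag = "numeric",
                 eigenvalues = "numeric", eigenvectors = "matrix",
                 kineticVariance = "numeric"))

setValidity("TICAModel", function(object) {
  if (any(object@eigenvalues > 1 + 1e-6))
    return("symmetrized tICA eigenvalues must be <= 1")
  kv <- object@kineticVariance
  if (length(kv) && abs(sum(kv) - 1) > 1e-8)
    return("kinetic variance fractions must sum to 1")
  TRUE
})

#' Markov state model
#'
#' Row-stochastic transition matrix at lag tau with stationary distribution
#' and eigenvalues.  Reversible estimates satisfy detailed balance
#' pi_i T_ij = pi_j T_ji.
#'
#' @slot transitionMatrix row-stochastic matrix over the active states
#' @slot lag lag time tau, ns
#' @slot stationary stationary distribution pi
#' @slot eigenvalues real eigenvalues, lambda_1 = 1 first
#' @slot activeSet original (1-based) microstate indices of the active set
#' @export
setClass("MarkovModel",
  representation(transitionMatrix = "matrix", lag = "numeric",
                 stationary = "numeric", eigenvalues = "numeric",
                 activeSet = "integer"))

setValidity("MarkovModel", function(object) {
  Tm <- object@transitionMatrix
  if (any(abs(rowSums(Tm) - 1) > 1e-12)) return("rows of T must sum to 1")
  p <- object@stationary
  if (max(abs(p %*% Tm - p)) > 1e-10) return("pi is not stationary under T")
  db <- p * Tm - t(p * Tm)
  if (max(abs(db)) > 1e-10) return("detailed balance violated")
  if (abs(object@eigenvalues[1] - 1) > 1e-10) return("lambda_1 must equal 1")
  TRUE
})

#' Macrostate (coarse-grained) kinetic model
#'
#' Fuzzy memberships of microstates into N metastable macrostates with the
#' coarse transition matrix at the model lag, macrostate populations and
#' lifetimes (lifetime_k = lag / (1 - T_kk)).
#'
#' @slot memberships microstates x N matrix, rows sum to 1
#' @slot coarseT N x N coarse transition matrix at lag
#' @slot populations macrostate stationary populations
#' @slot lifetimes macrostate lifetimes, ns
#' @slot lag ns
#' @slot activeSet microstate indices the membership rows refer to
#' @export
setClass("MacrostateModel",
  representation(memberships = "matrix", coarseT = "matrix",
                 populations = "numeric", lifetimes = "numeric",
                 lag = "numeric", activeSet = "integer"))

setValidity("MacrostateModel", function(object) {
  chi <- object@memberships
  if (any(chi < -1e-10 | chi > 1 + 1e-10)) return("memberships must lie in [0,1]")
  if (any(abs(rowSums(chi) - 1) > 1e-8)) return("membership rows must sum to 1")
  if (abs(sum(object@populations) - 1) > 1e-8)
    return("macro populations must sum to 1")
  if (any(object@lifetimes <= 0)) return("lifetimes must be positive")
  TRUE
})

## ---- result containers ---------------------------------------------------

#' Transition path theory result
#'
#' Forward/backward committors, gross and net reactive fluxes (per lag time),
#' the total A-to-B flux and the ranked pathway decomposition.
#'
#' @slot forwardCommittor q+ per state (0 on A, 1 on B)
#' @slot backwardCommittor q- per state
#' @slot grossFlux f_ij = pi_i q-_i T_ij q+_j (diagonal 0)
#' @slot netFlux f+_ij = max(f_ij - f_ji, 0)
#' @slot totalFlux total reactive A-to-B flux per lag
#' @slot rate TPT rate: totalFlux / sum(pi_i q-_i), per ns
#' @slot pathways data.frame: path (string), flux, fraction
#' @export
setClass("TPTResult",
  representation(forwardCommittor = "numeric", backwardCommittor = "numeric",
                 grossFlux = "matrix", netFlux = "matrix",
                 totalFlux = "numeric", rate = "numeric",
                 pathways = "data.frame"))

#' Kinetics summary (rates, free energies)
#'
#' Binding kinetics derived from mean first passage times at a stated ligand
#' concentration and temperature: k_on = 1/(MFPT_on * C), k_off = 1/MFPT_off,
#' simulation-concentration binding free energy and its 1 M standard-state
#' counterpart.
#'
#' @slot mfptOn ns
#' @slot mfptOff ns
#' @slot kOn 1/(M s)
#' @slot kOff 1/s
#' @slot concentration mol/L
#' @slot temperature K
#' @slot dGsim kcal/mol at the simulation concentration
#' @slot dG0 kcal/mol at 1 M standard state
#' @export
setClass("KineticsSummary",
  representation(mfptOn = "numeric", mfptOff = "numeric", kOn = "numeric",
                 kOff = "numeric", concentration = "numeric",
                 temperature = "numeric", dGsim = "numeric", dG0 = "numeric"))

setValidity("KineticsSummary", function(object) {
  if (object@mfptOn <= 0 || object@mfptOff <= 0) return("MFPTs must be positive")
  kon <- 1e9 / (object@mfptOn * object@concentration)
  koff <- 1e9 / object@mfptOff
  if (abs(kon - object@kOn) > 1e-6 * kon) return("k_on inconsistent with MFPT_on")
  if (abs(koff - object@kOff) > 1e-6 * koff) return("k_off inconsistent with MFPT_off")
  TRUE
})

#' Activation barrier estimate from transition path times
#'
#' Barrier heights obtained from the transition-path-time relation
#' k_off = (1/tau_TPT) exp(-dG*_unbinding / RT) and the thermodynamic cycle
#' dG*_binding = dG_binding + dG*_unbinding.
#'
#' @slot tauTPT mean transition path time, ns
#' @slot dGUnbindingRT unbinding barrier, RT units
#' @slot dGUnbindingKcal unbinding barrier, kcal/mol
#' @slot dGBindingRT binding barrier, RT units (NA if not derived)
#' @slot dGBindingKcal binding barrier, kcal/mol
#' @slot temperature K
#' @slot inputs list recording the k_off and dG_binding sources used
#' @export
setClass("BarrierEstimate",
  representation(tauTPT = "numeric", dGUnbindingRT = "numeric",
                 dGUnbindingKcal = "numeric", dGBindingRT = "numeric",
                 dGBindingKcal = "numeric", temperature = "numeric",
                 inputs = "list"))

## ---- biased-sampling containers ------------------------------------------

#' Umbrella sampling window
#'
#' @slot center restraint center, nm
#' @slot forceConstant harmonic force constant, kcal/mol/nm^2
#' @slot samples sampled collective-variable values, nm
#' @slot samplingTime ns
#' @export
setClass("UmbrellaWindow",
  representation(center = "numeric", forceConstant = "numeric",
                 samples = "numeric", samplingTime = "numeric"))

setValidity("UmbrellaWindow", function(object) {
  if (object@forceConstant <= 0) return("force constant must be positive")
  if (!all(is.finite(object@samples))) return("non-finite samples")
  TRUE
})

#' Potential of mean force profile
#'
#' Free energy as a function of the collective variable, minimum pinned to 0,
#' defined only on bins with non-zero total counts.
#'
#' @slot binCenters nm
#' @slot freeEnergy kcal/mol (min 0)
#' @slot counts bins x windows count matrix (diagnostics)
#' @export
setClass("PMFProfile",
  representation(binCenters = "numeric", freeEnergy = "numeric",
                 counts = "matrix"))

setValidity("PMFProfile", function(object) {
  fe <- object@freeEnergy[is.finite(object@freeEnergy)]
  if (length(fe) && abs(min(fe)) > 1e-9) return("profile minimum must be pinned to 0")
  TRUE
})

#' Well-tempered metadynamics hills log
#'
#' @slot times deposition times, ns (strictly increasing)
#' @slot centers hill centers, CV units
#' @slot width Gaussian width sigma, CV units
#' @slot heights deposited (post-tempering) heights, kcal/mol
#' @slot biasFactor well-tempered bias factor Gamma
#' @slot pace deposition period, ns
#' @export
setClass("HillsLog",
  representation(times = "numeric", centers = "numeric", width = "numeric",
                 heights = "numeric", biasFactor = "numeric", pace = "numeric"))

setValidity("HillsLog", function(object) {
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("deposition times must be strictly increasing")
  if (any(object@heights <= 0)) return("hill heights must be positive")
  TRUE
})

#' Escape record from an infrequent metadynamics run
#'
#' @slot simulatedTime biased time to escape, ns
#' @slot alpha acceleration factor (>= 1 for repulsive bias)
#' @slot rescaledTime simulatedTime * alpha, ns
#' @slot seed RNG seed of the run
#' @slot escaped logical; FALSE marks a censored run
#' @export
setClass("EscapeRecord",
  representation(simulatedTime = "numeric", alpha = "numeric",
                 rescaledTime = "numeric", seed = "integer",
                 escaped = "logical"))

#' Poisson rate fit with Kolmogorov-Smirnov reliability
#'
#' @slot nEvents number of escape times fitted
#' @slot meanTime MLE mean escape time, ns
#' @slot rate 1/s (1/meanTime, converted)
#' @slot ksStatistic KS statistic against the fitted exponential
#' @slot pValue asymptotic KS p-value
#' @export
setClass("RateFit",
  representation(nEvents = "integer", meanTime = "numeric", rate = "numeric",
                 ksStatistic = "numeric", pValue = "numeric"))

setValidity("RateFit", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p-value out of [0,1]")
  if (abs(object@rate - 1e9 / object@meanTime) > 1e-6 * object@rate)
    return("rate must equal 1/mean (unit-converted)")
  TRUE
})
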