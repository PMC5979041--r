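.potentialCode <- c(harmonic = 1L, double_well = 2L, binding_landscape_2d = 3L)

#' Analytic potential constructors
#'
#' `potentialSpec` builds a [PotentialSpec-class] for one of the built-in
#' analytic forms.  Energies in kcal/mol, lengths in nm.
#'
#' * `harmonic`: U = k/2 * |x - center|^2; params `k`, `center` (recycled to
#'   the dimension).
#' * `double_well` (1D): U = height * ((x/a)^2 - 1)^2 + tilt * x, minima near
#'   -a and +a separated by a barrier of `height` at x = 0; a non-zero `tilt`
#'   makes the landscape asymmetric.
#' * `binding_landscape_2d`: a harmonic confining wall of stiffness `wallK`
#'   beyond radius `wallRadius` plus Gaussian wells (depth, cx, cy, sigma per
#'   well).  The default well layout has four basins emulating a
#'   ligand-binding landscape: a shallow bulk basin far from the origin, two
#'   gateway intermediates and a deep cavity basin at the origin.
#'
#' @param form one of `"harmonic"`, `"double_well"`, `"binding_landscape_2d"`
#' @param ... named parameters for the chosen form (see Details)
#' @return a [PotentialSpec-class]
#' @examples
#' potentialSpec("double_well", height = 3.6, a = 1)
#' @export
potentialSpec <- function(form = c("harmonic", "double_well",
                                   "binding_landscape_2d"), ...) {
  form <- match.arg(form)
  p <- list(...)
  if (form == "harmonic") {
    k <- p$k %||% 1
    center <- p$center %||% 0
    dim <- length(center)
    params <- c(k = k, center)
  } else if (form == "double_well") {
    params <- c(height = p$height %||% 3.6, a = p$a %||% 1,
                tilt = p$tilt %||% 0)
    dim <- 1L
  } else {
    wells <- p$wells %||% defaultBindingWells()
    params <- c(wallRadius = p$wallRadius %||% 3, wallK = p$wallK %||% 20,
                as.vector(t(as.matrix(wells))))
    dim <- 2L
  }
  new("PotentialSpec", form = form, params = as.numeric(params),
      dim = as.integer(dim))
}

#' @rdname potentialSpec
#' @details `defaultBindingWells()` returns the default four-basin well table
#'   of the 2D binding landscape: a deep cavity well at the origin, two
#'   gateway wells at intermediate radius and a broad shallow bulk well.
#' @export
defaultBindingWells <- function() {
  data.frame(
    depth = c(4.8, 1.2, 1.0, 0.6),
    cx    = c(0.0, 0.9, 0.6, 2.2),
    cy    = c(0.0, 0.5, -0.9, 0.0),
    sigma = c(0.25, 0.2, 0.2, 0.6))
}

#' Evaluate an analytic potential
#'
#' @param spec a [PotentialSpec-class]
#' @param x positions: numeric vector (one point) or matrix (points x dim)
#' @return `potentialEnergy`: energies in kcal/mol; `potentialGradient`:
#'   gradient matrix in kcal/mol/nm
#' @export
potentialEnergy <- function(spec, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = spec@dim)
  cpp_potential_eval(.potentialCode[[spec@form]], spec@params, x)$energy
}

#' @rdname potentialEnergy
#' @export
potentialGradient <- function(spec, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = spec@dim)
  cpp_potential_eval(.potentialCode[[spec@form]], spec@params, x)$gradient
}

#' Langevin integrator parameters
#'
#' @param dt time step, ns
#' @param kT thermal energy, kcal/mol (default kT at 303 K)
#' @param friction friction coefficient, kcal/mol ns/nm^2
#' @param nSteps number of steps
#' @param seed RNG seed
#' @param stride save every `stride`-th step
#' @return a [LangevinParams-class]
#' @export
langevinParams <- function(dt = 1e-3, kT = thermalEnergy(), friction = 1,
                           nSteps = 1e5, seed = 1L, stride = 1L) {
  new("LangevinParams", dt = dt, kT = kT, friction = friction,
      nSteps = as.numeric(nSteps), seed = as.integer(seed),
      stride = as.integer(stride))
}

#' Overdamped Langevin dynamics on an analytic potential
#'
#' Integrates x <- x - (dt/friction) grad U(x) + sqrt(2 kT dt/friction) xi
#' with standard normal xi; reproducible for a fixed seed.  A heuristic
#' stability check rejects steps so large that the drift per step at the
#' start point exceeds the domain scale.
#'
#' @param potential a [PotentialSpec-class]
#' @param params a [LangevinParams-class]
#' @param start starting position (finite, length = potential dimension)
#' @return matrix of saved positions (frames x dim); attribute
#'   `frameInterval` gives dt * stride in ns
#' @export
simulateLangevin <- function(potential, params, start) {
  validObject(params)
  if (!all(is.finite(start))) stopf("non-finite start position")
  if (length(start) != potential@dim)
    stopf("start has length %d but potential is %d-dimensional",
          length(start), potential@dim)
  g0 <- max(abs(potentialGradient(potential, start)))
  scale <- max(1, max(abs(start)))
  if (params@dt * g0 / params@friction > scale)
    stopf("dt too large for this potential (drift per step exceeds domain scale)")
  set.seed(params@seed)
  res <- cpp_langevin(.potentialCode[[potential@form]], potential@params,
                      as.numeric(start), params@dt, params@kT,
                      params@friction, params@nSteps, params@stride,
                      0, 0, 0L, numeric(potential@dim),
                      FALSE, 0L, 0, 1, 6, Inf, 0, 0L)
  pos <- res$positions
  attr(pos, "frameInterval") <- params@dt * params@stride
  pos
}

#' State-conditioned Gaussian feature emission
#'
#' Converts a discrete trajectory into a continuous multivariate feature
#' trajectory by drawing each frame's feature vector from a spherical
#' Gaussian centred on its state's emission center, producing observables
#' with metastable structure for dimensionality-reduction and clustering
#' tests.
#'
#' @param dtraj a [DiscreteTrajectory-class]
#' @param centers matrix (states x features) of emission centers
#' @param spread per-state Gaussian standard deviations (recycled; > 0, or 0
#'   for the degenerate noiseless case)
#' @param seed RNG seed
#' @return a [FeatureTrajectory-class] with the same frame count
#' @export
emitFeatures <- function(dtraj, centers, spread, seed) {
  centers <- as.matrix(centers)
  if (nrow(centers) != dtraj@nStates)
    stopf("need one emission center per state (%d centers for %d states)",
          nrow(centers), dtraj@nStates)
  spread <- rep_len(spread, dtraj@nStates)
  if (any(spread < 0)) stopf("emission spreads must be non-negative")
  set.seed(as.integer(seed))
  s <- dtraj@states
  nf <- length(s)
  d <- ncol(centers)
  X <- centers[s, , drop = FALSE] +
    matrix(rnorm(nf * d), nf, d) * spread[s]
  labels <- colnames(centers) %||% paste0("f", seq_len(d))
  new("FeatureTrajectory", values = X, labels = labels,
      frameInterval = dtraj@frameInterval)
}
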