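# shared fixtures and cached heavy computations

toyHoloPath <- function() {
  system.file("extdata", "toy_holo.pdb", package = "ligandMSM")
}

# a small reversible MarkovModel built from explicit detailed-balance pairs
makeReversibleModel <- function(Tm, lag = 1) {
  pi <- stationaryOfT(Tm)
  ev <- sort(Re(eigen(Tm, only.values = TRUE)$values), decreasing = TRUE)
  ev[1] <- 1
  new("MarkovModel", transitionMatrix = Tm, lag = lag, stationary = pi,
      eigenvalues = ev, activeSet = seq_len(nrow(Tm)))
}

stationaryOfT <- function(Tm) {
  e <- eigen(t(Tm))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}

# random reversible transition matrix via symmetric counts
randomReversibleT <- function(n, seed) {
  set.seed(seed)
  X <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  X <- X + t(X)
  X / rowSums(X)
}

# birth-death (tridiagonal) reversible chain
birthDeathT <- function(p) {
  n <- length(p) + 1
  Tm <- diag(n) * 0
  for (i in seq_len(n - 1)) {
    Tm[i, i + 1] <- p[i]
    Tm[i + 1, i] <- p[i] / 2
  }
  diag(Tm) <- 1 - rowSums(Tm)
  Tm
}

# cache for the expensive end-to-end benchmark runs shared across test files
.benchCache <- new.env(parent = emptyenv())

benchmarkRun <- function(seed, nBoot = 0L) {
  key <- sprintf("s%d_b%d", seed, nBoot)
  if (!is.null(.benchCache[[key]])) return(.benchCache[[key]])
  rep <- runPipeline(list(seed = seed, n_clusters = 100L,
                          n_bootstrap = as.integer(nBoot)))
  .benchCache[[key]] <- rep
  rep
}

# label-permutation-invariant macrostate comparison: sorted populations
sortedPopulations <- function(macro) sort(populations(macro))

# cached WHAM study on the asymmetric 8 kT double well
cachedWhamDoubleWell <- function() {
  if (!is.null(.benchCache$wham)) return(.benchCache$wham)
  kT <- thermalEnergy()
  pot <- potentialSpec("double_well", height = 8 * kT, a = 0.5, tilt = 0.6)
  # dt resolves the stiff restraint (dt * k / friction << 1); 20 ns/window
  lp <- langevinParams(dt = 2e-6, kT = kT, friction = 0.1, nSteps = 1e7,
                       seed = 5, stride = 100L)
  ws <- harvestWindows(pot, seq(-0.8, 0.8, by = 0.05), 8000, lp)
  prof <- whamSolve(ws)
  .benchCache$wham <- list(profile = prof, potential = pot, kT = kT,
                           windows = ws)
  .benchCache$wham
}

whamRMSDkT <- function(study, minCount = 50) {
  prof <- study$profile
  ok <- is.finite(prof@freeEnergy) & rowSums(prof@counts) > minCount
  xs <- prof@binCenters[ok]
  ref <- potentialEnergy(study$potential, matrix(xs, ncol = 1))
  fe <- prof@freeEnergy[ok]
  sqrt(mean((fe + mean(ref - fe) - ref)^2)) / study$kT
}

# cached infrequent-metadynamics study on the ~8 kT double well
metadynStudyRun <- function(seed, kT = 0.6, height0 = 1.2, ...) {
  runInfrequentMetadyn(
    potentialSpec("double_well", height = 8 * kT, a = 1),
    langevinParams(dt = 1e-3, kT = kT, friction = 0.1, nSteps = 5e6,
                   seed = seed),
    start = -1, escapeThreshold = 0.9, width = 0.1, height0 = height0, ...)
}

cachedMetadynStudy <- function() {
  if (!is.null(.benchCache$metadyn)) return(.benchCache$metadyn)
  unbiased <- vapply(1:25, function(i)
    metadynStudyRun(seed = derivedSeed(900, i),
                    height0 = 0)$record@simulatedTime, numeric(1))
  runs <- lapply(1:15, function(i) metadynStudyRun(seed = derivedSeed(42, i)))
  .benchCache$metadyn <- list(unbiased = unbiased, runs = runs)
  .benchCache$metadyn
}

# estimator used in bootstrap coverage checks: sorted populations + MFPTs
benchmarkEstimator <- function(msmLag = 10, n = 4) {
  function(dtr) {
    mm <- estimateReversible(countMatrix(dtr, msmLag))
    mac <- coarseGrain(mm, dtr, n = n, lag = msmLag)
    ids <- identifyBoundUnbound(mac)
    c(sort(populations(mac)),
      mfptOn = mfpt(mac, ids$unbound, ids$bound),
      mfptOff = mfpt(mac, ids$bound, ids$unbound))
  }
}
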