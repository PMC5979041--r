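flatWindows <- function(centers, forceConstant = 8000, seed = 1,
                        nSteps = 2e6) {
  pot <- potentialSpec("harmonic", k = 1e-12, center = 0)  # essentially flat
  harvestWindows(pot, centers, forceConstant,
                 langevinParams(dt = 2e-6, kT = thermalEnergy(),
                                friction = 0.1, nSteps = nSteps, seed = seed,
                                stride = 10L))
}

test_that("umbrella windows sample the restraint's harmonic distribution", {
  kT <- thermalEnergy()
  w <- flatWindows(c(0, 0.05), seed = 3)[[1]]
  kk <- kJToKcal(8000)
  v <- var(w@samples)
  nEff <- 2e6 * 2e-6 / (0.1 / kk)       # total time over the OU correlation time
  expect_lt(abs(v - kT / kk) / (kT / kk), 3 * sqrt(2 / nEff) + 0.02)
  expect_error(harvestWindows(potentialSpec("harmonic", k = 1),
                              c(0.1, 0.0), 8000, langevinParams()),
               "sorted")
})

test_that("adjacent flat-potential windows overlap sufficiently", {
  ws <- flatWindows(c(0, 0.05), seed = 9)
  # histogram overlap coefficient vs the Gaussian formula 2*Phi(-d/(2*sd))
  sdw <- sqrt(thermalEnergy() / kJToKcal(8000))
  refOverlap <- 2 * pnorm(-0.025 / sdw)
  breaks <- seq(-0.15, 0.2, by = 0.005)
  h1 <- hist(ws[[1]]@samples, breaks = breaks, plot = FALSE)$density
  h2 <- hist(ws[[2]]@samples, breaks = breaks, plot = FALSE)$density
  overlap <- sum(pmin(h1, h2)) * 0.005
  expect_gt(overlap, 0.1)
  expect_lt(abs(overlap - refOverlap), 0.1)
})

test_that("single near-unbiased window reduces WHAM to the raw histogram", {
  kT <- thermalEnergy()
  pot <- potentialSpec("harmonic", k = 2, center = 0)
  lp <- langevinParams(dt = 1e-3, kT = kT, friction = 0.5, nSteps = 2e5,
                       seed = 21)
  w <- harvestWindows(pot, 0, forceConstant = 1e-6, params = lp)
  prof <- whamSolve(w, nBins = 30, kT = kT)
  h <- prof@counts[, 1]
  ok <- h > 0
  ref <- -kT * log(h[ok])
  ref <- ref - min(ref)
  expect_equal(prof@freeEnergy[ok], ref, tolerance = 1e-6)
})

test_that("WHAM reconstructs an analytic double well to high accuracy", {
  study <- cachedWhamDoubleWell()
  expect_lt(whamRMSDkT(study), 0.2)
})

test_that("WHAM is invariant to window duplication and center-ordering gauge", {
  pot <- potentialSpec("double_well", height = 2, a = 0.4)
  lp <- langevinParams(dt = 5e-5, kT = 0.6, friction = 0.1, nSteps = 3e4,
                       seed = 2)
  ws <- harvestWindows(pot, seq(-0.6, 0.6, by = 0.05), 8000, lp)
  p1 <- whamSolve(ws, nBins = 40)
  p2 <- whamSolve(c(ws, ws), nBins = 40)       # duplicated data
  expect_equal(p1@freeEnergy, p2@freeEnergy, tolerance = 1e-6)
  expect_equal(min(p1@freeEnergy, na.rm = TRUE), 0)
  # non-overlapping windows are reported as a gap
  gap <- ws[c(1, length(ws))]
  expect_error(whamSolve(gap, nBins = 60), "overlap")
})

test_that("free-energy lookups interpolate and fold changes multiply", {
  # analytic harmonic profile
  xs <- seq(-1, 1, by = 0.02)
  prof <- new("PMFProfile", binCenters = xs, freeEnergy = 0.5 * 3 * xs^2,
              counts = matrix(1L, length(xs), 1))
  expect_equal(dGBetween(prof, 0, 0.5), 0.5 * 3 * 0.25, tolerance = 1e-3)
  expect_error(dGBetween(prof, 0, 2), "outside")
  expect_equal(foldChange(2.21, 303), 39, tolerance = 0.01)
  expect_equal(foldChange(0, 400), 1)
  a <- 1.3; b <- 0.9
  expect_equal(foldChange(a + b), foldChange(a) * foldChange(b),
               tolerance = 1e-12)
})

test_that("PMF error shrinks as per-window sampling doubles", {
  kT <- thermalEnergy()
  pot <- potentialSpec("double_well", height = 4 * kT, a = 0.5)
  rmsdAt <- function(nSteps) {
    errs <- vapply(1:3, function(s) {
      lp <- langevinParams(dt = 2e-6, kT = kT, friction = 0.1,
                           nSteps = nSteps, seed = 100 + s, stride = 10L)
      ws <- harvestWindows(pot, seq(-0.8, 0.8, by = 0.05), 8000, lp)
      # fine bins resolve the stiff windows, so statistical noise (not the
      # bin-discretization floor) dominates and halves with sampling
      prof <- whamSolve(ws, nBins = 320)
      ok <- is.finite(prof@freeEnergy) & rowSums(prof@counts) > 20
      xs <- prof@binCenters[ok]
      ref <- potentialEnergy(pot, matrix(xs, ncol = 1))
      fe <- prof@freeEnergy[ok]
      sqrt(mean((fe + mean(ref - fe) - ref)^2))
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(2.5e5, 5e5, 1e6, 2e6), rmsdAt, numeric(1))
  expect_true(all(diff(e) < 0))
})
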