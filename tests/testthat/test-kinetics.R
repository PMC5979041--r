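test_that("MFPT solves the absorbing linear system", {
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  mm <- makeReversibleModel(Tm, lag = 1)
  expect_equal(mfpt(mm, 1, 2), 10)       # geometric: 1/0.1 steps of 1 ns
  expect_equal(mfpt(mm, 1, 1), 0)        # source equals target
  # 4-state network: discretized-chain MFPT matches the continuous oracle
  net <- benchmarkNetwork()
  o <- ctmcOracle(net)
  lag <- 10
  Texact <- as.matrix(Matrix::expm(Matrix::Matrix(rateMatrix(net) * lag)))
  mmN <- new("MarkovModel", transitionMatrix = Texact, lag = lag,
             stationary = unname(o$stationary),
             eigenvalues = sort(Re(eigen(Texact,
                                         only.values = TRUE)$values),
                                decreasing = TRUE),
             activeSet = 1:4)
  expect_lt(abs(mfpt(mmN, 1, 4) - o$mfpt[1, 4]), lag)
  # off-direction: point sampling misses target visits shorter than the lag,
  # each miss costing roughly another recurrence time -- the derived
  # discretization bound is lag + MFPT * P(dwell < lag)
  pMiss <- 1 - exp(-(-rateMatrix(net)[1, 1]) * lag)
  expect_lt(abs(mfpt(mmN, 4, 1) - o$mfpt[4, 1]), lag + o$mfpt[4, 1] * pMiss)
})

test_that("rate constants convert MFPTs at the stated concentration", {
  r <- ratesFromMFPT(5163, 3.2e6, 9.55e-3)
  expect_equal(r$kOn, 2.03e7, tolerance = 0.005)
  expect_equal(r$kOff, 312.5, tolerance = 1e-9)
  expect_equal(ratesFromMFPT(1, 1, 1)$kOn, 1e9)    # unit identity
  expect_error(ratesFromMFPT(1, 1, 0), "concentration")
  # unit round trip to 1e-12 relative
  k <- ratesFromMFPT(1234.5, 6.789e5, 0.012)
  expect_equal(1 / (k$kOn * 0.012) * 1e9, 1234.5, tolerance = 1e-12)
  expect_equal(1e9 / k$kOff, 6.789e5, tolerance = 1e-12)
})

test_that("binding free energy applies the standard-state correction", {
  g <- bindingDG(0.9983, 0.0011, 303, 9.55e-3)
  expect_equal(g$dG0, -6.9, tolerance = 0.01)
  g0 <- bindingDG(0.5, 0.5, 303, 1)
  expect_equal(g0$dGsim, 0)
  expect_equal(g0$dG0, 0)
  expect_error(bindingDG(0, 0.5, 303, 1), "positive")
})

test_that("standard-state free energy is concentration-invariant under ideal dilution", {
  # bimolecular surrogate on the oracle network: in the ideal-dilute regime
  # pi_unbound/pi_bound scales linearly with 1/C, so dG0 is C-independent
  o <- ctmcOracle(benchmarkNetwork())
  piB <- o$stationary[4]; piU <- o$stationary[1]
  C0 <- 9.55e-3
  vals <- vapply(c(0.5, 1, 2, 5), function(scale) {
    C <- C0 * scale
    bindingDG(piB, piU / scale, 303, C)$dG0
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 1e-9)
})

test_that("activation barriers follow the transition-path-time relation", {
  b <- barrierUnbinding(7, 0.95e3, 303)
  expect_equal(b@dGUnbindingRT, 11.9, tolerance = 0.01)
  expect_warning(b0 <- barrierUnbinding(1, 1e9), "non-positive")
  expect_equal(b0@dGUnbindingRT, 0)
  expect_warning(bw <- barrierUnbinding(exp(1), 1e9), "non-positive")
  expect_equal(bw@dGUnbindingRT, -1, tolerance = 1e-9)
  b2 <- barrierBinding(-4.2, b, 303)
  expect_equal(b2@dGBindingRT, 5, tolerance = 0.02)
  # dG_binding = 0 leaves the barrier unchanged
  expect_equal(barrierBinding(0, b)@dGBindingRT, b@dGUnbindingRT)
  # round trip: dG*_bind - dG*_unb recovers dG_binding/RT exactly
  RT <- kB * 303
  expect_equal((b2@dGBindingRT - b2@dGUnbindingRT) * RT, -4.2,
               tolerance = 1e-12)
  expect_error(barrierUnbinding(-1, 10), "positive")
})

test_that("trajectory bootstrap is deterministic and calibrated", {
  set.seed(50)
  trajs <- lapply(1:30, function(i) rnorm(100))
  bc <- bootstrapCI(trajs, function(tr) mean(unlist(tr)), nBoot = 200,
                    seed = 4)
  bc2 <- bootstrapCI(trajs, function(tr) mean(unlist(tr)), nBoot = 200,
                     seed = 4)
  expect_identical(bc$replicates, bc2$replicates)
  # constant estimator has zero spread
  expect_equal(bootstrapCI(trajs, function(tr) 1, nBoot = 50, seed = 1)$sd, 0)
  # sample-mean estimator: bootstrap sd near sigma/sqrt(n)
  ses <- vapply(1:5, function(s) {
    set.seed(s + 200)
    tr <- lapply(1:40, function(i) rnorm(1))
    bootstrapCI(tr, function(x) mean(unlist(x)), nBoot = 200, seed = s)$sd
  }, numeric(1))
  expect_lt(abs(mean(ses) - 1 / sqrt(40)) / (1 / sqrt(40)), 0.3)
  expect_error(bootstrapCI(trajs[1], mean), "at least 2")
  expect_error(bootstrapCI(trajs, function(tr) stop("boom"), nBoot = 10,
                           seed = 1), "failed")
})
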