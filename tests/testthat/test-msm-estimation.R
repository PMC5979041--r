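dtrajOf <- function(states, nStates = max(states), fi = 1) {
  new("DiscreteTrajectory", states = as.integer(states),
      nStates = as.integer(nStates), frameInterval = fi)
}

test_that("count matrices use sliding windows and find the connected set", {
  cm <- countMatrix(dtrajOf(c(1, 2, 1, 2)), lag = 1)
  expect_equal(cm$counts, matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE))
  cm2 <- countMatrix(dtrajOf(c(1, 1, 1), nStates = 2), lag = 1)
  expect_equal(cm2$counts, matrix(c(2, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(cm2$activeSet, 1L)
  # brute-force pair enumeration on a random trajectory
  set.seed(6)
  s <- sample(1:3, 1000, replace = TRUE)
  cm3 <- countMatrix(dtrajOf(s), lag = 2)
  ref <- matrix(0L, 3, 3)
  for (t in 1:998) ref[s[t], s[t + 2]] <- ref[s[t], s[t + 2]] + 1L
  expect_equal(cm3$counts, ref)
  expect_error(countMatrix(dtrajOf(c(1, 2)), lag = 5), "trajectory")
  expect_error(countMatrix(dtrajOf(1:3), lag = 0.5), "multiple")
})

test_that("reversible estimator reduces to row normalization for symmetric counts", {
  C <- matrix(c(10, 4, 4, 20), 2, 2)
  mm <- estimateReversible(C, lag = 1)
  expect_equal(transitionMatrix(mm), C / rowSums(C), tolerance = 1e-9)
})

test_that("reversible MLE satisfies detailed balance and beats other reversible fits", {
  C <- matrix(c(90, 10, 40, 60), 2, 2, byrow = TRUE)
  mm <- estimateReversible(C, lag = 1)
  Tm <- transitionMatrix(mm)
  pi <- stationaryDistribution(mm)
  expect_lt(max(abs(pi * Tm - t(pi * Tm))), 1e-10)
  llHat <- transitionLogLik(Tm, C)
  # 2-state closed form: maximize the likelihood over the detailed-balance
  # family directly (independent numeric oracle)
  negll <- function(par) {
    a <- plogis(par[1]); b <- plogis(par[2])
    -transitionLogLik(matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE), C)
  }
  opt <- optim(c(0, 0), negll, method = "BFGS")
  expect_equal(llHat, -opt$value, tolerance = 1e-7)
  aHat <- plogis(opt$par[1]); bHat <- plogis(opt$par[2])
  piRef <- c(bHat, aHat) / (aHat + bHat)
  expect_equal(pi, piRef, tolerance = 1e-4, ignore_attr = TRUE)
  # any detailed-balance competitor has lower likelihood
  set.seed(3)
  for (i in 1:20) {
    p <- runif(2, 0.01, 0.99)
    Tc <- matrix(c(1 - p[1], p[1], p[2], 1 - p[2]), 2, 2, byrow = TRUE)
    expect_lte(transitionLogLik(Tc, C), llHat + 1e-9)
  }
})

test_that("estimated models satisfy every Markov-model invariant", {
  set.seed(11)
  for (rep in 1:5) {
    s <- cumsum(sample(c(-1, 0, 1), 3000, replace = TRUE,
                       prob = c(0.2, 0.6, 0.2)))
    s <- ((s %% 5) + 5) %% 5 + 1
    mm <- estimateReversible(countMatrix(dtrajOf(s), lag = 1))
    Tm <- transitionMatrix(mm); pi <- stationaryDistribution(mm)
    expect_lt(max(abs(rowSums(Tm) - 1)), 1e-12)
    expect_lt(max(abs(pi %*% Tm - pi)), 1e-10)
    expect_lt(max(abs(pi * Tm - t(pi * Tm))), 1e-10)
    expect_equal(mm@eigenvalues[1], 1)
    expect_true(all(abs(mm@eigenvalues) <= 1 + 1e-10))
  }
})

test_that("implied timescales follow the defining formula and are lag-stable", {
  # formula: lambda_2 = exp(-1) at tau = 10 -> t_2 = 10
  expect_equal(-10 / log(exp(-1)), 10)
  # a chain sampled from an exact Markov matrix keeps t_2 flat across lags
  Tm <- matrix(c(0.95, 0.05, 0.02, 0.98), 2, 2, byrow = TRUE)
  set.seed(5)
  s <- ligandMSM:::cpp_markov_sample(Tm, 1L, 2e5)
  its <- impliedTimescales(dtrajOf(s), lags = c(1, 2, 4, 8), nTimescales = 1)
  t2 <- its$timescale[its$index == 2]
  expect_lt(max(abs(t2 - t2[1])) / t2[1], 0.1)
  # analytic relaxation of a 2-state CTMC: t_2 ~ 1/(k01 + k10)
  net <- kineticNetwork(matrix(c(0, 0.05, 0.05, 0), 2, 2, byrow = TRUE))
  d <- simulateCTMC(net, 2e5, 1, seed = 9)
  its2 <- impliedTimescales(d, lags = c(5, 10), nTimescales = 1)
  expect_lt(abs(its2$timescale[1] - 10) / 10, 0.1)
})

test_that("implied timescales are invariant under trajectory duplication", {
  set.seed(14)
  s <- sample(1:3, 5000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  d <- dtrajOf(s)
  a <- impliedTimescales(d, lags = c(1, 2))
  b <- impliedTimescales(list(d, d, d), lags = c(1, 2))
  expect_equal(a$timescale, b$timescale, tolerance = 1e-12)
})
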