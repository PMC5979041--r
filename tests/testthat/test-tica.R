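makeTelegraphFeatures <- function(seed, nFrames = 5e4, rate = 0.05,
                                  noiseDims = 1) {
  net <- kineticNetwork(matrix(c(0, rate, rate, 0), 2, 2, byrow = TRUE))
  d <- simulateCTMC(net, nFrames, 1, seed = seed)
  set.seed(seed + 1000)
  slow <- ifelse(stateSequence(d) == 1, -1, 1) + rnorm(length(d@states), sd = 0.05)
  X <- cbind(slow, matrix(rnorm(length(slow) * noiseDims), ncol = noiseDims))
  new("FeatureTrajectory", values = X,
      labels = paste0("f", seq_len(ncol(X))), frameInterval = 1)
}

test_that("the first tIC aligns with a slow telegraph coordinate", {
  f <- makeTelegraphFeatures(seed = 2)
  m <- estimateTICA(f, lag = 5)
  v <- m@eigenvectors[, 1]
  cosine <- abs(v[1]) / sqrt(sum(v^2))
  expect_gt(cosine, 0.99)
  expect_true(all(m@eigenvalues <= 1 + 1e-8))
  expect_equal(sum(m@kineticVariance), 1, tolerance = 1e-9)
})

test_that("leading tICA eigenvalue estimates the two-state relaxation", {
  # 2-state symmetric CTMC with total exit-rate sum k: autocorrelation of the
  # state indicator decays as exp(-k t)
  k <- 0.04 + 0.04
  lag <- 10
  lams <- vapply(1:6, function(s) {
    f <- makeTelegraphFeatures(seed = 100 + s, nFrames = 4e4, rate = 0.04)
    estimateTICA(f, lag = lag)@eigenvalues[1]
  }, numeric(1))
  se <- sd(lams) / sqrt(length(lams))
  # small attenuation from the 5% measurement noise on the indicator
  expect_lt(abs(mean(lams) - exp(-k * lag)), 3 * se + 0.01)
})

test_that("tICA validates its inputs", {
  f <- makeTelegraphFeatures(seed = 3, nFrames = 500)
  expect_error(estimateTICA(f, lag = 0), "positive")
  expect_warning(
    expect_error(estimateTICA(f, lag = 1000), "all trajectories"),
    "skipped")
  f2 <- makeTelegraphFeatures(seed = 4, nFrames = 5000)
  expect_warning(m <- estimateTICA(list(f2, makeTelegraphFeatures(5, 50)),
                                   lag = 100), "skipped")
  expect_s4_class(m, "TICAModel")
})

test_that("projection rules select components as documented", {
  m <- new("TICAModel", center = c(0, 0, 0), lag = 1,
           eigenvalues = c(0.9, 0.43, 0.35),
           eigenvectors = diag(3),
           kineticVariance = c(0.9, 0.06, 0.04) / 1)
  f <- new("FeatureTrajectory", values = matrix(rnorm(30), 10, 3),
           labels = c("a", "b", "c"), frameInterval = 1)
  expect_equal(attr(projectTICA(m, f, kineticVarianceCutoff = 0.95),
                    "nComponents"), 2)           # cumulative 0.96 at n = 2
  expect_equal(attr(projectTICA(m, f, kineticVarianceCutoff = 1.0),
                    "nComponents"), 3)           # all components
  expect_error(projectTICA(m, f, kineticVarianceCutoff = 1.2), "> 1")
  # projecting the model's own center gives the zero vector
  fc <- new("FeatureTrajectory", values = matrix(m@center, 1, 3),
            labels = c("a", "b", "c"), frameInterval = 1)
  expect_equal(projectTICA(m, fc, n = 3)[[1]], matrix(0, 1, 3),
               ignore_attr = TRUE)
})

test_that("k-means recovers well-separated clouds and is deterministic", {
  set.seed(42)
  centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, -5, 2), 5, 2, byrow = TRUE)
  X <- centers[rep(1:5, each = 200), ] + matrix(rnorm(2000, sd = 0.2), 1000, 2)
  cl <- clusterKMeans(X, k = 5, seed = 9)
  got <- stateSequence(cl$dtrajs[[1]])
  truth <- rep(1:5, each = 200)
  # relabel-invariant partition equality
  expect_equal(length(unique(paste(got, truth))), 5)
  # k = 1: single cluster at the global mean
  cl1 <- clusterKMeans(X, k = 1, seed = 9)
  expect_equal(as.vector(cl1$centers), colMeans(X), tolerance = 1e-12)
  # determinism
  cl2 <- clusterKMeans(X, k = 5, seed = 9)
  expect_identical(stateSequence(cl2$dtrajs[[1]]), got)
  expect_identical(cl2$centers, cl$centers)
  expect_error(clusterKMeans(X[1:3, ], k = 5, seed = 1), "fewer")
})

test_that("k-means objective is competitive with the stats reference", {
  set.seed(13)
  X <- matrix(rnorm(600), 300, 2)
  cl <- clusterKMeans(X, k = 4, seed = 5)
  wssOurs <- sum(vapply(seq_len(nrow(X)), function(i)
    sum((X[i, ] - cl$centers[stateSequence(cl$dtrajs[[1]])[i], ])^2),
    numeric(1)))
  ref <- stats::kmeans(X, centers = 4, nstart = 10)
  expect_lt(wssOurs, ref$tot.withinss * 1.05)
})
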