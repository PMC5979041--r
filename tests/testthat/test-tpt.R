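test_that("committors honour boundary conditions and symmetry", {
  Tm <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3,
               byrow = TRUE)
  mm <- makeReversibleModel(Tm)
  q <- committorForward(mm, 1, 3)
  expect_equal(q[1], 0)
  expect_equal(q[3], 1)                 # target committor is exactly 1
  expect_equal(q[2], 0.5)               # symmetric chain midpoint
  expect_equal(committorBackward(mm, 1, 3), 1 - q, tolerance = 1e-10)
  expect_error(committorForward(mm, 1, 1), "disjoint")
})

test_that("committors match Monte Carlo first-hit probabilities", {
  Tm <- randomReversibleT(6, seed = 17)
  mm <- makeReversibleModel(Tm)
  A <- 1L; B <- 6L
  q <- committorForward(mm, A, B)
  set.seed(31)
  for (s in 2:5) {
    mc <- ligandMSM:::cpp_mc_first_hit(Tm, A, B, as.integer(s), 20000L, 1e6)
    phat <- mc$hitsB / 20000
    se <- sqrt(max(phat * (1 - phat), 1e-6) / 20000)
    expect_lt(abs(phat - q[s]), 3.5 * se)
  }
})

test_that("reactive flux is conserved and matches closed forms", {
  # linear chain A-I-B: flux through the intermediate is conserved
  Tm <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3,
               byrow = TRUE)
  mm <- makeReversibleModel(Tm)
  r <- reactiveFlux(mm, 1, 3)
  expect_equal(sum(r@netFlux[, 2]), sum(r@netFlux[2, ]), tolerance = 1e-14)
  # adjacent A/B with a single connecting edge: total flux = pi_A T_AB
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  mm2 <- makeReversibleModel(T2)
  r2 <- reactiveFlux(mm2, 1, 2)
  expect_equal(r2@totalFlux,
               stationaryDistribution(mm2)[1] * 0.1, tolerance = 1e-12)
})

test_that("total flux matches reactive transitions counted in a long chain", {
  Tm <- randomReversibleT(6, seed = 8)
  mm <- makeReversibleModel(Tm)
  A <- 1L; B <- 6L
  r <- reactiveFlux(mm, A, B)
  set.seed(91)
  s <- ligandMSM:::cpp_markov_sample(Tm, 1L, 4e5)
  # count A->B reactive completions: crossings that leave A and reach B
  # before returning to A
  lastA <- s == A
  from <- NA; nAB <- 0L
  for (t in seq_along(s)) {
    if (s[t] == A) from <- "A"
    else if (s[t] == B) { if (identical(from, "A")) nAB <- nAB + 1L; from <- "B" }
  }
  fluxHat <- nAB / length(s)
  se <- sqrt(nAB) / length(s)
  expect_lt(abs(fluxHat - r@totalFlux), 3 * se)
})

test_that("time-reversal symmetry: A->B flux equals B->A flux", {
  for (seed in c(4, 9)) {
    Tm <- randomReversibleT(5, seed = seed)
    mm <- makeReversibleModel(Tm)
    f1 <- reactiveFlux(mm, 1, 5, decompose = FALSE)@totalFlux
    f2 <- reactiveFlux(mm, 5, 1, decompose = FALSE)@totalFlux
    expect_equal(f1, f2, tolerance = 1e-10)
  }
})

test_that("committor is monotone along a birth-death chain", {
  Tm <- birthDeathT(c(0.3, 0.2, 0.25, 0.15, 0.3))
  mm <- makeReversibleModel(Tm)
  q <- committorForward(mm, 1, 6)
  expect_true(all(diff(q) >= -1e-12))
})

test_that("pathway decomposition extracts bottleneck paths in order", {
  # single chain: one path with fraction 1
  W <- matrix(0, 3, 3); W[1, 2] <- 0.5; W[2, 3] <- 0.5
  p <- decomposePathways(W, 1, 3)
  expect_equal(p$path, "1->2->3")
  expect_equal(p$fraction, 1)
  # parallel direct edge 0.75 + two-hop path with bottleneck 0.25
  W2 <- matrix(0, 3, 3); W2[1, 3] <- 0.75; W2[1, 2] <- 0.25; W2[2, 3] <- 0.25
  p2 <- decomposePathways(W2, 1, 3, residualFraction = 0.04)
  expect_equal(p2$path[1:2], c("1->3", "1->2->3"))
  expect_equal(p2$fraction[1:2], c(0.75, 0.25))
  expect_error(decomposePathways(matrix(c(0, 1, 1, 0), 2, 2), 1, 2),
               "2-cycle")
})

test_that("four-state decomposition agrees with exhaustive enumeration", {
  # direct unbound->bound edge plus two gateway routes
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.52; W[2, 4] <- 0.57; W[1, 3] <- 0.09; W[3, 2] <- 0.05
  W[3, 4] <- 0.04; W[1, 4] <- 0.39
  res <- decomposePathways(W, 1, 4, residualFraction = 1e-9)
  # independent greedy oracle: enumerate all simple paths, repeatedly take
  # the one with maximal bottleneck (ties broken identically by max search)
  enumPaths <- function() list(c(1, 4), c(1, 2, 4), c(1, 3, 4), c(1, 3, 2, 4))
  Wo <- W; out <- list()
  repeat {
    bns <- vapply(enumPaths(), function(p)
      min(Wo[cbind(p[-length(p)], p[-1])]), numeric(1))
    if (max(bns) <= 1e-12) break
    k <- which.max(bns)
    p <- enumPaths()[[k]]
    Wo[cbind(p[-length(p)], p[-1])] <- Wo[cbind(p[-length(p)], p[-1])] - bns[k]
    out[[length(out) + 1]] <- list(path = paste(p, collapse = "->"),
                                   flux = bns[k])
  }
  ref <- data.frame(path = vapply(out, `[[`, "", "path"),
                    flux = vapply(out, `[[`, 0, "flux"))
  ref <- ref[order(ref$flux, decreasing = TRUE), ]
  expect_equal(res$path, ref$path)
  expect_equal(res$flux, ref$flux, tolerance = 1e-12)
  expect_gte(sum(res$fraction), 0.99)
  # fractions are invariant to uniform flux rescaling
  res2 <- decomposePathways(W * 7, 1, 4, residualFraction = 1e-9)
  expect_equal(res2$fraction, res$fraction, tolerance = 1e-12)
})
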