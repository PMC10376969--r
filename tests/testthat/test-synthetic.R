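test_that("graph generation honors arc and bidirectionality counts", {
  for (spec in list(c(5, 5, 0), c(5, 8, 2), c(7, 10, 3), c(18, 10, 0))) {
    g <- makeGraph(spec[1], spec[2], spec[3], seed = 42)
    a <- adjacencyMatrix(g)
    expect_equal(sum(a), spec[2])
    expect_equal(sum(a * t(a)) / 2, spec[3])  # mutually-reversed pairs
    expect_true(all(diag(a) == 0))
    if (spec[2] >= spec[1] - 1)
      expect_true(amortEC:::.isWeaklyConnected(a))
  }
  # deterministic under a fixed seed
  expect_identical(adjacencyMatrix(makeGraph(6, 7, 1, seed = 9)),
                   adjacencyMatrix(makeGraph(6, 7, 1, seed = 9)))
})

test_that("graph generation saturates and rejects infeasible requests", {
  # the only 2-node graph with one bidirectional pair
  expect_equal(adjacencyMatrix(makeGraph(2, 2, 1, seed = 1)),
               matrix(c(0, 1, 1, 0), 2, 2))
  # full off-diagonal saturation
  expect_equal(adjacencyMatrix(makeGraph(3, 6, 3, seed = 1)),
               1 - diag(3))
  expect_error(makeGraph(3, 7, 0), "exceeds")
  expect_error(makeGraph(4, 4, 3), "nBidirectional")
  # 6 arcs on 3 nodes require all three pairs to be bidirectional
  expect_error(makeGraph(3, 6, 0), "infeasible")
})

test_that("unforced linear dynamics from rest stay at zero", {
  g <- makeGraph(4, 4, 0, seed = 2)
  x <- simulateSubject(g, 40, simOptions(noiseSd = 0), seed = 1)
  expect_equal(dim(x), c(4L, 40L))
  expect_true(all(x == 0))
})

test_that("a noise-free child reproduces its parent's lagged series", {
  # 2-node chain 1 -> 2 with innovations only on node 1: the recursion gives
  # x2[s] = a * x1[s-1] exactly
  a <- 0.7
  g <- GroundTruthGraph(matrix(c(0, 0, 1, 0), 2, 2))  # arc 1 -> 2
  opts <- simOptions(couplingStrength = a, noiseSd = c(1, 0))
  x <- simulateSubject(g, 100, opts, seed = 5)
  expect_equal(x[2, 2:100], a * x[1, 1:99], tolerance = 1e-12)

  # stepwise oracle over the full recursion, replayed from the same seed
  p <- 1L; burn <- 100L; total <- 100L + burn + p
  set.seed(5)
  noise <- matrix(stats::rnorm(2 * total), 2, total) * c(1, 0)
  xo <- matrix(0, 2, total)
  for (s in (p + 1):total) {
    xo[1, s] <- noise[1, s]
    xo[2, s] <- a * xo[1, s - 1] + noise[2, s]
  }
  expect_equal(unname(x), xo[, (total - 99):total], tolerance = 1e-12)
})

test_that("unstable coupling is rejected", {
  g <- GroundTruthGraph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(simulateSubject(g, 50, simOptions(couplingStrength = 1.2)),
               "spectral radius")
  expect_error(simulateCohort(g, 2, 50, simOptions(couplingStrength = 1.2)),
               "spectral radius")
})

test_that("simulator options change the generated series as described", {
  g <- makeGraph(5, 5, 0, seed = 3)
  base <- simOptions(couplingStrength = 0.5, noiseSd = 0.4)
  x0 <- simulateSubject(g, 60, base, seed = 7)
  # identical seed, identical options: bitwise reproducible
  expect_identical(x0, simulateSubject(g, 60, base, seed = 7))

  # global confound raises pairwise correlations on average
  xc <- simulateSubject(g, 2000,
                        simOptions(couplingStrength = 0.5, noiseSd = 0.4,
                                   globalConfound = TRUE), seed = 7)
  x1 <- simulateSubject(g, 2000, base, seed = 7)
  mco <- function(m) { w <- cor(t(m)); mean(w[upper.tri(w)]) }
  expect_gt(mco(xc), mco(x1))

  # nonlinearity bounds the propagated drive; hrf smoothing autocorrelates
  xnl <- simulateSubject(g, 60, simOptions(couplingStrength = 0.5,
                                           noiseSd = 0.4, nonlinear = TRUE),
                         seed = 7)
  expect_false(identical(x0, xnl))
  xh <- simulateSubject(g, 2000, simOptions(couplingStrength = 0.5,
                                            noiseSd = 0.4, hrfSmoothing = TRUE),
                        seed = 7)
  lag1 <- function(m) mean(sapply(seq_len(nrow(m)), function(i)
    cor(m[i, -1], m[i, -ncol(m)])))
  expect_gt(lag1(xh), lag1(x1))
})

test_that("cohorts have the declared shape and per-subject truths", {
  sim <- tinyCohort(m = 4, n = 4, t = 25, seed = 6, flip = 0)
  expect_s4_class(sim$cohort, "CohortTimeSeries")
  expect_equal(dim(cohortArray(sim$cohort)), c(4L, 4L, 25L))
  # flip probability zero: every subject shares the base truth
  base <- adjacencyMatrix(sim$truths[[1]])
  for (tr in sim$truths) expect_identical(adjacencyMatrix(tr), base)

  # nonzero flips give per-subject variations around the base graph
  g <- makeGraph(6, 6, 0, seed = 10)
  simf <- simulateCohort(g, 30, 20,
                         simOptions(couplingStrength = 0.4,
                                    subjectGraphFlipProb = 0.1), seed = 10)
  diffs <- vapply(simf$truths, function(tr)
    sum(abs(adjacencyMatrix(tr) - adjacencyMatrix(g))), numeric(1))
  expect_gt(sum(diffs), 0)        # some flips happened over 30 subjects
  expect_lt(mean(diffs), 6)       # but most arcs are shared

  # determinism of the whole cohort draw
  sim2 <- tinyCohort(m = 4, n = 4, t = 25, seed = 6, flip = 0)
  expect_identical(cohortArray(sim$cohort), cohortArray(sim2$cohort))
})

test_that("variance is stationary once transients are discarded", {
  g <- makeGraph(5, 5, 0, seed = 20)
  opts <- simOptions(couplingStrength = 0.5, noiseSd = 1)
  ratios <- sapply(1:10, function(seed) {
    xa <- simulateSubject(g, 200, opts, seed = seed)
    xb <- simulateSubject(g, 400, opts, seed = seed)
    va <- mean(apply(xa[, 101:200], 1, var))
    vb <- mean(apply(xb[, 201:400], 1, var))
    vb / va
  })
  expect_lt(abs(median(ratios) - 1), 0.5)
})

test_that("lagged regression ranks true arcs above non-arcs", {
  # independent oracle: per ordered pair (i, j), the |coefficient| of
  # x_i[t-1] in lm(x_j[t] ~ x_j[t-1] + x_i[t-1]) should separate arcs from
  # non-arcs on long, mildly noisy linear data
  g <- makeGraph(5, 5, 0, seed = 14)
  a <- adjacencyMatrix(g)
  x <- simulateSubject(g, 2000, simOptions(couplingStrength = 0.8,
                                           noiseSd = 0.1), seed = 14)
  n <- 5
  coefs <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    fit <- lm(x[j, -1] ~ x[j, -2000] + x[i, -2000])
    coefs[i, j] <- abs(coef(fit)[3])
  }
  arcVals <- coefs[a == 1]
  nonVals <- coefs[a == 0 & row(a) != col(a)]
  frac <- mean(outer(arcVals, nonVals, ">"))
  expect_gte(frac, 0.9)
})

test_that("z-scoring standardizes every region and rejects constants", {
  sim <- tinyCohort(m = 2, n = 3, t = 40, seed = 2)
  z <- zscoreCohort(sim$cohort)
  d <- cohortArray(z)
  for (s in 1:2) for (r in 1:3) {
    expect_equal(mean(d[s, r, ]), 0, tolerance = 1e-12)
    expect_equal(sd(d[s, r, ]), 1, tolerance = 1e-12)
  }
  dd <- cohortArray(sim$cohort); dd[1, 2, ] <- 3
  expect_error(zscoreCohort(CohortTimeSeries(dd)), "subject01.*R2|region R2")
})
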