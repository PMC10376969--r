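test_that("ELBO loss reproduces hand-computed values", {
  # perfect reconstruction + uniform rows against the uniform prior: zero
  sim <- tinyCohort(m = 2, n = 4, t = 20)
  d <- cohortArray(sim$cohort)
  uniformG <- matrix(1 / 3, 4, 4); diag(uniformG) <- 0
  expect_equal(elboLoss(sim$cohort, d, list(uniformG, uniformG)), 0)

  # KL of a single concentrated row: 0.8 ln 1.6 + 0.2 ln 0.4 = 0.19274...
  g <- matrix(0, 3, 3)
  g[1, 2] <- 0.8; g[1, 3] <- 0.2
  g[2, 1] <- 0.5; g[2, 3] <- 0.5
  g[3, 1] <- 0.5; g[3, 2] <- 0.5
  klHand <- 0.8 * log(0.8 / 0.5) + 0.2 * log(0.2 / 0.5)
  zero <- array(0, c(1, 3, 10))
  expect_equal(elboLoss(zero, zero, list(g)), klHand, tolerance = 1e-10)
  expect_equal(klHand, 0.19274, tolerance = 1e-4)

  # doubling the likelihood sd divides the reconstruction term by four
  set.seed(3)
  x <- array(rnorm(1 * 3 * 10), c(1, 3, 10))
  l1 <- elboLoss(x, zero, list(), trainingConfig(likelihoodSd = 1))
  l2 <- elboLoss(x, zero, list(), trainingConfig(likelihoodSd = 2))
  expect_equal(l1 / 4, l2, tolerance = 1e-12)
})

test_that("sparsity penalty is lambda times total absolute weight", {
  expect_equal(sparsityPenalty(list(matrix(0, 3, 3)), 1), 0)
  g <- matrix(1 / 3, 4, 4); diag(g) <- 0  # row-stochastic: mass n
  expect_equal(sparsityPenalty(list(g), 1), 4)
  expect_equal(sparsityPenalty(list(g, g), 0), 0)
  expect_equal(sparsityPenalty(list(g, g), 0.1), 0.8)
})

test_that("binarization thresholds strictly and clears the diagonal", {
  g <- matrix(0, 3, 3)
  g[1, ] <- c(0, 0.6, 0.25); g[2, ] <- c(0.15, 0, 0.3); g[3, ] <- c(0.31, 0.29, 0)
  b <- adjacencyMatrix(binarize(g, 0.3))
  expect_equal(which(b == 1), which(g > 0.3))       # 0.3 itself excluded
  expect_true(all(diag(b) == 0))
  expect_equal(sum(adjacencyMatrix(binarize(g, 0.9))), 0)   # tau >= max
  expect_equal(adjacencyMatrix(binarize(g, 1e-9)), (g > 1e-9) * 1)
})

test_that("amortized training is deterministic and reduces the loss", {
  sim <- tinyCohort(m = 4, n = 4, t = 30, seed = 31, flip = 0)
  co <- zscoreCohort(sim$cohort)
  tc <- trainingConfig(epochs = 30L, amortizeM = 2L, seed = 12)
  fit1 <- trainAmortized(co, tc, smallEnc(), smallDec())
  fit2 <- trainAmortized(co, tc, smallEnc(), smallDec())
  expect_identical(lapply(subjectGraphs(fit1$report), ecWeights),
                   lapply(subjectGraphs(fit2$report), ecWeights))
  expect_identical(lossTrace(fit1$report), lossTrace(fit2$report))

  trace <- lossTrace(fit1$report)
  expect_length(trace, 30)
  expect_true(all(is.finite(trace)))
  expect_lt(trace[30], trace[1])
  # every subject gets a row-stochastic graph
  for (g in subjectGraphs(fit1$report))
    expect_equal(rowSums(ecWeights(g)), rep(1, 4), tolerance = 1e-6)
})

test_that("adaptation is copy-on-write and collapses to zero-shot at 0 epochs", {
  sim <- tinyCohort(m = 3, n = 4, t = 30, seed = 17, flip = 0)
  co <- zscoreCohort(sim$cohort)
  tc <- trainingConfig(epochs = 15L, amortizeM = 3L, seed = 5)
  fit <- trainAmortized(co, tc, smallEnc(), smallDec())
  xnew <- subjectSeries(co, 2)

  before <- unlist(fit$state@encoder)
  g0 <- adaptSubject(fit$state, xnew, trainingConfig(adaptEpochs = 0L))
  # zero epochs: identical to the amortized model's zero-shot encoding
  expect_equal(ecWeights(g0), ecWeights(encodeGraph(co, fit$state)[[2]]),
               tolerance = 1e-12)

  gA <- adaptSubject(fit$state, xnew, trainingConfig(adaptEpochs = 5L, seed = 5))
  gB <- adaptSubject(fit$state, xnew, trainingConfig(adaptEpochs = 5L, seed = 5))
  expect_identical(ecWeights(gA), ecWeights(gB))      # deterministic
  expect_false(identical(ecWeights(gA), ecWeights(g0)))
  # the original state is untouched
  expect_identical(unlist(fit$state@encoder), before)
  expect_error(adaptSubject(fit$state, xnew[, 1:10], tc), "t = 10")
})

test_that("adaptation moves training-cohort subjects less than novel ones", {
  # paired comparison at the benchmark-like regime: the amortized model has
  # already fit its training subjects, so ten adaptation epochs displace
  # their graphs less (in total L1) than a genuinely novel subject's
  deltas <- sapply(1:5, function(seed) {
    g <- makeGraph(5, 5, 0, seed = seed)
    sim <- simulateCohort(g, m = 6, t = 200,
        opts = simOptions(couplingStrength = 0.8, noiseSd = 0.5,
                          subjectGraphFlipProb = 0), seed = seed)
    co <- zscoreCohort(sim$cohort)
    train <- CohortTimeSeries(cohortArray(co)[1:5, , , drop = FALSE])
    fit <- trainAmortized(train, trainingConfig(seed = seed),
                          encoderTestPreset(), decoderConfig())
    move <- function(x) {
      g0 <- ecWeights(adaptSubject(fit$state, x, trainingConfig(adaptEpochs = 0L)))
      g1 <- ecWeights(adaptSubject(fit$state, x, trainingConfig(adaptEpochs = 10L)))
      sum(abs(g1 - g0))
    }
    move(subjectSeries(co, 6)) - move(subjectSeries(co, 1))
  })
  expect_gt(median(deltas), 0)
})
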