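test_that("region embedding is a per-token linear map over the time axis", {
  enc <- smallEnc(); dec <- smallDec()
  state <- initModel(30, enc, dec, seed = 1)
  sim <- tinyCohort(m = 3, n = 4, t = 30)
  emb <- embedRegions(sim$cohort, state)
  expect_equal(dim(emb), c(3L, 4L, enc$hiddenDim))

  # zero input with zero bias embeds to zero (linearity)
  zero <- CohortTimeSeries(array(0, c(2, 4, 30)))
  expect_true(all(embedRegions(zero, state) == 0))

  # duplicating a region duplicates its embedding row
  d <- cohortArray(sim$cohort)
  d[1, 2, ] <- d[1, 1, ]
  emb2 <- embedRegions(CohortTimeSeries(d), state)
  expect_equal(emb2[1, 2, ], emb2[1, 1, ])

  # t mismatch is a shape error
  short <- CohortTimeSeries(array(rnorm(3 * 4 * 10), c(3, 4, 10)))
  expect_error(embedRegions(short, state), "t = 10")
})

test_that("self-attention reproduces hand-computed weights and outputs", {
  # D=1 construction giving Q = K = [1, 0]', V = [2, 4]'
  Xl <- matrix(c(1, 0), 2, 1)
  params <- list(Wq = matrix(1), Wk = matrix(1), Wv = matrix(-2), bv = 4)
  att <- selfAttentionHead(Xl, params)
  s <- exp(1) / (exp(1) + 1)  # softmax([1, 0])[1] = 0.731059
  expect_equal(att$weights[1, ], c(s, 1 - s), tolerance = 1e-10)
  expect_equal(att$output[1, 1], s * 2 + (1 - s) * 4, tolerance = 1e-10)
  expect_equal(att$output[1, 1], 2.53788, tolerance = 1e-5)
  expect_equal(rowSums(att$weights), c(1, 1), tolerance = 1e-12)

  # zero query/key projections: uniform attention averages the values
  set.seed(2)
  X2 <- matrix(rnorm(12), 4, 3)
  p0 <- list(Wq = matrix(0, 3, 3), Wk = matrix(0, 3, 3), Wv = diag(3))
  att0 <- selfAttentionHead(X2, p0)
  expect_equal(att0$output,
               matrix(colMeans(X2), 4, 3, byrow = TRUE), tolerance = 1e-12)

  # a single token attends only to itself
  att1 <- selfAttentionHead(X2[1, , drop = FALSE], p0)
  expect_equal(att1$output, X2[1, , drop = FALSE], tolerance = 1e-12)
})

test_that("encoded graphs are row-stochastic with a zero diagonal", {
  sim <- tinyCohort(m = 5, n = 5, t = 30)
  state <- initModel(30, smallEnc(), smallDec(), seed = 3)
  graphs <- encodeGraph(sim$cohort, state)
  expect_length(graphs, 5)
  for (g in graphs) {
    w <- ecWeights(g)
    expect_equal(dim(w), c(5L, 5L))
    expect_equal(rowSums(w), rep(1, 5), tolerance = 1e-6)
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0))
  }
})

test_that("the encoder is exactly equivariant under region relabeling", {
  sim <- tinyCohort(m = 2, n = 5, t = 30)
  state <- initModel(30, smallEnc(), smallDec(), seed = 4)
  g0 <- ecWeights(encodeGraph(sim$cohort, state)[[1]])

  perm <- c(3, 5, 1, 4, 2)
  d <- cohortArray(sim$cohort)[, perm, , drop = FALSE]
  gp <- ecWeights(encodeGraph(CohortTimeSeries(d), state)[[1]])
  expect_equal(gp, g0[perm, perm], tolerance = 1e-12)
})

test_that("encoding is deterministic for fixed parameters and input", {
  sim <- tinyCohort(m = 2, n = 4, t = 30)
  state <- initModel(30, smallEnc(), smallDec(), seed = 5)
  g1 <- lapply(encodeGraph(sim$cohort, state), ecWeights)
  g2 <- lapply(encodeGraph(sim$cohort, state), ecWeights)
  expect_identical(g1, g2)
})

test_that("decoding routes messages through the graph as specified", {
  dec <- decoderConfig(nHiddenLayers = 1L, lagWindow = 1L, hiddenWidth = 1L,
                       activation = "identity")
  state <- initModel(30, smallEnc(), dec, seed = 6)
  # identity single-layer map: W = [[1], [1]] chain, bias 0
  state@decoder[[1]]$W <- matrix(1); state@decoder[[1]]$b <- 0
  state@decoder[[2]]$W <- matrix(1); state@decoder[[2]]$b <- 0

  # G routes node 1 into node 2 only: prediction [0, 3] from window [3, 7]
  G <- matrix(c(0, 0, 1, 0), 2, 2)
  expect_equal(decodeNext(matrix(c(3, 7), 2, 1), G, state), c(0, 3))

  # all-zero graph and zero biases give the zero prediction
  expect_equal(decodeNext(matrix(c(3, 7), 2, 1), matrix(0, 2, 2), state),
               c(0, 0))
  expect_error(decodeNext(matrix(1, 2, 3), G, state), "K = 1")
})

test_that("decoder is linear in the window when the activation is identity", {
  dec <- smallDec(activation = "identity")
  state <- initModel(30, smallEnc(), dec, seed = 7)
  # zero biases so superposition is exact
  for (j in seq_along(state@decoder)) state@decoder[[j]]$b[] <- 0
  set.seed(7)
  G <- matrix(runif(16), 4, 4); diag(G) <- 0
  w1 <- matrix(rnorm(12), 4, 3)
  w2 <- matrix(rnorm(12), 4, 3)
  y1 <- decodeNext(w1, G, state)
  y2 <- decodeNext(w2, G, state)
  y12 <- decodeNext(2 * w1 + 3 * w2, G, state)
  expect_equal(y12, 2 * y1 + 3 * y2, tolerance = 1e-10)
})

test_that("teacher-forced reconstruction covers every valid timepoint", {
  sim <- tinyCohort(m = 3, n = 4, t = 30)
  dec <- smallDec()
  state <- initModel(30, smallEnc(), dec, seed = 8)
  graphs <- encodeGraph(sim$cohort, state)
  xhat <- reconstruct(sim$cohort, graphs, state)
  expect_equal(dim(xhat), c(3L, 4L, 30L - dec$lagWindow))
  expect_true(all(is.finite(xhat)))

  # boundary: t = K + 1 yields a single predicted slice
  K <- dec$lagWindow
  stateK <- initModel(K + 1L, smallEnc(), dec, seed = 8)
  co <- CohortTimeSeries(array(rnorm(2 * 4 * (K + 1)), c(2, 4, K + 1)))
  g2 <- encodeGraph(co, stateK)
  expect_equal(dim(reconstruct(co, g2, stateK))[3], 1L)

  # a 2-node copy chain with hand-set weights reproduces the lagged parent
  decI <- decoderConfig(nHiddenLayers = 1L, lagWindow = 1L, hiddenWidth = 1L,
                        activation = "identity")
  stateI <- initModel(30, smallEnc(), decI, seed = 9)
  stateI@decoder[[1]]$W <- matrix(1); stateI@decoder[[1]]$b <- 0
  stateI@decoder[[2]]$W <- matrix(1); stateI@decoder[[2]]$b <- 0
  x <- matrix(rnorm(2 * 30), 2, 30)
  co2 <- CohortTimeSeries(array(x, c(1, 2, 30)))
  G <- matrix(c(0, 0, 1, 0), 2, 2)  # 1 -> 2
  xh <- reconstruct(co2, list(G), stateI)
  expect_equal(xh[1, 2, ], x[1, 1:29], tolerance = 1e-12)
  expect_equal(xh[1, 1, ], rep(0, 29))
})
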