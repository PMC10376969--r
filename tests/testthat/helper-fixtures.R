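# Shared tiny fixtures: all data are generated in code at test time.

smallEnc <- function(...) encoderConfig(nLayers = 2L, nHeads = 2L,
                                        hiddenDim = 16L, ...)
smallDec <- function(...) decoderConfig(nHiddenLayers = 2L, lagWindow = 3L,
                                        hiddenWidth = 6L, ...)

tinyCohort <- function(m = 3L, n = 4L, t = 30L, seed = 11L, flip = 0) {
  g <- makeGraph(n, n, 0L, seed = seed)
  simulateCohort(g, m = m, t = t,
                 opts = simOptions(couplingStrength = 0.6, noiseSd = 0.5,
                                   subjectGraphFlipProb = flip),
                 seed = seed)
}

# independent oracle for arc classification: explicit enumeration of every
# unordered pair's state, if/else over the cases (no matrix arithmetic)
oracleArcCounts <- function(pred, truth) {
  n <- nrow(pred)
  ca <- ea <- ma <- ra <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p1 <- pred[i, j]; p2 <- pred[j, i]
      t1 <- truth[i, j]; t2 <- truth[j, i]
      matched <- p1 * t1 + p2 * t2
      ca <- ca + matched
      if (p1 + p2 == 1 && t1 + t2 == 1 && matched == 0) {
        ra <- ra + 1            # lone opposite arcs: a reversal
      } else {
        ea <- ea + (p1 + p2) - matched
        ma <- ma + (t1 + t2) - matched
      }
    }
  }
  list(ca = ca, ea = ea, ma = ma, ra = ra, ta = sum(pred),
       truthSize = sum(truth))
}

# all 2^6 binary 3-node digraphs (off-diagonal bit patterns)
allThreeNodeGraphs <- function() {
  off <- which(row(diag(3)) != col(diag(3)))
  lapply(0:63, function(bits) {
    a <- matrix(0, 3, 3)
    a[off] <- as.integer(intToBits(bits))[1:6]
    a
  })
}

randomBinaryGraph <- function(n, p = 0.3) {
  a <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(a) <- 0
  a
}
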