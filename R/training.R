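# Training engine: ELBO + sparsity objective, amortized cohort training,
# test-time adaptation, and graph binarization.
#
# Loss for a cohort:
#   sum_m sum_t (x - xhat)^2 / (2 * likelihoodSd^2)      (Gaussian NLL)
# + sum_m sum_rows KL(row || uniform off-diagonal prior)  (graph prior)
# + lambda * sum_m ||G_m||_1                              (sparsity)
# The KL uses natural log with probabilities clamped at 1e-12. Because the
# encoder rows are softmax-normalized, the L1 term is constant in value and
# gradient; it is kept for fidelity to the stated objective and because it
# becomes active for any unnormalized graph.

.klUniformRow <- function(g) {
  # g is the off-diagonal part of one row; the uniform prior puts mass
  # 1/(n-1) on each of its length(g) = n-1 entries
  p <- 1 / length(g)
  gc <- pmax(g, .EPS_PROB)
  # entries that are exactly 0 contribute 0 (limit of g * log g)
  sum(ifelse(g > 0, g * log(gc / p), 0))
}

# KL of a row-stochastic masked graph to the uniform-off-diagonal prior
.klGraph <- function(G) {
  n <- nrow(G)
  tot <- 0
  for (i in seq_len(n)) tot <- tot + .klUniformRow(G[i, -i])
  tot
}

# gradient of the KL wrt G entries (off-diagonal): log(g/p) + 1
.klGraphGrad <- function(G) {
  n <- nrow(G)
  p <- 1 / (n - 1)
  gc <- pmax(G, .EPS_PROB)
  d <- log(gc / p) + 1
  diag(d) <- 0
  d
}

#' ELBO training loss
#'
#' Reconstruction negative log-likelihood under a fixed-variance Gaussian
#' observation model plus the KL divergence of every graph row to a uniform
#' prior over its off-diagonal targets.
#'
#' @param X a [CohortTimeSeries-class] (or \code{m x n x t} array).
#' @param Xhat predicted array, \code{m x n x tp} with \code{tp <= t};
#'   compared against the last \code{tp} timepoints of \code{X}.
#' @param graphs list of [ECGraph-class] (or matrices), one per subject.
#' @param cfg a [trainingConfig()] list (uses \code{likelihoodSd}).
#' @return scalar loss.
#' @export
elboLoss <- function(X, Xhat, graphs, cfg = trainingConfig()) {
  d <- if (is(X, "CohortTimeSeries")) cohortArray(X) else as.array(X)
  tp <- dim(Xhat)[3L]
  t <- dim(d)[3L]
  if (tp > t) stop("prediction has more timepoints than the data")
  target <- d[, , (t - tp + 1L):t, drop = FALSE]
  recon <- sum((target - Xhat)^2) / (2 * cfg$likelihoodSd^2)
  kl <- sum(vapply(graphs, function(g) {
    w <- if (is(g, "ECGraph")) ecWeights(g) else as.matrix(g)
    .klGraph(w)
  }, numeric(1)))
  recon + kl
}

#' L1 sparsity penalty on graph weights
#'
#' @param graphs list of [ECGraph-class] (or matrices).
#' @param lambda penalty weight.
#' @return \code{lambda} times the sum of absolute weights over all graphs.
#' @export
sparsityPenalty <- function(graphs, lambda) {
  lambda * sum(vapply(graphs, function(g) {
    w <- if (is(g, "ECGraph")) ecWeights(g) else as.matrix(g)
    sum(abs(w))
  }, numeric(1)))
}

# loss + full gradients for one subject (n x t matrix)
.subjectLossGrads <- function(enc, dec, xs, encCfg, decCfg, cfg) {
  ef <- .encodeSubject(enc, xs, encCfg)
  df <- .decodeSubject(dec, xs, ef$G, decCfg)
  K <- decCfg$lagWindow
  t <- ncol(xs)
  target <- xs[, (K + 1L):t, drop = FALSE]
  resid <- df$Xhat - target
  recon <- sum(resid^2) / (2 * cfg$likelihoodSd^2)
  kl <- .klGraph(ef$G)
  l1 <- cfg$sparsityWeight * sum(abs(ef$G))
  loss <- recon + kl + l1

  dXhat <- resid / cfg$likelihoodSd^2
  db <- .decodeBackward(dec, decCfg, df$cache, dXhat)
  dG <- db$dG + .klGraphGrad(ef$G) + cfg$sparsityWeight * sign(ef$G)
  encGrads <- .encodeBackward(enc, encCfg, ef$cache, dG)
  list(loss = loss, recon = recon, kl = kl, l1 = l1,
       encGrads = encGrads, decGrads = db$grads, G = ef$G)
}

#' Train the amortized model on a cohort
#'
#' Minimizes the ELBO + sparsity objective with Adam. Each epoch processes
#' the subjects in groups of \code{cfg$amortizeM} per forward pass (a final
#' smaller group absorbs any remainder); gradients are accumulated within a
#' group and one optimizer step is taken per group. Fully deterministic for
#' a fixed \code{cfg$seed}.
#'
#' @param cohort a [CohortTimeSeries-class].
#' @param cfg a [trainingConfig()] list.
#' @param encCfg an [encoderConfig()] list.
#' @param decCfg a [decoderConfig()] list.
#' @return list with \code{state} (a trained [ModelState-class]) and
#'   \code{report} (a [TrainReport-class] holding the per-epoch loss trace
#'   and the final per-subject weighted graphs).
#' @examples
#' sim <- simulateCohort(makeGraph(4, 4, seed = 1), m = 2, t = 30,
#'                       opts = simOptions(subjectGraphFlipProb = 0), seed = 1)
#' fit <- trainAmortized(sim$cohort, trainingConfig(epochs = 3L, amortizeM = 2L),
#'                       encoderTestPreset(nLayers = 1L, hiddenDim = 16L),
#'                       decoderConfig(hiddenWidth = 8L))
#' lossTrace(fit$report)
#' @export
trainAmortized <- function(cohort, cfg = trainingConfig(),
                           encCfg = encoderConfig(), decCfg = decoderConfig()) {
  d <- cohortArray(cohort)
  m <- dim(d)[1L]; n <- dim(d)[2L]; t <- dim(d)[3L]
  if (m < 1L) stop("cohort must contain at least one subject")
  state <- initModel(t, encCfg, decCfg, seed = cfg$seed)
  enc <- state@encoder; dec <- state@decoder
  optE <- .adamInit(enc); optD <- .adamInit(dec)

  groups <- split(seq_len(m), ceiling(seq_len(m) / cfg$amortizeM))
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    epochLoss <- 0
    for (grp in groups) {
      gE <- .zeroLike(enc); gD <- .zeroLike(dec)
      for (s in grp) {
        xs <- matrix(d[s, , ], n, t)
        sl <- .subjectLossGrads(enc, dec, xs, encCfg, decCfg, cfg)
        gE <- .addGrads(gE, sl$encGrads)
        gD <- .addGrads(gD, sl$decGrads)
        epochLoss <- epochLoss + sl$loss
      }
      stE <- .adamStep(enc, gE, optE, cfg$lr); enc <- stE$params; optE <- stE$opt
      stD <- .adamStep(dec, gD, optD, cfg$lr); dec <- stD$params; optD <- stD$opt
    }
    if (!is.finite(epochLoss))
      stop("training diverged: non-finite loss at epoch ", epoch)
    trace[epoch] <- epochLoss
  }

  state@encoder <- enc; state@decoder <- dec
  graphs <- encodeGraph(cohort, state)
  report <- new("TrainReport", lossTrace = trace, graphs = graphs,
                seed = cfg$seed, config = cfg)
  list(state = state, report = report)
}

#' Adapt the amortized model to a single unseen subject
#'
#' Continues gradient descent for \code{cfg$adaptEpochs} epochs at
#' \code{cfg$adaptLr} on one subject's series (all parameters updated, fresh
#' optimizer moments), then returns that subject's weighted graph. The input
#' model state is never modified (copy-on-adapt).
#'
#' @param state a trained [ModelState-class].
#' @param Xnew \code{n x t} matrix for the new subject, with \code{t}
#'   matching the model.
#' @param cfg a [trainingConfig()] list.
#' @param returnState also return the adapted [ModelState-class].
#' @return an [ECGraph-class]; if \code{returnState}, a list
#'   \code{(graph, state)}.
#' @export
adaptSubject <- function(state, Xnew, cfg = trainingConfig(),
                         returnState = FALSE) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != state@timepoints)
    stop("subject has t = ", ncol(Xnew), " but the model expects t = ",
         state@timepoints)
  enc <- state@encoder; dec <- state@decoder
  encCfg <- state@encoderConfig; decCfg <- state@decoderConfig
  if (cfg$adaptEpochs > 0L) {
    optE <- .adamInit(enc); optD <- .adamInit(dec)
    for (epoch in seq_len(cfg$adaptEpochs)) {
      sl <- .subjectLossGrads(enc, dec, Xnew, encCfg, decCfg, cfg)
      if (!is.finite(sl$loss))
        stop("adaptation diverged: non-finite loss at epoch ", epoch)
      stE <- .adamStep(enc, sl$encGrads, optE, cfg$adaptLr)
      enc <- stE$params; optE <- stE$opt
      stD <- .adamStep(dec, sl$decGrads, optD, cfg$adaptLr)
      dec <- stD$params; optD <- stD$opt
    }
  }
  G <- .encodeSubject(enc, Xnew, encCfg)$G
  graph <- ECGraph(G, normalized = TRUE)
  if (returnState) {
    adapted <- state
    adapted@encoder <- enc; adapted@decoder <- dec
    list(graph = graph, state = adapted)
  } else graph
}

#' Binarize a weighted graph
#'
#' Retains arc \code{(i, j)} iff its weight strictly exceeds the threshold;
#' the diagonal is always absent.
#'
#' @param G an [ECGraph-class] or weight matrix.
#' @param tau threshold in (0, 1); default 0.3.
#' @return a [BinaryAdjacency-class].
#' @export
binarize <- function(G, tau = 0.3) {
  w <- if (is(G, "ECGraph")) ecWeights(G) else as.matrix(G)
  a <- (w > tau) * 1
  diag(a) <- 0
  BinaryAdjacency(a)
}
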