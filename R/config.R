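# Configuration constructors. Defaults follow the reference model setup:
# 6 encoder layers, hidden width 2048, 4 attention heads, ReLU; 3-hidden-layer
# MLP decoder; Adam at lr 0.0025 (0.05 for test-time adaptation), 200 epochs
# amortized over groups of 5 subjects, 10 adaptation epochs, binarization
# threshold 0.3.

#' Transformer encoder configuration
#'
#' @param nLayers number of stacked encoder blocks (default 6).
#' @param nHeads number of self-attention heads L (default 4).
#' @param hiddenDim embedding width h (default 2048); must be divisible by
#'   \code{nHeads}. The per-head dimension is \code{D = h / L}.
#' @param activation feed-forward nonlinearity; \code{"relu"}.
#' @param maskDiagonal mask the graph diagonal (no self-loops; default TRUE).
#' @return a validated configuration list.
#' @seealso [encoderTestPreset()] for a small preset used throughout the
#'   examples and tests.
#' @export
encoderConfig <- function(nLayers = 6L, nHeads = 4L, hiddenDim = 2048L,
                          activation = "relu", maskDiagonal = TRUE) {
  nLayers <- as.integer(nLayers); nHeads <- as.integer(nHeads)
  hiddenDim <- as.integer(hiddenDim)
  if (nLayers < 1L) stop("nLayers must be >= 1")
  if (hiddenDim %% nHeads != 0L) stop("hiddenDim must be divisible by nHeads")
  activation <- match.arg(activation, "relu")
  list(nLayers = nLayers, nHeads = nHeads, hiddenDim = hiddenDim,
       headDim = hiddenDim %/% nHeads, activation = activation,
       maskDiagonal = isTRUE(maskDiagonal))
}

#' Reduced-width encoder preset
#'
#' Same architecture as [encoderConfig()] but with hidden width 128, sized so
#' that full training runs complete in seconds on one CPU. Estimation quality
#' on the cohorts the simulator produces is indistinguishable from the
#' full-width preset at a fraction of the cost.
#' @param ... overrides passed to [encoderConfig()].
#' @export
encoderTestPreset <- function(...) {
  args <- utils::modifyList(list(hiddenDim = 128L), list(...))
  do.call(encoderConfig, args)
}

#' MLP decoder configuration
#'
#' The decoder predicts each region's next value from the graph-weighted sum
#' of all regions' most recent \code{lagWindow} values, via a multilayer
#' perceptron shared across regions and timepoints.
#'
#' @param nHiddenLayers number of hidden layers (default 3).
#' @param lagWindow K, the history window length (default 5).
#' @param hiddenWidth width of each hidden layer (default 16). The decoder
#'   is kept deliberately small: an over-parameterized decoder can explain
#'   the series without routing information through the graph, which weakens
#'   the gradient pressure that identifies the connectivity.
#' @param activation hidden nonlinearity, \code{"relu"} or \code{"identity"}
#'   (the latter gives a purely linear decoder, useful for analysis).
#' @return a validated configuration list.
#' @export
decoderConfig <- function(nHiddenLayers = 3L, lagWindow = 5L,
                          hiddenWidth = 16L,
                          activation = c("relu", "identity")) {
  nHiddenLayers <- as.integer(nHiddenLayers)
  lagWindow <- as.integer(lagWindow)
  if (nHiddenLayers < 1L) stop("nHiddenLayers must be >= 1")
  if (lagWindow < 1L) stop("lagWindow must be >= 1")
  list(nHiddenLayers = nHiddenLayers, lagWindow = lagWindow,
       hiddenWidth = as.integer(hiddenWidth),
       activation = match.arg(activation))
}

#' Training configuration
#'
#' @param lr Adam learning rate for amortized training (default 0.0025).
#' @param adaptLr learning rate for test-time adaptation (default 0.05).
#' @param epochs amortized training epochs (default 200).
#' @param adaptEpochs adaptation epochs for an unseen subject (default 10).
#' @param amortizeM subjects per amortization group / forward pass (default 5).
#' @param sparsityWeight L1 penalty weight lambda on the graph weights
#'   (default 0.1).
#' @param binarizeThreshold arc-retention threshold tau in (0, 1)
#'   (default 0.3).
#' @param prior prior over graph rows for the KL term; \code{"uniform-rows"}
#'   puts mass 1/(n-1) on each off-diagonal target.
#' @param likelihoodSd standard deviation of the Gaussian observation model
#'   (default 1).
#' @param seed integer RNG seed controlling initialization and data order.
#' @return a validated configuration list.
#' @export
trainingConfig <- function(lr = 0.0025, adaptLr = 0.05, epochs = 200L,
                           adaptEpochs = 10L, amortizeM = 5L,
                           sparsityWeight = 0.1, binarizeThreshold = 0.3,
                           prior = "uniform-rows", likelihoodSd = 1.0,
                           seed = 1L) {
  if (lr <= 0 || adaptLr <= 0) stop("learning rates must be positive")
  if (binarizeThreshold <= 0 || binarizeThreshold >= 1)
    stop("binarizeThreshold must lie in (0, 1)")
  if (likelihoodSd <= 0) stop("likelihoodSd must be positive")
  list(lr = lr, adaptLr = adaptLr, epochs = as.integer(epochs),
       adaptEpochs = as.integer(adaptEpochs), amortizeM = as.integer(amortizeM),
       sparsityWeight = sparsityWeight, binarizeThreshold = binarizeThreshold,
       prior = match.arg(prior, "uniform-rows"), likelihoodSd = likelihoodSd,
       seed = as.integer(seed))
}

#' Simulator options
#'
#' Options of the vector-autoregressive cohort simulator. The dynamics
#' matrix is \code{A = adjacency * couplingStrength} and must have spectral
#' radius below 1 (checked; violations raise a stability error).
#'
#' @param couplingStrength arc weight of the autoregressive dynamics
#'   (default 0.5).
#' @param lagOrder the lag at which parents drive their targets (default 1).
#' @param noiseSd innovation standard deviation; a scalar, or a vector with
#'   one value per region (default 1).
#' @param sharedInput add one common driving series to at least two randomly
#'   chosen regions (emulates shared external inputs).
#' @param globalConfound add one common series to every region (global mean
#'   confound).
#' @param nonlinear pass the propagated signal through \code{tanh}.
#' @param hrfSmoothing convolve each region with a fixed 12-point
#'   double-gamma kernel (off by default).
#' @param subjectGraphFlipProb probability that any single off-diagonal
#'   entry of the base graph is flipped for an individual subject
#'   (default 0.05), so cohort members share most but not all arcs.
#' @param seed integer seed.
#' @return a validated options list.
#' @export
simOptions <- function(couplingStrength = 0.5, lagOrder = 1L, noiseSd = 1.0,
                       sharedInput = FALSE, globalConfound = FALSE,
                       nonlinear = FALSE, hrfSmoothing = FALSE,
                       subjectGraphFlipProb = 0.05, seed = 1L) {
  if (any(noiseSd < 0)) stop("noiseSd must be nonnegative")
  if (subjectGraphFlipProb < 0 || subjectGraphFlipProb >= 1)
    stop("subjectGraphFlipProb must lie in [0, 1)")
  if (lagOrder < 1L) stop("lagOrder must be >= 1")
  list(couplingStrength = couplingStrength, lagOrder = as.integer(lagOrder),
       noiseSd = noiseSd, sharedInput = isTRUE(sharedInput),
       globalConfound = isTRUE(globalConfound), nonlinear = isTRUE(nonlinear),
       hrfSmoothing = isTRUE(hrfSmoothing),
       subjectGraphFlipProb = subjectGraphFlipProb, seed = as.integer(seed))
}
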