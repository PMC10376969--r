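# Amortized encoder-decoder model.
#
# Encoder: regions are the sequence tokens; each region's t-length series is
# linearly embedded to an h-vector, passed through nLayers standard
# transformer blocks (multi-head self-attention + feed-forward, each with a
# residual connection and layer normalization), and a pairwise graph head
# turns the token features into n x n outgoing-edge logits. The diagonal is
# masked to -Inf and a row-wise softmax yields a row-stochastic directed
# graph G: entry (i, j) is the estimated influence of region i on region j.
#
# The graph head uses two feed-forward layers that produce a "source" and a
# "target" vector per token; logit(i, j) = s_i . u_j / sqrt(d). Scoring
# pairs of tokens (rather than mapping each token to n fixed output units)
# makes the graph exactly equivariant under region reordering: there is no
# positional encoding over regions, so relabeling regions permutes the rows
# and columns of G identically.
#
# Decoder: Granger-style message passing. For target region j the incoming
# message at time s is sum_i G[i, j] * x_i[s]; the most recent K messages
# form the input to an MLP (shared across regions and timepoints) that
# predicts x_j at the next step.

#' Initialize an amortized encoder-decoder model
#'
#' Allocates all trainable encoder and decoder parameter arrays for time
#' series of length \code{t}. The model is region-count agnostic (the graph
#' head scores token pairs) but the time axis is embedded, so \code{t} is
#' fixed at construction.
#'
#' @param t time-series length the model will consume.
#' @param encCfg an [encoderConfig()] list.
#' @param decCfg a [decoderConfig()] list.
#' @param seed integer seed for the parameter initialization.
#' @return a [ModelState-class].
#' @examples
#' state <- initModel(50, encoderTestPreset(nLayers = 2L), decoderConfig())
#' state
#' @export
initModel <- function(t, encCfg = encoderConfig(), decCfg = decoderConfig(),
                      seed = 1L) {
  set.seed(seed)
  h <- encCfg$hiddenDim; L <- encCfg$nHeads; D <- encCfg$headDim
  dg <- D  # pairwise-head score dimension

  blocks <- vector("list", encCfg$nLayers)
  for (b in seq_len(encCfg$nLayers)) {
    heads <- vector("list", L)
    for (l in seq_len(L)) {
      heads[[l]] <- list(Wq = .initW(D, D), bq = numeric(D),
                         Wk = .initW(D, D), bk = numeric(D),
                         Wv = .initW(D, D), bv = numeric(D))
    }
    blocks[[b]] <- list(heads = heads,
                        ln1g = rep(1, h), ln1b = numeric(h),
                        W1 = .initW(h, h), b1 = numeric(h),
                        W2 = .initW(h, h), b2 = numeric(h),
                        ln2g = rep(1, h), ln2b = numeric(h))
  }
  encoder <- list(
    We = .initW(t, h), be = numeric(h),
    blocks = blocks,
    Wg1 = .initW(h, h), bg1 = numeric(h),
    Wg2 = .initW(h, 2L * dg), bg2 = numeric(2L * dg))

  widths <- c(decCfg$lagWindow, rep(decCfg$hiddenWidth, decCfg$nHiddenLayers), 1L)
  decoder <- vector("list", length(widths) - 1L)
  for (j in seq_along(decoder)) {
    decoder[[j]] <- list(W = .initW(widths[j], widths[j + 1L]),
                         b = numeric(widths[j + 1L]))
  }
  names(decoder) <- sprintf("layer%d", seq_along(decoder))

  new("ModelState", encoder = encoder, decoder = decoder,
      encoderConfig = encCfg, decoderConfig = decCfg,
      timepoints = as.integer(t), seed = as.integer(seed))
}

# ---- encoder forward -------------------------------------------------------

# one subject: X is n x t; returns G plus the full cache for backprop
.encodeSubject <- function(enc, X, cfg) {
  h <- cfg$hiddenDim; L <- cfg$nHeads; D <- cfg$headDim
  n <- nrow(X)
  Xp <- .addBias(X %*% enc$We, enc$be)
  cache <- list(X = X, embed = Xp, blocks = vector("list", cfg$nLayers))

  for (b in seq_len(cfg$nLayers)) {
    blk <- enc$blocks[[b]]
    bc <- list(input = Xp, heads = vector("list", L))
    MH <- matrix(0, n, h)
    for (l in seq_len(L)) {
      idx <- ((l - 1L) * D + 1L):(l * D)
      Xs <- Xp[, idx, drop = FALSE]
      hp <- blk$heads[[l]]
      Q <- .addBias(Xs %*% hp$Wq, hp$bq)
      K <- .addBias(Xs %*% hp$Wk, hp$bk)
      V <- .addBias(Xs %*% hp$Wv, hp$bv)
      S <- .rowSoftmax(Q %*% t(K) / sqrt(D))
      A <- S %*% V
      MH[, idx] <- A
      bc$heads[[l]] <- list(Xs = Xs, Q = Q, K = K, V = V, S = S)
    }
    r1 <- Xp + MH
    ln1 <- .layerNormForward(r1, blk$ln1g, blk$ln1b)
    pre <- .addBias(ln1$y %*% blk$W1, blk$b1)
    act <- .relu(pre)
    ff <- .addBias(act %*% blk$W2, blk$b2)
    r2 <- ln1$y + ff
    ln2 <- .layerNormForward(r2, blk$ln2g, blk$ln2b)
    bc$ln1 <- ln1; bc$pre <- pre; bc$act <- act; bc$ln2 <- ln2
    cache$blocks[[b]] <- bc
    Xp <- ln2$y
  }

  dgd <- D
  H1pre <- .addBias(Xp %*% enc$Wg1, enc$bg1)
  H1 <- .relu(H1pre)
  H2 <- .addBias(H1 %*% enc$Wg2, enc$bg2)
  Sv <- H2[, seq_len(dgd), drop = FALSE]
  Uv <- H2[, dgd + seq_len(dgd), drop = FALSE]
  logits <- Sv %*% t(Uv) / sqrt(dgd)
  mask <- if (cfg$maskDiagonal) diag(n) == 1 else NULL
  G <- .rowSoftmax(logits, mask)
  cache$tokens <- Xp; cache$H1pre <- H1pre; cache$H1 <- H1
  cache$Sv <- Sv; cache$Uv <- Uv; cache$G <- G; cache$mask <- mask
  list(G = G, cache = cache)
}

# backward: dG (n x n) -> gradients for every encoder parameter
.encodeBackward <- function(enc, cfg, cache, dG) {
  h <- cfg$hiddenDim; L <- cfg$nHeads; D <- cfg$headDim
  dgd <- D
  g <- .zeroLike(enc)

  dLogits <- .softmaxBackward(cache$G, dG)
  dSv <- dLogits %*% cache$Uv / sqrt(dgd)
  dUv <- t(dLogits) %*% cache$Sv / sqrt(dgd)
  dH2 <- cbind(dSv, dUv)
  g$Wg2 <- t(cache$H1) %*% dH2
  g$bg2 <- colSums(dH2)
  dH1 <- dH2 %*% t(enc$Wg2)
  dH1[cache$H1pre <= 0] <- 0
  g$Wg1 <- t(cache$tokens) %*% dH1
  g$bg1 <- colSums(dH1)
  dXp <- dH1 %*% t(enc$Wg1)

  for (b in rev(seq_len(cfg$nLayers))) {
    blk <- enc$blocks[[b]]
    bc <- cache$blocks[[b]]
    gb <- g$blocks[[b]]

    l2 <- .layerNormBackward(dXp, bc$ln2)
    gb$ln2g <- l2$dg; gb$ln2b <- l2$db
    dr2 <- l2$dx
    # r2 = ln1$y + ff
    dff <- dr2
    gb$W2 <- t(bc$act) %*% dff
    gb$b2 <- colSums(dff)
    dact <- dff %*% t(blk$W2)
    dact[bc$pre <= 0] <- 0
    gb$W1 <- t(bc$ln1$y) %*% dact
    gb$b1 <- colSums(dact)
    dln1y <- dr2 + dact %*% t(blk$W1)

    l1 <- .layerNormBackward(dln1y, bc$ln1)
    gb$ln1g <- l1$dg; gb$ln1b <- l1$db
    dr1 <- l1$dx
    # r1 = input + MH
    dIn <- dr1
    for (l in seq_len(L)) {
      idx <- ((l - 1L) * D + 1L):(l * D)
      hc <- bc$heads[[l]]
      hp <- blk$heads[[l]]
      dA <- dr1[, idx, drop = FALSE]
      dV <- t(hc$S) %*% dA
      dS <- dA %*% t(hc$V)
      dZ <- .softmaxBackward(hc$S, dS)
      dQ <- dZ %*% hc$K / sqrt(D)
      dK <- t(dZ) %*% hc$Q / sqrt(D)
      gh <- gb$heads[[l]]
      gh$Wq <- t(hc$Xs) %*% dQ; gh$bq <- colSums(dQ)
      gh$Wk <- t(hc$Xs) %*% dK; gh$bk <- colSums(dK)
      gh$Wv <- t(hc$Xs) %*% dV; gh$bv <- colSums(dV)
      gb$heads[[l]] <- gh
      dXs <- dQ %*% t(hp$Wq) + dK %*% t(hp$Wk) + dV %*% t(hp$Wv)
      dIn[, idx] <- dIn[, idx] + dXs
    }
    g$blocks[[b]] <- gb
    dXp <- dIn
  }

  g$We <- t(cache$X) %*% dXp
  g$be <- colSums(dXp)
  g
}

# ---- decoder forward -------------------------------------------------------

.decActivate <- function(x, activation) {
  if (activation == "relu") .relu(x) else x
}

# X n x t, G n x n. Predicts columns (K+1)..t; returns n x (t-K) plus cache.
.decodeSubject <- function(dec, X, G, decCfg) {
  K <- decCfg$lagWindow
  n <- nrow(X); t <- ncol(X)
  if (t <= K) stop("time series must be longer than the lag window K")
  M <- t(G) %*% X                    # incoming messages, n x t
  nw <- t - K
  B <- matrix(0, n * nw, K)          # row (s-1)*n + j : window for region j
  for (k in seq_len(K)) B[, k] <- as.vector(M[, k:(k + nw - 1L), drop = FALSE])

  Hs <- vector("list", length(dec))
  Pre <- vector("list", length(dec))
  Hin <- B
  for (j in seq_along(dec)) {
    pre <- .addBias(Hin %*% dec[[j]]$W, dec[[j]]$b)
    Pre[[j]] <- pre
    Hin <- if (j < length(dec)) .decActivate(pre, decCfg$activation) else pre
    Hs[[j]] <- Hin
  }
  Xhat <- matrix(Hs[[length(dec)]], n, nw)
  list(Xhat = Xhat,
       cache = list(X = X, G = G, M = M, B = B, Hs = Hs, Pre = Pre, nw = nw))
}

# backward from dXhat: returns decoder grads and dG
.decodeBackward <- function(dec, decCfg, cache, dXhat) {
  K <- decCfg$lagWindow
  n <- nrow(cache$X); nw <- cache$nw
  g <- .zeroLike(dec)
  dH <- matrix(as.vector(dXhat), n * nw, 1L)
  for (j in rev(seq_along(dec))) {
    if (j < length(dec)) {
      if (decCfg$activation == "relu") dH[cache$Pre[[j]] <= 0] <- 0
    }
    Hin <- if (j == 1L) cache$B else cache$Hs[[j - 1L]]
    g[[j]]$W <- t(Hin) %*% dH
    g[[j]]$b <- colSums(dH)
    dH <- dH %*% t(dec[[j]]$W)
  }
  dB <- dH                             # n*nw x K
  dM <- matrix(0, n, ncol(cache$X))
  for (k in seq_len(K)) {
    dM[, k:(k + nw - 1L)] <- dM[, k:(k + nw - 1L)] + matrix(dB[, k], n, nw)
  }
  dG <- cache$X %*% t(dM)
  list(grads = g, dG = dG)
}

# ---- exported operations ---------------------------------------------------

#' Embed region time series
#'
#' Applies the model's linear time-axis embedding: each region's t-length
#' series becomes an h-vector; the subject and region axes are untouched.
#'
#' @param X a [CohortTimeSeries-class] with \code{t} matching the model.
#' @param state a [ModelState-class].
#' @return an \code{m x n x h} array.
#' @export
embedRegions <- function(X, state) {
  d <- cohortArray(X)
  if (dim(d)[3L] != state@timepoints)
    stop("cohort has t = ", dim(d)[3L], " but the model embedding expects t = ",
         state@timepoints)
  h <- state@encoderConfig$hiddenDim
  out <- array(0, c(dim(d)[1L], dim(d)[2L], h))
  for (s in seq_len(dim(d)[1L])) {
    xs <- matrix(d[s, , ], dim(d)[2L], dim(d)[3L])
    out[s, , ] <- .addBias(xs %*% state@encoder$We, state@encoder$be)
  }
  out
}

#' Scaled dot-product self-attention for one head
#'
#' Computes \code{Attention = rowsoftmax(Q K' / sqrt(D)) V} where Q, K, V are
#' affine transformations of the head's input slice. Attention-weight rows
#' sum to one.
#'
#' @param Xl \code{n x D} input slice for this head (tokens are regions).
#' @param params list with projection matrices \code{Wq}, \code{Wk},
#'   \code{Wv} (each \code{D x D}) and optional bias vectors \code{bq},
#'   \code{bk}, \code{bv}.
#' @return list with \code{output} (\code{n x D}) and \code{weights}
#'   (\code{n x n} attention matrix).
#' @export
selfAttentionHead <- function(Xl, params) {
  Xl <- as.matrix(Xl)
  D <- ncol(Xl)
  zb <- numeric(D)
  Q <- .addBias(Xl %*% params$Wq, if (is.null(params$bq)) zb else params$bq)
  K <- .addBias(Xl %*% params$Wk, if (is.null(params$bk)) zb else params$bk)
  V <- .addBias(Xl %*% params$Wv, if (is.null(params$bv)) zb else params$bv)
  logits <- Q %*% t(K) / sqrt(D)
  if (!all(is.finite(logits))) stop("non-finite attention logits")
  S <- .rowSoftmax(logits)
  list(output = S %*% V, weights = S)
}

#' Encode a cohort into per-subject effective-connectivity graphs
#'
#' Full encoder forward pass: embedding, \code{nLayers} transformer blocks,
#' pairwise graph head, diagonal mask and row-wise softmax. Each returned
#' graph is row-stochastic with a zero diagonal.
#'
#' @param X a [CohortTimeSeries-class].
#' @param state a [ModelState-class].
#' @return list of \code{m} [ECGraph-class] objects.
#' @export
encodeGraph <- function(X, state) {
  d <- cohortArray(X)
  if (dim(d)[3L] != state@timepoints)
    stop("cohort has t = ", dim(d)[3L], " but the model expects t = ",
         state@timepoints)
  lapply(seq_len(dim(d)[1L]), function(s) {
    xs <- matrix(d[s, , ], dim(d)[2L], dim(d)[3L])
    ECGraph(.encodeSubject(state@encoder, xs, state@encoderConfig)$G,
            normalized = TRUE)
  })
}

#' Predict the next time step from a history window
#'
#' Message passing \code{t(G) \%*\% Xwindow} gives each target region K
#' incoming weighted sums; the decoder MLP maps that K-vector to the region's
#' next value.
#'
#' @param Xwindow \code{n x K} matrix of the most recent K timepoints.
#' @param G an [ECGraph-class] or plain weight matrix.
#' @param state a [ModelState-class].
#' @return length-\code{n} numeric prediction.
#' @export
decodeNext <- function(Xwindow, G, state) {
  Xwindow <- as.matrix(Xwindow)
  K <- state@decoderConfig$lagWindow
  if (ncol(Xwindow) != K)
    stop("window has ", ncol(Xwindow), " columns but the decoder expects K = ", K)
  w <- if (is(G, "ECGraph")) ecWeights(G) else as.matrix(G)
  B <- t(w) %*% Xwindow                 # n x K messages
  H <- B
  dec <- state@decoder
  for (j in seq_along(dec)) {
    H <- .addBias(H %*% dec[[j]]$W, dec[[j]]$b)
    if (j < length(dec)) H <- .decActivate(H, state@decoderConfig$activation)
  }
  as.numeric(H)
}

#' Teacher-forced one-step-ahead reconstruction
#'
#' For every subject and every valid timepoint, predicts the next value of
#' each region from the preceding K observed values under that subject's
#' graph.
#'
#' @param X a [CohortTimeSeries-class].
#' @param graphs list of \code{m} [ECGraph-class] objects (one per subject).
#' @param state a [ModelState-class].
#' @return an \code{m x n x (t - K)} array of predictions for timepoints
#'   \code{K+1, ..., t}.
#' @export
reconstruct <- function(X, graphs, state) {
  d <- cohortArray(X)
  m <- dim(d)[1L]; n <- dim(d)[2L]; t <- dim(d)[3L]
  K <- state@decoderConfig$lagWindow
  if (t <= K) stop("time series must be longer than the lag window K")
  if (length(graphs) != m) stop("need one graph per subject")
  out <- array(0, c(m, n, t - K))
  for (s in seq_len(m)) {
    xs <- matrix(d[s, , ], n, t)
    w <- if (is(graphs[[s]], "ECGraph")) ecWeights(graphs[[s]]) else as.matrix(graphs[[s]])
    out[s, , ] <- .decodeSubject(state@decoder, xs, w, state@decoderConfig)$Xhat
  }
  out
}
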