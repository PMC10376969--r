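# Internal numeric primitives shared by the encoder, decoder and optimizer.
# All operate on plain base-R matrices; parameters live in nested named lists
# whose leaves are numeric matrices/vectors.

.EPS_PROB <- 1e-12   # clamp for log-probabilities in the KL term
.EPS_LN   <- 1e-5    # layer-norm variance floor

# Row-wise softmax. Entries where `mask` is TRUE are forced to probability 0
# (logit -Inf). Rows that are entirely masked are disallowed upstream.
.rowSoftmax <- function(z, mask = NULL) {
  if (!is.null(mask)) z[mask] <- -Inf
  mx <- apply(z, 1L, max)
  e <- exp(z - mx)
  e[!is.finite(e)] <- 0
  e / rowSums(e)
}

# Backward through a row-wise softmax: given probabilities `p` and upstream
# gradient `dp`, returns gradient w.r.t. the logits. Masked entries have p=0
# and therefore receive zero gradient automatically.
.softmaxBackward <- function(p, dp) {
  s <- rowSums(dp * p)
  p * (dp - s)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.addBias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

# Layer normalization over the feature (column) axis, per row, with gain g
# and shift b. Returns output plus the cache needed by the backward pass.
.layerNormForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .EPS_LN)
  xhat <- xc * inv
  y <- .addBias(sweep(xhat, 2L, g, "*"), b)
  list(y = y, xhat = xhat, inv = inv, g = g)
}

.layerNormBackward <- function(dy, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2L, cache$g, "*")
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  dx <- cache$inv * (dxh - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# ---- nested parameter-list algebra ----------------------------------------

.mapLeaves <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) .mapLeaves(f, el)) else f(a)
}

.map2Leaves <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .map2Leaves(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

.zeroLike <- function(a) .mapLeaves(function(x) x * 0, a)

.addGrads <- function(a, b) .map2Leaves(`+`, a, b)

.flattenLeaves <- function(a) {
  if (is.list(a)) unlist(lapply(a, .flattenLeaves), use.names = FALSE)
  else as.numeric(a)
}

# ---- Adam optimizer over nested lists -------------------------------------

.adamInit <- function(params) list(m = .zeroLike(params), v = .zeroLike(params), step = 0L)

.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$step <- opt$step + 1L
  opt$m <- .map2Leaves(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- .map2Leaves(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  c1 <- 1 - beta1^opt$step
  c2 <- 1 - beta2^opt$step
  upd <- .map2Leaves(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps), opt$m, opt$v)
  params <- .map2Leaves(`-`, params, upd)
  list(params = params, opt = opt)
}

# Glorot-style normal initialization for a fan_in x fan_out weight matrix.
.initW <- function(fin, fout, scale = 1) {
  matrix(stats::rnorm(fin * fout, sd = scale * sqrt(2 / (fin + fout))), fin, fout)
}

.spectralRadius <- function(a) {
  if (all(a == 0)) return(0)
  max(Mod(eigen(a, only.values = TRUE)$values))
}

.isWeaklyConnected <- function(adj) {
  n <- nrow(adj)
  if (n == 1L) return(TRUE)
  und <- (adj + t(adj)) > 0
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(und[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}
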