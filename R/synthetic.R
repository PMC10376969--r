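# Synthetic cohort simulator: ground-truth digraphs plus fMRI-like
# multi-subject time series with the statistical structure of the standard
# network-recovery benchmark regimes (5-18 nodes, 5-10 arcs, 200-500
# timepoints, 50-60 subjects, optional nonlinearity, shared exogenous
# inputs, global mean confound, bidirectional arcs).

# amplitude of the shared-input and global-confound series relative to
# unit-variance white noise
.CONFOUND_SCALE <- 0.5
.BURN_IN <- 100L

#' Generate a ground-truth directed graph
#'
#' Draws a random digraph with exactly \code{nArcs} arcs of which exactly
#' \code{nBidirectional} pairs are mutually reversed (both \code{i -> j} and
#' \code{j -> i}). When \code{nArcs >= nNodes - 1} the graph is guaranteed
#' weakly connected (rejection sampling).
#'
#' @param nNodes number of nodes.
#' @param nArcs total number of directed arcs; a bidirectional pair counts
#'   as two arcs.
#' @param nBidirectional number of mutually-reversed pairs (default 0).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [GroundTruthGraph-class].
#' @examples
#' g <- makeGraph(5, 5, seed = 1)
#' arcList(g)
#' @export
makeGraph <- function(nNodes, nArcs, nBidirectional = 0L, seed = 1L) {
  nNodes <- as.integer(nNodes); nArcs <- as.integer(nArcs)
  nBidirectional <- as.integer(nBidirectional)
  if (nNodes < 2L) stop("need at least 2 nodes")
  nPairs <- (nNodes * (nNodes - 1L)) %/% 2L
  if (nArcs > nNodes * (nNodes - 1L)) stop("nArcs exceeds the number of ordered pairs")
  if (2L * nBidirectional > nArcs) stop("nBidirectional * 2 exceeds nArcs")
  nSingle <- nArcs - 2L * nBidirectional
  if (nBidirectional + nSingle > nPairs)
    stop("infeasible arc counts: ", nArcs, " arcs with ", nBidirectional,
         " bidirectional pairs do not fit on ", nNodes, " nodes")
  needConnected <- nArcs >= nNodes - 1L
  pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)

  set.seed(seed)
  for (attempt in seq_len(1000L)) {
    sel <- sample.int(nrow(pairs), nBidirectional + nSingle)
    adj <- matrix(0, nNodes, nNodes)
    bidir <- sel[seq_len(nBidirectional)]
    for (k in bidir) {
      adj[pairs[k, 1L], pairs[k, 2L]] <- 1
      adj[pairs[k, 2L], pairs[k, 1L]] <- 1
    }
    single <- sel[-seq_len(nBidirectional)]
    if (nBidirectional == 0L) single <- sel
    for (k in single) {
      if (stats::runif(1) < 0.5)
        adj[pairs[k, 1L], pairs[k, 2L]] <- 1
      else
        adj[pairs[k, 2L], pairs[k, 1L]] <- 1
    }
    if (!needConnected || .isWeaklyConnected(adj))
      return(GroundTruthGraph(adj))
  }
  stop("failed to draw a weakly connected graph with the requested counts")
}

.doubleGammaKernel <- function(len = 12L) {
  s <- seq_len(len) - 1L
  k <- stats::dgamma(s, shape = 6, rate = 1) -
    0.35 * stats::dgamma(s, shape = 12, rate = 1)
  k / sum(k)
}

# expand a scalar-or-vector noise sd to one value per region
.noiseSdVec <- function(noiseSd, n) {
  if (length(noiseSd) == 1L) rep(noiseSd, n)
  else if (length(noiseSd) == n) noiseSd
  else stop("noiseSd must be a scalar or have one value per region")
}

#' Simulate one subject's region time series
#'
#' Runs a lag-\code{p} autoregression on the graph: with
#' \code{A = adjacency * couplingStrength},
#' \code{x_t = sigma(t(A) \%*\% x_{t-p}) + inputs + confound + noise}, where
#' \code{sigma} is \code{tanh} when \code{opts$nonlinear} and identity
#' otherwise. A burn-in of 100 steps is discarded so the returned
#' \code{t} points are free of initial-condition transients. Optionally each
#' region is convolved with a fixed double-gamma haemodynamic-shaped kernel.
#'
#' @param graph a [GroundTruthGraph-class].
#' @param t number of timepoints to return.
#' @param opts a [simOptions()] list.
#' @param seed integer seed; output is bitwise reproducible given the seed.
#' @return an \code{n x t} numeric matrix.
#' @export
simulateSubject <- function(graph, t, opts = simOptions(), seed = opts$seed) {
  adj <- adjacencyMatrix(graph)
  n <- nrow(adj)
  a <- adj * opts$couplingStrength
  if (.spectralRadius(a) >= 1)
    stop("unstable dynamics: spectral radius of the coupling matrix is >= 1")
  p <- opts$lagOrder
  if (t < p + 2L) stop("t must be at least lagOrder + 2")
  total <- t + .BURN_IN + p
  sdv <- .noiseSdVec(opts$noiseSd, n)

  set.seed(seed)
  noise <- matrix(stats::rnorm(n * total), n, total) * sdv
  shared <- if (opts$sharedInput) stats::rnorm(total) else NULL
  sharedNodes <- if (opts$sharedInput) sort(sample.int(n, max(2L, n %/% 2L))) else integer()
  confound <- if (opts$globalConfound) stats::rnorm(total) else NULL

  at <- t(a)
  x <- matrix(0, n, total)
  for (s in (p + 1L):total) {
    drive <- at %*% x[, s - p]
    if (opts$nonlinear) drive <- tanh(drive)
    v <- drive + noise[, s]
    if (!is.null(shared)) v[sharedNodes] <- v[sharedNodes] + .CONFOUND_SCALE * shared[s]
    if (!is.null(confound)) v <- v + .CONFOUND_SCALE * confound[s]
    x[, s] <- v
  }
  if (opts$hrfSmoothing) {
    k <- .doubleGammaKernel()
    x <- t(apply(x, 1L, function(row) {
      stats::convolve(row, rev(k), type = "open")[seq_along(row)]
    }))
  }
  out <- x[, (total - t + 1L):total, drop = FALSE]
  rownames(out) <- sprintf("R%d", seq_len(n))
  out
}

# flip off-diagonal entries of the base adjacency independently, rejecting
# draws whose dynamics would be unstable
.flipGraph <- function(adj, flipProb, coupling, maxTries = 100L) {
  n <- nrow(adj)
  off <- which(row(adj) != col(adj))
  for (k in seq_len(maxTries)) {
    a2 <- adj
    flips <- off[stats::runif(length(off)) < flipProb]
    a2[flips] <- 1 - a2[flips]
    if (.spectralRadius(a2 * coupling) < 1) return(a2)
  }
  stop("could not draw a stable subject graph after ", maxTries, " attempts")
}

#' Simulate a multi-subject cohort
#'
#' Each subject uses an individual ground-truth graph obtained by flipping
#' every off-diagonal entry of the base adjacency independently with
#' probability \code{opts$subjectGraphFlipProb} (re-checked for dynamical
#' stability), so subjects share most but not all arcs.
#'
#' @param graph base [GroundTruthGraph-class].
#' @param m number of subjects.
#' @param t timepoints per subject.
#' @param opts a [simOptions()] list.
#' @param seed integer seed.
#' @return a list with elements \code{cohort} (a [CohortTimeSeries-class])
#'   and \code{truths} (list of \code{m} [GroundTruthGraph-class] objects).
#' @examples
#' sim <- simulateCohort(makeGraph(5, 5, seed = 1), m = 3, t = 50,
#'                       opts = simOptions(subjectGraphFlipProb = 0), seed = 1)
#' nSubjects(sim$cohort)
#' @export
simulateCohort <- function(graph, m, t, opts = simOptions(), seed = opts$seed) {
  if (m < 1L) stop("m must be >= 1")
  adj <- adjacencyMatrix(graph)
  if (.spectralRadius(adj * opts$couplingStrength) >= 1)
    stop("unstable dynamics: spectral radius of the coupling matrix is >= 1")
  set.seed(seed)
  truths <- vector("list", m)
  subjSeeds <- sample.int(.Machine$integer.max - 1L, m)
  data <- NULL
  for (s in seq_len(m)) {
    a2 <- if (opts$subjectGraphFlipProb > 0)
      .flipGraph(adj, opts$subjectGraphFlipProb, opts$couplingStrength)
    else adj
    truths[[s]] <- GroundTruthGraph(a2)
    xs <- simulateSubject(truths[[s]], t, opts, seed = subjSeeds[s])
    if (is.null(data)) data <- array(0, c(m, nrow(xs), ncol(xs)))
    data[s, , ] <- xs
  }
  list(cohort = CohortTimeSeries(data), truths = truths)
}

#' Z-score a cohort per subject and region
#'
#' Centers and scales every region's series to zero mean and unit (sample)
#' standard deviation, subject by subject. Constant series raise an error
#' naming the subject and region.
#'
#' @param x a [CohortTimeSeries-class].
#' @return a [CohortTimeSeries-class] of the same shape.
#' @export
zscoreCohort <- function(x) {
  d <- cohortArray(x)
  for (s in seq_len(dim(d)[1L])) {
    for (r in seq_len(dim(d)[2L])) {
      v <- d[s, r, ]
      sv <- stats::sd(v)
      if (!is.finite(sv) || sv < 1e-12)
        stop(sprintf("degenerate (constant) series for subject %s, region %s",
                     subjectIds(x)[s], regionLabels(x)[r]))
      d[s, r, ] <- (v - mean(v)) / sv
    }
  }
  CohortTimeSeries(d, subjectIds(x), regionLabels(x))
}
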