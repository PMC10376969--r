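# Functional-connectivity estimation and FC-guided refinement of the
# effective-connectivity graph (the second phase of the estimation
# procedure): the Pearson correlation matrix W acts as the query-key pair of
# an attention step and the learned EC graph as the value, so the refined
# graph is G' = G %*% rowsoftmax(W).

#' Pearson functional connectivity of one subject
#'
#' Entry \code{(i, j)} is \code{cov(x_i, x_j) / (sd_i * sd_j)}; the same
#' normalization is used for covariance and standard deviation, so the
#' sample/population distinction cancels. Symmetric with unit diagonal.
#'
#' @param X \code{n x t} matrix of region time series.
#' @return an [FCMatrix-class].
#' @examples
#' fcValues(pearsonFC(rbind(1:4, c(1, 3, 2, 4))))
#' @export
pearsonFC <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 1L, stats::sd)
  bad <- which(!is.finite(sds) | sds < 1e-12)
  if (length(bad)) {
    lbl <- if (!is.null(rownames(X))) rownames(X)[bad[1L]] else as.character(bad[1L])
    stop("degenerate (zero-variance) series for region ", lbl)
  }
  W <- stats::cor(t(X))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  FCMatrix(W)
}

#' Refine an EC graph with FC guidance
#'
#' Normalizes each row of the correlation matrix with a softmax and combines
#' it with the weighted EC graph. In the default \code{"matmul"} mode
#' \code{G' = G \%*\% rowsoftmax(W)} (a product of row-stochastic matrices,
#' so a row-stochastic G stays row-stochastic); in \code{"hadamard"} mode
#' \code{G' = G * rowsoftmax(W)} elementwise.
#'
#' @param G an [ECGraph-class] or weight matrix.
#' @param W an [FCMatrix-class] or correlation matrix.
#' @param mode \code{"matmul"} (default) or \code{"hadamard"}.
#' @return an [ECGraph-class].
#' @export
guideEC <- function(G, W, mode = c("matmul", "hadamard")) {
  mode <- match.arg(mode)
  g <- if (is(G, "ECGraph")) ecWeights(G) else as.matrix(G)
  w <- if (is(W, "FCMatrix")) fcValues(W) else as.matrix(W)
  if (!identical(dim(g), dim(w)))
    stop("EC graph and FC matrix dimensions do not match")
  S <- .rowSoftmax(w)
  if (mode == "matmul") {
    out <- g %*% S
    norm <- is(G, "ECGraph") && G@normalized
  } else {
    out <- g * S
    norm <- FALSE
  }
  ECGraph(out, normalized = norm)
}

#' Undirected skeleton from a correlation matrix
#'
#' Diagnostic helper: edge \code{{i, j}} is present iff
#' \code{|w_ij| > tauFc}.
#'
#' @param W an [FCMatrix-class] or correlation matrix.
#' @param tauFc threshold in \code{[0, 1)}.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @export
fcSkeleton <- function(W, tauFc) {
  if (tauFc < 0 || tauFc >= 1) stop("tauFc must lie in [0, 1)")
  w <- if (is(W, "FCMatrix")) fcValues(W) else as.matrix(W)
  sk <- (abs(w) > tauFc) * 1
  diag(sk) <- 0
  sk
}
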