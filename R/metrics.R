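# Graph-recovery evaluation: arc classification against the ground truth
# and precision / recall / F1 / structural Hamming distance, with
# cohort-level mean +/- sd aggregation.

#' Classify predicted arcs against the ground truth
#'
#' Arcs are matched within each unordered node pair. A predicted arc
#' \code{(i, j)} is correct (CA) when the truth has \code{(i, j)}. It is
#' reversed (RA) when the pair carries exactly one predicted and exactly one
#' truth arc and they point in opposite directions -- a reversal is counted
#' once, never additionally as an extra or missing arc. Remaining unmatched
#' predicted arcs are extra (EA) and remaining unmatched truth arcs are
#' missing (MA). Bidirectional pairs count as two arcs throughout, so a
#' bidirectional prediction over a single truth arc is one CA plus one EA.
#' This matching makes SHD = EA + MA + RA a true edit distance, symmetric in
#' its arguments (EA and MA swap, RA is invariant).
#'
#' @param pred,truth [BinaryAdjacency-class] objects or 0/1 matrices of
#'   matching size.
#' @return an [ArcCounts-class].
#' @examples
#' truth <- matrix(0, 3, 3); truth[1, 2] <- truth[2, 3] <- 1
#' pred <- matrix(0, 3, 3); pred[2, 1] <- pred[2, 3] <- pred[1, 3] <- 1
#' classifyArcs(pred, truth)
#' @export
classifyArcs <- function(pred, truth) {
  p <- .asBinaryMatrix(pred, "predicted")
  g <- .asBinaryMatrix(truth, "truth")
  if (!identical(dim(p), dim(g)))
    stop("predicted and truth graphs must have the same size")
  ca <- sum(p == 1 & g == 1)
  # reversal: the pair holds a single predicted and a single truth arc,
  # pointing in opposite directions
  ra <- sum(p == 1 & t(p) == 0 & g == 0 & t(g) == 1)
  ta <- sum(p)
  ea <- ta - ca - ra
  ma <- sum(g) - ca - ra
  ArcCounts(ca = ca, ea = ea, ma = ma, ra = ra, ta = ta, truthSize = sum(g))
}

#' Compute graph-recovery metrics from arc counts
#'
#' Precision = CA/TA (0 when TA = 0), Recall = CA/|G|, F1 their harmonic
#' mean (0 when both are 0), SHD = EA + MA + RA.
#'
#' @param counts an [ArcCounts-class].
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(counts) {
  if (counts@truthSize == 0L)
    stop("metrics are undefined for an empty ground-truth graph")
  precision <- if (counts@ta == 0L) 0 else counts@ca / counts@ta
  recall <- counts@ca / counts@truthSize
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  new("MetricsReport", precision = precision, recall = recall, f1 = f1,
      shd = counts@ea + counts@ma + counts@ra, counts = counts)
}

#' Evaluate a cohort of predicted graphs
#'
#' Computes a per-subject [MetricsReport-class] and the cohort mean and
#' population standard deviation of each metric.
#'
#' @param preds,truths equal-length lists of binary graphs.
#' @return list with \code{perSubject} (list of [MetricsReport-class]) and
#'   \code{summary} (data.frame with columns metric, mean, sd).
#' @export
evaluateCohort <- function(preds, truths) {
  if (length(preds) != length(truths))
    stop("preds and truths must have the same length")
  reports <- mapply(function(p, g) computeMetrics(classifyArcs(p, g)),
                    preds, truths, SIMPLIFY = FALSE)
  vals <- vapply(reports, function(r)
    c(precision = r@precision, recall = r@recall, f1 = r@f1,
      shd = as.numeric(r@shd)), numeric(4))
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  summary <- data.frame(
    metric = rownames(vals),
    mean = apply(vals, 1L, mean),
    sd = apply(vals, 1L, popSd),
    row.names = NULL)
  list(perSubject = reports, summary = summary)
}

#' Consensus graph by edge frequency
#'
#' Keeps an arc iff it appears in at least
#' \code{ceiling(minFraction * length(graphs))} of the subject graphs.
#'
#' @param graphs nonempty list of binary graphs.
#' @param minFraction fraction in \code{(0, 1]}.
#' @return a [BinaryAdjacency-class].
#' @export
edgeFrequency <- function(graphs, minFraction) {
  if (!length(graphs)) stop("graphs list must be nonempty")
  if (minFraction <= 0 || minFraction > 1)
    stop("minFraction must lie in (0, 1]")
  mats <- lapply(graphs, .asBinaryMatrix)
  counts <- Reduce(`+`, mats)
  need <- ceiling(minFraction * length(mats))
  BinaryAdjacency((counts >= need) * 1)
}
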