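# Constructors, accessors and show() methods for the S4 containers.

#' Construct a CohortTimeSeries
#'
#' @param data numeric \code{m x n x t} array (subjects x regions x time).
#' @param subjectIds optional character vector of subject labels.
#' @param regionLabels optional character vector of region labels.
#' @return a [CohortTimeSeries-class].
#' @examples
#' x <- CohortTimeSeries(array(rnorm(2 * 3 * 10), c(2, 3, 10)))
#' nSubjects(x); nRegions(x); nTimepoints(x)
#' @export
CohortTimeSeries <- function(data, subjectIds = NULL, regionLabels = NULL) {
  data <- as.array(data)
  if (is.null(subjectIds)) subjectIds <- sprintf("subject%02d", seq_len(dim(data)[1L]))
  if (is.null(regionLabels)) regionLabels <- sprintf("R%d", seq_len(dim(data)[2L]))
  new("CohortTimeSeries", data = data, subjectIds = as.character(subjectIds),
      regionLabels = as.character(regionLabels))
}

#' @rdname CohortTimeSeries-class
setMethod("nSubjects", "CohortTimeSeries", function(x) dim(x@data)[1L])
#' @rdname CohortTimeSeries-class
setMethod("nRegions", "CohortTimeSeries", function(x) dim(x@data)[2L])
#' @rdname CohortTimeSeries-class
setMethod("nTimepoints", "CohortTimeSeries", function(x) dim(x@data)[3L])
#' @rdname CohortTimeSeries-class
setMethod("subjectIds", "CohortTimeSeries", function(x) x@subjectIds)
#' @rdname CohortTimeSeries-class
setMethod("regionLabels", "CohortTimeSeries", function(x) x@regionLabels)
#' @rdname CohortTimeSeries-class
setMethod("cohortArray", "CohortTimeSeries", function(x) x@data)

#' @rdname CohortTimeSeries-class
setMethod("subjectSeries", "CohortTimeSeries", function(x, i) {
  if (is.character(i)) i <- match(i, x@subjectIds)
  m <- x@data[i, , , drop = TRUE]
  m <- matrix(m, dim(x@data)[2L], dim(x@data)[3L])
  rownames(m) <- x@regionLabels
  m
})

setMethod("show", "CohortTimeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("CohortTimeSeries: %d subjects x %d regions x %d timepoints\n",
              d[1L], d[2L], d[3L]))
  cat("regions:", paste(utils::head(object@regionLabels, 8L), collapse = ", "),
      if (d[2L] > 8L) "..." else "", "\n")
})

#' Construct a BinaryAdjacency
#'
#' @param adjacency square 0/1 matrix with zero diagonal.
#' @return a [BinaryAdjacency-class].
#' @export
BinaryAdjacency <- function(adjacency) {
  storage.mode(adjacency) <- "double"
  new("BinaryAdjacency", adjacency = unname(adjacency))
}

#' Construct a GroundTruthGraph
#'
#' @param adjacency square 0/1 matrix with zero diagonal.
#' @return a [GroundTruthGraph-class].
#' @export
GroundTruthGraph <- function(adjacency) {
  storage.mode(adjacency) <- "double"
  new("GroundTruthGraph", adjacency = unname(adjacency))
}

#' @rdname adjacencyMatrix
setMethod("adjacencyMatrix", "BinaryAdjacency", function(x) x@adjacency)
#' @rdname nNodes
setMethod("nNodes", "BinaryAdjacency", function(x) nrow(x@adjacency))

#' @rdname arcList
setMethod("arcList", "BinaryAdjacency", function(x) {
  idx <- which(x@adjacency == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("source", "target")
  rownames(idx) <- NULL
  idx
})

setMethod("show", "BinaryAdjacency", function(object) {
  cat(sprintf("%s: %d nodes, %d arcs\n", class(object),
              nrow(object@adjacency), sum(object@adjacency)))
})

#' Construct an ECGraph
#'
#' @param weights nonnegative square matrix; entry \code{(i, j)} is the
#'   influence of region \code{i} on region \code{j}.
#' @param normalized whether rows sum to one (row-softmax output).
#' @return an [ECGraph-class].
#' @export
ECGraph <- function(weights, normalized = FALSE) {
  new("ECGraph", weights = unname(as.matrix(weights)), normalized = normalized)
}

#' @rdname ecWeights
setMethod("ecWeights", "ECGraph", function(x) x@weights)
#' @rdname nNodes
setMethod("nNodes", "ECGraph", function(x) nrow(x@weights))

setMethod("show", "ECGraph", function(object) {
  cat(sprintf("ECGraph: %d regions, %s\n", nrow(object@weights),
              if (object@normalized) "row-stochastic" else "unnormalized"))
})

#' Construct an FCMatrix
#'
#' @param values symmetric correlation matrix with unit diagonal.
#' @return an [FCMatrix-class].
#' @export
FCMatrix <- function(values) new("FCMatrix", values = unname(as.matrix(values)))

#' @rdname fcValues
setMethod("fcValues", "FCMatrix", function(x) x@values)
#' @rdname nNodes
setMethod("nNodes", "FCMatrix", function(x) nrow(x@values))

setMethod("show", "FCMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("FCMatrix: %d regions, |r| range [%.3f, %.3f]\n",
              nrow(object@values), min(abs(off)), max(abs(off))))
})

#' Construct an ArcCounts
#'
#' @param ca,ea,ma,ra,ta,truthSize nonnegative integer counts.
#' @return an [ArcCounts-class].
#' @export
ArcCounts <- function(ca, ea, ma, ra, ta, truthSize) {
  new("ArcCounts", ca = as.integer(ca), ea = as.integer(ea),
      ma = as.integer(ma), ra = as.integer(ra), ta = as.integer(ta),
      truthSize = as.integer(truthSize))
}

setMethod("show", "ArcCounts", function(object) {
  cat(sprintf("ArcCounts: CA=%d EA=%d MA=%d RA=%d TA=%d |G|=%d\n",
              object@ca, object@ea, object@ma, object@ra, object@ta,
              object@truthSize))
})

#' Coerce an ArcCounts to a named vector
#' @param x an [ArcCounts-class].
#' @param ... ignored.
#' @export
as.vector.ArcCounts <- function(x, ...) {
  c(CA = x@ca, EA = x@ea, MA = x@ma, RA = x@ra, TA = x@ta, truth = x@truthSize)
}

#' @rdname arcCounts
setMethod("arcCounts", "MetricsReport", function(x) x@counts)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: P=%.3f R=%.3f F1=%.3f SHD=%d\n",
              object@precision, object@recall, object@f1, object@shd))
})

setMethod("show", "ModelState", function(object) {
  np <- length(.flattenLeaves(object@encoder)) + length(.flattenLeaves(object@decoder))
  cat(sprintf(
    "ModelState: %d-layer encoder (h=%d, %d heads), %d-hidden-layer decoder (K=%d), t=%d, %d parameters\n",
    object@encoderConfig$nLayers, object@encoderConfig$hiddenDim,
    object@encoderConfig$nHeads, object@decoderConfig$nHiddenLayers,
    object@decoderConfig$lagWindow, object@timepoints, np))
})

#' @rdname lossTrace
setMethod("lossTrace", "TrainReport", function(x) x@lossTrace)
#' @rdname subjectGraphs
setMethod("subjectGraphs", "TrainReport", function(x) x@graphs)

setMethod("show", "TrainReport", function(object) {
  n <- length(object@lossTrace)
  cat(sprintf("TrainReport: %d epochs, loss %.4g -> %.4g, %d subject graphs\n",
              n, object@lossTrace[1L], object@lossTrace[n], length(object@graphs)))
})

# internal: accept either a BinaryAdjacency-ish object or a plain matrix
.asBinaryMatrix <- function(x, what = "graph") {
  a <- if (is(x, "BinaryAdjacency")) x@adjacency else as.matrix(x)
  if (nrow(a) != ncol(a)) stop(what, " adjacency must be square")
  if (!all(a %in% c(0, 1))) stop(what, " adjacency must be binary (0/1)")
  if (any(diag(a) != 0)) stop(what, " adjacency must have a zero diagonal")
  a
}
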