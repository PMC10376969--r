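#' @rdname CohortTimeSeries-class
#' @param x a \code{CohortTimeSeries}.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname CohortTimeSeries-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname CohortTimeSeries-class
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname CohortTimeSeries-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname CohortTimeSeries-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname CohortTimeSeries-class
#' @param i subject index or id.
#' @export
setGeneric("subjectSeries", function(x, i) standardGeneric("subjectSeries"))

#' @rdname CohortTimeSeries-class
#' @export
setGeneric("cohortArray", function(x) standardGeneric("cohortArray"))

#' Extract the adjacency matrix of a binary graph
#' @param x a [BinaryAdjacency-class] or [GroundTruthGraph-class].
#' @return base 0/1 matrix.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Number of nodes of a graph object
#' @param x a graph object.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Ordered arc list (source, target) of a binary graph
#' @param x a [BinaryAdjacency-class].
#' @return two-column integer matrix, one row per arc.
#' @export
setGeneric("arcList", function(x) standardGeneric("arcList"))

#' Extract the weight matrix of an effective-connectivity graph
#' @param x an [ECGraph-class].
#' @export
setGeneric("ecWeights", function(x) standardGeneric("ecWeights"))

#' Extract the correlation matrix of a functional-connectivity object
#' @param x an [FCMatrix-class].
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))

#' Arc counts of a metrics report
#' @param x a [MetricsReport-class].
#' @export
setGeneric("arcCounts", function(x) standardGeneric("arcCounts"))

#' Per-epoch loss trace of a training run
#' @param x a [TrainReport-class].
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' Final per-subject graphs of a training run
#' @param x a [TrainReport-class].
#' @export
setGeneric("subjectGraphs", function(x) standardGeneric("subjectGraphs"))
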