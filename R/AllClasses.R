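#' @import methods
NULL

#' Multi-subject ROI time-series cohort
#'
#' Container for a cohort of fMRI region-of-interest (ROI) signals: an
#' \code{m x n x t} array of \code{m} subjects, \code{n} regions and
#' \code{t} timepoints, with subject and region labels.
#'
#' @slot data numeric array of dimension \code{m x n x t}; all values finite.
#' @slot subjectIds character vector of length \code{m}.
#' @slot regionLabels character vector of length \code{n}.
#'
#' @seealso [CohortTimeSeries()], [simulateCohort()], [readCohort()]
#' @export
setClass("CohortTimeSeries",
  representation(data = "array", subjectIds = "character",
                 regionLabels = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
      return("data must be an m x n x t array")
    if (!all(is.finite(d)))
      return("time-series values must all be finite")
    if (length(object@subjectIds) != dim(d)[1L])
      return("subjectIds length must equal the number of subjects")
    if (length(object@regionLabels) != dim(d)[2L])
      return("regionLabels length must equal the number of regions")
    TRUE
  })

#' Binary directed adjacency matrix
#'
#' An \code{n x n} 0/1 matrix with zero diagonal; entry \code{(i, j) = 1}
#' means an arc from region \code{i} to region \code{j}. Bidirectional pairs
#' (both \code{(i, j)} and \code{(j, i)} set) are permitted and counted as
#' two arcs throughout.
#'
#' @slot adjacency numeric/integer 0-1 matrix, zero diagonal.
#' @export
setClass("BinaryAdjacency",
  representation(adjacency = "matrix"),
  validity = function(object) {
    a <- object@adjacency
    if (nrow(a) != ncol(a)) return("adjacency must be square")
    if (!all(a %in% c(0, 1))) return("adjacency entries must be 0 or 1")
    if (any(diag(a) != 0)) return("self-loops (diagonal entries) are not allowed")
    TRUE
  })

#' Ground-truth directed graph for simulation
#'
#' A [BinaryAdjacency-class] used as the data-generating network of the
#' cohort simulator.
#' @export
setClass("GroundTruthGraph", contains = "BinaryAdjacency")

#' Weighted effective-connectivity graph
#'
#' Nonnegative \code{n x n} weighted directed adjacency; entry \code{(i, j)}
#' is the estimated influence of region \code{i} on region \code{j}. When
#' \code{normalized} is \code{TRUE} each row sums to 1 (the encoder's
#' row-softmax output) and the diagonal is zero.
#'
#' @slot weights nonnegative numeric matrix.
#' @slot normalized logical scalar.
#' @export
setClass("ECGraph",
  representation(weights = "matrix", normalized = "logical"),
  validity = function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weights must be square")
    if (any(w < -1e-12)) return("weights must be nonnegative")
    if (isTRUE(object@normalized)) {
      if (any(abs(rowSums(w) - 1) > 1e-6))
        return("normalized graph rows must sum to 1")
    }
    TRUE
  })

#' Functional-connectivity (Pearson correlation) matrix
#'
#' Symmetric matrix of Pearson correlations between region time series,
#' unit diagonal, entries in \code{[-1, 1]}.
#'
#' @slot values numeric matrix.
#' @export
setClass("FCMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    w <- object@values
    if (nrow(w) != ncol(w)) return("correlation matrix must be square")
    if (max(abs(w - t(w))) > 1e-10) return("correlation matrix must be symmetric")
    if (any(abs(diag(w) - 1) > 1e-10)) return("diagonal must be 1")
    if (any(w < -1 - 1e-10) || any(w > 1 + 1e-10))
      return("correlations must lie in [-1, 1]")
    TRUE
  })

#' Arc-classification counts
#'
#' Counts from comparing a predicted binary graph against the ground truth:
#' correct (CA), extra (EA), missing (MA) and reversed (RA) arcs, the number
#' of predicted arcs (TA) and the number of truth arcs (`truthSize`).
#' Invariantly \code{CA + EA + RA = TA}.
#'
#' @slot ca,ea,ma,ra,ta,truthSize nonnegative integers.
#' @export
setClass("ArcCounts",
  representation(ca = "integer", ea = "integer", ma = "integer",
                 ra = "integer", ta = "integer", truthSize = "integer"),
  validity = function(object) {
    v <- c(object@ca, object@ea, object@ma, object@ra, object@ta, object@truthSize)
    if (any(v < 0L)) return("counts must be nonnegative")
    if (object@ca + object@ea + object@ra != object@ta)
      return("CA + EA + RA must equal TA")
    TRUE
  })

#' Graph-recovery metrics for one subject
#'
#' Precision, recall, F1 and structural Hamming distance (SHD = EA + MA + RA)
#' derived from an [ArcCounts-class].
#'
#' @slot precision,recall,f1 numeric in \code{[0, 1]}.
#' @slot shd nonnegative integer.
#' @slot counts the underlying [ArcCounts-class].
#' @export
setClass("MetricsReport",
  representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                 shd = "integer", counts = "ArcCounts"),
  validity = function(object) {
    if (object@shd != object@counts@ea + object@counts@ma + object@counts@ra)
      return("shd must equal EA + MA + RA")
    TRUE
  })

#' Trained encoder-decoder parameters
#'
#' Holds all trainable encoder and decoder parameter arrays together with the
#' architecture configuration and the time-series length the model was built
#' for (the input embedding maps the time axis, so \code{timepoints} is fixed
#' at construction).
#'
#' @slot encoder,decoder nested lists of numeric parameter arrays.
#' @slot encoderConfig,decoderConfig configuration lists
#'   (see [encoderConfig()], [decoderConfig()]).
#' @slot timepoints integer time-series length.
#' @slot seed integer seed used at initialization.
#' @export
setClass("ModelState",
  representation(encoder = "list", decoder = "list",
                 encoderConfig = "list", decoderConfig = "list",
                 timepoints = "integer", seed = "integer"))

#' Training report
#'
#' Per-epoch loss trace, the final per-subject weighted graphs, and an echo
#' of the training configuration.
#'
#' @slot lossTrace numeric vector, one total loss per epoch.
#' @slot graphs list of [ECGraph-class], one per subject.
#' @slot seed integer.
#' @slot config the [trainingConfig()] list used.
#' @export
setClass("TrainReport",
  representation(lossTrace = "numeric", graphs = "list",
                 seed = "integer", config = "list"))
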