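# File formats: per-subject CSV cohorts, stacked-matrix cohorts (subjects
# concatenated along time, the layout used by the public netsim-style
# benchmark bundles), RDS bundles, adjacency/edge-list graph files, YAML run
# configurations and JSON reports.

#' Write a cohort to a directory
#'
#' Writes one CSV per subject (rows = regions, first column the region
#' label, remaining columns timepoints), a truth edge-list TSV per subject
#' when truths are supplied, a JSON manifest (n, t, m, seed, options), and a
#' single RDS bundle holding data plus truths.
#'
#' @param cohort a [CohortTimeSeries-class].
#' @param dir output directory (created if needed).
#' @param truths optional list of [GroundTruthGraph-class] per subject.
#' @param seed,opts echoed into the manifest.
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir, truths = NULL, seed = NA_integer_,
                        opts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- nSubjects(cohort)
  for (s in seq_len(m)) {
    xs <- subjectSeries(cohort, s)
    df <- data.frame(region = regionLabels(cohort), xs, check.names = FALSE)
    colnames(df) <- c("region", sprintf("t%d", seq_len(ncol(xs))))
    utils::write.csv(df, file.path(dir, sprintf("%s.csv", subjectIds(cohort)[s])),
                     row.names = FALSE)
    if (!is.null(truths)) {
      al <- arcList(truths[[s]])
      utils::write.table(
        data.frame(source = regionLabels(cohort)[al[, 1L]],
                   target = regionLabels(cohort)[al[, 2L]]),
        file.path(dir, sprintf("truth_%s.tsv", subjectIds(cohort)[s])),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  manifest <- list(m = m, n = nRegions(cohort), t = nTimepoints(cohort),
                   seed = seed, subjects = subjectIds(cohort),
                   regions = regionLabels(cohort))
  if (!is.null(opts)) manifest$options <- opts
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(data = cohortArray(cohort), subjectIds = subjectIds(cohort),
               regionLabels = regionLabels(cohort), truths = truths),
          file.path(dir, "cohort_bundle.rds"))
  invisible(dir)
}

.checkFinite <- function(d, subjectIds, regionLabels) {
  for (s in seq_len(dim(d)[1L])) {
    bad <- which(!is.finite(d[s, , , drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-finite value in subject %s, region %s",
                   subjectIds[s], regionLabels[bad[1L, 2L]]))
    }
  }
}

#' Read a cohort from disk
#'
#' Recognized layouts: a directory of per-subject CSVs as written by
#' [writeCohort()] (with optional truth edge lists and RDS bundle), a single
#' RDS bundle file, or a stacked-matrix text file in which the \code{m}
#' subjects' \code{t x n} blocks are concatenated along the time (row) axis
#' -- the layout used by the public benchmark bundles -- split using
#' \code{tPerSubject}.
#'
#' @param path directory or file.
#' @param layout \code{"auto"}, \code{"dir"}, \code{"bundle"} or
#'   \code{"stacked"}.
#' @param tPerSubject per-subject series length, required for
#'   \code{"stacked"}.
#' @param normalize z-score each region per subject (default TRUE).
#' @return list with \code{cohort} (a [CohortTimeSeries-class]) and
#'   \code{truths} (list of [GroundTruthGraph-class] or NULL).
#' @export
readCohort <- function(path, layout = c("auto", "dir", "bundle", "stacked"),
                       tPerSubject = NULL, normalize = TRUE) {
  layout <- match.arg(layout)
  if (layout == "auto") {
    layout <- if (dir.exists(path)) "dir"
    else if (grepl("\\.rds$", path, ignore.case = TRUE)) "bundle"
    else if (!is.null(tPerSubject)) "stacked"
    else stop("unknown cohort layout for ", path,
              " (need a CSV directory, an .rds bundle, or tPerSubject for a stacked matrix)")
  }
  raw <- switch(layout,
    dir = .readCohortDir(path),
    bundle = .readCohortBundle(path),
    stacked = .readCohortStacked(path, tPerSubject))
  .checkFinite(raw$d, raw$ids, raw$regions)
  cohort <- CohortTimeSeries(raw$d, raw$ids, raw$regions)
  if (normalize) cohort <- zscoreCohort(cohort)
  list(cohort = cohort, truths = raw$truths)
}

.readCohortDir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("^truth_", basename(files))]
  if (!length(files)) stop("unknown cohort layout: no subject CSV files in ", path)
  mats <- lapply(files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  })
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1L, ])) > 1L || length(unique(dims[2L, ])) > 1L)
    stop("ragged cohort: subjects have differing region or timepoint counts")
  m <- length(mats); n <- nrow(mats[[1L]]); t <- ncol(mats[[1L]])
  d <- array(0, c(m, n, t))
  for (s in seq_len(m)) d[s, , ] <- mats[[s]]
  ids <- sub("\\.csv$", "", basename(files))
  regions <- rownames(mats[[1L]])
  truths <- NULL
  tf <- file.path(path, sprintf("truth_%s.tsv", ids))
  if (all(file.exists(tf))) {
    truths <- lapply(tf, function(f) {
      el <- utils::read.table(f, sep = "\t", header = TRUE,
                              colClasses = "character")
      a <- matrix(0, n, n)
      if (nrow(el))
        a[cbind(match(el$source, regions), match(el$target, regions))] <- 1
      GroundTruthGraph(a)
    })
  }
  list(d = d, ids = ids, regions = regions, truths = truths)
}

.readCohortBundle <- function(path) {
  b <- readRDS(path)
  if (!is.list(b) || is.null(b$data))
    stop("unknown cohort layout: ", path, " is not a cohort bundle")
  list(d = b$data, ids = b$subjectIds, regions = b$regionLabels,
       truths = b$truths)
}

.readCohortStacked <- function(path, tPerSubject) {
  raw <- as.matrix(utils::read.table(path, header = FALSE,
                                     sep = "", comment.char = "#"))
  if (nrow(raw) %% tPerSubject != 0L)
    stop("ragged cohort: stacked file has ", nrow(raw),
         " rows, not a multiple of tPerSubject = ", tPerSubject)
  m <- nrow(raw) %/% tPerSubject
  n <- ncol(raw)
  d <- array(0, c(m, n, tPerSubject))
  for (s in seq_len(m)) {
    block <- raw[((s - 1L) * tPerSubject + 1L):(s * tPerSubject), , drop = FALSE]
    d[s, , ] <- t(block)
  }
  list(d = d, ids = sprintf("subject%02d", seq_len(m)),
       regions = sprintf("R%d", seq_len(n)), truths = NULL)
}

#' Write / read a square graph matrix as labeled CSV
#'
#' @param x an [ECGraph-class], [BinaryAdjacency-class] or matrix.
#' @param path file path.
#' @param labels optional region labels.
#' @return \code{writeGraphCSV} the path invisibly; \code{readGraphCSV} the
#'   matrix with labels as dimnames.
#' @export
writeGraphCSV <- function(x, path, labels = NULL) {
  w <- if (is(x, "ECGraph")) ecWeights(x)
       else if (is(x, "BinaryAdjacency")) adjacencyMatrix(x)
       else as.matrix(x)
  if (is.null(labels)) labels <- sprintf("R%d", seq_len(nrow(w)))
  dimnames(w) <- list(labels, labels)
  utils::write.csv(w, path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeGraphCSV
#' @export
readGraphCSV <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a weighted edge list
#'
#' TSV with columns source, target, weight (off-diagonal nonzero entries).
#'
#' @param x an [ECGraph-class] or matrix.
#' @param path file path.
#' @param labels optional region labels.
#' @export
writeEdgeList <- function(x, path, labels = NULL) {
  w <- if (is(x, "ECGraph")) ecWeights(x) else as.matrix(x)
  if (is.null(labels)) labels <- sprintf("R%d", seq_len(nrow(w)))
  idx <- which(w != 0 & row(w) != col(w), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  utils::write.table(
    data.frame(source = labels[idx[, 1L]], target = labels[idx[, 2L]],
               weight = w[idx]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding all parameter arrays and both architecture
#' configurations, plus a library-agnostic JSON sidecar
#' (\code{<path>.json}) with the parameter shapes, configurations and seed.
#'
#' @param state a [ModelState-class].
#' @param path file path (.rds).
#' @export
saveModelState <- function(state, path) {
  saveRDS(list(encoder = state@encoder, decoder = state@decoder,
               encoderConfig = state@encoderConfig,
               decoderConfig = state@decoderConfig,
               timepoints = state@timepoints, seed = state@seed),
          path)
  shapes <- function(p) .mapLeaves(function(x)
    if (is.matrix(x)) dim(x) else length(x), p)
  jsonlite::write_json(
    list(timepoints = state@timepoints, seed = state@seed,
         encoderConfig = state@encoderConfig,
         decoderConfig = state@decoderConfig,
         encoderShapes = shapes(state@encoder),
         decoderShapes = shapes(state@decoder)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModelState
#' @export
loadModelState <- function(path) {
  b <- readRDS(path)
  new("ModelState", encoder = b$encoder, decoder = b$decoder,
      encoderConfig = b$encoderConfig, decoderConfig = b$decoderConfig,
      timepoints = b$timepoints, seed = b$seed)
}
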