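#' Read a drug-target interaction matrix from labeled TSV
#'
#' The file dialect is a tab-separated table with one header row of
#' identifiers and one leading label column. The benchmark interaction files
#' ship targets-as-rows (drugs in the header), so the default orientation is
#' \code{"drugs-as-columns"}; the returned object is always in canonical
#' drugs-as-rows form. Auto-detection is deliberately avoided: it can
#' misfire on square matrices.
#'
#' @param path TSV file path
#' @param orientation \code{"drugs-as-columns"} (default) or
#'   \code{"drugs-as-rows"}, describing the file on disk
#' @return an \linkS4class{InteractionMatrix} (drugs as rows)
#' @export
readInteractionMatrix <- function(path,
                                  orientation = c("drugs-as-columns",
                                                  "drugs-as-rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("non-binary interaction value at row '%s', column '%s' in %s",
                 rownames(m)[i], colnames(m)[j], path))
  }
  if (orientation == "drugs-as-columns") m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicate drug identifiers in ", path)
  if (anyDuplicated(colnames(m)))
    stop("duplicate target identifiers in ", path)
  InteractionMatrix(m)
}

#' Write an interaction matrix as labeled TSV
#'
#' @param x an \linkS4class{InteractionMatrix}
#' @param path output file
#' @param orientation layout on disk; default canonical drugs-as-rows
#' @return \code{path}, invisibly
#' @export
writeInteractionMatrix <- function(x, path,
                                   orientation = c("drugs-as-rows",
                                                   "drugs-as-columns")) {
  orientation <- match.arg(orientation)
  m <- x@values
  if (orientation == "drugs-as-columns") m <- t(m)
  .writeLabeledTSV(m, path)
}

#' Read a similarity matrix from labeled TSV
#'
#' Values must be numeric, in [0, 1], and square with matching row/column
#' identifiers. Small asymmetries (at most 1e-6) are averaged away as
#' \code{(S + t(S))/2}; anything larger is an error -- loud failure beats
#' silent corruption. The diagonal is forced to the declared convention.
#'
#' @param path TSV file path
#' @param diagonal diagonal convention of the similarity,
#'   \code{"unit"} or \code{"zero"}
#' @return a \linkS4class{SimilarityMatrix}
#' @export
readSimilarityMatrix <- function(path, diagonal = c("unit", "zero")) {
  diagonal <- match.arg(diagonal)
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("similarity matrix in ", path, " is not square")
  if (any(is.na(m))) stop("non-numeric similarity value in ", path)
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9) {
    bad <- which(m < -1e-9 | m > 1 + 1e-9)[1]
    stop(sprintf("similarity value %g outside [0, 1] in %s", m[bad], path))
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop(sprintf("similarity matrix in %s is asymmetric (max deviation %g)",
                 path, asym))
  m <- (m + t(m)) / 2
  SimilarityMatrix(m, ids = rownames(m), diagonal = diagonal)
}

#' Write a similarity matrix as labeled TSV
#'
#' @param x a \linkS4class{SimilarityMatrix}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeSimilarityMatrix <- function(x, path) .writeLabeledTSV(x@values, path)

.writeLabeledTSV <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dataset bundle as a directory of labeled TSV files
#'
#' Writes \code{interactions.tsv} (drugs-as-rows) plus one
#' \code{drug_sim_<name>.tsv} and \code{target_sim_<name>.tsv} per view --
#' the same dialect \code{readDatasetBundle} consumes.
#'
#' @param bundle a \linkS4class{DatasetBundle}
#' @param dir output directory (created if absent)
#' @return \code{dir}, invisibly
#' @export
writeDatasetBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeInteractionMatrix(bundle@interactions, file.path(dir, "interactions.tsv"))
  for (nm in names(bundle@drugSims))
    writeSimilarityMatrix(bundle@drugSims[[nm]],
                          file.path(dir, paste0("drug_sim_", nm, ".tsv")))
  for (nm in names(bundle@targetSims))
    writeSimilarityMatrix(bundle@targetSims[[nm]],
                          file.path(dir, paste0("target_sim_", nm, ".tsv")))
  invisible(dir)
}

#' Read a dataset bundle from a directory of labeled TSV files
#'
#' @param dir directory containing \code{interactions.tsv} and
#'   \code{drug_sim_*.tsv} / \code{target_sim_*.tsv} files
#' @param orientation orientation of the interaction file on disk
#' @param diagonal diagonal convention of the similarity files
#' @return a \linkS4class{DatasetBundle}
#' @export
readDatasetBundle <- function(dir, orientation = "drugs-as-rows",
                              diagonal = "unit") {
  dti <- readInteractionMatrix(file.path(dir, "interactions.tsv"),
                               orientation = orientation)
  readSims <- function(prefix) {
    files <- sort(list.files(dir, pattern = paste0("^", prefix, ".*\\.tsv$"),
                             full.names = TRUE))
    sims <- lapply(files, readSimilarityMatrix, diagonal = diagonal)
    names(sims) <- sub("\\.tsv$", "", sub(paste0("^", prefix), "",
                                          basename(files)))
    sims
  }
  DatasetBundle(dti, drugSims = readSims("drug_sim_"),
                targetSims = readSims("target_sim_"))
}

#' Dataset summary statistics
#'
#' Counts of drugs, targets, known and unknown drug-target pairs, and the
#' sparsity ratio, defined as the number of known DTIs divided by the number
#' of unknown DTIs (0 when there are no known interactions).
#'
#' @param x a \linkS4class{DatasetBundle} or \linkS4class{InteractionMatrix}
#' @return named list with \code{nDrugs}, \code{nTargets}, \code{known},
#'   \code{unknown}, \code{sparsity}
#' @examples
#' toy <- makeWorkedToy()
#' datasetStatistics(toy)
#' @export
setGeneric("datasetStatistics", function(x) standardGeneric("datasetStatistics"))

#' @rdname datasetStatistics
#' @export
setMethod("datasetStatistics", "InteractionMatrix", function(x) {
  n <- nDrugs(x); m <- nTargets(x)
  known <- as.integer(sum(x@values))
  unknown <- n * m - known
  list(nDrugs = n, nTargets = m, known = known, unknown = unknown,
       sparsity = if (known == 0) 0 else known / unknown)
})

#' @rdname datasetStatistics
#' @export
setMethod("datasetStatistics", "DatasetBundle",
          function(x) datasetStatistics(x@interactions))
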