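# Plain-text interchange: predictor tables, label files, trace and
# selectivity exports. All formats are TSV with headers so runs can be
# audited with standard command-line tools.

#' Read a delimited predictor table
#'
#' Expects a header row of variable ids and a first column of sample ids.
#'
#' @param path file path (TSV by default).
#' @param sep field separator.
#' @return numeric matrix with sample-id rownames.
#' @export
readPredictorTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a predictor table
#'
#' @param X numeric matrix, sample-id rownames, variable-id colnames.
#' @param path output file path.
#' @param sep field separator.
#' @export
writePredictorTable <- function(X, path, sep = "\t") {
  df <- data.frame(sample = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column label file (sample id, class)
#'
#' @param path file path.
#' @param sep field separator.
#' @return named character vector of class labels.
#' @export
readLabels <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("label file needs columns: sample id, class")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Assemble a labeled dataset from table and label files
#'
#' Samples are matched by id; every sample in the predictor table must be
#' labeled.
#'
#' @param featurePath predictor-table TSV (see [readPredictorTable()]).
#' @param labelPath two-column label TSV (see [readLabels()]).
#' @param positiveClass label coded as 1 (default: second sorted label).
#' @return a [LabeledDataset-class].
#' @export
readLabeledDataset <- function(featurePath, labelPath,
                               positiveClass = NULL) {
  X <- readPredictorTable(featurePath)
  lab <- readLabels(labelPath)
  missing <- setdiff(rownames(X), names(lab))
  if (length(missing))
    stop("unlabeled samples: ", paste(missing, collapse = ", "))
  LabeledDataset(X, lab[rownames(X)], positiveClass = positiveClass)
}

#' Write an elimination trace as TSV
#'
#' One row per iteration with the retained-variable count, performance,
#' estimated dimension, flag/elimination counts and (optionally) the
#' McNemar p-value against the optimum iteration.
#'
#' @param trace an [EliminationTrace-class].
#' @param path output file path.
#' @param d rejection level used to annotate the chosen iteration; NULL
#'   writes the trace without the second-regularization columns.
#' @export
writeEliminationTrace <- function(trace, path, d = NULL) {
  df <- as.data.frame(trace)
  if (!is.null(d)) {
    fin <- chooseFinalIteration(trace, d)
    pv <- rep(NA_real_, nrow(df))
    pv[seq.int(fin$gStar, nrow(df))] <- fin$pValues
    df$pValueVsOptimum <- pv
    df$chosen <- seq_len(nrow(df)) == fin$gFinal
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a selectivity profile as TSV, sorted descending
#'
#' @param profile a [SelectivityProfile-class].
#' @param path output file path.
#' @export
writeSelectivityProfile <- function(profile, path) {
  ord <- order(-profile@scores, names(profile@scores))
  df <- data.frame(variable = names(profile@scores)[ord],
                   score = unname(profile@scores[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
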