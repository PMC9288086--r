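# Tab-separated readers and writers for every intermediate table. All files
# are UTF-8 TSV with a header row and '.' as decimal separator.

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read / write pipeline tables
#'
#' TSV round-trip helpers for the annotation, design, count, peptide and
#' activity tables. Count matrices are written with a leading gene_id
#' column.
#'
#' @param path file path.
#' @param x object to write.
#' @return readers return a data.frame (or matrix for counts); writers
#'   return the path invisibly.
#' @name lignoreg-io
NULL

#' @rdname lignoreg-io
#' @export
readGeneAnnotation <- function(path) .readTSV(path)

#' @rdname lignoreg-io
#' @export
writeGeneAnnotation <- function(x, path) .writeTSV(x, path)

#' @rdname lignoreg-io
#' @export
readSampleDesign <- function(path) .readTSV(path)

#' @rdname lignoreg-io
#' @export
writeSampleDesign <- function(x, path) .writeTSV(x, path)

#' @rdname lignoreg-io
#' @export
readCountMatrix <- function(path) {
  df <- .readTSV(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname lignoreg-io
#' @export
writeCountMatrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' @rdname lignoreg-io
#' @export
readExpressionMatrix <- function(path) {
  df <- .readTSV(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname lignoreg-io
#' @export
writeExpressionMatrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' @rdname lignoreg-io
#' @export
readPeptideTable <- function(path) .readTSV(path)

#' @rdname lignoreg-io
#' @export
writePeptideTable <- function(x, path) .writeTSV(x, path)

#' @rdname lignoreg-io
#' @export
readActivityTable <- function(path) .readTSV(path)

#' @rdname lignoreg-io
#' @export
writeActivityTable <- function(x, path) .writeTSV(x, path)
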