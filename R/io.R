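## Readers and writers for the plain-text formats the pipeline touches:
## 10x-style MTX triplets, dense TSV matrices, tissue-positions CSV (both
## headered and headerless dialects), and GMT gene sets.

#' Read a 10x-style MTX triplet into an expression matrix
#'
#' @param matrixPath Path to the MatrixMarket file.
#' @param featuresPath Path to features/genes file (first column = gene id),
#'   one line per matrix row.
#' @param barcodesPath Path to barcodes file, one line per matrix column.
#' @return A raw-counts \code{SummarizedExperiment}
#'   (see \code{\link{ExpressionMatrix}}).
#' @export
readMTX <- function(matrixPath, featuresPath, barcodesPath) {
  for (p in c(matrixPath, featuresPath, barcodesPath))
    if (!file.exists(p)) hxStop("file not found: ", p)
  m <- tryCatch(Matrix::readMM(matrixPath),
                error = function(e) hxStop("malformed MTX file ", matrixPath,
                                           ": ", conditionMessage(e)))
  feats <- read.table(featuresPath, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  bcs <- read.table(barcodesPath, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(feats))
    hxStop("format error: MTX declares ", nrow(m), " rows but ",
           featuresPath, " has ", length(feats), " lines")
  if (ncol(m) != length(bcs))
    hxStop("format error: MTX declares ", ncol(m), " columns but ",
           barcodesPath, " has ", length(bcs), " lines")
  dense <- as.matrix(m)
  dimnames(dense) <- list(feats, bcs)
  ExpressionMatrix(dense, "raw_counts")
}

#' Write an expression matrix as an MTX triplet
#'
#' @param x Expression container or matrix (raw counts).
#' @param dir Output directory; writes matrix.mtx, features.tsv, barcodes.tsv.
#' @return \code{dir}, invisibly.
#' @export
writeMTX <- function(x, dir) {
  m <- exprValues(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense TSV expression matrix
#'
#' First column holds gene ids, header row holds sample ids. Duplicate gene
#' rows are collapsed by sum (raw counts) or mean (lognorm) with a warning.
#'
#' @param path Path to the TSV file.
#' @param valueKind "raw_counts" or "lognorm".
#' @return A \code{SummarizedExperiment} expression container.
#' @export
readDenseTSV <- function(path, valueKind = c("raw_counts", "lognorm")) {
  valueKind <- match.arg(valueKind)
  if (!file.exists(path)) hxStop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA,
                   comment.char = "")
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      hxStop(sprintf("format error in %s: non-numeric cell at row %d, column '%s'",
                     path, bad, colnames(vals)[j]))
    }
    if (anyNA(col))
      hxStop(sprintf("format error in %s: missing value at row %d, column '%s'",
                     path, which(is.na(col))[1L], colnames(vals)[j]))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    fun <- if (valueKind == "raw_counts") "sum" else "mean"
    hxWarn("collapsing ", sum(duplicated(genes)), " duplicate gene row(s) by ",
           fun)
    m <- rowsum(m, group = genes, reorder = FALSE)
    if (fun == "mean") m <- m / as.vector(table(genes)[rownames(m)])
  }
  ExpressionMatrix(m, valueKind)
}

#' Write a dense TSV expression matrix
#'
#' @param x Expression container or matrix.
#' @param path Output path.
#' @param idColumn Name for the gene-id column.
#' @return \code{path}, invisibly.
#' @export
writeDenseTSV <- function(x, path, idColumn = "gene_id") {
  m <- exprValues(x)
  df <- data.frame(m, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), idColumn), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.POS_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
               "px_row", "px_col")

#' Read a 10x tissue-positions CSV
#'
#' Accepts both the headerless (Space Ranger < 2.0) and headered dialects;
#' the header is auto-detected. Only spots with \code{in_tissue == 1} are
#' retained. Pixel row/col are mapped to \code{px_y}/\code{px_x}.
#'
#' @param path Path to the positions CSV.
#' @param barcodes Optional character vector of expression-column barcodes;
#'   if supplied, every barcode must appear in the file.
#' @return data.frame with columns barcode, array_row, array_col, px_x, px_y.
#' @export
readPositions <- function(path, barcodes = NULL) {
  if (!file.exists(path)) hxStop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- read.table(path, sep = ",", header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) != 6L)
    hxStop("format error: positions file must have 6 columns, found ",
           ncol(df))
  colnames(df) <- .POS_COLS
  df <- df[df$in_tissue == 1, , drop = FALSE]
  out <- data.frame(barcode = as.character(df$barcode),
                    array_row = as.numeric(df$array_row),
                    array_col = as.numeric(df$array_col),
                    px_x = as.numeric(df$px_col),
                    px_y = as.numeric(df$px_row),
                    stringsAsFactors = FALSE)
  if (!is.null(barcodes)) {
    missing <- setdiff(barcodes, out$barcode)
    if (length(missing))
      hxStop("barcodes present in expression but absent from positions: ",
             paste(missing, collapse = ", "))
    out <- out[match(barcodes, out$barcode), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a tissue-positions CSV (headered dialect)
#'
#' @param coords data.frame as returned by \code{readPositions} or
#'   \code{spotCoords}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePositions <- function(coords, path) {
  df <- data.frame(barcode = coords$barcode, in_tissue = 1L,
                   array_row = coords$array_row, array_col = coords$array_col,
                   px_row = coords$px_y, px_col = coords$px_x)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: tab-separated lines of name, description, then gene symbols.
#' Gene lists are kept in file order and de-duplicated (with a warning).
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (a signature set).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) hxStop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      hxStop(sprintf("format error in %s line %d: GMT lines need name, description, and >= 1 gene",
                     path, i))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      hxWarn("de-duplicated ", sum(duplicated(genes)), " gene(s) in set '",
             fields[1L], "'")
      genes <- genes[!duplicated(genes)]
    }
    out[[fields[1L]]] <- genes
  }
  out
}

#' Write a GMT gene-set file
#'
#' @param signatures Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(signatures, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(signatures))
  lines <- vapply(seq_along(signatures), function(i) {
    paste(c(names(signatures)[i], descriptions[i], signatures[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Match a signature against the genes of a matrix
#'
#' Exact, case-sensitive symbol matching; absent genes are reported.
#'
#' @param signature Character vector of gene symbols.
#' @param geneIds Rownames of the expression matrix.
#' @param name Signature name used in the log message.
#' @return The matched subset of \code{signature}, in signature order.
#' @export
matchSignature <- function(signature, geneIds, name = "signature") {
  hit <- signature[signature %in% geneIds]
  absent <- setdiff(signature, geneIds)
  if (length(absent))
    hxLog(sprintf("%s: %d/%d gene(s) absent from matrix: %s", name,
                  length(absent), length(signature),
                  paste(absent, collapse = ", ")))
  hit
}
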