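## On-disk layout for one slide: an MTX triplet plus a tissue-positions CSV,
## with ground truth (when present) kept in a separate truth/ subdirectory
## so it never flows into pipeline inputs.

#' Write a SpatialSlide to a directory
#'
#' Writes matrix.mtx + features.tsv + barcodes.tsv, tissue_positions.csv,
#' and, when ground truth is attached, truth/regions.tsv and
#' truth/props.tsv. Simulated slides additionally get their program gene
#' sets as programs.gmt.
#'
#' @param slide A \linkS4class{SpatialSlide}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSlide <- function(slide, dir) {
  stopifnot(methods::is(slide, "SpatialSlide"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMTX(slide, dir)
  writePositions(spotCoords(slide), file.path(dir, "tissue_positions.csv"))
  sp <- S4Vectors::metadata(slide)$sim_params
  if (!is.null(sp))
    writeGMT(sp$programGenes, file.path(dir, "programs.gmt"))
  tr <- truthRegion(slide)
  tp <- truthProps(slide)
  if (!is.null(tr) || !is.null(tp)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    if (!is.null(tr))
      write.table(data.frame(barcode = names(tr), region = tr),
                  file.path(tdir, "regions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(tp))
      write.table(data.frame(barcode = rownames(tp), tp,
                             check.names = FALSE),
                  file.path(tdir, "props.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  invisible(dir)
}

#' Read a SpatialSlide from a directory
#'
#' @param dir Directory written by \code{writeSlide} (or 10x-style export
#'   with matrix.mtx, features.tsv, barcodes.tsv, tissue_positions.csv).
#' @param withTruth Attach truth/ ground truth when present (off by
#'   default; truth is for tests and evaluation only).
#' @return A \linkS4class{SpatialSlide}.
#' @export
readSlide <- function(dir, withTruth = FALSE) {
  em <- readMTX(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                file.path(dir, "barcodes.tsv"))
  counts <- exprValues(em)
  pos <- readPositions(file.path(dir, "tissue_positions.csv"),
                       barcodes = colnames(counts))
  tr <- NULL
  tp <- NULL
  if (withTruth) {
    rpath <- file.path(dir, "truth", "regions.tsv")
    if (file.exists(rpath)) {
      df <- read.table(rpath, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
      tr <- stats::setNames(df$region, df$barcode)
    }
    ppath <- file.path(dir, "truth", "props.tsv")
    if (file.exists(ppath)) {
      df <- read.table(ppath, sep = "\t", header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE)
      tp <- as.matrix(df[, -1L, drop = FALSE])
      rownames(tp) <- df$barcode
    }
  }
  SpatialSlide(counts, pos, valueKind = "raw_counts", truthRegion = tr,
               truthProps = tp)
}
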