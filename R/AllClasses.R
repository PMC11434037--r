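#' SpatialSlide: a spot-lattice expression experiment
#'
#' An S4 container for one spatial-transcriptomics slide: a genes x spots
#' expression assay plus per-spot hexagonal lattice coordinates (array
#' row/col and pixel x/y centers), and optional ground truth (region labels
#' and cell-type proportions) carried by synthetic slides. Extends
#' \linkS4class{SummarizedExperiment}; coordinates live in \code{colData}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}; required colData
#'   columns are \code{array_row}, \code{array_col}, \code{px_x},
#'   \code{px_y}.
#' @aliases SpatialSlide-class
#' @exportClass SpatialSlide
setClass("SpatialSlide", contains = "SummarizedExperiment")

setValidity("SpatialSlide", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("array_row", "array_col", "px_x", "px_y")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (ncol(object) >= 1L) {
    for (nm in need)
      if (!is.numeric(cd[[nm]]) || anyNA(cd[[nm]]))
        return(paste("colData column", nm, "must be numeric without NA"))
    if (anyDuplicated(paste(cd$px_x, cd$px_y, sep = "_")))
      return("two spots share identical pixel centers")
  }
  vk <- S4Vectors::metadata(object)$value_kind
  if (!is.null(vk) && !vk %in% .VALUE_KINDS)
    return("value_kind must be raw_counts or lognorm")
  tp <- S4Vectors::metadata(object)$truth_props
  if (!is.null(tp) && nrow(tp) != ncol(object))
    return("truth_props must have one row per spot")
  TRUE
})

#' Construct a SpatialSlide
#'
#' @param counts Genes x spots numeric matrix (rownames = genes, colnames =
#'   spot barcodes).
#' @param positions data.frame with columns \code{barcode}, \code{array_row},
#'   \code{array_col}, \code{px_x}, \code{px_y}; must cover every expression
#'   column (extra rows are dropped).
#' @param valueKind "raw_counts" or "lognorm".
#' @param truthRegion Optional per-spot ground-truth labels
#'   (Mal/Bdy/nMal), named by barcode or in column order.
#' @param truthProps Optional spots x cell-type proportion matrix.
#' @return A \linkS4class{SpatialSlide}.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' pos <- data.frame(barcode = paste0("s", 1:4), array_row = c(0, 0, 1, 1),
#'                   array_col = c(0, 1, 0, 1), px_x = c(0, 1, 0.5, 1.5),
#'                   px_y = c(0, 0, 0.866, 0.866))
#' sl <- SpatialSlide(m, pos)
#' @export
SpatialSlide <- function(counts, positions,
                         valueKind = c("raw_counts", "lognorm"),
                         truthRegion = NULL, truthProps = NULL) {
  valueKind <- match.arg(valueKind)
  .check_expr_matrix(counts, valueKind)
  if (!all(c("barcode", "array_row", "array_col", "px_x", "px_y") %in%
           colnames(positions)))
    hxStop("positions needs columns barcode, array_row, array_col, px_x, px_y")
  idx <- match(colnames(counts), positions$barcode)
  if (anyNA(idx))
    hxStop("barcodes missing from positions: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(
    array_row = as.numeric(positions$array_row[idx]),
    array_col = as.numeric(positions$array_col[idx]),
    px_x = as.numeric(positions$px_x[idx]),
    px_y = as.numeric(positions$px_y[idx]),
    row.names = colnames(counts))
  if (!is.null(truthRegion)) {
    if (!is.null(names(truthRegion)))
      truthRegion <- truthRegion[colnames(counts)]
    cd$truth_region <- as.character(truthRegion)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(counts), valueKind), colData = cd)
  S4Vectors::metadata(se)$value_kind <- valueKind
  if (!is.null(truthProps)) {
    truthProps <- truthProps[colnames(counts), , drop = FALSE]
    S4Vectors::metadata(se)$truth_props <- truthProps
  }
  methods::new("SpatialSlide", se)
}

#' @describeIn SpatialSlide Spot center coordinates as a data.frame
#'   (barcode, array_row, array_col, px_x, px_y).
#' @param x A SpatialSlide.
#' @export
spotCoords <- function(x) {
  stopifnot(methods::is(x, "SpatialSlide"))
  cd <- SummarizedExperiment::colData(x)
  data.frame(barcode = colnames(x), array_row = cd$array_row,
             array_col = cd$array_col, px_x = cd$px_x, px_y = cd$px_y,
             stringsAsFactors = FALSE)
}

#' @describeIn SpatialSlide Ground-truth region labels (or NULL).
#' @export
truthRegion <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("truth_region" %in% colnames(cd))
    stats::setNames(cd$truth_region, colnames(x)) else NULL
}

#' @describeIn SpatialSlide Ground-truth spot cell-type proportions (or NULL).
#' @export
truthProps <- function(x) S4Vectors::metadata(x)$truth_props

setMethod("show", "SpatialSlide", function(object) {
  cat(sprintf("SpatialSlide: %d genes x %d spots (%s)\n",
              nrow(object), ncol(object),
              S4Vectors::metadata(object)$value_kind))
  tr <- truthRegion(object)
  if (!is.null(tr)) {
    tab <- table(factor(tr, levels = c("Mal", "Bdy", "nMal")))
    cat("truth regions:", paste(names(tab), tab, sep = "=", collapse = " "),
        "\n")
  }
})

#' RegionAssignment: per-spot tumor-region labels
#'
#' Result of tumor-boundary delineation: each spot carries exactly one label
#' in {Mal, Bdy, nMal} and the extrapolation layer at which the label was
#' fixed (0 = malignant core seed).
#'
#' @slot spot_id character, spot barcodes.
#' @slot label factor with levels Mal, Bdy, nMal.
#' @slot layer integer, extrapolation layer per spot.
#' @aliases RegionAssignment-class
#' @exportClass RegionAssignment
setClass("RegionAssignment",
         representation(spot_id = "character", label = "factor",
                        layer = "integer"))

setValidity("RegionAssignment", function(object) {
  n <- length(object@spot_id)
  if (length(object@label) != n || length(object@layer) != n)
    return("spot_id, label, layer must have equal length")
  if (anyDuplicated(object@spot_id))
    return("every spot must be labeled exactly once")
  if (!identical(levels(object@label), c("Mal", "Bdy", "nMal")))
    return("label levels must be Mal, Bdy, nMal")
  if (anyNA(object@label) || anyNA(object@layer))
    return("labels and layers must be complete")
  if (any(object@layer == 0L & object@label != "Mal"))
    return("layer-0 (core) spots must be labeled Mal")
  TRUE
})

#' Construct a RegionAssignment
#'
#' @param spotId Character spot barcodes.
#' @param label Labels in {Mal, Bdy, nMal}.
#' @param layer Integer extrapolation layer per spot (0 for core).
#' @return A \linkS4class{RegionAssignment}.
#' @export
RegionAssignment <- function(spotId, label, layer) {
  methods::new("RegionAssignment", spot_id = as.character(spotId),
               label = factor(as.character(label),
                              levels = c("Mal", "Bdy", "nMal")),
               layer = as.integer(layer))
}

#' @describeIn RegionAssignment Labels as a named factor.
#' @param x A RegionAssignment.
#' @export
regionLabels <- function(x) {
  stopifnot(methods::is(x, "RegionAssignment"))
  stats::setNames(x@label, x@spot_id)
}

#' @describeIn RegionAssignment Extrapolation layers as a named integer vector.
#' @export
regionLayers <- function(x) {
  stopifnot(methods::is(x, "RegionAssignment"))
  stats::setNames(x@layer, x@spot_id)
}

#' @describeIn RegionAssignment As a data.frame (barcode, label, layer).
#' @export
regionTable <- function(x) {
  stopifnot(methods::is(x, "RegionAssignment"))
  data.frame(barcode = x@spot_id, label = as.character(x@label),
             layer = x@layer, stringsAsFactors = FALSE)
}

setMethod("show", "RegionAssignment", function(object) {
  tab <- table(object@label)
  cat(sprintf("RegionAssignment: %d spots (%s), %d extrapolation layer(s)\n",
              length(object@spot_id),
              paste(names(tab), tab, sep = "=", collapse = " "),
              max(object@layer)))
})
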