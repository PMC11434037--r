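#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats sd quantile median rnbinom runif rbinom rexp rnorm
#'   wilcox.test fisher.test cor p.adjust pchisq pf pt lm anova setNames
#'   complete.cases
#' @importFrom utils read.table write.table head
NULL

## minimal stderr logger; every stochastic operation logs its seed through here
.hx_log_level <- new.env(parent = emptyenv())
.hx_log_level$level <- "INFO"

.level_rank <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Set the package log level
#'
#' @param level One of "DEBUG", "INFO", "WARN", "ERROR".
#' @return The previous level, invisibly.
#' @export
hxLogLevel <- function(level = c("INFO", "DEBUG", "WARN", "ERROR")) {
  level <- match.arg(level)
  old <- .hx_log_level$level
  .hx_log_level$level <- level
  invisible(old)
}

hxLog <- function(..., level = "INFO") {
  if (.level_rank[[level]] >= .level_rank[[.hx_log_level$level]]) {
    message(sprintf("%s [hypoxiaTME] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

hxWarn <- function(...) warning(paste0(...), call. = FALSE)

hxStop <- function(...) stop(paste0(...), call. = FALSE)

## value_kind handling ------------------------------------------------------

.VALUE_KINDS <- c("raw_counts", "lognorm")

.check_expr_matrix <- function(values, value_kind) {
  if (!is.matrix(values) || !is.numeric(values))
    hxStop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    hxStop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    hxStop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    hxStop("duplicate sample identifiers in expression matrix")
  if (anyNA(values) || any(!is.finite(values)))
    hxStop("expression matrix contains missing or non-finite values")
  if (any(values < 0))
    hxStop("expression values must be non-negative")
  if (identical(value_kind, "raw_counts") &&
      any(abs(values - round(values)) > 1e-8))
    hxStop("raw_counts matrix must hold non-negative integers")
  invisible(TRUE)
}

#' Construct an expression matrix container
#'
#' Wraps a genes x samples numeric matrix in a
#' \linkS4class{SummarizedExperiment} whose metadata records whether values
#' are raw counts or log-normalized, enforcing unique identifiers,
#' non-negativity, and integrality of counts.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples/cells/spots in columns (colnames = identifiers).
#' @param valueKind Either "raw_counts" or "lognorm".
#' @return A \code{SummarizedExperiment} with one assay named after
#'   \code{valueKind}.
#' @examples
#' m <- matrix(0:5, nrow = 2, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' em <- ExpressionMatrix(m, "raw_counts")
#' valueKind(em)
#' @export
ExpressionMatrix <- function(values, valueKind = c("raw_counts", "lognorm")) {
  valueKind <- match.arg(valueKind)
  .check_expr_matrix(values, valueKind)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(values), valueKind))
  S4Vectors::metadata(se)$value_kind <- valueKind
  se
}

#' Value kind of an expression container
#'
#' @param x A \code{SummarizedExperiment} built by \code{ExpressionMatrix()}
#'   or \code{SpatialSlide()}, or a plain matrix (returns NA).
#' @return "raw_counts", "lognorm", or NA.
#' @export
valueKind <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    vk <- S4Vectors::metadata(x)$value_kind
    if (is.null(vk)) NA_character_ else vk
  } else {
    NA_character_
  }
}

#' Extract the expression values of a container as a base matrix
#'
#' @param x A \code{SummarizedExperiment} (first assay is taken) or a matrix.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
exprValues <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(as.matrix(SummarizedExperiment::assay(x, 1L)))
  if (is.matrix(x)) return(x)
  hxStop("expected a SummarizedExperiment or a matrix")
}

#' Log-normalize a count matrix
#'
#' Counts-per-10k per column followed by log1p, the convention used for all
#' normalized values in this package.
#'
#' @param x Count container (\code{SummarizedExperiment} or matrix).
#' @return If given a \code{SummarizedExperiment}, one with an added
#'   "lognorm" assay and value_kind switched to lognorm; otherwise the
#'   normalized matrix.
#' @export
logNormalize <- function(x) {
  m <- exprValues(x)
  cs <- colSums(m)
  cs[cs == 0] <- 1           # all-zero column stays all-zero
  ln <- log1p(sweep(m, 2L, cs, "/") * 1e4)
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "lognorm", withDimnames = FALSE) <- ln
    S4Vectors::metadata(x)$value_kind <- "lognorm"
    x
  } else {
    ln
  }
}

## return the lognorm view of any expression input
.lognorm_values <- function(x) {
  m <- exprValues(x)
  vk <- valueKind(x)
  if (identical(vk, "lognorm")) return(m)
  if (identical(vk, "raw_counts")) return(logNormalize(m))
  ## plain matrix: treat integer-valued non-negative matrices as counts
  if (all(m >= 0) && all(abs(m - round(m)) < 1e-8) && max(m) > 50)
    return(logNormalize(m))
  m
}

.seed_log <- function(op, seed) {
  hxLog(sprintf("%s: seed = %d", op, as.integer(seed)))
}

## restore RNG state on exit so generators are pure functions of their params
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
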