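## Immunophenoscore (IPS): sum over four immune categories (effector cells,
## suppressor cells, MHC molecules, checkpoints/immunomodulators) of
## averaged +/-1-weighted sample Z-scores. Higher = more immunogenic.

.IPS_CATEGORIES <- c("effector_cells", "suppressor_cells", "mhc",
                     "checkpoints")

.validate_ips_config <- function(config) {
  if (!identical(sort(names(config$categories)), sort(.IPS_CATEGORIES)))
    hxStop("IPS config must define categories: ",
           paste(.IPS_CATEGORIES, collapse = ", "))
  fixed <- c(acCD4 = 1, acCD8 = 1, TemCD4 = 1, TemCD8 = 1, Tregs = -1,
             MDSCs = -1, ICOS = 1, CD27 = 1, "PD-1" = -1, CTLA4 = -1,
             LAG3 = -1, TIGIT = -1, TIM3 = -1, "PD-L1" = -1, "PD-L2" = -1)
  for (cat in names(config$categories)) {
    for (det in config$categories[[cat]]) {
      if (!det$weight %in% c(-1, 1))
        hxStop("determinant ", det$name, ": weight must be +1 or -1")
      if (!length(det$genes))
        hxStop("determinant ", det$name, ": empty gene list")
      if (det$name %in% names(fixed) && det$weight != fixed[[det$name]])
        hxStop("determinant ", det$name, " must carry weight ",
               fixed[[det$name]])
      if (cat == "mhc" && det$weight != 1)
        hxStop("MHC determinants must carry weight +1")
    }
  }
  invisible(config)
}

#' Default immunophenoscore configuration
#'
#' Reads the packaged configuration
#' (\code{inst/extdata/ips_config.json}): four categories of determinants,
#' each a (metagene) gene list with a +1 or -1 weight. Determinant gene
#' memberships not fixed by the scheme are flagged
#' \code{listed_in_source = false} in the file and are meant to be
#' overridden via \code{loadIPSConfig}.
#'
#' @return Validated IPS configuration list.
#' @export
defaultIPSConfig <- function() {
  path <- system.file("extdata", "ips_config.json", package = "hypoxiaTME",
                      mustWork = TRUE)
  loadIPSConfig(path)
}

#' Load an immunophenoscore configuration from JSON
#'
#' @param path Path to a JSON file with a \code{categories} object mapping
#'   each of effector_cells, suppressor_cells, mhc, checkpoints to a list of
#'   determinants (\code{name}, \code{genes}, \code{weight} in {-1, +1}).
#' @return Validated IPS configuration list.
#' @export
loadIPSConfig <- function(path) {
  config <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .validate_ips_config(config)
}

#' Per-gene, per-sample Z-scores
#'
#' Z-score of each gene across samples (sample standard deviation, n - 1
#' denominator); zero-variance genes get all-zero rows. Requested genes
#' absent from the matrix are dropped with a warning.
#'
#' @param expr Expression container or matrix.
#' @param genes Genes to score (default: all).
#' @return Genes x samples Z matrix.
#' @export
sampleZscores <- function(expr, genes = NULL) {
  m <- exprValues(expr)
  if (ncol(m) < 2L) hxStop("Z-scores need at least 2 samples")
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(m))
    if (length(absent))
      hxWarn("genes absent from matrix, excluded: ",
             paste(absent, collapse = ", "))
    m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Weighted determinant value
#'
#' Mean Z over the determinant's genes (those present in the Z matrix),
#' multiplied by the determinant's +/-1 weight. Returns NULL (with a
#' warning) when no gene matches.
#'
#' @param Z Genes x samples Z matrix from \code{sampleZscores}.
#' @param determinant List with \code{name}, \code{genes}, \code{weight}.
#' @return Named per-sample numeric vector, or NULL.
#' @export
determinantValue <- function(Z, determinant) {
  genes <- intersect(unlist(determinant$genes), rownames(Z))
  if (!length(genes)) {
    hxWarn("determinant ", determinant$name,
           " dropped: no genes matched")
    return(NULL)
  }
  determinant$weight * colMeans(Z[genes, , drop = FALSE])
}

#' Compute the immunophenoscore
#'
#' Each category's value is the mean of its determinants' weighted values;
#' the IPS is the sum of the four category values.
#'
#' @param expr Expression container or matrix (>= 2 samples).
#' @param config IPS configuration (default \code{defaultIPSConfig()}).
#' @return data.frame: sample_id, one column per category, ips.
#' @examples
#' m <- matrix(rlnorm(40), nrow = 4,
#'             dimnames = list(c("CD8A", "FOXP3", "HLA-A", "PDCD1"),
#'                             paste0("s", 1:10)))
#' head(computeIPS(m))
#' @export
computeIPS <- function(expr, config = defaultIPSConfig()) {
  .validate_ips_config(config)
  m <- exprValues(expr)
  if (ncol(m) < 2L) hxStop("IPS needs at least 2 samples")
  all_genes <- unique(unlist(lapply(unlist(config$categories,
                                           recursive = FALSE),
                                    function(d) unlist(d$genes))))
  Z <- sampleZscores(m, all_genes)
  cat_values <- lapply(.IPS_CATEGORIES, function(cat) {
    vals <- Filter(Negate(is.null),
                   lapply(config$categories[[cat]],
                          function(d) determinantValue(Z, d)))
    if (!length(vals))
      hxStop("category ", cat, " has no matched determinant")
    colMeans(do.call(rbind, vals))
  })
  names(cat_values) <- .IPS_CATEGORIES
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  for (cat in .IPS_CATEGORIES) out[[cat]] <- cat_values[[cat]]
  out$ips <- Reduce(`+`, cat_values)
  out
}
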