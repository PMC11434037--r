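## Single-sample signature scoring: a weighted Kolmogorov-Smirnov rank walk
## (ssGSEA-style) for bulk and spot columns, and the mean scaled-expression
## scorer used when columns are single cells.

.HYPOXIA_GENES <- c("ACOT7", "ADM", "ALDOA", "CDKN3", "ENO1", "LDHA", "MIF",
                    "MRPS17", "NDRG1", "P4HA1", "PGAM1", "SLC2A1", "TPI1",
                    "TUBB6", "VEGFA")

.TEX_MARKERS <- c("PDCD1", "LAG3", "HAVCR2", "CD8A", "CD8B", "CD3E",
                  "ENTPD1", "TGAE", "ITGAE", "BATF", "NR4A1")

#' The 15-gene hypoxia signature
#'
#' HIF1A-associated genes used to rank samples, spots, and cells by hypoxic
#' state. Also shipped as \code{inst/extdata/hypoxia_signature.gmt}.
#'
#' @return Character vector of 15 gene symbols.
#' @examples hypoxiaSignature()
#' @export
hypoxiaSignature <- function() .HYPOXIA_GENES

#' Exhausted T-cell (Tex) marker set
#'
#' Inhibitory-receptor and CD8 lineage markers used to call Tex spots. The
#' published marker list spells one integrin "TGAE"; the set carries that
#' spelling together with the standard symbol ITGAE so that whichever is
#' present in a matrix matches.
#'
#' @return Character vector of marker symbols.
#' @export
texSignature <- function() .TEX_MARKERS

#' Rank-based single-sample enrichment score
#'
#' For each sample, genes are ranked within the sample (average ranks for
#' ties, largest expression = rank N) and walked from highest to lowest
#' rank. Signature genes ("hits") contribute increments proportional to
#' rank^\code{weightExponent} (normalized to sum 1); non-signature genes
#' decrement uniformly by 1/(N - Ng). The score is the sum of the running
#' hit-minus-miss difference over all N positions, divided by N. Depends on
#' expression only through within-sample ranks, so any strictly monotone
#' per-sample transformation leaves scores unchanged.
#'
#' @param expr Expression container or genes x samples matrix.
#' @param signature Character vector of gene symbols.
#' @param weightExponent Exponent on the rank weight for hits (default 0.25).
#' @param signatureName Name carried in the result attributes.
#' @return Named numeric score vector (one per sample) with attributes
#'   \code{signature} and \code{method = "rank_enrichment"}.
#' @examples
#' m <- matrix(c(6:1, 1:6), ncol = 2,
#'             dimnames = list(paste0("g", 1:6), c("a", "b")))
#' scoreRankEnrichment(m, c("g1", "g2"))
#' @export
scoreRankEnrichment <- function(expr, signature, weightExponent = 0.25,
                                signatureName = "signature") {
  m <- exprValues(expr)
  sig <- unique(signature)
  matched <- matchSignature(sig, rownames(m), signatureName)
  N <- nrow(m)
  Ng <- length(matched)
  if (Ng < 2L)
    hxStop(signatureName, ": fewer than 2 signature genes matched (", Ng, ")")
  if (Ng >= N)
    hxStop(signatureName, ": signature covers all genes; no misses to walk")
  hit <- rownames(m) %in% matched
  scores <- vapply(seq_len(ncol(m)), function(j) {
    r <- rank(m[, j], ties.method = "average")
    ord <- order(-r)
    hito <- hit[ord]
    w <- (r[ord]^weightExponent) * hito
    w <- w / sum(w)
    miss <- (!hito) / (N - Ng)
    sum(cumsum(w - miss)) / N
  }, numeric(1))
  names(scores) <- colnames(m)
  structure(scores, signature = signatureName, method = "rank_enrichment")
}

#' Mean scaled-expression signature score
#'
#' Each gene is z-scored across samples (sample standard deviation, n - 1
#' denominator; zero-variance genes contribute 0); the score is the mean
#' z-score over the matched signature genes. This is the per-cell scorer
#' used whenever matrix columns are single cells.
#'
#' @inheritParams scoreRankEnrichment
#' @return Named numeric score vector with attributes \code{signature} and
#'   \code{method = "mean_scaled"}.
#' @export
scoreMeanScaled <- function(expr, signature, signatureName = "signature") {
  m <- exprValues(expr)
  matched <- matchSignature(unique(signature), rownames(m), signatureName)
  if (length(matched) < 1L)
    hxStop(signatureName, ": no signature genes matched")
  sub <- m[matched, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  scores <- colMeans(z)
  structure(scores, signature = signatureName, method = "mean_scaled")
}

#' Score several signatures at once
#'
#' @param expr Expression container or matrix.
#' @param signatures Named list of gene-symbol vectors.
#' @param method "rank" (weighted-KS rank walk) or "mean-scaled".
#' @param weightExponent Passed to \code{scoreRankEnrichment}.
#' @return Long data.frame (sample_id, signature, score).
#' @export
scoreSignatures <- function(expr, signatures, method = c("rank", "mean-scaled"),
                            weightExponent = 0.25) {
  method <- match.arg(method)
  stopifnot(length(signatures) >= 1L, !is.null(names(signatures)))
  rows <- lapply(names(signatures), function(nm) {
    s <- if (method == "rank")
      scoreRankEnrichment(expr, signatures[[nm]], weightExponent, nm)
    else scoreMeanScaled(expr, signatures[[nm]], nm)
    data.frame(sample_id = names(s), signature = nm, score = as.numeric(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median split of a score vector
#'
#' Scores strictly above the median are "high"; scores at or below it are
#' "low" (deterministic tie rule).
#'
#' @param scores Named numeric vector.
#' @return Named character vector of "high"/"low" labels.
#' @examples
#' medianSplit(c(a = 1, b = 2, c = 3, d = 4))
#' @export
medianSplit <- function(scores) {
  if (length(scores) < 2L) hxStop("median split needs at least 2 samples")
  if (max(scores) == min(scores))
    hxStop("all scores identical; no median split possible")
  med <- stats::median(scores)
  stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}
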