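## Pseudotime ordering on a 1-D differentiation axis, per-gene trend tests
## (natural-spline F-test), the three-stage cross-dataset TF filter,
## TF-hypoxia correlation classification, and subset-proportion fold
## changes between hypoxia groups.

#' Order cells along a 1-D differentiation axis
#'
#' Cells are projected on the first principal component of log-normalized
#' expression; the axis is oriented so the root-state cells' mean
#' projection is minimal, then min-max rescaled to [0, 1]. Swapping the
#' root to the opposite end of the axis maps pseudotime t to 1 - t.
#'
#' @param expr Expression container or matrix (columns = cells).
#' @param rootLabel Subset label of the root (starting) state.
#' @param labels Named (or column-ordered) character cell labels.
#' @return Named numeric pseudotime in [0, 1].
#' @export
orderPseudotime <- function(expr, rootLabel, labels) {
  m <- .lognorm_values(expr)
  if (ncol(m) < 10L) hxStop("pseudotime ordering needs at least 10 cells")
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- as.character(labels)
  if (!rootLabel %in% labels)
    hxStop("root label '", rootLabel, "' absent from cell labels")
  xc <- m - rowMeans(m)
  sv <- svd(t(xc), nu = 1L, nv = 1L)
  if (sv$d[1L] < 1e-10)
    hxStop("degenerate expression: first principal component is zero")
  proj <- drop(sv$u[, 1L]) * sv$d[1L]
  names(proj) <- colnames(m)
  root <- labels == rootLabel
  if (mean(proj[root]) > mean(proj[!root])) proj <- -proj
  (proj - min(proj)) / (max(proj) - min(proj))
}

#' Test one gene for a trend along pseudotime
#'
#' F-test comparing a natural cubic spline fit (df = 3) of expression on
#' pseudotime against the intercept-only model. Direction is the sign of
#' (mean over the top pseudotime tercile) - (mean over the bottom
#' tercile), "flat" when the difference is below 1e-8. Constant genes get
#' p = 1 and direction "flat". The test depends on pseudotime only through
#' its order, so affine rescalings of pseudotime leave p unchanged.
#'
#' @param exprGene Numeric expression of one gene across cells.
#' @param pseudotime Numeric pseudotime of the same cells.
#' @return List: p_value, direction, start_mean, end_mean.
#' @export
trendTest <- function(exprGene, pseudotime) {
  stopifnot(length(exprGene) == length(pseudotime))
  if (length(exprGene) < 10L) hxStop("trend test needs at least 10 cells")
  qs <- stats::quantile(pseudotime, c(1 / 3, 2 / 3), names = FALSE)
  start_mean <- mean(exprGene[pseudotime <= qs[1L]])
  end_mean <- mean(exprGene[pseudotime >= qs[2L]])
  if (stats::sd(exprGene) == 0)
    return(list(p_value = 1, direction = "flat", start_mean = start_mean,
                end_mean = end_mean))
  fit <- stats::lm(exprGene ~ splines::ns(pseudotime, df = 3))
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]],
                 lower.tail = FALSE)
  diff <- end_mean - start_mean
  direction <- if (abs(diff) < 1e-8) "flat"
               else if (diff > 0) "increasing" else "decreasing"
  list(p_value = p, direction = direction, start_mean = start_mean,
       end_mean = end_mean)
}

#' Trend-test every gene of a matrix along pseudotime
#'
#' Applies \code{trendTest} per gene and corrects p-values across the
#' tested genes by Benjamini-Hochberg.
#'
#' @param expr Expression container or matrix (columns = cells).
#' @param pseudotime Named or column-ordered numeric pseudotime.
#' @param genes Genes to test (default: all).
#' @return data.frame: gene, p_value, q_value, direction, start_mean,
#'   end_mean.
#' @export
trendTestAll <- function(expr, pseudotime, genes = NULL) {
  m <- exprValues(expr)
  if (!is.null(names(pseudotime))) pseudotime <- pseudotime[colnames(m)]
  if (is.null(genes)) genes <- rownames(m)
  genes <- intersect(genes, rownames(m))
  rows <- lapply(genes, function(g) {
    r <- trendTest(m[g, ], pseudotime)
    data.frame(gene = g, p_value = r$p_value, direction = r$direction,
               start_mean = r$start_mean, end_mean = r$end_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("gene", "p_value", "q_value", "direction", "start_mean",
          "end_mean")]
}

#' Three-stage cross-dataset filter for differentiation-related TFs
#'
#' A TF passes within one dataset when its trend is significant (p < 0.05
#' and BH q < 0.05) and its expression is higher at the end state than the
#' start state (end_mean > start_mean; TFs declining along pseudotime are
#' filtered out). A TF is retained when it passes in at least half of all
#' datasets (>= n/2, so ties at exactly half are kept).
#'
#' @param perDatasetResults List of \code{trendTestAll} data.frames, one
#'   per dataset.
#' @param tfList Character vector of TF symbols to consider.
#' @param pThreshold,qThreshold Significance thresholds (default 0.05).
#' @return Character vector of retained TFs, with a \code{counts}
#'   attribute (per-TF number of passing datasets).
#' @export
filterDifferentiationTFs <- function(perDatasetResults, tfList,
                                     pThreshold = 0.05, qThreshold = 0.05) {
  n <- length(perDatasetResults)
  if (!length(tfList)) {
    hxWarn("empty TF list; nothing to filter")
    return(structure(character(), counts = integer()))
  }
  counts <- vapply(tfList, function(tf) {
    sum(vapply(perDatasetResults, function(res) {
      row <- res[res$gene == tf, , drop = FALSE]
      nrow(row) == 1L && row$p_value < pThreshold &&
        row$q_value < qThreshold && row$end_mean > row$start_mean
    }, logical(1)))
  }, integer(1))
  retained <- tfList[counts >= n / 2]
  structure(retained, counts = counts)
}

#' Classify TF-hypoxia correlation within a dataset
#'
#' Spearman correlation of each TF's expression with the per-cell hypoxia
#' score: "positive" when Rs > 0 with p < alpha, "negative" when Rs < 0
#' with p < alpha, otherwise "ns" (constant TFs are "ns").
#'
#' @param tfExpr TFs x cells matrix (or vector for a single TF).
#' @param hypoxiaScores Per-cell hypoxia scores.
#' @param alpha Significance level (default 0.05).
#' @return data.frame: tf, rho, p, class.
#' @export
classifyTfHypoxia <- function(tfExpr, hypoxiaScores, alpha = 0.05) {
  if (is.null(dim(tfExpr)))
    tfExpr <- matrix(tfExpr, nrow = 1L,
                     dimnames = list("TF", names(tfExpr)))
  if (!is.null(names(hypoxiaScores)) && !is.null(colnames(tfExpr)))
    hypoxiaScores <- hypoxiaScores[colnames(tfExpr)]
  rows <- lapply(rownames(tfExpr), function(tf) {
    x <- tfExpr[tf, ]
    if (stats::sd(x) == 0 || stats::sd(hypoxiaScores) == 0)
      return(data.frame(tf = tf, rho = NA_real_, p = NA_real_,
                        class = "ns", stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, hypoxiaScores,
                                           method = "spearman"))
    cls <- if (ct$p.value < alpha && ct$estimate > 0) "positive"
           else if (ct$p.value < alpha && ct$estimate < 0) "negative"
           else "ns"
    data.frame(tf = tf, rho = unname(ct$estimate), p = ct$p.value,
               class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize TF-hypoxia classes across datasets
#'
#' Per-TF proportion of datasets falling in each class (the input for a
#' class-proportion pie chart).
#'
#' @param perDatasetClasses List of \code{classifyTfHypoxia} data.frames.
#' @return data.frame: tf, positive, negative, ns (proportions).
#' @export
summarizeTfClasses <- function(perDatasetClasses) {
  tfs <- unique(unlist(lapply(perDatasetClasses, `[[`, "tf")))
  rows <- lapply(tfs, function(tf) {
    cls <- vapply(perDatasetClasses, function(df) {
      r <- df[df$tf == tf, "class"]
      if (length(r)) r else NA_character_
    }, character(1))
    cls <- cls[!is.na(cls)]
    data.frame(tf = tf,
               positive = mean(cls == "positive"),
               negative = mean(cls == "negative"),
               ns = mean(cls == "ns"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subset-proportion fold change between hypoxia groups
#'
#' Per cell subset: FC = (proportion in the hypoxia-high group) /
#' (proportion in the hypoxia-low group), with \code{pseudocount} cells
#' added to every subset count before forming proportions (so subsets
#' absent from one group stay finite).
#'
#' @param subsetLabels Character subset label per cell.
#' @param groupLabels Character "high"/"low" hypoxia group per cell.
#' @param pseudocount Cells added to each subset count (default 0.5).
#' @return data.frame: subset, n_high, n_low, prop_high, prop_low, fc,
#'   log2_fc.
#' @export
subsetFoldChange <- function(subsetLabels, groupLabels, pseudocount = 0.5) {
  stopifnot(length(subsetLabels) == length(groupLabels))
  if (!any(groupLabels == "high") || !any(groupLabels == "low"))
    hxStop("both hypoxia groups must be non-empty")
  subsets <- sort(unique(subsetLabels))
  k <- length(subsets)
  n_high <- vapply(subsets, function(s)
    sum(subsetLabels == s & groupLabels == "high"), numeric(1))
  n_low <- vapply(subsets, function(s)
    sum(subsetLabels == s & groupLabels == "low"), numeric(1))
  prop_high <- (n_high + pseudocount) /
    (sum(groupLabels == "high") + k * pseudocount)
  prop_low <- (n_low + pseudocount) /
    (sum(groupLabels == "low") + k * pseudocount)
  fc <- prop_high / prop_low
  data.frame(subset = subsets, n_high = n_high, n_low = n_low,
             prop_high = prop_high, prop_low = prop_low, fc = fc,
             log2_fc = log2(fc), stringsAsFactors = FALSE)
}
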