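## Spot deconvolution against reference cell-type signatures (non-negative
## least squares over marker genes), ALCAM-high macrophage gating, Tex spot
## calling, and first-outer-circle co-localization testing.

#' Build a reference signature matrix from labeled single cells
#'
#' Per cell type: mean of linear-scale normalized expression, restricted to
#' the \code{topK} most type-specific genes by log fold change against the
#' remaining cells.
#'
#' @param scExpr Single-cell expression container or matrix.
#' @param cellLabels Named (or column-ordered) character vector of cell-type
#'   labels.
#' @param topK Marker genes retained per type.
#' @param minCells Minimum cells required per type.
#' @return List of class \code{ReferenceSignatureMatrix}: \code{profiles}
#'   (genes x types, linear scale) and \code{markers} (named list).
#' @export
buildReference <- function(scExpr, cellLabels, topK = 50L, minCells = 10L) {
  ln <- .lognorm_values(scExpr)
  m <- expm1(ln)                       # linear-scale normalized expression
  if (!is.null(names(cellLabels))) cellLabels <- cellLabels[colnames(m)]
  cellLabels <- as.character(cellLabels)
  stopifnot(length(cellLabels) == ncol(m))
  types <- sort(unique(cellLabels))
  if (length(types) < 2L) hxStop("need at least 2 cell types")
  counts <- table(cellLabels)
  small <- names(counts)[counts < minCells]
  if (length(small))
    hxStop("cell type(s) with fewer than ", minCells, " cells: ",
           paste(small, collapse = ", "))
  log_means <- vapply(types, function(ty)
    rowMeans(ln[, cellLabels == ty, drop = FALSE]), numeric(nrow(ln)))
  markers <- lapply(types, function(ty) {
    lfc <- log_means[, ty] - rowMeans(log_means[, types != ty, drop = FALSE])
    rownames(ln)[order(lfc, decreasing = TRUE)[seq_len(min(topK, nrow(ln)))]]
  })
  names(markers) <- types
  profiles <- vapply(types, function(ty)
    rowMeans(m[, cellLabels == ty, drop = FALSE]), numeric(nrow(m)))
  rownames(profiles) <- rownames(m)
  structure(list(profiles = profiles, markers = markers),
            class = "ReferenceSignatureMatrix")
}

#' @export
print.ReferenceSignatureMatrix <- function(x, ...) {
  cat(sprintf("ReferenceSignatureMatrix: %d genes x %d types (%s)\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(colnames(x$profiles), collapse = ", ")))
  invisible(x)
}

#' Deconvolve spot cell-type composition by non-negative least squares
#'
#' Per spot, solves min || y - S w ||^2 with w >= 0 on linear-scale
#' normalized expression over the union of the reference marker genes, and
#' normalizes w to proportions. Spots with an all-zero solution (or all-zero
#' expression over the marker genes) get missing proportions.
#'
#' @param slide \linkS4class{SpatialSlide} or expression container.
#' @param ref A \code{ReferenceSignatureMatrix}.
#' @return Spots x types matrix of proportions (rows summing to 1, or NA).
#' @export
deconvolveSpots <- function(slide, ref) {
  stopifnot(inherits(ref, "ReferenceSignatureMatrix"))
  ln <- .lognorm_values(slide)
  y_all <- expm1(ln)
  genes <- intersect(unique(unlist(ref$markers)), rownames(y_all))
  for (ty in colnames(ref$profiles)) {
    shared <- intersect(ref$markers[[ty]], genes)
    if (length(shared) < 2L)
      hxStop("fewer than 2 shared marker genes for cell type ", ty)
  }
  S <- ref$profiles[genes, , drop = FALSE]
  Y <- y_all[genes, , drop = FALSE]
  props <- matrix(NA_real_, ncol(Y), ncol(S),
                  dimnames = list(colnames(Y), colnames(S)))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (all(y == 0)) next
    w <- pracma::lsqnonneg(S, y)$x
    if (sum(w) > 0) props[j, ] <- w / sum(w)
  }
  props
}

#' Gate ALCAM-high and ALCAM-low macrophage spots
#'
#' Macrophage-containing spots (macrophage proportion >=
#' \code{macThreshold}) are split at the median of log-normalized ALCAM
#' expression; ties at the median go low.
#'
#' @param slide \linkS4class{SpatialSlide}.
#' @param props Spots x types proportion matrix from
#'   \code{deconvolveSpots}.
#' @param macThreshold Minimum macrophage proportion.
#' @param gene Gating gene (default "ALCAM").
#' @param macType Column of \code{props} holding macrophages.
#' @return Named character vector in {alcam_high_mac, alcam_low_mac, none}.
#' @export
gateAlcamMacrophages <- function(slide, props, macThreshold = 0.1,
                                 gene = "ALCAM", macType = "Macrophage") {
  ln <- .lognorm_values(slide)
  if (!gene %in% rownames(ln)) hxStop("gene ", gene, " absent from slide")
  if (!macType %in% colnames(props))
    hxStop("cell type ", macType, " absent from proportions")
  props <- props[colnames(ln), , drop = FALSE]
  labels <- stats::setNames(rep("none", ncol(ln)), colnames(ln))
  mac <- !is.na(props[, macType]) & props[, macType] >= macThreshold
  if (!any(mac)) {
    hxWarn("no spot passes the macrophage proportion threshold")
    return(labels)
  }
  expr <- ln[gene, mac]
  if (max(expr) == min(expr)) {
    hxWarn("ALCAM expression constant across macrophage spots; all gated low")
    labels[mac] <- "alcam_low_mac"
    return(labels)
  }
  split <- medianSplit(expr)
  labels[names(split)] <- ifelse(split == "high", "alcam_high_mac",
                                 "alcam_low_mac")
  labels
}

#' Identify exhausted T-cell (Tex) spots
#'
#' Tex score per spot by the rank-walk scorer on the Tex marker set; Tex
#' spots have score at or above the \code{scoreQuantile} quantile, and
#' (when proportions are supplied) a T-cell proportion of at least
#' \code{minTProportion}.
#'
#' @param slide \linkS4class{SpatialSlide}.
#' @param texMarkers Marker set (default \code{texSignature()}).
#' @param props Optional proportions from \code{deconvolveSpots}.
#' @param scoreQuantile Tex-score quantile for spot calling.
#' @param tTypes Column(s) of \code{props} counting as T cells.
#' @param minTProportion Minimum summed T-cell proportion.
#' @return Character vector of Tex spot barcodes.
#' @export
identifyTexSpots <- function(slide, texMarkers = texSignature(),
                             props = NULL, scoreQuantile = 0.75,
                             tTypes = c("TexT", "EffectorT", "Tcell"),
                             minTProportion = 0.05) {
  m <- exprValues(slide)
  matched <- texMarkers[texMarkers %in% rownames(m)]
  if (length(matched) < 3L)
    hxStop("fewer than 3 Tex markers matched (", length(matched), ")")
  score <- scoreRankEnrichment(slide, matched, signatureName = "Tex")
  thr <- stats::quantile(score, scoreQuantile, names = FALSE)
  tex <- names(score)[score >= thr]
  ## all-zero marker expression gives tied minimal scores; require signal
  zero_sig <- colSums(m[matched, , drop = FALSE]) == 0
  tex <- setdiff(tex, colnames(m)[zero_sig])
  if (!is.null(props)) {
    tt <- intersect(tTypes, colnames(props))
    if (length(tt)) {
      tp <- rowSums(props[, tt, drop = FALSE])
      pass <- rownames(props)[!is.na(tp) & tp >= minTProportion]
      tex <- intersect(tex, pass)
    }
  }
  tex
}

#' First-outer-circle co-localization of Tex and ALCAM-high macrophage spots
#'
#' A Tex spot is colocalized when it is itself an ALCAM-high macrophage
#' spot (the two populations share the spot) or when any of its lattice
#' neighbors (the first outer circle) is one.
#'
#' @param texSpots Character vector of Tex spot barcodes.
#' @param alcamHighSpots Character vector of ALCAM-high macrophage spot
#'   barcodes.
#' @param graph A \code{NeighborGraph} covering all listed spots.
#' @return data.frame (spot, flag in {colocalized, not_colocalized},
#'   partners as comma-separated barcodes).
#' @export
colocalize <- function(texSpots, alcamHighSpots, graph) {
  stopifnot(inherits(graph, "NeighborGraph"))
  unknown <- setdiff(c(texSpots, alcamHighSpots), graph$spot_ids)
  if (length(unknown))
    hxStop("spots absent from graph: ", paste(unknown, collapse = ", "))
  rows <- lapply(texSpots, function(s) {
    partners <- intersect(c(s, graph$adjacency[[s]]), alcamHighSpots)
    data.frame(spot = s,
               flag = if (length(partners)) "colocalized"
                      else "not_colocalized",
               partners = paste(partners, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(spot = character(), flag = character(),
                      partners = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Compare exhaustion scores between colocalized and non-colocalized Tex
#' spots
#'
#' Two-sided Wilcoxon rank-sum test (exact when group sizes allow and no
#' ties are present) plus group medians.
#'
#' @param exhaustionScores Named numeric exhaustion-score vector.
#' @param coloc data.frame from \code{colocalize}.
#' @return List: statistic, p, median_colocalized, median_not, n per group.
#' @export
compareColocalizedExhaustion <- function(exhaustionScores, coloc) {
  sc <- exhaustionScores[coloc$spot]
  grp <- coloc$flag
  n1 <- sum(grp == "colocalized")
  n2 <- sum(grp == "not_colocalized")
  if (n1 < 2L || n2 < 2L)
    hxStop("need >= 2 spots per group (colocalized = ", n1,
           ", not_colocalized = ", n2, ")")
  a <- sc[grp == "colocalized"]
  b <- sc[grp == "not_colocalized"]
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = (n1 + n2) <= 25 && !anyDuplicated(sc))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_colocalized = stats::median(a),
       median_not = stats::median(b), n_colocalized = n1,
       n_not = n2)
}

#' Region enrichment of a spot label set
#'
#' Per region: observed/expected ratio of labeled spots and a Fisher exact
#' p-value on the labeled x in-region 2x2 table.
#'
#' @param labeledSpots Character vector of labeled spot barcodes.
#' @param regions A \linkS4class{RegionAssignment}.
#' @return data.frame (region, n_region, n_labeled, ratio, p).
#' @export
regionEnrichment <- function(labeledSpots, regions) {
  stopifnot(methods::is(regions, "RegionAssignment"))
  lab <- regionLabels(regions)
  total <- length(lab)
  labeled <- names(lab) %in% labeledSpots
  n_lab <- sum(labeled)
  rows <- lapply(c("Mal", "Bdy", "nMal"), function(r) {
    in_r <- lab == r
    obs <- sum(labeled & in_r)
    expected <- n_lab * sum(in_r) / total
    ratio <- if (n_lab == 0L) 0 else if (expected > 0) obs / expected
             else NA_real_
    p <- if (n_lab == 0L) 1 else
      stats::fisher.test(matrix(c(obs, sum(in_r) - obs, n_lab - obs,
                                  total - sum(in_r) - (n_lab - obs)),
                                nrow = 2L))$p.value
    data.frame(region = r, n_region = sum(in_r), n_labeled = obs,
               ratio = ratio, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
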