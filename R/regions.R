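## Spatial-region machinery: QC filters, the hexagonal neighbor graph,
## malignant-core identification, layer-wise tumor-boundary extrapolation,
## and region-wise score summaries.

#' QC-filter a spatial slide
#'
#' Genes are kept when detected (count > 0) in at least 5 capture spots and
#' carrying a total count of at least 100; spots are kept when they contain
#' at least 500 total transcripts. The gene filter is applied first; spot
#' totals are computed on the filtered gene set.
#'
#' @param slide A raw-counts \linkS4class{SpatialSlide}.
#' @param minSpotsPerGene,minGeneTotal,minSpotTotal The three thresholds.
#' @return The filtered \linkS4class{SpatialSlide}.
#' @export
qcFilter <- function(slide, minSpotsPerGene = 5L, minGeneTotal = 100,
                     minSpotTotal = 500) {
  stopifnot(methods::is(slide, "SpatialSlide"))
  if (!identical(valueKind(slide), "raw_counts"))
    hxStop("qcFilter expects a raw_counts slide")
  m <- exprValues(slide)
  keep_genes <- rowSums(m > 0) >= minSpotsPerGene &
    rowSums(m) >= minGeneTotal
  if (!any(keep_genes))
    hxStop("no genes pass QC (0 of ", nrow(m), ")")
  m2 <- m[keep_genes, , drop = FALSE]
  keep_spots <- colSums(m2) >= minSpotTotal
  if (!any(keep_spots))
    hxStop("no spots pass QC (0 of ", ncol(m), ")")
  hxLog(sprintf("qcFilter: %d/%d genes, %d/%d spots retained",
                sum(keep_genes), nrow(m), sum(keep_spots), ncol(m)))
  out <- slide[keep_genes, keep_spots]
  tp <- S4Vectors::metadata(out)$truth_props
  if (!is.null(tp))
    S4Vectors::metadata(out)$truth_props <- tp[colnames(out), , drop = FALSE]
  out
}

#' Build the spot neighbor graph
#'
#' Spacing is the minimal pairwise center-to-center distance; two spots are
#' neighbors when their distance is at most \code{scale * spacing}. On a
#' pure hexagonal lattice with the default scale this yields the six
#' immediate neighbors.
#'
#' @param slide A \linkS4class{SpatialSlide}, or a data.frame with columns
#'   barcode, px_x, px_y.
#' @param scale Multiplier on the spacing for the adjacency threshold.
#' @return An object of class \code{NeighborGraph}: list with
#'   \code{spot_ids}, \code{adjacency} (named list of neighbor barcodes),
#'   and \code{spacing}.
#' @export
buildNeighborGraph <- function(slide, scale = 1.2) {
  coords <- if (methods::is(slide, "SpatialSlide")) spotCoords(slide)
            else slide
  stopifnot(all(c("barcode", "px_x", "px_y") %in% colnames(coords)))
  n <- nrow(coords)
  if (n < 2L) hxStop("need at least 2 spots with distinct centers")
  d <- as.matrix(stats::dist(coords[, c("px_x", "px_y")]))
  diag(d) <- Inf
  spacing <- min(d)
  if (spacing == 0) hxStop("coincident spot centers")
  adj <- lapply(seq_len(n), function(i)
    coords$barcode[which(d[i, ] <= scale * spacing)])
  names(adj) <- coords$barcode
  structure(list(spot_ids = coords$barcode, adjacency = adj,
                 spacing = spacing),
            class = "NeighborGraph")
}

#' @export
print.NeighborGraph <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf("NeighborGraph: %d spots, spacing %.4g, degree %d-%d\n",
              length(x$spot_ids), x$spacing, min(deg), max(deg)))
  invisible(x)
}

.graph_igraph <- function(graph, ids = graph$spot_ids) {
  edges <- do.call(rbind, lapply(ids, function(s) {
    nb <- intersect(graph$adjacency[[s]], ids)
    if (length(nb)) cbind(s, nb) else NULL
  }))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (!is.null(edges)) {
    edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
    if (nrow(edges))
      g <- igraph::add_edges(g, t(matrix(match(edges, ids),
                                         ncol = 2)))
  }
  g
}

#' Identify the malignant core of a slide
#'
#' Scores each spot with the malignancy signature (rank-walk scorer), keeps
#' spots at or above the \code{coreQuantile} score quantile, and restricts
#' to the largest connected component of the neighbor graph.
#'
#' @param slide A QC-filtered \linkS4class{SpatialSlide}.
#' @param malignancySignature Character vector of malignancy program genes.
#' @param graph A \code{NeighborGraph} for the slide (built if NULL).
#' @param coreQuantile Score quantile defining candidate core spots.
#' @return Character vector of core spot barcodes.
#' @export
identifyMalignantCore <- function(slide, malignancySignature, graph = NULL,
                                  coreQuantile = 0.90) {
  stopifnot(methods::is(slide, "SpatialSlide"))
  if (is.null(graph)) graph <- buildNeighborGraph(slide)
  score <- scoreRankEnrichment(slide, malignancySignature,
                               signatureName = "malignancy")
  thr <- stats::quantile(score, coreQuantile, names = FALSE)
  cand <- names(score)[score >= thr]
  g <- .graph_igraph(graph, cand)
  comp <- igraph::components(g)
  if (comp$no == 0L || length(cand) == 0L)
    hxStop("empty malignant core; lower coreQuantile")
  biggest <- which.max(comp$csize)
  core <- cand[comp$membership == biggest]
  if (!length(core))
    hxStop("empty malignant core after connectivity restriction; ",
           "lower coreQuantile")
  hxLog(sprintf("malignant core: %d spot(s) (quantile %.2f)", length(core),
                coreQuantile))
  core
}

## top-k PCA embedding of spots: log-normalized, per-gene centered,
## deterministic SVD with the largest-magnitude loading of each component
## made positive. Components below the Gavish-Donoho optimal hard
## threshold for singular values (estimated from the spectrum median) are
## treated as noise and dropped, so distances are not dominated by a
## noise floor accumulated over signal-free dimensions.
.spot_pca <- function(slide, k = 10L) {
  ln <- .lognorm_values(slide)
  xc <- ln - rowMeans(ln)
  sv <- svd(t(xc))                       # spots x genes
  beta <- min(dim(xc)) / max(dim(xc))
  omega <- 0.56 * beta^3 - 0.95 * beta^2 + 1.82 * beta + 1.43
  tau <- omega * stats::median(sv$d)
  k <- min(k, max(1L, sum(sv$d > tau)), sum(sv$d > 1e-10))
  if (k < 1L) hxStop("degenerate expression matrix: no principal components")
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  emb <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                 diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  rownames(emb) <- colnames(slide)
  emb
}

#' Delineate the tumor boundary by layer-wise extrapolation
#'
#' Starting from the malignant core (layer 0), each extrapolation layer
#' visits the unlabeled neighbors of the current Mal set: a spot becomes Mal
#' when its distance to the core centroid in the slide's top-10 principal
#' component space is at most the \code{centroidQuantile} quantile of the
#' core spots' own distances to that centroid, and Bdy otherwise.
#' Extrapolation completes when a layer adds no Mal spot (those final
#' frontier spots stay Bdy) or \code{maxLayers} is reached; all remaining
#' spots are nMal.
#'
#' @param slide A QC-filtered \linkS4class{SpatialSlide}.
#' @param graph A \code{NeighborGraph} for the slide.
#' @param core Character vector of core spot barcodes.
#' @param centroidQuantile Acceptance quantile on core-to-centroid
#'   distances.
#' @param maxLayers Cap on extrapolation layers (default: the lattice
#'   diameter in spacing units).
#' @param nPCs Number of principal components for the expression-space
#'   distance.
#' @return A \linkS4class{RegionAssignment}.
#' @export
delineateBoundary <- function(slide, graph = NULL, core,
                              centroidQuantile = 0.95, maxLayers = NULL,
                              nPCs = 10L) {
  stopifnot(methods::is(slide, "SpatialSlide"), length(core) >= 1L)
  if (is.null(graph)) graph <- buildNeighborGraph(slide)
  ids <- colnames(slide)
  if (!all(core %in% ids)) hxStop("core contains unknown spot barcodes")
  if (is.null(maxLayers)) {
    co <- spotCoords(slide)
    diam <- max(stats::dist(co[, c("px_x", "px_y")]))
    maxLayers <- max(1L, ceiling(diam / graph$spacing))
  }
  if (setequal(core, ids)) {
    hxWarn("core covers every spot; no boundary exists")
    return(RegionAssignment(ids, rep("Mal", length(ids)),
                            ifelse(ids %in% core, 0L, 0L)))
  }
  emb <- .spot_pca(slide, k = nPCs)

  label <- stats::setNames(rep(NA_character_, length(ids)), ids)
  layer <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  label[core] <- "Mal"
  layer[core] <- 0L

  mal_set <- core
  mal_frontier <- core
  k <- 0L
  while (k < maxLayers && length(mal_frontier)) {
    k <- k + 1L
    ## frontier neighbors that are unlabeled, plus provisional Bdy spots
    ## adjacent to the new frontier: a spot rejected at an earlier layer is
    ## re-tested once the Mal centroid has moved toward it, and its Bdy
    ## label only becomes final when extrapolation completes
    cand <- unique(unlist(graph$adjacency[mal_frontier], use.names = FALSE))
    cand <- cand[is.na(label[cand]) |
                   (!is.na(label[cand]) & label[cand] == "Bdy")]
    cand <- setdiff(cand, mal_set)
    if (!length(cand)) break
    ## centroid of the current Mal set; acceptance radius from the core
    ## spots' own spread around it
    centroid <- colMeans(emb[mal_set, , drop = FALSE])
    core_d <- sqrt(rowSums(sweep(emb[core, , drop = FALSE], 2L,
                                 centroid)^2))
    thr <- stats::quantile(core_d, centroidQuantile, names = FALSE)
    cand_d <- sqrt(rowSums(sweep(emb[cand, , drop = FALSE], 2L,
                                 centroid)^2))
    accept <- cand_d <= thr
    newly <- is.na(label[cand]) | accept
    label[cand[newly]] <- ifelse(accept[newly], "Mal", "Bdy")
    layer[cand[newly]] <- k
    mal_frontier <- cand[accept]
    mal_set <- c(mal_set, mal_frontier)
    if (!any(accept)) break
  }
  rest <- is.na(label)
  label[rest] <- "nMal"
  layer[rest] <- k + 1L
  hxLog(sprintf("delineateBoundary: %d layers, Mal=%d Bdy=%d nMal=%d", k,
                sum(label == "Mal"), sum(label == "Bdy"),
                sum(label == "nMal")))
  RegionAssignment(ids, label, layer)
}

#' Summarize a score vector by region
#'
#' Per-region mean score, a per-slide min-max normalization of the three
#' region means to [0, 1], and two-sided Wilcoxon rank-sum tests for
#' Mal vs Bdy and Bdy vs nMal.
#'
#' @param scores Named numeric score vector (one per spot).
#' @param regions A \linkS4class{RegionAssignment} covering the same spots.
#' @return List with \code{summary} (region, n, mean, normalized) and
#'   \code{tests} (contrast, statistic, p); empty regions get NA means and
#'   their tests are skipped.
#' @export
summarizeRegionScores <- function(scores, regions) {
  stopifnot(methods::is(regions, "RegionAssignment"))
  lab <- regionLabels(regions)
  common <- intersect(names(scores), names(lab))
  if (!length(common)) hxStop("scores and regions share no spots")
  scores <- scores[common]
  lab <- lab[common]
  regs <- c("Mal", "Bdy", "nMal")
  means <- vapply(regs, function(r)
    if (any(lab == r)) mean(scores[lab == r]) else NA_real_, numeric(1))
  rng <- range(means, na.rm = TRUE)
  normalized <- if (diff(rng) > 0) (means - rng[1]) / diff(rng)
                else ifelse(is.na(means), NA_real_, 0.5)
  summary <- data.frame(region = regs,
                        n = as.integer(table(lab)[regs]),
                        mean = means, normalized = normalized,
                        stringsAsFactors = FALSE)
  run_test <- function(a, b) {
    if (sum(lab == a) < 1L || sum(lab == b) < 1L)
      return(c(statistic = NA_real_, p = NA_real_))
    wt <- stats::wilcox.test(scores[lab == a], scores[lab == b],
                             exact = FALSE)
    c(statistic = unname(wt$statistic), p = wt$p.value)
  }
  t1 <- run_test("Mal", "Bdy")
  t2 <- run_test("Bdy", "nMal")
  tests <- data.frame(contrast = c("Mal_vs_Bdy", "Bdy_vs_nMal"),
                      statistic = c(t1[1], t2[1]), p = c(t1[2], t2[2]),
                      stringsAsFactors = FALSE)
  list(summary = summary, tests = tests)
}
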