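## Synthetic-data generators with full ground truth: hex-lattice spatial
## slides (malignant core / boundary ring / non-malignant exterior), staged
## bulk cohorts with a graded hypoxia program, and single-cell T-cell
## datasets with a naive -> exhausted pseudotime axis. All generators are
## pure functions of their parameter objects.

#' Default cell-type program gene sets for slide simulation
#'
#' Six programs: hypoxia (the packaged 15-gene signature), malignancy,
#' macrophage (carries ALCAM and CD68), exhausted T (Tex markers),
#' effector T, and stromal. Names outside the shipped signatures are
#' synthetic symbols.
#'
#' @return Named list of gene-symbol vectors.
#' @export
defaultProgramGenes <- function() {
  list(
    hypoxia    = hypoxiaSignature(),
    malignancy = sprintf("MALG%02d", 1:20),
    macrophage = c("CD68", "CD163", "ALCAM", sprintf("MACR%02d", 1:17)),
    tex        = c("PDCD1", "LAG3", "HAVCR2", "CD8A", "CD8B", "CD3E",
                   "ENTPD1", "ITGAE", "BATF", "NR4A1"),
    effector   = c("GZMB", "PRF1", "IFNG", sprintf("EFFT%02d", 1:12)),
    stromal    = c("COL1A1", "COL1A2", "DCN", "LUM", "PDGFRB",
                   sprintf("STRM%02d", 1:15))
  )
}

.SLIDE_CELL_TYPES <- c("Malignant", "Macrophage", "TexT", "EffectorT",
                       "Stromal")

.default_region_alpha <- function() {
  list(
    Mal  = c(Malignant = 8,   Macrophage = 0.6, TexT = 0.6, EffectorT = 0.3,
             Stromal = 0.5),
    Bdy  = c(Malignant = 2.5, Macrophage = 3,   TexT = 2.5, EffectorT = 0.5,
             Stromal = 1.5),
    nMal = c(Malignant = 0.2, Macrophage = 1,   TexT = 0.3, EffectorT = 2,
             Stromal = 4)
  )
}

#' Parameters for spatial-slide simulation
#'
#' @param nRings Hex-lattice radius (rings around the center spot); the
#'   slide has 1 + 3*nRings*(nRings+1) spots.
#' @param coreRadius Rings (from the center) forming the malignant core;
#'   ring coreRadius + 1 is the ground-truth boundary.
#' @param nGenes Total gene count (program genes plus background filler).
#' @param programGenes Named list of program gene sets (see
#'   \code{defaultProgramGenes}).
#' @param hypoxiaGradient Log-fold increase of the hypoxia program from the
#'   slide exterior to its center (>= 0).
#' @param mixDirichletAlpha Per-region Dirichlet concentration vectors over
#'   cell types (named list Mal/Bdy/nMal).
#' @param regionSharpness Multiplier on all concentration vectors; larger
#'   values give purer, better-separated regional cell mixtures.
#' @param libsizeMean Expected transcripts per spot.
#' @param nbDispersion Negative-binomial dispersion (variance =
#'   mu + mu^2/dispersion).
#' @param programMean Mean expression of a program gene in its own cell type
#'   (baseline elsewhere is 0.2).
#' @param alcamBdyFactor Multiplier on the ALCAM mean in boundary-region
#'   spots (1 = no boundary-specific ALCAM elevation).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A validated parameter object of class \code{SlideSimParams}.
#' @export
slideSimParams <- function(nRings = 8L, coreRadius = 3L, nGenes = 600L,
                           programGenes = defaultProgramGenes(),
                           hypoxiaGradient = 1.5,
                           mixDirichletAlpha = .default_region_alpha(),
                           regionSharpness = 1,
                           libsizeMean = 20000, nbDispersion = 2,
                           programMean = 10, alcamBdyFactor = 1,
                           seed = 1L) {
  p <- list(nRings = as.integer(nRings), coreRadius = as.integer(coreRadius),
            nGenes = as.integer(nGenes), programGenes = programGenes,
            hypoxiaGradient = hypoxiaGradient,
            mixDirichletAlpha = lapply(mixDirichletAlpha,
                                       function(a) a * regionSharpness),
            libsizeMean = libsizeMean, nbDispersion = nbDispersion,
            programMean = programMean, alcamBdyFactor = alcamBdyFactor,
            seed = as.integer(seed))
  if (p$coreRadius >= p$nRings)
    hxStop("coreRadius must be smaller than nRings")
  if (p$hypoxiaGradient < 0) hxStop("hypoxiaGradient must be >= 0")
  if (any(unlist(p$mixDirichletAlpha) <= 0))
    hxStop("all Dirichlet concentrations must be > 0")
  if (p$nbDispersion <= 0 || p$libsizeMean <= 0)
    hxStop("libsizeMean and nbDispersion must be > 0")
  if (!all(c("Mal", "Bdy", "nMal") %in% names(p$mixDirichletAlpha)))
    hxStop("mixDirichletAlpha needs Mal, Bdy, nMal entries")
  if (p$nGenes < length(unique(unlist(p$programGenes))) + 10L)
    hxStop("nGenes too small for the program gene sets")
  class(p) <- "SlideSimParams"
  p
}

#' Axial hex lattice of a given radius
#'
#' Axial coordinates (q, r); pixel centers x = q + r/2, y = r * sqrt(3)/2,
#' so the 6-neighbor center-to-center distance is exactly 1.
#'
#' @param nRings Lattice radius.
#' @return data.frame with q, r, ring (hex distance to origin), px_x, px_y.
#' @export
hexLattice <- function(nRings) {
  qs <- rep(-nRings:nRings, each = 2L * nRings + 1L)
  rs <- rep(-nRings:nRings, times = 2L * nRings + 1L)
  ring <- (abs(qs) + abs(rs) + abs(qs + rs)) / 2L
  keep <- ring <= nRings
  data.frame(q = qs[keep], r = rs[keep], ring = as.integer(ring[keep]),
             px_x = qs[keep] + rs[keep] / 2, px_y = rs[keep] * sqrt(3) / 2)
}

## gene x cell-type baseline mean matrix shared by the slide and
## reference-cell generators
.program_mean_matrix <- function(params) {
  prog <- params$programGenes
  prog_genes <- unique(unlist(prog))
  n_bg <- params$nGenes - length(prog_genes)
  genes <- c(prog_genes, sprintf("BGRD%04d", seq_len(n_bg)))
  M <- matrix(0.2, nrow = length(genes), ncol = length(.SLIDE_CELL_TYPES),
              dimnames = list(genes, .SLIDE_CELL_TYPES))
  owner <- c(malignancy = "Malignant", macrophage = "Macrophage",
             tex = "TexT", effector = "EffectorT", stromal = "Stromal")
  for (pg in names(owner))
    M[prog[[pg]], owner[[pg]]] <- params$programMean
  M[prog$hypoxia, ] <- 1   # hypoxia program expressed by every cell type
  list(M = M, genes = genes)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate one spatial slide
#'
#' Builds the hex lattice, labels ground-truth regions by ring index
#' (ring <= coreRadius is Mal, ring == coreRadius + 1 is Bdy, the rest
#' nMal), draws per-spot cell-type mixtures from the region's Dirichlet,
#' forms gene means as the mixture of cell-type program means with the
#' hypoxia program scaled by exp(hypoxiaGradient * (1 - ring/nRings)),
#' rescales spot means to the target library size, and draws
#' negative-binomial counts.
#'
#' @param params A \code{slideSimParams()} object.
#' @return A \linkS4class{SpatialSlide} (raw counts) with
#'   \code{truthRegion}, \code{truthProps}, and a \code{ring} colData column.
#' @examples
#' sl <- simulateSlide(slideSimParams(nRings = 2, coreRadius = 0, seed = 1))
#' table(truthRegion(sl))
#' @export
simulateSlide <- function(params) {
  stopifnot(inherits(params, "SlideSimParams"))
  .seed_log("simulateSlide", params$seed)
  .with_seed(params$seed, {
    lat <- hexLattice(params$nRings)
    n_spots <- nrow(lat)
    region <- ifelse(lat$ring <= params$coreRadius, "Mal",
                     ifelse(lat$ring == params$coreRadius + 1L, "Bdy",
                            "nMal"))
    barcode <- sprintf("spot_%04d", seq_len(n_spots))

    prog <- params$programGenes
    mm <- .program_mean_matrix(params)
    M <- mm$M
    genes <- mm$genes

    props <- t(vapply(seq_len(n_spots), function(i)
      .rdirichlet1(params$mixDirichletAlpha[[region[i]]]),
      numeric(length(.SLIDE_CELL_TYPES))))
    dimnames(props) <- list(barcode, .SLIDE_CELL_TYPES)

    mu <- M %*% t(props)                       # genes x spots
    hyp_factor <- exp(params$hypoxiaGradient * (1 - lat$ring / params$nRings))
    mu[prog$hypoxia, ] <- sweep(mu[prog$hypoxia, , drop = FALSE], 2L,
                                hyp_factor, "*")
    if (params$alcamBdyFactor != 1 && "ALCAM" %in% genes)
      mu["ALCAM", region == "Bdy"] <- mu["ALCAM", region == "Bdy"] *
        params$alcamBdyFactor
    ## one global scale so the average spot hits the target library size;
    ## spot totals then vary with composition, as in real tissue
    mu <- mu * (params$libsizeMean / mean(colSums(mu)))

    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = params$nbDispersion),
                     nrow = length(genes),
                     dimnames = list(genes, barcode))
    pos <- data.frame(barcode = barcode, array_row = lat$r,
                      array_col = lat$q, px_x = lat$px_x, px_y = lat$px_y,
                      stringsAsFactors = FALSE)
    slide <- SpatialSlide(counts, pos, valueKind = "raw_counts",
                          truthRegion = stats::setNames(region, barcode),
                          truthProps = props)
    SummarizedExperiment::colData(slide)$ring <- lat$ring
    S4Vectors::metadata(slide)$sim_params <- params
    slide
  })
}

#' Parameters for staged bulk-cohort simulation
#'
#' @param nPerStage Samples per stage.
#' @param nStages Number of successive stages (>= 2).
#' @param hypoxiaSlope Per-stage shift of the latent hypoxia program (log
#'   scale); 0 gives a null cohort.
#' @param survivalHazardRatio Log-hazard multiplier per unit latent hypoxia.
#' @param censorRate Probability a survival time is right-censored.
#' @param nGenes Total genes (15 hypoxia + background).
#' @param noiseSd Standard deviation of the per-sample latent hypoxia noise.
#' @param baseTime Baseline mean survival (days) at latent hypoxia 0.
#' @param pairedFraction Fraction of samples receiving a paired on-treatment
#'   profile (hypoxia shifted down for responders, up for non-responders).
#' @param onShift Size of that on-treatment latent shift.
#' @param seed Integer seed.
#' @return Parameter object of class \code{CohortSimParams}.
#' @export
cohortSimParams <- function(nPerStage = 20L, nStages = 9L, hypoxiaSlope = 0.5,
                            survivalHazardRatio = 0.8, censorRate = 0.2,
                            nGenes = 500L, noiseSd = 0.8, baseTime = 720,
                            pairedFraction = 0.4, onShift = 0.8, seed = 1L) {
  p <- list(nPerStage = as.integer(nPerStage), nStages = as.integer(nStages),
            hypoxiaSlope = hypoxiaSlope,
            survivalHazardRatio = survivalHazardRatio,
            censorRate = censorRate, nGenes = as.integer(nGenes),
            noiseSd = noiseSd, baseTime = baseTime,
            pairedFraction = pairedFraction, onShift = onShift,
            seed = as.integer(seed))
  if (p$nStages < 2L) hxStop("nStages must be >= 2")
  if (p$censorRate < 0 || p$censorRate > 1)
    hxStop("censorRate must lie in [0, 1]")
  class(p) <- "CohortSimParams"
  p
}

.cohort_expression <- function(latent, genes, hyp_genes) {
  ## per-sample gene means: background lognormal spread, hypoxia program
  ## scaled by exp(latent)
  n <- length(latent)
  base <- stats::rlnorm(length(genes), meanlog = log(5), sdlog = 0.4)
  mu <- matrix(rep(base, n), ncol = n,
               dimnames = list(genes, names(latent)))
  mu[hyp_genes, ] <- sweep(mu[hyp_genes, , drop = FALSE], 2L, exp(latent),
                           "*")
  matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = 10),
         nrow = length(genes), dimnames = dimnames(mu))
}

#' Simulate a staged bulk cohort with survival and ICB-response annotation
#'
#' Each sample in stage s carries latent hypoxia
#' h = hypoxiaSlope * s + N(0, noiseSd); the 15 hypoxia-signature gene means
#' scale with exp(h). Survival times are exponential with hazard
#' proportional to exp(survivalHazardRatio * h); response is Bernoulli with
#' logit decreasing in h (responders CR/PR, non-responders PD or SD); a
#' \code{pairedFraction} subset receives a paired on-treatment profile whose
#' latent hypoxia is shifted down for responders and up for non-responders.
#'
#' @param params A \code{cohortSimParams()} object.
#' @return List with \code{expr} (raw-counts container; columns are
#'   "<sample>_pre"/"<sample>_on"), \code{metadata} (sample_id, patient_id,
#'   stage, timepoint, time, event, response, responder), and \code{truth}
#'   (latent hypoxia per profile).
#' @export
simulateBulkCohort <- function(params) {
  stopifnot(inherits(params, "CohortSimParams"))
  .seed_log("simulateBulkCohort", params$seed)
  .with_seed(params$seed, {
    n <- params$nPerStage * params$nStages
    stage <- rep(seq_len(params$nStages) - 1L, each = params$nPerStage)
    patient <- sprintf("P%04d", seq_len(n))
    latent <- params$hypoxiaSlope * stage + stats::rnorm(n, 0, params$noiseSd)

    rate <- exp(params$survivalHazardRatio * latent) / params$baseTime
    t_event <- stats::rexp(n, rate = rate)
    cens <- stats::runif(n) < params$censorRate
    time <- ifelse(cens, stats::runif(n) * t_event, t_event)
    time <- pmax(time, 1 / 24)      # at least one hour of follow-up
    event <- as.integer(!cens)

    p_resp <- stats::plogis(0.5 - 1.0 * (latent - mean(latent)))
    responder <- stats::rbinom(n, 1L, p_resp) == 1L
    response <- ifelse(responder,
                       sample(c("CR", "PR"), n, replace = TRUE),
                       sample(c("PD", "SD"), n, replace = TRUE,
                              prob = c(0.7, 0.3)))

    paired <- stats::runif(n) < params$pairedFraction
    lat_on <- latent + ifelse(responder, -params$onShift, params$onShift)

    ids <- c(paste0(patient, "_pre"),
             paste0(patient[paired], "_on", recycle0 = TRUE))
    lat_all <- stats::setNames(c(latent, lat_on[paired]), ids)

    hyp <- hypoxiaSignature()
    n_bg <- params$nGenes - length(hyp)
    genes <- c(hyp, sprintf("BGRD%04d", seq_len(n_bg)))
    counts <- .cohort_expression(lat_all, genes, hyp)

    meta <- data.frame(
      sample_id = ids,
      patient_id = c(patient, patient[paired]),
      stage = c(stage, stage[paired]),
      timepoint = c(rep("pre", n), rep("on", sum(paired))),
      time = c(time, time[paired]),
      event = c(event, event[paired]),
      response = c(response, response[paired]),
      responder = c(responder, responder[paired]),
      stringsAsFactors = FALSE)
    list(expr = ExpressionMatrix(counts, "raw_counts"), metadata = meta,
         truth = data.frame(sample_id = ids, latent_hypoxia = lat_all,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate labeled reference single cells matching the slide's programs
#'
#' Draws negative-binomial single-cell profiles from the same per-cell-type
#' program means the slide generator mixes, for building a deconvolution
#' reference with \code{\link{buildReference}}.
#'
#' @param params A \code{slideSimParams()} object.
#' @param nPerType Cells per cell type.
#' @param libsize Expected transcripts per cell.
#' @param seed Integer seed (defaults to the slide seed + 1).
#' @return List: \code{expr} (raw-counts container), \code{labels} (named
#'   cell-type labels).
#' @export
simulateReferenceCells <- function(params, nPerType = 50L, libsize = 5000,
                                   seed = params$seed + 1L) {
  stopifnot(inherits(params, "SlideSimParams"))
  .seed_log("simulateReferenceCells", seed)
  .with_seed(seed, {
    mm <- .program_mean_matrix(params)
    types <- rep(.SLIDE_CELL_TYPES, each = nPerType)
    cells <- sprintf("cell_%04d", seq_along(types))
    mu <- mm$M[, types, drop = FALSE]
    mu <- sweep(mu, 2L, colSums(mu), "/") * libsize
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = params$nbDispersion),
                     nrow = length(mm$genes),
                     dimnames = list(mm$genes, cells))
    list(expr = ExpressionMatrix(counts, "raw_counts"),
         labels = stats::setNames(types, cells))
  })
}

.TCELL_SUBSETS <- c("NaiveLike", "EarlyActiv", "EffectorMemory", "Tpex",
                    "Tex")

#' Simulate single-cell CD8 T-cell datasets along a differentiation axis
#'
#' Pseudotime is uniform on [0, 1]; naive markers (TCF7, SELL, LEF1, CCR7)
#' decrease and exhaustion markers plus the hypoxia program increase along
#' it. The TFs in \code{exhaustionTfSet} increase in every dataset; the
#' designated \code{inconsistentTf} increases in exactly
#' \code{nIncreasingDatasets} of the \code{nDatasets} datasets (flat
#' elsewhere), which exercises the cross-dataset consistency filter. Subset
#' labels are pseudotime quintiles NaiveLike -> Tex.
#'
#' @param nCells Cells per dataset (>= 50).
#' @param nDatasets Number of datasets.
#' @param exhaustionTfSet TFs rising with differentiation in all datasets.
#' @param inconsistentTf Single TF with configurable cross-dataset behavior.
#' @param nIncreasingDatasets In how many datasets \code{inconsistentTf}
#'   increases (the first k datasets).
#' @param nGenes Total genes.
#' @param noiseSd Gaussian noise on the lognorm scale.
#' @param seed Integer seed.
#' @return List of per-dataset lists: \code{expr} (lognorm container),
#'   \code{pseudotime} (named, the ground truth), \code{labels} (subsets).
#' @export
simulateTcells <- function(nCells = 200L, nDatasets = 4L,
                           exhaustionTfSet = c("TOX", "NR4A1", "BATF",
                                               "IRF4", "PRDM1"),
                           inconsistentTf = "JUNB",
                           nIncreasingDatasets = nDatasets,
                           nGenes = 300L, noiseSd = 0.3, seed = 1L) {
  if (nCells < 50L) hxStop("need at least 50 cells per dataset")
  if (nIncreasingDatasets > nDatasets)
    hxStop("nIncreasingDatasets cannot exceed nDatasets")
  .seed_log("simulateTcells", seed)
  .with_seed(seed, {
    naive <- c("TCF7", "SELL", "LEF1", "CCR7")
    exh <- c("PDCD1", "LAG3", "HAVCR2", "TIGIT", "CTLA4", "ENTPD1")
    hyp <- hypoxiaSignature()
    core <- unique(c(naive, exh, hyp, exhaustionTfSet, inconsistentTf))
    n_bg <- nGenes - length(core)
    genes <- c(core, sprintf("BGRD%04d", seq_len(n_bg)))

    lapply(seq_len(nDatasets), function(d) {
      t <- sort(stats::runif(nCells))
      cells <- sprintf("ds%d_cell%04d", d, seq_len(nCells))
      names(t) <- cells
      mu <- matrix(1, nrow = length(genes), ncol = nCells,
                   dimnames = list(genes, cells))
      mu[naive, ] <- rep(2.5 - 2 * t, each = length(naive))
      mu[exh, ] <- rep(0.3 + 2.2 * t, each = length(exh))
      mu[hyp, ] <- rep(0.5 + 1.5 * t, each = length(hyp))
      mu[exhaustionTfSet, ] <- rep(0.3 + 2 * t,
                                   each = length(exhaustionTfSet))
      mu[inconsistentTf, ] <- if (d <= nIncreasingDatasets)
        0.3 + 2 * t else rep(1, nCells)
      vals <- pmax(mu + matrix(stats::rnorm(length(mu), 0, noiseSd),
                               nrow = nrow(mu)), 0)
      labels <- .TCELL_SUBSETS[pmin(floor(t * 5) + 1L, 5L)]
      names(labels) <- cells
      list(expr = ExpressionMatrix(vals, "lognorm"), pseudotime = t,
           labels = labels)
    })
  })
}
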