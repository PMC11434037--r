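ref_from_profiles <- function(profiles, markers) {
  structure(list(profiles = profiles, markers = markers),
            class = "ReferenceSignatureMatrix")
}

test_that("reference building separates disjoint marker programs", {
  set.seed(3)
  genes <- c(paste0("A", 1:5), paste0("B", 1:5), paste0("C", 1:10))
  cells <- paste0("c", 1:40)
  m <- matrix(rpois(20 * 40, 1), 20, 40, dimnames = list(genes, cells))
  lab <- rep(c("T1", "T2"), each = 20)
  m[1:5, lab == "T1"] <- m[1:5, lab == "T1"] + 50L
  m[6:10, lab == "T2"] <- m[6:10, lab == "T2"] + 50L
  ref <- buildReference(m, setNames(lab, cells), topK = 5)
  expect_setequal(ref$markers$T1, paste0("A", 1:5))
  expect_setequal(ref$markers$T2, paste0("B", 1:5))
  # profiles block-structured: each type's markers dominate its own column
  expect_true(all(ref$profiles[paste0("A", 1:5), "T1"] >
                    ref$profiles[paste0("A", 1:5), "T2"]))

  expect_error(buildReference(m, setNames(rep("T1", 40), cells)),
               "2 cell types")
  expect_error(buildReference(m, setNames(c(rep("T1", 35), rep("T2", 5)),
                                          cells)), "fewer than 10")
})

test_that("reference from simulated cells ranks each type's program first", {
  p <- slideSimParams(seed = 5)
  rc <- simulateReferenceCells(p, nPerType = 30, seed = 6)
  ref <- buildReference(rc$expr, rc$labels, topK = 10)
  prog <- defaultProgramGenes()
  expect_true(all(ref$markers$Malignant %in% prog$malignancy))
  expect_true(all(ref$markers$Macrophage %in% prog$macrophage))
  expect_true(all(ref$markers$TexT %in% prog$tex))
})

test_that("NNLS recovers exact mixtures and flags empty spots", {
  S <- matrix(c(10, 0, 0, 10), 2,
              dimnames = list(c("gA", "gB"), c("T1", "T2")))
  ref <- ref_from_profiles(S, list(T1 = c("gA", "gB"), T2 = c("gA", "gB")))
  y <- matrix(c(3, 7, 0, 0), 2,
              dimnames = list(c("gA", "gB"), c("spot1", "spot2")))
  # supply linear values via a lognorm container holding log1p(values)
  props <- deconvolveSpots(ExpressionMatrix(log1p(y), "lognorm"), ref)
  expect_equal(unname(props["spot1", ]), c(0.3, 0.7), tolerance = 1e-9)
  expect_true(all(is.na(props["spot2", ])))
})

test_that("NNLS recovers noiseless mixtures of reference columns to 1e-6", {
  set.seed(1)
  genes <- paste0("g", 1:30)
  S <- matrix(rexp(90, 1 / 5), 30, 3,
              dimnames = list(genes, c("T1", "T2", "T3")))
  ref <- ref_from_profiles(S, list(T1 = genes[1:10], T2 = genes[11:20],
                                   T3 = genes[21:30]))
  W <- t(sapply(1:20, function(i) { w <- runif(3); w / sum(w) }))
  Y <- S %*% t(W)
  colnames(Y) <- paste0("spot", 1:20)
  props <- deconvolveSpots(ExpressionMatrix(log1p(Y), "lognorm"), ref)
  expect_lt(max(abs(props - W)), 1e-6)
})

test_that("NNLS tolerates 5% Gaussian noise within 0.05 mean absolute error", {
  set.seed(7)
  genes <- paste0("g", 1:60)
  S <- matrix(rexp(180, 1 / 10), 60, 3,
              dimnames = list(genes, c("T1", "T2", "T3")))
  ref <- ref_from_profiles(S, list(T1 = genes[1:20], T2 = genes[21:40],
                                   T3 = genes[41:60]))
  W <- matrix(rep(c(0.2, 0.3, 0.5), each = 100), 100, 3)
  Y <- S %*% t(W)
  Y <- Y + matrix(rnorm(length(Y), 0, 0.05 * mean(Y)), nrow(Y))
  Y[Y < 0] <- 0
  colnames(Y) <- paste0("spot", 1:100)
  props <- deconvolveSpots(ExpressionMatrix(log1p(Y), "lognorm"), ref)
  mae <- colMeans(abs(props - W))
  expect_true(all(mae < 0.05))
})

test_that("ALCAM gating: threshold gate, median split, constant expression", {
  genes <- c("ALCAM", "other")
  bc <- paste0("s", 1:6)
  ln <- matrix(c(1, 2, 3, 4, 9, 9,     # ALCAM lognorm
                 5, 5, 5, 5, 5, 5), 2, byrow = TRUE,
               dimnames = list(genes, bc))
  props <- matrix(c(rep(0.5, 4), 0.01, 0.01), 6, 1,
                  dimnames = list(bc, "Macrophage"))
  x <- ExpressionMatrix(ln, "lognorm")
  lab <- gateAlcamMacrophages(x, props)
  expect_identical(unname(lab[1:4]), c("alcam_low_mac", "alcam_low_mac",
                                       "alcam_high_mac", "alcam_high_mac"))
  expect_identical(unname(lab[5:6]), c("none", "none"))

  expect_warning(none <- gateAlcamMacrophages(x, props * 0),
                 "no spot passes")
  expect_true(all(none == "none"))

  ln2 <- ln; ln2["ALCAM", ] <- 2
  expect_warning(
    lab2 <- gateAlcamMacrophages(ExpressionMatrix(ln2, "lognorm"), props),
    "constant")
  expect_true(all(lab2[1:4] == "alcam_low_mac"))

  expect_error(gateAlcamMacrophages(x, props, gene = "MISSING"), "absent")
})

test_that("ALCAM-high macrophage spots are boundary-enriched when simulated so", {
  sl <- simulateSlide(slideSimParams(regionSharpness = 10,
                                     alcamBdyFactor = 6, seed = 3))
  q <- qcFilter(sl)
  tp <- truthProps(q)
  lab <- gateAlcamMacrophages(q, tp)
  tr <- truthRegion(q)
  high <- names(lab)[lab == "alcam_high_mac"]
  reg <- RegionAssignment(names(tr), tr, ifelse(tr == "Mal", 0L, 1L))
  enr <- regionEnrichment(high, reg)
  bdy <- enr[enr$region == "Bdy", ]
  expect_gt(bdy$ratio, 1)
  expect_lt(bdy$p, 0.05)
})

test_that("Tex spot calling: markers, degenerate slides, quantile boundary", {
  genes <- c("PDCD1", "LAG3", "HAVCR2", "CD8A", paste0("bg", 1:20))
  bc <- paste0("s", 1:8)
  m <- matrix(rpois(24 * 8, 2), 24, 8, dimnames = list(genes, bc))
  m[1:4, 1:2] <- 60L
  tex <- identifyTexSpots(ExpressionMatrix(m, "raw_counts"))
  expect_setequal(tex, c("s1", "s2"))

  m0 <- m; m0[1:4, ] <- 0L
  expect_length(identifyTexSpots(ExpressionMatrix(m0, "raw_counts")), 0L)

  all_spots <- identifyTexSpots(ExpressionMatrix(m, "raw_counts"),
                                scoreQuantile = 0)
  expect_setequal(all_spots, bc)

  props <- matrix(c(rep(0.5, 2), rep(0.001, 6)), 8, 1,
                  dimnames = list(bc, "TexT"))
  gated <- identifyTexSpots(ExpressionMatrix(m, "raw_counts"),
                            props = props, scoreQuantile = 0)
  expect_setequal(gated, c("s1", "s2"))

  expect_error(identifyTexSpots(ExpressionMatrix(m[5:24, , drop = FALSE],
                                                 "raw_counts")),
               "fewer than 3")
})

test_that("first-outer-circle co-localization follows the spot and neighbor rules", {
  lat <- hexLattice(2)
  pos <- data.frame(barcode = paste0("s", seq_len(nrow(lat))),
                    px_x = lat$px_x, px_y = lat$px_y)
  g <- buildNeighborGraph(pos)
  center <- pos$barcode[lat$ring == 0]
  ring1 <- pos$barcode[lat$ring == 1]
  ring2 <- pos$barcode[lat$ring == 2]

  # Tex spot that is itself ALCAM-high: colocalized
  co1 <- colocalize(center, center, g)
  expect_identical(co1$flag, "colocalized")
  expect_identical(co1$partners, center)

  # ALCAM-high one edge away: colocalized; two edges away: not
  co2 <- colocalize(center, ring1[1], g)
  expect_identical(co2$flag, "colocalized")
  co3 <- colocalize(center, setdiff(ring2, unlist(g$adjacency[center])), g)
  expect_identical(co3$flag, "not_colocalized")

  # invariance to spot-list ordering
  texs <- c(center, ring1[1:3])
  alcam <- ring2[1:4]
  a <- colocalize(texs, alcam, g)
  b <- colocalize(rev(texs), sample(alcam), g)
  expect_identical(a[order(a$spot), "flag"], b[order(b$spot), "flag"])

  expect_error(colocalize("nope", center, g), "absent")
})

test_that("exhaustion contrast: identical distributions, exact small-sample p", {
  coloc <- data.frame(spot = paste0("s", 1:6),
                      flag = rep(c("colocalized", "not_colocalized"),
                                 each = 3))
  sc <- setNames(c(1, 2, 3, 1, 2, 3), paste0("s", 1:6))
  res <- compareColocalizedExhaustion(sc, coloc)
  expect_equal(res$p, 1)

  sc2 <- setNames(c(4, 5, 6, 1, 2, 3), paste0("s", 1:6))
  res2 <- compareColocalizedExhaustion(sc2, coloc)
  expect_equal(res2$p, 0.1)
  expect_equal(res2$statistic, 9)      # rank-sum W for the first group
  expect_gt(res2$median_colocalized, res2$median_not)

  expect_error(compareColocalizedExhaustion(
    sc, data.frame(spot = "s1", flag = "colocalized")), ">= 2")
})

test_that("rank-sum p matches exhaustive permutation enumeration (n <= 10)", {
  set.seed(11)
  for (i in 1:30) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    a <- rnorm(n1)
    b <- rnorm(n2)
    coloc <- data.frame(
      spot = paste0("s", seq_len(n1 + n2)),
      flag = rep(c("colocalized", "not_colocalized"), c(n1, n2)))
    sc <- setNames(c(a, b), coloc$spot)
    res <- compareColocalizedExhaustion(sc, coloc)
    expect_equal(res$p, oracle_wilcox_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("co-localization with an exhaustion shift raises the colocalized group", {
  sl <- simulateSlide(slideSimParams(regionSharpness = 10,
                                     alcamBdyFactor = 6, seed = 2))
  q <- qcFilter(sl)
  g <- buildNeighborGraph(q)
  props <- truthProps(q)
  alcam <- gateAlcamMacrophages(q, props, macThreshold = 0.2)
  tex <- identifyTexSpots(q, props = props, scoreQuantile = 0.5)
  coloc <- colocalize(tex, names(alcam)[alcam == "alcam_high_mac"], g)
  expect_gte(sum(coloc$flag == "colocalized"), 30)
  expect_gte(sum(coloc$flag == "not_colocalized"), 30)

  # +1 shift of the exhaustion program (lognorm scale) at colocalized spots
  ln <- logNormalize(q)
  m <- exprValues(ln)
  shift_spots <- coloc$spot[coloc$flag == "colocalized"]
  tex_genes <- intersect(texSignature(), rownames(m))
  m[tex_genes, shift_spots] <- m[tex_genes, shift_spots] + 1
  exh <- scoreMeanScaled(m, texSignature(), "exhaustion")
  res <- compareColocalizedExhaustion(exh, coloc)
  expect_gt(res$median_colocalized, res$median_not)
  expect_lt(res$p, 0.05)
})

test_that("region enrichment: uniform null, concentrated labels, empty set", {
  set.seed(5)
  n <- 90
  ids <- paste0("s", 1:n)
  reg <- RegionAssignment(ids, rep(c("Mal", "Bdy", "nMal"), each = 30),
                          rep(c(0L, 1L, 2L), each = 30))
  uniform <- ids[seq(1, n, by = 3)]
  enr <- regionEnrichment(uniform, reg)
  expect_true(all(abs(enr$ratio - 1) < 1e-9))
  expect_true(all(enr$p > 0.5))

  bdy_ids <- ids[31:40]
  enr2 <- regionEnrichment(bdy_ids, reg)
  row <- enr2[enr2$region == "Bdy", ]
  expect_equal(row$ratio, (10 / 90) / (30 / 90) * 9)   # obs/exp = 10/(10*30/90)
  expect_equal(row$ratio, 3)
  expect_equal(row$p, fisher.test(matrix(c(10, 20, 0, 60), 2))$p.value)

  enr3 <- regionEnrichment(character(), reg)
  expect_true(all(enr3$ratio == 0))
  expect_true(all(enr3$p == 1))
})
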