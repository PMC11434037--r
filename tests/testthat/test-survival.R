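sim_cohort <- function(n, seed, hr = 1) {
  set.seed(seed)
  score <- rnorm(n)
  time <- rexp(n, rate = exp(hr * score) / 100)
  event <- as.integer(runif(n) > 0.25)
  survivalCohort(paste0("s", seq_len(n)), score, pmax(time, 0.1), event)
}

test_that("Spearman screen: perfect correlations and the BH hand example", {
  set.seed(1)
  scores <- setNames(rnorm(20), paste0("s", 1:20))
  feats <- cbind(same = scores,
                 rev = -scores,
                 noise = rnorm(20),
                 const = rep(1, 20))
  rownames(feats) <- names(scores)
  out <- spearmanScreen(scores, feats)
  expect_equal(out$rho[out$feature == "same"], 1)
  expect_equal(out$rho[out$feature == "rev"], -1)
  expect_true(is.na(out$rho[out$feature == "const"]))
  expect_true(is.na(out$q[out$feature == "const"]))

  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("Spearman p-values match cor.test conventions at both regimes", {
  set.seed(2)
  # small n: exact enumeration against cor.test's exact p (no ties)
  for (i in 1:5) {
    x <- rnorm(7)
    y <- rnorm(7)
    out <- spearmanScreen(setNames(x, paste0("s", 1:7)),
                          matrix(y, 7, dimnames = list(paste0("s", 1:7),
                                                       "f")))
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(out$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(out$p, ct$p.value, tolerance = 1e-9)
  }
  # larger n: t-approximation
  x <- rnorm(40)
  y <- x + rnorm(40, 0, 2)
  out <- spearmanScreen(setNames(x, paste0("s", 1:40)),
                        matrix(y, 40, dimnames = list(paste0("s", 1:40),
                                                      "f")))
  r <- cor(rank(x), rank(y))
  tstat <- r * sqrt(38 / (1 - r^2))
  expect_equal(out$p, 2 * pt(-abs(tstat), 38), tolerance = 1e-12)
})

test_that("Spearman screen controls the false discovery rate under the null", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    scores <- setNames(rnorm(100), paste0("s", 1:100))
    feats <- matrix(rnorm(100 * 200), 100, 200,
                    dimnames = list(names(scores), paste0("f", 1:200)))
    mean(spearmanScreen(scores, feats)$significant)
  }, numeric(1))
  expect_gte(sum(hits < 0.05), 19L)
})

test_that("group comparisons: identical multisets, exact enumeration, pairing", {
  same <- suppressWarnings(
    groupCompare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)))
  expect_equal(same$p, 1)

  sep <- groupCompare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(sep$p, 0.1)

  zero_diff <- groupCompare(c(1, 2, 3), paired = TRUE,
                            scores2 = c(1, 2, 3))
  expect_equal(zero_diff$p, 1)

  set.seed(4)
  x <- rnorm(8); y <- rnorm(8)
  pr <- groupCompare(x, paired = TRUE, scores2 = y)
  expect_equal(pr$p, wilcox.test(x, y, paired = TRUE)$p.value)

  expect_error(groupCompare(1:4, c("a", "a", "a", "b")), ">= 2")
  expect_error(groupCompare(1:6, rep("a", 6)), "two groups")
})

test_that("response contrasts follow the pooling rules and detect shifts", {
  mk <- function(resp, score) {
    survivalCohort(paste0("s", seq_along(resp)), score,
                   rep(100, length(resp)), rep(1, length(resp)),
                   response = resp)
  }
  expect_error(responseContrast(mk(rep("PD", 6), rnorm(6))), "empty")

  set.seed(5)
  resp <- rep(c("CR", "PD"), each = 30)
  score <- c(rnorm(30, -1), rnorm(30, 0))
  rc <- responseContrast(mk(resp, score))
  expect_lt(rc$score_test$p, 0.05)
  expect_lt(rc$score_test$median["responder"],
            rc$score_test$median["non_responder"])

  # IMvigor pooling: SD joins the responder group
  resp2 <- c(rep("PR", 10), rep("SD", 10), rep("PD", 10))
  rc2 <- responseContrast(mk(resp2, rnorm(30)), pooling = "imvigor")
  expect_equal(sum(rc2$groups == "responder"), 20L)
  rc3 <- responseContrast(mk(resp2, rnorm(30)), pooling = "pd-vs-prcr")
  expect_equal(sum(rc3$groups == "responder"), 10L)
  expect_false(any(grepl("^s1[1-9]$|^s20$", names(rc3$groups))))  # SD out
})

test_that("on-minus-pre deltas contrast responders against non-responders", {
  sim <- simulateBulkCohort(cohortSimParams(nPerStage = 40, nStages = 2,
                                            hypoxiaSlope = 0,
                                            pairedFraction = 1, seed = 5))
  score <- scoreRankEnrichment(sim$expr, hypoxiaSignature())
  md <- sim$metadata
  cohort <- survivalCohort(md$sample_id, score[md$sample_id], md$time,
                           md$event, response = md$response,
                           timepoint = md$timepoint,
                           patientId = md$patient_id)
  rc <- responseContrast(cohort)
  expect_false(is.null(rc$delta_test))
  med <- tapply(rc$delta$delta, rc$delta$group, median)
  expect_lt(med["responder"], med["non_responder"])
  expect_lt(rc$delta_test$p, 0.05)
})

test_that("log-rank statistic agrees with survdiff and is label-symmetric", {
  for (seed in 1:5) {
    co <- sim_cohort(30, seed, hr = 0.5)
    g1 <- co$score > median(co$score)
    st <- logrankStatistic(co$time, co$event, g1)
    sd_ <- survival::survdiff(survival::Surv(co$time, co$event) ~ g1)
    expect_equal(st$chisq, unname(sd_$chisq), tolerance = 1e-9)
    flip <- logrankStatistic(co$time, co$event, !g1)
    expect_equal(flip$chisq, st$chisq, tolerance = 1e-9)
    expect_equal(flip$z, -st$z, tolerance = 1e-9)
  }
})

test_that("optimal cutpoint: separated toy, degenerate input, constraints", {
  co <- survivalCohort(paste0("s", 1:12),
                       score = c(1, 2, 3, 1.5, 2.5, 1.2, 10, 11, 12, 10.5,
                                 11.5, 10.2),
                       time = c(1, 2, 3, 2, 1, 3, 50, 60, 70, 55, 65, 52),
                       event = rep(1, 12))
  cp <- optimalCutpoint(co)
  expect_gt(cp$cutpoint, 3)
  expect_lt(cp$cutpoint, 10)
  expect_identical(unname(cp$groups[co$score > cp$cutpoint][1]), "high")

  flat <- survivalCohort(paste0("s", 1:12), rep(1, 12), 1:12,
                         rep(1, 12))
  expect_error(optimalCutpoint(flat), "identical")
  expect_error(optimalCutpoint(co[1:8, ]), "10 samples")
})

test_that("optimal cutpoint equals the exhaustive oracle on random cohorts", {
  for (seed in 1:10) {
    co <- sim_cohort(40, 100 + seed, hr = 0.7)
    cp <- optimalCutpoint(co)
    oracle <- oracle_best_cutpoint(co$score, co$time, co$event)
    expect_equal(cp$cutpoint, oracle$cutpoint, tolerance = 1e-12)
    expect_equal(cp$statistic, oracle$statistic, tolerance = 1e-9)
  }
})

test_that("KM curves: identical groups, hand-computed medians, degenerate groups", {
  co <- survivalCohort(paste0("s", 1:6), rnorm(6), rep(c(1, 2, 3), 2),
                       rep(1, 6))
  km <- kmLogrank(co, rep(c("a", "b"), each = 3))
  expect_equal(km$chisq, 0, tolerance = 1e-9)
  expect_equal(km$p, 1, tolerance = 1e-9)

  co2 <- survivalCohort(paste0("s", 1:6), rnorm(6),
                        c(1, 2, 3, 10, 20, 30), rep(1, 6))
  km2 <- kmLogrank(co2, rep(c("a", "b"), each = 3))
  # product-limit estimate crosses 0.5 at the second event of each group
  expect_equal(unname(km2$medians), c(2, 20))

  co3 <- survivalCohort(c("x", "y"), c(0, 1), c(1, 1), c(1, 1))
  km3 <- kmLogrank(co3, c("a", "b"))
  expect_equal(km3$chisq, 0, tolerance = 1e-9)

  # zero-event group: chi-square still computed, median undefined
  co4 <- survivalCohort(paste0("s", 1:8), rnorm(8), c(1:4, 2:5),
                        c(1, 1, 1, 1, 0, 0, 0, 0))
  km4 <- kmLogrank(co4, rep(c("a", "b"), each = 4))
  expect_true(is.finite(km4$chisq))
  expect_true(is.na(km4$medians["b"]))
})

test_that("KM estimates are valid survival curves", {
  co <- sim_cohort(40, 77, hr = 0.5)
  grp <- ifelse(co$score > median(co$score), "high", "low")
  km <- kmLogrank(co, grp)
  for (g in c("high", "low")) {
    cv <- km$curves[km$curves$group == g, ]
    expect_true(all(diff(cv$surv) <= 1e-12))      # non-increasing
    expect_true(all(cv$surv >= 0 & cv$surv <= 1))
    first_event <- min(cv$time[cv$n_event > 0])
    expect_true(all(cv$surv[cv$time < first_event] == 1))
  }
})

test_that("survival cohort validation enforces its invariants", {
  expect_error(survivalCohort("a", 1, -1, 1), "> 0")
  expect_error(survivalCohort("a", 1, 1, 2), "0/1")
  expect_error(survivalCohort("a", 1, 1, 1, response = "XX"), "unknown")
})
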