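## Association screens, group comparisons, ICB-response contrasts, and
## survival machinery: maximally selected log-rank cutpoints, Kaplan-Meier
## curves, and the two-group log-rank test.

#' Assemble and validate a survival cohort table
#'
#' @param sampleId Sample identifiers.
#' @param score Per-sample score (e.g. hypoxia score).
#' @param time Survival time in days (> 0).
#' @param event Event indicator (0 = censored, 1 = event).
#' @param response Optional RECIST class (CR/PR/SD/PD).
#' @param timepoint Optional treatment timepoint (pre/on).
#' @param patientId Optional patient id pairing pre/on rows.
#' @return data.frame of class \code{SurvivalCohort}.
#' @export
survivalCohort <- function(sampleId, score, time, event, response = NULL,
                           timepoint = NULL, patientId = NULL) {
  n <- length(sampleId)
  stopifnot(length(score) == n, length(time) == n, length(event) == n)
  if (any(time <= 0)) hxStop("survival times must be > 0")
  if (!all(event %in% c(0, 1))) hxStop("event must be 0/1")
  df <- data.frame(sample_id = as.character(sampleId), score = score,
                   time = time, event = as.integer(event),
                   stringsAsFactors = FALSE)
  if (!is.null(response)) {
    bad <- setdiff(unique(response), c("CR", "PR", "SD", "PD", NA))
    if (length(bad)) hxStop("unknown response class: ",
                            paste(bad, collapse = ", "))
    df$response <- response
  }
  if (!is.null(timepoint)) {
    stopifnot(all(timepoint %in% c("pre", "on")))
    df$timepoint <- timepoint
  }
  if (!is.null(patientId)) df$patient_id <- as.character(patientId)
  class(df) <- c("SurvivalCohort", "data.frame")
  df
}

## Spearman rho with average-rank ties; p by t-approximation, or exact
## enumeration of rank permutations when n <= 9
.spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    den <- sqrt(sum(rxc^2))
    ryc <- ry - mean(ry)
    ## each row permutes ry; sum(ry[perm] * rxc) suffices since sum(rxc) = 0
    rhos <- as.vector(matrix(ry[perms], nrow = nrow(perms)) %*% rxc) /
      (den * sqrt(sum(ryc^2)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(c(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p)
}

## all permutations of 1..n as an n! x n matrix (n <= 9)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    block <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, 1L] <- i
    rest <- seq_len(n)[-i]
    out[block, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Spearman association screen with FDR control
#'
#' Spearman correlation (average-rank ties) of a score vector against each
#' feature; p by the t-approximation (exact permutation enumeration when
#' n <= 9), q by Benjamini-Hochberg across features, significance flagged
#' at q < 0.05.
#'
#' @param scores Named numeric per-sample scores.
#' @param features Samples x features numeric matrix (or features in
#'   columns of a data.frame).
#' @param fdrThreshold Significance threshold on q.
#' @return data.frame: feature, rho, p, q, significant. Constant features
#'   get NA rho/p and are excluded from the BH correction.
#' @export
spearmanScreen <- function(scores, features, fdrThreshold = 0.05) {
  features <- as.matrix(features)
  if (!is.null(names(scores)) && !is.null(rownames(features)))
    features <- features[names(scores), , drop = FALSE]
  stopifnot(nrow(features) == length(scores))
  if (length(scores) < 4L) hxStop("need at least 4 paired observations")
  res <- t(apply(features, 2L, function(f) .spearman_p(scores, f)))
  out <- data.frame(feature = colnames(features), rho = res[, "rho"],
                    p = res[, "p"], stringsAsFactors = FALSE)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$q) & out$q < fdrThreshold
  rownames(out) <- NULL
  out
}

#' Two-group score comparison
#'
#' Two-sided Wilcoxon rank-sum test (unpaired) or signed-rank test
#' (paired): exact when total n <= 25 without ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param scores Numeric scores.
#' @param groupLabels Two-level group label per score (unpaired), or NULL
#'   when \code{paired}.
#' @param paired Logical; when TRUE, \code{scores} and \code{scores2} are
#'   matched pairs.
#' @param scores2 Second member of each pair (paired mode).
#' @return List: statistic, p, n per group (or n_pairs).
#' @export
groupCompare <- function(scores, groupLabels = NULL, paired = FALSE,
                         scores2 = NULL) {
  if (paired) {
    stopifnot(!is.null(scores2), length(scores2) == length(scores))
    d <- scores - scores2
    if (all(d == 0))
      return(list(statistic = 0, p = 1, n_pairs = length(d)))
    exact <- length(d) <= 25 && !anyDuplicated(abs(d[d != 0])) &&
      !any(d == 0)
    wt <- stats::wilcox.test(scores, scores2, paired = TRUE, exact = exact)
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                n_pairs = length(d)))
  }
  groups <- unique(groupLabels)
  if (length(groups) != 2L) hxStop("need exactly two groups, found ",
                                   length(groups))
  a <- scores[groupLabels == groups[1L]]
  b <- scores[groupLabels == groups[2L]]
  if (length(a) < 2L || length(b) < 2L)
    hxStop("each group needs >= 2 samples")
  exact <- (length(a) + length(b)) <= 25 && !anyDuplicated(c(a, b))
  wt <- stats::wilcox.test(a, b, exact = exact)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = stats::setNames(c(length(a), length(b)), groups))
}

#' Immunotherapy response contrast
#'
#' Assigns responder/non-responder groups by the chosen pooling
#' ("pd-vs-prcr": CR/PR vs PD, SD excluded; "imvigor": CR/PR/SD vs PD),
#' compares pre-treatment scores between groups, and where paired pre/on
#' profiles exist additionally contrasts the per-patient on-minus-pre score
#' change between responders and non-responders.
#'
#' @param cohort A \code{survivalCohort} (or data.frame) with columns
#'   sample_id, score, response, and optionally timepoint + patient_id.
#' @param pooling Response pooling rule.
#' @return List: groups (per-sample), score_test, delta (per-patient
#'   on - pre changes with responder flag), delta_test (NULL without
#'   pairs).
#' @export
responseContrast <- function(cohort,
                             pooling = c("pd-vs-prcr", "imvigor")) {
  pooling <- match.arg(pooling)
  if (!"response" %in% colnames(cohort))
    hxStop("cohort carries no response labels")
  pre <- if ("timepoint" %in% colnames(cohort))
    cohort[cohort$timepoint == "pre", , drop = FALSE] else cohort
  resp_classes <- if (pooling == "pd-vs-prcr") c("CR", "PR")
                  else c("CR", "PR", "SD")
  grp <- ifelse(pre$response %in% resp_classes, "responder",
                ifelse(pre$response == "PD", "non_responder", NA))
  keep <- !is.na(grp)
  if (sum(grp[keep] == "responder") == 0L ||
      sum(grp[keep] == "non_responder") == 0L)
    hxStop("pooling '", pooling, "' leaves an empty response group")
  score_test <- groupCompare(pre$score[keep], grp[keep])
  score_test$median <- c(
    responder = stats::median(pre$score[keep][grp[keep] == "responder"]),
    non_responder = stats::median(pre$score[keep][grp[keep] ==
                                                    "non_responder"]))
  delta <- NULL
  delta_test <- NULL
  if (all(c("timepoint", "patient_id") %in% colnames(cohort))) {
    pre_rows <- cohort[cohort$timepoint == "pre", ]
    on_rows <- cohort[cohort$timepoint == "on", ]
    shared <- intersect(pre_rows$patient_id, on_rows$patient_id)
    if (length(shared)) {
      d <- on_rows$score[match(shared, on_rows$patient_id)] -
        pre_rows$score[match(shared, pre_rows$patient_id)]
      resp <- pre_rows$response[match(shared, pre_rows$patient_id)]
      dgrp <- ifelse(resp %in% resp_classes, "responder",
                     ifelse(resp == "PD", "non_responder", NA))
      delta <- data.frame(patient_id = shared, delta = d, group = dgrp,
                          stringsAsFactors = FALSE)
      ok <- !is.na(dgrp)
      if (sum(dgrp[ok] == "responder") >= 2L &&
          sum(dgrp[ok] == "non_responder") >= 2L)
        delta_test <- groupCompare(d[ok], dgrp[ok])
    }
  }
  list(groups = stats::setNames(grp, pre$sample_id)[keep],
       score_test = score_test, delta = delta, delta_test = delta_test)
}

#' Two-group log-rank statistic (hypergeometric form)
#'
#' Observed minus expected events in group 1 over distinct event times,
#' with the hypergeometric variance; returns the standardized statistic z
#' and the chi-square z^2.
#'
#' @param time Survival times.
#' @param event Event indicators (0/1).
#' @param inGroup1 Logical membership of group 1.
#' @return List: z, chisq, observed, expected.
#' @export
logrankStatistic <- function(time, event, inGroup1) {
  etimes <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & inGroup1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & inGroup1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  z <- if (V > 0) (O1 - E1) / sqrt(V) else 0
  list(z = z, chisq = z^2, observed = O1, expected = E1)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' candidate cutpoint (midpoints between consecutive distinct scores)
#' whose low/high split keeps each group at least \code{minFraction} of
#' the samples, and returns the cutpoint maximizing the absolute
#' standardized statistic (ties resolved toward the smaller cutpoint).
#'
#' @param cohort \code{survivalCohort} or data.frame with score, time,
#'   event.
#' @param minFraction Minimum group fraction for admissible splits.
#' @return List of class \code{CutpointResult}: cutpoint, statistic (the
#'   maximal absolute standardized log-rank statistic), groups (named
#'   high/low labels), n_candidates.
#' @export
optimalCutpoint <- function(cohort, minFraction = 0.1) {
  score <- cohort$score
  n <- length(score)
  if (n < 10L) hxStop("optimal cutpoint needs >= 10 samples")
  if (sum(cohort$event) < 3L) hxStop("optimal cutpoint needs >= 3 events")
  s <- sort(unique(score))
  if (length(s) < 2L) hxStop("all scores identical; no admissible cutpoint")
  cands <- (head(s, -1L) + s[-1L]) / 2
  min_n <- minFraction * n
  best <- NULL
  for (cut in cands) {
    high <- score > cut
    if (sum(high) < min_n || sum(!high) < min_n) next
    st <- logrankStatistic(cohort$time, cohort$event, high)
    if (is.null(best) || abs(st$z) > best$statistic + 1e-12) {
      best <- list(cutpoint = cut, statistic = abs(st$z))
    }
  }
  if (is.null(best))
    hxStop("no candidate cutpoint satisfies the group-size constraint")
  groups <- ifelse(score > best$cutpoint, "high", "low")
  names(groups) <- cohort$sample_id
  structure(list(cutpoint = best$cutpoint, statistic = best$statistic,
                 groups = groups,
                 n_candidates = length(cands)),
            class = "CutpointResult")
}

#' @export
print.CutpointResult <- function(x, ...) {
  cat(sprintf("CutpointResult: cutpoint %.4g, |standardized log-rank| %.3f, high n=%d low n=%d\n",
              x$cutpoint, x$statistic, sum(x$groups == "high"),
              sum(x$groups == "low")))
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per group (via the survival package), per-group
#' median survival (the earliest time the estimate drops to <= 0.5, NA
#' when it never does), and the two-group log-rank chi-square (1 df) with
#' its p-value.
#'
#' @param cohort \code{survivalCohort} or data.frame with time and event.
#' @param groupLabels Two-level group label per sample.
#' @return List: curves (data.frame group/time/n_risk/n_event/surv),
#'   chisq, p, medians (named).
#' @export
kmLogrank <- function(cohort, groupLabels) {
  time <- cohort$time
  event <- cohort$event
  stopifnot(length(groupLabels) == length(time))
  groups <- sort(unique(groupLabels))
  if (length(groups) != 2L) hxStop("need exactly two groups")
  g <- factor(groupLabels, levels = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^g=", "", strata), time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  medians <- vapply(groups, function(gr) {
    cv <- curves[curves$group == gr, ]
    hit <- which(cv$surv <= 0.5)
    if (length(hit)) cv$time[min(hit)] else NA_real_
  }, numeric(1))
  if (sum(event) == 0L) hxStop("no events in either group")
  ## own hypergeometric form: well-defined even when the variance is zero
  ## (degenerate groups), where the statistic is 0 by convention
  chisq <- logrankStatistic(time, event, g == groups[1L])$chisq
  list(curves = curves, chisq = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       medians = medians)
}
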