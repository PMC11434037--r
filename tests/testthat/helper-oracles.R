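# Independent brute-force oracles, written as naive transcriptions of the
# definitions they check. They share no code with the package internals.

# Weighted-KS rank-walk score: loop over positions from highest to lowest
# expression, accumulating the running hit-minus-miss difference.
oracle_rank_walk <- function(x, signature_genes, exponent = 0.25) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- names(sort(-r))            # highest expression first, stable
  N <- length(x)
  hits <- ord %in% signature_genes
  Ng <- sum(hits)
  hit_w <- numeric(N)
  for (i in seq_len(N)) if (hits[i]) hit_w[i] <- r[ord[i]]^exponent
  hit_w <- hit_w / sum(hit_w)
  running <- 0
  total <- 0
  for (i in seq_len(N)) {
    if (hits[i]) running <- running + hit_w[i]
    else running <- running - 1 / (N - Ng)
    total <- total + running
  }
  total / N
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations into the two group sizes.
oracle_wilcox_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  stats <- apply(idx, 2, function(i) sum(r[i]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up: q_i = min over j >= i of m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in m:1) {
    val <- m * p[o[i]] / i
    q_sorted[i] <- if (i == m) val else min(val, q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Standardized log-rank statistic computed event-time by event-time from
# first principles (no shared code with logrankStatistic).
oracle_logrank_z <- function(time, event, g1) {
  ts <- sort(unique(time[event == 1]))
  o <- 0; e <- 0; v <- 0
  for (tt in ts) {
    Y <- time >= tt
    Y1 <- Y & g1
    dd <- sum(time == tt & event == 1)
    dd1 <- sum(time == tt & event == 1 & g1)
    o <- o + dd1
    e <- e + dd * sum(Y1) / sum(Y)
    if (sum(Y) > 1)
      v <- v + dd * sum(Y1) * (sum(Y) - sum(Y1)) * (sum(Y) - dd) /
        (sum(Y)^2 * (sum(Y) - 1))
  }
  if (v <= 0) return(0)
  (o - e) / sqrt(v)
}

# Exhaustive maximally selected cutpoint: scan every admissible midpoint.
oracle_best_cutpoint <- function(score, time, event, min_frac = 0.1) {
  s <- sort(unique(score))
  cands <- (s[-length(s)] + s[-1]) / 2
  best_cut <- NA_real_
  best_stat <- -Inf
  for (ct in cands) {
    hi <- score > ct
    if (sum(hi) < min_frac * length(score) ||
        sum(!hi) < min_frac * length(score)) next
    z <- abs(oracle_logrank_z(time, event, hi))
    if (z > best_stat + 1e-12) { best_stat <- z; best_cut <- ct }
  }
  list(cutpoint = best_cut, statistic = best_stat)
}

# Tiny constructed slide: a hex patch whose counts come from two
# well-separated programs (malignant core vs everything else).
make_two_program_slide <- function(n_rings = 2, mal_rings = 0, seed = 42,
                                   sep = 50) {
  set.seed(seed)
  lat <- hexLattice(n_rings)
  n <- nrow(lat)
  barcode <- sprintf("s%03d", seq_len(n))
  genes <- c(sprintf("MALG%02d", 1:10), sprintf("OTHR%02d", 1:10),
             sprintf("BGRD%02d", 1:30))
  mu <- matrix(5, length(genes), n, dimnames = list(genes, barcode))
  is_mal <- lat$ring <= mal_rings
  mu[1:10, is_mal] <- sep
  mu[11:20, !is_mal] <- sep
  counts <- matrix(rpois(length(mu), as.vector(mu)), nrow = length(genes),
                   dimnames = dimnames(mu))
  pos <- data.frame(barcode = barcode, array_row = lat$r,
                    array_col = lat$q, px_x = lat$px_x, px_y = lat$px_y)
  truth <- ifelse(lat$ring <= mal_rings, "Mal",
                  ifelse(lat$ring == mal_rings + 1, "Bdy", "nMal"))
  SpatialSlide(counts, pos, truthRegion = setNames(truth, barcode))
}
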