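# Independent oracles used to validate the package's own implementations.
# Each is written directly from the defining formula or by exhaustive
# enumeration, deliberately sharing no code with the package internals.

# exact binomial upper tail by term-by-term summation
oracle_binom_tail <- function(k, n, e) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(vapply(k:n, function(x) choose(n, x) * e^x * (1 - e)^(n - x), 0))
}

# Tukey 1-df non-additivity statistic computed with explicit loops
oracle_tukey <- function(y) {
  rmeans <- apply(y, 1, mean); cmeans <- apply(y, 2, mean); gm <- mean(y)
  N <- 0; ss_resid <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    N <- N + y[i, j] * (rmeans[i] - gm) * (cmeans[j] - gm)
    ss_resid <- ss_resid + (y[i, j] - rmeans[i] - cmeans[j] + gm)^2
  }
  ss_nonadd <- N^2 / (sum((rmeans - gm)^2) * sum((cmeans - gm)^2))
  Fv <- ss_nonadd / ((ss_resid - ss_nonadd) / 5)
  list(F = Fv, p = stats::pf(Fv, 1, 5, lower.tail = FALSE))
}

# brute-force average-linkage agglomeration from a distance matrix;
# returns the sequence of merge heights
oracle_average_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exhaustive best collinear chain (strictly increasing q and t, gap
# constraint on both axes) by depth-first enumeration over chains;
# score ties broken towards longer chains, mirroring the package rule
oracle_best_chain <- function(q, t, s, gap_penalty, max_gap) {
  n <- length(q)
  best <- list(score = -Inf, rows = integer())
  extend <- function(rows, score) {
    if (score > best$score ||
        (score == best$score && length(rows) > length(best$rows))) {
      best <<- list(score = score, rows = rows)
    }
    last <- rows[length(rows)]
    for (i in seq_len(n)) {
      dq <- q[i] - q[last]; dt <- t[i] - t[last]
      if (dq >= 1 && dt >= 1 && dq - 1 <= max_gap && dt - 1 <= max_gap) {
        extend(c(rows, i), score + s[i] - gap_penalty * ((dq - 1) + (dt - 1)))
      }
    }
  }
  for (i in seq_len(n)) extend(i, s[i])
  best
}

# exhaustive best chain over both orientations (same preferred on ties)
oracle_best_chain_both <- function(q, t, s, gap_penalty, max_gap) {
  same <- oracle_best_chain(q, t, s, gap_penalty, max_gap)
  inv <- oracle_best_chain(q, -t, s, gap_penalty, max_gap)
  if (inv$score > same$score ||
      (inv$score == same$score && length(inv$rows) > length(same$rows))) {
    inv
  } else same
}

# best-first chain extraction using the exhaustive oracle; returns the
# ordered vector of extracted chain scores
oracle_extract_chains <- function(q, t, s, gap_penalty, max_gap, min_anchors) {
  remaining <- seq_along(q)
  scores <- numeric(0)
  while (length(remaining) >= min_anchors) {
    best <- oracle_best_chain_both(q[remaining], t[remaining], s[remaining],
                                   gap_penalty, max_gap)
    if (length(best$rows) < min_anchors) break
    scores <- c(scores, best$score)
    remaining <- remaining[-best$rows]
  }
  scores
}

# literal per-query hit filter
oracle_filter_hits <- function(hits, e_max = 1e-20, margin = 0.6) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (hits$evalue[i] > e_max) next
    same_q <- hits$qseqid == hits$qseqid[i] & hits$evalue <= e_max
    keep[i] <- hits$bitscore[i] >= margin * max(hits$bitscore[same_q])
  }
  hits[keep, ]
}
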