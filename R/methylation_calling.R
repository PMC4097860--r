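#' Estimate the bisulfite non-conversion rate from an unmethylated spike-in
#'
#' The unmethylated lambda control carries no true methylation, so any
#' methylated read observed there reflects failed bisulfite conversion.
#' The pooled estimate is `e = sum(k) / sum(n)` over all control sites.
#'
#' @param lambda_sites Tibble of control cytosines with `meth_reads` and
#'   `total_reads` columns.
#' @return One-row tibble: `e`, `meth_reads`, `total_reads`, and a
#'   binomial standard error `se`.
#' @export
estimate_nonconversion <- function(lambda_sites) {
  k <- sum(lambda_sites$meth_reads)
  n <- sum(lambda_sites$total_reads)
  if (n == 0) abort("control absent: total read count over lambda sites is 0")
  e <- k / n
  tibble(e = e, meth_reads = k, total_reads = n,
         se = sqrt(e * (1 - e) / n))
}

#' Assign the sequence context of a cytosine
#'
#' CG if the next base (in the strand's 5'-to-3' direction) is G, CHG if the
#' base after next is G, otherwise CHH.  Sites whose context window is
#' truncated by the chromosome end are assigned CHH (the asymmetric
#' fallback).  Vectorised over `chrom`, `pos`, `strand`.
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param chrom,pos,strand Site coordinates (1-based; strand `"+"`/`"-"`).
#' @return Character vector of contexts in `c("CG", "CHG", "CHH")`.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome)) {
      abort(sprintf("chromosome '%s' not in genome", ch))
    }
    s <- strsplit(toupper(genome[[ch]]), "", fixed = TRUE)[[1]]
    p <- pos[idx]; st <- strand[idx]
    if (any(p < 1 | p > length(s))) abort("position outside chromosome")
    base <- s[p]
    bad <- (st == "+" & base != "C") | (st == "-" & base != "G")
    if (any(bad)) {
      abort(sprintf("base at %s:%d(%s) is not a cytosine on that strand",
                    ch, p[which(bad)[1]], st[which(bad)[1]]))
    }
    n1 <- ifelse(st == "+", s[p + 1L], s[ifelse(p >= 2L, p - 1L, NA_integer_)])
    n2 <- ifelse(st == "+", s[p + 2L], s[ifelse(p >= 3L, p - 2L, NA_integer_)])
    want <- ifelse(st == "+", "G", "C")
    out[idx] <- ifelse(!is.na(n1) & n1 == want, "CG",
                       ifelse(!is.na(n2) & n2 == want, "CHG", "CHH"))
  }
  out
}

#' Call methylated cytosines with a spike-in-calibrated binomial test
#'
#' For each site with depth `n >= min_depth`, the one-sided binomial upper
#' tail `p = P(X >= k | n, e)` is computed under the null that all observed
#' methylated reads are non-conversion artefacts at rate `e`.
#' Benjamini-Hochberg correction is applied jointly across all tested sites
#' (or within each context with `per_context = TRUE`); a site is called
#' methylated iff `q < alpha`.  Strands are tested independently.
#'
#' @param sites Tibble with `meth_reads`, `total_reads` and (for
#'   `per_context`) `context` columns; other columns pass through.
#' @param e Non-conversion rate in `[0, 1)`, e.g. from
#'   [estimate_nonconversion()].
#' @param alpha False discovery rate threshold.
#' @param min_depth Minimum depth for a site to be tested; shallower sites
#'   are `status = "untested"` with `NA` p/q.
#' @param per_context Apply BH within each context instead of jointly.
#' @return Input tibble with added `ratio`, `p_value`, `q_value`, `status`
#'   columns, class `meth_calls`.
#' @export
call_sites <- function(sites, e, alpha = 0.05, min_depth = 1,
                       per_context = FALSE) {
  if (is.data.frame(e)) e <- e$e[1]
  if (e >= 1 || e < 0) abort("e must lie in [0, 1)")
  k <- sites$meth_reads; n <- sites$total_reads
  if (any(k > n | k < 0)) abort("need 0 <= meth_reads <= total_reads")
  out <- sites %>% mutate(ratio = ifelse(n > 0, k / n, NA_real_))
  if (nrow(out) == 0) {
    out <- out %>% mutate(p_value = numeric(0), q_value = numeric(0),
                          status = character(0))
    class(out) <- c("meth_calls", class(out))
    return(out)
  }
  tested <- n >= min_depth
  p <- rep(NA_real_, nrow(out))
  # upper tail P(X >= k) = P(X > k - 1)
  p[tested] <- stats::pbinom(k[tested] - 1, n[tested], e, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(out))
  if (per_context) {
    for (cx in unique(out$context[tested])) {
      sel <- tested & out$context == cx
      q[sel] <- stats::p.adjust(p[sel], method = "BH")
    }
  } else {
    q[tested] <- stats::p.adjust(p[tested], method = "BH")
  }
  out <- out %>% mutate(
    p_value = p, q_value = q,
    status = ifelse(!tested, "untested",
                    ifelse(q < alpha, "methylated", "unmethylated")))
  class(out) <- c("meth_calls", unique(class(out)))
  attr(out, "call_params") <- list(e = e, alpha = alpha,
                                   min_depth = min_depth,
                                   per_context = per_context)
  out
}
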