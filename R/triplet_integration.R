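#' Gene-body methylation of genes
#'
#' Convenience summary: the read-level or site-level mCG/mCHG/mCHH level of
#' each gene's body (exons plus introns) from a call table and gene parts.
#'
#' @param calls A `meth_calls` tibble.
#' @param features Feature tibble (`gene_id`, `chrom`, `part`, `start`,
#'   `end`); body parts are exons, introns and UTRs.
#' @param min_depth Minimum tested depth.
#' @return Tibble: `gene_id`, `context`, `level` (fraction of tested body
#'   sites called methylated).
#' @export
gene_body_methylation <- function(calls, features, min_depth = 1) {
  body <- features %>%
    filter(!.data$part %in% c("promoter", "downstream"))
  pairs <- overlap_pairs(calls, body)
  if (!nrow(pairs)) {
    return(tibble(gene_id = character(), context = character(),
                  level = numeric()))
  }
  tibble(gene_id = body$gene_id[pairs$feature_row],
         context = calls$context[pairs$site_row],
         status = calls$status[pairs$site_row],
         n = calls$total_reads[pairs$site_row]) %>%
    filter(.data$status != "untested", .data$n >= min_depth) %>%
    group_by(.data$gene_id, .data$context) %>%
    summarise(level = mean(.data$status == "methylated"), .groups = "drop")
}

#' Expression summarised in gene-body methylation bins
#'
#' Bins genes by their gene-body mCG level into `n_bins` equal-width bins
#' on `[0, 1]` and summarises `ln(FPKM + 1)` per bin, exposing the
#' non-linear relation between moderate gene-body methylation and
#' expression.
#'
#' @param genes Tibble with one row per gene carrying `mCG` (gene-body
#'   level in `[0,1]`) and `fpkm` columns.
#' @param n_bins Number of equal-width bins.
#' @return Tibble of class `meth_expr_bins`: `bin`, `bin_mid`, `n`,
#'   `q1`, `median`, `q3` of transformed expression.  Empty bins are
#'   reported with `n = 0`.
#' @export
methylation_expression_bins <- function(genes, n_bins = 10) {
  if (any(genes$mCG < 0 | genes$mCG > 1, na.rm = TRUE)) {
    abort("mCG levels must lie in [0, 1]")
  }
  y <- transform_expression(genes$fpkm)
  bin <- pmin(floor(genes$mCG * n_bins) + 1, n_bins)
  occ <- tibble(bin = bin, y = y) %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$bin) %>%
    summarise(n = n(),
              q1 = stats::quantile(.data$y, 0.25),
              median = stats::median(.data$y),
              q3 = stats::quantile(.data$y, 0.75), .groups = "drop")
  out <- tibble(bin = seq_len(n_bins)) %>%
    left_join(occ, by = "bin") %>%
    mutate(n = as.integer(tidyr::replace_na(.data$n, 0)),
           bin_mid = (.data$bin - 0.5) / n_bins) %>%
    select("bin", "bin_mid", "n", "q1", "median", "q3")
  class(out) <- c("meth_expr_bins", class(out))
  out
}

#' Compare gene-body methylation distributions across sub-genomes
#'
#' Summarises the per-gene gene-body methylation distribution of each
#' sub-genome per context and tests for a location difference across the
#' three sub-genomes with the Kruskal-Wallis rank test (distribution-free;
#' no test named in the source tradition for this comparison).
#'
#' @param syntelogs Syntelog table (`LF`, `MF1`, `MF2` gene ids).
#' @param levels Tibble `gene_id`, `context`, `level` (e.g. from
#'   [gene_body_methylation()]).
#' @return List: `summary` (sub-genome x context medians, quartiles, n)
#'   and `tests` (`context`, `kruskal_p`; `NA` when any sub-genome has
#'   fewer than 2 genes in that context).
#' @export
subgenome_methylation_comparison <- function(syntelogs, levels) {
  subg <- c("LF", "MF1", "MF2")
  long <- syntelogs %>%
    tidyr::pivot_longer(dplyr::all_of(subg), names_to = "subgenome",
                        values_to = "gene_id") %>%
    filter(!is.na(.data$gene_id)) %>%
    inner_join(levels, by = "gene_id")
  summary <- long %>% group_by(.data$subgenome, .data$context) %>%
    summarise(n = n(), q1 = stats::quantile(.data$level, 0.25),
              median = stats::median(.data$level),
              q3 = stats::quantile(.data$level, 0.75), .groups = "drop")
  tests <- long %>% group_by(.data$context) %>%
    summarise(kruskal_p = {
      counts <- table(factor(.data$subgenome, levels = subg))
      if (any(counts < 2)) NA_real_
      else stats::kruskal.test(.data$level,
                               factor(.data$subgenome))$p.value
    }, .groups = "drop")
  list(summary = summary, tests = tests)
}

#' Triplet-level correlation matrix of expression and methylation
#'
#' Builds the 12x12 Pearson correlation matrix across triplets of the
#' four per-copy variables (FPKM and the three methylation contexts for
#' LF, MF1, MF2) and orders the variables by their angular position on the
#' plane of the first two principal components of the correlation matrix
#' (the corrgram convention); the sign of each component is fixed so its
#' first nonzero loading is non-negative, making the ordering
#' deterministic.
#'
#' @param profiles Tibble: `triplet_id` plus 12 numeric columns (e.g.
#'   `LF_fpkm`, `LF_mCG`, ..., `MF2_mCHH`).  Zero-variance variables are
#'   excluded with a message.
#' @return Object of class `triplet_correlation`: `cor` (correlation
#'   matrix), `ordering` (variable names in angular order), `excluded`.
#' @export
triplet_correlation <- function(profiles) {
  vars <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  X <- as.matrix(profiles[, vars])
  if (nrow(X) < 3) abort("need at least 3 triplets")
  v <- apply(X, 2, stats::var)
  excluded <- vars[v == 0 | is.na(v)]
  if (length(excluded)) {
    inform(paste("excluding zero-variance variables:",
                 paste(excluded, collapse = ", ")))
  }
  X <- X[, setdiff(vars, excluded), drop = FALSE]
  cm <- stats::cor(X)
  eg <- eigen(cm, symmetric = TRUE)
  pc <- eg$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    nz <- which(abs(pc[, j]) > 1e-12)[1]
    if (!is.na(nz) && pc[nz, j] < 0) pc[, j] <- -pc[, j]
  }
  ang <- atan2(pc[, 2], pc[, 1])
  ordering <- colnames(cm)[order(ang)]
  structure(list(cor = cm, ordering = ordering, excluded = excluded,
                 pc = pc),
            class = "triplet_correlation")
}

#' @export
print.triplet_correlation <- function(x, ...) {
  cat("Triplet correlation matrix over", ncol(x$cor), "variables\n")
  cat("PCA ordering:", paste(x$ordering, collapse = " "), "\n")
  invisible(x)
}
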