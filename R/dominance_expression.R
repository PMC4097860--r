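#' Log-transform an FPKM matrix
#'
#' `y = ln(FPKM + 1)`, elementwise.  All downstream dominance calculations
#' operate on this scale.
#'
#' @param fpkm Numeric matrix (or vector) of non-negative FPKM values.
#' @return Transformed object of the same shape.
#' @export
transform_expression <- function(fpkm) {
  if (any(fpkm < 0)) abort("FPKM values must be non-negative")
  log(fpkm + 1)
}

#' Sub-genome with the highest mean expression
#'
#' Means are taken over the four tissues for each sub-genome row of the
#' transformed matrix; ties are broken in the fixed order LF > MF1 > MF2
#' and flagged.
#'
#' @param y 3x4 transformed matrix with rows LF, MF1, MF2.
#' @return List: `subgenome` label and logical `tie`.
#' @export
highest_subgenome <- function(y) {
  stopifnot(nrow(y) == 3)
  labs <- rownames(y) %||% c("LF", "MF1", "MF2")
  m <- rowMeans(y)
  list(subgenome = labs[which.max(m)], tie = sum(m == max(m)) > 1)
}

#' Tukey one-degree-of-freedom test for non-additivity
#'
#' For an unreplicated 3 sub-genome x 4 tissue table there is no pure error
#' term, so interaction is tested with Tukey's single-degree-of-freedom
#' multiplicative term: with row effects `a_i = rowmean - grandmean` and
#' column effects `b_j = colmean - grandmean`,
#' `N = sum y_ij a_i b_j`, `SS_nonadd = N^2 / (sum a_i^2 * sum b_j^2)`,
#' `SS_resid = sum (y_ij - rowmean_i - colmean_j + grandmean)^2`, and
#' `F = SS_nonadd / ((SS_resid - SS_nonadd) / 5)` on (1, 5) df.
#' Degenerate tables (zero row or column variance, or residual entirely
#' absorbed by the non-additivity term) return `p = 1` with a flag.
#'
#' @param y 3x4 numeric matrix on the transformed scale.
#' @param tol Relative tolerance for degenerate denominators.
#' @return One-row tibble: `F_statistic`, `p_value`, `degenerate`.
#' @export
tukey_test <- function(y, tol = 1e-12) {
  if (!is.matrix(y) || nrow(y) != 3 || ncol(y) != 4) {
    abort("y must be a 3x4 matrix (sub-genomes x tissues)")
  }
  res <- tukey_test_many(matrix(as.numeric(t(y)), nrow = 1), tol = tol)
  tibble(F_statistic = res$F_statistic, p_value = res$p_value,
         degenerate = res$degenerate)
}

# vectorised Tukey 1-df test over many 3x4 tables; ymat is n x 12 with
# tissue varying fastest within sub-genome (rows LF,MF1,MF2 concatenated)
tukey_test_many <- function(ymat, tol = 1e-12) {
  n <- nrow(ymat)
  idx <- matrix(seq_len(12), nrow = 3, byrow = TRUE)  # [subgenome, tissue]
  rm_ <- sapply(1:3, function(i) rowMeans(ymat[, idx[i, ], drop = FALSE]))
  cm_ <- sapply(1:4, function(j) rowMeans(ymat[, idx[, j], drop = FALSE]))
  rm_ <- matrix(rm_, n, 3); cm_ <- matrix(cm_, n, 4)
  gm <- rowMeans(ymat)
  a <- rm_ - gm; b <- cm_ - gm
  ssa <- rowSums(a^2); ssb <- rowSums(b^2)
  N <- numeric(n); ss_resid <- numeric(n)
  for (i in 1:3) for (j in 1:4) {
    r <- ymat[, idx[i, j]] - rm_[, i] - cm_[, j] + gm
    N <- N + ymat[, idx[i, j]] * a[, i] * b[, j]
    ss_resid <- ss_resid + r^2
  }
  denom <- ssa * ssb
  ss_nonadd <- ifelse(denom > 0, N^2 / denom, 0)
  rem <- ss_resid - ss_nonadd
  scale_ref <- pmax(ss_resid, 1)
  degenerate <- ssa <= tol | ssb <= tol | rem <= tol * scale_ref
  Fv <- ifelse(degenerate, NA_real_, ss_nonadd / (rem / 5))
  p <- ifelse(degenerate, 1, stats::pf(Fv, 1, 5, lower.tail = FALSE))
  list(F_statistic = Fv, p_value = p, degenerate = degenerate)
}

#' Test sub-genome dominance across fully retained triplets
#'
#' Transforms the FPKM table to `ln(FPKM+1)`, records the sub-genome with
#' the highest mean expression per triplet, and applies the Tukey
#' one-degree-of-freedom interaction test ([tukey_test()]) to each 3x4
#' table.
#'
#' @param triplets Tibble with `triplet_id`, `subgenome` (LF/MF1/MF2) and
#'   FPKM columns `leaf`, `root`, `flower`, `pod` (three rows per triplet),
#'   e.g. from [simulate_expression_triplets()].
#' @param transform Apply the `ln(x+1)` transform (set `FALSE` if the
#'   values are already transformed).
#' @param alpha Significance threshold carried to summaries.
#' @return Object of class `dominance_fit`; see [tidy()] for the
#'   per-triplet table and [glance()] for the summary.
#' @export
dominance_test <- function(triplets, transform = TRUE, alpha = 0.05) {
  tissues <- c("leaf", "root", "flower", "pod")
  subg <- c("LF", "MF1", "MF2")
  wide <- triplets %>%
    arrange(.data$triplet_id, match(.data$subgenome, subg))
  ids <- unique(wide$triplet_id)
  if (nrow(wide) != 3 * length(ids)) {
    abort("each triplet needs exactly one row per sub-genome")
  }
  ymat <- as.matrix(wide[, tissues])
  if (transform) ymat <- transform_expression(ymat)
  n <- length(ids)
  ymat12 <- matrix(t(ymat), nrow = n, byrow = TRUE)  # n x 12, LF cols 1:4
  res <- tukey_test_many(ymat12)
  rowmeans <- sapply(1:3, function(i)
    rowMeans(ymat12[, (i - 1) * 4 + 1:4, drop = FALSE]))
  rowmeans <- matrix(rowmeans, n, 3)
  top <- apply(rowmeans, 1, which.max)  # which.max breaks ties low = LF first
  tie <- rowSums(rowmeans == rowmeans[cbind(seq_len(n), top)]) > 1
  results <- tibble(triplet_id = ids,
                    highest_subgenome = subg[top],
                    tie = tie,
                    F_statistic = res$F_statistic,
                    p_value = res$p_value,
                    degenerate = res$degenerate)
  structure(list(results = results, alpha = alpha, n_triplets = n),
            class = "dominance_fit")
}

#' @export
tidy.dominance_fit <- function(x, ...) x$results

#' @export
glance.dominance_fit <- function(x, ...) {
  s <- dominance_summary(x$results, alpha = x$alpha)
  tibble(n_triplets = x$n_triplets, n_significant = s$n_significant,
         lf_share = s$shares[["LF"]], mf1_share = s$shares[["MF1"]],
         mf2_share = s$shares[["MF2"]], alpha = x$alpha)
}

#' @export
print.dominance_fit <- function(x, ...) {
  cat("Sub-genome dominance fit:", x$n_triplets, "triplets\n")
  print(glance(x))
  invisible(x)
}

#' Summarise dominance among significant triplets
#'
#' Counts triplets with Tukey `p < alpha` and, among them, the share of
#' each sub-genome recorded as highest-expressed.
#'
#' @param results Per-triplet tibble (from [tidy()] on a `dominance_fit`)
#'   or the fit itself.
#' @param alpha Significance threshold.
#' @return List: `n_significant`, `n_total`, and named `shares` (summing
#'   to 1 when any triplet is significant, otherwise 0).
#' @export
dominance_summary <- function(results, alpha = 0.05) {
  if (inherits(results, "dominance_fit")) results <- results$results
  subg <- c("LF", "MF1", "MF2")
  if (nrow(results) == 0) {
    return(list(n_significant = 0L, n_total = 0L,
                shares = setNames(rep(0, 3), subg)))
  }
  sig <- results[results$p_value < alpha, ]
  shares <- if (nrow(sig)) {
    table(factor(sig$highest_subgenome, levels = subg)) / nrow(sig)
  } else setNames(rep(0, 3), subg)
  list(n_significant = nrow(sig), n_total = nrow(results),
       shares = setNames(as.numeric(shares), subg))
}

#' Cumulative dominance curve along the Tukey p-value ranking
#'
#' Triplets are sorted by ascending interaction p-value (ties by
#' `triplet_id`); at each rank the cumulative proportion of triplets whose
#' highest-expressed copy is LF, MF1 or MF2 is reported.
#'
#' @param results Per-triplet tibble or a `dominance_fit`.
#' @return Tidy tibble: `rank`, `triplet_id`, `p_value`, then cumulative
#'   fractions `LF`, `MF1`, `MF2` (summing to 1 at every rank).
#' @export
cumulative_dominance_curve <- function(results) {
  if (inherits(results, "dominance_fit")) results <- results$results
  subg <- c("LF", "MF1", "MF2")
  res <- results %>% arrange(.data$p_value, .data$triplet_id) %>%
    mutate(rank = row_number())
  for (g in subg) {
    res[[g]] <- cumsum(res$highest_subgenome == g) / res$rank
  }
  out <- res %>% select("rank", "triplet_id", "p_value",
                        dplyr::all_of(subg))
  class(out) <- c("dominance_curve", class(out))
  out
}

#' Cluster tissue expression profiles
#'
#' Agglomerative average-linkage clustering of per-gene expression
#' profiles using `1 - Pearson correlation` as the distance, cut to
#' exactly `k` clusters.  Genes with zero variance across tissues carry no
#' profile shape and are filtered out first (their count is reported).
#'
#' @param expr Tibble: `gene_id` plus one numeric column per tissue
#'   (transformed values).
#' @param k Number of clusters.
#' @param transform Apply `ln(x+1)` first.
#' @return Object of class `expression_clustering`: `assignments`
#'   (`gene_id`, `cluster`), `tree` (an [stats::hclust] object),
#'   `n_filtered`.
#' @export
cluster_expression_profiles <- function(expr, k = 15, transform = FALSE) {
  vals <- as.matrix(expr[, vapply(expr, is.numeric, logical(1))])
  rownames(vals) <- expr$gene_id
  if (transform) vals <- transform_expression(vals)
  v <- apply(vals, 1, stats::var)
  keep <- v > 0 & !is.na(v)
  n_filtered <- sum(!keep)
  if (n_filtered) inform(sprintf("filtered %d zero-variance genes", n_filtered))
  vals <- vals[keep, , drop = FALSE]
  if (k > nrow(vals)) abort("k exceeds the number of clusterable genes")
  d <- stats::as.dist(1 - stats::cor(t(vals)))
  tree <- stats::hclust(d, method = "average")
  if (any(diff(tree$height) < -1e-8)) {
    warn("merge heights are not monotone non-decreasing")
  }
  cl <- stats::cutree(tree, k = k)
  structure(list(assignments = tibble(gene_id = rownames(vals),
                                      cluster = as.integer(cl)),
                 tree = tree, n_filtered = n_filtered, k = k),
            class = "expression_clustering")
}

#' @export
tidy.expression_clustering <- function(x, ...) x$assignments

#' @export
glance.expression_clustering <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignments), n_filtered = x$n_filtered)
}

#' Export a clustering merge tree as Newick
#'
#' @param clustering An `expression_clustering` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_cluster_tree <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Fraction of triplets separated across expression clusters
#'
#' A triplet is separated when its clustered members do not all fall in
#' one cluster.  The primary statistic is the fraction of clustered
#' triplet-member genes belonging to separated triplets; the fraction of
#' triplets separated (among triplets with at least two clustered members)
#' is reported as secondary.
#'
#' @param assignments Tibble `gene_id`, `cluster` (or an
#'   `expression_clustering`).
#' @param syntelogs Syntelog table with `LF`, `MF1`, `MF2` gene-id columns;
#'   only fully retained rows are used.
#' @return One-row tibble: `gene_fraction`, `triplet_fraction`,
#'   `n_triplets`, `n_separated`, `n_genes`.
#' @export
triplet_separation <- function(assignments, syntelogs) {
  if (inherits(assignments, "expression_clustering")) {
    assignments <- assignments$assignments
  }
  trip <- syntelogs[stats::complete.cases(syntelogs[, c("LF", "MF1", "MF2")]), ]
  trip$.trip <- if ("triplet_id" %in% names(trip)) trip$triplet_id
                else sprintf("trip%05d", seq_len(nrow(trip)))
  long <- trip %>%
    tidyr::pivot_longer(dplyr::all_of(c("LF", "MF1", "MF2")),
                        names_to = "subgenome", values_to = "gene_id") %>%
    inner_join(assignments, by = "gene_id")
  per_trip <- long %>% group_by(.data$.trip) %>%
    summarise(n_members = n(), n_clusters = n_distinct(.data$cluster),
              .groups = "drop") %>%
    mutate(separated = .data$n_clusters > 1)
  eligible <- per_trip %>% filter(.data$n_members >= 2)
  gene_tbl <- long %>% inner_join(per_trip, by = ".trip")
  tibble(
    gene_fraction = if (nrow(gene_tbl)) mean(gene_tbl$separated) else NA_real_,
    triplet_fraction = if (nrow(eligible)) mean(eligible$separated) else NA_real_,
    n_triplets = nrow(per_trip),
    n_separated = sum(per_trip$separated),
    n_genes = nrow(gene_tbl))
}
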