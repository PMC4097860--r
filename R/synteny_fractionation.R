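#' Filter homology hits by E-value and bit-score margin
#'
#' Keeps hits with `evalue <= e_max` whose bit score lies within the top
#' 40% margin below the per-query best, i.e. `bitscore >= 0.6 * best`
#' (`mode = "margin"`, the default reading).  `mode = "quantile"` instead
#' keeps, per query, hits at or above the 60th percentile of bit scores
#' among E-value-passing hits.
#'
#' @param hits Tibble: `qseqid`, `sseqid`, `bitscore`, `evalue`.
#' @param e_max E-value cutoff.
#' @param margin Retained fraction of the best bit score (margin mode).
#' @param mode `"margin"` or `"quantile"`.
#' @return Filtered tibble.
#' @export
filter_hits <- function(hits, e_max = 1e-20, margin = 0.6,
                        mode = c("margin", "quantile")) {
  mode <- match.arg(mode)
  h <- hits %>% filter(.data$evalue <= e_max)
  if (!nrow(h)) return(h)
  if (mode == "margin") {
    h %>% group_by(.data$qseqid) %>%
      filter(.data$bitscore >= margin * max(.data$bitscore)) %>%
      ungroup()
  } else {
    h %>% group_by(.data$qseqid) %>%
      filter(.data$bitscore >= stats::quantile(.data$bitscore, margin)) %>%
      ungroup()
  }
}

# best chain by DP over anchors with strictly increasing query_index and
# strictly increasing target_index (orientation handled by caller via
# negated target indices); score ties are broken towards longer chains so
# that extraction is deterministic; returns list(rows, score)
best_chain_dp <- function(q, t, s, gap_penalty, max_gap) {
  n <- length(q)
  ord <- order(q, t)
  q <- q[ord]; t <- t[ord]; s <- s[ord]
  dp <- s; len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      dq <- q[i] - q[j]; dt <- t[i] - t[j]
      if (dq < 1 || dt < 1) next
      if (dq - 1 > max_gap || dt - 1 > max_gap) next
      cand <- dp[j] + s[i] - gap_penalty * ((dq - 1) + (dt - 1))
      if (cand > dp[i] || (cand == dp[i] && len[j] + 1L > len[i])) {
        dp[i] <- cand; prev[i] <- j; len[i] <- len[j] + 1L
      }
    }
  }
  best <- which(dp == max(dp))
  best <- best[which.max(len[best])]
  path <- integer(0); i <- best
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  list(rows = ord[path], score = dp[best])
}

#' Chain collinear anchors by dynamic programming
#'
#' Builds maximal-score collinear chains over gene-order anchors, scoring
#' `sum(anchor scores) - gap_penalty * sum(gaps)` where the gap of a
#' transition is the number of intervening gene positions on each axis;
#' transitions are allowed only when both index gaps are at most
#' `max_gap_genes`.  Both orientations (target index increasing and
#' decreasing) are searched; chains are extracted best-first, each anchor
#' used by at most one chain; chains with fewer than `min_anchors` anchors
#' are discarded.
#'
#' @param anchors Tibble with `query_index`, `target_index`, `score`;
#'   optional `query_chrom`/`target_chrom` columns partition the search,
#'   and any further columns (e.g. `query_gene`, `block`) pass through.
#' @param gap_penalty Penalty per intervening gene position.
#' @param max_gap_genes Maximum intervening genes on either axis.
#' @param min_anchors Minimum anchors per reported chain.
#' @return Long tibble: one row per chained anchor with `chain_id`,
#'   `orientation`, `chain_score`, `n_anchors` plus the anchor columns.
#' @export
chain_anchors <- function(anchors, gap_penalty = 1, max_gap_genes = 10,
                          min_anchors = 5) {
  if (!nrow(anchors)) {
    return(bind_cols(tibble(chain_id = integer(), orientation = character(),
                            chain_score = numeric(), n_anchors = integer()),
                     anchors))
  }
  grp <- interaction(
    anchors[["query_chrom"]] %||% rep("*", nrow(anchors)),
    anchors[["target_chrom"]] %||% rep("*", nrow(anchors)),
    drop = TRUE)
  chains <- list(); next_id <- 1L
  for (g in levels(grp)) {
    sub <- anchors[grp == g, , drop = FALSE]
    remaining <- rep(TRUE, nrow(sub))
    repeat {
      idx <- which(remaining)
      if (length(idx) < min_anchors) break
      q <- sub$query_index[idx]; t <- sub$target_index[idx]
      s <- sub$score[idx]
      same <- best_chain_dp(q, t, s, gap_penalty, max_gap_genes)
      inv <- best_chain_dp(q, -t, s, gap_penalty, max_gap_genes)
      use_inv <- inv$score > same$score ||
        (inv$score == same$score &&
           length(inv$rows) > length(same$rows))
      best <- if (use_inv) inv else same
      if (length(best$rows) < min_anchors) break
      rows <- idx[best$rows]
      chains[[next_id]] <- sub[rows, , drop = FALSE] %>%
        mutate(chain_id = next_id,
               orientation = if (use_inv) "inverted" else "same",
               chain_score = best$score,
               n_anchors = length(rows))
      remaining[rows] <- FALSE
      next_id <- next_id + 1L
    }
  }
  if (!length(chains)) {
    return(bind_cols(tibble(chain_id = integer(), orientation = character(),
                            chain_score = numeric(), n_anchors = integer()),
                     anchors[0, , drop = FALSE]))
  }
  bind_rows(chains) %>%
    select("chain_id", "orientation", "chain_score", "n_anchors",
           dplyr::everything())
}

#' Resolve query genes shared between chains
#'
#' A query gene participating in more than one chain (via duplicated
#' targets) is kept only in the highest-scoring chain and removed from the
#' weaker ones; chains falling below `min_anchors` afterwards are deleted.
#' Pruned chains' scores are recomputed as the sum of their remaining
#' anchor scores.
#'
#' @param chains Long chain tibble from [chain_anchors()] with a query
#'   gene identifier column.
#' @param min_anchors Minimum surviving anchors per chain.
#' @param gene_col Column identifying the query gene (default
#'   `"query_gene"`, falling back to `query_index` if absent).
#' @return Long chain tibble with the overlap removed.
#' @export
resolve_chain_overlaps <- function(chains, min_anchors = 5,
                                   gene_col = "query_gene") {
  if (!nrow(chains)) return(chains)
  if (!gene_col %in% names(chains)) gene_col <- "query_index"
  out <- chains %>%
    group_by(.data[[gene_col]]) %>%
    filter(.data$chain_score == max(.data$chain_score),
           .data$chain_id == min(.data$chain_id[
             .data$chain_score == max(.data$chain_score)])) %>%
    ungroup() %>%
    group_by(.data$chain_id) %>%
    mutate(n_anchors = n(), chain_score = sum(.data$score)) %>%
    ungroup() %>%
    filter(.data$n_anchors >= min_anchors)
  out
}

#' Rank block copies and assign sub-genome labels
#'
#' Within each ancestral block, the (up to three) chain copies are ranked
#' by the fraction of the block's ancestral genes they retain; ranks 1-3
#' become LF, MF1, MF2.  An external partition table overrides the
#' ranking.  More than three copies of a block are flagged and the extras
#' left unassigned.  The syntelog table is assembled from chain
#' membership.
#'
#' @param chains Long chain tibble with `chain_id`, `block`,
#'   `target_gene`, `target_index` and `query_gene` columns.
#' @param block_sizes Tibble `block`, `n_ancestral` (ancestral genes per
#'   block).
#' @param partition Optional tibble `chain_id`, `subgenome` overriding the
#'   retention ranking.
#' @return List: `chain_labels` (`chain_id`, `block`, `retained_fraction`,
#'   `subgenome`, `flagged`), `syntelogs` (`ancestral_gene`, `block`,
#'   `LF`, `MF1`, `MF2`).
#' @export
assign_subgenomes <- function(chains, block_sizes, partition = NULL) {
  subg <- c("LF", "MF1", "MF2")
  per_chain <- chains %>%
    group_by(.data$chain_id, .data$block) %>%
    summarise(n_retained = n_distinct(.data$target_gene), .groups = "drop") %>%
    left_join(block_sizes, by = "block") %>%
    mutate(retained_fraction = .data$n_retained / .data$n_ancestral)
  if (is.null(partition)) {
    per_chain <- per_chain %>%
      group_by(.data$block) %>%
      arrange(dplyr::desc(.data$retained_fraction), .data$chain_id,
              .by_group = TRUE) %>%
      mutate(rank = row_number(),
             subgenome = ifelse(.data$rank <= 3, subg[pmin(.data$rank, 3)],
                                "unassigned"),
             flagged = n() > 3) %>%
      ungroup() %>% select(-"rank")
  } else {
    per_chain <- per_chain %>%
      left_join(partition, by = "chain_id") %>%
      mutate(subgenome = tidyr::replace_na(.data$subgenome, "unassigned"),
             flagged = FALSE)
  }
  labeled <- chains %>%
    inner_join(per_chain %>% select("chain_id", "subgenome"), by = "chain_id") %>%
    filter(.data$subgenome != "unassigned")
  if (any(duplicated(labeled$query_gene))) {
    abort("a query gene appears in more than one labeled chain; run resolve_chain_overlaps() first")
  }
  syn <- labeled %>%
    distinct(.data$target_gene, .data$block, .data$subgenome, .data$query_gene) %>%
    tidyr::pivot_wider(names_from = "subgenome", values_from = "query_gene")
  for (g in subg) if (!g %in% names(syn)) syn[[g]] <- NA_character_
  syn <- syn %>% rename(ancestral_gene = "target_gene") %>%
    select("ancestral_gene", "block", dplyr::all_of(subg)) %>%
    arrange(.data$ancestral_gene)
  list(chain_labels = per_chain, syntelogs = syn)
}

#' Per-sub-genome retention statistics and fully retained triplets
#'
#' @param syntelogs Syntelog table with `LF`, `MF1`, `MF2` columns over all
#'   ancestral genes (absent copies `NA`).
#' @return List: `retention` (tibble `subgenome`, `n_retained`,
#'   `retention_pct` over the ancestral gene count), `triplets` (rows with
#'   all three copies present), `n_ancestral`.
#' @export
retention_stats <- function(syntelogs) {
  if (!nrow(syntelogs)) abort("empty syntelog table")
  subg <- c("LF", "MF1", "MF2")
  n <- nrow(syntelogs)
  retention <- tibble(
    subgenome = subg,
    n_retained = unname(vapply(subg, function(g)
      sum(!is.na(syntelogs[[g]])), 0L)),
    retention_pct = 100 * unname(vapply(subg, function(g)
      mean(!is.na(syntelogs[[g]])), 0)))
  triplets <- syntelogs[stats::complete.cases(syntelogs[, subg]), ]
  list(retention = retention, triplets = triplets, n_ancestral = n)
}

#' Classify genes as syntenic, non-syntenic or species-specific
#'
#' Anchors of syntenic chains are `syntenic`.  Genes with no homology hit
#' at all are `species_specific`.  The rest -- genes outside ancestral
#' blocks, or inside block boundaries without a syntenic orthologue but
#' homologous to a gene elsewhere -- are `non_syntenic`.  Tandem
#' duplication is an additional flag: a within-genome homologous pair on
#' one chromosome separated by at most `tandem_max_separation` intervening
#' genes.
#'
#' @param genes Tibble: `gene_id`, `chrom`, `gene_index` (gene-order
#'   position on its chromosome).
#' @param chains Long chain tibble (its `query_gene` values are the
#'   syntenic anchors).
#' @param hits Homology hit table (`qseqid` per gene; absence means no
#'   homology).
#' @param self_hits Optional within-genome homology table (`qseqid`,
#'   `sseqid`) used for the tandem flag.
#' @param tandem_max_separation Maximum intervening genes for a tandem
#'   pair.
#' @return `genes` with added `category` and logical `tandem` columns.
#' @export
classify_genes <- function(genes, chains, hits, self_hits = NULL,
                           tandem_max_separation = 5) {
  anchor_genes <- unique(chains[["query_gene"]])
  hit_genes <- unique(hits$qseqid)
  unknown <- setdiff(anchor_genes, genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("gene '%s' is a chain anchor but absent from the annotation",
                  unknown[1]))
  }
  out <- genes %>%
    mutate(category = ifelse(.data$gene_id %in% anchor_genes, "syntenic",
                             ifelse(.data$gene_id %in% hit_genes,
                                    "non_syntenic", "species_specific")),
           tandem = FALSE)
  if (!is.null(self_hits) && nrow(self_hits)) {
    idx <- setNames(genes$gene_index, genes$gene_id)
    chr <- setNames(genes$chrom, genes$gene_id)
    sh <- self_hits %>%
      filter(.data$qseqid != .data$sseqid,
             .data$qseqid %in% genes$gene_id,
             .data$sseqid %in% genes$gene_id) %>%
      filter(chr[.data$qseqid] == chr[.data$sseqid],
             abs(idx[.data$qseqid] - idx[.data$sseqid]) - 1 <=
               tandem_max_separation)
    out$tandem <- out$gene_id %in% c(sh$qseqid, sh$sseqid)
  }
  out
}
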