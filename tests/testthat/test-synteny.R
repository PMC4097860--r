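test_that("hit filtering applies the E-value and bit-score margin rules", {
  single <- tibble::tibble(qseqid = "q1", sseqid = "t1",
                           bitscore = 50, evalue = 1e-30)
  expect_equal(nrow(filter_hits(single)), 1)

  trio <- tibble::tibble(qseqid = "q1", sseqid = c("t1", "t2", "t3"),
                         bitscore = c(100, 61, 59), evalue = 1e-30)
  kept <- filter_hits(trio)
  expect_setequal(kept$sseqid, c("t1", "t2"))

  # E-value gate applies before the margin; the best is per E-passing query
  gated <- tibble::tibble(qseqid = "q1", sseqid = c("t1", "t2"),
                          bitscore = c(100, 90),
                          evalue = c(1e-10, 1e-30))
  expect_equal(filter_hits(gated)$sseqid, "t2")

  expect_equal(nrow(filter_hits(trio[0, ])), 0)
})

test_that("hit filtering equals the literal per-row oracle on a toy table", {
  set.seed(111)
  toy <- tibble::tibble(
    qseqid = rep(c("q1", "q2", "q3"), c(4, 3, 3)),
    sseqid = sprintf("t%02d", 1:10),
    bitscore = c(100, 61, 59, 80, 200, 119, 121, 40, 39, 10),
    evalue = c(rep(1e-30, 3), 1e-5, rep(1e-25, 3), rep(1e-21, 3)))
  got <- filter_hits(toy)
  want <- oracle_filter_hits(toy)
  expect_equal(dplyr::arrange(got, .data$sseqid),
               dplyr::arrange(want, .data$sseqid))

  # quantile mode keeps per-query hits at or above the 60th percentile
  q <- filter_hits(toy, mode = "quantile")
  q1 <- toy %>% dplyr::filter(qseqid == "q1", evalue <= 1e-20)
  expect_setequal(q$sseqid[q$qseqid == "q1"],
                  q1$sseqid[q1$bitscore >= quantile(q1$bitscore, 0.6)])
})

test_that("chaining recovers simple collinear runs and orientations", {
  perfect <- tibble::tibble(query_index = 1:3, target_index = 1:3, score = 1)
  ch <- chain_anchors(perfect, min_anchors = 3)
  expect_equal(dplyr::n_distinct(ch$chain_id), 1)
  expect_equal(ch$chain_score[1], 3)
  expect_equal(ch$orientation[1], "same")
  expect_equal(ch$n_anchors[1], 3)

  inverted <- tibble::tibble(query_index = 1:4, target_index = 9:6, score = 1)
  chi <- chain_anchors(inverted, min_anchors = 3)
  expect_equal(chi$orientation[1], "inverted")
  expect_equal(chi$n_anchors[1], 4)

  empty <- chain_anchors(perfect[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("chain_id", "orientation", "chain_score") %in%
                    names(empty)))

  # gaps beyond max_gap_genes break a chain
  gappy <- tibble::tibble(query_index = c(1:3, 20:22),
                          target_index = c(1:3, 20:22), score = 1)
  chg <- chain_anchors(gappy, max_gap_genes = 5, min_anchors = 3)
  expect_equal(dplyr::n_distinct(chg$chain_id), 2)

  # gap cost: indices (1,2,5) on both axes cost 2 * (3 - 1) * gap_penalty
  skip <- tibble::tibble(query_index = c(1, 2, 5),
                         target_index = c(1, 2, 5), score = 2)
  chs <- chain_anchors(skip, gap_penalty = 0.5, max_gap_genes = 10,
                       min_anchors = 3)
  expect_equal(chs$chain_score[1], 6 - 0.5 * (2 + 2))
})

test_that("chain extraction equals exhaustive enumeration on random instances", {
  set.seed(112)
  for (i in 1:40) {
    n <- sample(6:12, 1)
    anchors <- tibble::tibble(
      query_index = sample(1:15, n),
      target_index = sample(1:15, n),
      score = round(runif(n, 1, 3), 3))
    got <- chain_anchors(anchors, gap_penalty = 1, max_gap_genes = 6,
                         min_anchors = 3)
    want <- oracle_extract_chains(anchors$query_index, anchors$target_index,
                                  anchors$score, gap_penalty = 1,
                                  max_gap = 6, min_anchors = 3)
    got_scores <- got %>% dplyr::distinct(chain_id, chain_score) %>%
      dplyr::pull(chain_score)
    expect_equal(got_scores, want, tolerance = 1e-12)
  }
})

test_that("overlap resolution keeps shared genes in the stronger chain", {
  chains <- tibble::tibble(
    chain_id = rep(c(1L, 2L), c(5, 5)),
    chain_score = rep(c(10, 7), c(5, 5)),
    n_anchors = 5L,
    score = 1,
    query_gene = c(sprintf("g%d", 1:5), sprintf("g%d", c(1, 6, 7, 8, 9))))
  res <- resolve_chain_overlaps(chains, min_anchors = 4)
  expect_true("g1" %in% res$query_gene[res$chain_id == 1])
  expect_false("g1" %in% res$query_gene[res$chain_id == 2])
  expect_equal(res$n_anchors[res$chain_id == 2][1], 4L)
  # pruned chain score recomputed from surviving anchor scores
  expect_equal(res$chain_score[res$chain_id == 2][1], 4)

  # chains falling below min_anchors are deleted entirely
  res5 <- resolve_chain_overlaps(chains, min_anchors = 5)
  expect_false(2L %in% res5$chain_id)

  disjoint <- dplyr::mutate(chains,
                            query_gene = sprintf("g%d", 1:10))
  resd <- resolve_chain_overlaps(disjoint, min_anchors = 4)
  expect_equal(nrow(resd), 10)
})

test_that("sub-genome assignment ranks block copies by retained fraction", {
  mk_chain <- function(id, block, genes, prefix) {
    tibble::tibble(chain_id = id, block = block,
                   target_gene = genes,
                   target_index = seq_along(genes),
                   query_gene = paste0(prefix, genes),
                   score = 1)
  }
  anc <- sprintf("A%03d", 1:20)
  chains <- dplyr::bind_rows(
    mk_chain(1L, "A", anc[1:10], "x"),   # retains 10/20
    mk_chain(2L, "A", anc[1:7], "y"),    # retains 7/20
    mk_chain(3L, "A", anc[c(1:5, 20)], "z"))  # retains 6/20
  sizes <- tibble::tibble(block = "A", n_ancestral = 20L)
  asg <- assign_subgenomes(chains, sizes)
  lab <- asg$chain_labels
  expect_equal(lab$subgenome[order(lab$chain_id)], c("LF", "MF1", "MF2"))
  expect_equal(lab$retained_fraction[order(lab$chain_id)],
               c(0.5, 0.35, 0.3))
  expect_false(any(lab$flagged))
  # syntelog table: ancestral gene 1 retained in all three copies
  row1 <- asg$syntelogs[asg$syntelogs$ancestral_gene == "A001", ]
  expect_equal(unname(unlist(row1[, c("LF", "MF1", "MF2")])),
               c("xA001", "yA001", "zA001"))
  # gene retained only in the LF copy
  row9 <- asg$syntelogs[asg$syntelogs$ancestral_gene == "A009", ]
  expect_true(is.na(row9$MF1) && is.na(row9$MF2))

  # single copy -> LF only
  solo <- assign_subgenomes(mk_chain(1L, "B", anc[1:5], "s"),
                            tibble::tibble(block = "B", n_ancestral = 10L))
  expect_equal(solo$chain_labels$subgenome, "LF")
  expect_true(all(is.na(solo$syntelogs$MF1)))

  # >3 copies flagged, extras unassigned
  four <- dplyr::bind_rows(chains, mk_chain(4L, "A", anc[1:2], "w"))
  asg4 <- assign_subgenomes(four, sizes)
  expect_true(all(asg4$chain_labels$flagged))
  expect_equal(asg4$chain_labels$subgenome[asg4$chain_labels$chain_id == 4],
               "unassigned")

  # external partition overrides the ranking
  part <- tibble::tibble(chain_id = 1:3,
                         subgenome = c("MF2", "LF", "MF1"))
  asgp <- assign_subgenomes(chains, sizes, partition = part)
  expect_equal(asgp$chain_labels$subgenome[
    order(asgp$chain_labels$chain_id)], c("MF2", "LF", "MF1"))

  # duplicated query gene across labeled chains is an error
  dup <- dplyr::bind_rows(mk_chain(1L, "A", anc[1:5], "x"),
                          mk_chain(2L, "A", anc[6:10], "x")[1, ] %>%
                            dplyr::mutate(query_gene = "xA001"))
  expect_error(assign_subgenomes(dup, sizes), "more than one labeled chain")
})

test_that("retention statistics match their closed forms", {
  full <- tibble::tibble(ancestral_gene = sprintf("a%d", 1:4),
                         LF = "x", MF1 = "y", MF2 = "z")
  rs <- retention_stats(full)
  expect_equal(rs$retention$retention_pct, c(100, 100, 100))
  expect_equal(nrow(rs$triplets), 4)

  one <- tibble::tibble(ancestral_gene = "a1", LF = "x",
                        MF1 = NA_character_, MF2 = "z")
  rs1 <- retention_stats(one)
  expect_equal(rs1$retention$retention_pct, c(100, 0, 100))
  expect_equal(nrow(rs1$triplets), 0)
  expect_equal(rs1$n_ancestral, 1)

  expect_error(retention_stats(full[0, ]), "empty")
})

test_that("gene classification matches a hand-derived 20-gene oracle", {
  # 20 genes on one chromosome; genes g01..g05 are chain anchors;
  # g06..g08 have off-block homology only; the rest have no hits;
  # (g09, g10) adjacent tandem pair, (g12, g15) tandem at separation 2
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                          chrom = "c1", gene_index = 1:20)
  chains <- tibble::tibble(query_gene = sprintf("g%02d", 1:5))
  hits <- tibble::tibble(qseqid = sprintf("g%02d", c(1:8, 9, 10, 12, 15)),
                         sseqid = "At", bitscore = 100, evalue = 1e-30)
  self_hits <- tibble::tibble(
    qseqid = c("g09", "g12", "g03", "g01"),
    sseqid = c("g10", "g15", "g18", "g01"))  # g03-g18 too far; self-pair ignored
  out <- classify_genes(genes, chains, hits, self_hits)
  expect_equal(out$category[1:5], rep("syntenic", 5))
  expect_equal(out$category[6:8], rep("non_syntenic", 3))
  expect_equal(out$category[9:10], rep("non_syntenic", 2))
  expect_equal(out$category[c(11, 16:20)], rep("species_specific", 6))
  expect_setequal(out$gene_id[out$tandem], c("g09", "g10", "g12", "g15"))

  expect_error(
    classify_genes(genes, tibble::tibble(query_gene = "ghost"), hits),
    "absent from the annotation")
})
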