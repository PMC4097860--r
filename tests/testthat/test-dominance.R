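make_triplets <- function(mats) {
  # mats: named list triplet_id -> 3x4 FPKM matrix (rows LF, MF1, MF2)
  purrr::imap_dfr(mats, function(m, id) {
    tibble::tibble(triplet_id = id, subgenome = c("LF", "MF1", "MF2"),
                   leaf = m[, 1], root = m[, 2], flower = m[, 3],
                   pod = m[, 4])
  })
}

test_that("expression transform matches its closed forms", {
  expect_equal(transform_expression(0), 0)
  expect_equal(transform_expression(exp(1) - 1), 1)
  expect_equal(transform_expression(matrix(0, 3, 4)), matrix(0, 3, 4))
  expect_error(transform_expression(-0.1), "non-negative")
})

test_that("highest sub-genome uses row means with the fixed tie order", {
  y <- rbind(LF = rep(2, 4), MF1 = rep(1, 4), MF2 = rep(0, 4))
  expect_equal(highest_subgenome(y)$subgenome, "LF")
  expect_false(highest_subgenome(y)$tie)

  tie <- matrix(1, 3, 4, dimnames = list(c("LF", "MF1", "MF2"), NULL))
  ht <- highest_subgenome(tie)
  expect_equal(ht$subgenome, "LF")
  expect_true(ht$tie)

  y2 <- rbind(LF = rep(0, 4), MF1 = rep(3, 4), MF2 = rep(1, 4))
  expect_equal(highest_subgenome(y2)$subgenome, "MF1")
})

test_that("Tukey test flags degenerate tables and matches the oracle", {
  a <- c(1, 2, 4); b <- c(0, 1, 3, 6)
  additive <- outer(a, b, `+`)
  res_add <- tukey_test(additive)
  expect_true(res_add$degenerate)
  expect_equal(res_add$p_value, 1)

  res_const <- tukey_test(matrix(5, 3, 4))
  expect_true(res_const$degenerate)
  expect_equal(res_const$p_value, 1)

  # an exactly multiplicative table y_ij = (1+i)(1+j) has its residual
  # fully absorbed by the single-df term (r_ij is proportional to a_i b_j),
  # so the remainder denominator vanishes and the degenerate rule fires
  mult <- outer(1 + 0:2, 1 + 0:3)
  expect_true(tukey_test(mult)$degenerate)

  # perturbed multiplicative table: formula applies, matches the oracle
  set.seed(100)
  noisy <- mult + matrix(rnorm(12, sd = 0.1), 3, 4)
  got <- tukey_test(noisy)
  want <- oracle_tukey(noisy)
  expect_false(got$degenerate)
  expect_equal(got$F_statistic, want$F, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  expect_error(tukey_test(matrix(1, 2, 4)), "3x4")
})

test_that("Tukey statistic matches the oracle on random tables and is invariant under a grand shift", {
  # Note: the statistic is *not* invariant under per-row or per-column
  # shifts -- N = sum r_ij a_i b_j involves the estimated main effects,
  # which such shifts change.  Only the overall location cancels.
  set.seed(101)
  for (i in 1:50) {
    y <- matrix(rnorm(12), 3, 4)
    got <- tukey_test(y)
    want <- oracle_tukey(y)
    expect_equal(got$F_statistic, want$F, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(tukey_test(y + rnorm(1))$F_statistic, got$F_statistic,
                 tolerance = 1e-8)
  }
})

test_that("dominance fit ties the pieces together with tidy/glance", {
  set.seed(102)
  mats <- purrr::map(1:20, ~ matrix(rexp(12), 3, 4))
  names(mats) <- sprintf("t%02d", 1:20)
  fit <- dominance_test(make_triplets(mats))
  td <- tidy(fit)
  expect_equal(nrow(td), 20)
  expect_true(all(td$highest_subgenome %in% c("LF", "MF1", "MF2")))
  # per-triplet rows agree with the scalar API
  for (i in c(1, 7, 20)) {
    single <- tukey_test(transform_expression(mats[[i]]))
    expect_equal(td$F_statistic[td$triplet_id == names(mats)[i]],
                 single$F_statistic, tolerance = 1e-10)
    expect_equal(td$highest_subgenome[td$triplet_id == names(mats)[i]],
                 highest_subgenome(transform_expression(mats[[i]]))$subgenome)
  }
  gl <- glance(fit)
  expect_equal(gl$n_triplets, 20)
  expect_equal(gl$lf_share + gl$mf1_share + gl$mf2_share,
               ifelse(gl$n_significant > 0, 1, 0))
  expect_error(dominance_test(make_triplets(mats)[-1, ]),
               "exactly one row")
})

test_that("dominance summary counts significant triplets and their shares", {
  res <- tibble::tibble(triplet_id = sprintf("t%d", 1:6),
                        highest_subgenome = c("LF", "LF", "MF1",
                                              "MF2", "LF", "MF1"),
                        p_value = c(0.01, 0.02, 0.03, 0.2, 1, 1))
  s <- dominance_summary(res, alpha = 0.05)
  expect_equal(s$n_significant, 3L)
  expect_equal(s$shares, c(LF = 2 / 3, MF1 = 1 / 3, MF2 = 0))
  expect_equal(sum(s$shares), 1)

  allnull <- dplyr::mutate(res, p_value = 1)
  expect_equal(dominance_summary(allnull)$n_significant, 0L)
  expect_equal(dominance_summary(res[0, ])$n_total, 0L)
})

test_that("the cumulative dominance curve is a running label frequency", {
  one <- tibble::tibble(triplet_id = "t1", highest_subgenome = "LF",
                        p_value = 0.5)
  c1 <- cumulative_dominance_curve(one)
  expect_equal(c1$LF, 1)
  expect_equal(c1$MF1, 0)
  expect_equal(c1$MF2, 0)

  alt <- tibble::tibble(triplet_id = sprintf("t%d", 1:6),
                        highest_subgenome = rep(c("LF", "MF1"), 3),
                        p_value = (1:6) / 10)
  ca <- cumulative_dominance_curve(alt)
  expect_equal(ca$LF[c(2, 4, 6)], rep(0.5, 3))
  expect_equal(ca$rank, 1:6)
  expect_equal(ca$LF + ca$MF1 + ca$MF2, rep(1, 6))
  # sorted ascending in p
  expect_true(all(diff(ca$p_value) >= 0))
})

test_that("clustering matches the brute-force average-linkage oracle", {
  set.seed(103)
  for (rep in 1:5) {
    expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                           leaf = rnorm(30), root = rnorm(30),
                           flower = rnorm(30), pod = rnorm(30))
    cl <- cluster_expression_profiles(expr, k = 5)
    X <- as.matrix(expr[, -1])
    D <- as.matrix(stats::as.dist(1 - stats::cor(t(X))))
    expect_equal(cl$tree$height, oracle_average_linkage_heights(D),
                 tolerance = 1e-10)
    expect_equal(dplyr::n_distinct(cl$assignments$cluster), 5L)
  }
})

test_that("clustering handles identical, anti-correlated and degenerate genes", {
  expr <- tibble::tibble(gene_id = c("a", "b", "neg", "flat", "other"),
                         leaf = c(1, 2, -1, 3, 0),
                         root = c(2, 4, -2, 3, 1),
                         flower = c(3, 6, -3, 3, 0),
                         pod = c(4, 8, -4, 3, 5))
  expect_message(cl <- cluster_expression_profiles(expr, k = 2),
                 "filtered 1 zero-variance")
  expect_equal(cl$n_filtered, 1L)
  expect_false("flat" %in% cl$assignments$gene_id)
  # identical shapes (a, b) sit at distance 0 and merge first
  expect_equal(min(cl$tree$height), 0, tolerance = 1e-12)
  same <- cl$assignments$cluster[match(c("a", "b"), cl$assignments$gene_id)]
  expect_equal(same[1], same[2])
  # a gene and its exact negation sit at the maximum distance 2
  D <- 1 - stats::cor(t(as.matrix(expr[expr$gene_id %in% c("a", "neg"),
                                       -1])))
  expect_equal(max(D), 2, tolerance = 1e-12)
  expect_equal(glance(cl)$n_genes, 4L)
  expect_error(cluster_expression_profiles(expr, k = 10), "k exceeds")
})

test_that("merge trees export as readable Newick", {
  set.seed(104)
  expr <- tibble::tibble(gene_id = sprintf("g%d", 1:8),
                         leaf = rnorm(8), root = rnorm(8),
                         flower = rnorm(8), pod = rnorm(8))
  cl <- cluster_expression_profiles(expr, k = 3)
  path <- tempfile(fileext = ".nwk")
  on.exit(unlink(path))
  export_cluster_tree(cl, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, expr$gene_id)
})

test_that("triplet separation covers the all-together and all-apart poles", {
  syn <- tibble::tibble(LF = c("a1", "b1"), MF1 = c("a2", "b2"),
                        MF2 = c("a3", "b3"))
  together <- tibble::tibble(gene_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                             cluster = c(1L, 1L, 1L, 2L, 2L, 2L))
  s0 <- triplet_separation(together, syn)
  expect_equal(s0$gene_fraction, 0)
  expect_equal(s0$triplet_fraction, 0)

  apart <- dplyr::mutate(together, cluster = 1:6)
  s1 <- triplet_separation(apart, syn)
  expect_equal(s1$gene_fraction, 1)
  expect_equal(s1$triplet_fraction, 1)
  expect_equal(s1$n_triplets, 2L)

  # partially clustered triplet: only triplets with >= 2 clustered members
  # enter the triplet-level denominator
  partial <- together[-(1:2), ]  # a3 alone for triplet a
  sp <- triplet_separation(partial, syn)
  expect_equal(sp$triplet_fraction, 0)  # only triplet b eligible, together
})
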