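#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles every parameter of the synthetic-data generators in one validated
#' list.  Defaults emulate the study conditions of a mesopolyploid Brassica
#' leaf methylome: mean bisulfite read depth of 7.29 per strand, true
#' methylation levels CG 0.55 / CHG 0.09 / CHH 0.02, sub-genome retention
#' probabilities (0.50, 0.35, 0.30) for LF/MF1/MF2, a bisulfite
#' non-conversion error of 0.005, and a half-tetrad mapping population of
#' 49 progeny scored at 50 markers on a 2-Morgan chromosome.
#'
#' @param seed Integer seed; every generator is bit-for-bit reproducible
#'   given the same config.
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param gc_fraction GC content of the simulated sequence, in `[0,1]`.
#' @param n_ancestral_genes Number of ancestral (pre-triplication) genes.
#' @param retention_probs Named 3-vector of per-sub-genome retention
#'   probabilities `c(LF=, MF1=, MF2=)`.
#' @param n_blocks Number of ancestral blocks the ancestral genes are cut
#'   into (contiguous, roughly equal).
#' @param true_meth_levels Named vector of per-context true methylation
#'   probabilities `c(CG=, CHG=, CHH=)`.
#' @param feature_meth_levels Optional named list overriding true levels by
#'   feature class (`promoter`, `body`, `downstream`, `intergenic`); each
#'   element either a single proportion (all contexts) or a named
#'   per-context vector.
#' @param depth_lambda Mean Poisson read depth per strand.
#' @param nonconversion_e Bisulfite non-conversion error (probability an
#'   unmethylated cytosine reads methylated).
#' @param mosaic_levels If `TRUE`, a site's true level is used directly as
#'   its per-read methylation probability (mosaic sites); default is a
#'   Bernoulli all-or-none state per site, matching a binomial read model.
#' @param expr_model List of expression-model parameters on the
#'   `ln(FPKM+1)` scale: `mu`, `sigma_G`, `sigma_T`, `sigma_GT`,
#'   `sigma_eps`, `lf_shift_delta` (additive shift of the LF row),
#'   `interaction_mode` (`"none"`, `"multiplicative"` or `"free"`), and
#'   `interaction_lambda` (coefficient of the multiplicative term).
#' @param meiosis List: `map_length_morgans`, `centromere_pos_bp` (default
#'   40% of the chromosome), `n_progeny`, `n_markers`, `missing_rate`.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1000000L,
                       gc_fraction = 0.36,
                       n_ancestral_genes = 500L,
                       retention_probs = c(LF = 0.50, MF1 = 0.35, MF2 = 0.30),
                       n_blocks = 24L,
                       true_meth_levels = c(CG = 0.55, CHG = 0.09, CHH = 0.02),
                       feature_meth_levels = NULL,
                       depth_lambda = 7.29,
                       nonconversion_e = 0.005,
                       mosaic_levels = FALSE,
                       expr_model = list(),
                       meiosis = list()) {
  expr_defaults <- list(mu = 2, sigma_G = 0.5, sigma_T = 0.5, sigma_GT = 0.3,
                        sigma_eps = 0.3, lf_shift_delta = 0,
                        interaction_mode = "none", interaction_lambda = 1)
  meiosis_defaults <- list(map_length_morgans = 2,
                           centromere_pos_bp = round(0.4 * chrom_length_bp),
                           n_progeny = 49L, n_markers = 50L,
                           missing_rate = 0)
  expr_model <- utils::modifyList(expr_defaults, expr_model)
  meiosis <- utils::modifyList(meiosis_defaults, meiosis)

  stopifnot(length(retention_probs) == 3)
  if (is.null(names(retention_probs))) {
    names(retention_probs) <- c("LF", "MF1", "MF2")
  }
  props <- c(gc_fraction, retention_probs, true_meth_levels, nonconversion_e)
  if (any(props < 0 | props > 1)) {
    abort("all proportions must lie in [0, 1]")
  }
  if (n_chromosomes < 1 || chrom_length_bp < 1 || n_ancestral_genes < 0) {
    abort("counts must be positive (n_ancestral_genes may be 0)")
  }
  if (!expr_model$interaction_mode %in% c("none", "multiplicative", "free")) {
    abort("interaction_mode must be none, multiplicative or free")
  }
  if (depth_lambda <= 0) abort("depth_lambda must be positive")
  if (meiosis$map_length_morgans < 0) abort("map length must be >= 0")

  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 gc_fraction = gc_fraction,
                 n_ancestral_genes = as.integer(n_ancestral_genes),
                 retention_probs = retention_probs,
                 n_blocks = as.integer(n_blocks),
                 true_meth_levels = true_meth_levels,
                 feature_meth_levels = feature_meth_levels,
                 depth_lambda = depth_lambda,
                 nonconversion_e = nonconversion_e,
                 mosaic_levels = mosaic_levels,
                 expr_model = expr_model,
                 meiosis = meiosis),
            class = "sim_config")
}

# Each generator seeds the RNG from config$seed plus a fixed per-generator
# offset, so generators are individually reproducible regardless of call order.
seed_for <- function(config, offset) set.seed(config$seed + offset)

#' Simulate a genome sequence and gene models
#'
#' Draws a random genome at the configured GC content and places
#' non-overlapping gene models (promoter, 5' UTR, exons, introns, 3' UTR,
#' downstream) on both strands.  Promoter and downstream windows are 2,000 bp.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes to place (default `n_ancestral_genes`).
#' @param promoter_bp,downstream_bp Flank widths in bp.
#' @return List of class `sim_genome` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `genes` (one row per gene: `gene_id`,
#'   `chrom`, `strand`, `start`, `end`), and `features` (one row per gene
#'   part, 1-based inclusive coordinates).
#' @export
simulate_genome_and_genes <- function(config, n_genes = NULL,
                                      promoter_bp = 2000L,
                                      downstream_bp = 2000L) {
  seed_for(config, 0L)
  n_genes <- as.integer(n_genes %||% config$n_ancestral_genes)
  gc <- config$gc_fraction
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp

  seqs <- vapply(chroms, function(ch) {
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  if (n_genes == 0) {
    empty <- tibble(gene_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer())
    feat <- tibble(gene_id = character(), chrom = character(),
                   strand = character(), part = character(),
                   start = integer(), end = integer())
    return(structure(list(genome = genome, genes = empty, features = feat,
                          config = config), class = "sim_genome"))
  }

  per_chrom <- diff(floor(seq(0, n_genes, length.out = length(chroms) + 1)))
  genes <- list(); features <- list(); gi <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- promoter_bp + 1L
    for (g in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      n_ex <- sample(1:4, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(80:200, n_ex - 1, replace = TRUE) else integer()
      u5 <- sample(100:200, 1); u3 <- sample(150:250, 1)
      body <- u5 + sum(ex_len) + sum(in_len) + u3
      strand <- sample(c("+", "-"), 1)
      s <- cursor; e <- s + body - 1L
      if (e + downstream_bp > L) {
        abort(sprintf("chromosome %s too short to place %d genes",
                      chroms[ci], per_chrom[ci]))
      }
      id <- sprintf("Bo%05d", gi)
      # internal layout in plus coordinates; 5' side depends on strand
      seg_len <- c(u5, as.vector(rbind(ex_len, c(in_len, NA)))[
        seq_len(2 * n_ex - 1)], u3)
      seg_part <- c("five_prime_UTR",
                    rep(c("exon", "intron"), length.out = 2 * n_ex - 1),
                    "three_prime_UTR")
      if (strand == "-") { seg_len <- rev(seg_len); seg_part <- rev(seg_part) }
      seg_end <- s - 1L + cumsum(seg_len)
      seg_start <- seg_end - seg_len + 1L
      prom <- if (strand == "+") c(s - promoter_bp, s - 1L) else c(e + 1L, e + promoter_bp)
      down <- if (strand == "+") c(e + 1L, e + downstream_bp) else c(s - downstream_bp, s - 1L)
      features[[gi]] <- tibble(
        gene_id = id, chrom = chroms[ci], strand = strand,
        part = c("promoter", seg_part, "downstream"),
        start = as.integer(c(prom[1], seg_start, down[1])),
        end = as.integer(c(prom[2], seg_end, down[2])))
      genes[[gi]] <- tibble(gene_id = id, chrom = chroms[ci], strand = strand,
                            start = as.integer(s), end = as.integer(e))
      cursor <- e + downstream_bp + promoter_bp + sample(0:500, 1) + 1L
    }
  }
  structure(list(genome = genome, genes = bind_rows(genes),
                 features = bind_rows(features), config = config),
            class = "sim_genome")
}

#' Simulate biased fractionation of a triplicated genome
#'
#' Each ancestral gene is independently retained in sub-genome g with
#' probability `retention_probs[g]`; retained copies are placed collinearly,
#' one query chromosome per sub-genome.  A homology hit table containing the
#' true anchors (low E-value, high bit score) plus decoy hits is emitted
#' alongside the anchors and the ground-truth syntelog table.
#'
#' @param config A [sim_config()].
#' @param n_decoys Number of decoy homology hits to add.
#' @return List of class `sim_fractionation`: `syntelogs` (ancestral gene x
#'   LF/MF1/MF2 retention table with `block`), `anchors` (true collinear
#'   anchors with `query_chrom`, `query_gene`, `query_index`,
#'   `target_index`, `block`, `subgenome`), `hits` (BLAST-tabular-like).
#' @export
simulate_fractionation <- function(config, n_decoys = 200L) {
  seed_for(config, 1L)
  n <- config$n_ancestral_genes
  probs <- config$retention_probs
  anc <- sprintf("At%05d", seq_len(n))
  block <- if (n > 0) {
    LETTERS[pmin(config$n_blocks,
                 ceiling(seq_len(n) / ceiling(n / config$n_blocks)))]
  } else character()
  keep <- matrix(FALSE, n, 3, dimnames = list(NULL, names(probs)))
  for (g in seq_along(probs)) keep[, g] <- stats::rbinom(n, 1L, probs[g]) == 1L

  subg <- names(probs)
  ids <- matrix(NA_character_, n, 3, dimnames = list(NULL, subg))
  anchors <- list()
  for (g in seq_along(subg)) {
    ret <- which(keep[, g])
    if (length(ret)) {
      ids[ret, g] <- sprintf("%s_g%05d", subg[g], seq_along(ret))
      anchors[[g]] <- tibble(
        block = block[ret],
        subgenome = subg[g],
        query_chrom = paste0("chr", subg[g]),
        query_gene = ids[ret, g],
        query_index = seq_along(ret),
        target_gene = anc[ret],
        target_index = ret,
        score = 1)
    }
  }
  anchors <- bind_rows(anchors)
  syntelogs <- tibble(ancestral_gene = anc, block = block,
                      LF = ids[, "LF"], MF1 = ids[, "MF1"], MF2 = ids[, "MF2"])

  true_hits <- if (nrow(anchors)) {
    tibble(qseqid = anchors$query_gene, sseqid = anchors$target_gene,
           bitscore = round(runif(nrow(anchors), 180, 240), 1),
           evalue = 10^(-runif(nrow(anchors), 40, 80)))
  } else {
    tibble(qseqid = character(), sseqid = character(),
           bitscore = numeric(), evalue = numeric())
  }
  decoys <- if (n_decoys > 0 && nrow(anchors) > 1) {
    tibble(qseqid = sample(anchors$query_gene, n_decoys, replace = TRUE),
           sseqid = sample(anc, n_decoys, replace = TRUE),
           bitscore = round(runif(n_decoys, 30, 90), 1),
           evalue = 10^(-runif(n_decoys, 2, 30)))
  } else NULL
  structure(list(syntelogs = syntelogs, anchors = anchors,
                 hits = bind_rows(true_hits, decoys), config = config),
            class = "sim_fractionation")
}

# scan one chromosome sequence for cytosines on both strands; truncated
# contexts at sequence ends fall through to CHH
scan_cytosines <- function(seq, chrom) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(ch)
  ip <- which(ch == "C")
  n1 <- ch[ip + 1L]; n2 <- ch[ip + 2L]
  ctx_p <- ifelse(!is.na(n1) & n1 == "G", "CG",
                  ifelse(!is.na(n2) & n2 == "G", "CHG", "CHH"))
  im <- which(ch == "G")
  p1 <- ch[ifelse(im >= 2L, im - 1L, NA_integer_)]
  p2 <- ch[ifelse(im >= 3L, im - 2L, NA_integer_)]
  ctx_m <- ifelse(!is.na(p1) & p1 == "C", "CG",
                  ifelse(!is.na(p2) & p2 == "C", "CHG", "CHH"))
  tibble(chrom = chrom,
         pos = c(ip, im),
         strand = rep(c("+", "-"), c(length(ip), length(im))),
         context = c(ctx_p, ctx_m))
}

#' Simulate per-cytosine bisulfite counts with a lambda spike-in
#'
#' Scans the simulated genome for cytosines on both strands, assigns the
#' sequence context (CG / CHG / CHH), draws a true methylation state per
#' site, a Poisson read depth per strand, and observed methylated reads
#' from `Binomial(n, m + (1 - m) * e)` where `e` is the bisulfite
#' non-conversion error.  An unmethylated lambda control sequence is
#' simulated alongside: its sites carry zero true methylation, so observed
#' positives there arise only from non-conversion.
#'
#' @param config A [sim_config()].
#' @param sim_genome Result of [simulate_genome_and_genes()]; if `NULL` a
#'   genome is generated from `config` first.
#' @param n_sites_per_context Optional cap: subsample to at most this many
#'   sites per context (genome sites only).
#' @param lambda_bp Length of the simulated lambda control sequence.
#' @return List of class `sim_methylome` with `sites` and `lambda` tibbles
#'   (`chrom`, `pos`, `strand`, `context`, `meth_reads`, `total_reads`,
#'   `true_m` the simulated per-site methylation level).  Zero-coverage
#'   sites are emitted; exclusion is a downstream decision.
#' @export
simulate_methylome_counts <- function(config, sim_genome = NULL,
                                      n_sites_per_context = NULL,
                                      lambda_bp = 48502L) {
  if (is.null(sim_genome)) sim_genome <- simulate_genome_and_genes(config)
  seed_for(config, 2L)
  sites <- bind_rows(lapply(names(sim_genome$genome), function(ch) {
    scan_cytosines(as.character(sim_genome$genome[[ch]]), ch)
  }))
  if (!is.null(n_sites_per_context) && nrow(sites)) {
    sites <- sites %>%
      group_by(.data$context) %>%
      slice(sort(sample(n(), min(n(), n_sites_per_context)))) %>%
      ungroup()
  }

  lev <- config$true_meth_levels[sites$context]
  fml <- config$feature_meth_levels
  if (!is.null(fml) && nrow(sim_genome$features)) {
    cls <- classify_site_feature(sites, sim_genome$features, names(fml))
    for (k in names(fml)) {
      hit <- which(cls == k)
      if (!length(hit)) next
      ov <- fml[[k]]
      lev[hit] <- if (length(ov) == 1 && is.null(names(ov))) ov
                  else unname(ov[sites$context[hit]])
    }
  }
  e <- config$nonconversion_e
  m <- if (config$mosaic_levels) as.numeric(lev)
       else stats::rbinom(nrow(sites), 1L, lev)
  n_reads <- stats::rpois(nrow(sites), config$depth_lambda)
  k_reads <- stats::rbinom(nrow(sites), n_reads, m + (1 - m) * e)
  sites <- sites %>% mutate(meth_reads = k_reads, total_reads = n_reads,
                            true_m = m)

  lam_seq <- paste(sample(c("A", "C", "G", "T"), lambda_bp, replace = TRUE),
                   collapse = "")
  lam <- scan_cytosines(lam_seq, "lambda")
  lam_n <- stats::rpois(nrow(lam), config$depth_lambda)
  lam_k <- stats::rbinom(nrow(lam), lam_n, e)
  lam <- lam %>% mutate(meth_reads = lam_k, total_reads = lam_n, true_m = 0)

  structure(list(sites = sites, lambda = lam, config = config),
            class = "sim_methylome")
}

# site feature class by gene part (parts are disjoint); sites outside any
# part are "intergenic".  Class names usable in feature_meth_levels are the
# part names plus "body" (any non-flank part without its own entry).
classify_site_feature <- function(sites, features, level_names = character()) {
  cls <- rep("intergenic", nrow(sites))
  pairs <- overlap_pairs(sites, features)
  cls[pairs$site_row] <- features$part[pairs$feature_row]
  body_parts <- c("five_prime_UTR", "exon", "intron", "three_prime_UTR")
  if ("body" %in% level_names) {
    cls[cls %in% setdiff(body_parts, level_names)] <- "body"
  }
  cls
}

#' Simulate FPKM tables for fully retained gene triplets
#'
#' Realizes the additive-plus-interaction model on the `ln(FPKM+1)` scale:
#' `y_ij = mu + G_i + T_j + GT_ij + eps_ij`, with the interaction term zero,
#' multiplicative (`lambda * G_i * T_j`, the alternative the Tukey test is
#' powered against) or freely drawn, and an optional additive dominance
#' shift of the LF row.  Back-transformed FPKM values are `exp(y) - 1`
#' clipped at zero.
#'
#' @param config A [sim_config()].
#' @param syntelogs Syntelog table (e.g. from [simulate_fractionation()]);
#'   only fully retained rows are used.
#' @return Tibble with one row per triplet copy: `triplet_id`, `subgenome`,
#'   `gene_id`, and FPKM columns `leaf`, `root`, `flower`, `pod`.
#' @export
simulate_expression_triplets <- function(config, syntelogs) {
  seed_for(config, 3L)
  trip <- syntelogs[stats::complete.cases(syntelogs[, c("LF", "MF1", "MF2")]), ]
  n <- nrow(trip)
  tissues <- c("leaf", "root", "flower", "pod")
  subg <- c("LF", "MF1", "MF2")
  if (n == 0) {
    return(tibble(triplet_id = character(), subgenome = character(),
                  gene_id = character(),
                  leaf = numeric(), root = numeric(), flower = numeric(),
                  pod = numeric()))
  }
  em <- config$expr_model
  G <- matrix(rnorm(n * 3, 0, em$sigma_G), n, 3)
  Tm <- matrix(rnorm(n * 4, 0, em$sigma_T), n, 4)
  y <- array(0, c(n, 3, 4))
  for (i in 1:3) for (j in 1:4) {
    gt <- switch(em$interaction_mode,
                 none = 0,
                 multiplicative = em$interaction_lambda * G[, i] * Tm[, j],
                 free = rnorm(n, 0, em$sigma_GT))
    y[, i, j] <- em$mu + G[, i] + Tm[, j] + gt +
      rnorm(n, 0, em$sigma_eps)
  }
  y[, 1, ] <- y[, 1, ] + em$lf_shift_delta
  fpkm <- pmax(exp(y) - 1, 0)

  out <- lapply(1:3, function(i) {
    v <- fpkm[, i, , drop = FALSE]
    tibble(triplet_id = sprintf("T%05d", seq_len(n)),
           subgenome = subg[i],
           gene_id = trip[[subg[i]]],
           leaf = v[, 1, 1], root = v[, 1, 2],
           flower = v[, 1, 3], pod = v[, 1, 4])
  })
  bind_rows(out) %>% arrange(.data$triplet_id,
                             match(.data$subgenome, subg))
}

#' Simulate progeny genotypes from first-division-restitution gametes
#'
#' Each meiosis places chiasmata by a Poisson process on the genetic map
#' (Haldane mapping, no interference), exchanging arms distal to the
#' crossover relative to the centromere between one chromatid of each
#' homolog.  The FDR gamete takes one chromatid from each homolog (sisters
#' chosen uniformly), so both parental centromeres are present and a marker
#' is heterozygous iff its two chromatids carry different parental alleles.
#'
#' Under this model the expected heterozygosity at map distance `d` Morgans
#' from the centromere is `1 - (1 - exp(-3 d)) / 3`: it decays from 1 at the
#' centromere to the classical half-tetrad asymptote of 2/3, because the two
#' chromatids transmitted by one meiosis share chiasmata and are therefore
#' not independent.
#'
#' One independent meiosis is simulated per configured chromosome; the
#' marker layout and centromere position apply to every chromosome.
#'
#' @param config A [sim_config()]; meiosis parameters are read from
#'   `config$meiosis`.
#' @return Tibble of class `progeny_genotypes`: columns `marker`, `chrom`,
#'   `pos_bp`, `map_pos` (Morgans), then one column per progeny with states
#'   `"het"`, `"homA"`, `"homB"` or `"missing"`.
#' @export
simulate_fdr_progeny <- function(config) {
  seed_for(config, 4L)
  me <- config$meiosis
  L <- config$chrom_length_bp
  if (me$centromere_pos_bp < 1 || me$centromere_pos_bp > L) {
    abort("centromere position outside the chromosome")
  }
  n_mark <- me$n_markers
  pos_bp <- round(seq(1, L, length.out = n_mark))
  map_pos <- me$map_length_morgans * pos_bp / L
  cen_d <- me$map_length_morgans * me$centromere_pos_bp / L

  one_chrom <- function(ch) {
    geno <- matrix("", n_mark, me$n_progeny)
    for (p in seq_len(me$n_progeny)) {
      # chromatids 1,2 = homolog A sisters; 3,4 = homolog B sisters
      alle <- matrix(rep(c(0L, 0L, 1L, 1L), each = n_mark), n_mark, 4)
      n_x <- stats::rpois(1, 2 * me$map_length_morgans)
      if (n_x > 0) {
        xs <- sort(runif(n_x, 0, me$map_length_morgans))
        for (x in xs) {
          i <- sample(1:2, 1); j <- sample(3:4, 1)
          distal <- if (x >= cen_d) map_pos > x else map_pos < x
          tmp <- alle[distal, i]
          alle[distal, i] <- alle[distal, j]
          alle[distal, j] <- tmp
        }
      }
      a <- alle[, sample(1:2, 1)]
      b <- alle[, sample(3:4, 1)]
      geno[, p] <- ifelse(a != b, "het", ifelse(a == 0L, "homA", "homB"))
    }
    if (me$missing_rate > 0) {
      geno[runif(length(geno)) < me$missing_rate] <- "missing"
    }
    colnames(geno) <- sprintf("P%03d", seq_len(me$n_progeny))
    bind_cols(
      tibble(marker = sprintf("%s_M%03d", ch, seq_len(n_mark)), chrom = ch,
             pos_bp = as.integer(pos_bp), map_pos = map_pos),
      as_tibble(geno))
  }
  out <- bind_rows(lapply(sprintf("chr%d", seq_len(config$n_chromosomes)),
                          one_chrom))
  class(out) <- c("progeny_genotypes", class(out))
  out
}
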