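# ---- validation helpers -----------------------------------------------------

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
}

check_pos <- function(pos) {
  if (any(pos < 1)) abort("coordinates are 1-based; pos must be >= 1")
}

# ---- FASTA ------------------------------------------------------------------

#' Write a genome to FASTA (60-column lines)
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file
#' @param path Input file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

# ---- GFF3 -------------------------------------------------------------------

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and UTR features (1-based inclusive); promoter
#' and downstream windows and introns are derived on reading, not stored.
#'
#' @param features Feature tibble: `gene_id`, `chrom`, `strand`, `part`,
#'   `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  check_strand(features$strand)
  check_pos(features$start)
  stored <- features %>%
    filter(.data$part %in% c("exon", "five_prime_UTR", "three_prime_UTR"))
  span <- features %>%
    filter(!.data$part %in% c("promoter", "downstream")) %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  rows <- bind_rows(
    span %>% mutate(type = "gene", ID = .data$gene_id, Parent = NA_character_),
    span %>% mutate(type = "mRNA", ID = paste0(.data$gene_id, ".1"),
                    Parent = .data$gene_id),
    stored %>% mutate(type = .data$part, ID = NA_character_,
                      Parent = paste0(.data$gene_id, ".1"))) %>%
    arrange(.data$chrom, .data$gene_id, .data$start,
            match(.data$type, c("gene", "mRNA", "five_prime_UTR", "exon",
                                "three_prime_UTR")))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    type = rows$type, ID = rows$ID, Parent = rows$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 and derive gene parts
#'
#' Introns are derived as gaps between consecutive exons of the primary
#' mRNA (the one with the longest summed CDS, falling back to exon length;
#' ties broken by ID), and 2,000-bp promoter/downstream windows are added.
#'
#' @param path GFF3 file with gene/mRNA/exon/UTR features.
#' @param promoter_bp,downstream_bp Derived flank widths.
#' @return List: `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`)
#'   and `features` (per-part rows including derived introns, promoter and
#'   downstream).
#' @export
read_gff3 <- function(path, promoter_bp = 2000L, downstream_bp = 2000L) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr)) %>%
    mutate(seqnames = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
  if (any(!df$strand %in% c("+", "-"))) {
    bad <- which(!df$strand %in% c("+", "-"))[1]
    abort(sprintf("unknown strand '%s' at feature %d", df$strand[bad], bad))
  }
  first_parent <- function(p) vapply(p, function(x)
    if (length(x)) as.character(x)[1] else NA_character_, "")
  df$parent1 <- if ("Parent" %in% names(df)) first_parent(df$Parent)
                else NA_character_
  genes <- df %>% filter(.data$type == "gene") %>%
    transmute(gene_id = .data$ID, chrom = .data$seqnames,
              strand = .data$strand,
              start = as.integer(.data$start), end = as.integer(.data$end))
  mrna <- df %>% filter(.data$type == "mRNA") %>%
    transmute(mrna_id = .data$ID, gene_id = .data$parent1)
  parts <- df %>%
    filter(.data$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR")) %>%
    transmute(part = .data$type, mrna_id = .data$parent1,
              chrom = .data$seqnames, strand = .data$strand,
              start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    inner_join(mrna, by = "mrna_id")
  # primary mRNA per gene: longest CDS sum (exon sum if no CDS), ties by id
  len_by <- parts %>%
    group_by(.data$gene_id, .data$mrna_id) %>%
    summarise(cds_len = sum((.data$end - .data$start + 1)[.data$part == "CDS"]),
              exon_len = sum((.data$end - .data$start + 1)[.data$part == "exon"]),
              .groups = "drop") %>%
    mutate(len = ifelse(.data$cds_len > 0, .data$cds_len, .data$exon_len)) %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$len), .data$mrna_id, .by_group = TRUE) %>%
    slice(1) %>% ungroup()
  parts <- parts %>% filter(.data$mrna_id %in% len_by$mrna_id,
                            .data$part != "CDS")
  # exon-outside-gene check
  chk <- parts %>% inner_join(genes, by = c("gene_id", "chrom", "strand"),
                              suffix = c("", ".g"))
  bad <- chk$start < chk$start.g | chk$end > chk$end.g
  if (any(bad)) {
    abort(sprintf("feature outside gene span for gene %s",
                  chk$gene_id[which(bad)[1]]))
  }
  introns <- parts %>% filter(.data$part == "exon") %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    dplyr::reframe(istart = utils::head(.data$end, -1) + 1L,
                   iend = utils::tail(.data$start, -1) - 1L) %>%
    mutate(part = "intron") %>%
    filter(.data$iend >= .data$istart) %>%
    rename(start = "istart", end = "iend")
  prom <- genes %>% mutate(
    part = "promoter",
    fstart = ifelse(.data$strand == "+", .data$start - promoter_bp,
                    .data$end + 1L),
    fend = ifelse(.data$strand == "+", .data$start - 1L,
                  .data$end + promoter_bp))
  down <- genes %>% mutate(
    part = "downstream",
    fstart = ifelse(.data$strand == "+", .data$end + 1L,
                    .data$start - downstream_bp),
    fend = ifelse(.data$strand == "+", .data$end + downstream_bp,
                  .data$start - 1L))
  flanks <- bind_rows(prom, down) %>%
    dplyr::transmute(gene_id = .data$gene_id, chrom = .data$chrom,
                     strand = .data$strand, part = .data$part,
                     start = as.integer(.data$fstart),
                     end = as.integer(.data$fend))
  features <- bind_rows(
    parts %>% select("gene_id", "chrom", "strand", "part", "start", "end"),
    introns %>% select("gene_id", "chrom", "strand", "part", "start", "end"),
    flanks) %>%
    arrange(.data$chrom, .data$gene_id, .data$start)
  list(genes = genes, features = features)
}

# ---- TSV dialects -----------------------------------------------------------

#' Read a per-cytosine methylation count table
#'
#' Dialect: tab-separated with header columns `chrom`, `pos`, `strand`,
#' `context`, `ratio`, `eff_CT_count`, `C_count`; 1-based positions.
#'
#' @param path Input file.
#' @return Tibble: `chrom`, `pos`, `strand`, `context`, `ratio`,
#'   `meth_reads`, `total_reads`.
#' @export
read_meth_tsv <- function(path) {
  x <- read_tsv_quiet(path)
  if ("chrom" %in% names(x)) x$chrom <- as.character(x$chrom)
  need <- c("chrom", "pos", "strand", "context", "eff_CT_count", "C_count")
  if (!all(need %in% names(x))) {
    abort(paste("methylation TSV must have columns:",
                paste(need, collapse = ", ")))
  }
  check_pos(x$pos); check_strand(x$strand)
  if (!all(x$context %in% c("CG", "CHG", "CHH"))) abort("invalid context")
  if (any(x$C_count > x$eff_CT_count | x$C_count < 0)) {
    abort("need 0 <= C_count <= eff_CT_count")
  }
  x %>% transmute(chrom = .data$chrom, pos = as.integer(.data$pos),
                  strand = .data$strand, context = .data$context,
                  ratio = ifelse(.data$eff_CT_count > 0,
                                 .data$C_count / .data$eff_CT_count, NA_real_),
                  meth_reads = as.integer(.data$C_count),
                  total_reads = as.integer(.data$eff_CT_count))
}

#' Write a per-cytosine methylation count table
#' @param sites Tibble with `chrom`, `pos`, `strand`, `context`,
#'   `meth_reads`, `total_reads`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meth_tsv <- function(sites, path) {
  out <- sites %>%
    transmute(chrom = .data$chrom, pos = .data$pos, strand = .data$strand,
              context = .data$context,
              ratio = ifelse(.data$total_reads > 0,
                             .data$meth_reads / .data$total_reads, NA_real_),
              eff_CT_count = .data$total_reads, C_count = .data$meth_reads)
  write_tsv_prov(out, path)
}

#' Write methylation calls (count dialect plus `p`, `q`, `status`)
#' @param calls A `meth_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls %>%
    transmute(chrom = .data$chrom, pos = .data$pos, strand = .data$strand,
              context = .data$context, ratio = .data$ratio,
              eff_CT_count = .data$total_reads, C_count = .data$meth_reads,
              p = .data$p_value, q = .data$q_value, status = .data$status)
  write_tsv_prov(out, path)
}

#' Read an FPKM expression table (`gene_id` + leaf/root/flower/pod)
#' @param path Input file.
#' @return Tibble.
#' @export
read_expression_tsv <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols(gene_id = "c"))
  need <- c("gene_id", "leaf", "root", "flower", "pod")
  if (!all(need %in% names(x))) {
    abort("expression TSV needs gene_id + leaf/root/flower/pod columns")
  }
  x
}

#' Write an FPKM expression table
#' @param expr Tibble with `gene_id` and tissue columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) write_tsv_prov(expr, path)

#' Read a triplet table (`triplet_id`, `lf_gene`, `mf1_gene`, `mf2_gene`)
#' @param path Input file.
#' @return Tibble: `triplet_id`, `LF`, `MF1`, `MF2`.
#' @export
read_triplets_tsv <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  need <- c("triplet_id", "lf_gene", "mf1_gene", "mf2_gene")
  if (!all(need %in% names(x))) {
    abort("triplet TSV needs triplet_id, lf_gene, mf1_gene, mf2_gene")
  }
  x %>% rename(LF = "lf_gene", MF1 = "mf1_gene", MF2 = "mf2_gene")
}

#' Write a triplet table
#' @param triplets Tibble with `triplet_id`, `LF`, `MF1`, `MF2`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_triplets_tsv <- function(triplets, path) {
  write_tsv_prov(triplets %>% rename(lf_gene = "LF", mf1_gene = "MF1",
                                     mf2_gene = "MF2"), path)
}

#' Read a progeny genotype matrix (`marker`, `chrom`, `pos`, one column
#' per progeny)
#' @param path Input file.
#' @return Wide genotype tibble with `pos_bp`.
#' @export
read_genotypes_tsv <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("marker", "chrom", "pos") %in% names(x))) {
    abort("genotype TSV needs marker, chrom, pos + progeny columns")
  }
  check_pos(x$pos)
  x %>% rename(pos_bp = "pos")
}

#' Write a progeny genotype matrix
#' @param genotypes Wide genotype tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  out <- genotypes %>% rename(pos = "pos_bp")
  if ("map_pos" %in% names(out)) out$map_pos <- NULL
  write_tsv_prov(out, path)
}

#' Read a homology hit table (BLAST tabular subset)
#' @param path Input file with `qseqid`, `sseqid`, `bitscore`, `evalue`.
#' @return Tibble.
#' @export
read_hits_tsv <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols(qseqid = "c",
                                                    sseqid = "c"))
  need <- c("qseqid", "sseqid", "bitscore", "evalue")
  if (!all(need %in% names(x))) {
    abort("hits TSV needs qseqid, sseqid, bitscore, evalue")
  }
  if (any(x$evalue < 0)) abort("evalue must be >= 0")
  x
}

#' Write a homology hit table
#' @param hits Tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) write_tsv_prov(hits, path)

#' Write a binned track as bedGraph
#'
#' Converts the package's 1-based inclusive bins to bedGraph's 0-based
#' half-open intervals; `NA` bins are dropped.
#'
#' @param track Tibble from [binned_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  out <- track %>% filter(!is.na(.data$value)) %>%
    transmute(chrom = .data$chrom, start = .data$start - 1L, end = .data$end,
              value = .data$value)
  writeLines(c(provenance_line(),
               paste(out$chrom, out$start, out$end, out$value, sep = "\t")),
             path)
  invisible(path)
}
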