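# match call positions to 1-based inclusive intervals, per chromosome;
# returns a tibble of (site_row, feature_row) index pairs
overlap_pairs <- function(sites, intervals) {
  pairs <- list()
  for (ch in unique(intervals$chrom)) {
    si <- which(sites$chrom == ch)
    fi <- which(intervals$chrom == ch)
    if (!length(si) || !length(fi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], sites$pos[si]),
      IRanges::IRanges(intervals$start[fi], intervals$end[fi]))
    pairs[[ch]] <- tibble(site_row = si[S4Vectors::queryHits(hits)],
                          feature_row = fi[S4Vectors::subjectHits(hits)])
  }
  if (!length(pairs)) {
    return(tibble(site_row = integer(), feature_row = integer()))
  }
  bind_rows(pairs)
}

#' Genome-wide methylation level per sequence context
#'
#' The level of a context is the percentage of its tested cytosines
#' (depth `>= min_depth`) called methylated, matching the site-fraction
#' reading of genome-wide summaries such as "54.9% of all CGs".
#'
#' @param calls A `meth_calls` tibble from [call_sites()].
#' @param min_depth Minimum depth entering the denominator.
#' @return Tibble `context`, `n_tested`, `n_methylated`, `level_pct`.
#'   Contexts with no tested site are absent (missing, not 0).
#' @export
context_levels <- function(calls, min_depth = 1) {
  calls %>%
    filter(.data$status != "untested", .data$total_reads >= min_depth) %>%
    group_by(.data$context) %>%
    summarise(n_tested = n(),
              n_methylated = sum(.data$status == "methylated"),
              level_pct = 100 * .data$n_methylated[1] / .data$n_tested[1],
              .groups = "drop")
}

#' Methylation level per gene part or gene category
#'
#' For every (part or category, context) cell, the fraction of tested
#' sites falling inside the corresponding intervals that were called
#' methylated.  A site overlapped by several features (e.g. the abutting
#' promoter and downstream windows of neighbouring genes) contributes to
#' each.  `weighted = TRUE` reports the read-weighted alternative
#' `sum(k) / sum(n)` instead of the site fraction.
#'
#' @param calls A `meth_calls` tibble.
#' @param features Feature tibble with `chrom`, `start`, `end` and the
#'   grouping column.
#' @param by Grouping column of `features`, `"part"` or `"category"`.
#' @param weighted Use read-weighted levels.
#' @param min_depth Minimum depth entering denominators.
#' @return Tibble (group, `context`, `n_sites`, `level`).  Cells with no
#'   overlapping tested site are absent.
#' @export
feature_levels <- function(calls, features, by = "part", weighted = FALSE,
                           min_depth = 1) {
  if (!by %in% names(features)) abort(sprintf("features lacks column '%s'", by))
  chrom_len <- calls %>% group_by(.data$chrom) %>%
    summarise(maxpos = max(.data$pos), .groups = "drop")
  if (any(features$start < 1)) abort("feature beyond chromosome bounds")
  pairs <- overlap_pairs(calls, features)
  if (!nrow(pairs)) {
    return(tibble(!!by := character(), context = character(),
                  n_sites = integer(), level = numeric()))
  }
  df <- tibble(group = features[[by]][pairs$feature_row],
               context = calls$context[pairs$site_row],
               status = calls$status[pairs$site_row],
               k = calls$meth_reads[pairs$site_row],
               n = calls$total_reads[pairs$site_row]) %>%
    filter(.data$status != "untested", .data$n >= min_depth)
  out <- df %>% group_by(.data$group, .data$context) %>%
    summarise(n_sites = n(),
              level = if (weighted) sum(.data$k) / sum(.data$n)
                      else mean(.data$status == "methylated"),
              .groups = "drop")
  names(out)[1] <- by
  out
}

#' Metagene methylation profile
#'
#' Averages per-gene methylation across genes in fixed-width flank bins
#' (upstream and downstream of the gene body, anchored at the annotated
#' start and stop) and a fixed number of length-scaled body bins.
#' Coordinates are flipped for minus-strand genes.  The per-bin value is
#' the mean over genes of the per-gene fraction of tested sites called
#' methylated in that bin (genes equally weighted); `pooled = TRUE`
#' pools sites across genes instead.
#'
#' @param calls A `meth_calls` tibble.
#' @param genes Gene tibble: `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param upstream_bp,downstream_bp Flank widths (multiples of `bin_bp`).
#' @param n_body_bins Number of body bins.
#' @param bin_bp Flank bin width.
#' @param pooled Pool sites across genes instead of per-gene averaging.
#' @return Tibble of class `metagene_profile`: `context`, `bin` (1-based
#'   across upstream, body, downstream), `region`, `level`, `n_genes`.
#'   Genes shorter than `n_body_bins` bases are skipped; the count is kept
#'   in attribute `n_skipped`.
#' @export
metagene_profile <- function(calls, genes, upstream_bp = 2000,
                             n_body_bins = 40, downstream_bp = 2000,
                             bin_bp = 100, pooled = FALSE) {
  n_up <- upstream_bp / bin_bp; n_down <- downstream_bp / bin_bp
  if (n_up != round(n_up) || n_down != round(n_down)) {
    abort("flank widths must be multiples of bin_bp")
  }
  width <- genes$end - genes$start + 1
  skip <- width < n_body_bins
  n_skipped <- sum(skip)
  if (n_skipped) inform(sprintf("skipping %d genes shorter than %d bp",
                                n_skipped, n_body_bins))
  genes <- genes[!skip, , drop = FALSE]
  regions <- genes %>% mutate(rstart = .data$start - ifelse(.data$strand == "+", upstream_bp, downstream_bp),
                              rend = .data$end + ifelse(.data$strand == "+", downstream_bp, upstream_bp))
  pairs <- overlap_pairs(calls,
                         tibble(chrom = regions$chrom,
                                start = pmax(1, regions$rstart),
                                end = regions$rend))
  tested <- calls$status[pairs$site_row] != "untested"
  pairs <- pairs[tested, , drop = FALSE]
  n_total <- n_up + n_body_bins + n_down
  if (!nrow(pairs)) {
    out <- tibble(context = character(), bin = integer(), region = character(),
                  level = numeric(), n_genes = integer())
  } else {
    g <- genes[pairs$feature_row, ]
    pos <- calls$pos[pairs$site_row]
    w <- g$end - g$start + 1
    # signed offset from the 5' gene boundary, in gene orientation
    off5 <- ifelse(g$strand == "+", pos - g$start, g$end - pos)
    off3 <- ifelse(g$strand == "+", pos - g$end, g$start - pos)
    bin <- ifelse(off5 < 0,
                  n_up + 1 + floor(off5 / bin_bp),            # upstream
                  ifelse(off3 > 0,
                         n_up + n_body_bins + ceiling(off3 / bin_bp),  # downstream
                         n_up + 1 + floor(off5 / w * n_body_bins)))    # body
    bin <- pmin(pmax(bin, 1), n_total)
    df <- tibble(gene_id = g$gene_id,
                 context = calls$context[pairs$site_row],
                 meth = calls$status[pairs$site_row] == "methylated",
                 bin = as.integer(bin))
    out <- if (pooled) {
      df %>% group_by(.data$context, .data$bin) %>%
        summarise(level = mean(.data$meth), n_genes = n_distinct(.data$gene_id),
                  .groups = "drop")
    } else {
      df %>% group_by(.data$context, .data$bin, .data$gene_id) %>%
        summarise(gl = mean(.data$meth), .groups = "drop") %>%
        group_by(.data$context, .data$bin) %>%
        summarise(level = mean(.data$gl), n_genes = n(), .groups = "drop")
    }
    out <- out %>% mutate(region = ifelse(.data$bin <= n_up, "upstream",
                                          ifelse(.data$bin <= n_up + n_body_bins,
                                                 "body", "downstream"))) %>%
      select("context", "bin", "region", "level", "n_genes")
  }
  class(out) <- c("metagene_profile", class(out))
  attr(out, "bin_spec") <- list(upstream_bp = upstream_bp,
                                n_body_bins = n_body_bins,
                                downstream_bp = downstream_bp, bin_bp = bin_bp)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Fixed-width genome track of a positional value
#'
#' Bins per-site or per-gene values into non-overlapping windows per
#' chromosome (default 500 kb, as used for whole-genome expression and
#' methylation rings).  The last partial window is kept.
#'
#' @param x Tibble with `chrom`, `pos` and (unless counting) the value
#'   column.
#' @param bin_bp Window width in bp.
#' @param statistic `"mean"`, `"median"` or `"count"`.
#' @param value_col Name of the value column.
#' @return Tibble `chrom`, `bin`, `start`, `end`, `value`.  Empty bins
#'   between occupied ones are emitted with `NA` value.
#' @export
binned_track <- function(x, bin_bp = 500000, statistic = c("mean", "median", "count"),
                         value_col = "value") {
  statistic <- match.arg(statistic)
  if (bin_bp <= 0) abort("bin_bp must be positive")
  stat_fun <- switch(statistic, mean = mean, median = stats::median,
                     count = length)
  vals <- if (statistic == "count") rep(1, nrow(x)) else x[[value_col]]
  occupied <- x %>%
    mutate(.bin = floor((.data$pos - 1) / bin_bp) + 1, .val = vals) %>%
    group_by(.data$chrom, .data$.bin) %>%
    summarise(value = stat_fun(.data$.val), .groups = "drop")
  # fill unoccupied interior bins with NA (count bins stay meaningful as 0)
  out <- occupied %>% group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      left_join(tibble(.bin = as.numeric(seq_len(max(d$.bin)))), d,
                by = ".bin")
    }) %>%
    ungroup() %>%
    mutate(value = if (statistic == "count")
      tidyr::replace_na(.data$value, 0) else .data$value)
  out %>%
    mutate(bin = as.integer(.data$.bin),
           start = as.integer((.data$bin - 1) * bin_bp + 1),
           end = as.integer(.data$bin * bin_bp)) %>%
    select("chrom", "bin", "start", "end", "value") %>%
    arrange(.data$chrom, .data$bin)
}
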