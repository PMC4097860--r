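#' Per-marker heterozygosity frequency profile
#'
#' In progeny of first-division-restitution unreduced gametes both
#' parental centromeres are retained, so heterozygosity is complete at the
#' centromere and decays with map distance; the per-marker het frequency
#' is the raw signal for centromere prediction.  Missing states are
#' excluded from denominators (no imputation).
#'
#' @param genotypes Wide genotype tibble: `marker`, `chrom`, `pos_bp`
#'   (optional `map_pos`), then one column per progeny with states
#'   `"het"`, `"homA"`, `"homB"`, `"missing"` (e.g. from
#'   [simulate_fdr_progeny()]).
#' @return Tibble of class `het_profile`: `marker`, `chrom`, `pos_bp`,
#'   `n_typed`, `het_freq` (`NA` when all progeny are missing).
#' @export
heterozygosity_profile <- function(genotypes) {
  meta_cols <- intersect(c("marker", "chrom", "pos_bp", "map_pos"),
                         names(genotypes))
  states <- as.matrix(genotypes[, setdiff(names(genotypes), meta_cols)])
  ok <- states %in% c("het", "homA", "homB", "missing")
  if (!all(ok)) abort("invalid genotype state; expected het/homA/homB/missing")
  typed <- states != "missing"
  n_typed <- rowSums(typed)
  het <- rowSums(states == "het")
  out <- genotypes[, meta_cols] %>%
    mutate(n_typed = as.integer(n_typed),
           het_freq = ifelse(n_typed > 0, het / n_typed, NA_real_))
  class(out) <- c("het_profile", class(out))
  out
}

#' Estimate a centromere position from a heterozygosity profile
#'
#' Smooths the het frequency with a moving average over marker index
#' (default; `bp_space = TRUE` smooths over a bp window instead), takes
#' the position of the smoothed maximum as the point estimate (ties:
#' midpoint of the tied run), and reports the contiguous run of markers
#' with smoothed het within `support_drop` of the maximum as the support
#' interval.
#'
#' @param profile A single-chromosome `het_profile` tibble.
#' @param smoothing_window Moving-average window (markers, odd
#'   recommended), or window width in bp with `bp_space = TRUE`.
#' @param support_drop Drop from the maximum defining the interval; a
#'   profile whose total range is below this is flagged flat and returns
#'   `NA`.
#' @param bp_space Smooth in bp space instead of marker-index space.
#' @return One-row tibble: `chrom`, `centromere_bp`, `interval_start_bp`,
#'   `interval_end_bp`, `peak_het`, `n_markers`, `flat`.
#' @export
estimate_centromere <- function(profile, smoothing_window = 5,
                                support_drop = 0.05, bp_space = FALSE) {
  profile <- profile %>% filter(!is.na(.data$het_freq)) %>%
    arrange(.data$pos_bp)
  n <- nrow(profile)
  if (n < smoothing_window && !bp_space) {
    abort("fewer markers than the smoothing window")
  }
  sm <- if (bp_space) {
    vapply(seq_len(n), function(i) {
      win <- abs(profile$pos_bp - profile$pos_bp[i]) <= smoothing_window / 2
      mean(profile$het_freq[win])
    }, 0)
  } else {
    zoo::rollapply(profile$het_freq, smoothing_window, mean,
                   partial = TRUE, align = "center")
  }
  chrom <- profile$chrom[1] %||% NA_character_
  if (max(sm) - min(sm) < support_drop) {
    return(tibble(chrom = chrom, centromere_bp = NA_real_,
                  interval_start_bp = NA_real_, interval_end_bp = NA_real_,
                  peak_het = max(sm), n_markers = n, flat = TRUE))
  }
  mx <- max(sm)
  # ties: midpoint of the tied run containing the first maximum
  tied <- which(sm == mx)
  runs <- split(tied, cumsum(c(1, diff(tied) != 1)))
  run <- runs[[1]]
  point <- mean(profile$pos_bp[range(run)])
  # support interval: contiguous run around the peak with sm >= mx - drop
  ok <- sm >= mx - support_drop
  lo <- run[1]; hi <- run[length(run)]
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  while (hi < n && ok[hi + 1]) hi <- hi + 1
  tibble(chrom = chrom, centromere_bp = point,
         interval_start_bp = profile$pos_bp[lo],
         interval_end_bp = profile$pos_bp[hi],
         peak_het = mx, n_markers = n, flat = FALSE)
}

#' Estimate centromeres for every chromosome of a genotype matrix
#'
#' @param genotypes Wide genotype tibble (see
#'   [heterozygosity_profile()]).
#' @inheritParams estimate_centromere
#' @return Tibble with one row per chromosome.
#' @export
estimate_centromeres <- function(genotypes, smoothing_window = 5,
                                 support_drop = 0.05, bp_space = FALSE) {
  prof <- heterozygosity_profile(genotypes)
  prof %>% group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      estimate_centromere(mutate(d, chrom = key$chrom),
                          smoothing_window = smoothing_window,
                          support_drop = support_drop,
                          bp_space = bp_space) %>% select(-"chrom")
    }) %>%
    ungroup()
}
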