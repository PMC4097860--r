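#' Chi-square test for gene-family expansion across species
#'
#' Per family, a Pearson chi-square test of the observed per-species gene
#' counts against expected counts proportional to the species' genome-wide
#' totals (`null = "proportional"`; `"equal"` uses equal shares).
#' P-values are Bonferroni-adjusted across families, and the
#' expanded species -- the one with the largest positive Pearson residual
#' -- is identified only for families significant after correction.
#' Families whose expected counts include a cell below 1 are flagged as
#' unreliable for the chi-square approximation.
#'
#' @param counts Tibble: `family_id` plus one non-negative count column
#'   per species.
#' @param totals Named numeric vector of genome-wide per-species totals
#'   (default: column sums of `counts`).
#' @param alpha Family-wise significance threshold after Bonferroni.
#' @param null `"proportional"` or `"equal"`.
#' @return Tibble: `family_id`, `chi2`, `df`, `p`, `p_bonferroni`,
#'   `expanded_species` (`NA` unless significant), `low_expected`.
#'   Families with total count 0 are skipped with a message.
#' @export
family_expansion_test <- function(counts, totals = NULL, alpha = 0.05,
                                  null = c("proportional", "equal")) {
  null <- match.arg(null)
  species <- names(counts)[vapply(counts, is.numeric, logical(1))]
  if (length(species) < 2) abort("need at least 2 species count columns")
  O <- as.matrix(counts[, species])
  if (any(O < 0)) abort("counts must be non-negative")
  if (is.null(totals)) totals <- colSums(O)
  totals <- totals[species]
  if (sum(totals > 0) < 2) abort("need >= 2 species with nonzero totals")
  share <- if (null == "proportional") totals / sum(totals)
           else rep(1 / length(species), length(species))

  tot <- rowSums(O)
  zero <- tot == 0
  if (any(zero)) {
    inform(sprintf("skipping %d families with total count 0", sum(zero)))
  }
  E <- outer(tot, share)
  resid <- (O - E) / sqrt(E)
  chi2 <- rowSums((O - E)^2 / E)
  chi2[zero] <- NA_real_
  df <- length(species) - 1
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  n_tested <- sum(!zero)
  p_bonf <- pmin(1, p * n_tested)
  expanded <- vapply(seq_len(nrow(O)), function(i) {
    r <- resid[i, ]
    if (all(is.na(r))) NA_character_ else species[which.max(r)]
  }, character(1))
  expanded[zero | p_bonf >= alpha] <- NA_character_
  out <- tibble(family_id = counts$family_id,
                chi2 = chi2, df = df, p = p, p_bonferroni = p_bonf,
                expanded_species = expanded,
                low_expected = !zero & apply(E < 1, 1, any))
  out[!zero, , drop = FALSE]
}
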