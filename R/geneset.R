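# Fisher's-exact enrichment of external (e.g. clinical DE) gene sets in the
# genes enriched in each spatial domain.

#' Domain-enriched gene sets from enrichment statistics
#'
#' Per domain, the genes significant at `fdr < fdr_cut` with positive
#' t-statistic (i.e. enriched in, not depleted from, the domain).
#'
#' @param stats an enrichment-model `EnrichmentStats`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param t_positive require t > 0 (default `TRUE`).
#' @return named list of [gene_set()], one per domain (possibly empty sets
#'   are dropped).
#' @export
domain_enriched_sets <- function(stats, fdr_cut = 0.05, t_positive = TRUE) {
  stopifnot(is(stats, "EnrichmentStats"), !is.null(stats$fdr))
  out <- list()
  for (d in colnames(stats$fdr)) {
    sel <- !is.na(stats$fdr[, d]) & stats$fdr[, d] < fdr_cut
    if (t_positive) sel <- sel & stats$t[, d] > 0
    if (any(sel)) out[[d]] <- gene_set(d, stats$genes[sel])
  }
  out
}

#' Fisher's exact enrichment of gene sets in domain-enriched genes
#'
#' For each (domain, gene set) pair, forms the 2x2 table of membership in
#' the set by membership in the domain's enriched genes over the stated
#' gene universe. The odds ratio is the sample cross-product
#' `OR = (a d)/(b c)` with `a` the overlap (0/0-free: `Inf` when `b c = 0`
#' and `a d > 0`, `0` when `a d = 0`); the p-value is the exact
#' hypergeometric tail (one-sided "greater" by default). BH FDR across all
#' (domain, set) pairs.
#'
#' @param domain_sets named list of [gene_set()] (e.g. from
#'   [domain_enriched_sets()]).
#' @param clinical_sets list of [gene_set()] to test.
#' @param universe character vector of background genes — typically the
#'   genes that survived the low-expression filter of [pseudobulk()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return data.frame of class `EnrichmentTable` with one row per
#'   (domain, set): `domain`, `set`, `overlap_count`, `set_size`,
#'   `domain_enriched_count`, `universe_size`, `odds_ratio`, `p`, `fdr`.
#' @export
fisher_enrichment <- function(domain_sets, clinical_sets, universe,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  all_sets <- c(domain_sets, clinical_sets)
  for (gs in all_sets) {
    out <- setdiff(gs$genes, universe)
    if (length(out))
      stop_cm("gene set '%s' has genes outside the universe: %s", gs$name,
              paste(utils::head(out, 5), collapse = ", "))
  }
  N <- length(universe)
  rows <- list()
  for (dn in names(domain_sets)) {
    dom <- intersect(domain_sets[[dn]]$genes, universe)
    for (gs in clinical_sets) {
      set <- gs$genes
      a <- length(intersect(set, dom))
      b <- length(set) - a
      cc <- length(dom) - a
      d <- N - a - b - cc
      or <- if (a * d == 0) 0 else if (b * cc == 0) Inf else (a * d) / (b * cc)
      p <- if (alternative == "greater") {
        phyper(a - 1, length(set), N - length(set), length(dom),
               lower.tail = FALSE)
      } else {
        stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "two.sided")$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        domain = dn, set = gs$name, overlap_count = a,
        set_size = length(set), domain_enriched_count = length(dom),
        universe_size = N, odds_ratio = or, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh(res$p)
  class(res) <- c("EnrichmentTable", "data.frame")
  res
}
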