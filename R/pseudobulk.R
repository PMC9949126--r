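#' Pseudo-bulk spots by (section, domain)
#'
#' Sums UMI counts of all QC-passing spots sharing a tissue section and a
#' spatial-domain label into one expression profile, the unit at which the
#' differential-expression models operate. Groups with fewer than `min_spots`
#' spots are dropped (with a message), mirroring the practice of excluding
#' unstable tiny pseudo-bulk samples. Log expression is
#' `log2(CPM + pseudocount)` on the pseudo-bulk library. Genes with nonzero
#' counts in fewer than `min_expr_frac` of the retained samples are flagged
#' low-expression and excluded from modeling (they stay in the counts).
#'
#' @param sections a `SpotMatrix` or list of them (one per section).
#' @param grouping metadata column holding the domain label at the requested
#'   clustering resolution (default `"domain_label"`).
#' @param min_spots minimum spots per (section, domain) pseudo-bulk sample.
#' @param pseudocount added to CPM before log2.
#' @param min_expr_frac minimum fraction of samples in which a gene must be
#'   nonzero to enter the models.
#' @return an object of class `PseudobulkSet`: integer `counts`
#'   (samples x genes), `logexpr`, `sample_meta`
#'   (`section_id`, `donor_id`, `domain_label`, `position`, `n_spots`), and
#'   logical `gene_keep`.
#' @export
pseudobulk <- function(sections, grouping = "domain_label", min_spots = 10,
                       pseudocount = 0.5, min_expr_frac = 0.1) {
  if (is(sections, "SpotMatrix")) sections <- list(sections)
  blocks <- list(); meta <- list()
  for (sm in sections) {
    if (is.null(sm$meta[[grouping]]) || all(is.na(sm$meta[[grouping]])))
      stop_cm("no '%s' labels available at the requested resolution", grouping)
    sv <- qc_view(sm)
    grp <- sv$meta[[grouping]]
    for (d in sort(unique(grp))) {
      idx <- which(grp == d)
      sec <- sv$meta$sample_id[idx[1]]
      if (length(idx) < min_spots) {
        message(sprintf("dropping pseudobulk sample %s/%s: %d < %d spots",
                        sec, d, length(idx), min_spots))
        next
      }
      blocks[[length(blocks) + 1L]] <-
        Matrix::colSums(sv$counts[idx, , drop = FALSE])
      meta[[length(meta) + 1L]] <- data.frame(
        section_id = sec,
        donor_id = sv$meta$donor_id[idx[1]],
        domain_label = d,
        position = sv$meta$position[idx[1]] %||% NA_character_,
        n_spots = length(idx), stringsAsFactors = FALSE)
    }
  }
  if (length(blocks) == 0) stop_cm("no pseudobulk samples retained")
  counts <- do.call(rbind, blocks)
  sample_meta <- do.call(rbind, meta)
  rownames(counts) <- rownames(sample_meta) <-
    paste(sample_meta$section_id, sample_meta$domain_label, sep = "_")
  libsize <- rowSums(counts)
  logexpr <- log2(1e6 * counts / libsize + pseudocount)
  gene_keep <- colMeans(counts > 0) >= min_expr_frac
  structure(list(counts = counts, logexpr = logexpr,
                 sample_meta = sample_meta, gene_keep = gene_keep,
                 pseudocount = pseudocount),
            class = "PseudobulkSet")
}

#' @export
print.PseudobulkSet <- function(x, ...) {
  cat(sprintf(
    "PseudobulkSet: %d samples x %d genes (%d modeled), %d sections, %d domains\n",
    nrow(x$counts), ncol(x$counts), sum(x$gene_keep),
    length(unique(x$sample_meta$section_id)),
    length(unique(x$sample_meta$domain_label))))
  invisible(x)
}
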