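# Ligand-receptor spatial mapping: cell-type specificity of each partner,
# per-domain spot co-expression with a one-vs-rest domain test, and a
# dominant-cell-type colocalization network. LR pairs enter as a list
# (catalog construction is upstream of this package).

#' A ligand-receptor pair
#'
#' @param ligand,receptor gene ids.
#' @param partner optional intracellular partner gene id.
#' @return an object of class `LRPair`.
#' @export
lr_pair <- function(ligand, receptor, partner = NULL) {
  structure(list(ligand = ligand, receptor = receptor, partner = partner),
            class = "LRPair")
}

cell_cpm <- function(cells) {
  tot <- rowSums(cells$counts)
  1e6 * cells$counts / pmax(tot, 1)
}

#' Cell-type specificity measure (SPM) of a gene
#'
#' Let x be the vector of mean normalized expression (CPM) of the gene
#' across cell types. The SPM of type i is `x_i / ||x||_2` — the cosine of
#' x with the unit vector of that type — so SPM lies in `[0, 1]`, equals 1
#' for exclusive expression, `1/sqrt(n)` under uniform expression over n
#' types, and the squared SPMs sum to 1.
#'
#' @param cells a [cell_profile_set()].
#' @param gene gene id.
#' @return named numeric vector of SPM per cell type; all-`NA` (with a
#'   warning) when the gene is expressed nowhere.
#' @export
specificity_measure <- function(cells, gene) {
  if (!gene %in% cells$gene_ids) stop_cm("gene '%s' not present", gene)
  cpm <- cell_cpm(cells)[, gene]
  x0 <- tapply(cpm, cells$cell_type, mean)
  x <- setNames(as.numeric(x0), names(x0))
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) {
    warning(sprintf("gene '%s' unexpressed in all types; SPM undefined", gene))
    return(setNames(rep(NA_real_, length(x)), names(x)))
  }
  x / nrm
}

#' Specificity table for several genes
#' @param cells a [cell_profile_set()].
#' @param genes gene ids.
#' @return data.frame of class `SpecificityTable` (gene, cell_type, spm).
#' @export
specificity_table <- function(cells, genes) {
  rows <- lapply(genes, function(g) {
    s <- specificity_measure(cells, g)
    data.frame(gene = g, cell_type = names(s), spm = unname(s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("SpecificityTable", "data.frame")
  res
}

#' Within-cell-type co-expression percentage of a gene pair
#'
#' Percentage of cells of the given type with nonzero counts of both genes.
#'
#' @param cells a [cell_profile_set()].
#' @param geneA,geneB gene ids.
#' @param cell_type label to restrict to.
#' @return percentage in `[0, 100]`.
#' @export
cotype_coexpression <- function(cells, geneA, geneB, cell_type) {
  idx <- cells$cell_type == cell_type
  if (!any(idx)) stop_cm("no cells of type '%s'", cell_type)
  miss <- setdiff(c(geneA, geneB), cells$gene_ids)
  if (length(miss) == length(unique(c(geneA, geneB))) && length(miss) > 0)
    return(0)
  has <- function(g) if (g %in% cells$gene_ids)
    cells$counts[idx, g] > 0 else rep(FALSE, sum(idx))
  100 * mean(has(geneA) & has(geneB))
}

coexpr_flags <- function(sm, pair) {
  miss <- setdiff(c(pair$ligand, pair$receptor), sm$gene_ids)
  if (length(miss))
    return(rep(FALSE, nrow(sm$counts)))
  (sm$counts[, pair$ligand] > 0) & (sm$counts[, pair$receptor] > 0)
}

#' Per-domain spot co-expression of a ligand-receptor pair
#'
#' A spot co-expresses the pair iff both genes have raw count > 0 (spot-
#' level presence as the proxy for contact-dependent signaling). Reports,
#' per (section, domain), the proportion of the domain's QC-passing spots
#' that co-express, and per domain a one-sided paired test (paired across
#' sections) of the domain's per-section proportion against the mean
#' per-section proportion of all other domains, with BH adjustment across
#' domains. Sections lacking the domain are omitted from its pairing.
#'
#' @param sections a `SpotMatrix` or list of them.
#' @param pair an [lr_pair()].
#' @param test `"t"` (paired one-sided t-test, default) or `"wilcoxon"`
#'   (paired one-sided signed-rank).
#' @return list of class `CoexprResult`: `by_section_domain` data.frame
#'   (`section_id`, `domain`, `n_spots`, `n_coexpr`, `proportion`) and
#'   `by_domain` data.frame (`domain`, `mean_prop`, `mean_prop_others`,
#'   `statistic`, `p`, `fdr`, `n_sections`).
#' @export
coexpression_by_domain <- function(sections, pair, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (is(sections, "SpotMatrix")) sections <- list(sections)
  rows <- list()
  for (sm in sections) {
    sv <- qc_view(sm)
    co <- coexpr_flags(sv, pair)
    for (d in sort(unique(sv$meta$domain_label))) {
      idx <- sv$meta$domain_label == d
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = sv$meta$sample_id[1], domain = d,
        n_spots = sum(idx), n_coexpr = sum(co[idx]),
        proportion = mean(co[idx]), stringsAsFactors = FALSE)
    }
  }
  bs <- do.call(rbind, rows)
  domains <- sort(unique(bs$domain))
  per <- lapply(domains, function(d) {
    tgt <- bs[bs$domain == d, ]
    diffs <- vapply(tgt$section_id, function(s) {
      others <- bs[bs$section_id == s & bs$domain != d, "proportion"]
      if (length(others) == 0) return(NA_real_)
      tgt$proportion[tgt$section_id == s] - mean(others)
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 2 || sd(diffs) == 0) {
      stat <- 0; p <- 1
    } else if (test == "t") {
      stat <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
      p <- pt(stat, df = length(diffs) - 1, lower.tail = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(diffs, alternative = "greater"))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(domain = d, mean_prop = mean(tgt$proportion),
               mean_prop_others = mean(tgt$proportion) - mean(diffs),
               statistic = stat, p = p, n_sections = length(diffs),
               stringsAsFactors = FALSE)
  })
  bd <- do.call(rbind, per)
  bd$fdr <- bh(bd$p)
  structure(list(by_section_domain = bs, by_domain = bd, pair = pair,
                 test = test),
            class = "CoexprResult")
}

#' @export
print.CoexprResult <- function(x, ...) {
  cat(sprintf("CoexprResult (%s-%s): %d domains\n",
              x$pair$ligand, x$pair$receptor, nrow(x$by_domain)))
  print(x$by_domain[order(x$by_domain$p), ], row.names = FALSE)
  invisible(x)
}

#' Dominant-cell-type colocalization network of an LR pair
#'
#' For every co-expressing spot (both genes count > 0), takes the spot's
#' `top_k` cell types by deconvolution-predicted count (ties broken by the
#' prediction matrix's fixed cell-type order), increments each type's node
#' weight and the count of every unordered pair among them, pooling over
#' sections; the edge score is the pair count divided by the total number
#' of co-expressing spots.
#'
#' @param sections a `SpotMatrix` or list of them.
#' @param pair an [lr_pair()].
#' @param preds a [prediction_matrix()] or list of them aligned with
#'   `sections` (spot ids must match).
#' @param top_k number of dominant cell types per spot (default 3).
#' @return list of class `ColocNetwork`: `nodes` (`cell_type`, `weight`),
#'   `edges` (`type_a`, `type_b`, `count`, `score`), `n_coexpr`.
#' @export
colocalization_network <- function(sections, pair, preds, top_k = 3) {
  if (is(sections, "SpotMatrix")) sections <- list(sections)
  if (is(preds, "PredictionMatrix")) preds <- list(preds)
  if (length(sections) != length(preds))
    stop_cm("need one prediction matrix per section")
  types <- preds[[1]]$cell_types
  if (top_k > length(types))
    stop_cm("top_k = %d exceeds %d cell types", top_k, length(types))
  node_w <- setNames(numeric(length(types)), types)
  edge_n <- list()
  n_co <- 0L
  for (i in seq_along(sections)) {
    sv <- qc_view(sections[[i]])
    pv <- preds[[i]]$values
    pv <- pv[match(sv$spot_ids, rownames(pv)), , drop = FALSE]
    if (anyNA(pv[, 1])) stop_cm("prediction spot ids do not match section %d", i)
    co <- which(coexpr_flags(sv, pair))
    n_co <- n_co + length(co)
    for (s in co) {
      # ties broken by fixed cell-type order (order() is stable)
      top <- types[order(-pv[s, ])[seq_len(top_k)]]
      node_w[top] <- node_w[top] + 1
      prs <- utils::combn(sort(top), 2)
      for (j in seq_len(ncol(prs))) {
        key <- paste(prs[1, j], prs[2, j], sep = "|")
        edge_n[[key]] <- (edge_n[[key]] %||% 0L) + 1L
      }
    }
  }
  if (n_co == 0L) {
    edges <- data.frame(type_a = character(0), type_b = character(0),
                        count = integer(0), score = numeric(0))
  } else {
    keys <- names(edge_n)
    ab <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    edges <- data.frame(type_a = ab[, 1], type_b = ab[, 2],
                        count = unlist(edge_n, use.names = FALSE),
                        stringsAsFactors = FALSE)
    edges$score <- edges$count / n_co
    edges <- edges[order(-edges$score, edges$type_a, edges$type_b), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = data.frame(cell_type = types,
                                    weight = unname(node_w),
                                    stringsAsFactors = FALSE),
                 edges = edges, n_coexpr = n_co, top_k = top_k),
            class = "ColocNetwork")
}

#' @export
print.ColocNetwork <- function(x, ...) {
  cat(sprintf("ColocNetwork: %d co-expressing spots, %d edges (top_k = %d)\n",
              x$n_coexpr, nrow(x$edges), x$top_k))
  print(utils::head(x$edges, 10), row.names = FALSE)
  invisible(x)
}
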