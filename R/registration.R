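# Spatial registration: assign anatomical identity to data-driven clusters
# by correlating their gene-level enrichment t-statistics with those of a
# reference (e.g. manually annotated histological layers).

#' Correlate enrichment statistics of query clusters with a reference
#'
#' The gene universe is the intersection of query and reference gene ids
#' (at least 30 genes required), optionally restricted to the union over
#' reference domains of each domain's `top_n` genes by t-statistic. Each
#' query cluster's t-vector is then correlated with each reference domain's
#' t-vector.
#'
#' @param query,reference enrichment-model `EnrichmentStats` or plain
#'   genes x domains t-statistic matrices (rownames = gene ids).
#' @param top_n restrict to each reference domain's top `top_n` genes by t
#'   (default `NULL`: all shared genes).
#' @param method correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return an object of class `RegistrationResult`: correlation matrix
#'   `cor` (query clusters x reference domains), `genes_used`, `method`,
#'   `top_n`.
#' @export
correlate_stats <- function(query, reference, top_n = NULL,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  qt <- t_matrix(query); rt <- t_matrix(reference)
  shared <- intersect(rownames(qt), rownames(rt))
  if (length(shared) < 30)
    stop_cm("only %d shared genes between query and reference (need >= 30)",
            length(shared))
  if (!is.null(top_n)) {
    rsub <- rt[shared, , drop = FALSE]
    keep <- unique(unlist(lapply(seq_len(ncol(rsub)), function(j)
      shared[order(rsub[, j], decreasing = TRUE)[seq_len(min(top_n,
                                                             nrow(rsub)))]])))
    shared <- keep
  }
  qt <- qt[shared, , drop = FALSE]; rt <- rt[shared, , drop = FALSE]
  zero_q <- apply(qt, 2, sd) == 0; zero_r <- apply(rt, 2, sd) == 0
  if (any(zero_q) || any(zero_r))
    warning("zero-variance t-vector(s); their correlations set to 0")
  cc <- matrix(0, ncol(qt), ncol(rt),
               dimnames = list(colnames(qt), colnames(rt)))
  ok_q <- which(!zero_q); ok_r <- which(!zero_r)
  if (length(ok_q) && length(ok_r))
    cc[ok_q, ok_r] <- cor(qt[, ok_q, drop = FALSE], rt[, ok_r, drop = FALSE],
                          method = method)
  structure(list(cor = cc, genes_used = shared, method = method,
                 top_n = top_n %||% "all"),
            class = "RegistrationResult")
}

#' @export
print.RegistrationResult <- function(x, ...) {
  cat(sprintf("RegistrationResult: %d query clusters x %d references (%s, %d genes)\n",
              nrow(x$cor), ncol(x$cor), x$method, length(x$genes_used)))
  print(round(x$cor, 3))
  invisible(x)
}

#' Annotate clusters from a registration correlation matrix
#'
#' Per query cluster the reference correlations are sorted decreasingly,
#' c1 >= c2 >= ...; the annotation starts with the top reference, and
#' reference i+1 is appended while the relative successive drop
#' `(c_i - c_{i+1}) / c_i` stays below `merge_ratio` and `c_{i+1} > 0`
#' (negative correlations never merge). Labels join the included reference
#' names with `"/"` (e.g. `"L1/L2"`). Confidence is `"good"` iff the top
#' correlation exceeds `cutoff`, else `"poor"`. An all-zero row is labeled
#' `"unassigned"` with poor confidence.
#'
#' @param rr a [correlate_stats()] result (or a bare correlation matrix).
#' @param cutoff good-confidence threshold on the top correlation
#'   (default 0.25).
#' @param merge_ratio relative-drop threshold governing multi-reference
#'   labels; 0.1 is typical when annotating spatial domains, 0.25 when
#'   annotating snRNA-seq clusters.
#' @return a data.frame of class `AnnotationTable`: one row per cluster
#'   with `cluster`, `label`, `confidence`, `top_cor`, `n_merged`.
#' @export
annotate_clusters <- function(rr, cutoff = 0.25, merge_ratio = 0.1) {
  stopifnot(cutoff > 0, cutoff < 1, merge_ratio > 0, merge_ratio < 1)
  cc <- if (is.matrix(rr)) rr else rr$cor
  out <- lapply(rownames(cc), function(q) {
    r <- cc[q, ]
    if (all(r == 0))
      return(data.frame(cluster = q, label = "unassigned",
                        confidence = "poor", top_cor = 0, n_merged = 0L,
                        stringsAsFactors = FALSE))
    ord <- order(r, decreasing = TRUE)
    rs <- r[ord]
    keep <- 1L
    while (keep < length(rs) &&
           rs[keep + 1] > 0 &&
           (rs[keep] - rs[keep + 1]) / rs[keep] < merge_ratio)
      keep <- keep + 1L
    data.frame(cluster = q,
               label = paste(names(rs)[seq_len(keep)], collapse = "/"),
               confidence = if (rs[1] > cutoff) "good" else "poor",
               top_cor = unname(rs[1]), n_merged = keep,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("AnnotationTable", "data.frame")
  res
}

#' Register query clusters end to end
#'
#' Convenience wrapper: [correlate_stats()] then [annotate_clusters()].
#'
#' @inheritParams correlate_stats
#' @inheritParams annotate_clusters
#' @return list with `registration` and `annotation`.
#' @export
register_clusters <- function(query, reference, cutoff = 0.25,
                              merge_ratio = 0.1, top_n = NULL,
                              method = "pearson") {
  rr <- correlate_stats(query, reference, top_n = top_n, method = method)
  list(registration = rr,
       annotation = annotate_clusters(rr, cutoff, merge_ratio))
}
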