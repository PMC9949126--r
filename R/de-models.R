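# Differential-expression models on pseudo-bulk profiles.
#
# All three models (enrichment = one-vs-all, ANOVA, pairwise) share a
# fixed-design linear-model engine fitted gene-wise by QR, with
# method-of-moments empirical-Bayes variance moderation: per-gene residual
# variances s2_g on d residual df are shrunk toward their mean s0^2 with
# prior df d0,
#   s2_tilde = (d0 * s0^2 + d * s2_g) / (d0 + d),
# and t/F statistics use s2_tilde on d + d0 df. d0 = 0 recovers the ordinary
# unmoderated statistics exactly.

new_enrichment_stats <- function(model, genes, ...) {
  structure(c(list(model = model, genes = genes), list(...)),
            class = "EnrichmentStats")
}

#' @export
print.EnrichmentStats <- function(x, ...) {
  extra <- if (!is.null(x$t)) sprintf(", %d contrasts", ncol(x$t)) else ""
  cat(sprintf("EnrichmentStats [%s]: %d genes%s\n",
              x$model, length(x$genes), extra))
  invisible(x)
}

#' Extract the gene-by-domain t-statistic matrix
#' @param stats an enrichment-model `EnrichmentStats` or a numeric matrix.
#' @return numeric matrix, genes x domains.
#' @export
t_matrix <- function(stats) {
  if (is.matrix(stats)) return(stats)
  if (!is(stats, "EnrichmentStats") || is.null(stats$t))
    stop_cm("need an enrichment-model EnrichmentStats (with a t matrix)")
  stats$t
}

#' @export
as.data.frame.EnrichmentStats <- function(x, ...) {
  if (x$model %in% c("anova", "position")) return(x$table)
  df <- data.frame(gene = rep(x$genes, ncol(x$t)),
                   domain = rep(colnames(x$t), each = nrow(x$t)),
                   t = as.vector(x$t), logFC = as.vector(x$logFC),
                   p = as.vector(x$p), fdr = as.vector(x$fdr),
                   stringsAsFactors = FALSE)
  if (x$model == "pairwise") {
    i <- match(df$domain, paste(x$pair_table$domain_a, x$pair_table$domain_b,
                                sep = "|"))
    df <- data.frame(gene = df$gene,
                     domain_a = x$pair_table$domain_a[i],
                     domain_b = x$pair_table$domain_b[i],
                     t = df$t, logFC = df$logFC, p = df$p, fdr = df$fdr,
                     stringsAsFactors = FALSE)
  }
  df
}

# Gene-wise least squares for a shared design. Y: samples x genes.
# Returns per-gene residual variance, df, and for a chosen coefficient its
# estimate and unscaled variance.
fit_genewise_lm <- function(Y, X, coef_idx = NULL) {
  qrX <- qr(X)
  d <- nrow(X) - qrX$rank
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% ifelse(is.na(beta), 0, beta)
  rss <- colSums(res^2)
  s2 <- if (d > 0) rss / d else rep(NA_real_, ncol(Y))
  out <- list(d = d, s2 = s2, rss = rss)
  if (!is.null(coef_idx)) {
    XtXi <- chol2inv(qr.R(qrX))[seq_len(qrX$rank), seq_len(qrX$rank),
                                drop = FALSE]
    # map pivoted position of the requested coefficient
    pos <- match(coef_idx, qrX$pivot)
    out$coef <- beta[coef_idx, ]
    out$v_unscaled <- XtXi[pos, pos]
  }
  out
}

moderate_var <- function(s2, d, prior_df) {
  s2[!is.finite(s2)] <- 0
  if (prior_df <= 0) return(list(s2 = s2, df = d))
  s0 <- mean(s2)
  list(s2 = (prior_df * s0 + d * s2) / (prior_df + d), df = d + prior_df)
}

design_blocking <- function(meta, donor_blocking) {
  if (!donor_blocking || length(unique(meta$donor_id)) < 2)
    return(NULL)
  stats::model.matrix(~donor_id, data = meta)[, -1, drop = FALSE]
}

two_group_stats <- function(Y, grp, block, prior_df) {
  X <- cbind(`(Intercept)` = 1, grp = as.numeric(grp))
  if (!is.null(block)) X <- cbind(X, block)
  fit <- fit_genewise_lm(Y, X, coef_idx = 2L)
  mod <- moderate_var(fit$s2, fit$d, prior_df)
  se <- sqrt(mod$s2 * fit$v_unscaled)
  t <- ifelse(se > 0, fit$coef / se, 0)
  t[!is.finite(t)] <- 0
  p <- 2 * pt(-abs(t), df = mod$df)
  logFC <- fit$coef
  logFC[!is.finite(logFC)] <- 0
  list(t = t, logFC = logFC, p = p)
}

#' Enrichment model: one-vs-all domain contrasts
#'
#' For every spatial domain, fits (per gene) a linear model of pseudo-bulk
#' log2 CPM on an indicator of membership in that domain, optionally with
#' donor fixed-effect blocking columns, and reports the moderated
#' t-statistic, log2 fold-change (the indicator coefficient), p-value, and
#' Benjamini-Hochberg FDR across genes within each domain. These t-statistics
#' are the currency of spatial registration.
#'
#' @param pb a [pseudobulk()] result.
#' @param donor_blocking add donor as fixed covariate columns (default
#'   `TRUE`); identifiable because domains vary within donor.
#' @param prior_df prior degrees of freedom of the variance moderation;
#'   `0` gives the ordinary pooled-variance statistics.
#' @return an `EnrichmentStats` with genes x domains matrices `t`, `logFC`,
#'   `p`, `fdr`.
#' @export
enrichment_model <- function(pb, donor_blocking = TRUE, prior_df = 4) {
  meta <- pb$sample_meta
  Y <- pb$logexpr[, pb$gene_keep, drop = FALSE]
  block <- design_blocking(meta, donor_blocking)
  domains <- sort(unique(meta$domain_label))
  genes <- colnames(Y)
  mk <- function() matrix(NA_real_, length(genes), length(domains),
                          dimnames = list(genes, domains))
  t_m <- mk(); lfc <- mk(); p_m <- mk(); fdr <- mk()
  for (d in domains) {
    grp <- meta$domain_label == d
    if (length(unique(meta$section_id[grp])) < 2) {
      warning(sprintf("domain %s present in <2 sections; skipped", d))
      next
    }
    st <- two_group_stats(Y, grp, block, prior_df)
    t_m[, d] <- st$t; lfc[, d] <- st$logFC; p_m[, d] <- st$p
    fdr[, d] <- bh(st$p)
  }
  new_enrichment_stats("enrichment", genes, domains = domains,
                       t = t_m, logFC = lfc, p = p_m, fdr = fdr,
                       prior_df = prior_df, donor_blocking = donor_blocking)
}

anova_like <- function(pb, factor_col, donor_blocking, prior_df, model_tag) {
  meta <- pb$sample_meta
  Y <- pb$logexpr[, pb$gene_keep, drop = FALSE]
  block <- design_blocking(meta, donor_blocking)
  f <- factor(meta[[factor_col]])
  if (nlevels(f) < 2) stop_cm("factor '%s' has <2 levels", factor_col)
  X1 <- cbind(stats::model.matrix(~f), block)
  X0 <- cbind(matrix(1, nrow(Y), 1), block)
  fit1 <- fit_genewise_lm(Y, X1)
  fit0 <- fit_genewise_lm(Y, X0)
  q <- fit0$d - fit1$d # extra parameters of the full model
  mod <- moderate_var(fit1$s2, fit1$d, prior_df)
  Fstat <- ifelse(mod$s2 > 0, (fit0$rss - fit1$rss) / q / mod$s2, 0)
  Fstat[!is.finite(Fstat) | Fstat < 0] <- 0
  p <- pf(Fstat, q, mod$df, lower.tail = FALSE)
  p[Fstat == 0] <- 1
  tab <- data.frame(gene = colnames(Y), F = Fstat, p = p, fdr = bh(p),
                    stringsAsFactors = FALSE)
  new_enrichment_stats(model_tag, colnames(Y), table = tab,
                       prior_df = prior_df, donor_blocking = donor_blocking)
}

#' ANOVA model: any-difference-across-domains F test
#'
#' Per gene, moderated F-test of the spatial-domain factor against an
#' intercept-only model (both including donor blocking columns when
#' requested), with BH FDR across genes.
#'
#' @inheritParams enrichment_model
#' @return an `EnrichmentStats` with a per-gene table of `F`, `p`, `fdr`.
#' @export
anova_model <- function(pb, donor_blocking = TRUE, prior_df = 4) {
  anova_like(pb, "domain_label", donor_blocking, prior_df, "anova")
}

#' Position model: differential expression along the anterior-posterior axis
#'
#' Same machinery as [anova_model()] with the section position
#' (Ant/Mid/Post) as the factor instead of the spatial domain.
#'
#' @inheritParams enrichment_model
#' @return an `EnrichmentStats` with a per-gene table of `F`, `p`, `fdr`.
#' @export
position_de <- function(pb, donor_blocking = TRUE, prior_df = 4) {
  anova_like(pb, "position", donor_blocking, prior_df, "position")
}

#' Pairwise model: every unordered domain pair
#'
#' For each unordered pair (a, b) of domains, restricts to their pseudo-bulk
#' samples and fits the two-group contrast of [enrichment_model()]; the sign
#' convention is a minus b for the pair labeled `"a|b"` (domains in sorted
#' order), so t(a,b) = -t(b,a). BH FDR across genes within each pair.
#'
#' @inheritParams enrichment_model
#' @return an `EnrichmentStats` with genes x pairs matrices and a
#'   `pair_table` (`domain_a`, `domain_b`).
#' @export
pairwise_model <- function(pb, donor_blocking = TRUE, prior_df = 4) {
  meta <- pb$sample_meta
  Y <- pb$logexpr[, pb$gene_keep, drop = FALSE]
  domains <- sort(unique(meta$domain_label))
  pairs <- utils::combn(domains, 2)
  genes <- colnames(Y)
  cn <- paste(pairs[1, ], pairs[2, ], sep = "|")
  mk <- function() matrix(NA_real_, length(genes), ncol(pairs),
                          dimnames = list(genes, cn))
  t_m <- mk(); lfc <- mk(); p_m <- mk(); fdr <- mk()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    idx <- meta$domain_label %in% c(a, b)
    sub <- meta[idx, , drop = FALSE]
    block <- design_blocking(sub, donor_blocking)
    st <- two_group_stats(Y[idx, , drop = FALSE],
                          sub$domain_label == a, block, prior_df)
    t_m[, j] <- st$t; lfc[, j] <- st$logFC; p_m[, j] <- st$p
    fdr[, j] <- bh(st$p)
  }
  new_enrichment_stats("pairwise", genes,
                       pair_table = data.frame(domain_a = pairs[1, ],
                                               domain_b = pairs[2, ],
                                               stringsAsFactors = FALSE),
                       t = t_m, logFC = lfc, p = p_m, fdr = fdr,
                       prior_df = prior_df)
}
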