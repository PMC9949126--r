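#' Serialize pipeline result tables as TSV
#'
#' Writes enrichment statistics, registration results, benchmark metrics or
#' plain data.frames as tab-separated text with a header. Numeric values are
#' written with full double precision (15 significant digits), so a
#' write/read round trip is lossless to at least 12 significant digits;
#' missing values are written as `NA` and read back as missing.
#'
#' @param obj an `EnrichmentStats`, `RegistrationResult`, or data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(obj, path) UseMethod("write_tables")

write_tsv_ <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_cm("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @export
write_tables.data.frame <- function(obj, path) write_tsv_(obj, path)

#' @export
write_tables.EnrichmentStats <- function(obj, path) {
  write_tsv_(as.data.frame(obj), path)
}

#' @export
write_tables.RegistrationResult <- function(obj, path) {
  df <- data.frame(query = rownames(obj$cor), obj$cor, check.names = FALSE)
  write_tsv_(df, path)
}

#' Read enrichment statistics written by [write_tables()]
#'
#' @param path TSV path.
#' @return an `EnrichmentStats` object of the model recorded in the file.
#' @export
read_enrichment_stats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (all(c("domain_a", "domain_b") %in% names(df))) {
    pairs <- unique(df[, c("domain_a", "domain_b")])
    key <- paste(df$domain_a, df$domain_b, sep = "|")
    genes <- unique(df$gene)
    mk <- function(col) {
      m <- matrix(NA_real_, length(genes), nrow(pairs),
                  dimnames = list(genes, paste(pairs$domain_a, pairs$domain_b,
                                               sep = "|")))
      m[cbind(match(df$gene, genes), match(key, colnames(m)))] <- df[[col]]
      m
    }
    return(new_enrichment_stats("pairwise", genes,
                                t = mk("t"), logFC = mk("logFC"),
                                p = mk("p"), fdr = mk("fdr"),
                                pair_table = pairs))
  }
  if ("F" %in% names(df)) {
    model <- attr(df, "model") %||% "anova"
    return(new_enrichment_stats(model, df$gene, table = df))
  }
  genes <- unique(df$gene)
  domains <- unique(df$domain)
  mk <- function(col) {
    m <- matrix(NA_real_, length(genes), length(domains),
                dimnames = list(genes, domains))
    m[cbind(match(df$gene, genes), match(df$domain, domains))] <- df[[col]]
    m
  }
  new_enrichment_stats("enrichment", genes, t = mk("t"), logFC = mk("logFC"),
                       p = mk("p"), fdr = mk("fdr"))
}

#' Read a reference t-statistic matrix from TSV
#'
#' Accepts the gene-by-domain layout used to exchange enrichment statistics
#' with external studies (first column gene id, remaining columns one
#' reference domain each).
#'
#' @param path TSV path.
#' @return numeric matrix, genes x domains, rownames = gene ids.
#' @export
read_t_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a gene-by-domain t-statistic matrix as TSV
#'
#' @param stats an enrichment-model `EnrichmentStats` or a numeric matrix.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_t_matrix <- function(stats, path) {
  m <- t_matrix(stats)
  write_tsv_(data.frame(gene = rownames(m), m, check.names = FALSE), path)
}
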