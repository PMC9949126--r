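#' Spot-level expression container
#'
#' A `SpotMatrix` bundles a sparse spots-by-genes UMI count matrix with spot
#' coordinates and per-spot metadata (sample, donor, anterior/middle/posterior
#' position, spatial-domain label, optional manual layer annotation, and a QC
#' flag). It is the unit the whole pipeline consumes: one object per tissue
#' section, or a list of them for a study.
#'
#' @param counts integer matrix or `Matrix::dgCMatrix`, spots x genes,
#'   non-negative UMI counts.
#' @param coords numeric matrix with one row per spot and columns `x`, `y`.
#'   Coordinates are full-resolution 2D reals; no lattice topology is assumed
#'   anywhere downstream, only Euclidean distances are used.
#' @param meta data.frame with one row per spot. Recognised columns:
#'   `sample_id`, `donor_id`, `position` (one of `"Ant"`, `"Mid"`, `"Post"`),
#'   `domain_label`, `manual_layer` (optional, `L1`..`L6`/`WM`), `qc_pass`
#'   (initialised `TRUE` when absent).
#' @param gene_ids,spot_ids character vectors; default to the dimnames of
#'   `counts`.
#'
#' @return An object of class `SpotMatrix`.
#' @export
spot_matrix <- function(counts, coords, meta,
                        gene_ids = colnames(counts),
                        spot_ids = rownames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop_cm("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop_cm("counts must be integers")
  n <- nrow(counts)
  if (is.null(spot_ids)) spot_ids <- sprintf("spot%04d", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(ncol(counts)))
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y")
  if (nrow(coords) != n || nrow(meta) != n)
    stop_cm("dimension mismatch: counts has %d spots, coords %d, meta %d",
            n, nrow(coords), nrow(meta))
  if (length(gene_ids) != ncol(counts))
    stop_cm("gene_ids length %d != %d genes", length(gene_ids), ncol(counts))
  if (anyDuplicated(spot_ids))
    stop_cm("duplicate spot barcodes: %s",
            paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (is.null(meta$qc_pass)) meta$qc_pass <- TRUE
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- spot_ids
  dimnames(counts) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  structure(
    list(counts = counts, gene_ids = gene_ids, spot_ids = spot_ids,
         coords = coords, meta = meta),
    class = "SpotMatrix"
  )
}

#' @export
print.SpotMatrix <- function(x, ...) {
  cat(sprintf("SpotMatrix: %d spots x %d genes (%d QC-pass)\n",
              nrow(x$counts), ncol(x$counts), sum(x$meta$qc_pass)))
  cat(sprintf("  samples: %s\n",
              paste(unique(x$meta$sample_id), collapse = ", ")))
  invisible(x)
}

#' @export
dim.SpotMatrix <- function(x) dim(x$counts)

#' Subset a SpotMatrix by spots
#'
#' @param sm a `SpotMatrix`.
#' @param idx logical or integer spot index.
#' @return a `SpotMatrix` restricted to the selected spots.
#' @export
subset_spots <- function(sm, idx) {
  spot_matrix(sm$counts[idx, , drop = FALSE], sm$coords[idx, , drop = FALSE],
              sm$meta[idx, , drop = FALSE], gene_ids = sm$gene_ids,
              spot_ids = sm$spot_ids[idx])
}

#' Spot library sizes
#' @param sm a `SpotMatrix`.
#' @return numeric vector of per-spot total UMI counts.
#' @export
spot_totals <- function(sm) Matrix::rowSums(sm$counts)

# I/O -----------------------------------------------------------------------

#' Read a spot matrix from MatrixMarket + companion tables
#'
#' Reads the 10x-style on-disk layout: a MatrixMarket coordinate file with
#' genes as rows and spots as columns, a features TSV (gene ids, no header), a
#' barcodes TSV (spot ids, no header), a positions CSV (`barcode,x,y`), and a
#' metadata CSV (`barcode,sample_id,donor_id,position,domain_label` and
#' optionally `manual_layer`). In memory the orientation is spots x genes.
#'
#' @param mtx_path,features_path,barcodes_path,positions_path,meta_path file
#'   paths as described above.
#' @return a [spot_matrix()] with `qc_pass` initialised to `TRUE`.
#' @export
read_spot_matrix <- function(mtx_path, features_path, barcodes_path,
                             positions_path, meta_path) {
  m <- Matrix::readMM(mtx_path)           # genes x spots on disk
  features <- read.delim(features_path, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (length(features) != nrow(m))
    stop_cm("format error in %s: %d features but matrix has %d rows",
            features_path, length(features), nrow(m))
  if (length(barcodes) != ncol(m))
    stop_cm("format error in %s: %d barcodes but matrix has %d columns",
            barcodes_path, length(barcodes), ncol(m))
  if (anyDuplicated(barcodes))
    stop_cm("duplicate barcodes in %s", barcodes_path)
  pos <- read.csv(positions_path, stringsAsFactors = FALSE)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  if (nrow(pos) != length(barcodes))
    stop_cm("format error in %s: %d rows but %d barcodes",
            positions_path, nrow(pos), length(barcodes))
  if (nrow(meta) != length(barcodes))
    stop_cm("format error in %s: %d rows but %d barcodes",
            meta_path, nrow(meta), length(barcodes))
  pos <- pos[match(barcodes, pos$barcode), ]
  meta <- meta[match(barcodes, meta$barcode), ]
  if (anyNA(pos$barcode) || anyNA(meta$barcode))
    stop_cm("positions/meta barcodes do not match the barcodes file")
  meta$barcode <- NULL
  if (!is.null(meta$manual_layer))
    meta$manual_layer[meta$manual_layer == ""] <- NA
  meta$qc_pass <- TRUE
  spot_matrix(Matrix::t(m), cbind(x = pos$x, y = pos$y), meta,
              gene_ids = features, spot_ids = barcodes)
}

#' Write a spot matrix as MatrixMarket + companion tables
#'
#' Inverse of [read_spot_matrix()]; writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, `positions.csv`, `meta.csv` into `dir`.
#'
#' @param sm a `SpotMatrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_matrix <- function(sm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(sm$counts), file.path(dir, "matrix.mtx"))
  writeLines(sm$gene_ids, file.path(dir, "features.tsv"))
  writeLines(sm$spot_ids, file.path(dir, "barcodes.tsv"))
  write.csv(data.frame(barcode = sm$spot_ids, x = sm$coords[, "x"],
                       y = sm$coords[, "y"]),
            file.path(dir, "positions.csv"), row.names = FALSE)
  meta <- sm$meta
  meta$qc_pass <- NULL
  write.csv(cbind(barcode = sm$spot_ids, meta),
            file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

# QC ------------------------------------------------------------------------

#' Flag low-library-size spots
#'
#' Spots whose total UMI count falls below `min_umi` are flagged
#' `qc_pass = FALSE` and excluded from all downstream views. The attached
#' `qc_summary` reports excluded/retained counts and the excluded percentage,
#' computed as excluded / (excluded + retained) x 100.
#'
#' @param sm a `SpotMatrix`.
#' @param min_umi non-negative integer library-size threshold. No threshold is
#'   hard-coded; studies choose it per dataset.
#' @return a `SpotMatrix` with updated `qc_pass` and a `qc_summary` element
#'   (`excluded`, `retained`, `pct_excluded`).
#' @export
filter_spots <- function(sm, min_umi) {
  stopifnot(min_umi >= 0)
  pass <- spot_totals(sm) >= min_umi
  if (!any(pass)) stop_cm("empty section after QC (min_umi = %s)", min_umi)
  sm$meta$qc_pass <- pass
  sm$qc_summary <- list(
    excluded = sum(!pass), retained = sum(pass),
    pct_excluded = qc_excluded_pct(sum(!pass), sum(pass)))
  sm
}

#' Percentage of spots excluded by QC
#'
#' @param excluded,retained spot counts.
#' @return excluded / (excluded + retained) x 100.
#' @export
#' @examples
#' qc_excluded_pct(4866, 113927) # 4.1% of all measured spots
qc_excluded_pct <- function(excluded, retained) {
  excluded / (excluded + retained) * 100
}

#' Restrict to QC-passing spots
#' @param sm a `SpotMatrix`.
#' @return a `SpotMatrix` containing only `qc_pass` spots.
#' @export
qc_view <- function(sm) subset_spots(sm, sm$meta$qc_pass)
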