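#' Single-nucleus expression profiles
#'
#' Cells-by-genes UMI counts with a per-cell type label (broad or
#' layer-resolution, e.g. `"Excit_L5"`) and donor id. Used for cell-type
#' specificity scores and co-expression percentages.
#'
#' @param counts integer matrix, cells x genes, non-negative.
#' @param cell_type character vector, one label per cell.
#' @param donor_id character vector, one donor per cell.
#' @param gene_ids gene identifiers; default `colnames(counts)`.
#' @return an object of class `CellProfileSet`.
#' @export
cell_profile_set <- function(counts, cell_type, donor_id = NULL,
                             gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_cm("counts must be non-negative integers")
  if (length(cell_type) != nrow(counts))
    stop_cm("one cell_type label per cell required")
  if (anyNA(cell_type)) stop_cm("every cell must be labeled")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(ncol(counts)))
  colnames(counts) <- gene_ids
  structure(list(counts = counts, cell_type = as.character(cell_type),
                 donor_id = donor_id, gene_ids = gene_ids),
            class = "CellProfileSet")
}

#' @export
print.CellProfileSet <- function(x, ...) {
  cat(sprintf("CellProfileSet: %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_type))))
  invisible(x)
}

#' Spot-deconvolution predictions
#'
#' Non-negative spots-by-cell-types matrix of predicted cell counts, as
#' emitted by an external deconvolution tool (or the synthetic stand-in).
#'
#' @param values non-negative numeric matrix, spots x cell types.
#' @param method_name name of the producing method.
#' @param resolution `"broad"` or `"layer"`.
#' @param spot_ids,cell_types dimension names; default from `values`.
#' @return an object of class `PredictionMatrix`.
#' @export
prediction_matrix <- function(values, method_name = "unknown",
                              resolution = c("layer", "broad"),
                              spot_ids = rownames(values),
                              cell_types = colnames(values)) {
  resolution <- match.arg(resolution)
  values <- as.matrix(values)
  if (any(values < 0)) stop_cm("predicted values must be >= 0")
  if (is.null(spot_ids)) spot_ids <- sprintf("spot%04d", seq_len(nrow(values)))
  dimnames(values) <- list(spot_ids, cell_types)
  structure(list(values = values, method_name = method_name,
                 resolution = resolution, spot_ids = spot_ids,
                 cell_types = cell_types),
            class = "PredictionMatrix")
}

#' @export
print.PredictionMatrix <- function(x, ...) {
  cat(sprintf("PredictionMatrix [%s, %s]: %d spots x %d cell types\n",
              x$method_name, x$resolution, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-nucleus immunofluorescence intensities
#'
#' One row per nucleus: position and the 4 marker-channel intensities
#' (NeuN marking neurons, OLIG2 oligodendrocytes, GFAP astrocytes, TMEM119
#' microglia), optionally with a known class label.
#'
#' @param x,y numeric positions (same units as spot coordinates).
#' @param intensity numeric matrix, nuclei x 4, non-negative, columns
#'   `NeuN`, `OLIG2`, `GFAP`, `TMEM119`.
#' @param true_class optional factor/character in
#'   `{neuron, oligo, astro, micro, other}`.
#' @return a data.frame of class `NucleusTable`.
#' @export
nucleus_table <- function(x, y, intensity, true_class = NULL) {
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != 4) stop_cm("intensity must have 4 channels")
  if (any(intensity < 0)) stop_cm("intensities must be >= 0")
  colnames(intensity) <- c("NeuN", "OLIG2", "GFAP", "TMEM119")
  nt <- data.frame(x = x, y = y, intensity,
                   stringsAsFactors = FALSE)
  if (!is.null(true_class)) nt$true_class <- as.character(true_class)
  class(nt) <- c("NucleusTable", "data.frame")
  nt
}

intensity_channels <- c("NeuN", "OLIG2", "GFAP", "TMEM119")

#' A named gene set
#'
#' @param name set name (e.g. a clinical DE contrast).
#' @param genes character vector of gene identifiers, non-empty after
#'   deduplication.
#' @return an object of class `GeneSet`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop_cm("gene set '%s' is empty", name)
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a two-column TSV
#'
#' Expects columns `set_name` and `gene_id` (with header).
#'
#' @param path TSV file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  sets <- split(tab$gene_id, tab$set_name)
  lapply(setNames(names(sets), names(sets)),
         function(nm) gene_set(nm, sets[[nm]]))
}
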