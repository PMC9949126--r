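# Small fixtures built in code.

# a hand-sized section: n spots on a line, given count matrix
tiny_section <- function(counts, domain = rep("D1", nrow(counts)),
                         sample_id = "S1", donor_id = "Br01",
                         layer = NULL, coords = NULL) {
  n <- nrow(counts)
  if (is.null(coords)) coords <- cbind(x = seq_len(n) / n, y = 0.5)
  meta <- data.frame(sample_id = sample_id, donor_id = donor_id,
                     position = "Ant", domain_label = domain,
                     qc_pass = TRUE, stringsAsFactors = FALSE)
  if (!is.null(layer)) meta$manual_layer <- layer
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("%s_s%02d", sample_id, seq_len(n))
  spot_matrix(counts, coords, meta)
}

# cells with exact per-cell totals so CPM means are controllable
tiny_cells <- function(counts_list, types) {
  counts <- do.call(rbind, counts_list)
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  cell_profile_set(counts, types)
}

# a small simulated study shared by several tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_sections(
        sim_config(n_sections = 4, n_donors = 2, n_genes = 600,
                   n_spots_per_section = 180), seed = 42)
    cache
  }
})
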