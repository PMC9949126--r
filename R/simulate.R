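# Synthetic layered-cortex generator.
#
# Emulates what the pipeline needs from a Visium-style study of laminar
# tissue: horizontal layer bands with layer-restricted marker genes, donor
# random intercepts shared across genes (so they act like library-size
# factors and make donor blocking consequential), lognormal spot library
# sizes, negative-binomial UMI counts, laminar cell-type compositions per
# spot, noisy deconvolution predictions, and separable immunofluorescence
# intensity classes. Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults describe a desk-scale study in the image of a multi-donor,
#' multi-section laminar design: 6 sections from 3 donors (anterior, middle
#' and posterior positions), 2000 genes of which 20 per layer are markers
#' over-expressed 2^2 = 4-fold in their layer, 7 layers (L1-L6 plus white
#' matter) as horizontal depth bands, one ground-truth spatial domain per
#' layer. Bands default to equal thickness so pseudo-bulk groups carry
#' comparable spot counts (and hence comparable variances, as the
#' equal-variance contrast models assume).
#'
#' @param n_sections,n_donors,n_genes,n_spots_per_section study dimensions.
#' @param layers named numeric vector of layer depth fractions (must sum
#'   to 1), ordered from the pial surface downward.
#' @param domain_to_layer named character vector mapping ground-truth domain
#'   labels to layer names; default one domain per layer (`D1` -> `L1`, ...).
#' @param n_markers_per_layer markers per layer.
#' @param effect_size log2 fold-change of a marker in its own layer.
#' @param donor_sd SD of the gene-shared donor lognormal intercept (log
#'   scale).
#' @param libsize_sdlog SD (log scale) of per-spot library-size factors.
#' @param mean_umi_per_spot expected total UMI of an average spot.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param cells_per_spot mean cells per spot (truncated Poisson, >= 1).
#' @param n_cells_per_type cells per type emitted by [simulate_cells()].
#' @param cell_mean_umi expected total UMI per cell in [simulate_cells()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sections = 6, n_donors = 3, n_genes = 2000,
                       n_spots_per_section = 240,
                       layers = setNames(rep(1 / 7, 7),
                                         c(paste0("L", 1:6), "WM")),
                       domain_to_layer = NULL,
                       n_markers_per_layer = 20,
                       effect_size = 2,
                       donor_sd = 0.2,
                       libsize_sdlog = 0.3,
                       mean_umi_per_spot = 1000,
                       nb_dispersion = 0.25,
                       cells_per_spot = 3,
                       n_cells_per_type = 50,
                       cell_mean_umi = 800) {
  if (abs(sum(layers) - 1) > 1e-8) stop_cm("layer depth fractions must sum to 1")
  if (effect_size < 0) stop_cm("effect_size must be >= 0")
  if (is.null(domain_to_layer))
    domain_to_layer <- setNames(names(layers),
                                paste0("D", seq_along(layers)))
  if (n_markers_per_layer * length(layers) > n_genes)
    stop_cm("config error: %d markers x %d layers exceeds %d genes",
            n_markers_per_layer, length(layers), n_genes)
  structure(as.list(environment()), class = "sim_config")
}

# cell types used throughout: layer-resolved excitatory neurons plus glia.
# Glia inherit the marker structure of their home layer (Astro -> L1,
# Oligo/OPC -> WM); Inhib and Micro are non-laminar.
sim_cell_types <- function(cfg) {
  gm <- setdiff(names(cfg$layers), "WM")
  types <- c(paste0("Excit_", gm), "Inhib", "Astro", "Oligo", "OPC", "Micro")
  home <- c(setNames(gm, paste0("Excit_", gm)),
            Inhib = NA, Astro = "L1", Oligo = "WM", OPC = "WM", Micro = NA)
  list(types = types, home = home[types])
}

# per-layer cell-type composition probabilities (rows = layers)
sim_composition_probs <- function(cfg) {
  ct <- sim_cell_types(cfg)
  probs <- matrix(0, length(cfg$layers), length(ct$types),
                  dimnames = list(names(cfg$layers), ct$types))
  for (ly in names(cfg$layers)) {
    p <- setNames(numeric(length(ct$types)), ct$types)
    if (ly == "WM") {
      p[c("Oligo", "OPC", "Astro", "Micro", "Inhib")] <-
        c(0.60, 0.12, 0.05, 0.05, 0.03)
      p[paste0("Excit_", "L6")] <- 0.15
    } else {
      p[paste0("Excit_", ly)] <- 0.55
      p["Inhib"] <- 0.15
      p["Astro"] <- if (ly == "L1") 0.18 else 0.04
      p["Oligo"] <- 0.04
      p["OPC"] <- 0.02
      p["Micro"] <- 0.05
      p <- p / sum(p)
    }
    probs[ly, ] <- p / sum(p)
  }
  probs
}

sim_marker_assignment <- function(cfg) {
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  assignment <- setNames(rep(NA_character_, cfg$n_genes), genes)
  k <- cfg$n_markers_per_layer
  for (i in seq_along(cfg$layers))
    assignment[seq((i - 1) * k + 1, i * k)] <- names(cfg$layers)[i]
  assignment
}

#' Simulate layered spatial sections with known ground truth
#'
#' Spots sit on a jittered grid in the unit square; the layer of a spot is
#' set by which depth band its y-coordinate falls in, and its domain label
#' is the ground-truth domain of that layer. Gene means follow
#' `mu = baseline * 2^(effect_size * is_marker_of_own_layer) * donor_factor
#' * libsize_factor` and counts are negative binomial. Also draws a true
#' cell-type composition per spot (multinomial over the layer's composition)
#' used by the deconvolution benchmark.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the generator is deterministic given
#'   (config, seed).
#' @return a list with `sections` (list of [spot_matrix()]) and
#'   `truth` (class `GroundTruth`): `marker_assignment` (gene -> layer or
#'   NA), `domain_to_layer`, `cell_type_layer`, `true_spot_composition`
#'   (per-section spots x cell-types count matrices),
#'   `nuclei_class_means`, and the per-gene `baseline` used.
#' @export
simulate_sections <- function(cfg, seed = 1) {
  set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  marker <- sim_marker_assignment(cfg)
  layer_names <- names(cfg$layers)
  layer_of_domain <- cfg$domain_to_layer
  domain_of_layer <- setNames(names(layer_of_domain), layer_of_domain)
  breaks <- cumsum(c(0, cfg$layers))
  # gene relative abundances (shared across sections)
  w <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  baseline <- cfg$mean_umi_per_spot * w / sum(w)
  donor_factor <- setNames(exp(rnorm(cfg$n_donors, 0, cfg$donor_sd)),
                           sprintf("Br%02d", seq_len(cfg$n_donors)))
  ct <- sim_cell_types(cfg)
  comp_probs <- sim_composition_probs(cfg)
  positions <- c("Ant", "Mid", "Post")
  sections <- vector("list", cfg$n_sections)
  compositions <- vector("list", cfg$n_sections)
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  for (s in seq_len(cfg$n_sections)) {
    donor <- names(donor_factor)[(s - 1) %% cfg$n_donors + 1]
    pos <- positions[((s - 1) %/% cfg$n_donors) %% 3 + 1]
    n <- cfg$n_spots_per_section
    nx <- ceiling(sqrt(n))
    gx <- ((seq_len(n) - 1) %% nx + 0.5) / nx
    gy <- ((seq_len(n) - 1) %/% nx + 0.5) / ceiling(n / nx)
    xy <- cbind(x = gx + runif(n, -0.3, 0.3) / nx,
                y = pmin(pmax(gy + runif(n, -0.3, 0.3) / nx, 0), 1 - 1e-9))
    layer <- layer_names[findInterval(xy[, "y"], breaks,
                                      rightmost.closed = TRUE)]
    libsize <- rlnorm(n, 0, cfg$libsize_sdlog)
    is_marker <- outer(layer, marker, `==`) # spots x genes
    is_marker[is.na(is_marker)] <- FALSE
    mu <- (libsize * donor_factor[donor]) *
      (rep(1, n) %o% baseline) * 2^(cfg$effect_size * is_marker)
    counts <- if (is.finite(size)) {
      matrix(rnbinom(n * cfg$n_genes, size = size, mu = mu), n, cfg$n_genes)
    } else {
      matrix(rpois(n * cfg$n_genes, lambda = mu), n, cfg$n_genes)
    }
    sample_id <- sprintf("%s_%s", donor, tolower(pos))
    meta <- data.frame(sample_id = sample_id, donor_id = donor,
                       position = pos,
                       domain_label = unname(domain_of_layer[layer]),
                       manual_layer = layer, qc_pass = TRUE,
                       stringsAsFactors = FALSE)
    spot_ids <- sprintf("%s_s%03d", sample_id, seq_len(n))
    dimnames(counts) <- list(spot_ids, genes)
    sections[[s]] <- spot_matrix(counts, xy, meta, gene_ids = genes,
                                 spot_ids = spot_ids)
    # true cell-type composition per spot
    ncell <- pmax(1, rpois(n, cfg$cells_per_spot))
    comp <- t(vapply(seq_len(n), function(i)
      rmultinom(1, ncell[i], comp_probs[layer[i], ])[, 1],
      numeric(length(ct$types))))
    dimnames(comp) <- list(spot_ids, ct$types)
    compositions[[s]] <- comp
  }
  names(sections) <- names(compositions) <-
    vapply(sections, function(s) s$meta$sample_id[1], "")
  truth <- structure(list(
    marker_assignment = marker,
    domain_to_layer = layer_of_domain,
    cell_type_layer = ct$home,
    true_spot_composition = compositions,
    nuclei_class_means = nuclei_class_means(),
    baseline = setNames(baseline, genes),
    config = cfg, seed = seed), class = "GroundTruth")
  list(sections = sections, truth = truth)
}

#' Simulate single-nucleus profiles sharing the layer-marker structure
#'
#' Each cell type over-expresses the markers of its home layer by the
#' configured effect size (`Excit_Lx` the layer-x markers, `Astro` the L1
#' markers, `Oligo`/`OPC` the WM markers); `Inhib` and `Micro` are
#' non-laminar and stay at baseline.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param proportions optional named vector of cell-type proportions; by
#'   default every type gets `cfg$n_cells_per_type` cells. Types with
#'   proportion 0 emit no cells.
#' @return list with `cells` (a [cell_profile_set()]) and `truth`
#'   (marker assignment and cell-type home layers).
#' @export
simulate_cells <- function(cfg, seed = 1, proportions = NULL) {
  set.seed(seed + 1L)
  ct <- sim_cell_types(cfg)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  marker <- sim_marker_assignment(cfg)
  w <- rlnorm(cfg$n_genes, 0, 1)
  baseline <- cfg$cell_mean_umi * w / sum(w)
  if (is.null(proportions)) {
    n_cells <- setNames(rep(cfg$n_cells_per_type, length(ct$types)), ct$types)
  } else {
    total <- cfg$n_cells_per_type * length(ct$types)
    p <- setNames(rep(0, length(ct$types)), ct$types)
    p[intersect(names(proportions), ct$types)] <-
      proportions[intersect(names(proportions), ct$types)]
    n_cells <- round(total * p / sum(p))
  }
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  rows <- list(); labels <- character(0)
  for (ty in ct$types) {
    if (n_cells[ty] == 0) next
    home <- ct$home[ty]
    fold <- rep(1, cfg$n_genes)
    if (!is.na(home)) fold[!is.na(marker) & marker == home] <-
        2^cfg$effect_size
    lib <- rlnorm(n_cells[ty], 0, cfg$libsize_sdlog)
    mu <- lib %o% (baseline * fold)
    cnt <- if (is.finite(size)) {
      matrix(rnbinom(length(mu), size = size, mu = mu), nrow(mu), ncol(mu))
    } else matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
    rows[[ty]] <- cnt
    labels <- c(labels, rep(ty, n_cells[ty]))
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- genes
  rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  cells <- cell_profile_set(counts, labels,
                            donor_id = rep("Br01", nrow(counts)),
                            gene_ids = genes)
  list(cells = cells,
       truth = list(marker_assignment = marker, cell_type_layer = ct$home))
}

#' Noisy deconvolution predictions from a known composition
#'
#' Multiplies the true spot x cell-type counts by i.i.d. multiplicative
#' lognormal noise `exp(N(0, noise_sd^2))` (so `noise_sd = 0` returns the
#' truth exactly); values are never negative by construction.
#'
#' @param truth a `GroundTruth` from [simulate_sections()], or a single
#'   spots x cell-types matrix.
#' @param noise_sd log-scale noise SD.
#' @param seed integer seed.
#' @param method_name label stored in the result.
#' @return a list of [prediction_matrix()] (one per section), or a single
#'   one when `truth` is a matrix.
#' @export
simulate_predictions <- function(truth, noise_sd = 0.3, seed = 1,
                                 method_name = "synthetic") {
  set.seed(seed + 2L)
  noisy <- function(m) {
    v <- m * exp(matrix(rnorm(length(m), 0, noise_sd), nrow(m), ncol(m)))
    prediction_matrix(v, method_name = method_name, resolution = "layer")
  }
  if (is.matrix(truth)) return(noisy(truth))
  lapply(truth$true_spot_composition, noisy)
}

nuclei_class_means <- function(base = 50, separation = 4) {
  classes <- c("neuron", "oligo", "astro", "micro", "other")
  m <- matrix(base, length(classes), 4,
              dimnames = list(classes, intensity_channels))
  m["neuron", "NeuN"] <- base * (1 + separation)
  m["oligo", "OLIG2"] <- base * (1 + separation)
  m["astro", "GFAP"] <- base * (1 + separation)
  m["micro", "TMEM119"] <- base * (1 + separation)
  m
}

#' Simulate immunofluorescence nuclei with class-specific intensities
#'
#' Draws nuclei of the five broad classes (neuron/oligo/astro/micro/other)
#' with lognormal channel intensities; each class's marker channel mean is
#' lifted by the `separation` factor, so large separation makes the classes
#' linearly separable and `separation = 0` collapses them onto a single
#' distribution.
#'
#' @param n number of nuclei.
#' @param separation between-class mean distance scale (0 = none).
#' @param seed integer seed.
#' @param proportions named class proportions (default
#'   neuron .40, oligo .25, astro .15, micro .10, other .10).
#' @param sdlog within-class lognormal SD.
#' @return a [nucleus_table()] with `true_class` filled in; positions
#'   uniform on the unit square.
#' @export
simulate_nuclei <- function(n = 500, separation = 4, seed = 1,
                            proportions = c(neuron = 0.40, oligo = 0.25,
                                            astro = 0.15, micro = 0.10,
                                            other = 0.10),
                            sdlog = 0.25) {
  set.seed(seed + 3L)
  means <- nuclei_class_means(separation = separation)
  cls <- rep(names(proportions), diff(round(cumsum(
    c(0, proportions / sum(proportions)) * n))))
  cls <- c(cls, rep(names(proportions)[1], n - length(cls)))
  intensity <- t(vapply(cls, function(k)
    rlnorm(4, meanlog = log(means[k, ]), sdlog = sdlog), numeric(4)))
  nucleus_table(x = runif(n), y = runif(n), intensity = intensity,
                true_class = cls)
}
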