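# Benchmarking spot-deconvolution outputs against an image-derived gold
# standard: CART classification of immunolabeled nuclei, assignment of
# nuclei to spots, a layer-localization tally, Pearson/RMSE scoring of
# predicted vs gold counts, and broad-vs-fine resolution consistency.

#' Fit a CART nucleus classifier
#'
#' A binary decision tree (Gini impurity splits, via `rpart`) on the four
#' fluorescence-intensity channels, predicting the broad nucleus class.
#' Deterministic given the input order; depth and leaf size default to
#' values suited to 4 features and 4-5 classes.
#'
#' @param nt a [nucleus_table()] with `true_class` filled for the training
#'   subset (rows with `NA` class are ignored).
#' @param max_depth maximum tree depth (default 4).
#' @param min_leaf minimum observations per leaf (default 5).
#' @return an object of class `cart_classifier` wrapping the fitted tree.
#' @export
fit_cart <- function(nt, max_depth = 4, min_leaf = 5) {
  train <- nt[!is.na(nt$true_class), , drop = FALSE]
  if (length(unique(train$true_class)) < 2)
    stop_cm("CART training needs >= 2 classes")
  fit <- rpart::rpart(
    factor(true_class) ~ NeuN + OLIG2 + GFAP + TMEM119,
    data = train, method = "class",
    control = rpart::rpart.control(maxdepth = max_depth,
                                   minbucket = min_leaf,
                                   minsplit = 2 * min_leaf,
                                   cp = 0, xval = 0))
  structure(list(fit = fit, max_depth = max_depth, min_leaf = min_leaf),
            class = "cart_classifier")
}

#' @export
print.cart_classifier <- function(x, ...) {
  cat("CART nucleus classifier:\n")
  print(x$fit)
  invisible(x)
}

#' Classify nuclei with a fitted CART
#'
#' @param classifier a [fit_cart()] result.
#' @param nt a [nucleus_table()].
#' @return `nt` with a `pred_class` column appended.
#' @export
classify_nuclei <- function(classifier, nt) {
  nt$pred_class <- as.character(predict(classifier$fit, newdata = nt,
                                        type = "class"))
  nt
}

#' Aggregate classified nuclei into gold-standard spot counts
#'
#' Each nucleus is assigned to the nearest spot center within `spot_radius`
#' (Euclidean distance; exact ties go to the lowest spot index); nuclei
#' outside every spot are dropped and their number reported in the
#' `n_dropped` attribute.
#'
#' @param nt a [nucleus_table()]; uses `pred_class` if present, else
#'   `true_class`.
#' @param sm a `SpotMatrix` supplying spot centers.
#' @param spot_radius radius in the same units as the coordinates.
#' @return a [prediction_matrix()] (`method_name = "gold"`) of per-spot
#'   class counts, with attribute `n_dropped`.
#' @export
nuclei_to_spot_counts <- function(nt, sm, spot_radius) {
  cls <- nt$pred_class %||% nt$true_class
  if (is.null(cls)) stop_cm("nuclei carry neither pred_class nor true_class")
  classes <- sort(unique(cls))
  counts <- matrix(0, nrow(sm$counts), length(classes),
                   dimnames = list(sm$spot_ids, classes))
  dx <- outer(nt$x, sm$coords[, "x"], `-`)
  dy <- outer(nt$y, sm$coords[, "y"], `-`)
  dist2 <- dx^2 + dy^2
  nearest <- max.col(-dist2, ties.method = "first")
  within <- dist2[cbind(seq_len(nrow(nt)), nearest)] <= spot_radius^2
  for (i in which(within))
    counts[nearest[i], cls[i]] <- counts[nearest[i], cls[i]] + 1
  out <- prediction_matrix(counts, method_name = "gold",
                           resolution = "broad")
  attr(out, "n_dropped") <- sum(!within)
  out
}

# default map from layer-resolution cell types to the four immunolabeled
# broad classes; types mapping to NA are dropped from metric comparisons.
#' Collapse layer-resolution predictions onto broad classes
#'
#' Sums predicted counts of cell types mapping to the same broad class
#' (default: `Excit_*` and `Inhib` to neuron, `Oligo` — and `OPC` when
#' `include_opc` — to oligo, `Astro` to astro, `Micro` to micro; anything
#' else dropped).
#'
#' @param preds a [prediction_matrix()].
#' @param map optional named character vector cell type -> class overriding
#'   the default.
#' @param include_opc count OPC as oligo (default `FALSE`).
#' @return a [prediction_matrix()] at broad resolution.
#' @export
collapse_predictions <- function(preds, map = NULL, include_opc = FALSE) {
  if (is.null(map)) {
    types <- preds$cell_types
    map <- setNames(rep(NA_character_, length(types)), types)
    map[grepl("^Excit", types) | grepl("^Inhib", types)] <- "neuron"
    map[types == "Oligo"] <- "oligo"
    if (include_opc) map[types == "OPC"] <- "oligo"
    map[types == "Astro"] <- "astro"
    map[types == "Micro"] <- "micro"
  }
  keep <- !is.na(map[preds$cell_types])
  grp <- map[preds$cell_types][keep]
  v <- preds$values[, keep, drop = FALSE]
  out <- t(rowsum(t(v), grp))
  prediction_matrix(out, method_name = preds$method_name,
                    resolution = "broad")
}

#' Layer-localization tally ("O/X" score)
#'
#' For every cell type: mean predicted count over the spots of each
#' manually annotated layer, per section; averaged across sections; the
#' layer profile is row-normalized to proportions and the argmax layer
#' taken. The type is a match ("O") iff the argmax layer is among its
#' expected layers; a strict tie for the maximum is no match. Types whose
#' expectation is `"any"` carry no laminar expectation and always count as
#' matches. The score is matches / number of tallied cell types.
#'
#' @param preds a [prediction_matrix()] or list of them (one per section).
#' @param sections matching `SpotMatrix` (or list) carrying `manual_layer`.
#' @param expected_map named list or character vector cell type ->
#'   expected layer(s); the value `"any"` matches every layer. Default:
#'   `Excit_Lx` -> Lx, `Astro` -> L1, `Oligo`/`OPC` -> WM,
#'   `Inhib`/`Micro` -> any.
#' @return list of class `LayerTally`: `per_type` data.frame
#'   (`cell_type`, `argmax_layer`, `tie`, `match`), `score`, and a
#'   `"m of n"` `label`.
#' @export
layer_localization_tally <- function(preds, sections, expected_map = NULL) {
  if (is(preds, "PredictionMatrix")) preds <- list(preds)
  if (is(sections, "SpotMatrix")) sections <- list(sections)
  stopifnot(length(preds) == length(sections))
  types <- preds[[1]]$cell_types
  if (is.null(expected_map)) {
    expected_map <- lapply(setNames(types, types), function(ty) {
      if (grepl("^Excit_", ty)) sub("^Excit_", "", ty)
      else if (ty == "Astro") "L1"
      else if (ty %in% c("Oligo", "OPC")) "WM"
      else "any"
    })
  }
  # mean predicted count per (layer, type), per section, then averaged
  per_section <- lapply(seq_along(preds), function(i) {
    sv <- qc_view(sections[[i]])
    pv <- preds[[i]]$values[match(sv$spot_ids, rownames(preds[[i]]$values)),
                            , drop = FALSE]
    lay <- sv$meta$manual_layer
    ok <- !is.na(lay)
    rowsum(pv[ok, , drop = FALSE], lay[ok]) /
      as.vector(table(lay[ok])[sort(unique(lay[ok]))])
  })
  layers <- sort(unique(unlist(lapply(per_section, rownames))))
  acc <- matrix(0, length(layers), length(types),
                dimnames = list(layers, types))
  cnt <- acc
  for (m in per_section) {
    acc[rownames(m), ] <- acc[rownames(m), ] + m
    cnt[rownames(m), ] <- cnt[rownames(m), ] + 1
  }
  avg <- acc / pmax(cnt, 1)
  rows <- lapply(types, function(ty) {
    prof <- avg[, ty]
    tot <- sum(prof)
    prop <- if (tot > 0) prof / tot else prof
    mx <- max(prop)
    tie <- sum(prop == mx) > 1
    arg <- if (tie) NA_character_ else layers[which.max(prop)]
    exp_l <- expected_map[[ty]]
    # types expected anywhere have no laminar expectation to violate; the
    # strict-tie-is-no-match rule applies to laminar expectations only
    match_ <- if (identical(exp_l, "any")) TRUE else !tie && arg %in% exp_l
    data.frame(cell_type = ty, argmax_layer = arg, tie = tie,
               match = match_, stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, rows)
  structure(list(per_type = per_type,
                 score = mean(per_type$match),
                 label = sprintf("%d of %d", sum(per_type$match),
                                 nrow(per_type))),
            class = "LayerTally")
}

#' @export
print.LayerTally <- function(x, ...) {
  cat(sprintf("Layer tally: %s cell types correctly localized\n", x$label))
  invisible(x)
}

#' Pearson/RMSE of predictions against the gold standard
#'
#' Per (section, cell class): Pearson correlation and RMSE between the
#' per-spot predicted and gold counts; the per-method summary averages all
#' (section, class) values into a single r and a single RMSE. Pairs with a
#' zero-variance vector have undefined r and are excluded from the r
#' average with a warning (their RMSE still counts).
#'
#' @param preds a broad-resolution [prediction_matrix()] or list (one per
#'   section); collapse layer-resolution predictions first with
#'   [collapse_predictions()].
#' @param gold matching gold [prediction_matrix()] or list.
#' @param classes classes to score (default: intersection, minus
#'   `"other"`).
#' @return list of class `BenchMetrics`: `per_pair` data.frame
#'   (`section`, `class`, `pearson_r`, `rmse`), `mean_r`, `mean_rmse`,
#'   `method_name`.
#' @export
prediction_metrics <- function(preds, gold, classes = NULL) {
  if (is(preds, "PredictionMatrix")) preds <- list(preds)
  if (is(gold, "PredictionMatrix")) gold <- list(gold)
  stopifnot(length(preds) == length(gold))
  if (is.null(classes))
    classes <- setdiff(intersect(preds[[1]]$cell_types,
                                 gold[[1]]$cell_types), "other")
  if (length(classes) == 0) stop_cm("no shared cell classes to score")
  rows <- list()
  for (i in seq_along(preds)) {
    pv <- preds[[i]]$values
    gv <- gold[[i]]$values[match(rownames(pv), rownames(gold[[i]]$values)),
                           , drop = FALSE]
    for (cl in classes) {
      p <- pv[, cl]; g <- gv[, cl]
      r <- if (sd(p) == 0 || sd(g) == 0) {
        warning(sprintf("zero variance for %s in section %d; r undefined",
                        cl, i))
        NA_real_
      } else cor(p, g)
      rows[[length(rows) + 1L]] <- data.frame(
        section = i, class = cl, pearson_r = r,
        rmse = sqrt(mean((p - g)^2)), stringsAsFactors = FALSE)
    }
  }
  per_pair <- do.call(rbind, rows)
  structure(list(per_pair = per_pair,
                 mean_r = mean(per_pair$pearson_r, na.rm = TRUE),
                 mean_rmse = mean(per_pair$rmse),
                 method_name = preds[[1]]$method_name),
            class = "BenchMetrics")
}

#' @export
print.BenchMetrics <- function(x, ...) {
  cat(sprintf("BenchMetrics [%s]: mean r = %.4f, mean RMSE = %.4f (%d pairs)\n",
              x$method_name, x$mean_r, x$mean_rmse, nrow(x$per_pair)))
  invisible(x)
}

#' Broad-vs-fine resolution consistency
#'
#' Section-wide totals per broad class should match exactly between a
#' method's broad-resolution run and its layer-resolution run collapsed to
#' broad classes; reports the relative difference
#' `|sum(broad) - sum(fine collapsed)| / sum(broad)` per class and
#' section.
#'
#' @param broad broad-resolution [prediction_matrix()] or list.
#' @param fine layer-resolution [prediction_matrix()] or list; collapsed
#'   internally via [collapse_predictions()].
#' @param include_opc passed to [collapse_predictions()].
#' @return data.frame (`section`, `class`, `broad_total`, `fine_total`,
#'   `rel_diff`).
#' @export
resolution_consistency <- function(broad, fine, include_opc = FALSE) {
  if (is(broad, "PredictionMatrix")) broad <- list(broad)
  if (is(fine, "PredictionMatrix")) fine <- list(fine)
  stopifnot(length(broad) == length(fine))
  rows <- list()
  for (i in seq_along(broad)) {
    fc <- collapse_predictions(fine[[i]], include_opc = include_opc)
    cls <- intersect(broad[[i]]$cell_types, fc$cell_types)
    for (cl in cls) {
      b <- sum(broad[[i]]$values[, cl]); f <- sum(fc$values[, cl])
      rows[[length(rows) + 1L]] <- data.frame(
        section = i, class = cl, broad_total = b, fine_total = f,
        rel_diff = if (b > 0) abs(b - f) / b else as.numeric(f > 0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
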