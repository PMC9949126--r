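test_that("CART attains training accuracy 1 on well-separated classes", {
  nt <- simulate_nuclei(400, separation = 6, seed = 1)
  fit <- fit_cart(nt)
  pred <- classify_nuclei(fit, nt)
  expect_equal(mean(pred$pred_class == nt$true_class), 1)
  # single-class training is refused
  one <- nt[nt$true_class == "neuron", ]
  expect_error(fit_cart(one), "2 classes")
})

test_that("CART root split matches the exhaustive Gini oracle", {
  set.seed(23)
  for (i in 1:5) {
    nt <- simulate_nuclei(150, separation = 3, seed = 60 + i)
    fit <- fit_cart(nt)$fit
    X <- as.matrix(nt[, c("NeuN", "OLIG2", "GFAP", "TMEM119")])
    best <- oracle_best_gini_split(X, nt$true_class)
    split_var <- as.character(fit$frame$var[1])
    split_val <- fit$splits[1, "index"]
    expect_identical(split_var, best$feature)
    # within one observation gap of the oracle threshold
    v <- sort(unique(X[, best$feature]))
    gap <- max(diff(v))
    expect_lt(abs(split_val - best$threshold), gap + 1e-9)
  }
})

test_that("single-feature threshold is learned within one observation gap", {
  set.seed(3)
  n <- 100
  theta <- 2.5
  x <- c(runif(n / 2, 0, theta - 0.1), runif(n / 2, theta + 0.1, 5))
  cls <- rep(c("other", "neuron"), each = n / 2)
  nt <- nucleus_table(x = runif(n), y = runif(n),
                      intensity = cbind(x, 1, 1, 1), true_class = cls)
  fit <- fit_cart(nt)$fit
  expect_identical(as.character(fit$frame$var[1]), "NeuN")
  expect_lt(abs(fit$splits[1, "index"] - theta), 0.2 + 1e-9)
})

test_that("permuted labels give held-out accuracy near the majority rate", {
  nt <- simulate_nuclei(600, separation = 4, seed = 9)
  set.seed(10)
  nt$true_class <- sample(nt$true_class)
  train <- nt[1:300, ]; test <- nt[301:600, ]
  fit <- fit_cart(train)
  pred <- classify_nuclei(fit, test)
  acc <- mean(pred$pred_class == test$true_class)
  maj <- max(table(test$true_class)) / nrow(test)
  expect_lt(abs(acc - maj), 0.15)
})

test_that("nuclei are assigned to the nearest spot within the radius", {
  counts <- matrix(1L, 3, 2)
  sm <- tiny_section(counts, coords = cbind(x = c(0, 1, 2), y = 0))
  nt <- nucleus_table(x = c(0, 0.5, 1.6, 10), y = rep(0, 4),
                      intensity = matrix(1, 4, 4),
                      true_class = c("neuron", "oligo", "astro", "micro"))
  gold <- nuclei_to_spot_counts(nt, sm, spot_radius = 0.6)
  # nucleus at a spot center is assigned there
  expect_equal(gold$values[1, "neuron"], 1)
  # equidistant nucleus (0.5 from spots 1 and 2) goes to the lowest index
  expect_equal(gold$values[1, "oligo"], 1)
  expect_equal(gold$values[2, "oligo"], 0)
  # 1.6 is nearer spot 3 (0.4) than spot 2 (0.6)
  expect_equal(gold$values[3, "astro"], 1)
  # the far nucleus is dropped and logged
  expect_equal(attr(gold, "n_dropped"), 1)
  # conservation: assigned nuclei equal total gold counts
  expect_equal(sum(gold$values), nrow(nt) - attr(gold, "n_dropped"))
})

test_that("gold counts reconstruct the truth when nuclei sit on spot centers", {
  sim <- small_sim()
  sm <- sim$sections[[1]]
  comp <- sim$truth$true_spot_composition[[1]]
  broad <- t(rowsum(t(comp), c(Excit_L1 = "neuron", Excit_L2 = "neuron",
                               Excit_L3 = "neuron", Excit_L4 = "neuron",
                               Excit_L5 = "neuron", Excit_L6 = "neuron",
                               Inhib = "neuron", Astro = "astro",
                               Oligo = "oligo", OPC = "oligo",
                               Micro = "micro")[colnames(comp)]))
  idx <- rep(seq_len(nrow(broad)), rowSums(broad))
  cls <- unlist(apply(broad, 1, function(r) rep(colnames(broad), r)))
  nt <- nucleus_table(x = sm$coords[idx, "x"], y = sm$coords[idx, "y"],
                      intensity = matrix(1, length(idx), 4),
                      true_class = cls)
  gold <- nuclei_to_spot_counts(nt, sm, spot_radius = 1e-6)
  expect_equal(gold$values[, colnames(broad)], broad[rownames(gold$values), ],
               ignore_attr = TRUE)
  expect_equal(attr(gold, "n_dropped"), 0)
})

test_that("noise-free predictions score perfectly on every benchmark metric", {
  sim <- small_sim()
  preds <- simulate_predictions(sim$truth, noise_sd = 0)
  # layer tally: every laminar type localizes to its expected layer
  tally <- layer_localization_tally(preds, sim$sections)
  expect_equal(tally$score, 1)
  expect_match(tally$label, "of")
  # Pearson/RMSE against the (identical) truth
  gold <- lapply(sim$truth$true_spot_composition, function(m)
    prediction_matrix(m, method_name = "truth"))
  pm <- prediction_metrics(lapply(preds, collapse_predictions),
                           lapply(gold, collapse_predictions))
  expect_equal(pm$mean_r, 1, tolerance = 1e-12)
  expect_equal(pm$mean_rmse, 0, tolerance = 1e-12)
  # resolution consistency: broad derived from fine matches exactly
  broad <- lapply(preds, collapse_predictions)
  rc <- resolution_consistency(broad, preds)
  expect_true(all(rc$rel_diff == 0))
  # scaling the fine predictions by 2 gives relative difference 1
  fine2 <- lapply(preds, function(p)
    prediction_matrix(p$values * 2, resolution = "layer"))
  rc2 <- resolution_consistency(broad, fine2)
  expect_true(all(abs(rc2$rel_diff - 1) < 1e-12))
})

test_that("uniform predictions tie on every layer and score 0", {
  sim <- small_sim()
  uni <- lapply(sim$sections, function(sm)
    prediction_matrix(matrix(1, nrow(sm$counts), 3,
                             dimnames = list(sm$spot_ids,
                                             c("Excit_L1", "Astro", "Oligo")))))
  tally <- layer_localization_tally(uni, sim$sections)
  expect_true(all(tally$per_type$tie))
  expect_equal(tally$score, 0)
})

test_that("prediction metrics match a hand-computed toy case", {
  gold <- prediction_matrix(cbind(neuron = c(1, 2, 3)),
                            spot_ids = paste0("s", 1:3))
  pred <- prediction_matrix(cbind(neuron = c(2, 2, 5)),
                            spot_ids = paste0("s", 1:3))
  pm <- prediction_metrics(pred, gold, classes = "neuron")
  expect_equal(pm$mean_r, cor(c(1, 2, 3), c(2, 2, 5)), tolerance = 1e-12)
  expect_equal(pm$mean_rmse, sqrt(mean(c(1, 0, 2)^2)), tolerance = 1e-12)
  # predictions offset by a constant keep r = 1 with rmse = |c|
  pred2 <- prediction_matrix(cbind(neuron = c(1, 2, 3) + 2),
                             spot_ids = paste0("s", 1:3))
  pm2 <- prediction_metrics(pred2, gold, classes = "neuron")
  expect_equal(pm2$mean_r, 1, tolerance = 1e-12)
  expect_equal(pm2$mean_rmse, 2, tolerance = 1e-12)
  # zero-variance vectors are excluded from the r average with a warning
  flat <- prediction_matrix(cbind(neuron = c(2, 2, 2)),
                            spot_ids = paste0("s", 1:3))
  expect_warning(pm3 <- prediction_metrics(flat, gold, classes = "neuron"),
                 "zero variance")
  expect_true(is.nan(pm3$mean_r))
})

test_that("layer tally degrades (weakly) as prediction noise grows", {
  scores <- sapply(1:10, function(s) {
    cfg <- sim_config(n_sections = 2, n_donors = 2, n_genes = 60,
                      n_markers_per_layer = 5, n_spots_per_section = 220)
    sim <- simulate_sections(cfg, seed = 300 + s)
    vapply(c(0, 1, 3), function(ns) {
      preds <- simulate_predictions(sim$truth, noise_sd = ns, seed = s)
      layer_localization_tally(preds, sim$sections)$score
    }, numeric(1))
  })
  avg <- rowMeans(scores)
  expect_equal(avg[1], 1)
  expect_true(all(diff(avg) <= 0))
})
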