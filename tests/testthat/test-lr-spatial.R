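test_that("SPM closed forms: exclusivity, uniformity, unit norm", {
  # gene expressed in exactly one of 4 types -> SPM 1 there, 0 elsewhere
  mk_cell <- function(g, rest) cbind(lr = g, other = rest)
  counts <- rbind(mk_cell(10, 90), mk_cell(12, 88),
                  mk_cell(0, 100), mk_cell(0, 100),
                  mk_cell(0, 100), mk_cell(0, 100),
                  mk_cell(0, 100), mk_cell(0, 100))
  cells <- tiny_cells(list(counts), rep(c("A", "B", "C", "D"), each = 2))
  s <- specificity_measure(cells, "lr")
  expect_equal(unname(s["A"]), 1)
  expect_equal(unname(s[c("B", "C", "D")]), rep(0, 3))
  # equal expression over n types -> 1/sqrt(n) each; sum of squares 1
  counts2 <- do.call(rbind, rep(list(cbind(lr = 5, other = 95)), 8))
  cells2 <- tiny_cells(list(counts2), rep(c("A", "B", "C", "D"), each = 2))
  s2 <- specificity_measure(cells2, "lr")
  expect_equal(unname(s2), rep(1 / sqrt(4), 4), tolerance = 1e-12)
  expect_equal(sum(s2^2), 1, tolerance = 1e-12)
  # mean expression [3, 4] over 2 types -> SPM [0.6, 0.8]
  counts3 <- rbind(cbind(lr = 3, other = 97), cbind(lr = 4, other = 96))
  cells3 <- tiny_cells(list(counts3), c("A", "B"))
  expect_equal(unname(specificity_measure(cells3, "lr")), c(0.6, 0.8),
               tolerance = 1e-12)
  # unexpressed gene: SPM undefined, reported missing
  counts4 <- rbind(cbind(lr = 0, other = 1), cbind(lr = 0, other = 1))
  cells4 <- tiny_cells(list(counts4), c("A", "B"))
  expect_warning(s4 <- specificity_measure(cells4, "lr"), "undefined")
  expect_true(all(is.na(s4)))
})

test_that("SPM squared sums to 1 for any expressed gene (property)", {
  out <- simulate_cells(sim_config(n_genes = 200, n_cells_per_type = 20),
                        seed = 4)
  set.seed(2)
  for (g in sample(out$cells$gene_ids, 20)) {
    s <- suppressWarnings(specificity_measure(out$cells, g))
    if (!anyNA(s)) expect_equal(sum(s^2), 1, tolerance = 1e-10)
  }
})

test_that("within-type co-expression percentage counts double-positive cells", {
  counts <- cbind(A = c(1, 0, 2, 1), B = c(1, 1, 0, 3))
  cells <- tiny_cells(list(counts), rep("T1", 4))
  expect_equal(cotype_coexpression(cells, "A", "B", "T1"), 50)
  # same gene twice equals the percentage expressing that gene
  expect_equal(cotype_coexpression(cells, "A", "A", "T1"), 75)
  # genes absent from the panel -> 0
  expect_equal(cotype_coexpression(cells, "nope1", "nope2", "T1"), 0)
})

test_that("co-expression flags are monotone in counts", {
  counts <- rbind(c(0, 1), c(1, 1), c(3, 0))
  sm <- tiny_section(counts, domain = c("D1", "D1", "D2"))
  pair <- lr_pair("g01", "g02")
  r1 <- coexpression_by_domain(sm, pair)
  expect_equal(r1$by_section_domain$n_coexpr, c(1, 0))
  # adding counts never unsets a co-expression flag
  sm2 <- sm
  sm2$counts <- sm$counts + 1
  r2 <- coexpression_by_domain(sm2, pair)
  expect_true(all(r2$by_section_domain$n_coexpr >=
                  r1$by_section_domain$n_coexpr))
})

test_that("domain test matches the hand-computed paired t oracle", {
  # 2 sections; domain A proportions 0.4, 0.5; domain B 0.1, 0.1
  mk_sec <- function(sid, pA, pB, n = 10) {
    co <- function(p) {
      m <- matrix(0, n, 2)
      if (round(p * n) > 0) m[seq_len(round(p * n)), ] <- 1
      m
    }
    counts <- rbind(co(pA), co(pB))
    colnames(counts) <- c("L", "R")
    tiny_section(counts, domain = rep(c("A", "B"), each = n),
                 sample_id = sid)
  }
  secs <- list(mk_sec("S1", 0.4, 0.1), mk_sec("S2", 0.5, 0.1))
  res <- coexpression_by_domain(secs, lr_pair("L", "R"))
  bd <- res$by_domain
  # diffs for A vs others-mean: [0.3, 0.4] -> t = 0.35 / (0.0707/sqrt(2)) = 7
  expect_equal(bd$statistic[bd$domain == "A"], 7, tolerance = 1e-10)
  expect_equal(bd$p[bd$domain == "A"], pt(7, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(bd$statistic[bd$domain == "A"], 0)
  # a never-expressed pair gives all-zero proportions and p = 1
  res0 <- coexpression_by_domain(secs, lr_pair("L", "missing"))
  expect_true(all(res0$by_section_domain$proportion == 0))
  expect_true(all(res0$by_domain$p == 1))
})

test_that("the planted domain attains max co-expression and smallest p", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_sections = 4, n_donors = 2, n_genes = 400,
                      n_spots_per_section = 160)
    sim <- simulate_sections(cfg, seed = 200 + s)
    mk <- sim$truth$marker_assignment
    # two markers of the layer generating D7, picked at moderate abundance
    # (sparsely detected spot-wise, like real LR transcripts)
    ly <- sim$truth$domain_to_layer["D7"]
    cand <- names(mk)[!is.na(mk) & mk == ly]
    cand <- cand[order(abs(sim$truth$baseline[cand] - 0.4))][1:2]
    res <- coexpression_by_domain(sim$sections, lr_pair(cand[1], cand[2]))
    bd <- res$by_domain
    bd$domain[which.max(bd$mean_prop)] == "D7" &&
      bd$domain[which.min(bd$p)] == "D7"
  }, logical(1))
  expect_true(all(hits))
})

test_that("colocalization network obeys its counting identities", {
  # 1 co-expressing spot with dominant {A, B, C} -> all three edges score 1
  counts <- rbind(c(1, 1), c(0, 5))
  sm <- tiny_section(counts, domain = c("D1", "D1"))
  pv <- rbind(c(A = 5, B = 4, C = 3, D = 0.1),
              c(A = 0, B = 1, C = 2, D = 9))
  rownames(pv) <- sm$spot_ids
  preds <- prediction_matrix(pv)
  net <- colocalization_network(sm, lr_pair("g01", "g02"), preds, top_k = 3)
  expect_equal(net$n_coexpr, 1)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$score, rep(1, 3))
  expect_setequal(paste(net$edges$type_a, net$edges$type_b),
                  c("A B", "A C", "B C"))
  # node-weight conservation: sum = top_k x co-expressing spots
  expect_equal(sum(net$nodes$weight), 3 * net$n_coexpr)
  # no co-expressing spots -> empty network
  net0 <- colocalization_network(sm, lr_pair("g01", "missing"), preds)
  expect_equal(net0$n_coexpr, 0)
  expect_equal(nrow(net0$edges), 0)
  # top_k beyond the panel errors
  expect_error(colocalization_network(sm, lr_pair("g01", "g02"), preds,
                                      top_k = 9), "top_k")
})

test_that("a planted co-dominant pair attains the maximal edge score", {
  sim <- small_sim()
  secs <- sim$sections
  pair <- lr_pair("gene00001", "gene00002")
  set.seed(13)
  preds <- lapply(secs, function(sm) {
    n <- nrow(sm$counts)
    v <- matrix(runif(n * 5, 0, 1), n, 5,
                dimnames = list(sm$spot_ids,
                                c("X", "Y", "Z", "W", "V")))
    co <- (sm$counts[, "gene00001"] > 0) & (sm$counts[, "gene00002"] > 0)
    v[co, "X"] <- 10; v[co, "Y"] <- 9 # X, Y always co-dominate
    prediction_matrix(v)
  })
  net <- colocalization_network(secs, pair, preds, top_k = 3)
  expect_gt(net$n_coexpr, 0)
  top_edge <- net$edges[1, ]
  expect_identical(paste(top_edge$type_a, top_edge$type_b), "X Y")
  expect_equal(top_edge$score, 1)
  expect_true(all(net$edges$score >= 0 & net$edges$score <= 1))
  expect_equal(sum(net$nodes$weight), 3 * net$n_coexpr)
})
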