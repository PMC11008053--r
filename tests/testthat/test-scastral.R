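test_that("CPM normalization has the stated closed forms", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "c1"))
  expect_equal(unname(cpm_normalize(m)[, 1]), c(250000, 250000, 500000))
  m2 <- cbind(m, c2 = c(0, 4, 4))
  cpm <- cpm_normalize(m2)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(cpm["a", "c2"], 0)
})

test_that("tf-idf follows the gene-frequency / inverse-cell-frequency form", {
  # gene expressed in 1 of 100 cells -> idf = ln(100 / 2) = ln(50)
  x <- matrix(0, 2, 100, dimnames = list(c("g1", "g2"), NULL))
  x[1, 1] <- 10
  x[2, ] <- 5
  tf <- tfidf_rescale(x)
  idf <- attr(tf, "idf")
  expect_equal(unname(idf["g1"]), log(100 / 2))
  expect_equal(unname(idf["g2"]), log(100 / 101))   # near 0, negative
  # single cell: tf sums to 1 over expressed panel genes
  x1 <- matrix(c(3, 1, 0), 3, 1, dimnames = list(c("a", "b", "c"), "c1"))
  tf1 <- tfidf_rescale(x1, idf = setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(sum(tf1), 1)                          # idf 1 -> pure tf
  # all-zero cell maps to zeros
  xz <- cbind(x1, c2 = c(0, 0, 0))
  expect_equal(unname(tfidf_rescale(xz)[, "c2"]), c(0, 0, 0))
})

test_that("pair building yields 2n pairs with correct class structure", {
  labels <- rep(c("tolerant", "sensitive"), c(6, 4))
  pr <- build_pairs(labels, seed = 3)
  expect_equal(nrow(pr), 20)
  expect_true(all(pr$i != pr$j | pr$label == -1))    # self excluded for +1
  pos <- pr$label == 1
  expect_true(all(labels[pr$i[pos]] == labels[pr$j[pos]]))
  expect_true(all(labels[pr$i[!pos]] != labels[pr$j[!pos]]))
  expect_true(all(pr$i[pos] != pr$j[pos]))
  expect_identical(pr, build_pairs(labels, seed = 3))
  expect_error(build_pairs(rep("tolerant", 5)), "two classes")
})

test_that("contrastive loss has its analytic fixed points", {
  z <- c(1, 0, 1)
  expect_equal(contrastive_loss(z, z, 1, x = 1:3, xhat = 1:3, w_lat = 0),
               0)
  expect_equal(contrastive_loss(c(1, 0), c(0, 1), -1, w_lat = 0), 0)
  expect_equal(contrastive_loss(z, z, -1, w_lat = 0), 1)
  expect_warning(l <- contrastive_loss(c(0, 0), z[1:2], 1, w_lat = 0),
                 "zero-norm")
  expect_equal(l, 0)
})

test_that("training separates a separable fixture and is reproducible", {
  fx <- fixture_scastral(n_per_class = 125, n_genes = 300, seed = 7)
  fit <- scastral(fx$counts, fx$labels, fx$panel, fast_cfg(seed = 11))
  expect_gte(fit$accuracy, 0.9)
  # embedding geometry: intra-class cosine distance < inter-class
  tfi <- clonetrace:::scastral_input(fx$counts, fx$panel, idf = fit$idf)
  Z <- clonetrace:::l2_normalize_rows(clonetrace:::ae_encode(fit$par, t(tfi)))
  D <- 1 - Z %*% t(Z)
  tol <- fx$labels == "tolerant"
  intra <- mean(c(D[tol, tol][upper.tri(D[tol, tol])],
                  D[!tol, !tol][upper.tri(D[!tol, !tol])]))
  inter <- mean(D[tol, !tol])
  expect_lt(intra, inter)
  # determinism of the full fit + predict path
  fit2 <- scastral(fx$counts, fx$labels, fx$panel, fast_cfg(seed = 11))
  p1 <- predict(fit, fx$counts)
  p2 <- predict(fit2, fx$counts)
  expect_identical(p1$prob_tolerant, p2$prob_tolerant)
})

test_that("prediction applies the probability threshold and fraction rules", {
  fx <- fixture_scastral(n_per_class = 100, n_genes = 250, seed = 8)
  fit <- scastral(fx$counts, fx$labels, fx$panel, fast_cfg(seed = 5))
  pred <- predict(fit, fx$counts, threshold = 0.75)
  # class follows the winning probability; undetermined iff <= threshold
  win <- pmax(pred$prob_tolerant, pred$prob_sensitive)
  expect_true(all((pred$class == "undetermined") == (win <= 0.75)))
  expect_true(all(pred$class[pred$class != "undetermined"] ==
                    ifelse(pred$prob_tolerant[pred$class != "undetermined"] >
                             pred$prob_sensitive[pred$class != "undetermined"],
                           "tolerant", "sensitive")))
  fr <- attr(pred, "fractions")
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # per-sample fractions sum to 1
  samples <- rep(c("s1", "s2"), length.out = nrow(pred))
  pf <- prediction_fractions(pred, samples)
  expect_equal(pf$tolerant + pf$sensitive + pf$undetermined, c(1, 1))
  # serialization round-trip reproduces identical probabilities
  path <- tempfile(fileext = ".rds")
  save_scastral(fit, path)
  fit_back <- load_scastral(path)
  pred_back <- predict(fit_back, fx$counts, threshold = 0.75)
  expect_equal(pred_back$prob_tolerant, pred$prob_tolerant,
               tolerance = 1e-6)
})

test_that("pseudobulk prediction scales with summed counts", {
  fx <- fixture_scastral(n_per_class = 100, n_genes = 250, seed = 9)
  fit <- scastral(fx$counts, fx$labels, fx$panel, fast_cfg(seed = 6))
  # a pseudobulk of copies of one cell is that cell scaled: same class
  cell <- fx$counts[, 1, drop = FALSE]
  rep10 <- cell[, rep(1, 10)]
  colnames(rep10) <- sprintf("r%02d", 1:10)
  pb <- predict_pseudobulk(fit, rep10, samples = rep("s", 10))
  single <- predict(fit, cell)
  expect_equal(pb$prob_tolerant, single$prob_tolerant, tolerance = 1e-9)
  expect_error(predict_pseudobulk(fit, cell * 0, samples = "s"), "empty")
})

test_that("AUROC matches the pROC oracle and PFI isolates signal", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- rnorm(200)
  labels <- ifelse(runif(200) < plogis(scores), "tolerant", "sensitive")
  expect_equal(clonetrace:::auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("sensitive", "tolerant"),
                                              direction = "<", quiet = TRUE))))
  # one informative gene among noise: largest importance; constant gene 0
  set.seed(11)
  n <- 160
  labels <- rep(c("tolerant", "sensitive"), each = n / 2)
  counts <- matrix(rpois(8 * n, 40), 8, n,
                   dimnames = list(sprintf("g%d", 1:8),
                                   sprintf("c%03d", seq_len(n))))
  counts[1, labels == "tolerant"] <- rpois(n / 2, 160)  # the signal gene
  panel <- rownames(counts)
  fit <- scastral(counts, labels, panel,
                  fast_cfg(seed = 2, n_batches = 4L))
  imp <- pfi(fit, counts, labels, n_rep = 30, seed = 3)
  expect_equal(imp$gene[which.max(imp$importance)], "g1")
  # pure-noise genes carry (near-)zero importance
  expect_lt(median(abs(imp$importance[imp$gene != "g1"])), 0.02)
  expect_gt(imp$baseline_auroc[1], 0.8)
})

test_that("random panel benchmark is reproducible and validates inputs", {
  fx <- fixture_scastral(n_per_class = 60, n_genes = 200, seed = 12)
  ev <- fixture_eval_samples(c(0.1, 0.5, 0.9), cells_per_sample = 30,
                             n_genes = 200, seed = 13)
  cfg <- fast_cfg(seed = 1, max_epochs = 10L, patience = 5L)
  b1 <- random_panel_benchmark(fx$counts, fx$labels, ev$counts, ev$samples,
                               ev$truth, fx$panel, panel_size = 20,
                               n_sim = 2, cfg = cfg, seed = 4)
  b2 <- random_panel_benchmark(fx$counts, fx$labels, ev$counts, ev$samples,
                               ev$truth, fx$panel, panel_size = 20,
                               n_sim = 2, cfg = cfg, seed = 4)
  expect_identical(b1, b2)
  expect_length(b1$null_scores, 2)
  expect_error(
    random_panel_benchmark(fx$counts, fx$labels, ev$counts, ev$samples,
                           ev$truth, fx$panel, panel_size = 1e5,
                           n_sim = 1, cfg = cfg),
    "exceeds")
  expect_error(
    random_panel_benchmark(fx$counts, fx$labels, ev$counts, ev$samples,
                           ev$truth, fx$panel, n_sim = 0, cfg = cfg),
    "n_sim")
})
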