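# Shared fixture builders and independent oracles.

# balanced two-class expression fixture (tolerant vs sensitive)
fixture_marker_sim <- function(n_per_class = 500, n_genes = 2000,
                               effect_log2fc = 1, seed = 1,
                               doublet_rate = 0, mito_outlier_rate = 0) {
  cells <- data.frame(
    cell = sprintf("c%05d", seq_len(2 * n_per_class)),
    response = rep(c("tolerant", "sensitive"), each = n_per_class),
    timepoint = 0, stringsAsFactors = FALSE)
  cfg <- expression_config(n_genes = n_genes, n_marker_up = 50,
                           n_marker_down = 25,
                           effect_log2fc = effect_log2fc,
                           doublet_rate = doublet_rate,
                           mito_outlier_rate = mito_outlier_rate,
                           seed = seed)
  simulate_expression(cells, cfg)
}

# founder population of `n` equal-sized single-integration lineages
fixture_founder <- function(n = 2336) {
  data.frame(cell = sprintf("f%05d", seq_len(n)), n_integrations = 1L,
             barcode = seq_len(n), multi = FALSE, stringsAsFactors = FALSE)
}

# small separable classifier fixture; panel = the true marker genes
fixture_scastral <- function(n_per_class = 150, n_genes = 400, seed = 7) {
  sim <- fixture_marker_sim(n_per_class, n_genes, effect_log2fc = 1,
                            seed = seed)
  list(counts = sim$counts, labels = sim$cells$response,
       panel = sim$markers$gene, markers = sim$markers)
}

# reduced training budget for fast classifier tests
fast_cfg <- function(seed = 1, ...) {
  args <- list(max_epochs = 40L, patience = 10L, minibatch = 64L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scastral_config, args)
}

# oracle: exhaustive whitelist scan for Hamming-1 correction
brute_force_correct <- function(putative, vocabulary) {
  if (putative %in% vocabulary) return(putative)
  k <- nchar(putative)
  pm <- strsplit(putative, "")[[1]]
  vm <- matrix(unlist(strsplit(vocabulary, ""), use.names = FALSE),
               nrow = length(vocabulary), ncol = k, byrow = TRUE)
  d <- rowSums(vm != matrix(pm, length(vocabulary), k, byrow = TRUE))
  hits <- vocabulary[d == 1]
  if (length(hits) == 1) hits else NA_character_
}

# oracle: exact two-sided rank-sum p by enumeration of all group assignments
exact_wilcox_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  v <- c(x, y)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- mean(us)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# sample multi-timepoint eval "cell lines" with planted tolerant fractions;
# param_seed ties the gene-level parameters to the training fixture
fixture_eval_samples <- function(fractions, cells_per_sample = 40,
                                 n_genes = 400, seed = 21,
                                 param_seed = NULL) {
  n_s <- length(fractions)
  n_tol <- round(fractions * cells_per_sample)
  resp <- unlist(lapply(seq_len(n_s), function(i)
    rep(c("tolerant", "sensitive"),
        c(n_tol[i], cells_per_sample - n_tol[i]))))
  cells <- data.frame(
    cell = sprintf("e%05d", seq_along(resp)), response = resp,
    timepoint = 0, stringsAsFactors = FALSE)
  cfg <- expression_config(n_genes = n_genes, n_marker_up = 50,
                           n_marker_down = 25, effect_log2fc = 1,
                           doublet_rate = 0, mito_outlier_rate = 0,
                           seed = seed, param_seed = param_seed)
  sim <- simulate_expression(cells, cfg)
  samples <- rep(sprintf("line%02d", seq_len(n_s)), each = cells_per_sample)
  truth <- setNames(n_tol / cells_per_sample,
                    sprintf("line%02d", seq_len(n_s)))
  list(counts = sim$counts, samples = samples, truth = truth)
}
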