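test_that("whitelist words have exact lengths, are distinct and reproducible", {
  wl <- make_whitelist(100, 1000, seed = 1)
  expect_length(wl$bc14, 100)
  expect_length(wl$bc30, 1000)
  expect_true(all(nchar(wl$bc14) == 14))
  expect_true(all(nchar(wl$bc30) == 30))
  expect_false(anyDuplicated(wl$bc14) > 0)
  expect_false(anyDuplicated(wl$bc30) > 0)
  expect_true(all(grepl("^[ACGT]+$", wl$bc14)))

  wl1 <- make_whitelist(1, 1, seed = 0)
  cas <- lineage_cassette(wl1, 1)
  expect_equal(nchar(cas$cassette), 48)
  expect_equal(substr(cas$cassette, 15, 18), "TGGT")

  expect_identical(make_whitelist(50, 80, seed = 9),
                   make_whitelist(50, 80, seed = 9))
  expect_error(make_whitelist(4^14, 10), "too large")
})

test_that("infection follows the Poisson low-MOI model", {
  f0 <- simulate_infection(population_config(n_cells = 500, moi = 0,
                                             library_size = 100, seed = 1))
  expect_equal(sum(f0$cells$n_integrations), 0)
  expect_equal(n_distinct_barcodes(f0), 0)

  cfg <- population_config(n_cells = 50000, moi = 0.05,
                           library_size = 1e7, seed = 4)
  f <- simulate_infection(cfg)
  p_inf <- mean(f$cells$n_integrations > 0)
  p_exp <- 1 - exp(-0.05)
  se <- sqrt(p_exp * (1 - p_exp) / 50000)
  expect_lt(abs(p_inf - p_exp), 3 * se)
  # reported lineage is the first integration; multi-integration flagged
  expect_true(all(f$cells$multi == (f$cells$n_integrations > 1)))
  expect_true(all(is.na(f$cells$barcode) == (f$cells$n_integrations == 0)))
  expect_identical(simulate_infection(cfg), simulate_infection(cfg))
})

test_that("selection reproduces the configured clonal structure", {
  founder <- fixture_founder(2336)
  sel <- simulate_selection(founder,
                            selection_config(cells_per_timepoint = 500,
                                             seed = 2))
  expect_equal(sum(sel$classes$response == "tolerant"), 192)
  expect_equal(sum(sel$classes$dynamics == "dominant", na.rm = TRUE), 2)
  expect_true(all(abs(colSums(sel$freq) - 1) < 1e-9))
  # dominant combined expected frequency strictly increases
  dom <- as.character(sel$classes$lineage[sel$classes$dynamics %in% "dominant"])
  expect_true(all(diff(colSums(sel$freq[dom, , drop = FALSE])) > 0))
  # every sampled cell's lineage is in the class map
  expect_true(all(sel$cells$lineage %in% sel$classes$lineage))
})

test_that("neutral dynamics: advantage 1 with no sensitive decay is constant", {
  founder <- fixture_founder(200)
  sel <- simulate_selection(
    founder, selection_config(frac_tolerant = 1, n_dominant = 0,
                              advantage = 1, cells_per_timepoint = 100,
                              seed = 3))
  expect_true(all(abs(sel$freq - sel$freq[, 1]) < 1e-12))
  expect_error(
    simulate_selection(founder,
                       selection_config(cells_per_timepoint = 10000)),
    "exceeds")
})

test_that("expression model places the configured marker effects", {
  sim <- fixture_marker_sim(n_per_class = 500, n_genes = 500, seed = 5)
  tol <- sim$cells$response == "tolerant"
  up <- sim$markers$gene[sim$markers$sign == 1]
  ratio <- rowMeans(sim$counts[up, tol]) / rowMeans(sim$counts[up, !tol])
  expect_lt(abs(mean(ratio) - 2), 0.2)     # 2^1 within 10 %
  expect_false(any(sim$cells$doublet))     # doublet_rate = 0

  # null effect: marker and non-marker genes indistinguishable
  sim0 <- fixture_marker_sim(n_per_class = 150, n_genes = 300,
                             effect_log2fc = 0, seed = 6)
  norm <- lognormalize(sim0$counts)
  mk <- rank_sum_markers(norm, sim0$cells$response)
  expect_lte(length(attr(mk, "up")) + length(attr(mk, "down")), 2)

  simd <- fixture_marker_sim(n_per_class = 100, n_genes = 200, seed = 7,
                             doublet_rate = 0.1)
  expect_equal(sum(simd$cells$doublet), 20)
})

test_that("cassette reads carry the truth at the stated offsets", {
  wl <- make_whitelist(20, 50, seed = 2)
  cells <- data.frame(cell = sprintf("c%03d", 1:10),
                      lineage = c(1:5, 996:1000))
  out <- write_reads(cells, wl, withr::local_tempdir(), error_rate = 0,
                     reads_per_cell = 5, seed = 3)
  fq <- read_fastq_pair(out$r1, out$r2)
  expect_length(fq$r1, 50)                 # 10 cells x 5 reads, paired
  expect_length(fq$r2, 50)
  expect_identical(names(fq$r1), names(fq$r2))
  # flank 10 nt, then bc14 (11-24), anchor (25-28), bc30 (29-58)
  expect_true(all(substr(fq$r2, 25, 28) == "TGGT"))
  cas <- lineage_cassette(wl, cells$lineage)
  expected <- rep(paste0(cas$bc14, "TGGT", cas$bc30), each = 5)
  expect_identical(unname(substr(fq$r2, 11, 58)), expected)
  expect_true(all(nchar(fq$r1) == 28))
  expect_error(write_reads(cells, wl, tempdir(), read2_length = 50),
               ">= flank5 \\+ 48")
})

test_that("substitution errors hit the cassette at the binomial rate", {
  wl <- make_whitelist(20, 50, seed = 2)
  n_cells <- 1000
  cells <- data.frame(cell = sprintf("c%04d", seq_len(n_cells)),
                      lineage = sample(1000, n_cells, replace = TRUE))
  out <- write_reads(cells, wl, withr::local_tempdir(), error_rate = 0.01,
                     reads_per_cell = 10, seed = 4)
  fq <- read_fastq_pair(out$r1, out$r2)
  cas <- lineage_cassette(wl, cells$lineage)
  truth48 <- rep(paste0(cas$bc14, "TGGT", cas$bc30), each = 10)
  frac_err <- mean(substr(fq$r2, 11, 58) != truth48)
  expect_lt(abs(frac_err - (1 - 0.99^48)), 0.03)
})

test_that("fixed seeds give byte-identical FASTQ output", {
  wl <- make_whitelist(5, 5, seed = 1)
  cells <- data.frame(cell = sprintf("c%02d", 1:8),
                      lineage = sample(25, 8))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reads(cells, wl, d1, error_rate = 0.01, seed = 11)
  write_reads(cells, wl, d2, error_rate = 0.01, seed = 11)
  expect_identical(readBin(file.path(d1, "R2.fastq.gz"), "raw", 1e6),
                   readBin(file.path(d2, "R2.fastq.gz"), "raw", 1e6))
})

test_that("count matrices round-trip through MatrixMarket", {
  sim <- fixture_marker_sim(n_per_class = 30, n_genes = 100, seed = 8)
  d <- withr::local_tempdir()
  write_counts_mtx(sim$counts, d, genes = sim$genes, cells = sim$cells)
  back <- read_counts_mtx(d)
  expect_equal(as.matrix(back$counts), sim$counts)
  expect_equal(back$genes$mito, sim$genes$mito)
  expect_equal(back$cells$response, sim$cells$response)
})
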