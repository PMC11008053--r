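test_that("hamming counts mismatching positions and rejects unequal lengths", {
  expect_equal(hamming("TGGT", "TGGT"), 0)
  expect_equal(hamming("TGGT", "TGAT"), 1)
  expect_equal(hamming("AAAA", "TTTT"), 4)
  expect_error(hamming("AAA", "AAAA"), "equal length")
})

test_that("anchor search respects flank constraints and match preference", {
  a14 <- strrep("A", 14); c30 <- strrep("C", 30)
  expect_equal(find_anchor(paste0(a14, "TGGT", c30)), 15)
  # one mismatch allowed
  expect_equal(find_anchor(paste0(a14, "TGCT", c30)), 15)
  # no 14-nt upstream flank -> no valid position
  expect_true(is.na(find_anchor(paste0("TGGT", c30))))
  # insufficient downstream flank
  expect_true(is.na(find_anchor(paste0(a14, "TGGT", strrep("C", 29)))))
  # exact match beats an earlier 1-mismatch match
  seq <- paste0(a14, "TGAT", strrep("A", 10), "TGGT", c30)
  expect_equal(find_anchor(seq), 29)
  # among equals, leftmost valid position wins
  seq2 <- paste0(a14, "TGGT", strrep("A", 10), "TGGT", c30)
  expect_equal(find_anchor(seq2), 15)
})

test_that("barcode correction accepts unique Hamming-1 neighbours only", {
  vocab <- c(strrep("A", 14), paste0("C", strrep("A", 13)))
  expect_equal(correct_barcode(strrep("A", 14), vocab), strrep("A", 14))
  # unique neighbour
  v1 <- strrep("A", 14)
  mut <- paste0(substr(v1, 1, 7), "T", substr(v1, 9, 14))
  expect_equal(correct_barcode(mut, v1), v1)
  # distance 1 to two vocabulary words -> uncorrectable
  expect_true(is.na(correct_barcode(paste0("G", strrep("A", 13)), vocab)))
  expect_error(correct_barcode("AAAA", vocab), "length")
})

test_that("barcode correction matches brute-force enumeration", {
  set.seed(42)
  wl <- make_whitelist(30, 40, seed = 5)
  for (rep in 1:200) {
    if (rep %% 2 == 0) {
      vocab <- wl$bc14
      put <- paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = "")
      base <- sample(vocab, 1)
      # half the cases: mutate a vocabulary word 0-2 times
      if (rep %% 4 == 0) {
        pos <- sample(14, sample(0:2, 1))
        s <- strsplit(base, "")[[1]]
        s[pos] <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
        put <- paste(s, collapse = "")
      }
    } else {
      vocab <- wl$bc30
      base <- sample(vocab, 1)
      pos <- sample(30, sample(0:2, 1))
      s <- strsplit(base, "")[[1]]
      s[pos] <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
      put <- paste(s, collapse = "")
    }
    expect_identical(correct_barcode(put, vocab),
                     brute_force_correct(put, vocab))
  }
})

test_that("read parsing applies the sequential bc14-first correction logic", {
  wl <- make_whitelist(10, 10, seed = 3)
  mk_read <- function(b14, b30) paste0(strrep("G", 14), b14, "TGGT", b30,
                                       strrep("G", 5))
  mutate_at <- function(s, pos, to = "T") {
    v <- strsplit(s, "")[[1]]
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  clean <- mk_read(wl$bc14[1], wl$bc30[1])
  h <- parse_reads(clean, wl)
  expect_equal(h$status, "ok")
  expect_equal(h$bc14, wl$bc14[1])
  expect_false(h$bc14_corrected)
  expect_false(h$bc30_corrected)
  expect_equal(h$lineage, paste(wl$bc14[1], wl$bc30[1], sep = ":"))

  one_err <- mk_read(mutate_at(wl$bc14[1], 3), wl$bc30[1])
  h1 <- parse_reads(one_err, wl)
  expect_equal(h1$status, "ok")
  expect_equal(h1$bc14, wl$bc14[1])
  expect_true(h1$bc14_corrected)
  expect_false(h1$bc30_corrected)

  two_err <- mk_read(mutate_at(wl$bc14[1], c(3, 9)), wl$bc30[1])
  expect_equal(parse_reads(two_err, wl)$status, "rejected")

  # both absent: bc30 corrected only because bc14 correction succeeded
  both <- mk_read(mutate_at(wl$bc14[1], 3), mutate_at(wl$bc30[1], 11))
  hb <- parse_reads(both, wl)
  expect_equal(hb$status, "ok")
  expect_true(hb$bc14_corrected && hb$bc30_corrected)
  # bc14 dead -> bc30 not rescued even though it is correctable
  dead <- mk_read(mutate_at(wl$bc14[1], c(3, 9)), mutate_at(wl$bc30[1], 11))
  expect_equal(parse_reads(dead, wl)$status, "rejected")
})

test_that("accepted hits always carry whitelisted barcodes", {
  set.seed(9)
  wl <- make_whitelist(15, 15, seed = 4)
  cells <- data.frame(cell = sprintf("c%03d", 1:60),
                      lineage = sample(225, 60, TRUE))
  out <- write_reads(cells, wl, withr::local_tempdir(), error_rate = 0.05,
                     reads_per_cell = 3, seed = 5)
  fq <- read_fastq_pair(out$r1, out$r2)
  h <- parse_reads(fq$r2, wl)
  ok <- h$status == "ok"
  expect_true(all(h$bc14[ok] %in% wl$bc14))
  expect_true(all(h$bc30[ok] %in% wl$bc30))
  expect_true(all(is.na(h$bc14[!ok])))
})

test_that("read-1 splitting uses fixed offsets and skips short reads", {
  r1 <- c(paste0(strrep("A", 16), strrep("C", 12)),
          paste0(strrep("G", 16), strrep("T", 12), "ACGT"),
          strrep("A", 27))
  cu <- extract_cell_umi(r1)
  expect_equal(cu$cell[1:2], c(strrep("A", 16), strrep("G", 16)))
  expect_equal(cu$umi[1:2], c(strrep("C", 12), strrep("T", 12)))
  expect_true(is.na(cu$cell[3]))
  expect_equal(cu$skipped, 1)
})

test_that("lineage assignment takes UMI majority with documented tie-breaks", {
  rec <- function(cell, lineage, umi) data.frame(cell = cell,
                                                 lineage = lineage,
                                                 umi = umi)
  # clear UMI majority
  r <- rbind(rec("c1", "L1", sprintf("u%d", 1:5)),
             rec("c1", "L2", sprintf("v%d", 1:2)))
  a <- assign_lineages(r)
  expect_equal(a$lineage, "L1")
  expect_equal(a$umi_support, 5)
  expect_equal(a$runner_up_support, 2)
  expect_false(a$ambiguous)

  # UMI tie broken by read count (L2 has duplicate reads of same UMIs)
  r2 <- rbind(rec("c1", "L1", c("u1", "u2")),
              rec("c1", "L2", c("v1", "v2", "v1")))
  a2 <- assign_lineages(r2)
  expect_equal(a2$lineage, "L2")
  expect_false(a2$ambiguous)

  # full tie -> lexicographically smallest, flagged ambiguous
  r3 <- rbind(rec("c1", "L2", c("u1", "u2", "u3")),
              rec("c1", "L1", c("v1", "v2", "v3")))
  a3 <- assign_lineages(r3)
  expect_equal(a3$lineage, "L1")
  expect_true(a3$ambiguous)
  expect_equal(a3$runner_up_support, 3)

  expect_equal(nrow(assign_lineages(rec(character(0), character(0),
                                        character(0)))), 0)
})

test_that("lineage assignment is independent of record order", {
  set.seed(13)
  rec <- data.frame(
    cell = sample(sprintf("c%02d", 1:10), 300, TRUE),
    lineage = sample(c("L1", "L2", "L3"), 300, TRUE),
    umi = sample(sprintf("u%02d", 1:30), 300, TRUE))
  a <- assign_lineages(rec)
  for (i in 1:5) {
    b <- assign_lineages(rec[sample(nrow(rec)), ])
    expect_identical(b[order(b$cell), ], a[order(a$cell), ])
  }
})

test_that("end-to-end retrieval recovers every cell at zero error rate", {
  wl <- make_whitelist(20, 50, seed = 2)
  set.seed(3)
  cells <- data.frame(cell = sprintf("c%03d", 1:100),
                      lineage = sample(1000, 100, TRUE))
  out <- write_reads(cells, wl, withr::local_tempdir(), error_rate = 0,
                     reads_per_cell = 5, seed = 3)
  tr <- trace_lineages(out$r1, out$r2, wl)
  m <- merge(tr$table, out$truth, by.x = "cell", by.y = "cell_barcode")
  expect_equal(nrow(m), 100)
  expect_true(all(m$lineage.x == m$lineage_id))
  expect_equal(tr$stats$accepted, tr$stats$reads_total)
})

test_that("trace output files are written on request", {
  wl <- make_whitelist(5, 5, seed = 1)
  cells <- data.frame(cell = "c1", lineage = 7)
  out <- write_reads(cells, wl, withr::local_tempdir(), seed = 2)
  d <- withr::local_tempdir()
  trace_lineages(out$r1, out$r2, wl, out_dir = d)
  expect_true(file.exists(file.path(d, "cell_lineage.tsv")))
  st <- jsonlite::read_json(file.path(d, "trace_stats.json"))
  expect_equal(st$cells_assigned, 1)
})
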