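#' Write synthetic paired-end cassette reads
#'
#' Emits 10x-style paired FASTQ for sampled cells: read 1 is a 16-nt cell
#' barcode followed by a 12-nt UMI; read 2 is a random 5' flank, the 48-nt
#' `bc14 + TGGT + bc30` cassette, and a poly-A-like tail padding the read
#' to `read2_length`. Substitution errors are injected i.i.d. per base of
#' read 2 at `error_rate`; read 1 is left exact (cell-barcode whitelist
#' matching is out of scope, so synthetic cell barcodes are error-free by
#' design). Output is gzip-compressed, Phred+33 qualities fixed at 'I'.
#'
#' @param cells data.frame with columns `cell` (id) and `lineage`
#'   (1-based pool index, mapped to a whitelist pair by
#'   [lineage_cassette()]).
#' @param wl A [make_whitelist()] object; `max(lineage)` must not exceed
#'   `length(wl$bc14) * length(wl$bc30)`.
#' @param dir Output directory; `R1.fastq.gz` and `R2.fastq.gz` are
#'   written there.
#' @param error_rate Per-base substitution probability on read 2.
#' @param reads_per_cell Cassette reads emitted per cell, each with its
#'   own UMI.
#' @param read2_length Total read-2 length (flank + 48 + tail); must be at
#'   least `flank5 + 48`.
#' @param flank5 Length of the random 5' flank preceding the cassette.
#' @param seed Integer RNG seed; fixed seed gives byte-identical files.
#' @return Invisibly, a list with `r1`, `r2` (paths) and `truth`
#'   (data.frame `cell`, `cell_barcode`, `lineage` index, `lineage_id`
#'   `"bc14:bc30"` string).
#' @export
write_reads <- function(cells, wl, dir, error_rate = 0,
                        reads_per_cell = 5L, read2_length = 90L,
                        flank5 = 10L, seed = 1L) {
  stopifnot(inherits(wl, "whitelist"),
            all(c("cell", "lineage") %in% names(cells)),
            error_rate >= 0, error_rate < 1, reads_per_cell >= 1)
  if (read2_length < flank5 + 48L)
    stop("read2_length must be >= flank5 + 48 (the cassette length)")
  if (anyNA(cells$lineage)) stop("every cell must have a lineage barcode")
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  n_cells <- nrow(cells)
  cas <- lineage_cassette(wl, cells$lineage)
  cell_bc <- random_kmers(n_cells, 16L)

  n_reads <- n_cells * reads_per_cell
  cell_of_read <- rep(seq_len(n_cells), each = reads_per_cell)
  umi <- random_kmers_with_replacement(n_reads, 12L)
  r1 <- paste0(cell_bc[cell_of_read], umi)

  flank <- random_kmers_with_replacement(n_reads, flank5)
  tail_len <- read2_length - flank5 - 48L
  tail <- if (tail_len > 0) strrep("A", tail_len) else ""
  r2 <- paste0(flank, cas$cassette[cell_of_read], tail)
  if (error_rate > 0) r2 <- inject_substitutions(r2, error_rate)

  ids <- sprintf("%s_r%03d", cells$cell[cell_of_read],
                 rep(seq_len(reads_per_cell), times = n_cells))
  f1 <- file.path(dir, "R1.fastq.gz"); f2 <- file.path(dir, "R2.fastq.gz")
  write_fastq(f1, ids, r1)
  write_fastq(f2, ids, r2)
  invisible(list(
    r1 = f1, r2 = f2,
    truth = data.frame(cell = cells$cell, cell_barcode = cell_bc,
                       lineage = cells$lineage, lineage_id = cas$lineage,
                       stringsAsFactors = FALSE)))
}

# n random k-mers, duplicates allowed (UMIs, flanks)
random_kmers_with_replacement <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), ncol = k)
  apply(m, 1L, paste0, collapse = "")
}

# i.i.d. substitutions at `rate`, each to a uniformly random *different* base
inject_substitutions <- function(seqs, rate) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  hit <- which(matrix(runif(length(chars)) < rate, nrow = nrow(chars)))
  if (length(hit)) {
    old <- chars[hit]
    # shift by 1-3 positions in the base alphabet: always a different base
    pos <- match(old, c("A", "C", "G", "T"))
    chars[hit] <- c("A", "C", "G", "T")[
      ((pos - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  apply(chars, 1L, paste0, collapse = "")
}

write_fastq <- function(path, ids, seqs) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                strrep("I", nchar(seqs)))
  writeLines(rec, con)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character vectors (sequences named by record id).
#'
#' @param r1,r2 Paths to the two FASTQ(.gz) files.
#' @return List with character vectors `r1` and `r2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2))
    stop("read 1 and read 2 files have different record counts")
  list(r1 = setNames(as.character(s1), names(s1)),
       r2 = setNames(as.character(s2), names(s2)))
}
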