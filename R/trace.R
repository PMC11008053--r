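#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming("TGGT", "TGAT") # 1
#' @export
hamming <- function(a, b) hamming_cpp(a, b)

#' Locate the TGGT anchor in a read-2 sequence
#'
#' Searches for the 4-nt `TGGT` anchor allowing at most one mismatch,
#' restricted to positions with at least 14 nt upstream (the putative
#' bc14) and 30 nt downstream (the putative bc30). Exact matches are
#' preferred over 1-mismatch matches; among equals the leftmost valid
#' position wins.
#'
#' @param seq Character vector of read-2 sequences.
#' @return Integer vector of 1-based anchor start positions (`NA` where no
#'   valid position exists).
#' @export
find_anchor <- function(seq) {
  p <- vapply(seq, find_anchor_cpp, integer(1), USE.NAMES = FALSE)
  ifelse(p < 0L, NA_integer_, p + 1L)
}

#' Whitelist-correct a putative barcode
#'
#' A putative barcode already in the vocabulary is returned unchanged.
#' Otherwise it is replaced by the vocabulary member at Hamming distance
#' one — but only if that member is unique; with zero or two or more
#' distance-1 neighbours the barcode is uncorrectable and `NA` is
#' returned.
#'
#' @param putative Character scalar; length must match the vocabulary
#'   word length.
#' @param vocabulary Character vector of legal barcodes.
#' @return The corrected barcode, or `NA_character_`.
#' @export
correct_barcode <- function(putative, vocabulary) {
  as.character(correct_barcode_cpp(putative, vocabulary))
}

#' Parse cassette reads against a whitelist
#'
#' For each read-2 sequence: locate the anchor ([find_anchor()]), take the
#' 14 nt before it as putative bc14 and the 30 nt after it as putative
#' bc30, then apply the retrieval acceptance logic — a whitelisted pair is
#' accepted as-is; if exactly one barcode is absent it is corrected on its
#' own ([correct_barcode()]); if both are absent, bc14 is corrected first
#' and bc30 is attempted only when bc14 correction succeeded. Reads whose
#' barcodes cannot both be placed in the whitelist are rejected, so an
#' accepted hit always carries whitelisted barcodes.
#'
#' @param read2 Character vector of read-2 sequences.
#' @param wl A [make_whitelist()] / [read_whitelist()] object.
#' @return data.frame, one row per read: `status` (`"ok"`, `"no_anchor"`,
#'   `"rejected"`), `anchor_pos` (1-based), `anchor_mismatches`, `bc14`,
#'   `bc30`, `bc14_corrected`, `bc30_corrected`, `lineage`
#'   (`"bc14:bc30"` or `NA`).
#' @export
parse_reads <- function(read2, wl) {
  stopifnot(inherits(wl, "whitelist"))
  df <- parse_reads_cpp(read2, wl$bc14, wl$bc30)
  df$status <- c("ok", "no_anchor", "rejected")[df$status + 1L]
  df$anchor_pos <- ifelse(df$anchor_pos < 0L, NA_integer_,
                          df$anchor_pos + 1L)
  df$lineage <- ifelse(df$status == "ok",
                       paste(df$bc14, df$bc30, sep = ":"), NA_character_)
  df
}

#' Split read-1 sequences into cell barcode and UMI
#'
#' Fixed-offset split of 10x-style read 1: positions 1-16 are the cell
#' barcode, 17-28 the UMI; trailing bases are ignored. Reads shorter than
#' 28 nt are skipped (returned as `NA`) and counted.
#'
#' @param read1 Character vector of read-1 sequences.
#' @return List with character vectors `cell`, `umi` (NA for skipped
#'   reads) and the integer `skipped` count.
#' @export
extract_cell_umi <- function(read1) {
  ok <- nchar(read1) >= 28L
  cell <- ifelse(ok, substr(read1, 1L, 16L), NA_character_)
  umi <- ifelse(ok, substr(read1, 17L, 28L), NA_character_)
  list(cell = cell, umi = umi, skipped = sum(!ok))
}

#' Assign each cell its most abundant lineage barcode
#'
#' Per cell, each candidate lineage's abundance is the number of distinct
#' UMIs supporting it (deduplicating PCR copies); the most abundant
#' lineage is assigned. UMI-count ties are broken by read count, then by
#' the lexicographically smallest lineage id; a tie that survives to the
#' lexicographic rule is flagged ambiguous. Cells with no surviving record
#' are absent from the table.
#'
#' @param records data.frame with columns `cell`, `umi`, `lineage` (one
#'   row per accepted read).
#' @return data.frame, one row per cell: `cell`, `lineage`, `umi_support`,
#'   `read_support`, `runner_up_support` (second-best UMI support, 0 if
#'   none), `ambiguous`.
#' @export
assign_lineages <- function(records) {
  cols <- c("cell", "umi", "lineage")
  stopifnot(all(cols %in% names(records)))
  records <- records[complete.cases(records[, cols]), cols, drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(cell = character(0), lineage = character(0),
                      umi_support = integer(0), read_support = integer(0),
                      runner_up_support = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  key <- paste(records$cell, records$lineage, sep = "\r")
  read_support <- table(key)
  dedup <- !duplicated(paste(key, records$umi, sep = "\r"))
  umi_support <- table(key[dedup])
  k <- names(read_support)
  sp <- strsplit(k, "\r", fixed = TRUE)
  per <- data.frame(
    cell = vapply(sp, `[`, "", 1L),
    lineage = vapply(sp, `[`, "", 2L),
    umi_support = as.integer(umi_support[k]),
    read_support = as.integer(read_support[k]),
    stringsAsFactors = FALSE)
  ord <- order(per$cell, -per$umi_support, -per$read_support, per$lineage)
  per <- per[ord, , drop = FALSE]
  top <- !duplicated(per$cell)
  res <- per[top, , drop = FALSE]
  nxt <- per[which(top) + 1L, , drop = FALSE]       # may index past the end
  same_cell <- !is.na(nxt$cell) & nxt$cell == res$cell
  res$runner_up_support <- ifelse(same_cell, nxt$umi_support, 0L)
  res$ambiguous <- same_cell &
    nxt$umi_support == res$umi_support &
    nxt$read_support == res$read_support
  rownames(res) <- NULL
  res
}

#' Recover cell lineages from paired FASTQ
#'
#' End-to-end barcode retrieval: read the pair of FASTQ files, split read
#' 1 into cell barcode and UMI, parse read 2 against the whitelist with
#' anchor search and Hamming-1 correction, and assign each cell its most
#' abundant lineage.
#'
#' @param r1,r2 Paths to the paired FASTQ(.gz) files.
#' @param wl A `whitelist` object (or give `bc14_file`/`bc30_file`).
#' @param bc14_file,bc30_file Alternative to `wl`: whitelist text files.
#' @param out_dir Optional directory; if given, `cell_lineage.tsv` and
#'   `trace_stats.json` are written there.
#' @return List with `table` (the [assign_lineages()] data.frame) and
#'   `stats` (reads seen, short read-1 records, anchors found, corrected
#'   and rejected read counts, cells assigned).
#' @export
trace_lineages <- function(r1, r2, wl = NULL, bc14_file = NULL,
                           bc30_file = NULL, out_dir = NULL) {
  if (is.null(wl)) wl <- read_whitelist(bc14_file, bc30_file)
  fq <- read_fastq_pair(r1, r2)
  cu <- extract_cell_umi(fq$r1)
  hits <- parse_reads(fq$r2, wl)
  keep <- hits$status == "ok" & !is.na(cu$cell)
  table <- assign_lineages(data.frame(cell = cu$cell[keep],
                                      umi = cu$umi[keep],
                                      lineage = hits$lineage[keep],
                                      stringsAsFactors = FALSE))
  stats <- list(
    reads_total = length(fq$r2),
    read1_short = cu$skipped,
    anchors_found = sum(hits$status != "no_anchor"),
    accepted = sum(hits$status == "ok"),
    rejected = sum(hits$status == "rejected"),
    no_anchor = sum(hits$status == "no_anchor"),
    bc14_corrected = sum(hits$bc14_corrected, na.rm = TRUE),
    bc30_corrected = sum(hits$bc30_corrected, na.rm = TRUE),
    cells_assigned = nrow(table),
    cells_ambiguous = sum(table$ambiguous))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(table, file.path(out_dir, "cell_lineage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(stats, file.path(out_dir, "trace_stats.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(table = table, stats = stats)
}
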