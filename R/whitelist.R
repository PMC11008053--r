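#' Construct a lineage-barcode whitelist
#'
#' Builds the legal bc14/bc30 vocabularies that define a valid expressed
#' lineage barcode. A cassette is `bc14 + "TGGT" + bc30`, 48 nt in total.
#' Words are uniform random ACGT strings, distinct within each vocabulary.
#' bc14 words are constrained so that the composed cassette
#' `bc14 + TGGT + bc30` cannot present a spurious exact anchor upstream of
#' the true one: no bc14 contains `TGGT`, nor ends in `TGG` (which would
#' form `TGGT` with the anchor's first base). bc30 words are
#' unconstrained (downstream occurrences are never preferred by the
#' leftmost-exact anchor search). Hamming-distance-1 collisions between words are *not*
#' excluded: correction ambiguity is handled downstream, as in real
#' vocabularies.
#'
#' @param n14 Number of 14-nt bc14 words (the reference vocabulary has 100).
#' @param n30 Number of 30-nt bc30 words (the reference vocabulary has
#'   100,000).
#' @param seed Integer RNG seed; the same seed reproduces the whitelist
#'   exactly.
#' @return An object of class `whitelist`: a list with character vectors
#'   `bc14`, `bc30` and the constant `anchor = "TGGT"`.
#' @examples
#' wl <- make_whitelist(100, 1000, seed = 1)
#' nchar(wl$bc14[1]) # 14
#' @export
make_whitelist <- function(n14, n30, seed = 1L) {
  stopifnot(n14 >= 1, n30 >= 1)
  if (n14 > 4^14 / 2) stop("n14 too large for distinct anchor-free 14-mers")
  if (n30 > 4^15) stop("n30 too large for distinct 30-mers")
  set.seed(seed)
  bc14 <- random_kmers(n14, 14L, forbid = "TGGT|TGG$")
  bc30 <- random_kmers(n30, 30L)
  structure(list(bc14 = bc14, bc30 = bc30, anchor = "TGGT"),
            class = "whitelist")
}

# n distinct random k-mers; optionally rejecting words matching `forbid`
random_kmers <- function(n, k, forbid = NULL) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(c("A", "C", "G", "T"), (need + 8L) * k, replace = TRUE),
                ncol = k)
    w <- apply(m, 1L, paste0, collapse = "")
    if (!is.null(forbid)) w <- w[!grepl(forbid, w)]
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' @export
print.whitelist <- function(x, ...) {
  cat("Lineage-barcode whitelist:", length(x$bc14), "bc14 x",
      length(x$bc30), "bc30 words, anchor", x$anchor, "\n")
  invisible(x)
}

#' Compose the 48-nt cassette for a lineage index
#'
#' Lineage index `i` (1-based, `i <= n14 * n30`) maps deterministically to
#' the pair (bc14, bc30): bc14 index `(i - 1) %/% n30 + 1`, bc30 index
#' `(i - 1) %% n30 + 1`.
#'
#' @param wl A [make_whitelist()] object.
#' @param i Integer vector of lineage indices.
#' @return List with `bc14`, `bc30`, `cassette` (48-nt string) and
#'   `lineage` (`"bc14:bc30"` id) character vectors.
#' @export
lineage_cassette <- function(wl, i) {
  n30 <- length(wl$bc30)
  stopifnot(all(i >= 1), all(i <= length(wl$bc14) * n30))
  b14 <- wl$bc14[(i - 1L) %/% n30 + 1L]
  b30 <- wl$bc30[(i - 1L) %% n30 + 1L]
  list(bc14 = b14, bc30 = b30,
       cassette = paste0(b14, wl$anchor, b30),
       lineage = paste(b14, b30, sep = ":"))
}

#' Read a whitelist from plain-text files
#'
#' @param bc14_file,bc30_file Paths to text files, one barcode per line.
#' @return A `whitelist` object.
#' @export
read_whitelist <- function(bc14_file, bc30_file) {
  bc14 <- readLines(bc14_file)
  bc30 <- readLines(bc30_file)
  bc14 <- bc14[nzchar(bc14)]; bc30 <- bc30[nzchar(bc30)]
  stopifnot(all(nchar(bc14) == 14L), all(nchar(bc30) == 30L),
            !anyDuplicated(bc14), !anyDuplicated(bc30))
  structure(list(bc14 = bc14, bc30 = bc30, anchor = "TGGT"),
            class = "whitelist")
}

#' Write a whitelist to plain-text files
#'
#' @param wl A `whitelist` object.
#' @param dir Output directory; files `bc14.txt` and `bc30.txt` are created.
#' @return Invisibly, the two file paths.
#' @export
write_whitelist <- function(wl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f14 <- file.path(dir, "bc14.txt"); f30 <- file.path(dir, "bc30.txt")
  writeLines(wl$bc14, f14); writeLines(wl$bc30, f30)
  invisible(c(f14, f30))
}
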