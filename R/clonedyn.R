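#' Label cells by the fate of their lineage
#'
#' Retrospective labelling: a cell is "tolerant" iff its lineage barcode
#' belongs to the set of lineages that survived selection, "sensitive"
#' otherwise. Cells whose lineage assignment was ambiguous are excluded
#' (and counted), so class comparisons never rest on uncertain barcodes.
#'
#' @param table A [assign_lineages()] data.frame (`cell`, `lineage`,
#'   `ambiguous`).
#' @param tolerant_set Character vector of tolerant lineage ids.
#' @return List with `labels` (named character vector, cell -> class) and
#'   `excluded_ambiguous` count.
#' @export
label_cells <- function(table, tolerant_set) {
  if (length(tolerant_set) == 0) stop("tolerant_set must be non-empty")
  amb <- table$ambiguous
  kept <- table[!amb, , drop = FALSE]
  labels <- ifelse(kept$lineage %in% tolerant_set, "tolerant", "sensitive")
  list(labels = setNames(labels, kept$cell),
       excluded_ambiguous = sum(amb))
}

#' Log-normalize a count matrix
#'
#' Per-cell depth normalization: `ln(1 + scale * count / cell_total)`.
#'
#' @param counts genes x cells count matrix.
#' @param scale Size factor target (default 10,000).
#' @return Dense matrix of normalized values with the input dimnames.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("lognormalize: zero-total cell present")
  m <- as.matrix(counts)
  log1p(sweep(m, 2L, scale / total, `*`))
}

#' Wilcoxon rank-sum marker testing between two cell classes
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of tolerant vs sensitive
#' cells on log-normalized expression: exact null distribution when both
#' groups have at most `exact_max` cells and the gene has no tied values,
#' otherwise the normal approximation with tie correction and continuity
#' correction. Fold changes are computed on de-transformed means
#' (`expm1`), `log2((mu_t + eps) / (mu_s + eps))`. P-values are BH-adjusted
#' across genes; the marker panel is the set of genes with FDR below
#' `fdr_cut`, split by fold-change sign.
#'
#' @param norm genes x cells matrix of `ln(1+x)` normalized expression.
#' @param labels Character/factor vector over columns with values
#'   "tolerant"/"sensitive" (cells with other/NA labels are dropped).
#' @param fdr_cut Panel FDR threshold (default 0.05).
#' @param eps Fold-change pseudocount (default 1e-9).
#' @param exact_max Largest group size for the exact test (default 10).
#' @return Object of class `marker_table`: data.frame per gene with
#'   `gene`, `log2fc`, `p`, `fdr`, `pct_tolerant`, `pct_sensitive`;
#'   attributes `up` and `down` hold the significant gene panels (up =
#'   higher in tolerant).
#' @export
rank_sum_markers <- function(norm, labels, fdr_cut = 0.05, eps = 1e-9,
                             exact_max = 10) {
  labels <- as.character(labels)
  keep <- labels %in% c("tolerant", "sensitive")
  norm <- norm[, keep, drop = FALSE]
  labels <- labels[keep]
  g1 <- labels == "tolerant"
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 == 0 || n2 == 0)
    stop("rank_sum_markers: both classes must be non-empty")
  N <- n1 + n2
  res <- t(apply(norm, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[g1]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    has_ties <- any(ties > 1)
    if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
      p <- 2 * min(pwilcox(U, n1, n2), pwilcox(U - 1, n1, n2,
                                               lower.tail = FALSE))
      p <- min(1, p)
    } else {
      mu <- n1 * n2 / 2
      tie_term <- sum(ties^3 - ties) / (N * (N - 1))
      sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
      if (sigma == 0) {
        p <- 1
      } else {
        z <- U - mu
        z <- sign(z) * max(0, abs(z) - 0.5) / sigma   # continuity correction
        p <- 2 * pnorm(-abs(z))
      }
    }
    m1 <- mean(expm1(v[g1])); m2 <- mean(expm1(v[!g1]))
    c(log2fc = log2((m1 + eps) / (m2 + eps)), p = p,
      pct_tolerant = mean(v[g1] > 0), pct_sensitive = mean(v[!g1] > 0))
  }))
  out <- data.frame(gene = rownames(norm), res, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$fdr <- p.adjust(out$p, method = "BH")
  sig <- out$fdr < fdr_cut
  structure(out[, c("gene", "log2fc", "p", "fdr", "pct_tolerant",
                    "pct_sensitive")],
            up = out$gene[sig & out$log2fc > 0],
            down = out$gene[sig & out$log2fc < 0],
            class = c("marker_table", "data.frame"))
}

#' Per-timepoint clone frequencies
#'
#' The frequency of a lineage at a timepoint is simply the number of cells
#' assigned to it divided by the total number of cells sequenced at that
#' timepoint; lineages unobserved at a timepoint get 0.
#'
#' @param cells data.frame with columns `lineage` and `timepoint`.
#' @return Matrix lineages x timepoints of frequencies (columns sum to
#'   <= 1 relative to all cells; here every cell carries a lineage so
#'   columns sum to 1).
#' @export
clone_frequencies <- function(cells) {
  stopifnot(all(c("lineage", "timepoint") %in% names(cells)))
  tp <- sort(unique(cells$timepoint))
  if (length(tp) == 0) stop("no timepoints present")
  tab <- table(factor(cells$lineage), factor(cells$timepoint, levels = tp))
  n <- colSums(tab)
  if (any(n == 0)) stop("empty timepoint")
  sweep(unclass(tab), 2L, n, `/`)
}

#' Classify tolerant clones as dominant or neutral
#'
#' For each lineage, a two-proportion z-test (pooled, no continuity
#' correction) compares its cell-count share at the first and last
#' timepoints. A clone is called dominant iff the BH-adjusted p-value is
#' below `fdr_cut`, its frequency fold change (last / first) is at least
#' `min_fc`, and the change is an increase; everything else — including
#' lineages with zero counts at both ends — is neutral.
#'
#' @param counts_first,counts_last Named integer vectors of per-lineage
#'   cell counts at the first and last timepoints (names = lineage ids;
#'   a lineage missing from one vector counts 0 there).
#' @param n_first,n_last Total cells sequenced at the two timepoints;
#'   default `sum()` of the count vectors.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param min_fc Minimum frequency fold change (default 5).
#' @return data.frame per lineage: `lineage`, `freq_first`, `freq_last`,
#'   `fold_change`, `p`, `fdr`, `dynamics` ("dominant"/"neutral").
#' @export
classify_dominant <- function(counts_first, counts_last,
                              n_first = sum(counts_first),
                              n_last = sum(counts_last),
                              fdr_cut = 0.05, min_fc = 5) {
  lin <- union(names(counts_first), names(counts_last))
  if (length(lin) == 0) stop("no lineages to classify")
  x1 <- ifelse(is.na(counts_first[lin]), 0, counts_first[lin])
  x2 <- ifelse(is.na(counts_last[lin]), 0, counts_last[lin])
  p1 <- x1 / n_first; p2 <- x2 / n_last
  pooled <- (x1 + x2) / (n_first + n_last)
  se <- sqrt(pooled * (1 - pooled) * (1 / n_first + 1 / n_last))
  z <- ifelse(se > 0, (p2 - p1) / se, 0)
  p <- 2 * pnorm(-abs(z))
  fdr <- p.adjust(p, method = "BH")
  fc <- ifelse(p1 > 0, p2 / p1, ifelse(p2 > 0, Inf, 1))
  dom <- fdr < fdr_cut & fc >= min_fc & p2 > p1
  data.frame(lineage = lin, freq_first = p1, freq_last = p2,
             fold_change = fc, p = p, fdr = fdr,
             dynamics = ifelse(dom, "dominant", "neutral"),
             stringsAsFactors = FALSE, row.names = NULL)
}
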