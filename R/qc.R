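#' Per-cell QC metrics
#'
#' @param counts genes x cells count matrix (base or sparse).
#' @param mito Logical mask over rows marking mitochondrial genes, or a
#'   character prefix (default `"MT-"`) matched against rownames.
#' @return data.frame per cell: `cell`, `total_umi`, `mito_ratio`,
#'   `genes_detected`, `gene_umi_ratio`.
#' @export
cell_qc_metrics <- function(counts, mito = "MT-") {
  if (is.character(mito))
    mito <- startsWith(rownames(counts), mito)
  stopifnot(length(mito) == nrow(counts))
  total <- Matrix::colSums(counts)
  mt <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  detected <- Matrix::colSums(counts > 0)
  data.frame(cell = colnames(counts),
             total_umi = as.numeric(total),
             mito_ratio = ifelse(total > 0, mt / total, 0),
             genes_detected = as.numeric(detected),
             gene_umi_ratio = ifelse(total > 0, detected / total, 0),
             stringsAsFactors = FALSE)
}

#' Minimum-depth cell filter
#'
#' Cells with *fewer* than `min_umi` total UMIs are discarded; a cell at
#' exactly the threshold is kept.
#'
#' @param counts genes x cells count matrix.
#' @param min_umi Depth threshold (default 5,000 UMIs).
#' @return Character vector of kept cell ids.
#' @export
umi_filter <- function(counts, min_umi = 5000) {
  total <- Matrix::colSums(counts)
  colnames(counts)[total >= min_umi]
}

#' Loess-residual outlier flagging
#'
#' Fits a local linear regression of a per-cell ratio on log total UMI
#' count, converts residuals to robust z-scores
#' (`(r - median) / (1.4826 * MAD)`), computes one-tailed normal p-values
#' in the requested tail, adjusts them by Benjamini-Hochberg, and flags
#' cells with FDR below the cut. With constant input (MAD = 0) no cell
#' can deviate from the trend and nothing is flagged.
#'
#' @param x Per-cell log total UMI (natural log).
#' @param y Per-cell ratio (e.g. mitochondrial fraction).
#' @param tail `"upper"` flags unusually high ratios, `"lower"` unusually
#'   low ones.
#' @param fdr_cut FDR threshold (default 0.1).
#' @param span Loess smoothing fraction (default 0.75, local-linear).
#' @return data.frame per cell: `residual`, `z`, `p`, `fdr`, `flagged`.
#' @export
loess_outlier_filter <- function(x, y, tail = c("upper", "lower"),
                                 fdr_cut = 0.1, span = 0.75) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y))
  if (length(x) < 20)
    stop("loess outlier filter needs at least 20 cells")
  fit <- loess(y ~ x, span = span, degree = 1,
               family = "gaussian", surface = "direct")
  r <- y - predict(fit, x)
  s <- mad(r)
  if (s == 0) {
    z <- rep(0, length(r))
  } else {
    z <- (r - median(r)) / s
  }
  p <- if (tail == "upper") pnorm(z, lower.tail = FALSE) else pnorm(z)
  fdr <- p.adjust(p, method = "BH")
  flagged <- s > 0 & fdr < fdr_cut
  data.frame(residual = r, z = z, p = p, fdr = fdr, flagged = flagged)
}

#' Mitochondrial-fraction cell filter
#'
#' Applies [loess_outlier_filter()] with y = mitochondrial count fraction
#' against log total UMI, upper tail: cells whose mitochondrial load is
#' significantly above the depth-matched trend (FDR < `fdr_cut`) are
#' removed.
#'
#' @inheritParams cell_qc_metrics
#' @param fdr_cut FDR threshold (default 0.1).
#' @return List with `kept` (cell ids), `report` (the per-cell filter
#'   data.frame).
#' @export
mito_filter <- function(counts, mito = "MT-", fdr_cut = 0.1) {
  qc <- cell_qc_metrics(counts, mito)
  rep <- loess_outlier_filter(log(qc$total_umi), qc$mito_ratio,
                              tail = "upper", fdr_cut = fdr_cut)
  list(kept = qc$cell[!rep$flagged], report = cbind(qc, rep))
}

#' Doublet / concentrated-library cell filter
#'
#' Applies [loess_outlier_filter()] with y = detected genes per UMI
#' against log total UMI, lower tail: cells whose gene diversity is
#' significantly below the depth-matched trend — doublets and cells whose
#' high UMI count is concentrated in few genes — are removed.
#'
#' @inheritParams mito_filter
#' @return List with `kept` (cell ids), `report`.
#' @export
doublet_filter <- function(counts, mito = "MT-", fdr_cut = 0.1) {
  qc <- cell_qc_metrics(counts, mito)
  rep <- loess_outlier_filter(log(qc$total_umi), qc$gene_umi_ratio,
                              tail = "lower", fdr_cut = fdr_cut)
  list(kept = qc$cell[!rep$flagged], report = cbind(qc, rep))
}

#' Low-expression gene filter
#'
#' A gene is excluded only when *all three* conditions hold: expressed in
#' fewer than `min_cells` cells, expressed in less than `min_frac` of all
#' cells, and mean expression over all cells below `min_mean` UMIs.
#'
#' @param counts genes x cells count matrix.
#' @param min_cells Minimum expressing-cell count (default 50).
#' @param min_frac Minimum expressing-cell fraction (default 0.05).
#' @param min_mean Minimum mean UMI over all cells (default 1.12).
#' @return Character vector of kept gene ids.
#' @export
gene_filter <- function(counts, min_cells = 50, min_frac = 0.05,
                        min_mean = 1.12) {
  n_expr <- Matrix::rowSums(counts > 0)
  mean_expr <- Matrix::rowMeans(counts)
  drop <- n_expr < min_cells & n_expr / ncol(counts) < min_frac &
    mean_expr < min_mean
  rownames(counts)[!drop]
}

#' Full QC pipeline
#'
#' Applies the filters in sequence: UMI depth, mitochondrial fraction,
#' doublet ratio, then the gene filter on the surviving cells.
#'
#' @inheritParams mito_filter
#' @param min_umi Depth threshold for [umi_filter()].
#' @param min_cells,min_frac,min_mean Passed to [gene_filter()].
#' @return List with `counts` (filtered matrix), `kept_cells`,
#'   `kept_genes`, and `report` (per-cell metrics with per-filter flags
#'   for cells surviving the depth filter).
#' @export
run_qc <- function(counts, mito = "MT-", min_umi = 5000, fdr_cut = 0.1,
                   min_cells = 50, min_frac = 0.05, min_mean = 1.12) {
  deep <- umi_filter(counts, min_umi)
  m <- counts[, deep, drop = FALSE]
  mf <- mito_filter(m, mito, fdr_cut)
  m <- m[, mf$kept, drop = FALSE]
  df <- doublet_filter(m, mito, fdr_cut)
  m <- m[, df$kept, drop = FALSE]
  genes <- gene_filter(m, min_cells, min_frac, min_mean)
  m <- m[genes, , drop = FALSE]
  report <- mf$report[, c("cell", "total_umi", "mito_ratio",
                          "genes_detected", "gene_umi_ratio")]
  report$fdr_mito <- mf$report$fdr
  report$pass_mito <- !mf$report$flagged
  report$fdr_doublet <- df$report$fdr[match(report$cell, df$report$cell)]
  report$pass_doublet <- report$cell %in% df$kept
  list(counts = m, kept_cells = colnames(m), kept_genes = genes,
       report = report)
}
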