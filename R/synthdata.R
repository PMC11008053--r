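#' Configuration for a barcoded founder population
#'
#' Parameters of low-MOI lentiviral barcoding of a plated cell population.
#' Defaults reproduce the reference experiment: 50,000 cells transduced at
#' MOI 0.05 (so ~5% of cells carry at least one integration) from a
#' 10-million-barcode pool.
#'
#' @param n_cells Number of plated cells.
#' @param moi Mean lentiviral integrations per cell (Poisson rate).
#' @param library_size Number of distinct barcodes in the lentiviral pool.
#' @param n14,n30 bc14/bc30 vocabulary sizes; `library_size` must not
#'   exceed `n14 * n30`.
#' @param seed Integer RNG seed.
#' @return A `population_config` list.
#' @export
population_config <- function(n_cells = 50000L, moi = 0.05,
                              library_size = 1e7, n14 = 100L, n30 = 1e5,
                              seed = 1L) {
  stopifnot(n_cells > 0, moi >= 0, library_size >= 1,
            library_size <= n14 * n30)
  structure(list(n_cells = as.integer(n_cells), moi = moi,
                 library_size = library_size, n14 = as.integer(n14),
                 n30 = n30, seed = as.integer(seed)),
            class = "population_config")
}

#' Simulate lentiviral barcode integration
#'
#' Each cell receives `Poisson(moi)` integrations; every integration draws
#' a barcode uniformly (with replacement) from the pool, so barcode
#' collisions between founder cells are possible, as with a real
#' 10M-barcode library. A cell's reported lineage is its *first*
#' integration; cells with more than one integration are flagged so they
#' can be excluded downstream.
#'
#' @param cfg A [population_config()].
#' @return Object of class `founder_population`: list with `cells`
#'   (data.frame: `cell`, `n_integrations`, `barcode` = first-integration
#'   pool index or NA, `multi` flag), `integrations` (pool indices of all
#'   integration events) and `cfg`.
#' @examples
#' f <- simulate_infection(population_config(n_cells = 1000, seed = 3))
#' mean(f$cells$n_integrations > 0) # ~ 1 - exp(-0.05)
#' @export
simulate_infection <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  set.seed(cfg$seed)
  k <- rpois(cfg$n_cells, cfg$moi)
  total <- sum(k)
  draws <- if (total > 0) {
    ceiling(runif(total) * cfg$library_size)
  } else numeric(0)
  first <- rep(NA_real_, cfg$n_cells)
  if (total > 0) {
    idx <- which(k > 0)
    first[idx] <- draws[cumsum(k)[idx] - k[idx] + 1L]
  }
  cells <- data.frame(
    cell = sprintf("cell%06d", seq_len(cfg$n_cells)),
    n_integrations = k,
    barcode = first,
    multi = k > 1L,
    stringsAsFactors = FALSE)
  structure(list(cells = cells, integrations = draws, cfg = cfg),
            class = "founder_population")
}

#' @export
print.founder_population <- function(x, ...) {
  inf <- sum(x$cells$n_integrations > 0)
  cat(sprintf(
    "Founder population: %d cells, %d infected (%.2f%%), %d distinct barcodes\n",
    nrow(x$cells), inf, 100 * inf / nrow(x$cells),
    n_distinct_barcodes(x)))
  invisible(x)
}

#' Count distinct barcodes across all integration events
#'
#' @param founder A [simulate_infection()] result.
#' @return Integer count of unique pool barcodes present in the population.
#' @export
n_distinct_barcodes <- function(founder) {
  stopifnot(inherits(founder, "founder_population"))
  length(unique(founder$integrations))
}

#' Configuration for drug selection dynamics
#'
#' Defaults mirror the reference time course: of 2,336 founder lineages,
#' 8.2% (192) tolerate the drug; 2 of those are "dominant", expanding from
#' ~1% to a combined ~45% of the population by the last sampled day; cells
#' are sampled at days 0, 3, 6 and 9.
#'
#' @param frac_tolerant Fraction of founder lineages surviving selection.
#' @param n_dominant Number of tolerant lineages with a growth advantage.
#' @param advantage Per-interval multiplicative growth factor of dominant
#'   clones (relative abundance is multiplied by this between consecutive
#'   timepoints, then renormalized). The default 9 carries the two default
#'   dominant clones to a combined ~45% of the population by the last
#'   sampled day, the magnitude seen in the reference experiment.
#' @param timepoints Ordered day labels.
#' @param extinction_day Day at which sensitive lineages reach zero
#'   abundance (linear decay). The default 40 places extinction after the
#'   sampled window, as in the reference experiment where sensitive clones
#'   are still present at day 9 and gone only in the day-40 resistant
#'   line; neutral tolerant clones therefore keep a near-constant share
#'   across the sampled days.
#' @param cells_per_timepoint Cells sampled (multinomially) per day.
#' @param seed Integer RNG seed.
#' @return A `selection_config` list.
#' @export
selection_config <- function(frac_tolerant = 192 / 2336, n_dominant = 2L,
                             advantage = 9,
                             timepoints = c(0, 3, 6, 9),
                             extinction_day = 40,
                             cells_per_timepoint = 1000L, seed = 1L) {
  stopifnot(frac_tolerant > 0, frac_tolerant <= 1, n_dominant >= 0,
            advantage >= 1, length(timepoints) >= 2,
            !is.unsorted(timepoints, strictly = TRUE),
            extinction_day >= max(timepoints),
            cells_per_timepoint > 0)
  structure(list(frac_tolerant = frac_tolerant,
                 n_dominant = as.integer(n_dominant), advantage = advantage,
                 timepoints = timepoints, extinction_day = extinction_day,
                 cells_per_timepoint = as.integer(cells_per_timepoint),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Simulate clonal selection under drug treatment
#'
#' Tolerant lineages are drawn without replacement at rate
#' `frac_tolerant`; `n_dominant` of them additionally gain a multiplicative
#' growth `advantage` per inter-timepoint interval. Sensitive lineages
#' decay linearly to zero abundance at `extinction_day` (by default past
#' the sampled window, so they shrink but persist across the sampled
#' days). At each timepoint, `cells_per_timepoint` cells are sampled
#' multinomially from the lineage frequency vector.
#'
#' @param founder A [simulate_infection()] result (or a data.frame with
#'   columns `cell` and `barcode` giving one lineage per founder cell).
#' @param cfg A [selection_config()].
#' @return Object of class `clone_sim`: list with
#'   \describe{
#'     \item{classes}{data.frame `lineage`, `response`
#'       (tolerant/sensitive), `dynamics` (dominant/neutral/`NA` for
#'       sensitive lineages).}
#'     \item{freq}{true lineage-frequency matrix, lineages x timepoints
#'       (columns sum to 1).}
#'     \item{cells}{data.frame of sampled cells: `cell`, `lineage`
#'       (pool index), `timepoint`.}
#'     \item{timepoints}{the day labels.}
#'   }
#' @export
simulate_selection <- function(founder, cfg) {
  stopifnot(inherits(cfg, "selection_config"))
  cells <- if (inherits(founder, "founder_population")) founder$cells else founder
  cells <- cells[!is.na(cells$barcode) & cells$n_integrations %in% c(NA, 1) |
                   (!is.na(cells$barcode)), , drop = FALSE]
  cells <- cells[!is.na(cells$barcode), , drop = FALSE]
  if (nrow(cells) == 0) stop("founder population has no infected cells")
  set.seed(cfg$seed)
  tab <- table(cells$barcode)
  lineages <- as.numeric(names(tab))
  f0 <- as.numeric(tab) / sum(tab)
  L <- length(lineages)
  n_tol <- max(1L, round(cfg$frac_tolerant * L))
  if (cfg$n_dominant > n_tol)
    stop("n_dominant exceeds the number of tolerant lineages")
  tol_idx <- sample.int(L, n_tol)
  dom_idx <- if (cfg$n_dominant > 0) sample(tol_idx, cfg$n_dominant) else integer(0)
  response <- ifelse(seq_len(L) %in% tol_idx, "tolerant", "sensitive")
  dynamics <- rep(NA_character_, L)
  dynamics[tol_idx] <- "neutral"
  dynamics[dom_idx] <- "dominant"

  Tn <- length(cfg$timepoints)
  freq <- matrix(0, L, Tn,
                 dimnames = list(as.character(lineages),
                                 paste0("day", cfg$timepoints)))
  for (j in seq_len(Tn)) {
    w <- f0
    decay <- max(0, 1 - cfg$timepoints[j] / cfg$extinction_day)
    w[response == "sensitive"] <- w[response == "sensitive"] * decay
    w[dom_idx] <- w[dom_idx] * cfg$advantage^(j - 1)
    freq[, j] <- w / sum(w)
  }
  if (cfg$cells_per_timepoint > nrow(cells))
    stop("cells_per_timepoint exceeds the modelled population size")

  samp <- do.call(rbind, lapply(seq_len(Tn), function(j) {
    n <- as.vector(rmultinom(1, cfg$cells_per_timepoint, freq[, j]))
    data.frame(
      cell = sprintf("d%g_c%05d", cfg$timepoints[j],
                     seq_len(cfg$cells_per_timepoint)),
      lineage = rep(lineages, n),
      timepoint = cfg$timepoints[j],
      stringsAsFactors = FALSE)
  }))
  classes <- data.frame(lineage = lineages, response = response,
                        dynamics = dynamics, stringsAsFactors = FALSE)
  structure(list(classes = classes, freq = freq, cells = samp,
                 timepoints = cfg$timepoints, cfg = cfg),
            class = "clone_sim")
}

#' @export
print.clone_sim <- function(x, ...) {
  cat(sprintf(
    "Clone selection: %d lineages (%d tolerant, %d dominant), %d timepoints, %d cells\n",
    nrow(x$classes), sum(x$classes$response == "tolerant"),
    sum(x$classes$dynamics == "dominant", na.rm = TRUE),
    length(x$timepoints), nrow(x$cells)))
  invisible(x)
}

#' Configuration for the synthetic expression model
#'
#' Negative-binomial UMI counts with a marker program: `n_marker_up` genes
#' up-regulated (by `effect_log2fc` log2 units) in cells of tolerant
#' lineages, `n_marker_down` genes up-regulated in sensitive cells.
#' Baseline gene means are log-normal; dispersion is shared across genes.
#' A small block of mitochondrial genes carries a configurable fraction of
#' each cell's counts, inflated in a random subset of "damaged" cells, and
#' a fraction of cells are replaced by doublets (sums of two cells'
#' counts).
#'
#' @param n_genes Total genes (including `n_mito` mitochondrial ones).
#' @param n_marker_up Genes up in tolerant cells.
#' @param n_marker_down Genes up in sensitive cells.
#' @param effect_log2fc Marker effect size, log2 units.
#' @param nb_dispersion Negative-binomial dispersion (1/size); variance is
#'   `mu + dispersion * mu^2`.
#' @param mean_umi_per_cell Expected per-cell library size.
#' @param mito_frac_mean Baseline expected mitochondrial count fraction.
#' @param mito_frac_outlier Mitochondrial fraction in damaged outlier cells.
#' @param mito_outlier_rate Fraction of cells that are damaged outliers.
#' @param doublet_rate Fraction of cells replaced by synthetic doublets.
#' @param n_mito Number of mitochondrial genes (ids prefixed `MT-`).
#' @param seed Integer RNG seed for cell sampling (depths, counts,
#'   outliers, doublets).
#' @param param_seed Seed for the gene-level parameters (baseline means,
#'   marker placement). Defaults to `seed`; give several datasets the
#'   same `param_seed` and different `seed`s to simulate distinct cell
#'   samples from one shared transcriptome (e.g. independent cell lines).
#' @return An `expression_config` list.
#' @export
expression_config <- function(n_genes = 2000L, n_marker_up = 50L,
                              n_marker_down = 25L, effect_log2fc = 1,
                              nb_dispersion = 0.3,
                              mean_umi_per_cell = 10000,
                              mito_frac_mean = 0.05,
                              mito_frac_outlier = 0.4,
                              mito_outlier_rate = 0.01,
                              doublet_rate = 0.02, n_mito = 10L,
                              seed = 1L, param_seed = NULL) {
  stopifnot(n_genes > n_mito,
            n_marker_up + n_marker_down <= n_genes - n_mito,
            effect_log2fc >= 0, nb_dispersion > 0, mean_umi_per_cell > 0,
            mito_frac_mean >= 0, mito_frac_mean <= 1,
            mito_frac_outlier >= 0, mito_frac_outlier <= 1,
            mito_outlier_rate >= 0, mito_outlier_rate <= 1,
            doublet_rate >= 0, doublet_rate <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_marker_up = as.integer(n_marker_up),
                 n_marker_down = as.integer(n_marker_down),
                 effect_log2fc = effect_log2fc,
                 nb_dispersion = nb_dispersion,
                 mean_umi_per_cell = mean_umi_per_cell,
                 mito_frac_mean = mito_frac_mean,
                 mito_frac_outlier = mito_frac_outlier,
                 mito_outlier_rate = mito_outlier_rate,
                 doublet_rate = doublet_rate, n_mito = as.integer(n_mito),
                 seed = as.integer(seed),
                 param_seed = as.integer(if (is.null(param_seed)) seed
                                         else param_seed)),
            class = "expression_config")
}

#' Simulate a UMI count matrix for sampled cells
#'
#' @param cells data.frame of sampled cells with columns `cell`,
#'   `timepoint` and a per-cell class column `response` ("tolerant" /
#'   "sensitive"); typically built by joining a [simulate_selection()]
#'   sample with its lineage classes (see [simulate_experiment()]).
#' @param cfg An [expression_config()].
#' @return Object of class `expression_sim`: list with `counts` (genes x
#'   cells integer matrix), `genes` (data.frame `gene`, `mito`), `cells`
#'   (input annotations plus a `doublet` flag) and `markers` (data.frame
#'   `gene`, `sign` with +1 = up in tolerant, -1 = up in sensitive).
#' @export
simulate_expression <- function(cells, cfg) {
  stopifnot(inherits(cfg, "expression_config"),
            all(c("cell", "response") %in% names(cells)),
            all(cells$response %in% c("tolerant", "sensitive")))
  G <- cfg$n_genes; n <- nrow(cells); m <- cfg$n_mito
  genes <- c(sprintf("MT-%d", seq_len(m)),
             sprintf("G%04d", seq_len(G - m)))
  mito <- c(rep(TRUE, m), rep(FALSE, G - m))
  # gene-level parameters under param_seed: mito block takes
  # mito_frac_mean of the library, log-normal means for the rest,
  # scaled to the remaining budget
  set.seed(cfg$param_seed)
  mu <- numeric(G)
  mu[mito] <- cfg$mito_frac_mean * cfg$mean_umi_per_cell / m
  raw <- rlnorm(G - m, meanlog = 0, sdlog = 1.5)
  mu[!mito] <- raw / sum(raw) *
    (1 - cfg$mito_frac_mean) * cfg$mean_umi_per_cell
  up_idx <- m + seq_len(cfg$n_marker_up)
  dn_idx <- m + cfg$n_marker_up + seq_len(cfg$n_marker_down)
  set.seed(cfg$seed)
  markers <- data.frame(
    gene = genes[c(up_idx, dn_idx)],
    sign = rep(c(1L, -1L), c(cfg$n_marker_up, cfg$n_marker_down)),
    stringsAsFactors = FALSE)

  depth <- rlnorm(n, meanlog = 0, sdlog = 0.25)   # modest depth variation
  outlier <- runif(n) < cfg$mito_outlier_rate
  tol <- cells$response == "tolerant"
  fc <- 2^cfg$effect_log2fc

  budget <- sum(mu)
  counts <- matrix(0L, G, n, dimnames = list(genes, cells$cell))
  for (i in seq_len(n)) {
    mui <- mu
    if (tol[i]) mui[up_idx] <- mui[up_idx] * fc
    else mui[dn_idx] <- mui[dn_idx] * fc
    if (outlier[i]) {
      # damaged cell: mito block inflated to the outlier share
      s <- sum(mui[!mito])
      mui[mito] <- cfg$mito_frac_outlier / (1 - cfg$mito_frac_outlier) * s / m
    }
    # expression changes are compositional: expected library size is
    # independent of response class (capture depth is technical)
    mui <- mui * (budget / sum(mui))
    counts[, i] <- rnbinom(G, mu = mui * depth[i], size = 1 / cfg$nb_dispersion)
  }
  doublet <- rep(FALSE, n)
  n_dbl <- floor(cfg$doublet_rate * n)
  if (n_dbl > 0 && n >= 2) {
    tgt <- sample.int(n, n_dbl)
    for (i in tgt) {
      partner <- sample(setdiff(seq_len(n), i), 1L)
      counts[, i] <- counts[, i] + counts[, partner]
    }
    doublet[tgt] <- TRUE
  }
  cells_out <- cells
  cells_out$doublet <- doublet
  structure(list(counts = counts,
                 genes = data.frame(gene = genes, mito = mito,
                                    stringsAsFactors = FALSE),
                 cells = cells_out, markers = markers, cfg = cfg),
            class = "expression_sim")
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic expression: %d genes x %d cells, %d marker genes, %d doublets\n",
    nrow(x$counts), ncol(x$counts), nrow(x$markers), sum(x$cells$doublet)))
  invisible(x)
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: infection, selection, per-cell response labels and
#' expression, returning every piece of ground truth the pipeline's
#' recovery tests need.
#'
#' @param pop_cfg,sel_cfg,expr_cfg Config objects; defaults reproduce the
#'   reference study design at reduced sampling depth.
#' @return List with `founder`, `selection`, `expression` and a `truth`
#'   data.frame (`cell`, `lineage`, `response`, `dynamics`, `timepoint`,
#'   `doublet`).
#' @export
simulate_experiment <- function(pop_cfg = population_config(),
                                sel_cfg = selection_config(),
                                expr_cfg = expression_config()) {
  founder <- simulate_infection(pop_cfg)
  sel <- simulate_selection(founder, sel_cfg)
  ann <- merge(sel$cells, sel$classes, by = "lineage", sort = FALSE)
  ann <- ann[order(match(ann$cell, sel$cells$cell)), ]
  expr <- simulate_expression(ann, expr_cfg)
  truth <- expr$cells[, c("cell", "lineage", "response", "dynamics",
                          "timepoint", "doublet")]
  list(founder = founder, selection = sel, expression = expr, truth = truth)
}
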