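---
title: "Methods: expressed-barcode lineage tracing of drug-tolerant clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expressed-barcode lineage tracing of drug-tolerant clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a cancer cell population is exposed to escalating doses of a targeted
drug, a minority of clones tolerate the treatment and a few of those expand
to dominate the surviving population. `clonetrace` implements the
computational machinery for studying this process with *expressed* DNA
barcodes read out by single-cell RNA-seq: every founder cell carries a
heritable 48-nt cassette (`bc14 + TGGT + bc30`, drawn from fixed
vocabularies of 14-nt and 30-nt words) transcribed into polyadenylated
mRNA, so each sequenced cell reports both its transcriptome and its clone
of origin. On top of barcode recovery the package provides clone-level
analyses (retrospective tolerant-vs-sensitive marker testing, prospective
dominant-vs-neutral classification), a supervised pseudotime with spline
time-course testing, and a contrastive-embedding classifier of per-cell
drug response, together with a synthetic-data generator that emulates the
whole experimental design with known ground truth.

# Barcode retrieval

Read 1 of a 10x-style pair carries the cell barcode (16 nt) and UMI
(12 nt) at fixed offsets; read 2 carries the cassette. Retrieval follows
four rules:

1. **Anchor search.** The 4-nt `TGGT` anchor is located allowing at most
   one mismatch, restricted to positions with a full 14-nt upstream and
   30-nt downstream flank. Exact matches are preferred over one-mismatch
   matches; among equals the leftmost valid position wins. The preference
   order is our convention — the protocol does not say how multiple hits
   were resolved — chosen because it is deterministic and maximizes valid
   extractions.
2. **Whitelist correction.** A putative barcode absent from its
   vocabulary is replaced by the unique vocabulary word at Hamming
   distance 1; with zero or two or more candidates the barcode is
   uncorrectable. When *both* barcodes are absent, bc14 is corrected
   first and bc30 is attempted only if bc14 succeeded (the protocol's
   cost-saving rule). Accepted reads therefore always carry whitelisted
   barcodes.
3. **Assignment.** Each cell is assigned its most abundant lineage
   (`bc14:bc30` pair). Abundance is counted in distinct UMIs, which
   deduplicates PCR amplification; read count is the first tie-break and
   the lexicographically smallest id the last, with a flag marking ties
   that reach the lexicographic rule so downstream analyses can drop
   them. These counting choices are conventions; the protocol says only
   "most abundant".
4. **Cell barcodes are taken verbatim.** No 10x cell-barcode whitelist
   matching is performed; synthetic data has exact cell barcodes and the
   module's scope is cassette recovery. This is a documented limitation
   for real data.

The per-read operations (Hamming distance, anchor scan, vocabulary
correction) are implemented in C++ for throughput, mirroring common
practice for inner-loop string work in this field.

# Quality control

Cells with fewer than 5,000 UMIs are discarded (a cell at exactly the
threshold is kept). Two loess-based filters then remove damaged cells and
low-complexity artifacts: a local linear regression (span 0.75, degree 1)
of a per-cell ratio on the natural log of total UMI count, robust
z-scores of the residuals (`(r - median) / (1.4826 MAD)`), one-tailed
normal p-values, Benjamini–Hochberg adjustment, and a flag at FDR < 0.1.
The mitochondrial filter uses the mitochondrial count fraction (upper
tail); the doublet filter uses detected genes per UMI (lower tail). The
p-value construction is our convention — the protocol says only that
cells "deviate significantly" — chosen as the simplest testable reading.
With constant input the MAD is zero and nothing is flagged. Genes are
excluded only when all three conditions hold: expressed in fewer than 50
cells, in less than 5% of cells, and with mean expression below 1.12
UMIs over all cells (we read the average as a global mean, not a mean
over expressing cells). Filter order is depth, mitochondria, doublets,
genes.

A structural caveat found while validating on synthetic data: a
"doublet" built as the *sum of two random cells* from a homogeneous
population is slightly **more** diverse than a singlet at matched depth
(summing halves the relative NB overdispersion), so the
genes-per-UMI lower-tail rule has no power against such doublets in
principle. It does, by construction, remove cells whose high UMI count is
concentrated in a few genes — which is what the original filter's
authors emphasize it is for. The test suite therefore checks the
filter's type-I calibration on null data and its recovery of planted
concentrated-library cells, and does not claim synthetic summed-doublet
recovery.

# Clone-level analyses

**Retrospective.** Day-0 cells are labelled by the eventual fate of their
lineage (tolerant if the lineage survives selection), ambiguous
assignments excluded. Marker testing uses a two-sided Wilcoxon rank-sum
test per gene on log-normalized expression (`ln(1 + 1e4 x / total)`):
exact null distribution when both groups have at most 10 cells and no
ties, otherwise the normal approximation with tie and continuity
correction. Fold changes are computed on de-transformed means with a
1e-9 pseudocount; the marker panel is the set of genes at BH FDR < 0.05,
split by sign.

**Prospective.** A lineage's frequency at a timepoint is its cell count
divided by all cells sequenced at that timepoint. Dominance is called by
a two-proportion z-test of the first vs last timepoint (the reference
study reports the phenomenon without naming a test), gated by BH
FDR < 0.05, a frequency fold change of at least 5, and an increasing
direction; zero-count lineages are neutral by definition. The gates are
set so dynamics of the magnitude actually observed (two clones rising to
a combined ~45% of the population) are called while neutral clones are
not.

# Pseudotime and time-course testing

The supervised pseudotime is an L1-penalized cumulative-logit
(proportional-odds) regression of ordered day labels on standardized
log-normalized expression: `P(label <= k) = sigmoid(theta_k - w x)`,
fit by proximal gradient descent (ISTA with backtracking; thresholds
kept ordered by isotonic projection). The published tool this
re-specifies is built around the same penalized ordinal-logistic core;
its exact solver schedule and penalty path are not reproduced. `lambda`
is chosen on a stratified 20% hold-out by ordinal classification
accuracy, ties preferring the sparser model, and the sign of `w` is
fixed so pseudotime increases with the day label. Per-cell pseudotime is
the linear score `w x`.

Per gene and per clone group, expression ordered by pseudotime is
smoothed with a centered rolling median (window 51, truncated
symmetrically at the edges) and divided into 50 equal-count bins; the
bin value is the mean of smoothed values. Equal-count (not equal-width)
bins are our convention: they are robust to pseudotime density. The
dominant-vs-neutral time-course test regresses the 100 stacked bin
values on a cubic B-spline basis of bin index (3 df, the reference
tool's default) plus group and group-by-basis interactions, and
F-tests the group terms jointly against the shared-curve null; the
reference tool's empirical-Bayes moderation is replaced by this plain
F-test. Zero-variance genes get p = 1. Up-regulation requires FDR < 5%
and a positive mean bin difference. Temporal patterns among up-regulated
genes are found by k-means (k = 4, following the four patterns reported
in the reference analysis; the algorithm itself is our choice) on
z-scored profiles with 25 restarts and a fixed seed; if the data hold
fewer distinct profiles than k, the distinct profiles define the
clusters.

# The response classifier

The classifier embeds cells with a contrastive autoencoder and
classifies the embedding with a cosine-kernel SVM.

* **Input.** Raw counts are CPM-normalized, cut to the marker panel
  (374 genes in the reference analysis; the panel is a parameter), and
  tf-idf rescaled: tf is the gene's share of the cell's panel-restricted
  signal, idf is `ln(n_cells / (1 + n_expressing))`. The idf vector is
  frozen at training so single cells and pseudobulk are scored on the
  same scale.
* **Architecture.** Encoder `panel -> 64 -> 32` with ReLU after the
  first hidden layer and a linear 32-dim latent; the decoder mirrors the
  encoder. Implemented natively in R matrix algebra with hand-written
  backpropagation and Adam.
* **Pairs and loss.** Within each training batch every cell gets one
  random same-class partner (+1) and one random different-class partner
  (-1) — exactly 2n pairs. The loss is the weighted sum of the cosine
  embedding loss (`1 - cos` for +1 pairs, `max(0, cos - margin)` for -1
  pairs), the mean squared reconstruction error, and a latent
  regularization taken as the mean squared latent coordinate (the
  simplest reading of a "latent space regularization factor"). The
  weights are unstated in the protocol; defaults `w_cos = w_rec = 1`,
  `w_lat = 0.01`, `margin = 0` are conventions and configurable.
* **Training.** Cells are split into 5 class-stratified batches. Per
  batch: Adam (lr 1e-4), minibatches of 32 pairs, at most 250 epochs,
  early stopping when the validation pair loss (a stratified 10% of the
  batch's pairs; the protocol does not define the split) fails to
  improve for 20 epochs, best-epoch weights restored. A cosine-kernel
  SVM (C = 100) with Platt-calibrated probabilities is then fit on the
  batch's embeddings — realized exactly as a linear SVM on L2-normalized
  embeddings, since a linear kernel on unit vectors *is* the cosine
  kernel — and scored by raw argmax accuracy on the cells of the other
  four batches (the protocol does not say whether selection accuracy is
  thresholded; raw accuracy is the default here). The best of the five
  models is kept.
* **Prediction.** A cell is classed tolerant or sensitive only when the
  winning SVM probability exceeds 0.75, otherwise undetermined;
  per-sample fractions keep undetermined cells in the denominator.
  Pseudobulk profiles (summed counts per sample) go through the same
  pathway as one "cell" each.
* **Permutation feature importance.** Per panel gene, the mean drop in
  AUROC (tolerant-class probability vs true labels) over repeated
  shuffles of that gene's tf-idf values across cells, seeds derived from
  a master seed. The reference protocol uses 1,000 repetitions; tests
  use fewer.
* **Random-panel benchmark.** Re-trains the classifier on randomly drawn
  panels and compares the Spearman correlation between predicted and
  true per-sample tolerant fractions against the true panel's score.
  Degenerate (constant) predictions score 0 by convention.

# The synthetic-data generator

The generator emulates the study design end to end and is itself tested
code:

* **Barcoding.** Poisson(MOI) integrations per cell, barcodes drawn
  uniformly with replacement from the pool (collisions allowed, as with
  a 10M-barcode library). A cell's reported lineage is its first
  integration; multi-integration cells are flagged (at MOI 0.05 they are
  ~2.4% of infected cells). Defaults: 50,000 cells, MOI 0.05, 10^7
  barcodes — giving ~5% infection and ~2,500 distinct barcodes.
* **Vocabularies.** bc14 words exclude the anchor `TGGT` as a substring
  and the suffix `TGG` (which would compose a spurious exact anchor with
  the true anchor's first base and make those lineages unparseable);
  Hamming-1 collisions between words are allowed, so correction
  ambiguity remains possible, as in reality.
* **Selection.** Tolerant lineages drawn at rate 192/2336 (the reference
  survival fraction); 2 dominant clones with a multiplicative advantage
  per interval (default 9, which carries them to a combined ~45% of the
  population by day 9, the reported magnitude); sensitive lineages decay
  linearly to zero at `extinction_day = 40` — *after* the sampled window
  (days 0–9), so sensitive cells shrink but persist across the sampled
  days and neutral tolerant clones keep a near-constant share, matching
  the reported dynamics. Cells are sampled multinomially per timepoint.
* **Expression.** Negative-binomial counts with log-normal baseline
  means (sdlog 1.5), shared dispersion (0.3), modest log-normal depth
  variation (sdlog 0.25), a marker program (up in tolerant / up in
  sensitive) at a configurable log2 effect, a small mitochondrial block
  with damaged-cell outliers, and doublets formed by summing two random
  cells. Expected library size is renormalized per cell to a
  class-independent budget: expression changes are compositional, and
  capture depth is technical, so depth must not encode the response
  class (without this, every null gene acquires a small compositional
  shift and the marker test's empirical FDR is inflated by the
  generator rather than the test). Gene-level parameters take a separate
  `param_seed` so several datasets can share one "transcriptome" while
  sampling independent cells — used to emulate independent cell lines
  for transfer experiments.
* **Reads.** Read 1 = 16-nt cell barcode + 12-nt UMI (error-free by
  design, matching the retrieval module's scope); read 2 = 10-nt random
  flank + cassette + poly-A-like tail to 90 nt, with i.i.d. per-base
  substitutions at a configurable rate. Fixed seeds give byte-identical
  FASTQ.

What the generator does **not** emulate: indels, quality-score
structure, ambient RNA, a real transcriptome reference or gene-gene
correlation, cell-barcode sequencing errors, and biologically
heterogeneous cell types. Passing recovery tests on this generator shows
the pipeline implements its stated rules correctly and has the claimed
statistical behaviour under the stated noise model; it does not certify
performance on real libraries.

# Numerical choices and problem sizes

Tolerances and tie-breaks: anchor preference (exact, then leftmost);
lineage tie-breaks (UMI, read, lexicographic); MAD = 0 short-circuits
the loess filters; zero-variance genes get p = 1 in the spline test;
zero-norm latent vectors contribute 0 to the cosine loss with a warning;
constant benchmark predictions score 0. The ISTA solver runs up to 300
iterations to a 1e-7 relative-objective tolerance with backtracking from
step 1. All stochastic components (generator, batch splits, pair
building, weight initialization, SVM calibration, shuffles) are governed
by explicit integer seeds, and identical seeds reproduce identical
results to the byte where files are written.

The test suite exercises the pipeline at deliberately moderate sizes
chosen to probe each claim while keeping the suite quick: 10,000 read
pairs for retrieval recall, 2,000 genes by 1,000 cells (5 replicates)
for marker recovery, 192 tolerant lineages with 1,000 cells per
timepoint for dominance calls, 800 cells for pseudotime recovery, 2,000
null genes for spline-test calibration, 1,000 training cells for the
classifier and 100 random panels (trained under a reduced epoch budget)
for the panel benchmark. These sizes are the package's own choices for
its validation experiments.

# Known limitations

* No 10x cell-barcode correction; cells are keyed by raw 16-mers.
* Batch correction across captures is out of scope (a pass-through in
  this pipeline); apply an external tool between QC and the analyses if
  needed.
* The doublet filter's power limitation against homogeneous summed
  doublets, discussed above.
* The pseudotime is a linear score; non-linear trajectories are out of
  scope.
* The classifier's published external validations (drug-sensitivity
  databases, patient cohorts) depend on external data and are not
  reproduced here; the package validates the method's behaviour on
  synthetic ground truth instead.
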