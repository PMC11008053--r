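#' CPM normalization
#'
#' Counts-per-million per cell: `count * 1e6 / cell_total`.
#'
#' @param counts genes x cells count matrix.
#' @return Dense matrix of CPM values.
#' @export
cpm_normalize <- function(counts) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cpm_normalize: zero-total cell present")
  sweep(as.matrix(counts), 2L, 1e6 / total, `*`)
}

#' tf-idf rescaling of a panel-restricted expression matrix
#'
#' Genes play the role of terms and cells of documents: the term
#' frequency of gene g in cell c is its share of the cell's
#' panel-restricted signal, and the inverse document frequency is
#' `idf(g) = ln(n_cells / (1 + n_expressing))`, computed on the supplied
#' matrix unless a frozen `idf` vector is given (prediction-time use, so
#' single cells and pseudobulk are scored on the training scale).
#' All-zero cells map to all-zero vectors.
#'
#' @param x panel genes x cells matrix (CPM or counts; tf is
#'   scale-invariant per cell).
#' @param idf Optional frozen idf vector (named by gene or in row order).
#' @return Matrix of tf-idf values with the idf vector attached as
#'   attribute `"idf"`.
#' @export
tfidf_rescale <- function(x, idf = NULL) {
  x <- as.matrix(x)
  if (is.null(idf)) {
    idf <- log(ncol(x) / (1 + rowSums(x > 0)))
    names(idf) <- rownames(x)
  } else if (!is.null(names(idf)) && !is.null(rownames(x))) {
    idf <- idf[rownames(x)]
  }
  stopifnot(length(idf) == nrow(x))
  total <- colSums(x)
  tf <- sweep(x, 2L, ifelse(total > 0, total, 1), `/`)
  out <- tf * idf
  attr(out, "idf") <- idf
  out
}

#' Build contrastive training pairs
#'
#' For each cell of a batch: one uniformly random same-class partner
#' (pair label +1, self excluded) and one uniformly random
#' different-class partner (label -1) — exactly `2 n` pairs.
#'
#' @param labels Character/factor vector of per-cell class labels
#'   (exactly two classes, each with at least 2 cells).
#' @param seed RNG seed.
#' @return data.frame with columns `i`, `j` (cell indices) and `label`
#'   (+1 / -1).
#' @export
build_pairs <- function(labels, seed = 1L) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("build_pairs: batch must contain exactly two classes")
  if (any(table(labels) < 2)) stop("build_pairs: each class needs >= 2 cells")
  set.seed(seed)
  n <- length(labels)
  pos <- vapply(seq_len(n), function(i) {
    cand <- setdiff(which(labels == labels[i]), i)
    if (length(cand) == 1) cand else sample(cand, 1L)
  }, integer(1))
  neg <- vapply(seq_len(n), function(i) {
    cand <- which(labels != labels[i])
    if (length(cand) == 1) cand else sample(cand, 1L)
  }, integer(1))
  data.frame(i = rep(seq_len(n), 2L), j = c(pos, neg),
             label = rep(c(1L, -1L), each = n))
}

#' Contrastive autoencoder loss for one pair
#'
#' Weighted sum of three terms: the cosine embedding loss
#' (`1 - cos(z1, z2)` for +1 pairs, `max(0, cos(z1, z2) - margin)` for
#' -1 pairs), the mean squared reconstruction error, and the latent
#' regularization (mean squared latent coordinate). A zero-norm latent
#' vector makes the cosine term 0 by convention (with a warning).
#'
#' @param z1,z2 Latent vectors of the two cells.
#' @param label +1 (same class) or -1 (different class).
#' @param x,xhat Optional input and reconstruction (stacked for the two
#'   cells) for the reconstruction term.
#' @param w_cos,w_rec,w_lat Term weights.
#' @param margin Cosine margin for negative pairs.
#' @return The scalar loss.
#' @export
contrastive_loss <- function(z1, z2, label, x = NULL, xhat = NULL,
                             w_cos = 1, w_rec = 1, w_lat = 0.01,
                             margin = 0) {
  stopifnot(length(z1) == length(z2), label %in% c(-1, 1))
  n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
  if (n1 == 0 || n2 == 0) {
    warning("zero-norm latent vector: cosine term set to 0")
    l_cos <- 0
  } else {
    cs <- sum(z1 * z2) / (n1 * n2)
    l_cos <- if (label == 1) 1 - cs else max(0, cs - margin)
  }
  l_rec <- if (!is.null(x)) mean((x - xhat)^2) else 0
  l_lat <- mean(c(z1, z2)^2)
  w_cos * l_cos + w_rec * l_rec + w_lat * l_lat
}

#' Training configuration for the response classifier
#'
#' Defaults follow the published protocol: 5 class-stratified batches,
#' Adam with learning rate 1e-4, at most 250 epochs with early stopping
#' at patience 20, and a cosine-kernel SVM with regularization C = 100.
#' The three loss-term weights and the margin are conventions
#' (the protocol leaves them open): `w_cos = w_rec = 1`, `w_lat = 0.01`,
#' `margin = 0`.
#'
#' @param n_batches Number of stratified training batches.
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs per batch model.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param w_cos,w_rec,w_lat Loss-term weights.
#' @param margin Cosine margin for negative pairs.
#' @param svm_cost SVM regularization parameter C.
#' @param hidden Encoder hidden layer sizes (latent = last entry).
#' @param minibatch Pairs per Adam step.
#' @param val_frac Fraction of each batch's pairs held out for the
#'   validation loss (stratified by pair label).
#' @param seed Master RNG seed: fixes batch splits, pair building, weight
#'   initialization and SVM probability calibration.
#' @return A `scastral_config` list.
#' @export
scastral_config <- function(n_batches = 5L, lr = 1e-4, max_epochs = 250L,
                            patience = 20L, w_cos = 1, w_rec = 1,
                            w_lat = 0.01, margin = 0, svm_cost = 100,
                            hidden = c(64L, 32L), minibatch = 32L,
                            val_frac = 0.1, seed = 1L) {
  stopifnot(n_batches >= 2, lr > 0, patience < max_epochs,
            w_cos >= 0, w_rec >= 0, w_lat >= 0, length(hidden) == 2)
  structure(list(n_batches = as.integer(n_batches), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), w_cos = w_cos,
                 w_rec = w_rec, w_lat = w_lat, margin = margin,
                 svm_cost = svm_cost, hidden = as.integer(hidden),
                 minibatch = as.integer(minibatch), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "scastral_config")
}

# --- autoencoder internals --------------------------------------------------

ae_init <- function(p, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(W1 = matrix(rnorm(p * h1, 0, sqrt(2 / p)), p, h1),
       b1 = numeric(h1),
       W2 = matrix(rnorm(h1 * h2, 0, sqrt(2 / h1)), h1, h2),
       b2 = numeric(h2),
       W3 = matrix(rnorm(h2 * h1, 0, sqrt(2 / h2)), h2, h1),
       b3 = numeric(h1),
       W4 = matrix(rnorm(h1 * p, 0, sqrt(2 / h1)), h1, p),
       b4 = numeric(p))
}

ae_encode <- function(par, X) {
  H1 <- pmax(sweep(X %*% par$W1, 2L, par$b1, `+`), 0)
  sweep(H1 %*% par$W2, 2L, par$b2, `+`)
}

ae_forward <- function(par, X) {
  S1 <- sweep(X %*% par$W1, 2L, par$b1, `+`)
  H1 <- pmax(S1, 0)
  Z <- sweep(H1 %*% par$W2, 2L, par$b2, `+`)
  S3 <- sweep(Z %*% par$W3, 2L, par$b3, `+`)
  H2 <- pmax(S3, 0)
  Xhat <- sweep(H2 %*% par$W4, 2L, par$b4, `+`)
  list(S1 = S1, H1 = H1, Z = Z, S3 = S3, H2 = H2, Xhat = Xhat)
}

# loss (and gradients) over a set of pairs; X is cells x panel
ae_pair_loss <- function(par, X, pairs, cfg, grad = FALSE) {
  m <- nrow(pairs)
  Xs <- X[c(pairs$i, pairs$j), , drop = FALSE]   # 2m rows: A block then B block
  fw <- ae_forward(par, Xs)
  Z <- fw$Z
  d <- ncol(Z); p <- ncol(Xs); n2 <- nrow(Xs)
  ZA <- Z[seq_len(m), , drop = FALSE]
  ZB <- Z[m + seq_len(m), , drop = FALSE]
  na <- sqrt(rowSums(ZA^2)); nb <- sqrt(rowSums(ZB^2))
  ok <- na > 0 & nb > 0
  cs <- numeric(m)
  cs[ok] <- rowSums(ZA[ok, , drop = FALSE] * ZB[ok, , drop = FALSE]) /
    (na[ok] * nb[ok])
  pos <- pairs$label == 1
  l_cos_i <- ifelse(pos, 1 - cs, pmax(0, cs - cfg$margin))
  l_cos_i[!ok] <- 0
  l_cos <- mean(l_cos_i)
  l_rec <- mean((Xs - fw$Xhat)^2)
  l_lat <- mean(Z^2)
  loss <- cfg$w_cos * l_cos + cfg$w_rec * l_rec + cfg$w_lat * l_lat
  if (!grad)
    return(list(loss = loss, cos = l_cos, rec = l_rec, lat = l_lat))

  dXhat <- cfg$w_rec * 2 * (fw$Xhat - Xs) / (n2 * p)
  dZ <- cfg$w_lat * 2 * Z / (n2 * d)
  # cosine term: dL/dc is -1 for +1 pairs, +1 for active -1 pairs
  dLdc <- ifelse(pos, -1, ifelse(cs > cfg$margin, 1, 0)) / m * cfg$w_cos
  dLdc[!ok] <- 0
  act <- dLdc != 0
  if (any(act)) {
    ia <- which(act)
    dA <- (ZB[ia, , drop = FALSE] / (na[ia] * nb[ia])) -
      ZA[ia, , drop = FALSE] * (cs[ia] / na[ia]^2)
    dB <- (ZA[ia, , drop = FALSE] / (na[ia] * nb[ia])) -
      ZB[ia, , drop = FALSE] * (cs[ia] / nb[ia]^2)
    dZ[ia, ] <- dZ[ia, ] + dLdc[ia] * dA
    dZ[m + ia, ] <- dZ[m + ia, ] + dLdc[ia] * dB
  }
  # decoder backprop
  dW4 <- crossprod(fw$H2, dXhat); db4 <- colSums(dXhat)
  dH2 <- tcrossprod(dXhat, par$W4)
  dS3 <- dH2 * (fw$S3 > 0)
  dW3 <- crossprod(Z, dS3); db3 <- colSums(dS3)
  dZ <- dZ + tcrossprod(dS3, par$W3)
  # encoder backprop
  dW2 <- crossprod(fw$H1, dZ); db2 <- colSums(dZ)
  dH1 <- tcrossprod(dZ, par$W2)
  dS1 <- dH1 * (fw$S1 > 0)
  dW1 <- crossprod(Xs, dS1); db1 <- colSums(dS1)
  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4))
}

adam_state <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0), t = 0L)
}

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(par)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

# train one batch model: early stopping on validation loss, best weights kept
train_batch_model <- function(X, labels, cfg, seed) {
  set.seed(seed)
  pairs <- build_pairs(labels, seed = seed)
  val_idx <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$label),
                           function(ix) sample(ix, max(1L, round(cfg$val_frac * length(ix))))))
  tr_pairs <- pairs[-val_idx, , drop = FALSE]
  va_pairs <- pairs[val_idx, , drop = FALSE]
  par <- ae_init(ncol(X), cfg$hidden)
  st <- adam_state(par)
  best <- list(loss = Inf, par = par)
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(tr_pairs))
    for (start in seq(1L, nrow(tr_pairs), by = cfg$minibatch)) {
      mb <- tr_pairs[ord[start:min(start + cfg$minibatch - 1L,
                                   nrow(tr_pairs))], , drop = FALSE]
      g <- ae_pair_loss(par, X, mb, cfg, grad = TRUE)
      upd <- adam_step(par, g$grads, st, cfg$lr)
      par <- upd$par; st <- upd$st
    }
    vloss <- ae_pair_loss(par, X, va_pairs, cfg)$loss
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, par = par)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  best
}

l2_normalize_rows <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  Z / ifelse(nrm > 0, nrm, 1)
}

#' Fit the contrastive drug-response classifier
#'
#' Trains the two-step model: a contrastive autoencoder
#' (panel -> 64 -> 32, ReLU, mirrored decoder) embedding cells so that
#' same-class pairs are cosine-close and different-class pairs far, then
#' a cosine-kernel SVM (C = 100, Platt-calibrated probabilities) on the
#' embedding. Training cells are CPM-normalized, cut to the marker panel,
#' tf-idf rescaled (idf frozen into the model), and split into
#' `n_batches` class-stratified batches; one autoencoder + SVM is trained
#' per batch (Adam, lr 1e-4, early stopping on validation pair loss,
#' patience 20, max 250 epochs) and scored by raw classification accuracy
#' on the cells of the left-out batches; the best-scoring model is kept.
#' The cosine kernel is realized exactly as a linear kernel on
#' L2-normalized embeddings.
#'
#' @param counts genes x cells raw UMI count matrix.
#' @param labels Per-cell class labels, values `"tolerant"` /
#'   `"sensitive"` (>= 5 cells per class).
#' @param panel Character vector of marker gene ids defining the model
#'   input layout (the reference panel has 374 genes). Panel genes absent
#'   from `counts` are imputed as all-zero with a warning.
#' @param cfg A [scastral_config()].
#' @return Object of class `scastral`: the selected encoder parameters,
#'   SVM, panel, frozen idf, selection accuracy on left-out cells and
#'   per-batch accuracies.
#' @export
scastral <- function(counts, labels, panel, cfg = scastral_config()) {
  labels <- as.character(labels)
  stopifnot(ncol(counts) == length(labels),
            all(labels %in% c("tolerant", "sensitive")))
  if (min(table(labels)) < 5)
    stop("scastral: need at least 5 cells per class")
  tfi <- scastral_input(counts, panel, idf = NULL)
  idf <- attr(tfi, "idf")
  X <- t(tfi)                                    # cells x panel
  set.seed(cfg$seed)
  # class-stratified split into n_batches equal batches
  batch <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    batch[ix] <- rep_len(seq_len(cfg$n_batches), length(ix))
  }
  models <- vector("list", cfg$n_batches)
  accs <- numeric(cfg$n_batches)
  for (b in seq_len(cfg$n_batches)) {
    inb <- batch == b
    fit <- train_batch_model(X[inb, , drop = FALSE], labels[inb], cfg,
                             seed = cfg$seed + b)
    Zb <- l2_normalize_rows(ae_encode(fit$par, X[inb, , drop = FALSE]))
    set.seed(cfg$seed + b)
    svm <- e1071::svm(Zb, factor(labels[inb],
                                 levels = c("sensitive", "tolerant")),
                      kernel = "linear", cost = cfg$svm_cost,
                      probability = TRUE, scale = FALSE)
    Zout <- l2_normalize_rows(ae_encode(fit$par, X[!inb, , drop = FALSE]))
    pred <- predict(svm, Zout)
    accs[b] <- mean(as.character(pred) == labels[!inb])
    models[[b]] <- list(par = fit$par, svm = svm)
  }
  sel <- which.max(accs)
  structure(list(par = models[[sel]]$par, svm = models[[sel]]$svm,
                 panel = panel, idf = idf, accuracy = accs[sel],
                 batch_accuracies = accs, selected_batch = sel,
                 cfg = cfg),
            class = "scastral")
}

#' @export
print.scastral <- function(x, ...) {
  cat(sprintf(
    "Contrastive response classifier: %d-gene panel -> %d -> %d embedding + cosine SVM\n",
    length(x$panel), x$cfg$hidden[1], x$cfg$hidden[2]))
  cat(sprintf("  selected batch model %d of %d; left-out accuracy %.3f\n",
              x$selected_batch, x$cfg$n_batches, x$accuracy))
  invisible(x)
}

# CPM -> panel cut -> tf-idf (frozen idf if given); returns panel x cells
scastral_input <- function(counts, panel, idf = NULL) {
  cpm <- cpm_normalize(counts)
  missing <- setdiff(panel, rownames(cpm))
  if (length(missing) > 0) {
    warning(length(missing), " panel gene(s) absent from input; imputed as zero")
    zero <- matrix(0, length(missing), ncol(cpm),
                   dimnames = list(missing, colnames(cpm)))
    cpm <- rbind(cpm, zero)
  }
  tfidf_rescale(cpm[panel, , drop = FALSE], idf = idf)
}

#' Predict per-cell drug response
#'
#' New cells go through the frozen pipeline — CPM, panel cut, tf-idf with
#' the training idf, encoder, cosine SVM — and receive a class only when
#' the winning class probability exceeds `threshold` (default 0.75);
#' otherwise they are "undetermined". Fractions are computed over all
#' cells, keeping undetermined cells in the denominator.
#'
#' @param object A fitted [scastral()] model.
#' @param counts genes x cells raw count matrix.
#' @param threshold Classification probability threshold.
#' @param ... Unused.
#' @return Object of class `scastral_prediction`: data.frame per cell
#'   (`cell`, `prob_tolerant`, `prob_sensitive`, `class`) with the
#'   fraction summary in attribute `"fractions"`
#'   (tolerant/sensitive/undetermined, summing to 1).
#' @export
predict.scastral <- function(object, counts, threshold = 0.75, ...) {
  tfi <- scastral_input(counts, object$panel, idf = object$idf)
  Z <- l2_normalize_rows(ae_encode(object$par, t(tfi)))
  pr <- attr(predict(object$svm, Z, probability = TRUE), "probabilities")
  pt <- pr[, "tolerant"]; ps <- pr[, "sensitive"]
  cls <- ifelse(pmax(pt, ps) > threshold,
                ifelse(pt > ps, "tolerant", "sensitive"), "undetermined")
  out <- data.frame(cell = colnames(counts), prob_tolerant = pt,
                    prob_sensitive = ps, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  fr <- c(tolerant = mean(cls == "tolerant"),
          sensitive = mean(cls == "sensitive"),
          undetermined = mean(cls == "undetermined"))
  structure(out, fractions = fr, class = c("scastral_prediction",
                                           "data.frame"))
}

#' @export
print.scastral_prediction <- function(x, ...) {
  fr <- attr(x, "fractions")
  cat(sprintf(
    "Response prediction for %d cells: %.1f%% tolerant, %.1f%% sensitive, %.1f%% undetermined\n",
    nrow(x), 100 * fr["tolerant"], 100 * fr["sensitive"],
    100 * fr["undetermined"]))
  invisible(x)
}

#' Fraction of predicted tolerant cells per sample
#'
#' @param pred A [predict.scastral()] result.
#' @param samples Optional per-cell sample labels; if omitted the whole
#'   prediction is one sample.
#' @return data.frame per sample with the three class fractions (summing
#'   to 1).
#' @export
prediction_fractions <- function(pred, samples = NULL) {
  if (is.null(samples)) samples <- rep("all", nrow(pred))
  stopifnot(length(samples) == nrow(pred))
  do.call(rbind, lapply(split(seq_len(nrow(pred)), samples), function(ix) {
    cls <- pred$class[ix]
    data.frame(sample = samples[ix[1]],
               tolerant = mean(cls == "tolerant"),
               sensitive = mean(cls == "sensitive"),
               undetermined = mean(cls == "undetermined"),
               n = length(ix), stringsAsFactors = FALSE)
  }))
}

#' Predict response of pseudobulk profiles
#'
#' Sums UMI counts per sample and sends each pseudobulk profile through
#' the single-cell prediction pathway (one "cell" per sample; idf frozen
#' from training).
#'
#' @param object A fitted [scastral()] model.
#' @param counts genes x cells raw count matrix.
#' @param samples Per-cell sample labels.
#' @param threshold Classification probability threshold.
#' @return A `scastral_prediction` with one row per sample.
#' @export
predict_pseudobulk <- function(object, counts, samples, threshold = 0.75) {
  stopifnot(length(samples) == ncol(counts))
  m <- as.matrix(counts)
  agg <- vapply(split(seq_len(ncol(m)), samples),
                function(ix) rowSums(m[, ix, drop = FALSE]),
                numeric(nrow(m)))
  if (any(colSums(agg) == 0)) stop("empty pseudobulk sample")
  predict(object, agg, threshold = threshold)
}

# rank-based AUROC of scores for binary labels (positive class = `positive`)
auroc <- function(scores, labels, positive = "tolerant") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auroc: both classes required")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation feature importance
#'
#' The importance of a panel gene is the mean drop in AUROC (probability
#' of the tolerant class against the true labels) when that gene's
#' tf-idf values are shuffled across cells, over `n_rep` shuffles with
#' seeds derived deterministically from `seed`.
#'
#' @param object A fitted [scastral()] model.
#' @param counts genes x cells raw count matrix of labelled cells.
#' @param labels Per-cell `"tolerant"` / `"sensitive"` labels.
#' @param n_rep Number of shuffles per gene (the reference protocol uses
#'   1,000).
#' @param seed Master seed.
#' @return data.frame per panel gene: `gene`, `importance` (mean AUROC
#'   drop), `baseline_auroc`.
#' @export
pfi <- function(object, counts, labels, n_rep = 1000L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("pfi: both classes required")
  tfi <- scastral_input(counts, object$panel, idf = object$idf)
  X <- t(tfi)
  score <- function(Xm) {
    Z <- l2_normalize_rows(ae_encode(object$par, Xm))
    pr <- attr(predict(object$svm, Z, probability = TRUE), "probabilities")
    auroc(pr[, "tolerant"], labels)
  }
  base <- score(X)
  n <- nrow(X)
  imp <- vapply(seq_along(object$panel), function(g) {
    drops <- vapply(seq_len(n_rep), function(r) {
      set.seed(seed * 1000L + g * 131L + r)
      Xp <- X
      Xp[, g] <- Xp[sample.int(n), g]
      base - score(Xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  data.frame(gene = object$panel, importance = imp, baseline_auroc = base,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random-panel Monte-Carlo benchmark
#'
#' Evaluates whether the marker panel carries real predictive signal: in
#' each simulation a random panel of `panel_size` genes is drawn, the
#' classifier is re-trained on the training cells with that panel, the
#' predicted tolerant fractions of held-out samples are computed, and the
#' Spearman correlation with the samples' true tolerant fractions is
#' recorded. The true panel's score is returned alongside the null score
#' distribution.
#'
#' @param counts,labels Training cells (genes x cells, per-cell labels).
#' @param eval_counts genes x cells matrix of evaluation cells.
#' @param eval_samples Per-evaluation-cell sample labels.
#' @param eval_truth Named numeric vector: true tolerant fraction per
#'   evaluation sample.
#' @param panel The true marker panel.
#' @param panel_size Genes per random panel (default: the true panel's
#'   length).
#' @param n_sim Number of random panels (>= 1).
#' @param cfg A [scastral_config()] for the per-simulation trainings
#'   (scaled-down budgets are sensible here).
#' @param seed Master seed.
#' @param threshold Classification threshold used for fractions.
#' @return List with `true_score`, `null_scores` (length `n_sim`) and
#'   `quantile` (fraction of null scores below the true score).
#' @export
random_panel_benchmark <- function(counts, labels, eval_counts,
                                   eval_samples, eval_truth, panel,
                                   panel_size = length(panel),
                                   n_sim = 100L, cfg = scastral_config(),
                                   seed = 1L, threshold = 0.75) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (panel_size > nrow(counts)) stop("panel_size exceeds available genes")
  score_panel <- function(pn, sim_seed) {
    cfg_i <- cfg; cfg_i$seed <- sim_seed
    fit <- scastral(counts, labels, pn, cfg_i)
    pred <- predict(fit, eval_counts, threshold = threshold)
    fr <- prediction_fractions(pred, eval_samples)
    x <- fr$tolerant[match(names(eval_truth), fr$sample)]
    # constant predictions carry no association
    if (sd(x) == 0 || sd(eval_truth) == 0) return(0)
    cor(x, eval_truth, method = "spearman")
  }
  true_score <- score_panel(panel, seed)
  null_scores <- vapply(seq_len(n_sim), function(s) {
    set.seed(seed + 7919L * s)
    pn <- sample(rownames(counts), panel_size)
    score_panel(pn, seed + s)
  }, numeric(1))
  list(true_score = true_score, null_scores = null_scores,
       quantile = mean(null_scores < true_score))
}

#' Save / load a fitted classifier
#'
#' Round-trip serialization to a single file; a reloaded model reproduces
#' identical predictions.
#'
#' @param object A `scastral` model.
#' @param path File path (RDS archive).
#' @return `save_scastral` the path invisibly; `load_scastral` the model.
#' @export
save_scastral <- function(object, path) {
  stopifnot(inherits(object, "scastral"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_scastral
#' @export
load_scastral <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "scastral"))
  obj
}
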