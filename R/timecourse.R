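#' Supervised ordinal-regression pseudotime
#'
#' Orders cells along a continuous pseudotime supervised by their ordered
#' day labels, via L1-penalized cumulative-logit (proportional-odds)
#' regression: with standardized log-normalized expression `x` and gene
#' weights `w`, `P(label <= k) = sigmoid(theta_k - w.x)`, fit by proximal
#' gradient descent (ISTA with backtracking) maximizing the penalized
#' log-likelihood `sum log P(label | w.x, theta) - lambda * ||w||_1`.
#' Thresholds are kept ordered by isotonic projection after each step.
#' `lambda` is selected on a held-out 20% split (stratified by label) by
#' ordinal classification accuracy; ties prefer the larger (sparser)
#' penalty. The sign of `w` is fixed so that mean pseudotime is
#' non-decreasing in the day label.
#'
#' @param norm genes x cells matrix of log-normalized expression.
#' @param days Numeric vector over columns of ordered day labels (at
#'   least 2 distinct values, each with >= 10 cells).
#' @param lambda Candidate L1 penalties; default a log-spaced grid.
#' @param max_iter,tol Optimizer budget and relative-objective tolerance.
#' @param seed RNG seed for the validation split.
#' @return Object of class `pseudotime_fit`: gene weights `w`, thresholds
#'   `theta`, chosen `lambda`, per-cell `pseudotime`, held-out `accuracy`
#'   per candidate lambda, and the standardization (`center`, `scale`).
#' @export
fit_ordinal_pseudotime <- function(norm, days, lambda = NULL,
                                   max_iter = 300L, tol = 1e-7, seed = 1L) {
  stopifnot(ncol(norm) == length(days))
  lev <- sort(unique(days))
  if (length(lev) < 2) stop("need at least 2 ordered day labels")
  y <- match(days, lev)
  if (any(table(y) < 10)) stop("each day label needs at least 10 cells")
  set.seed(seed)
  X <- t(norm)                                   # cells x genes
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  n <- nrow(X)

  # stratified 80/20 split for lambda selection
  val <- unlist(lapply(split(seq_len(n), y), function(ix)
    sample(ix, max(1L, round(0.2 * length(ix))))))
  tr <- setdiff(seq_len(n), val)

  if (is.null(lambda)) lambda <- 10^seq(-2.5, 0.5, length.out = 7) / 10
  acc <- numeric(length(lambda))
  fits <- vector("list", length(lambda))
  for (i in seq_along(lambda)) {
    fits[[i]] <- ordinal_ista(X[tr, , drop = FALSE], y[tr],
                              length(lev), lambda[i], max_iter, tol)
    acc[i] <- ordinal_accuracy(X[val, , drop = FALSE], y[val], fits[[i]])
  }
  best <- which(acc == max(acc))
  best <- best[length(best)]                     # tie -> sparser model
  fit <- ordinal_ista(X, y, length(lev), lambda[best], max_iter, tol)
  pt <- drop(X %*% fit$w)
  # orient pseudotime along the day labels (constant pt -> leave as is)
  rho <- if (sd(pt) == 0) NA_real_ else cor(pt, y, method = "spearman")
  if (isTRUE(rho < 0)) {
    fit$w <- -fit$w
    fit$theta <- rev(-fit$theta)
    pt <- -pt
  }
  structure(list(w = setNames(fit$w, colnames(X)), theta = fit$theta,
                 lambda = lambda[best], lambda_grid = lambda,
                 accuracy = setNames(acc, signif(lambda, 3)),
                 pseudotime = setNames(pt, rownames(X)),
                 center = ctr, scale = scl, levels = lev),
            class = "pseudotime_fit")
}

#' @export
print.pseudotime_fit <- function(x, ...) {
  cat(sprintf(
    "Ordinal pseudotime: %d genes (%d non-zero weights), lambda = %.4g, held-out accuracy = %.3f\n",
    length(x$w), sum(x$w != 0), x$lambda, max(x$accuracy)))
  invisible(x)
}

#' @export
coef.pseudotime_fit <- function(object, ...) object$w

#' Project new cells onto a fitted pseudotime axis
#'
#' @param object A `pseudotime_fit`.
#' @param newdata genes x cells matrix on the same genes as the fit.
#' @param ... Unused.
#' @return Named numeric vector of pseudotimes.
#' @export
predict.pseudotime_fit <- function(object, newdata, ...) {
  X <- t(newdata[names(object$w), , drop = FALSE])
  X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  setNames(drop(X %*% object$w), rownames(X))
}

# cumulative-logit NLL, gradient and ISTA loop -------------------------------

ordinal_nll_grad <- function(X, y, K, w, theta) {
  eta <- drop(X %*% w)
  n <- length(y)
  thL <- c(-Inf, theta)[y]        # theta_{y-1}
  thU <- c(theta, Inf)[y]         # theta_y
  pU <- plogis(thU - eta)
  pL <- plogis(thL - eta)
  d <- pmax(pU - pL, 1e-12)
  nll <- -sum(log(d)) / n
  dU <- pU * (1 - pU)             # sigmoid derivative at upper threshold
  dL <- pL * (1 - pL)
  # d nll / d eta
  geta <- (dU - dL) / d / n
  gw <- drop(crossprod(X, geta))
  gtheta <- numeric(K - 1)
  for (k in seq_len(K - 1)) {
    gtheta[k] <- (-sum(dU[y == k] / d[y == k]) +
                    sum(dL[y == k + 1] / d[y == k + 1])) / n
  }
  list(nll = nll, gw = gw, gtheta = gtheta)
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# projection of theta onto the strictly increasing cone (isotonic + nudge)
project_ordered <- function(theta, eps = 1e-4) {
  if (length(theta) > 1) {
    iso <- stats::isoreg(seq_along(theta), theta)$yf
    theta <- iso + eps * (seq_along(theta) - 1)
  }
  theta
}

ordinal_ista <- function(X, y, K, lambda, max_iter, tol) {
  p <- ncol(X)
  w <- numeric(p)
  theta <- stats::qlogis(cumsum(tabulate(y, K) / length(y)))[seq_len(K - 1)]
  theta <- project_ordered(theta)
  step <- 1
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    g <- ordinal_nll_grad(X, y, K, w, theta)
    obj <- g$nll + lambda * sum(abs(w))
    # backtracking on the smooth part
    repeat {
      w_new <- soft_threshold(w - step * g$gw, step * lambda)
      th_new <- project_ordered(theta - step * g$gtheta)
      f_new <- ordinal_nll_grad(X, y, K, w_new, th_new)$nll
      dw <- w_new - w; dth <- th_new - theta
      quad <- g$nll + sum(g$gw * dw) + sum(g$gtheta * dth) +
        (sum(dw^2) + sum(dth^2)) / (2 * step)
      if (f_new <= quad + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    w <- w_new; theta <- th_new
    obj_new <- f_new + lambda * sum(abs(w))
    if (abs(obj_old - obj_new) < tol * max(1, abs(obj_old))) break
    obj_old <- obj_new
    step <- min(step * 1.5, 1e3)                 # allow the step to recover
  }
  list(w = w, theta = theta)
}

ordinal_accuracy <- function(X, y, fit) {
  eta <- drop(X %*% fit$w)
  K <- length(fit$theta) + 1L
  cuts <- c(-Inf, fit$theta, Inf)
  pred <- findInterval(eta, cuts, rightmost.closed = TRUE)
  # eta between theta_{k-1} and theta_k -> class k
  mean(pred == y)
}

#' Rolling-median smoothing and equal-count pseudotime binning
#'
#' Expression values ordered by pseudotime are smoothed with a centered
#' rolling median (window truncated symmetrically at the edges: position
#' `i` uses half-width `min((window-1)/2, i-1, n-i)`), then divided into
#' `n_bins` equal-count bins by pseudotime rank — when `n` is not a
#' multiple of `n_bins` the remainder cells are spread one-per-bin over
#' the leading bins. The bin value is the mean of the smoothed values in
#' the bin.
#'
#' @param values Numeric vector already ordered by pseudotime.
#' @param window Rolling-median window (default 51; must be odd).
#' @param n_bins Number of bins (default 50).
#' @return Numeric vector of `n_bins` smoothed bin means.
#' @export
smooth_and_bin <- function(values, window = 51L, n_bins = 50L) {
  n <- length(values)
  if (n < n_bins) stop("fewer values than bins")
  stopifnot(window %% 2L == 1L)
  sm <- rolling_median(values, window)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  as.numeric(tapply(sm, bin, mean))
}

rolling_median <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hw <- min(h, i - 1L, n - i)
    median(x[(i - hw):(i + hw)])
  }, numeric(1))
}

#' Binned pseudotime profiles for a gene set
#'
#' @param norm genes x cells matrix.
#' @param pseudotime Per-cell pseudotime over columns.
#' @param window,n_bins Passed to [smooth_and_bin()].
#' @return genes x `n_bins` matrix of binned profiles.
#' @export
bin_profiles <- function(norm, pseudotime, window = 51L, n_bins = 50L) {
  stopifnot(ncol(norm) == length(pseudotime))
  ord <- order(pseudotime)
  t(apply(norm[, ord, drop = FALSE], 1L, smooth_and_bin,
          window = window, n_bins = n_bins))
}

#' Spline time-course differential test between two binned profiles
#'
#' Per gene, the 2 x 50 stacked bin values are regressed on a cubic
#' B-spline basis of the bin index (3 df) plus a group indicator and
#' group x basis interactions; an F-test compares this against the
#' shared-curve null (basis only). Genes with zero variance across the
#' 100 values get p = 1 by convention. P-values are BH-adjusted; a gene
#' is called up-regulated iff FDR < `fdr_cut` and the mean bin difference
#' (group 1 minus group 2) is positive.
#'
#' @param profiles1,profiles2 genes x 50 binned profile matrices
#'   (group 1 = dominant, group 2 = neutral), same genes in the same
#'   order.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param df Spline degrees of freedom (default 3).
#' @return data.frame per gene: `gene`, `F`, `p`, `fdr`, `mean_diff`,
#'   `up` (logical call).
#' @export
spline_timecourse_test <- function(profiles1, profiles2, fdr_cut = 0.05,
                                   df = 3) {
  stopifnot(identical(dim(profiles1), dim(profiles2)),
            identical(rownames(profiles1), rownames(profiles2)))
  nb <- ncol(profiles1)
  bin <- rep(seq_len(nb), 2L)
  grp <- rep(c(1, 0), each = nb)
  B <- splines::bs(bin, df = df)
  X1 <- cbind(1, B, grp, B * grp)                # full: group + interactions
  X0 <- cbind(1, B)                              # null: shared curve
  H1 <- X1 %*% solve(crossprod(X1), t(X1))
  H0 <- X0 %*% solve(crossprod(X0), t(X0))
  Y <- rbind(t(profiles1), t(profiles2))         # 2*nb x genes
  R1 <- Y - H1 %*% Y
  R0 <- Y - H0 %*% Y
  rss1 <- colSums(R1^2)
  rss0 <- colSums(R0^2)
  df_diff <- ncol(X1) - ncol(X0)
  df_res <- 2 * nb - ncol(X1)
  Fstat <- ((rss0 - rss1) / df_diff) / (rss1 / df_res)
  p <- pf(Fstat, df_diff, df_res, lower.tail = FALSE)
  degenerate <- apply(Y, 2L, function(v) var(v) == 0)
  p[degenerate] <- 1
  Fstat[degenerate] <- 0
  fdr <- p.adjust(p, method = "BH")
  mean_diff <- rowMeans(profiles1) - rowMeans(profiles2)
  data.frame(gene = rownames(profiles1), F = Fstat, p = p, fdr = fdr,
             mean_diff = mean_diff,
             up = fdr < fdr_cut & mean_diff > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster temporal expression patterns
#'
#' Z-scores each gene's binned profile and partitions genes by k-means
#' (25 restarts, fixed seed). Zero-variance profiles are centered only.
#' When the data hold fewer distinct profiles than `k`, the distinct
#' profiles define the clusters directly (degenerate input).
#'
#' @param profiles genes x bins matrix (typically the up-regulated genes'
#'   binned profiles).
#' @param k Number of temporal patterns (default 4).
#' @param seed RNG seed.
#' @return List with `cluster` (named integer vector) and `centers`
#'   (k x bins matrix of mean z-scored profiles).
#' @export
cluster_temporal_patterns <- function(profiles, k = 4L, seed = 1L) {
  if (nrow(profiles) < k) stop("fewer genes than clusters")
  z <- t(apply(profiles, 1L, function(v) {
    s <- sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  distinct <- unique(z)
  set.seed(seed)
  if (nrow(distinct) < k) {
    cl <- match(apply(z, 1L, paste, collapse = ","),
                apply(distinct, 1L, paste, collapse = ","))
    centers <- distinct
  } else {
    km <- kmeans(z, centers = k, nstart = 25)
    cl <- km$cluster
    centers <- km$centers
  }
  list(cluster = setNames(cl, rownames(profiles)), centers = centers)
}
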