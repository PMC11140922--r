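#' Fit a two-class DAPC model
#'
#' PCA on the training dosages (centred; missing calls mean-imputed from
#' the training data only), followed by a linear discriminant on the
#' retained PC scores: the single axis (two classes) maximises
#' between-class over within-class variance,
#' \eqn{w = S_w^{-1}(m_1 - m_0)}, with a ridge of 1e-8 added when the
#' within-class scatter is singular. Prediction is nearest-centroid on the
#' discriminant axis, equivalent to the posterior argmax under
#' equal-covariance Gaussians with equal priors. Test samples never touch
#' the centring, loadings or discriminant.
#'
#' @param X training dosage matrix (samples x loci; NA allowed).
#' @param labels logical or 2-level factor class labels.
#' @param n_pcs PCs to retain (capped at the training rank).
#' @return object of class \code{dapc_model}.
#' @export
dapc_fit <- function(X, labels, n_pcs) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least 2 training samples per class")
  }
  X <- as.matrix(X)
  col_mu <- colMeans(X, na.rm = TRUE)
  col_mu[is.nan(col_mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- col_mu[j]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  n_pcs <- max(1L, min(n_pcs, rank))
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  S <- Xc %*% V
  m0 <- colMeans(S[!y, , drop = FALSE])
  m1 <- colMeans(S[y, , drop = FALSE])
  Sw <- crossprod(sweep(S[!y, , drop = FALSE], 2, m0)) +
        crossprod(sweep(S[y, , drop = FALSE], 2, m1))
  ridged <- FALSE
  w <- tryCatch(solve(Sw, m1 - m0), error = function(e) NULL)
  if (is.null(w) || rcond(Sw) < 1e-12) {
    ridged <- TRUE
    w <- solve(Sw + diag(1e-8, ncol(Sw)), m1 - m0)
  }
  d0 <- sum(m0 * w); d1 <- sum(m1 * w)
  train_axis <- as.numeric(S %*% w)
  train_pred <- abs(train_axis - d1) < abs(train_axis - d0)
  model <- structure(list(n_pcs = n_pcs, center = ctr, col_mu = col_mu,
                          loadings = V, w = w, centroids = c(no = d0, yes = d1),
                          ridged = ridged,
                          train_accuracy = mean(train_pred == y)),
                     class = "dapc_model")
  model
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d PCs, training accuracy %.3f%s\n",
              x$n_pcs, x$train_accuracy, if (x$ridged) " (ridged)" else ""))
  invisible(x)
}

#' Predict flight class with a fitted DAPC model
#' @param object a \code{dapc_model}.
#' @param newdata dosage matrix (samples x the same loci).
#' @param ... unused.
#' @return logical vector, TRUE = flight.
#' @export
predict.dapc_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- object$col_mu[j]
  S <- sweep(X, 2, object$center) %*% object$loadings
  axis <- as.numeric(S %*% object$w)
  abs(axis - object$centroids["yes"]) < abs(axis - object$centroids["no"])
}

#' Cross-validated choice of the retained PC count
#'
#' Stratified random train/validation splits; the grid value with the
#' highest mean validation success wins, ties going to the smallest PC
#' count. Deterministic for a fixed seed.
#'
#' @param X dosage matrix.
#' @param labels class labels.
#' @param grid candidate PC counts.
#' @param reps number of random splits (default 30).
#' @param train_frac training fraction per split (default 0.9).
#' @param seed RNG seed.
#' @return the selected PC count.
#' @export
xval_npcs <- function(X, labels, grid, reps = 30, train_frac = 0.9,
                      seed = 1L) {
  if (!length(grid)) stop("empty PC grid")
  grid <- sort(unique(as.integer(grid)))
  if (length(grid) == 1) return(grid)
  y <- as.logical(labels)
  idx0 <- which(!y); idx1 <- which(y)
  n0 <- floor(length(idx0) * train_frac); n1 <- floor(length(idx1) * train_frac)
  if (n0 < 2 || n1 < 2 || n0 >= length(idx0) || n1 >= length(idx1)) {
    stop("a class is too small to stratify at this training fraction")
  }
  set.seed(seed)
  succ <- matrix(NA_real_, reps, length(grid))
  for (r in seq_len(reps)) {
    tr <- c(sample(idx0, n0), sample(idx1, n1))
    va <- setdiff(seq_along(y), tr)
    for (gi in seq_along(grid)) {
      m <- dapc_fit(X[tr, , drop = FALSE], y[tr], grid[gi])
      succ[r, gi] <- mean(predict(m, X[va, , drop = FALSE]) == y[va])
    }
  }
  mean_succ <- colMeans(succ)
  grid[which.max(mean_succ)]  # which.max takes the first (smallest) maximiser
}

#' One-tailed binomial success test
#'
#' Upper-tail probability P(Binomial(n, p0) >= k) of observing at least k
#' correct assignments under chance success p0.
#'
#' @param k successes observed.
#' @param n trials.
#' @param p0 chance success probability in (0, 1).
#' @return the one-tailed p-value.
#' @export
binomial_success_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Replicated DAPC flight-capability profiling
#'
#' Per replicate: a stratified training set (\code{n_train_per_class} per
#' class, default 50/50) is drawn from across all samples;
#' cross-validation on the training set alone selects the retained PC
#' count; the model is fit and every remaining sample is assigned a flight
#' class; the success rate is tested one-tailed against a chance model.
#' The chance null p0 defaults to each replicate's test-set majority-class
#' proportion (conservative); a fixed 0.5 is available. Reports the mean
#' success and its standard error over replicates.
#'
#' @param gm a \code{genotype_matrix}.
#' @param labels binary flight classes parallel to \code{gm$samples}
#'   (NA dropped).
#' @param loci_subset locus ids or indices to profile on (e.g. the
#'   externally supported GWAS-outlier panel).
#' @param n_train_per_class training samples per class (default 50).
#' @param n_reps replicates (default 10).
#' @param pc_grid PC counts explored in cross-validation.
#' @param chance "majority" or "half".
#' @param seed root seed; replicate r uses seed + r.
#' @return object of class \code{profiling_report}.
#' @export
replicate_profiling <- function(gm, labels, loci_subset = NULL,
                                n_train_per_class = 50, n_reps = 10,
                                pc_grid = NULL,
                                chance = c("majority", "half"),
                                seed = 1L) {
  chance <- match.arg(chance)
  y <- as.logical(labels)
  keep <- !is.na(y)
  li <- if (is.null(loci_subset)) seq_len(ncol(gm$dosage)) else loci_subset
  if (is.character(li)) {
    li <- match(loci_subset, locus_ids(gm$loci))
    if (anyNA(li)) stop("loci_subset contains loci absent from the matrix")
  }
  X <- gm$dosage[keep, li, drop = FALSE]
  y <- y[keep]
  if (min(table(y)) < n_train_per_class + 2) {
    stop("insufficient class counts for the requested training size")
  }
  if (is.null(pc_grid)) {
    pc_grid <- unique(pmin(c(2, 4, 6, 8, 10, 12), min(ncol(X), 2 * n_train_per_class - 2)))
  }
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    tr <- c(sample(which(!y), n_train_per_class),
            sample(which(y), n_train_per_class))
    te <- setdiff(seq_along(y), tr)
    npc <- xval_npcs(X[tr, , drop = FALSE], y[tr], pc_grid, seed = seed + r)
    m <- dapc_fit(X[tr, , drop = FALSE], y[tr], npc)
    pred <- predict(m, X[te, , drop = FALSE])
    k <- sum(pred == y[te]); n <- length(te)
    p0 <- if (chance == "half") 0.5 else max(mean(y[te]), 1 - mean(y[te]))
    reps[[r]] <- data.frame(replicate = r, n_pcs = npc, n_test = n,
                            successes = k, success = k / n, p0 = p0,
                            p = binomial_success_test(k, n, p0))
  }
  tab <- do.call(rbind, reps)
  structure(list(replicates = tab,
                 mean_success = mean(tab$success),
                 se_success = stats::sd(tab$success) / sqrt(n_reps),
                 chance = chance),
            class = "profiling_report")
}

#' @export
print.profiling_report <- function(x, ...) {
  cat(sprintf("profiling_report: mean success %.3f (+/- %.3f SE) over %d replicates; %d replicate(s) with binomial p < 0.001\n",
              x$mean_success, x$se_success, nrow(x$replicates),
              sum(x$replicates$p < 0.001)))
  invisible(x)
}
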