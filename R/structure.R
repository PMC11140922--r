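#' KING-robust pairwise kinship
#'
#' For each sample pair the estimator uses pairwise-complete loci:
#' \deqn{\hat\phi_{ij} = (N_{het,het} - 2 N_{opp.hom}) / (N_{het}(i) + N_{het}(j))}
#' where the heterozygote counts in the denominator are taken over loci
#' non-missing in both samples. Self-kinship is 0.5 by convention, and a
#' duplicated sample yields exactly 0.5. The estimator is invariant to
#' ref/alt allele relabelling.
#'
#' @param gm a \code{genotype_matrix}.
#' @return object of class \code{kinship_matrix}: list(phi, samples,
#'   estimator); pairs sharing no informative locus are \code{NA}.
#' @export
king_kinship <- function(gm) {
  if (length(gm$samples) < 2) stop("need at least 2 samples")
  G <- gm$dosage
  M <- !is.na(G)
  H <- (G == 1L); H[!M] <- FALSE
  A0 <- (G == 0L); A0[!M] <- FALSE
  A2 <- (G == 2L); A2[!M] <- FALSE
  storage.mode(H) <- storage.mode(A0) <- storage.mode(A2) <- "double"
  Md <- M; storage.mode(Md) <- "double"
  n_hh <- H %*% t(H)
  n_opp <- A0 %*% t(A2) + A2 %*% t(A0)
  den <- H %*% t(Md) + Md %*% t(H)
  phi <- (n_hh - 2 * n_opp) / den
  phi[den == 0] <- NA_real_
  diag(phi) <- 0.5
  dimnames(phi) <- list(gm$samples, gm$samples)
  structure(list(phi = phi, samples = gm$samples, estimator = "king_robust"),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x$phi[upper.tri(x$phi)]
  cat(sprintf("kinship_matrix (%s): %d samples, off-diagonal range [%.3f, %.3f]\n",
              x$estimator, length(x$samples),
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Greedy partition into unrelated and related sample sets
#'
#' While any pair exceeds the kinship threshold, the sample with the most
#' above-threshold partners is moved to the related set (ties broken by
#' larger mean kinship, then lexicographic id); the remainder is the
#' unrelated set. Deterministic given the tie rule.
#'
#' @param kin a \code{kinship_matrix}.
#' @param threshold kinship cutoff (default 0.025).
#' @return named logical vector, TRUE = unrelated.
#' @export
partition_unrelated <- function(kin, threshold = 0.025) {
  phi <- kin$phi
  diag(phi) <- 0
  phi[is.na(phi)] <- 0
  active <- rep(TRUE, nrow(phi))
  names(active) <- kin$samples
  repeat {
    sub <- phi[active, active, drop = FALSE]
    deg <- rowSums(sub > threshold)
    if (!any(deg > 0)) break
    mx <- max(deg)
    cand <- which(deg == mx)
    if (length(cand) > 1) {
      mk <- rowMeans(sub[cand, , drop = FALSE])
      cand <- cand[mk == max(mk)]
      if (length(cand) > 1) cand <- cand[order(names(cand))][1]
    }
    active[names(cand)[1] %||% names(deg)[cand[1]]] <- FALSE
  }
  active
}

#' Unrelated-set PCA with projection of relatives
#'
#' Allele frequencies are estimated on the unrelated set; loci are centred
#' at \eqn{2\hat p} and scaled by \eqn{\sqrt{2\hat p(1-\hat p)}}, with
#' missing dosages mean-imputed per locus (PCA only). The
#' eigendecomposition is fit on the unrelated samples and related samples
#' are projected onto its loadings, so relatives never influence the axes.
#' Loci monomorphic in the unrelated set are dropped.
#'
#' @param gm a \code{genotype_matrix}.
#' @param unrelated logical vector (as from
#'   \code{\link{partition_unrelated}}).
#' @param K number of PCs to retain.
#' @return object of class \code{structure_model}: scores (all samples x
#'   K), loadings, eigenvalues, unrelated flags,
#'   \code{proportion_structure_explained}.
#' @export
pca_unrelated_project <- function(gm, unrelated, K) {
  if (!any(unrelated)) stop("unrelated set is empty")
  G <- gm$dosage
  Gu <- G[unrelated, , drop = FALSE]
  p_hat <- colMeans(Gu, na.rm = TRUE) / 2
  poly <- is.finite(p_hat) & p_hat > 0 & p_hat < 1
  if (!all(poly)) {
    message(sprintf("dropping %d locus/loci monomorphic in the unrelated set",
                    sum(!poly)))
  }
  G <- G[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  ctr <- 2 * p_hat
  scl <- sqrt(2 * p_hat * (1 - p_hat))
  X <- sweep(sweep(G, 2, ctr), 2, scl, "/")
  X[is.na(X)] <- 0  # mean imputation after centring
  Xu <- X[unrelated, , drop = FALSE]
  n_u <- nrow(Xu)
  if (K > n_u - 1) stop("K exceeds the rank of the unrelated set")
  sv <- svd(Xu)
  evals <- sv$d^2 / ncol(X)
  loadings <- sv$v[, seq_len(K), drop = FALSE]
  scores <- X %*% loadings
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(K))
  prop <- sum(evals[seq_len(K)]) / sum(evals)
  structure(list(K = K, scores = scores, loadings = loadings,
                 eigenvalues = evals, unrelated = unrelated,
                 centers = ctr, scales = scl, kept_loci = which(poly),
                 proportion_structure_explained = prop),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d PCs on %d unrelated samples (projected: %d); structure explained %.3f\n",
              x$K, sum(x$unrelated), sum(!x$unrelated),
              x$proportion_structure_explained))
  invisible(x)
}

#' PC-adjusted (residual) kinship
#'
#' Individual-specific allele frequencies \eqn{\hat\mu_{il}} come from a
#' per-locus linear regression of dosage/2 on the retained PC scores
#' (clamped to [0.01, 0.99]); kinship is the normalised cross-product of
#' the residual dosages
#' \deqn{\hat\phi_{ij} = \sum_l (g_{il}-2\hat\mu_{il})(g_{jl}-2\hat\mu_{jl}) /
#'       \sum_l 4\sqrt{\hat\mu_{il}(1-\hat\mu_{il})\hat\mu_{jl}(1-\hat\mu_{jl})}}
#' over loci non-missing in both samples. This isolates family-level
#' structure from the population structure already captured by the PCs.
#'
#' @param gm a \code{genotype_matrix}.
#' @param structure a \code{structure_model}.
#' @param K number of leading PCs used in the regressions (default: all
#'   retained).
#' @return a \code{kinship_matrix} with estimator tag "pc_adjusted".
#' @export
pc_adjusted_kinship <- function(gm, structure, K = structure$K) {
  S <- structure$scores[, seq_len(K), drop = FALSE]
  Z <- cbind(1, S)
  if (qr(Z)$rank < ncol(Z)) stop("degenerate regression: constant PC columns")
  G <- gm$dosage[, structure$kept_loci, drop = FALSE]
  M <- !is.na(G)
  Y <- G / 2
  Yf <- Y; Yf[!M] <- 0
  # per-locus least squares with missing handled by normal equations per
  # missingness pattern; with modest missingness the complete-data solve
  # is reused for fully observed loci
  mu <- matrix(NA_real_, nrow(G), ncol(G))
  full <- colSums(M) == nrow(G)
  if (any(full)) {
    beta <- solve(crossprod(Z), crossprod(Z, Y[, full, drop = FALSE]))
    mu[, full] <- Z %*% beta
  }
  for (j in which(!full)) {
    obs <- M[, j]
    if (sum(obs) <= ncol(Z)) { mu[, j] <- mean(Y[obs, j]); next }
    Zo <- Z[obs, , drop = FALSE]
    b <- tryCatch(solve(crossprod(Zo), crossprod(Zo, Y[obs, j])),
                  error = function(e) NULL)
    mu[, j] <- if (is.null(b)) mean(Y[obs, j]) else Z %*% b
  }
  mu <- pmin(pmax(mu, 0.01), 0.99)
  R <- (G - 2 * mu); R[!M] <- 0
  V <- 2 * sqrt(mu * (1 - mu)); V[!M] <- 0
  num <- R %*% t(R)
  den <- V %*% t(V)
  phi <- num / den
  phi[den == 0] <- NA_real_
  dimnames(phi) <- list(gm$samples, gm$samples)
  structure(list(phi = phi, samples = gm$samples, estimator = "pc_adjusted"),
            class = "kinship_matrix")
}

#' Leading eigenvectors of a kinship matrix, for use as covariates
#'
#' The GWAS models take kinship as fixed-effect covariates; this extracts
#' the leading eigenvectors of the (symmetrised) kinship matrix.
#'
#' @param kin a \code{kinship_matrix}.
#' @param n_factors how many eigenvectors (default 2).
#' @return samples x n_factors matrix.
#' @export
kinship_factors <- function(kin, n_factors = 2L) {
  phi <- kin$phi
  phi[is.na(phi)] <- 0
  phi <- (phi + t(phi)) / 2
  ev <- eigen(phi, symmetric = TRUE)
  f <- ev$vectors[, seq_len(n_factors), drop = FALSE]
  rownames(f) <- kin$samples
  colnames(f) <- paste0("KF", seq_len(n_factors))
  f
}
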