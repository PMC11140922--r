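#' Bin 0-5 flight scores into binary flight classes
#'
#' Scores 0-2 become "no flight" (FALSE), 3-5 "flight" (TRUE), reflecting
#' the bimodal score distribution that concentrates at 0 and 5.
#'
#' @param scores integer vector in 0..5 (NA allowed, propagated).
#' @return logical vector, TRUE = flight.
#' @export
bin_flight <- function(scores) {
  ok <- is.na(scores) | (scores %in% 0:5)
  if (!all(ok)) stop("flight scores must lie in 0..5")
  scores >= 3
}

null_fit <- function(y, Z, link) {
  if (link == "binomial") {
    fit <- stats::glm.fit(Z, y, family = stats::binomial())
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    conv <- fit$converged && all(w > 1e-10)
    aic <- fit$aic
    list(mu = mu, w = w, converged = conv, aic = aic, dispersion = 1)
  } else {
    fit <- stats::lm.fit(Z, y)
    mu <- fit$fitted.values
    res <- y - mu
    n <- length(y)
    sigma2 <- sum(res^2) / (n - ncol(Z))
    aic <- n * log(2 * pi * sum(res^2) / n) + n + 2 * (ncol(Z) + 1)
    list(mu = mu, w = rep(1, n), converged = TRUE,
         aic = aic, dispersion = sigma2)
  }
}

score_stats <- function(X, y, Z, fit, link) {
  # score test with the null fit only:
  #   U = x'(y - mu0),  V = x'Wx - x'WZ (Z'WZ)^-1 Z'Wx
  # gaussian: W = I, statistic scaled by the null residual variance
  w <- if (link == "binomial") fit$w else rep(1, length(y))
  r <- y - fit$mu
  U <- crossprod(X, r)
  WZ <- Z * w
  ZtWZ_inv <- solve(crossprod(Z, WZ))
  XtWZ <- crossprod(X * w, Z)
  V <- colSums(X * (X * w)) - rowSums((XtWZ %*% ZtWZ_inv) * XtWZ)
  if (link == "gaussian") {
    U <- U / fit$dispersion
    V <- V / fit$dispersion
  }
  stat <- as.numeric(U)^2 / V
  stat[V <= 1e-12] <- NA_real_
  list(stat = stat, sign = sign(as.numeric(U)))
}

#' Per-locus score-test association scan
#'
#' The null model (intercept + covariates) is fit once per phenotype —
#' IRLS for the binomial link (binary flight class), least squares for the
#' gaussian link (forewing length, mm). Each locus then contributes a
#' 1-df chi-square score statistic computed from the null fit only. Loci
#' with missing genotypes are tested on their observed subset, with the
#' null refit on that subset (cached per missingness pattern). Reports
#' per-locus p, BH-adjusted p, effect sign, and per-model AIC and the
#' genomic inflation factor lambda = median(chi2)/0.4549.
#'
#' @param gm a \code{genotype_matrix}.
#' @param phenotype numeric/logical vector named by or ordered as
#'   \code{gm$samples}; NAs dropped.
#' @param covariates matrix of covariates (PC scores, kinship factors) or
#'   NULL for intercept-only.
#' @param link "binomial" or "gaussian".
#' @return object of class \code{assoc_result} with a per-locus data.frame
#'   \code{table} and model diagnostics.
#' @export
score_test_scan <- function(gm, phenotype, covariates = NULL,
                            link = c("binomial", "gaussian")) {
  link <- match.arg(link)
  y <- as.numeric(phenotype)
  keep <- !is.na(y)
  y <- y[keep]
  G <- gm$dosage[keep, , drop = FALSE]
  n <- length(y)
  Z <- cbind(intercept = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE])
  fit0 <- null_fit(y, Z, link)
  if (!fit0$converged) {
    return(structure(list(table = NULL, link = link, converged = FALSE,
                          aic = NA_real_, lambda = NA_real_, n = n,
                          n_covariates = ncol(Z) - 1L),
                     class = "assoc_result"))
  }
  stat <- rep(NA_real_, ncol(G))
  sgn <- rep(NA_real_, ncol(G))
  cc <- colSums(is.na(G)) == 0
  if (any(cc)) {
    Xc <- G[, cc, drop = FALSE]
    s <- score_stats(Xc, y, Z, fit0, link)
    stat[cc] <- s$stat; sgn[cc] <- s$sign
  }
  if (any(!cc)) {
    patterns <- apply(!is.na(G[, !cc, drop = FALSE]), 2, paste0, collapse = "")
    idx_mc <- which(!cc)
    for (pat in unique(patterns)) {
      cols <- idx_mc[patterns == pat]
      obs <- !is.na(G[, cols[1]])
      if (sum(obs) <= ncol(Z) + 1) next
      fs <- null_fit(y[obs], Z[obs, , drop = FALSE], link)
      if (!fs$converged) next
      s <- score_stats(G[obs, cols, drop = FALSE], y[obs],
                       Z[obs, , drop = FALSE], fs, link)
      stat[cols] <- s$stat; sgn[cols] <- s$sign
    }
  }
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tab <- data.frame(contig = gm$loci$contig, pos = gm$loci$pos,
                    locus = locus_ids(gm$loci),
                    chi2 = stat, p = p, p_adj = adjust_p(p),
                    sign = sgn, stringsAsFactors = FALSE)
  lambda <- stats::median(stat, na.rm = TRUE) / stats::qchisq(0.5, 1)
  qq <- data.frame(expected = -log10(stats::ppoints(sum(!is.na(p)))),
                   observed = -log10(sort(p[!is.na(p)])))
  structure(list(table = tab, link = link, converged = TRUE,
                 aic = fit0$aic, lambda = lambda, qq = qq, n = n,
                 n_covariates = ncol(Z) - 1L),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (!x$converged) {
    cat("assoc_result: null model did not resolve\n")
    return(invisible(x))
  }
  cat(sprintf("assoc_result (%s): %d loci, n = %d, %d covariate(s); AIC %.1f, lambda %.3f; %d loci p < 0.05, %d p_adj < 0.05\n",
              x$link, nrow(x$table), x$n, x$n_covariates, x$aic, x$lambda,
              sum(x$table$p < 0.05, na.rm = TRUE),
              sum(x$table$p_adj < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg (default) or Bonferroni p adjustment
#' @param p p-values in [0,1] (NA allowed).
#' @param method "BH" or "bonferroni".
#' @return adjusted p-values.
#' @export
adjust_p <- function(p, method = c("BH", "bonferroni")) {
  stats::p.adjust(p, method = match.arg(method))
}

#' Scan a grid of PC counts and select a working model
#'
#' Runs one score-test scan per PC count. The default selection rule keeps
#' the largest PC count whose null model resolved statistically; AIC,
#' lambda and qq data for every grid member are retained for manual
#' override.
#'
#' @param gm a \code{genotype_matrix}.
#' @param phenotype as in \code{\link{score_test_scan}}.
#' @param structure a \code{structure_model} supplying PC scores.
#' @param pc_grid integer vector of candidate PC counts.
#' @param kin_factors optional kinship-factor covariates included in every
#'   model.
#' @param link error link.
#' @return list(results = named list of assoc_result, selected = PC count,
#'   selected_result).
#' @export
model_grid <- function(gm, phenotype, structure, pc_grid,
                       kin_factors = NULL, link = "binomial") {
  if (!length(pc_grid)) stop("empty PC grid")
  pc_grid <- sort(unique(as.integer(pc_grid)))
  res <- lapply(pc_grid, function(K) {
    cov <- if (K > 0) structure$scores[, seq_len(K), drop = FALSE] else NULL
    if (!is.null(kin_factors)) cov <- cbind(cov, kin_factors)
    score_test_scan(gm, phenotype, cov, link)
  })
  names(res) <- paste0("K", pc_grid)
  ok <- vapply(res, function(r) isTRUE(r$converged), logical(1))
  if (!any(ok)) stop("no model in the grid resolved statistically")
  sel <- max(pc_grid[ok])
  if (sel == min(pc_grid)) {
    warning("only the smallest-PC model resolved; structure correction may be inadequate")
  }
  list(results = res, selected = sel,
       selected_result = res[[paste0("K", sel)]])
}

#' LD-based candidate gene annotation
#'
#' For each locus with p below \code{p_max}, every locus lying within a
#' gene span on the same contig is checked for strong linkage
#' disequilibrium (genotype-dosage correlation |r| >= \code{r_min}); a
#' gene becomes a candidate if any such locus qualifies. An outlier
#' falling inside a gene annotates it directly (r = 1 with itself). Each
#' candidate gene records its best supporting marker and p.
#'
#' @param gm a \code{genotype_matrix} (same loci as the scan).
#' @param assoc an \code{assoc_result}.
#' @param genes gene table (gene_id, contig, start, end; 1-based
#'   inclusive).
#' @param r_min LD threshold (default 0.90).
#' @param p_max outlier p threshold on raw p (default 0.05).
#' @return object of class \code{candidate_set}: data.frame(gene_id,
#'   marker, p, r).
#' @export
ld_annotate <- function(gm, assoc, genes, r_min = 0.90, p_max = 0.05) {
  tab <- assoc$table
  out <- list()
  for (ct in unique(genes$contig)) {
    gsub_ <- genes[genes$contig == ct, , drop = FALSE]
    li <- which(gm$loci$contig == ct)
    if (!length(li)) next
    oi <- li[!is.na(tab$p[li]) & tab$p[li] < p_max]
    if (!length(oi)) next
    pos <- gm$loci$pos[li]
    for (gidx in seq_len(nrow(gsub_))) {
      inside <- li[pos >= gsub_$start[gidx] & pos <= gsub_$end[gidx]]
      if (!length(inside)) next
      best <- NULL
      for (o in oi) {
        if (o %in% inside) {
          r <- 1
        } else {
          r <- suppressWarnings(abs(stats::cor(gm$dosage[, o],
                                               gm$dosage[, inside, drop = FALSE],
                                               use = "pairwise.complete.obs")))
          r <- suppressWarnings(max(r, na.rm = TRUE))
          if (!is.finite(r)) r <- 0
        }
        if (r >= r_min && (is.null(best) || tab$p[o] < best$p)) {
          best <- list(marker = tab$locus[o], p = tab$p[o], r = r)
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gsub_$gene_id[gidx], marker = best$marker,
          p = best$p, r = best$r, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), marker = character(0),
               p = numeric(0), r = numeric(0), stringsAsFactors = FALSE)
  res <- res[!duplicated(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("candidate_set", "data.frame"))
}

#' Pairwise and all-way overlap of candidate gene sets
#'
#' @param sets named list of candidate gene id vectors (or
#'   \code{candidate_set} objects).
#' @return list(pairwise = count matrix, all = size of the all-way
#'   intersection, sizes = per-set sizes).
#' @export
candidate_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two candidate sets")
  ids <- lapply(sets, function(s) {
    if (inherits(s, "data.frame")) unique(s$gene_id) else unique(as.character(s))
  })
  k <- length(ids)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(ids[[i]], ids[[j]]))
  }
  list(pairwise = pw, all = length(Reduce(intersect, ids)),
       sizes = vapply(ids, length, integer(1)))
}
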