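#' Exact Hardy-Weinberg equilibrium test
#'
#' Full enumeration of heterozygote counts conditional on the observed
#' allele counts; the two-sided p-value sums the probabilities of all
#' heterozygote configurations no more probable than the observed one
#' (the standard exact HWE test of Wigginton, Cutler & Abecasis).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2L * n_aa + n_ab          # minor/major labelling is symmetric
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  het_vals <- seq(rare %% 2L, rare, by = 2L)
  # P(n_het | allele counts) via log factorials
  lf <- function(k) lgamma(k + 1)
  logp <- vapply(het_vals, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lf(n) - lf(hom_r) - lf(h) - lf(hom_c) + h * log(2) +
      lf(rare) + lf(2 * n - rare) - lf(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- n_ab
  sum(p[p <= p[match(obs, het_vals)] * (1 + 1e-12)])
}

new_qc_report <- function(seed) {
  structure(list(rules = list(), seed = seed), class = "qc_report")
}

log_rule <- function(report, rule, loci_dropped, samples_dropped = 0L) {
  report$rules[[rule]] <- list(rule = rule,
                               loci_dropped = as.integer(loci_dropped),
                               samples_dropped = as.integer(samples_dropped))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("variant QC report\n")
  for (r in x$rules) {
    cat(sprintf("  %-16s loci dropped: %4d   samples dropped: %d\n",
                r$rule, r$loci_dropped, r$samples_dropped))
  }
  invisible(x)
}

#' Rule 1: retain only biallelic SNPs or indels
#'
#' Biallelicity is enforced at read time; this re-validates and drops any
#' locus flagged multiallelic (and, when \code{snps_only}, indels).
#' Monomorphic loci are retained here — frequency is the MAF rule's job.
#'
#' @param gm a \code{genotype_matrix}.
#' @param snps_only drop flagged indels too.
#' @return filtered \code{genotype_matrix}.
#' @export
filter_biallelic <- function(gm, snps_only = FALSE) {
  keep <- rep(TRUE, nrow(gm$loci))
  if (!is.null(gm$loci$is_multiallelic)) keep <- keep & !gm$loci$is_multiallelic
  if (snps_only) keep <- keep & !gm$loci$is_indel
  gm_subset(gm, loci = keep)
}

#' Rule 2: drop loci violating HWE in the flight-capable controls
#'
#' The exact HWE test is computed on non-missing genotypes of the control
#' (ASM, flight-capable) samples; a locus is discarded iff p < alpha.
#' Pooled across controls by default; in per-colony mode a locus is
#' discarded if any single colony violates.
#'
#' @param gm a \code{genotype_matrix}.
#' @param control_ids sample ids of the control lineage.
#' @param alpha significance cutoff (default 1e-6).
#' @param colonies optional vector of colony labels parallel to
#'   \code{control_ids}; when given, the test runs per colony.
#' @return filtered \code{genotype_matrix}.
#' @export
hwe_filter <- function(gm, control_ids, alpha = 1e-6, colonies = NULL) {
  if (!length(control_ids)) stop("empty control set")
  if (!all(control_ids %in% gm$samples)) stop("control ids not all present")
  groups <- if (is.null(colonies)) list(control_ids) else split(control_ids, colonies)
  viol <- rep(FALSE, nrow(gm$loci))
  for (ids in groups) {
    g <- gm$dosage[match(ids, gm$samples), , drop = FALSE]
    p <- vapply(seq_len(ncol(g)), function(j) {
      gj <- g[, j]
      hwe_exact_test(sum(gj == 0L, na.rm = TRUE),
                     sum(gj == 1L, na.rm = TRUE),
                     sum(gj == 2L, na.rm = TRUE))
    }, numeric(1))
    viol <- viol | (p < alpha)
  }
  gm_subset(gm, loci = !viol)
}

#' Rule 3: joint global/ESM minor-allele-frequency filter
#'
#' A locus is discarded iff its global MAF is below \code{global_min} AND
#' its MAF within ESM samples is below \code{esm_min} (the combined
#' condition; failing only one bound retains the locus). MAF is computed
#' on non-missing calls; a locus with every call missing counts as MAF 0
#' and is discarded.
#'
#' @param gm a \code{genotype_matrix}.
#' @param esm_ids ESM sample ids.
#' @param global_min,esm_min thresholds (defaults 0.10 and 0.30).
#' @return filtered \code{genotype_matrix}.
#' @export
maf_filter <- function(gm, esm_ids, global_min = 0.10, esm_min = 0.30) {
  if (!all(esm_ids %in% gm$samples)) stop("esm ids not all present")
  esm <- gm$dosage[match(esm_ids, gm$samples), , drop = FALSE]
  g_maf <- apply(gm$dosage, 2, maf_of)
  e_maf <- apply(esm, 2, maf_of)
  drop <- (g_maf < global_min) & (e_maf < esm_min)
  gm_subset(gm, loci = !drop)
}

#' Rule 4: missingness / depth filter
#'
#' A locus is discarded iff its proportion of missing genotypes exceeds
#' \code{max_missing} OR its mean depth (averaged over all samples,
#' missing calls included at their recorded depth) is below
#' \code{min_mean_depth}; both comparisons are strict, as printed.
#'
#' @param gm a \code{genotype_matrix}.
#' @param max_missing missing-proportion bound (default 0.5).
#' @param min_mean_depth mean-depth bound (default 5).
#' @return filtered \code{genotype_matrix}.
#' @export
missing_depth_filter <- function(gm, max_missing = 0.5, min_mean_depth = 5) {
  missp <- colMeans(is.na(gm$dosage))
  mdep <- colMeans(gm$depth)
  gm_subset(gm, loci = !(missp > max_missing | mdep < min_mean_depth))
}

#' Rule 5: random pruning of loci in complete linkage disequilibrium
#'
#' Within each contig, for every locus pair whose genotype-dosage Pearson
#' correlation over pairwise-complete observations satisfies |r| = 1
#' (tolerance 1e-12), one member is discarded uniformly at random;
#' repeated until no such pair remains. Cross-contig pairs are never
#' compared.
#'
#' @param gm a \code{genotype_matrix}.
#' @param seed integer seed for the random tie-break.
#' @return filtered \code{genotype_matrix}.
#' @export
ld_prune_complete <- function(gm, seed = 1L) {
  set.seed(seed)
  keep <- rep(TRUE, nrow(gm$loci))
  for (ct in unique(gm$loci$contig)) {
    idx <- which(gm$loci$contig == ct & keep)
    if (length(idx) < 2) next
    repeat {
      act <- idx[keep[idx]]
      if (length(act) < 2) break
      r <- suppressWarnings(stats::cor(gm$dosage[, act, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r[!is.finite(r)] <- 0
      diag(r) <- 0
      hit <- which(abs(r) >= 1 - 1e-12, arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (!nrow(hit)) break
      pair <- hit[1, ]
      victim <- act[pair[sample.int(2, 1)]]
      keep[victim] <- FALSE
    }
  }
  gm_subset(gm, loci = keep)
}

#' Rule 6: drop high-missingness samples
#'
#' Samples with a missing-genotype proportion strictly above
#' \code{max_missing} are removed.
#'
#' @param gm a \code{genotype_matrix}.
#' @param max_missing bound (default 0.5), strict.
#' @return filtered \code{genotype_matrix}.
#' @export
sample_filter <- function(gm, max_missing = 0.5) {
  missp <- rowMeans(is.na(gm$dosage))
  keep <- missp <= max_missing
  if (!any(keep)) stop("all samples removed by the missingness filter")
  gm_subset(gm, samples = keep)
}

#' Run the full six-rule GWAS-track QC cascade
#'
#' Applies, in order: (1) biallelic validation, (2) exact-HWE filter in the
#' flight-capable (ASM, control) samples, (3) the joint global/ESM MAF
#' rule, (4) the missingness/mean-depth rule, (5) random pruning of
#' complete-LD pairs within contigs, and (6) removal of high-missingness
#' samples. The report accounts for every discarded locus and sample.
#'
#' @param gm a \code{genotype_matrix}.
#' @param samples sample table with \code{sample_id} and \code{lineage}.
#' @param hwe_alpha,global_min,esm_min,max_missing,min_mean_depth,sample_max_missing
#'   rule thresholds, defaulting to the printed values.
#' @param seed seed for the LD tie-break.
#' @param snps_only restrict to SNPs in rule 1.
#' @return list(gm, report).
#' @export
run_qc <- function(gm, samples, hwe_alpha = 1e-6,
                   global_min = 0.10, esm_min = 0.30,
                   max_missing = 0.5, min_mean_depth = 5,
                   sample_max_missing = 0.5, seed = 1L,
                   snps_only = FALSE) {
  samples <- validate_sample_table(samples)
  rep0 <- new_qc_report(seed)
  n0 <- nrow(gm$loci)
  gm1 <- filter_biallelic(gm, snps_only = snps_only)
  rep0 <- log_rule(rep0, "biallelic", n0 - nrow(gm1$loci))
  ctrl <- intersect(samples$sample_id[samples$lineage == "ASM"], gm1$samples)
  gm2 <- hwe_filter(gm1, ctrl, alpha = hwe_alpha)
  rep0 <- log_rule(rep0, "hwe_control", nrow(gm1$loci) - nrow(gm2$loci))
  esm <- intersect(samples$sample_id[samples$lineage == "ESM"], gm2$samples)
  gm3 <- maf_filter(gm2, esm, global_min = global_min, esm_min = esm_min)
  rep0 <- log_rule(rep0, "maf", nrow(gm2$loci) - nrow(gm3$loci))
  gm4 <- missing_depth_filter(gm3, max_missing = max_missing,
                              min_mean_depth = min_mean_depth)
  rep0 <- log_rule(rep0, "missing_depth", nrow(gm3$loci) - nrow(gm4$loci))
  gm5 <- ld_prune_complete(gm4, seed = seed)
  rep0 <- log_rule(rep0, "ld_complete", nrow(gm4$loci) - nrow(gm5$loci))
  gm6 <- sample_filter(gm5, max_missing = sample_max_missing)
  rep0 <- log_rule(rep0, "sample_missing", 0L,
                   length(gm5$samples) - length(gm6$samples))
  list(gm = gm6, report = rep0)
}
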