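#' Inbred-line whole-genome QC
#'
#' Retains biallelic SNPs only; calls with fewer than \code{min_depth}
#' reads (default 10, boundary inclusive) are set missing; loci with
#' heterozygosity above \code{max_het} among non-missing calls (possible
#' paralogs) or a genotyping rate below \code{min_rate} are discarded.
#'
#' @param gm a \code{genotype_matrix} with depth.
#' @param min_depth minimum reads per retained call (default 10).
#' @param max_het heterozygosity cutoff (default 0.93, strict >).
#' @param min_rate genotyping-rate cutoff (default 0.70, strict <).
#' @return filtered \code{genotype_matrix}.
#' @export
inbred_qc <- function(gm, min_depth = 10, max_het = 0.93, min_rate = 0.70) {
  gm <- filter_biallelic(gm, snps_only = TRUE)
  gm$dosage[gm$depth < min_depth] <- NA_integer_
  called <- !is.na(gm$dosage)
  rate <- colMeans(called)
  het <- colSums(gm$dosage == 1L, na.rm = TRUE) / pmax(colSums(called), 1L)
  keep <- !(het > max_het | rate < min_rate)
  gm_subset(gm, loci = keep)
}

inbred_groups <- function(samples) {
  role <- samples$role
  score <- samples$flight_score
  parents <- samples$sample_id[role == "parent"]
  if (length(parents) != 2) stop("need exactly 2 parents in the sample table")
  flyers <- samples$sample_id[score >= 5 & !is.na(score)]
  nonfly <- samples$sample_id[score <= 2 & !is.na(score)]
  if (!length(setdiff(flyers, parents)) || !length(setdiff(nonfly, parents))) {
    stop("empty flyer or non-flyer progeny group")
  }
  list(parents = parents, flyers = flyers, nonfly = nonfly)
}

#' Co-segregation filter for the inbred line
#'
#' In conjunction mode (default) a locus is a candidate iff the two
#' parents are opposite-homozygous AND every member of the flying group
#' (ASM parent plus score-5 progeny) is homozygous for one allele AND
#' every member of the non-flying group (ESM parent plus low-score
#' progeny) is heterozygous or homozygous for the opposite allele. In
#' union mode either the parent criterion or the progeny criterion alone
#' suffices. A missing genotype in any group member makes the locus
#' ineligible. Group membership comes from the sample table: parents join
#' the phenotype group their flight score indicates; occasional
#' heterozygotes are tolerated only among non-flyers.
#'
#' The per-locus allele-frequency difference is
#' |freq(flyer allele in flyers) - freq(flyer allele in non-flyers)|
#' by direct allele counting within each group.
#'
#' @param gm a \code{genotype_matrix} (post \code{\link{inbred_qc}}).
#' @param samples sample table with roles and flight scores.
#' @param mode "conjunction" or "union".
#' @return object of class \code{segregation_report}: candidate table with
#'   per-locus flags and frequency differences.
#' @export
segregating_candidates <- function(gm, samples, mode = c("conjunction", "union")) {
  mode <- match.arg(mode)
  samples <- validate_sample_table(samples)
  grp <- inbred_groups(samples)
  miss <- setdiff(c(grp$parents, grp$flyers, grp$nonfly), gm$samples)
  if (length(miss)) stop("sample(s) missing from the matrix: ",
                         paste(miss, collapse = ", "))
  P <- gm$dosage[match(grp$parents, gm$samples), , drop = FALSE]
  Fg <- gm$dosage[match(grp$flyers, gm$samples), , drop = FALSE]
  Ng <- gm$dosage[match(grp$nonfly, gm$samples), , drop = FALSE]
  L <- ncol(gm$dosage)

  eligible <- colSums(is.na(rbind(P, Fg, Ng))) == 0
  par_opp <- eligible & ((P[1, ] == 0L & P[2, ] == 2L) |
                         (P[1, ] == 2L & P[2, ] == 0L))
  fly_hom <- eligible & (colSums(Fg == 0L) == nrow(Fg) |
                         colSums(Fg == 2L) == nrow(Fg))
  # flyer-fixed allele dosage (0 or 2); only meaningful where fly_hom
  fly_allele <- ifelse(colSums(Fg == 2L) == nrow(Fg), 2L, 0L)
  opp <- 2L - fly_allele
  non_ok <- eligible & vapply(seq_len(L), function(j) {
    all(Ng[, j] == 1L | Ng[, j] == opp[j])
  }, logical(1))
  progeny_pattern <- fly_hom & non_ok
  cand <- if (mode == "conjunction") par_opp & progeny_pattern
          else par_opp | progeny_pattern

  # allele counting of the flyer allele within groups; where the flyer
  # group is not fixed, use the major flyer allele as reference
  ref_allele <- ifelse(fly_hom, fly_allele,
                       ifelse(colMeans(Fg, na.rm = TRUE) >= 1, 2L, 0L))
  freq_of <- function(Gp, j) {
    g <- Gp[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    cnt <- if (ref_allele[j] == 2L) sum(g) else sum(2L - g)
    cnt / (2 * length(g))
  }
  diffs <- vapply(seq_len(L), function(j) {
    abs(freq_of(Fg, j) - freq_of(Ng, j))
  }, numeric(1))

  idx <- which(cand)
  tab <- data.frame(locus = locus_ids(gm$loci)[idx],
                    contig = gm$loci$contig[idx],
                    pos = gm$loci$pos[idx],
                    parents_opposite_hom = par_opp[idx],
                    flyers_hom = fly_hom[idx],
                    nonflyers_het_or_opposite = non_ok[idx],
                    freq_diff = diffs[idx],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(candidates = tab, mode = mode,
                 groups = grp, n_tested = L),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("segregation_report (%s): %d candidate loci on %d contigs (of %d tested)\n",
              x$mode, nrow(x$candidates),
              length(unique(x$candidates$contig)), x$n_tested))
  if (nrow(x$candidates)) {
    cat(sprintf("  allele-frequency difference: mean %.3f, SD %.3f\n",
                mean(x$candidates$freq_diff),
                stats::sd(x$candidates$freq_diff)))
  }
  invisible(x)
}

#' Summary statistics of the co-segregation candidates
#'
#' @param report a \code{segregation_report}.
#' @return list(mean, sd, n_loci, n_contigs) of the per-locus
#'   flyer/non-flyer allele-frequency differences.
#' @export
segregation_summary <- function(report) {
  d <- report$candidates$freq_diff
  if (!length(d)) stop("no candidate loci to summarise")
  list(mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else 0,
       n_loci = length(d),
       n_contigs = length(unique(report$candidates$contig)))
}
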