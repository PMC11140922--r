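# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results with naive loops or
# closed forms so they never share code with the implementation.

rand_gm <- function(n = 20, L = 50, miss = 0.1, seed = 1,
                    depth_lambda = 12, n_contigs = 5) {
  set.seed(seed)
  p <- runif(L, 0.05, 0.95)
  g <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  g[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  depth <- matrix(rpois(n * L, depth_lambda), n, L)
  loci <- data.frame(contig = sprintf("c%d", ((seq_len(L) - 1) %% n_contigs) + 1),
                     pos = as.integer(seq_len(L) * 7),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  loci <- loci[order(loci$contig, loci$pos), ]
  genotype_matrix(g, depth, loci)
}

# direct per-locus recomputation of each QC rule with plain loops
oracle_maf_keep <- function(gm, esm_ids, g_min, e_min) {
  esm_rows <- match(esm_ids, gm$samples)
  sapply(seq_len(ncol(gm$dosage)), function(j) {
    mafv <- function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(0)
      f <- sum(g) / (2 * length(g)); min(f, 1 - f)
    }
    !(mafv(gm$dosage[, j]) < g_min && mafv(gm$dosage[esm_rows, j]) < e_min)
  })
}

oracle_missdepth_keep <- function(gm, max_miss, min_dep) {
  sapply(seq_len(ncol(gm$dosage)), function(j) {
    !(mean(is.na(gm$dosage[, j])) > max_miss || mean(gm$depth[, j]) < min_dep)
  })
}

oracle_sample_keep <- function(gm, max_miss) {
  sapply(seq_len(nrow(gm$dosage)), function(i) {
    !(mean(is.na(gm$dosage[i, ])) > max_miss)
  })
}

oracle_hwe_keep <- function(gm, ctrl_ids, alpha) {
  rows <- match(ctrl_ids, gm$samples)
  sapply(seq_len(ncol(gm$dosage)), function(j) {
    g <- gm$dosage[rows, j]; g <- g[!is.na(g)]
    oracle_hwe_p(sum(g == 0), sum(g == 1), sum(g == 2)) >= alpha
  })
}

# exact HWE p by direct enumeration with choose(); independent of the
# log-factorial implementation in the package
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  na <- 2 * n0 + n1
  rare <- min(na, 2 * n - na)
  hs <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hs, function(h) {
    hr <- (rare - h) / 2; hc <- n - h - hr
    exp(lchoose(n, hr) + lchoose(n - hr, h) + h * log(2) -
          lchoose(2 * n, rare))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == n1] + 1e-12])
}

# all pairs within contigs with |cor| == 1 on pairwise-complete cases
oracle_complete_ld_pairs <- function(gm) {
  out <- NULL
  for (ct in unique(gm$loci$contig)) {
    idx <- which(gm$loci$contig == ct)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      ok <- !is.na(gm$dosage[, i]) & !is.na(gm$dosage[, j])
      if (sum(ok) < 2) next
      r <- suppressWarnings(cor(gm$dosage[ok, i], gm$dosage[ok, j]))
      if (is.finite(r) && abs(r) >= 1 - 1e-12) out <- rbind(out, c(i, j))
    }
  }
  out
}

# weighted modularity of a partition (membership vector)
modularity_of <- function(A, mem) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (mem[i] == mem[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

# enumerate all set partitions of 1..n as membership vectors
all_partitions <- function(n) {
  parts <- list(c(1L))
  for (v in seq_len(n)[-1]) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_len(max(p) + 1L)) nxt[[length(nxt) + 1L]] <- c(p, b)
    }
    parts <- nxt
  }
  parts
}

oracle_best_partition <- function(A) {
  parts <- all_partitions(nrow(A))
  qs <- vapply(parts, function(p) modularity_of(A, p), numeric(1))
  parts[[which.max(qs)]]
}

canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, "", 1))]
}

membership_to_clusters <- function(mem, nodes) {
  canonical_clusters(unname(split(nodes, mem)))
}

# planted-partition weighted graph generator
planted_graph <- function(blocks, within = 1, between = 0.1,
                          p_within = 1, p_between = 1, seed = 1) {
  set.seed(seed)
  n <- sum(blocks)
  mem <- rep(seq_along(blocks), blocks)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (mem[i] == mem[j]) {
      if (runif(1) < p_within) A[i, j] <- A[j, i] <- within
    } else if (runif(1) < p_between) {
      A[i, j] <- A[j, i] <- between
    }
  }
  list(nodes = sprintf("n%02d", seq_len(n)), adjacency = A, membership = mem)
}

# Hudson Fst from two population allele-frequency vectors (ratio of
# averages form, on true frequencies)
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# structureless case/control cohort with optional planted loci
flat_cohort <- function(seed, n_loci, n_causal = 0, beta = 0,
                        n_families = 150, missing = 0) {
  simulate_cohort(synth_config(
    seed = seed, n_loci = n_loci, n_contigs = max(10, n_loci %/% 20),
    n_colonies_per_lineage = 1, families_per_colony = n_families,
    sibs_per_family = 1, fst_lineage = 0.01, fst_colony = 0.01,
    lineage_logit = 0, n_causal_flight = n_causal, n_causal_wing = 0,
    beta_flight = beta, missing_rate = missing))
}

make_terms <- function(sets, defs = NULL) {
  ids <- names(sets)
  terms <- lapply(ids, function(id) {
    list(term_id = id, name = id,
         definition = if (!is.null(defs)) defs[[id]] else "",
         genes = sets[[id]])
  })
  names(terms) <- ids
  terms
}
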