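#' Synthetic study-design configuration
#'
#' Defaults emulate the study system: two lineages (ESM typically
#' flightless, ASM flight-capable) with four colonies each, family
#' structure within colonies, ~300 genotyped females, flight scores massed
#' at 0 and 5, a handful of planted flight and forewing loci, and an
#' ESM x ASM inbred pedigree carried to F5.
#'
#' @param seed integer RNG seed.
#' @param n_colonies_per_lineage colonies per lineage (default 4, i.e. 8
#'   total as in the colony panel).
#' @param families_per_colony,sibs_per_family full-sib family layout; the
#'   product is the colony sample size (default 9 x 4 = 36, ~288 overall).
#' @param n_loci biallelic SNP loci simulated.
#' @param n_contigs loci are spread uniformly over this many contigs.
#' @param fst_lineage,fst_colony Balding-Nichols divergence of lineages
#'   from the ancestral pool and of colonies from their lineage.
#' @param n_causal_flight,n_causal_wing planted causal locus counts.
#' @param beta_flight log-odds per alternate allele on the flight liability.
#' @param beta_wing mm per alternate allele on forewing length.
#' @param lineage_logit baseline flight log-odds, +ASM / -ESM.
#' @param wing_mean_esm,wing_mean_asm,wing_sd forewing length model (mm).
#' @param missing_rate independent per-call missingness probability.
#' @param mean_depth Poisson mean of per-call read depth.
#' @param n_genes,terms_per_gene,n_terms annotation generator sizes.
#' @param inbred_generations pedigree depth (5 = F5).
#' @param inbred_progeny progeny reared per generation.
#' @param crossover_rate per-contig probability that a transmitted gamete
#'   switches parental haplotype (block inheritance).
#' @param inbred_n_causal,inbred_beta planted inbred-line flight loci.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L,
                         n_colonies_per_lineage = 4L,
                         families_per_colony = 9L,
                         sibs_per_family = 4L,
                         n_loci = 2000L,
                         n_contigs = 200L,
                         fst_lineage = 0.2,
                         fst_colony = 0.05,
                         n_causal_flight = 5L,
                         n_causal_wing = 5L,
                         beta_flight = 1.0,
                         beta_wing = 0.6,
                         lineage_logit = 2.5,
                         wing_mean_esm = 22,
                         wing_mean_asm = 27,
                         wing_sd = 1.5,
                         missing_rate = 0.02,
                         mean_depth = 20,
                         n_genes = 800L,
                         terms_per_gene = 3L,
                         n_terms = 80L,
                         inbred_generations = 5L,
                         inbred_progeny = 40L,
                         crossover_rate = 0.1,
                         inbred_n_causal = 10L,
                         inbred_beta = 2.0) {
  cfg <- as.list(environment())
  rates <- c(cfg$fst_lineage, cfg$fst_colony, cfg$missing_rate, cfg$crossover_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$fst_lineage <= 0 || cfg$fst_lineage >= 1 ||
      cfg$fst_colony <= 0 || cfg$fst_colony >= 1) {
    stop("Fst values must lie in (0, 1)")
  }
  counts <- c(cfg$n_loci, cfg$n_contigs, cfg$families_per_colony,
              cfg$sibs_per_family, cfg$n_colonies_per_lineage)
  if (any(counts < 1)) stop("counts must be positive")
  if (cfg$n_causal_flight + cfg$n_causal_wing > cfg$n_loci) {
    stop("causal loci exceed n_loci")
  }
  if (cfg$n_terms < cfg$terms_per_gene) {
    stop("term universe smaller than terms per gene")
  }
  class(cfg) <- "synth_config"
  cfg
}

bn_freq <- function(p_anc, fst, n) {
  # Balding-Nichols: daughter frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  stats::rbeta(n, a, b)
}

synth_loci <- function(n_loci, n_contigs, prefix = "ctg") {
  contig <- sprintf("%s%03d", prefix, ((seq_len(n_loci) - 1L) %% n_contigs) + 1L)
  pos <- integer(n_loci)
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    pos[idx] <- sort(sample.int(1e6, length(idx)))
  }
  alle <- matrix(c("A", "C", "G", "T")[
    t(replicate(n_loci, sample.int(4, 2)))], n_loci, 2)
  data.frame(contig = contig, pos = pos, ref = alle[, 1], alt = alle[, 2],
             is_indel = FALSE, stringsAsFactors = FALSE)
}

score_from_class <- function(cls) {
  # ordinal 0-5 mapping with mass pushed to the extremes
  n <- length(cls)
  hi <- sample(c(5L, 4L, 3L), n, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  lo <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  ifelse(cls, hi, lo)
}

#' Simulate the multi-colony GWAS cohort
#'
#' Allele frequencies are drawn hierarchically (ancestral -> lineage ->
#' colony, Balding-Nichols at the configured Fst values). Each colony is a
#' set of full-sib families: two parents are drawn from the colony
#' frequencies and sibling genotypes are formed from parental gametes.
#' Flight class comes from a logistic liability (lineage baseline, ASM
#' high, plus planted additive causal loci) mapped onto the 0-5 ordinal
#' score with mass concentrated at 0 and 5; forewing length is Gaussian
#' with its own planted additive loci. Missingness is independent
#' Bernoulli; depth is Poisson.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list(gm, samples, truth): the \code{genotype_matrix}, the sample
#'   table, and a truth record with causal locus indices/effects, family
#'   membership and drawn frequencies.
#' @export
simulate_cohort <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  L <- cfg$n_loci
  loci <- synth_loci(L, cfg$n_contigs)
  p_anc <- stats::runif(L, 0.1, 0.9)
  col_esm <- c("UC", "KG", sprintf("E%02d", seq_len(cfg$n_colonies_per_lineage)))[seq_len(cfg$n_colonies_per_lineage)]
  col_asm <- c("CJ", "CR", "CN", "RS", "RM", "JN",
               sprintf("A%02d", seq_len(cfg$n_colonies_per_lineage)))[seq_len(cfg$n_colonies_per_lineage)]
  p_lin <- list(ESM = bn_freq(p_anc, cfg$fst_lineage, L),
                ASM = bn_freq(p_anc, cfg$fst_lineage, L))
  colony_freq <- list()
  for (cl in col_esm) colony_freq[[cl]] <- bn_freq(p_lin$ESM, cfg$fst_colony, L)
  for (cl in col_asm) colony_freq[[cl]] <- bn_freq(p_lin$ASM, cfg$fst_colony, L)
  colony_lineage <- c(stats::setNames(rep("ESM", length(col_esm)), col_esm),
                      stats::setNames(rep("ASM", length(col_asm)), col_asm))

  n_per_col <- cfg$families_per_colony * cfg$sibs_per_family
  n <- n_per_col * length(colony_freq)
  dosage <- matrix(NA_integer_, n, L)
  colony <- character(n); family <- character(n)
  row <- 0L
  for (cl in names(colony_freq)) {
    p <- colony_freq[[cl]]
    for (f in seq_len(cfg$families_per_colony)) {
      # parental haplotypes drawn from colony frequencies
      hp <- rbind(stats::rbinom(L, 1, p), stats::rbinom(L, 1, p),
                  stats::rbinom(L, 1, p), stats::rbinom(L, 1, p))
      for (s in seq_len(cfg$sibs_per_family)) {
        row <- row + 1L
        g1 <- ifelse(stats::runif(L) < 0.5, hp[1, ], hp[2, ])
        g2 <- ifelse(stats::runif(L) < 0.5, hp[3, ], hp[4, ])
        dosage[row, ] <- as.integer(g1 + g2)
        colony[row] <- cl
        family[row] <- sprintf("%s_f%02d", cl, f)
      }
    }
  }
  lineage <- unname(colony_lineage[colony])

  causal_idx <- if (cfg$n_causal_flight + cfg$n_causal_wing > 0) {
    sample.int(L, cfg$n_causal_flight + cfg$n_causal_wing)
  } else integer(0)
  flight_idx <- utils::head(causal_idx, cfg$n_causal_flight)
  wing_idx <- utils::tail(causal_idx, cfg$n_causal_wing)

  g_eff <- if (length(flight_idx)) {
    dosage[, flight_idx, drop = FALSE] %*% rep(cfg$beta_flight, length(flight_idx))
  } else numeric(n)
  base <- ifelse(lineage == "ASM", cfg$lineage_logit, -cfg$lineage_logit)
  # centre each planted locus at its ancestral expected dosage so the
  # lineage baseline, not the draw of causal frequencies, sets prevalence
  centering <- if (length(flight_idx)) {
    cfg$beta_flight * sum(2 * p_anc[flight_idx])
  } else 0
  liab <- base + as.numeric(g_eff) - centering + stats::rlogis(n)
  flight_class <- liab > 0
  flight_score <- score_from_class(flight_class)

  w_eff <- if (length(wing_idx)) {
    dosage[, wing_idx, drop = FALSE] %*% rep(cfg$beta_wing, length(wing_idx))
  } else numeric(n)
  wing_mean <- ifelse(lineage == "ASM", cfg$wing_mean_asm, cfg$wing_mean_esm)
  w_ctr <- if (length(wing_idx)) cfg$beta_wing * sum(2 * p_anc[wing_idx]) else 0
  forewing <- wing_mean + as.numeric(w_eff) - w_ctr +
    stats::rnorm(n, 0, cfg$wing_sd)

  miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
  dosage[miss] <- NA_integer_
  depth <- matrix(stats::rpois(n * L, cfg$mean_depth), n, L)

  ids <- sprintf("%s_%03d", colony, stats::ave(seq_len(n), colony, FUN = seq_along))
  gm <- genotype_matrix(dosage, depth, loci, samples = ids)
  samples <- data.frame(sample_id = ids, colony = colony, lineage = lineage,
                        flight_score = flight_score,
                        forewing_length_mm = round(forewing, 2),
                        role = "cohort", family = family,
                        stringsAsFactors = FALSE)
  truth <- list(flight_causal = flight_idx, wing_causal = wing_idx,
                beta_flight = cfg$beta_flight, beta_wing = cfg$beta_wing,
                family = family, colony_freq = colony_freq,
                lineage_freq = p_lin, flight_class = flight_class)
  list(gm = gm, samples = samples, truth = truth)
}

inbred_gamete <- function(hap1, hap2, contig, crossover_rate) {
  # block inheritance: per contig pick a starting haplotype, switch with
  # probability crossover_rate at a uniform breakpoint inside the contig
  out <- integer(length(hap1))
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    first <- sample(c(TRUE, FALSE), 1)
    pick <- rep(first, length(idx))
    if (length(idx) > 1 && stats::runif(1) < crossover_rate) {
      bp <- sample(length(idx) - 1L, 1L)
      pick[(bp + 1L):length(idx)] <- !first
    }
    out[idx] <- ifelse(pick, hap1[idx], hap2[idx])
  }
  out
}

#' Simulate the ESM x ASM inbred line
#'
#' Two divergent parents (ESM female, ASM male) found the pedigree; each
#' subsequent generation is a single full-sib cross whose gametes inherit
#' whole per-contig blocks with a small crossover probability, mimicking
#' the strong linkage disequilibrium expected under repeated full-sib
#' mating. Planted causal loci (opposite-homozygous in the parents) drive
#' the flight score. The output holds the 2 parents plus 4 strongly flying
#' (score 5) and 4 non-flying (score <= 1) female progeny drawn from
#' generations F2 onward.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list(gm, samples, truth); \code{truth$pattern_loci} lists the
#'   loci that satisfy the parent/flyer/non-flyer co-segregation pattern in
#'   the emitted genotypes (verified by direct genotype inspection).
#' @export
simulate_inbred_lines <- function(cfg = synth_config()) {
  set.seed(cfg$seed + 1L)
  L <- cfg$n_loci
  loci <- synth_loci(L, cfg$n_contigs, prefix = "wgs")
  causal <- sort(sample.int(L, cfg$inbred_n_causal))
  # parent haplotypes: divergent frequencies; causal loci fixed opposite
  p_esm <- stats::rbeta(L, 0.8, 0.8) * 0.5        # skew ESM toward ref
  p_asm <- 1 - stats::rbeta(L, 0.8, 0.8) * 0.5
  esm_h <- rbind(stats::rbinom(L, 1, p_esm), stats::rbinom(L, 1, p_esm))
  asm_h <- rbind(stats::rbinom(L, 1, p_asm), stats::rbinom(L, 1, p_asm))
  esm_h[, causal] <- 0L
  asm_h[, causal] <- 1L

  liability <- function(ind) {
    cfg$inbred_beta * sum(ind$h1[causal] + ind$h2[causal] - 1)  # centered at het
  }
  cross <- function(mo, fa, n_prog) {
    lapply(seq_len(n_prog), function(i) {
      list(h1 = inbred_gamete(mo$h1, mo$h2, loci$contig, cfg$crossover_rate),
           h2 = inbred_gamete(fa$h1, fa$h2, loci$contig, cfg$crossover_rate))
    })
  }
  parents <- list(ESM_mother = list(h1 = esm_h[1, ], h2 = esm_h[2, ]),
                  ASM_father = list(h1 = asm_h[1, ], h2 = asm_h[2, ]))
  if (cfg$inbred_generations < 3 || cfg$inbred_progeny < 4) {
    stop("cannot produce 4 flying + 4 non-flying progeny: ",
         "need inbred_generations >= 3 and inbred_progeny >= 4")
  }
  # F1, then two phenotype-selected full-sib sublines (strong flight vs
  # minimal flight), mirroring selection of extreme egg masses each
  # generation; sequenced extremes are drawn from F2 onward
  f1 <- cross(parents[[1]], parents[[2]], cfg$inbred_progeny)
  liab1 <- vapply(f1, liability, numeric(1)) + stats::rnorm(length(f1), 0, 0.25)
  ordf1 <- order(liab1)
  line <- list(
    fly = list(mo = f1[[ordf1[length(ordf1)]]], fa = f1[[ordf1[length(ordf1) - 1]]]),
    nofly = list(mo = f1[[ordf1[1]]], fa = f1[[ordf1[2]]]))
  pool <- list(fly = list(), nofly = list())
  for (gen in 2:cfg$inbred_generations) {
    for (ln in c("fly", "nofly")) {
      prog <- cross(line[[ln]]$mo, line[[ln]]$fa, cfg$inbred_progeny)
      liab <- vapply(prog, liability, numeric(1)) +
        stats::rnorm(length(prog), 0, 0.25)
      ord <- if (ln == "fly") order(-liab) else order(liab)
      pool[[ln]][[sprintf("F%d", gen)]] <- prog[[ord[1]]]
      line[[ln]] <- list(mo = prog[[ord[1]]], fa = prog[[ord[2]]])
    }
  }
  pick_gens <- function(av) {
    # mirror the sequenced mix (one F2, one F3, two F5 when available)
    last <- av[length(av)]
    g <- c(av[1], av[min(2, length(av))], last, last)
    g[seq_len(4)]
  }
  gens <- names(pool$fly)
  sel <- pick_gens(gens)
  flyers <- pool$fly[sel]
  nonfly <- pool$nofly[sel]
  # duplicates of the same selected individual would be clones; re-draw
  # extra sibs for repeated generations instead
  dedup <- function(lst, ln) {
    seen <- character(0); out <- list()
    for (i in seq_along(lst)) {
      g <- names(lst)[i] %||% sel[i]
      if (g %in% seen) {
        prog <- cross(line[[ln]]$mo, line[[ln]]$fa, cfg$inbred_progeny)
        liab <- vapply(prog, liability, numeric(1))
        ord <- if (ln == "fly") order(-liab) else order(liab)
        out[[paste0(g, "_", i)]] <- prog[[ord[1]]]
      } else {
        out[[g]] <- lst[[i]]
        seen <- c(seen, g)
      }
    }
    out
  }
  flyers <- dedup(flyers, "fly")
  nonfly <- dedup(nonfly, "nofly")

  all_ind <- c(parents, flyers, nonfly)
  dosage <- t(vapply(all_ind, function(ind) as.integer(ind$h1 + ind$h2),
                     integer(L)))
  ids <- c("ESM_mother", "ASM_father",
           sprintf("fly_%d", 1:4), sprintf("nofly_%d", 1:4))
  rownames(dosage) <- ids
  depth <- matrix(stats::rpois(length(dosage), max(cfg$mean_depth, 30)),
                  nrow(dosage), ncol(dosage))
  gm <- genotype_matrix(dosage, depth, loci, samples = ids)
  scores <- c(0L, 5L, rep(5L, 4), c(1L, 1L, 1L, 2L))  # non-flyer mean 1.25
  samples <- data.frame(
    sample_id = ids,
    colony = c("UC", "RM", rep("IB", 8)),
    lineage = c("ESM", "ASM", rep("ASM", 4), rep("ESM", 4)),
    flight_score = scores,
    forewing_length_mm = NA_real_,
    role = c("parent", "parent", rep("progeny", 8)),
    stringsAsFactors = FALSE)

  # truth: loci satisfying the co-segregation pattern, by direct inspection
  par_opp <- (dosage[1, ] == 0L & dosage[2, ] == 2L) |
             (dosage[1, ] == 2L & dosage[2, ] == 0L)
  fly_rows <- c(2, 3:6); non_rows <- c(1, 7:10)
  pattern <- vapply(seq_len(L), function(j) {
    fg <- dosage[fly_rows, j]; ng <- dosage[non_rows, j]
    if (anyNA(fg) || anyNA(ng)) return(FALSE)
    if (!par_opp[j]) return(FALSE)
    if (!(all(fg == 0L) || all(fg == 2L))) return(FALSE)
    opp <- 2L - fg[1]
    all(ng == 1L | ng == opp)
  }, logical(1))
  truth <- list(causal = causal, pattern_loci = which(pattern),
                parents_opposite = which(par_opp))
  list(gm = gm, samples = samples, truth = truth)
}

#' Simulate a GO-annotated gene set
#'
#' Genes are tiled without overlap along the cohort contigs; GO terms get a
#' skewed (power-law) genes-per-term distribution; term names and
#' definitions are composed from a word pool seeded with the category
#' keywords so keyword categorization is exercised.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param contigs contig names to tile genes on (default: the cohort's).
#' @return list(genes, terms, scheme).
#' @export
simulate_annotation <- function(cfg = synth_config(),
                                contigs = sprintf("ctg%03d", seq_len(cfg$n_contigs))) {
  set.seed(cfg$seed + 2L)
  scheme <- category_scheme()
  ng <- cfg$n_genes
  contig <- sample(contigs, ng, replace = TRUE)
  genes <- do.call(rbind, lapply(unique(contig), function(ct) {
    k <- sum(contig == ct)
    starts <- sort(sample.int(9e5, k))
    width <- sample(20000:80000, k, replace = TRUE)
    ends <- starts + width
    if (k > 1) ends <- pmin(ends, c(starts[-1] - 1L, 1e6))  # no overlap
    data.frame(contig = ct, start = starts, end = pmax(ends, starts),
               stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("Lda.%04d", seq_len(ng))
  genes <- genes[c("gene_id", "contig", "start", "end")]

  pool <- c(unlist(scheme, use.names = FALSE),
            "protein", "cell", "pathway", "signal", "response", "binding",
            "membrane", "nuclear", "hormone", "enzyme", "larval", "pupal")
  pool <- unique(unlist(strsplit(pool, " ")))
  term_ids <- sprintf("GO:%07d", seq_len(cfg$n_terms))
  # skewed genes-per-term sizes (discrete power law)
  sizes <- pmax(1L, pmin(ng, as.integer(round(2 / stats::runif(cfg$n_terms)^0.8))))
  map <- do.call(rbind, lapply(seq_along(term_ids), function(i) {
    data.frame(gene_id = sample(genes$gene_id, sizes[i]),
               term_id = term_ids[i], stringsAsFactors = FALSE)
  }))
  defs <- data.frame(
    term_id = term_ids,
    name = vapply(term_ids, function(t) paste(sample(pool, 3), collapse = " "), ""),
    definition = vapply(term_ids, function(t) paste(sample(pool, 8), collapse = " "), ""),
    stringsAsFactors = FALSE)
  # every gene appears in the universe: top up genes with no term
  orphan <- setdiff(genes$gene_id, map$gene_id)
  if (length(orphan)) {
    map <- rbind(map, data.frame(gene_id = orphan,
                                 term_id = sample(term_ids, length(orphan), replace = TRUE),
                                 stringsAsFactors = FALSE))
  }
  map <- unique(map)
  list(genes = genes, terms = go_terms(map, defs), scheme = scheme, map = map,
       defs = defs)
}
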