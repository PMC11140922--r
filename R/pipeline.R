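default_pipeline_config <- function() {
  list(
    seed = 1L,
    synth = list(),                    # synth_config overrides
    qc = list(hwe_alpha = 1e-6, global_min = 0.10, esm_min = 0.30,
              max_missing = 0.5, min_mean_depth = 5,
              sample_max_missing = 0.5),
    structure = list(kinship_threshold = 0.025, n_pcs = 4L,
                     kin_factors = 2L),
    gwas = list(pc_grid = c(0L, 2L, 4L), r_min = 0.90, p_max = 0.05),
    enrich = list(alpha = 0.05, fdr = 0.05, edge_threshold = 0.5,
                  inflation = 2.0),
    profile = list(n_train_per_class = 50L, n_reps = 10L,
                   n_panel_loci = 12L, chance = "majority"))
}

#' Validate and normalise a pipeline configuration
#'
#' Unknown keys are rejected; defaults (the published threshold set: MAF
#' 0.10/0.30, HWE 1e-6, missingness 0.5, depth 5, kinship 0.025, LD r
#' 0.90, alpha 0.05, FDR 5%, 50/50 training, 10 replicates) fill any gap;
#' out-of-range values raise errors.
#'
#' @param config named list (possibly empty) of overrides, nested by
#'   stage.
#' @return the fully populated configuration list.
#' @export
validate_config <- function(config = list()) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "seed") { def$seed <- as.integer(config$seed); next }
    allowed <- if (sec == "synth") setdiff(names(formals(synth_config)), "seed")
               else names(def[[sec]])
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) stop(sprintf("unknown key(s) in '%s': %s", sec,
                                  paste(bad, collapse = ", ")))
    def[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  with(def$qc, {
    if (hwe_alpha < 0 || hwe_alpha > 1) stop("hwe_alpha out of range")
    if (global_min < 0 || global_min > 0.5 || esm_min < 0 || esm_min > 0.5)
      stop("MAF thresholds must lie in [0, 0.5]")
    if (max_missing < 0 || max_missing > 1) stop("max_missing out of range")
  })
  if (def$structure$kinship_threshold < 0) stop("kinship threshold must be non-negative")
  if (def$gwas$r_min < 0 || def$gwas$r_min > 1) stop("r_min out of range")
  if (def$gwas$p_max <= 0 || def$gwas$p_max > 1) stop("p_max out of range")
  if (def$enrich$inflation <= 1) stop("MCL inflation must exceed 1")
  if (def$profile$n_reps < 1) stop("need at least one profiling replicate")
  def
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes synth -> QC -> structure -> GWAS (flight and forewing) -> LD
#' gene annotation -> inbred co-segregation -> GO/category enrichment with
#' MCL clustering -> DAPC profiling, writing every stage artifact (VCF,
#' TSV, JSON) plus a reproducibility manifest with seeds, per-stage
#' timings and output digests into \code{out_dir}. All randomness derives
#' from the root seed.
#'
#' @param config configuration list (see \code{\link{validate_config}}).
#' @param out_dir output directory (created if absent); NULL skips file
#'   output.
#' @return list of stage results plus \code{manifest}, invisibly.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(config = cfg, seed = cfg$seed, stages = list(),
                   version = as.character(utils::packageVersion("flightsift")))
  artifacts <- character(0)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }
  emit <- function(obj, file, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
  }

  scfg <- do.call(synth_config, c(list(seed = cfg$seed), cfg$synth))
  cohort <- t_stage("synth_cohort", simulate_cohort(scfg))
  annot <- t_stage("synth_annotation", simulate_annotation(scfg))
  inb <- t_stage("synth_inbred", simulate_inbred_lines(scfg))
  emit(cohort$gm, "cohort.vcf", write_vcf)
  emit(cohort$samples, "phenotypes.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit(cohort$truth[c("flight_causal", "wing_causal")], "truth.json",
       write_json_out)

  qc <- t_stage("qc", do.call(run_qc, c(list(gm = cohort$gm,
                                             samples = cohort$samples,
                                             seed = cfg$seed), cfg$qc)))
  gmq <- qc$gm
  emit(gmq, "cohort_qc.vcf", write_vcf)

  stru <- t_stage("structure", {
    kin <- king_kinship(gmq)
    unrel <- partition_unrelated(kin, cfg$structure$kinship_threshold)
    sm <- pca_unrelated_project(gmq, unrel, cfg$structure$n_pcs)
    pk <- pc_adjusted_kinship(gmq, sm)
    list(kinship = kin, unrelated = unrel, model = sm,
         pc_kinship = pk,
         factors = kinship_factors(pk, cfg$structure$kin_factors))
  })

  ph <- cohort$samples[match(gmq$samples, cohort$samples$sample_id), ]
  flight <- bin_flight(ph$flight_score)
  gw <- t_stage("gwas", {
    fl <- model_grid(gmq, flight, stru$model, cfg$gwas$pc_grid,
                     kin_factors = stru$factors, link = "binomial")
    fw <- model_grid(gmq, ph$forewing_length_mm, stru$model,
                     cfg$gwas$pc_grid, kin_factors = stru$factors,
                     link = "gaussian")
    list(flight = fl, forewing = fw)
  })
  emit(gw$flight$selected_result$table, "assoc_flight.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  cand <- t_stage("ldannot", {
    list(flight = ld_annotate(gmq, gw$flight$selected_result, annot$genes,
                              cfg$gwas$r_min, cfg$gwas$p_max),
         forewing = ld_annotate(gmq, gw$forewing$selected_result,
                                annot$genes, cfg$gwas$r_min, cfg$gwas$p_max))
  })

  seg <- t_stage("inbred", {
    gmi <- inbred_qc(inb$gm)
    segregating_candidates(gmi, inb$samples)
  })

  enr <- t_stage("enrich", {
    universe <- annot$genes$gene_id
    cands <- unique(cand$flight$gene_id)
    if (length(cands) >= 1) {
      te <- term_enrichment(cands, annot$terms, universe,
                            alpha = cfg$enrich$alpha)
      etab <- te$table[te$table$enriched, , drop = FALSE]
      eterms <- annot$terms[etab$term_id]
      ecat <- categorize_terms(eterms, annot$scheme)
      rcat <- categorize_terms(annot$terms, annot$scheme)
      co <- category_overrepresentation(ecat, rcat, annot$scheme,
                                        fdr = cfg$enrich$fdr)
      clus <- if (length(eterms) >= 1) {
        g <- build_term_graph(eterms, cfg$enrich$edge_threshold)
        cl <- mcl_cluster(g, inflation = cfg$enrich$inflation)
        describe_clusters(cl, annot$terms, ecat, candidates = cands)
      } else NULL
      list(terms = te, categories = co, clusters = clus)
    } else NULL
  })

  prof <- t_stage("profile", {
    top <- gw$flight$selected_result$table
    panel <- order(top$p)[seq_len(min(cfg$profile$n_panel_loci, nrow(top)))]
    replicate_profiling(gmq, flight, panel,
                        n_train_per_class = min(cfg$profile$n_train_per_class,
                                                min(table(flight)) - 10L),
                        n_reps = cfg$profile$n_reps,
                        chance = cfg$profile$chance,
                        seed = cfg$seed)
  })

  if (!is.null(out_dir)) {
    emit(seg$candidates, "segregation.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit(prof$replicates, "profiling.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    manifest$digests <- as.list(tools::md5sum(artifacts))
    write_json_out(manifest[c("seed", "version", "stages", "digests")],
                   file.path(out_dir, "manifest.json"))
  }
  invisible(list(cohort = cohort, annotation = annot, inbred = inb,
                 qc = qc, structure = stru, gwas = gw, candidates = cand,
                 segregation = seg, enrichment = enr, profiling = prof,
                 manifest = manifest))
}
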