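#' Construct a genotype matrix
#'
#' The central genotype container used by every stage of the pipeline:
#' samples by biallelic loci, stored as alternate-allele dosage (0, 1, 2 or
#' \code{NA} for a missing call) together with the per-call sequencing depth.
#' Depth 0 does not imply a missing genotype: calls may have been imputed
#' upstream.
#'
#' @param dosage integer matrix, samples x loci, values in \{0,1,2\} or NA.
#' @param depth non-negative integer matrix of the same shape.
#' @param loci data.frame with columns \code{contig}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} and optionally \code{is_indel} (logical).
#' @param samples character vector of unique sample ids (defaults to
#'   rownames of \code{dosage}).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, depth = NULL, loci = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) samples <- rownames(dosage)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(dosage)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (length(samples) != nrow(dosage)) stop("samples/dosage shape mismatch")
  if (is.null(depth)) {
    depth <- matrix(0L, nrow(dosage), ncol(dosage))
  }
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (!all(dim(depth) == dim(dosage))) stop("depth/dosage shape mismatch")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  if (is.null(loci)) {
    loci <- data.frame(contig = rep("ctg1", ncol(dosage)),
                       pos = seq_len(ncol(dosage)),
                       ref = "A", alt = "T",
                       is_indel = FALSE,
                       stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$is_indel)) loci$is_indel <- nchar(loci$ref) != 1L | nchar(loci$alt) != 1L
  stopifnot(nrow(loci) == ncol(dosage))
  if (any(loci$pos < 1)) stop("locus positions are 1-based (>= 1)")
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  if (anyDuplicated(loci[, c("contig", "pos")])) {
    stop("(contig, position) must be unique within a matrix")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) stop("dosage values must be 0, 1, 2 or NA")
  rownames(dosage) <- rownames(depth) <- samples
  colnames(dosage) <- colnames(depth) <- locus_ids(loci)
  rownames(loci) <- NULL
  structure(list(dosage = dosage, depth = depth, loci = loci, samples = samples),
            class = "genotype_matrix")
}

locus_ids <- function(loci) paste(loci$contig, loci$pos, sep = ":")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d contigs), %.1f%% missing\n",
              length(x$samples), nrow(x$loci), length(unique(x$loci$contig)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a \code{genotype_matrix}.
#' @param samples,loci index vectors (logical, integer, or character sample
#'   ids for \code{samples}); \code{NULL} keeps everything.
#' @return the subsetted \code{genotype_matrix}.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else samples
  if (is.character(si)) si <- match(si, gm$samples)
  li <- if (is.null(loci)) seq_len(nrow(gm$loci)) else loci
  genotype_matrix(gm$dosage[si, li, drop = FALSE],
                  gm$depth[si, li, drop = FALSE],
                  gm$loci[li, , drop = FALSE],
                  gm$samples[si])
}

#' Test equality of two genotype matrices at the data-model level
#' @param a,b genotype matrices.
#' @return TRUE iff samples, loci, dosage and depth are identical.
#' @export
gm_identical <- function(a, b) {
  identical(a$samples, b$samples) &&
    isTRUE(all.equal(a$loci[c("contig", "pos", "ref", "alt")],
                     b$loci[c("contig", "pos", "ref", "alt")])) &&
    identical(unname(a$dosage), unname(b$dosage)) &&
    identical(unname(a$depth), unname(b$depth))
}

#' Read a VCF file into a genotype matrix
#'
#' Parses GT (required) and DP (optional; absent depth is recorded as 0).
#' Genotypes "./." or ".|." map to missing. Multiallelic records are
#' rejected unless \code{drop_multiallelic = TRUE}, in which case they are
#' dropped with a message; they are never split.
#'
#' @param path path to an uncompressed VCF 4.x file.
#' @param drop_multiallelic drop records with >1 ALT allele instead of
#'   raising an error.
#' @return a \code{genotype_matrix}; indels are flagged in
#'   \code{loci$is_indel}.
#' @export
read_vcf <- function(path, drop_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (!drop_multiallelic) {
      stop(sprintf("multiallelic record at %s:%s (record %d); only biallelic loci are supported",
                   fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]], which(multi)[1]))
    }
    message(sprintf("dropping %d multiallelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, ncol(gt), nrow(gt))
  clean <- gsub("\\|", "/", gt)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (k in names(code)) dosage[t(clean == k)] <- code[[k]]
  bad <- !is.na(clean) & !(clean %in% c(names(code), "./.", "."))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable genotype '%s' at record %d", gt[idx[1], idx[2]], idx[1]))
  }
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  depth <- if (is.null(dp) || all(is.na(dp))) {
    matrix(0L, ncol(gt), nrow(gt))
  } else {
    d <- t(dp); d[is.na(d)] <- 0; d
  }
  loci <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(dosage, depth, loci, samples = colnames(gt))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT:DP per call; missing genotypes become "./.". Round-trips with
#' \code{\link{read_vcf}} bit-identically at the data-model level.
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=flightsift",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  n_loc <- nrow(gm$loci)
  lines <- hdr
  if (n_loc > 0) {
    gt_str <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
    for (d in 0:2) gt_str[which(gm$dosage == d)] <- c("0/0", "0/1", "1/1")[d + 1]
    cell <- matrix(paste(gt_str, gm$depth, sep = ":"),
                   nrow(gm$dosage), ncol(gm$dosage))
    body <- vapply(seq_len(n_loc), function(j) {
      paste(c(gm$loci$contig[j], gm$loci$pos[j], ".", gm$loci$ref[j],
              gm$loci$alt[j], ".", "PASS", ".", "GT:DP", cell[, j]),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

COLONY_CODES <- c("UC", "KG", "CJ", "CR", "CN", "RS", "RM", "JN")

validate_sample_table <- function(ph) {
  need <- c("sample_id", "colony", "lineage")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample_id in phenotype table")
  if (!all(ph$lineage %in% c("ESM", "ASM"))) {
    stop("unknown lineage code: ", paste(setdiff(ph$lineage, c("ESM", "ASM")), collapse = ", "))
  }
  if (is.null(ph$flight_score)) ph$flight_score <- NA_integer_
  fs <- ph$flight_score[!is.na(ph$flight_score)]
  if (length(fs) && (any(fs < 0) || any(fs > 5) || any(fs != round(fs)))) {
    stop("flight_score must be an integer in 0..5")
  }
  if (is.null(ph$forewing_length_mm)) ph$forewing_length_mm <- NA_real_
  fw <- ph$forewing_length_mm[!is.na(ph$forewing_length_mm)]
  if (length(fw) && any(fw <= 0)) stop("forewing_length_mm must be positive")
  if (is.null(ph$role)) ph$role <- "cohort"
  if (!all(ph$role %in% c("cohort", "parent", "progeny"))) {
    stop("role must be one of cohort/parent/progeny")
  }
  ph
}

#' Read the phenotype, gene, GO and category tables
#'
#' All cross-references are validated: every gene id in the GO map must
#' exist in the gene table, and every term id must be defined.
#'
#' @param phenopath TSV with columns sample_id, colony, lineage,
#'   flight_score, forewing_length_mm, role.
#' @param genepath TSV with columns gene_id, contig, start, end
#'   (1-based inclusive).
#' @param gopath TSV gene-to-term map (gene_id, term_id).
#' @param termpath TSV term definitions (term_id, name, definition).
#' @param catpath JSON object mapping category name to a keyword array.
#' @return list with elements \code{samples}, \code{genes}, \code{terms},
#'   \code{scheme}.
#' @export
read_tables <- function(phenopath, genepath = NULL, gopath = NULL,
                        termpath = NULL, catpath = NULL) {
  ph <- utils::read.delim(phenopath, stringsAsFactors = FALSE)
  ph <- validate_sample_table(ph)
  out <- list(samples = ph, genes = NULL, terms = NULL, scheme = NULL)
  if (!is.null(genepath)) {
    gn <- utils::read.delim(genepath, stringsAsFactors = FALSE)
    if (any(gn$start > gn$end)) stop("gene start must be <= end")
    if (anyDuplicated(gn$gene_id)) stop("duplicate gene_id")
    out$genes <- gn
  }
  if (!is.null(gopath)) {
    if (is.null(out$genes)) stop("GO map given without a gene table")
    map <- utils::read.delim(gopath, stringsAsFactors = FALSE)
    dangling <- setdiff(map$gene_id, out$genes$gene_id)
    if (length(dangling)) stop("GO map names unknown gene(s): ",
                               paste(utils::head(dangling, 5), collapse = ", "))
    defs <- if (!is.null(termpath)) utils::read.delim(termpath, stringsAsFactors = FALSE)
            else data.frame(term_id = unique(map$term_id), name = "", definition = "")
    undef <- setdiff(map$term_id, defs$term_id)
    if (length(undef)) stop("GO map uses undefined term(s): ",
                            paste(utils::head(undef, 5), collapse = ", "))
    out$terms <- go_terms(map, defs)
  }
  if (!is.null(catpath)) {
    cats <- jsonlite::read_json(catpath, simplifyVector = TRUE)
    out$scheme <- category_scheme(cats)
  }
  out
}

#' Build a GO term list from a gene-term map and term definitions
#' @param map data.frame (gene_id, term_id).
#' @param defs data.frame (term_id, name, definition).
#' @return list of terms, each a list(term_id, name, definition, genes).
#' @export
go_terms <- function(map, defs) {
  by_term <- split(map$gene_id, map$term_id)
  terms <- lapply(names(by_term), function(tid) {
    i <- match(tid, defs$term_id)
    list(term_id = tid,
         name = if (!is.na(i)) defs$name[i] else "",
         definition = if (!is.na(i)) defs$definition[i] else "",
         genes = sort(unique(by_term[[tid]])))
  })
  names(terms) <- names(by_term)
  terms
}

#' The twelve flight-relevant functional categories
#'
#' Default category scheme: twelve manually defined functional categories
#' potentially relevant to the biology of flight (cognition, growth,
#' metabolism, morphology, movement, mutational mechanisms, neural
#' processes, biological rhythms, reproduction, sensory, sexual dimorphism,
#' social behavior), each with a lower-case keyword list matched against GO
#' term names and definitions.
#'
#' @return named list of keyword character vectors.
#' @export
default_categories <- function() {
  list(
    cognition = c("cognition", "learning", "memory", "decision"),
    growth = c("growth", "development", "differentiation", "morphogenesis",
               "proliferation"),
    metabolism = c("metabolic", "metabolism", "catabolic", "biosynthetic",
                   "glycolysis", "lipid", "oxidation"),
    morphology = c("morphology", "muscle", "wing", "cuticle", "skeletal",
                   "tissue"),
    movement = c("movement", "locomotion", "motility", "transport",
                 "flight"),
    mutation = c("mutation", "dna repair", "recombination", "transposition"),
    neural = c("neural", "neuron", "synaptic", "axon", "nervous"),
    rhythm = c("circadian", "rhythm", "photoperiod", "clock"),
    reproduction = c("reproduction", "reproductive", "oviposition", "mating",
                     "oogenesis"),
    sensory = c("sensory", "perception", "olfactory", "vision", "smell",
                "chemosensory"),
    sexual_dimorphism = c("sex differentiation", "dimorphism", "dosage compensation",
                          "sex determination"),
    social = c("social", "aggregation", "courtship", "communication")
  )
}

#' Construct a category scheme
#' @param categories named list of keyword vectors (default:
#'   \code{\link{default_categories}}).
#' @return object of class \code{category_scheme}.
#' @export
category_scheme <- function(categories = default_categories()) {
  if (is.null(names(categories)) || any(names(categories) == "")) {
    stop("categories must be named")
  }
  categories <- lapply(categories, function(k) {
    k <- tolower(as.character(k))
    if (!length(k)) stop("every category needs at least one keyword")
    k
  })
  structure(categories, class = "category_scheme")
}
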