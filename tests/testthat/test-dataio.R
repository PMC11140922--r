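test_that("genotype_matrix enforces its invariants", {
  expect_error(genotype_matrix(matrix(3L, 1, 1)), "dosage")
  expect_error(genotype_matrix(matrix(1L, 1, 1),
                               loci = data.frame(contig = "c", pos = 0,
                                                 ref = "A", alt = "T")),
               "1-based")
  expect_error(genotype_matrix(matrix(1L, 1, 1),
                               loci = data.frame(contig = "c", pos = 1,
                                                 ref = "A", alt = "A")),
               "differ")
  expect_error(genotype_matrix(matrix(1L, 1, 2),
                               loci = data.frame(contig = "c", pos = c(5, 5),
                                                 ref = "A", alt = "T")),
               "unique")
  expect_error(genotype_matrix(matrix(0L, 2, 1), samples = c("a", "a")),
               "unique")
  gm <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2))
  expect_equal(dim(gm), c(2L, 2L))
})

test_that("a single heterozygous VCF record is read as dosage 1", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "ctg1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"), path)
  gm <- read_vcf(path)
  expect_equal(unname(gm$dosage), matrix(1L, 1, 1))
  expect_equal(unname(gm$depth), matrix(0L, 1, 1))  # DP absent -> 0
})

test_that("multiallelic records are rejected unless explicitly dropped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "ctg1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1",
               "ctg1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t1/1"), path)
  expect_error(read_vcf(path), "multiallelic")
  gm <- suppressMessages(read_vcf(path, drop_multiallelic = TRUE))
  expect_equal(nrow(gm$loci), 1L)
  expect_equal(gm$loci$pos, 200L)
})

test_that("VCF round-trip preserves the data model exactly", {
  for (seed in 1:3) {
    gm <- rand_gm(10, 20, miss = 0.15, seed = seed)
    path <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(gm, path)
    back <- read_vcf(path)
    expect_true(gm_identical(gm, back))
  }
  # missing call emitted as ./.
  gm1 <- genotype_matrix(matrix(NA_integer_, 1, 1))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm1, p)
  expect_match(grep("^ctg", readLines(p), value = TRUE), "\\./\\.")
})

test_that("an empty matrix writes a header-only VCF", {
  gm <- genotype_matrix(matrix(integer(0), 2, 0),
                        loci = data.frame(contig = character(0),
                                          pos = integer(0),
                                          ref = character(0),
                                          alt = character(0)),
                        samples = c("a", "b"))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[length(lines)], "^#CHROM")
})

test_that("table readers validate ranges and cross-references", {
  ph <- data.frame(sample_id = c("s1", "s2"), colony = c("UC", "RM"),
                   lineage = c("ESM", "ASM"), flight_score = c(0L, 5L),
                   forewing_length_mm = c(21.0, 26.5), role = "cohort")
  pp <- withr::local_tempfile(fileext = ".tsv")
  write.table(ph, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_tables(pp)
  expect_equal(nrow(out$samples), 2L)

  bad <- ph; bad$flight_score[1] <- 7L
  write.table(bad, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tables(pp), "flight_score")

  bad <- ph; bad$lineage[1] <- "XSM"
  write.table(bad, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tables(pp), "lineage")

  write.table(ph, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  gn <- data.frame(gene_id = "g1", contig = "ctg1", start = 10L, end = 500L)
  gp <- withr::local_tempfile(fileext = ".tsv")
  write.table(gn, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  gomap <- data.frame(gene_id = "g2", term_id = "GO:1")
  op <- withr::local_tempfile(fileext = ".tsv")
  write.table(gomap, op, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tables(pp, gp, op), "unknown gene")

  gomap$gene_id <- "g1"
  write.table(gomap, op, sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(term_id = "GO:1", name = "n", definition = "d"),
              tp, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_tables(pp, gp, op, tp)
  expect_equal(length(out$terms), 1L)
  expect_equal(out$terms[["GO:1"]]$genes, "g1")
})
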