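inbred_fixture <- function(P1, P2, flyers, nonfly, depth = 30L) {
  # rows: ESM parent, ASM parent, 4 flyers, 4 non-flyers (columns = loci)
  g <- rbind(P1, P2, flyers, nonfly)
  ids <- c("mom", "dad", sprintf("f%d", seq_len(nrow(flyers))),
           sprintf("n%d", seq_len(nrow(nonfly))))
  gm <- genotype_matrix(g, matrix(depth, nrow(g), ncol(g)),
                        loci = data.frame(contig = "w1",
                                          pos = seq_len(ncol(g)) * 10L,
                                          ref = "A", alt = "T"),
                        samples = ids)
  st <- data.frame(sample_id = ids, colony = "IB",
                   lineage = c("ESM", "ASM", rep("ASM", nrow(flyers)),
                               rep("ESM", nrow(nonfly))),
                   flight_score = c(0L, 5L, rep(5L, nrow(flyers)),
                                    rep(1L, nrow(nonfly))),
                   forewing_length_mm = NA_real_,
                   role = c("parent", "parent",
                            rep("progeny", nrow(flyers) + nrow(nonfly))),
                   stringsAsFactors = FALSE)
  list(gm = gm, st = st)
}

test_that("inbred QC applies depth, heterozygosity and rate rules", {
  g <- matrix(1L, 10, 3)
  g[, 2] <- rep(c(0L, 2L), 5)
  g[, 3] <- c(rep(0L, 6), rep(NA_integer_, 4))
  dep <- matrix(30L, 10, 3)
  dep[1, 2] <- 9L   # low-depth call -> missing, rate 9/10 still fine
  gm <- genotype_matrix(g, dep)
  out <- inbred_qc(gm)
  # locus 1: all het (1.0 > 0.93) -> discarded
  # locus 2: het 0 after depth masking, rate 0.9 -> kept
  # locus 3: rate 0.6 < 0.7 -> discarded
  expect_equal(ncol(out$dosage), 1L)
  expect_true(is.na(out$dosage[1, 1]))   # depth-9 call was masked
  expect_equal(sum(is.na(out$dosage)), 1L)
})

test_that("perfect segregation is a candidate with difference 1", {
  fx <- inbred_fixture(P1 = rep(0L, 2), P2 = rep(2L, 2),
                       flyers = matrix(2L, 4, 2), nonfly = matrix(0L, 4, 2))
  rep <- segregating_candidates(fx$gm, fx$st)
  expect_equal(nrow(rep$candidates), 2L)
  expect_equal(rep$candidates$freq_diff, c(1, 1))
  s <- segregation_summary(rep)
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  expect_equal(s$n_contigs, 1L)
})

test_that("an occasional non-flyer heterozygote is tolerated and counted", {
  # flyers (incl. ASM parent) all hom-alt; non-flyers: one het among five
  fx <- inbred_fixture(P1 = 0L, P2 = 2L,
                       flyers = matrix(2L, 4, 1),
                       nonfly = matrix(c(0L, 0L, 0L, 1L), 4, 1))
  rep <- segregating_candidates(fx$gm, fx$st)
  expect_equal(nrow(rep$candidates), 1L)
  # flyer-allele frequency: flyers 10/10, non-flyers 1/10 -> 0.9
  expect_equal(rep$candidates$freq_diff, 0.9)
})

test_that("a single heterozygous flyer disqualifies the locus (conjunction)", {
  fx <- inbred_fixture(P1 = 0L, P2 = 2L,
                       flyers = matrix(c(2L, 2L, 2L, 1L), 4, 1),
                       nonfly = matrix(0L, 4, 1))
  rep <- segregating_candidates(fx$gm, fx$st)
  expect_equal(nrow(rep$candidates), 0L)
  # union mode admits it through the parent criterion
  repu <- segregating_candidates(fx$gm, fx$st, mode = "union")
  expect_equal(nrow(repu$candidates), 1L)
})

test_that("missing genotypes make a locus ineligible", {
  fly <- matrix(2L, 4, 1); fly[2, 1] <- NA_integer_
  fx <- inbred_fixture(P1 = 0L, P2 = 2L, flyers = fly,
                       nonfly = matrix(0L, 4, 1))
  rep <- segregating_candidates(fx$gm, fx$st)
  expect_equal(nrow(rep$candidates), 0L)
})

test_that("report is invariant to sample order and allele relabelling", {
  sim <- simulate_inbred_lines(synth_config(seed = 19, n_loci = 400,
                                            n_contigs = 40))
  base <- segregating_candidates(sim$gm, sim$samples)
  perm <- sample(length(sim$gm$samples))
  repp <- segregating_candidates(gm_subset(sim$gm, samples = perm),
                                 sim$samples[perm, ])
  expect_equal(repp$candidates[order(repp$candidates$locus), ],
               base$candidates[order(base$candidates$locus), ],
               ignore_attr = TRUE)
  flip <- sim$gm
  flip$dosage <- 2L - flip$dosage
  repf <- segregating_candidates(flip, sim$samples)
  expect_equal(repf$candidates$locus, base$candidates$locus)
  expect_equal(repf$candidates$freq_diff, base$candidates$freq_diff)
})

test_that("segregation summary matches hand computations", {
  fake <- structure(list(candidates = data.frame(
    locus = c("a:1", "b:1"), contig = c("a", "b"), pos = c(1L, 1L),
    parents_opposite_hom = TRUE, flyers_hom = TRUE,
    nonflyers_het_or_opposite = TRUE, freq_diff = c(0.9, 1.0)),
    mode = "conjunction", n_tested = 2L), class = "segregation_report")
  s <- segregation_summary(fake)
  expect_equal(s$mean, 0.95)
  expect_equal(s$sd, sd(c(0.9, 1)), tolerance = 1e-12)
  expect_equal(round(s$sd, 4), 0.0707)
  empty <- fake; empty$candidates <- fake$candidates[0, ]
  expect_error(segregation_summary(empty), "no candidate")
})
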