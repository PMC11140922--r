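test_that("flight scores bin at the 2/3 boundary", {
  expect_false(any(bin_flight(c(0L, 1L, 2L))))
  expect_true(all(bin_flight(c(3L, 4L, 5L))))
  expect_error(bin_flight(6L), "0..5")
  expect_true(is.na(bin_flight(NA_integer_)))
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(adjust_p(0.04), 0.04)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_p(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_p(c(0.01, 0.5), method = "bonferroni"), c(0.02, 1))
})

test_that("score statistic tracks the likelihood-ratio chi-square", {
  set.seed(31)
  n <- 300
  g <- matrix(rbinom(n * 50, 2, 0.4), n, 50)
  gm <- genotype_matrix(g)
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * g[, 1]))
  res <- score_test_scan(gm, y, link = "binomial")
  lrt <- vapply(1:50, function(j) {
    f1 <- glm(y ~ g[, j], family = binomial)
    f1$null.deviance - f1$deviance
  }, numeric(1))
  expect_lt(median(abs(res$table$chi2 - lrt)), 0.1)
})

test_that("scan is invariant to sample order and flips sign on allele swap", {
  gm <- rand_gm(60, 40, miss = 0, seed = 17)
  set.seed(17)
  y <- rbinom(60, 1, 0.5)
  base <- score_test_scan(gm, y, link = "binomial")
  perm <- sample(60)
  gmp <- gm_subset(gm, samples = perm)
  resp <- score_test_scan(gmp, y[perm], link = "binomial")
  expect_equal(resp$table$chi2, base$table$chi2, tolerance = 1e-9)
  gmf <- gm
  gmf$dosage <- 2L - gmf$dosage
  resf <- score_test_scan(gmf, y, link = "binomial")
  expect_equal(resf$table$chi2, base$table$chi2, tolerance = 1e-9)
  nz <- abs(base$table$chi2) > 1e-8
  expect_equal(resf$table$sign[nz], -base$table$sign[nz])
})

test_that("missing genotypes are handled per observed subset", {
  set.seed(23)
  n <- 120
  g <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  g[sample(n, 30), 4] <- NA_integer_
  gm <- genotype_matrix(g)
  y <- rbinom(n, 1, 0.5)
  res <- score_test_scan(gm, y, link = "binomial")
  # locus 4 must equal a from-scratch scan on its complete cases
  obs <- !is.na(g[, 4])
  gm_sub <- genotype_matrix(g[obs, 4, drop = FALSE])
  ref <- score_test_scan(gm_sub, y[obs], link = "binomial")
  expect_equal(res$table$chi2[4], ref$table$chi2[1], tolerance = 1e-10)
})

test_that("type-I error is nominal on a structureless null", {
  set.seed(41)
  n <- 300; L <- 4000
  g <- matrix(rbinom(n * L, 2, rep(runif(L, 0.1, 0.9), each = n)), n, L)
  gm <- genotype_matrix(g)
  y <- rbinom(n, 1, 0.5)
  res <- score_test_scan(gm, y, link = "binomial")
  rej <- mean(res$table$p < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.04 - 0.01)
  expect_lt(rej, 0.06 + 0.01)
})

test_that("the model grid selects the largest resolved PC count", {
  co <- flat_cohort(seed = 51, n_loci = 1500)
  y <- bin_flight(co$samples$flight_score)
  kin <- king_kinship(co$gm)
  un <- partition_unrelated(kin)
  sm <- suppressMessages(pca_unrelated_project(co$gm, un, 4))
  mg <- model_grid(co$gm, y, sm, c(0, 2, 4), link = "binomial")
  expect_equal(mg$selected, 4L)
  expect_length(mg$results, 3L)
  # p-vectors across adequate PC counts strongly correlated on null data
  rho <- cor(mg$results$K2$table$p, mg$results$K4$table$p, method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("LD annotation honours the r and p thresholds", {
  set.seed(61)
  n <- 200
  base <- rbinom(n, 2, 0.5)
  flip <- function(g, k) { i <- sample(n, k); g[i] <- (g[i] + 1L) %% 3L; g }
  g <- cbind(out_in = base,                 # inside gene A
             linked = flip(base, 4),       # inside gene B, r ~ 0.95
             weak = flip(base, 40),        # inside gene C, r < 0.9
             other = rbinom(n, 2, 0.5))
  loci <- data.frame(contig = "c1", pos = c(100L, 5000L, 9000L, 20000L),
                     ref = "A", alt = "T")
  gm <- genotype_matrix(g, loci = loci)
  genes <- data.frame(gene_id = c("A", "B", "C"), contig = "c1",
                      start = c(50L, 4900L, 8900L), end = c(150L, 5100L, 9100L))
  # association: make locus 1 the only outlier
  fake <- list(table = data.frame(contig = loci$contig, pos = loci$pos,
                                  locus = paste(loci$contig, loci$pos, sep = ":"),
                                  chi2 = c(30, 0.1, 0.1, 0.1),
                                  p = c(1e-7, 0.9, 0.9, 0.9),
                                  p_adj = c(4e-7, 0.9, 0.9, 0.9),
                                  sign = 1), converged = TRUE)
  class(fake) <- "assoc_result"
  r12 <- abs(cor(g[, 1], g[, 2])); r13 <- abs(cor(g[, 1], g[, 3]))
  expect_gt(r12, 0.90); expect_lt(r13, 0.90)
  cand <- ld_annotate(gm, fake, genes, r_min = 0.90, p_max = 0.05)
  expect_setequal(cand$gene_id, c("A", "B"))
  expect_equal(cand$p[cand$gene_id == "A"], 1e-7)
})

test_that("candidate overlap equals brute-force set arithmetic", {
  sets <- list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4"), c = "g9")
  ov <- candidate_overlap(sets)
  expect_equal(ov$pairwise["a", "b"], 2L)
  expect_equal(ov$pairwise["a", "c"], 0L)
  expect_equal(ov$all, 0L)
  same <- candidate_overlap(list(x = sets$a, y = sets$a))
  expect_equal(same$all, 3L)
  set.seed(7)
  rs <- replicate(3, sample(letters, 10), simplify = FALSE)
  names(rs) <- c("u", "v", "w")
  ov2 <- candidate_overlap(rs)
  expect_equal(ov2$pairwise["u", "w"], length(intersect(rs$u, rs$w)))
  expect_equal(ov2$all, length(Reduce(intersect, rs)))
})
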