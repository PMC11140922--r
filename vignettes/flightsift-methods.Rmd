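---
title: "Methods: flight-genetics inference in spongy moths with flightsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flight-genetics inference in spongy moths with flightsift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightsift)
```

## The scientific problem

Female European spongy moths (ESM, *Lymantria dispar dispar*) are typically
flightless while females of the Asian lineages (ASM) typically fly. Flight
capability is the trait that most directly determines the invasive spread
potential of intercepted specimens, so genetic markers of flight are a
practical biosurveillance tool. `flightsift` implements an integrated
inference pipeline for this problem: structure-corrected genome-wide
association on a multi-colony cohort, a co-segregation filter on an
ESM × ASM inbred pedigree, LD-based candidate-gene annotation, GO-category
over-representation with Markov clustering of enriched terms, and a
replicated DAPC classifier that measures how well a small marker panel
assigns moths to their binary flight class.

Every stage runs on synthetic data produced by the package's own generator,
so the full pipeline is exercisable and testable without any sequencing
download.

## Data model

Genotypes live in a `genotype_matrix`: samples × biallelic loci as
alternate-allele dosage (0/1/2, `NA` for a missing call) with a parallel
read-depth matrix. Depth 0 does not imply missingness, because calls may
have been imputed upstream of this package. Coordinates are 1-based
inclusive throughout (VCF/GFF convention). Indels are accepted on read and
flagged; the inbred-line track restricts to SNPs, the GWAS track keeps
both by default.

## The synthetic study design

`synth_config()` fixes the simulated study conditions; `simulate_cohort()`,
`simulate_inbred_lines()` and `simulate_annotation()` realise them.

* **Cohort structure.** Allele frequencies are drawn hierarchically —
  ancestral → lineage → colony — with Balding–Nichols betas at
  `fst_lineage = 0.2` and `fst_colony = 0.05`. Two lineages of four
  colonies each and 9 full-sib families of 4 per colony give 288 females,
  matching the scale of a genotyping-by-sequencing cohort of ~300. Sibling
  genotypes are assembled from common parental gametes so that full sibs
  carry realised kinship ≈ 0.25.
* **Flight phenotype.** A liability
  `lineage offset + Σ β·dosage + logistic noise` is thresholded at zero and
  mapped to the 0–5 behavioural score with 85% of each class's mass on the
  extreme score (0 or 5), reproducing the strongly bimodal score
  distribution that motivates binary binning at 0–2 vs 3–5. Standard
  logistic noise was chosen over Gaussian noise so that the configured
  per-allele effect *is* a log-odds ratio; `beta_flight = 1` and a lineage
  baseline of ±2.5 log-odds make ASM predominantly flight-capable and ESM
  predominantly flightless, with occasional exceptions in both lineages as
  real colonies show. Planted loci are centred at their ancestral expected
  dosage so the baseline, not the luck of the causal frequency draw, sets
  prevalence.
* **Forewing length.** Gaussian, mean 22 mm (ESM) / 27 mm (ASM), SD 1.5 mm,
  with its own additive planted loci (`beta_wing = 0.6` mm per allele).
* **Missingness and depth.** Independent Bernoulli missingness
  (default 2%) and Poisson depth (mean 20); the simplest models that make
  every QC rule exercisable.
* **Inbred pedigree.** One ESM mother and one ASM father with divergent
  genomes and `inbred_n_causal = 10` opposite-homozygous causal loci found
  the line. Gametes inherit whole per-contig blocks with a small crossover
  probability (`crossover_rate = 0.1`) rather than using a genetic map:
  no map exists for this system, and block inheritance creates the high
  within-line LD that repeated full-sib mating produces. After F1, two
  phenotype-selected full-sib sublines (strong flight vs minimal flight)
  are carried to F5, mirroring selection of extreme egg masses each
  generation; the selection intensity is a configuration knob because the
  real breeding scheme's intensity is not known. The emitted samples are
  the 2 parents plus 4 strongly flying (score 5) and 4 non-flying
  (scores 1,1,1,2 — mean 1.25) progeny drawn from F2 onward. The truth
  record lists the loci whose emitted genotypes satisfy the co-segregation
  pattern, verified by direct genotype inspection, independent of the
  filter implementation.
* **Annotation.** 800 genes of 20–80 kb tiled without overlap across the
  cohort contigs (gene-dense enough that a realistic fraction of scan loci
  falls inside genes), GO terms with a power-law genes-per-term
  distribution, and names/definitions composed from a word pool seeded
  with the category keywords so that keyword categorisation is exercised.
  The category scheme defaults to the twelve flight-relevant functional
  categories (cognition, growth, metabolism, morphology, movement,
  mutational mechanisms, neural processes, biological rhythms,
  reproduction, sensory, sexual dimorphism, social behaviour).

What the generator does **not** emulate: sequence-level reads, realistic
recombination maps, LD between cohort loci on the same contig (cohort loci
are drawn independently, so LD-based gene annotation in the synthetic
pipeline is dominated by loci physically inside genes), functionally
coherent GO assignments (term membership is random, so category
over-representation behaves as a null — typically no significant
categories — which is exactly what its calibration tests check), selection,
or mutation. Passing tests therefore demonstrate the statistical
correctness and calibration of each method, not that real spongy-moth data
would yield the same candidate counts.

## Variant QC

`run_qc()` applies six rules in a fixed order, mirroring how a
GBS call set is cleaned:

1. biallelic validation (multiallelics are rejected or dropped at read
   time; indels optionally excluded);
2. exact Hardy–Weinberg filter at p < 1e-6 computed **in the
   flight-capable (ASM, control) samples only**, so loci under putative
   flight-related selection in ESM are not discarded. The test is the
   exact conditional enumeration of heterozygote counts given allele
   counts, two-sided by summing configurations no more probable than the
   observed one; exact rather than asymptotic because genotype classes
   are small. Pooled across ASM by default with a per-colony option;
3. joint MAF rule: discard only when global MAF < 0.10 **and** ESM
   MAF < 0.30 (the ESM bound protects modest case-group frequency shifts);
4. missingness > 0.5 or mean depth < 5 (mean over all samples, strict
   inequalities as printed);
5. random pruning of within-contig locus pairs in complete LD
   (|r| = 1 within 1e-12 on pairwise-complete dosages; cross-contig
   "complete LD" is undefined without genome order and is never tested);
   the victim is chosen uniformly with a seeded RNG;
6. removal of samples with > 0.5 missingness.

Rule order matters (e.g. permuting MAF and LD pruning can change the kept
set); the cascade fixes the order above and the report accounts for every
discarded locus and sample. MAF is computed on observed calls.

## Structure: kinship, PCA, residual kinship

`king_kinship()` is the KING-robust estimator
φ̂ᵢⱼ = (N_het,het − 2·N_opp-hom) / (N_het(i) + N_het(j)) over
pairwise-complete loci. It is computed globally rather than within
geographic location: the greedy partition step needs a complete matrix,
and a global matrix is a conservative superset of per-location use.
`partition_unrelated()` removes, at threshold 0.025, whichever sample has
the most above-threshold partners (ties by larger mean kinship then
lexicographic id) until no pair exceeds the threshold.

`pca_unrelated_project()` standardises loci by unrelated-set allele
frequencies (centre 2p̂, scale √(2p̂(1−p̂)), missing calls mean-imputed for
PCA only), fits the eigenbasis on unrelateds and projects relatives, so
family structure cannot distort the axes. `pc_adjusted_kinship()` then
regresses dosage/2 on the retained PCs per locus to get
individual-specific frequencies (clamped to [0.01, 0.99] to avoid
degenerate variances at loci monomorphic within a subgroup) and forms the
residual kinship — family-level structure net of population structure.
Because the association models take covariates, not a random-effect
matrix, the leading eigenvectors of this residual kinship (default 2)
serve as the kinship covariates; how many such factors a fixed-effect
formulation should carry is genuinely open, so the count is exposed.

## Association scans

The models are fixed-effect GLMs — binomial for the binary flight class,
Gaussian for forewing length in mm (untransformed; the phenotype is
approximately normal) — with intercept, PC scores and kinship factors.
Each locus contributes a 1-df score test computed from the null fit only:
U = xᵀ(y − μ̂₀), V = xᵀWx − xᵀWZ(ZᵀWZ)⁻¹ZᵀWx, U²/V ~ χ²₁. The score
formulation needs one IRLS fit per phenotype rather than one per locus,
and agrees with the likelihood-ratio χ² to O(n⁻¹) (checked in the tests).
Loci with missing genotypes are tested on their complete cases with the
null refit per missingness pattern (complete-case, because imputation is
out of scope here). Diagnostics per model: AIC of the null fit, genomic
inflation factor λ = median(χ²)/0.4549, and qq data.

`model_grid()` explores increasing PC counts and keeps the largest count
whose null model resolved; λ and AIC are reported for manual override.
With the default family-structured cohort, some residual inflation
(λ ≈ 1.1–1.3) remains even at the selected model because two kinship
eigenvectors cannot absorb dozens of small full-sib families; the
replicate-population design, not perfect calibration, is the safeguard
the study design relies on. On unrelated structured cohorts the PCs
restore λ to [0.9, 1.1] (the calibration tests construct exactly that
condition). Multiple-testing adjustment is Benjamini–Hochberg by default
(Bonferroni available); the outlier definition for annotation uses raw
p < 0.05, with the single-marker p_adj < 0.05 threshold reported
separately.

`ld_annotate()` turns outlier SNPs into candidate genes: a gene is a
candidate iff some locus inside its span has |r| ≥ 0.90 with an outlier
on the same contig (a locus inside a gene annotates it trivially). |r| is
used because the sign of a dosage correlation is an arbitrary allele
labelling.

## Inbred-line co-segregation

`inbred_qc()` keeps biallelic SNPs, masks calls under 10 reads, and drops
loci with heterozygosity > 0.93 (paralog suspicion) or genotyping rate
< 70%. `segregating_candidates()` then selects loci where the parents are
opposite homozygous AND all strongly flying individuals (ASM parent and
score-5 progeny) are homozygous for one allele AND every non-flying
individual is heterozygous or opposite-homozygous — the conjunction
reading, which is how the realised candidate pattern is described; a
union mode is retained behind a flag because the protocol prose admits
either reading. Heterozygotes are tolerated only in the non-flyer group.
Group membership is taken from the phenotype table rather than re-derived
from score cutoffs. The per-locus allele-frequency difference between
groups is computed by direct allele counting with the flyer-fixed allele
as reference, and `segregation_summary()` reports its mean, SD, and the
candidate contig count.

## Enrichment, categories, clusters

`term_enrichment()` scores each GO term by the hypergeometric upper tail
of its overlap with the candidate set within the annotated universe
(enriched at p < 0.05). GO is treated as a flat term set — no hierarchy
propagation — because the category statistic needs term counts, not
parentage. `categorize_terms()` assigns terms to the twelve categories by
case-insensitive keyword match against name and definition
(multi-membership allowed; unmatched terms are "n/a"); the mapping is
deterministic and blind to which analysis supplied the genes.
`category_overrepresentation()` tests each category with a one-tailed
binomial against the category's share of the reference annotation,
BH-adjusted across the twelve categories within one analysis (not across
analyses). Unique enriched terms are counted per category test; counting
term-category assignments instead would double-count multi-category terms.

`build_term_graph()` links enriched terms by the overlap coefficient of
their gene sets (threshold 0.5 — chosen for interpretability; the
clustering front-ends this replaces do not document their internal edge
definition, so it is configurable). `mcl_cluster()` is a standard Markov
clustering implementation: self-loops at the maximum incident weight,
column-stochastic normalisation, alternating expansion (matrix squaring)
and inflation (elementwise power 2.0, renormalise), pruning entries below
1e-6, converging when the maximum column change drops below 1e-8 (cap 200
iterations, warning on cap). Clusters are connected components of the
converged support. `describe_clusters()` labels each cluster with the
four most common non-stopword tokens of its member definitions (ties by
frequency then alphabetical; the stopword list is minimal — tokens like
"regulation" are informative in this corpus and are kept), tallies
category hits and supporting genes, and flags clusters with ≥ 10 category
hits and/or ≥ 5 unique supporting genes as well-supported.

## DAPC profiling

`dapc_fit()` is PCA on training dosages followed by a linear discriminant
on the retained scores (one axis for two classes;
w = S_w⁻¹(m₁ − m₀) with a 1e-8 ridge if S_w is singular); assignment is
nearest centroid on that axis. Missing calls are mean-imputed from
training data only, and test samples never enter centring, loadings or
discriminant estimation — the leakage guard is asserted in the tests by
perturbing test genotypes and requiring an identical model.
`xval_npcs()` picks the retained PC count by stratified 90/10
cross-validation (30 splits; common DAPC practice, exposed as
configuration), ties to the smallest count. `replicate_profiling()`
repeats, ten times: draw a stratified 50/50 training set of 100, re-run
the PC cross-validation on that training set alone (re-selected per
replicate, the stricter reading), fit, predict all held-out samples, and
test the success count one-tailed against chance. Chance defaults to the
test set's majority-class proportion — more conservative than 0.5 when
classes are unbalanced — with 0.5 behind a flag. The report carries
per-replicate success and p plus the mean and SE over replicates.

## Orchestration and reproducibility

`validate_config()` injects the default threshold set (MAF 0.10/0.30,
HWE 1e-6, missingness 0.5, depth 5, kinship 0.025, LD r 0.90, α 0.05,
FDR 5%, 50/50 training, 10 replicates) and rejects unknown keys or
out-of-range values. `run_all()` executes
synth → QC → structure → GWAS → gene annotation → inbred → enrichment →
profiling, writes every artifact as VCF/TSV/JSON, and records a manifest
with the config snapshot, seeds, per-stage timings and MD5 digests of all
outputs; a rerun with the same seed reproduces the artifacts
byte-identically. All randomness derives from the single root seed. The
package is a library-first tool: the exported functions and `run_all()`
are the interface, and `scripts/acceptance.R` is a worked end-to-end
driver.

## Numerical choices and degenerate inputs

* Exact HWE enumeration works in log-space probabilities renormalised
  before summing, with a 1 + 1e-12 slack on the "no more probable"
  comparison to absorb floating-point ties.
* |r| = 1 detection in LD pruning and the r ≥ 0.90 annotation rule use
  pairwise-complete dosage correlations; undefined correlations (constant
  vectors) count as 0.
* PCA drops loci monomorphic in the unrelated set (their scale is 0).
* PC-Relate-style frequencies are clamped to [0.01, 0.99].
* Score tests return `NA` when the genotype is constant in the tested
  subset (V ≈ 0); such loci are excluded from λ and the qq data.
* A fully missing locus has MAF 0 and is discarded by the MAF rule with a
  log entry; a locus whose observed subset is smaller than the covariate
  count is skipped by the scan.
* MCL's component extraction is order-invariant; singleton clusters are
  legitimate output.

## Problem sizes in the shipped checks

The test-suite simulations use cohorts of ~300 samples with 200–10,000
loci, 5,000-locus kinship checks, 10-seed power replicates at 2,000 loci,
10,000-replicate calibration loops for the binomial category test, and
brute-force partition enumeration on graphs of up to 9 nodes (the
modularity oracle's enumeration grows as the Bell numbers, so exact
enumeration is feasible only below ~10 nodes; the planted-partition
recovery check runs at 15). These sizes were chosen as the smallest at
which each statistical property is stable.

## Known limitations

* Fixed-effect structure correction only; no random-effect mixed model.
  Residual family inflation on family-structured cohorts is reported (λ),
  not hidden.
* Complete-case handling of missing genotypes in the scans; no built-in
  imputation.
* GO hierarchy is not propagated; enrichment is over the flat term set.
* The cohort generator draws loci independently, so it cannot exercise
  LD-decay-based annotation beyond in-gene loci; the annotation logic is
  instead tested on constructed haplotype fixtures.
* The inbred generator's selection scheme guarantees phenotype-extreme
  progeny but, like any simulation, realises only one plausible breeding
  history.
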