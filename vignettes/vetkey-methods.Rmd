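---
title: "vetkey: methods, parameter choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vetkey: methods, parameter choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetkey)
```

## The problem

Incipient species retain ancestral polymorphism. In the mallard complex,
Mexican ducks share most of their genome-wide variation with mallards, and a
fraction of phenotypically mallard-like Mexican ducks are genetically pure —
immature males in particular can transiently express mallard-like plumage in
their formative cycle. Telling retained ancestry apart from recent
hybridization therefore needs genome-wide evidence interpreted with two
complementary statistics (model-based ancestry fractions and rare-allele
co-ancestry), and a morphological key is only trustworthy once it is
calibrated against genetically vetted reference birds. `vetkey` implements
that full chain at desk scale, together with a synthetic-data generator so
every stage is testable.

## SNP filtering

The filter chain runs MAF → missingness → LD, in that order, and each stage
appends its bookkeeping to `filterReport()` (removed + retained = input is
asserted in the tests).

* `filterMAF(maf_min = 0.005)` removes SNPs with minor-allele frequency
  strictly below 0.005 among non-missing calls — the conventional singleton
  screen for panels of a few hundred samples. A SNP at exactly the floor is
  retained.
* `filterMissingness(max_missing = 0.2)` removes SNPs missing in **at
  least** 20% of samples (inclusive boundary).
* `ldPrune(window_snps = 2, step_snps = 1, r2_max = 0.5)` slides a 2-SNP
  window one SNP at a time in the supplied SNP order and removes, uniformly
  at random (seeded), one member of any pair with squared Pearson dosage
  correlation strictly above 0.5, repeating until no pair exceeds the
  threshold. Correlations use complete pairs only (pairwise deletion) — no
  imputation is introduced at this stage. A pair at exactly r² = 0.5 is
  retained; a 1e-10 epsilon guards the boundary against floating-point noise
  in `cor()`.

Whether the original analysis pruned within loci or genome-wide is not
recoverable; we prune in supplied SNP order and say so. The chain is
idempotent stage by stage: re-running any filter on its own output removes
nothing.

## Ancestry proportions

`estimateAdmixture()` maximizes the standard admixture likelihood — dosage
`g_ij ~ Binomial(2, Σ_k q_ik f_kj)` — by EM block updates from a seeded
random start. We use EM rather than quasi-Newton block relaxation: the
likelihood target is identical, EM is simple and monotone (the
log-likelihood trace is kept on the object and asserted non-decreasing in
the tests), and desk-scale panels converge in seconds. The cost is slower
terminal convergence; `tol` (default 1e-4 on the log-likelihood gain) and
`max_iter` (500, best-so-far returned with a warning on non-convergence)
are exposed.

* **K selection** (`cvChooseK`): observed genotype entries are partitioned
  into folds (default 10, i.e. 10% masked per fit, mirroring common practice
  for this model family); masked dosages are predicted as `2 Σ_k q_ik f_kj`
  and the CV error is their mean squared deviation. The binomial-deviance
  variant used by the original tool is not replicated; squared error ranks K
  the same way on these panels.
* **Uncertainty** (`bootstrapSE`): B SNP-resampled refits, clusters aligned
  to the point estimate by greedy correlation matching of cluster
  allele-frequency vectors (deterministic given the point estimate);
  ambiguous alignments drop the replicate with a message. The SE is the
  per-cell standard deviation across aligned replicates.
* **Summed sides** (`combineClusters`): ancestry to a set of clusters is the
  sum of fractions; its standard error is `sqrt(Σ SE²)`, i.e. independence
  of the per-cluster bootstrap errors is assumed.

## Co-ancestry, siblings, and the two hybrid rules

`coancestryMatrix()` is a documented **analogue**, not a reimplementation,
of chromosome-painting co-ancestry: per SNP, the fraction of allele copies
two samples share (`1 − |g_a − g_b|/2`), averaged with weights
`w_j = −log p_j` so the rarest SNPs contribute the most information. The
weight is monotone in rarity and bounded once the MAF floor has been
applied. Only rank and threshold behaviour of this matrix is meaningful;
its numeric scale is package-specific, and tests are written at that level.

`detectSiblings(t_sd = 3)` flags within-population pairs above the
population's mean off-diagonal co-ancestry plus 3 SD (populations too small
to estimate an SD fall back to the pooled within-group distribution), merges
pairs by transitive closure, and corroborates each group: all members share
a sampling site, and all members share an mtDNA haplotype (full siblings
have one mother). A group failing an available corroboration is kept but
flagged unconfirmed; an absent haplotype table leaves that flag unknown
rather than failing the group. The 3 SD default was chosen because the
source analysis states only "higher than average"; 3 SD gives a specificity
that is actually testable under the simulation null. Representatives are
the lexicographically first id of each group, and
`dropToRepresentatives()` removes `Σ (size − 1)` samples.

Hybrid calling applies two rules and reports their concordance:

* **Assignment rule**: hybrid iff summed ancestry is strictly above 10% to
  *both* the focal taxon and the summed mallard types (a bird at exactly
  10% is pure). Point estimates are used for the call; bootstrap CIs are
  attached, and a bird whose mallard-side CI overlaps zero is flagged
  low-confidence. This matches the narrative order of the source analysis
  (calls first, CIs as qualification).
* **Co-ancestry rule**: hybrid iff mean co-ancestry to *each* parental side
  strictly exceeds the grand mean of between-side co-ancestry (the
  "higher than average" operationalized; the cutoff is exposed), **and** the
  bird's dendrogram attachment lies outside every parental population's
  clade. We evaluate the clade condition per reference *population* (merge
  height with each population exceeds that population's internal maximum
  merge height) rather than per side: a side made of several populations
  (wild plus domestic mallards) spans nearly the whole tree, which would
  make a per-side criterion unsatisfiable while the per-population version
  preserves the intent — the bird sits inside no parental cluster. Birds
  with higher co-ancestry to the domestic clusters than to wild mallards
  get a feral-parent suspicion flag.

On panels with shared ancestry and fine-scale structure the assignment rule
over-calls relative to the co-ancestry rule; the acceptance suite reproduces
that ordering qualitatively on an isolation-by-distance simulation.
Generation-class inference (F1 vs backcross posteriors) is out of scope;
backcrosses are genuinely harder and are not covered by the sensitivity
guarantees.

## Diversity statistics

Nucleotide diversity is the mean pairwise proportion of differing sites for
aligned sequences (pairwise deletion, via `ape::dist.dna`), and the average
over SNP sites of the unbiased per-site heterozygosity
`2p(1−p)·n/(n−1)` divided by the total assayed sites for genotype
partitions. ΦST is the Hudson-form estimator
`1 − (mean within-group pairwise diversity)/(between-group pairwise
diversity)`, computed on concatenated loci per partition: the original
tool's "composite" estimator is internal and unspecified, so this standard
pairwise-difference equivalent is used and documented as an analogue.
Negative estimates are clamped to zero with the raw value retained;
zero between-group diversity with positive within-group diversity is
undefined and flagged. Z-linked SNPs are carried as a partition label only —
statistics are computed identically to autosomal ones; sex-aware ploidy
correction is out of scope and noted here.

Haplotype collapsing is exact-sequence deduplication after uppercasing
(ambiguity characters isolate a sequence unless byte-identical), and
haplogroup assignment is nearest-reference Hamming distance with ties left
unassigned.

## The trait schema and cohort keys

The packaged schema (`inst/extdata/trait_schema.csv`) transcribes the
study's trait table: 16 plumage traits with consecutive ordinal scores from
0 (Mexican-duck state) to the mallard state (up to 3 for percent green in
the head; 2 for rump, tail curl, and under-tail coverts), plus 6 structural
traits and mass. Each trait lists the sex–age cohorts it applies to
(immature/adult × male/female, assigned by molt cycle). The diagnostic
("bolded") trait subset of the original table is not recoverable from the
available text, so the per-cohort diagnostic flags are populated from the
cohort applicability columns and marked provisional.

The plumage score PS is the sum of ordinal scores over the cohort's
applicable traits. **Missing traits contribute 0** and are counted in
`n_missing`: museum skins have unavoidable gaps, no imputation rule exists
for ordinal plumage states, and a zero contribution biases toward the
Mexican-duck class — the conservative direction — while the count keeps the
bias auditable.

Keys are calibrated per cohort from the observed PS ranges of genetically
vetted reference classes. The Mexican-duck interval is always forced to
[0, 4] — the boundary rule the key exists to enforce (PS = 4 is Mexican
duck; boundaries resolve to the lower class). When the observed hybrid and
mallard ranges overlap, or a reference class is absent, the upper classes
merge into a combined hybrid/mallard interval, mirroring the practical
inability to separate those two classes morphologically. Key calibration is
idempotent: rebuilding a key from its own classifications reproduces the
intervals.

Diagnostic-trait selection fits `MASS::lda` on the cohort's ordinal traits,
ranks traits by absolute standardized discriminant loading, and runs a
forward search maximizing leave-one-out accuracy (ties toward fewer traits,
then schema order) — the source reports "optimum combinations" without its
search procedure, so this deterministic, testable procedure is the
package's own choice. Singular within-class covariances fall back to a
ridge-regularized discriminant with a logged epsilon. Structural traits are
screened by one-way ANOVA with Tukey HSD pairwise comparisons at
alpha = 0.001 (the stricter of the two thresholds quoted in the source;
configurable) and are excluded from PS and keys.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Genotypes**: per-SNP ancestral frequencies Uniform(0.05, 0.95) — wide
  enough to keep the MAF filter non-trivial, bounded away from degenerate
  rare alleles — drifted per population by a Balding–Nichols Beta draw, so
  two populations with drift F have expected Hudson FST ≈ F. F1s take one
  gamete from each parental frequency vector; first backcrosses take one
  gamete from the recurrent parent and one from an F1 (75/25 expected
  ancestry); sibling groups are Mendelian offspring of two latent parents.
  Missingness is injected completely at random (the simplest model
  consistent with what the missingness filter is for).
* **Default cohort structure** mirrors the study design: three Mexican duck
  populations (40/20/30), wild mallard (30), game-farm mallard (20), Khaki
  Campbell (10), F1s with wild and domestic mothers, a backcross pair, and
  small sibling groups. Default drift values are F = 0.10/0.12/0.10 for the
  Mexican duck populations, 0.15 for wild mallard, and 0.30/0.35 for the
  domestic lineages. These are deliberately larger than the real system's
  autosomal differentiation: the real analysis resolved structure with
  ~12,700 SNPs, and at the desk-scale default of 2,000 SNPs the same
  per-SNP divergence carries too little information for *any* decision rule
  to separate F1s from purebreds. The defaults preserve the real data's
  resolving power and its ordering of divergences (Mexican duck populations
  ≈ wild mallard ≪ domestics) rather than its absolute FST values — so
  passing tests demonstrate that the decision rules work where the signal
  is resolvable, not that 2,000 SNPs would suffice on real birds.
* **mtDNA**: two haplogroup cores (OW-A, NW-B) 25 substitutions apart on a
  655-bp control-region-sized alignment, Poisson(1.5) private mutations per
  lineage; hybrids inherit the maternal lineage's haplogroup, siblings share
  one haplotype; domestic lineages are fixed for OW-A and wild mallards
  carry it at 31%, Mexican ducks at 1%.
* **Traits**: pure Mexican ducks draw null states except immature males,
  which express a random bundle of the variant traits (green in head, tail
  curl, rump, bill spotting, face/neck pattern) with probability 0.25. The
  overflow calibration reads the "97% stay at PS ≤ 4" constraint as applying
  to *all* pure immature males, so the overflow probability among
  expressers is (1 − 0.97)/0.25 = 0.12; that is the only reading under
  which key accuracy on immature males equals the configured 97%.
  Mallard-type birds draw each trait's maximum with probability 0.98 (most
  adult-male mallards score the cohort maximum). Hybrids draw a 50/50
  mixture of the parental state distributions with the three-level traits
  forced to the intermediate level, landing them between the parental PS
  ranges with configurable overlap — the real hybrid PS ranges per cohort
  are never printed, so overlap is a free knob, not an inferred quantity.

What the generator does **not** emulate: linkage and haplotype structure
within loci (the co-ancestry analogue therefore sees less information than
chromosome painting would), coalescent genealogies, clinal
isolation-by-distance within populations (population structure is discrete),
sequencing-depth-driven missingness, scorer error in plumage states, and any
correlation between genotype and trait noise. Passing tests show the
decision rules behave as specified under this model; they do not certify
performance on real ddRAD panels.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes a laptop handles in minutes:
2,000 SNPs and ~170–180 samples for parameter-recovery and sibling checks
(20 seeded replicates for the sibling sensitivity/specificity and
confirmed-count checks), 400–800 SNPs for structure and K-selection checks,
and a 5 × 8 panel for the grid-search optimality oracle (grid over q at
0.01 resolution with cluster frequencies held at the EM estimate — rows are
separable given the frequencies, so the conditional grid is the honest
tractable oracle). Likelihood terms are clamped to [1e-9, 1 − 1e-9] and
cluster frequencies to [1e-6, 1 − 1e-6]; the EM trace is asserted monotone
to 1e-6. All randomness flows from explicit integer seeds; identical
configurations are bit-identical end to end.

## Known limitations

* The co-ancestry matrix is an analogue; absolute values are not comparable
  with chromosome-painting output, only decisions built on it.
* The assignment-rule CIs assume independent per-cluster bootstrap errors.
* Backcross and later-generation hybrids are detected only opportunistically.
* Z-chromosome statistics ignore sex-specific ploidy.
* The ANOVA screen is per-trait and unadjusted across traits (alpha is
  strict instead).
* Key endpoints other than the fixed PS ≤ 4 boundary are calibrated values
  and move with the reference panel; they are exposed as data, not
  constants.
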