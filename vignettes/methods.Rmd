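---
title: "Methods: sex-biased gene evolution from expression, divergence and polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased gene evolution from expression, divergence and polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbiasevol)
```

## The scientific question

In dioecious plants such as willows, male and female individuals share a
genome but express parts of it differently, most strongly in reproductive
tissue (catkins). Genes with sex-biased expression are candidates for
sexual selection and sexual antagonism, and a recurring question is whether
they evolve faster or slower at the protein level than unbiased genes.
This package implements the full analysis chain needed to ask that
question: classify genes as male-biased (MB), female-biased (FB) or
unbiased (UB) from replicated RNA-seq counts in two tissues; estimate
branch-specific divergence (dN, dS) on the focal lineage of a five-taxon
willow/poplar phylogeny; count within-species polymorphisms (pN, pS) under
strict validity rules on a shared site basis; and contrast the categories
with sum-aggregated statistics, bootstrap confidence intervals, permutation
tests, McDonald-Kreitman/DoS selection tests and ENC codon-usage bias.

Because real data of this kind pass through heavy external machinery
(aligners, SNP callers, ML divergence estimators), the package ships a
synthetic-data generator with recorded ground truth, so that every stage
can be validated end to end: substitutions placed on known branches with
known omega, expression effects of known size injected into known genes,
and polymorphisms of known class at known frequencies.

## Expression classification

RPKM is `1e9 * count / (length_bp * library_size)`. A gene is considered
expressed in a tissue if at least half of the individuals (ceiling, so 2
of 3) of at least one sex reach 2 RPKM (inclusive). Counts are normalized
per tissue by TMM (trimmed mean of M-values, via edgeR, which is also the
framework the field uses for this design) and tested per gene with the
exact negative-binomial test of male vs female counts; p-values are BH
adjusted across tested genes. A gene is MB if its log2 male:female fold
change exceeds 1 with adjusted p < .05, FB if below -1, otherwise UB.

The fold change is computed from TMM-normalized mean abundances with a
pseudo-offset of 0.25 counts, so that genes silent in one sex have a
finite, large fold change rather than an infinite one. The five
fold-change classes used downstream are FC <= -3, -3 < FC <= -1,
-1 < FC < 1, 1 <= FC < 3 and FC >= 3.

For class summaries, "average expression" is the per-gene mean over
individuals of log2(RPKM + 1), averaged over genes; Wilcoxon rank-sum
tests are two-sided, falling back to the normal approximation with tie
correction whenever ties make the exact distribution unavailable.

## Alignment cleaning

Codon alignments are cleaned in three steps. First, every codon column
containing a gap in any taxon is removed, preserving frame. Second, a
two-pass sliding-window mask targets alignment and sequencing error: for
each taxon, codons whose amino acid differs from the majority amino acid
of the other taxa are counted in sliding windows; a window of 15 codons
with more than 7 mismatches, then (on the masked output) a window of 4
codons with more than 2 mismatches, is masked wholesale for that taxon.
Both thresholds are strict inequalities; windows slide by one codon and
overlapping masked windows union; codons with ambiguity characters and
majority ties are never counted (conservative); a window longer than the
alignment is clipped. Masking is idempotent. Third, genes whose clean
length after gap removal and masking is below 300 bp are dropped
(exactly 300 bp passes).

## Branch-specific divergence

The species tree is
`((S_viminalis, S_suchowensis), ((P_tremula, P_tremuloides), P_trichocarpa))`,
and divergence is estimated on the S. viminalis terminal branch. The
ancestral codon at the Salix ancestor node is reconstructed by Fitch
parsimony applied per nucleotide position at the trifurcation joining the
focal tip, the sister tip and the outgroup clade: a base present in at
least two of the three child sets wins. Two design points deserve
emphasis:

* The focal tip participates in the reconstruction. With only the sister
  and outgroups, a change on the short sister branch and a change on the
  much longer stem path produce identical site patterns, and any
  deterministic tie-break misattributes one entire class of deep
  substitutions to the focal branch (we measured roughly tenfold inflation
  of focal counts under that scheme on simulated data).
* Reconstruction is per nucleotide, not per codon. A focal-branch change
  and an outgroup-path change inside the same codon almost always hit
  different positions, so position-wise parsimony resolves codon columns
  that are hopelessly tied at the whole-codon level. Columns still tied at
  one position contribute both most-parsimonious candidate codons with
  weight 1/2 (synonymous double hits concentrate at third positions, and
  skipping such columns would bias dS downward by over 10%); columns tied
  at two or more positions are skipped and logged.

Given the ancestor, each focal-tip difference is classified by NG86
pathway counting: single-nucleotide differences directly, multi-nucleotide
codons by averaging synonymous/nonsynonymous steps over all mutational
orderings that avoid stop codons, with equal weights. Site totals use the
NG86 fractional-site definition on the ancestor sequence, with changes to
stop codons excluded from both numerator and denominator, so N + S equals
3 times the counted codons. Columns with a gap, an ambiguity or a mask in
any taxon are excluded from substitutions and sites alike. Genes with
dS > 2 would be considered saturated and are excluded (none arise at the
default simulation settings).

On simulated data this estimator is calibrated: regressing estimated on
true focal-branch counts gives slopes within a few percent of 1 for both
DN and DS, and an omega = 1 simulation is recovered within 5%.

## Polymorphism rules and codon matching

A site is a valid SNP iff (a) coverage is at least 20 in at least half
(ceiling) of the individuals of one sex, (b) the pooled minor allele
frequency over the individuals passing the coverage rule is at least 0.20,
and (c) at least 3 pooled reads support the alternate allele. SNPs are
classified synonymous/nonsynonymous by substituting the alternate base
into the reference codon; variants creating stops are nonsynonymous and
flagged; codons with several variants contribute each variant
independently and are flagged.

For the McDonald-Kreitman analysis, divergence and polymorphism must share
a site basis. A codon is "matched" iff all three of its sites pass the
coverage rule, it survived gap stripping, and it is unmasked in every
taxon; N, S, DN, DS, PN and PS are all recomputed over matched codons
only, so the same N and S denominators serve dN, pN and dS, pS.

## Category statistics

All category-level divergence and polymorphism statistics are
sum-aggregated: `sum(numerator) / sum(denominator)` over genes, never the
mean of per-gene ratios (which explodes for low-dS genes). For dN/dS this
is algebraically identical to estimating omega on the concatenation of the
category's genes, which the package emits as a cross-check column.
Confidence intervals are percentile bootstrap (1,000 replicates by
default), resampling genes; contrasts are two-sided permutation tests on
the difference of aggregates, shuffling category labels with group sizes
preserved and using the add-one correction
`p = (1 + #{|diff_perm| >= |diff_obs|}) / (reps + 1)`. Three pairwise
contrasts (MB-UB, FB-UB, MB-FB) are reported without multiplicity
adjustment. Genomic strata (autosomes plus recombining Z vs the
nonrecombining Z region, 3.5-8.8 Mbp in this system) are assigned by
interval overlap from a BED file or data frame.

The permutation statistic is the difference of sum-aggregates rather than
of means of per-gene ratios, for consistency with the aggregation
rationale above.

## Selection tests

Each gene's 2x2 table (DN, DS, PN, PS) gets a two-sided Fisher exact test;
fractional pathway-averaged D counts are rounded to the nearest integer
(ties up). Genes are excluded when any row or column margin of the table
is below 6 ("less than six", so margins of exactly 6 are kept). A gene is
called under positive selection when it is included, Fisher p < .05, and
dN/dS > pN/pS; the two-sidedness is conservative, with the ratio condition
supplying direction. DoS = DN/(DN+DS) - PN/(PN+PS) is computed from the
same rounded table and is undefined when either denominator is zero.
Category contrasts compare positive-selection proportions and DoS > 0
proportions by Fisher exact tests, and DoS distributions by Wilcoxon
rank-sum tests.

## Codon usage

ENC follows Wright: per amino-acid family with n observed codons and usage
proportions p, homozygosity F = (n * sum(p^2) - 1)/(n - 1); class averages
over twofold, threefold, fourfold and sixfold families give
Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61. Families with fewer
than 2 observations are dropped from their class average; a missing
threefold class (Ile absent) is recovered as F3 = (F2 + F4)/2; if the
twofold, fourfold or sixfold class is empty the gene is flagged and
excluded from category means. The statistic runs from 20 (one codon per
amino acid) to 61 (uniform usage). The finite-n correction makes Nc very
mildly length-dependent (shrinking as 1/n); usage proportions themselves
are length-invariant.

## Expression confounders

Because highly expressed genes tend to have lower dN/dS, the package
provides two confounder analyses: sum-aggregated dN/dS by quartile of mean
log2(RPKM+1) expression (quartile breaks over all genes), and an OLS
regression of per-gene dN/dS on expression, ordinal degree of sex bias and
their interaction. The bias coding is genuinely ambiguous in this design;
the default is signed (-2 for FC <= -3 through +2 for FC >= 3), with a
magnitude coding (0, 1, 2) available by argument. Genes with dS = 0 have
no defined ratio and are excluded with a count. dN/dS is regressed
untransformed.

## The generator and what it does (not) emulate

The generator is the package's test bed, not a model of any particular
dataset; its defaults encode the magnitudes a practitioner would call
realistic for this system.

* **Sequences.** A root sequence of sense codons is drawn per gene with
  family-preferred codons (C/G-ending) upweighted by a per-category
  profile, then evolved down the tree. On a branch of length l, each
  nucleotide site receives Poisson(l) attempted mutations; each attempt
  proposes a non-stop single-nucleotide neighbour
  (transition/transversion-weighted) and is accepted with probability 1 if
  synonymous, omega if nonsynonymous. Proposing among non-stop neighbours
  makes E[dS] = l and E[dN] = omega * l exactly under the NG86 site
  definition, so the counting estimator has a clean oracle. The default
  transition/transversion weight is 1 for the same reason; raising it
  reintroduces the classic NG86 bias and is available but not default.
  Defaults: focal branch length 0.0135 and omega UB = 0.22, MB = 0.195,
  FB = 0.21 (the magnitudes seen for this system); deeper branches up to
  0.06. Non-focal branches evolve at the UB omega. Configurations whose
  expected focal dS exceeds 2 are rejected as saturated.
* **Expression.** Negative-binomial counts (dispersion 0.1) around
  log-normal baselines for 3 male and 3 female individuals in catkin and
  leaf. MB genes get a +2 log2 male:female fold change in catkin (split
  symmetrically between sexes), FB genes the negative; leaf carries no
  injected bias, mirroring the near-absence of leaf sex bias in this
  tissue pair.
* **Polymorphism.** Per-site Poisson coverage (mean 30); synonymous SNPs
  at rate 0.011 per synonymous site and nonsynonymous SNPs at 0.25 times
  that rate per nonsynonymous site (giving pN/pS near 0.25); derived-allele
  counts uniform on 1..n so that both MAF-passing and MAF-failing sites
  occur; read counts binomial in allele dosage.

Not emulated: read-level artifacts (mapping error, base-quality structure,
strand bias), indels, recombination and linkage, gene families and
misassigned orthologs, and expression-correlated evolutionary rates.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under a clean generative model, not that any
particular biological conclusion about real data is reproduced.

## Numerical and scale choices

Randomness: every generator derives its stream from the configuration
seed (alignments: seed; expression: seed + 1; site tables: seed + 2), and
bootstrap/permutation helpers accept explicit seeds; identical inputs give
byte-identical outputs.

Validation sizes were chosen to make the checks statistically meaningful
on a single CPU in minutes: estimator calibration at 150 genes x 300
codons; type-I error of the permutation contrast on 500 null splits of a
240-gene pool at 399 permutations (attainable level 0.0475); power and
ordering of a true omega contrast (0.10 vs 0.22) on 50 independent runs
of 200 genes x 300 codons at 1,000 permutations; bootstrap coverage on
400 replicates of 60-gene pools at 999 bootstrap replicates. The coverage
band (93-97% for a nominal 95% interval) reflects both Monte-Carlo error
at that scale and the small-sample behaviour of percentile intervals for
ratio statistics.

Degenerate inputs are handled explicitly: zero library sizes, all-zero
samples, empty categories, zero denominators in any aggregate, genes with
no matched codons, unresolvable ancestor columns, and flagged ENC genes
are all either errors naming the offender or exclusions with a message,
never silent NAs.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes_per_category = 100,
                  gene_length_codons = 300)
res <- sexbias_pipeline(cfg, reps = 1000)
print(res)
summary(res)
```

The object carries the per-gene matched table (`res$genes`), the
category/stratum summary with CIs and permutation p-values
(`res$category_table`), selection and ENC contrasts, and the expression
regression. `write_simulated_data()` exports the simulated inputs as
FASTA/Newick/TSV for use outside R.

## Known limitations

* The divergence estimator is parsimony + NG86 counting, not maximum
  likelihood; at deep divergences or strong transition bias it inherits
  the known biases of counting estimators. Its calibration is established
  by simulation under the package's own generative model.
* The SNP validity rules operate on site tables; read-level caller
  parameters (base quality, strand filters, homozygote frequency) are
  upstream of this package and not reproducible from a site table.
* The expression test uses a tissue-wise exact NB test with tagwise
  dispersion; p-values are contract-compatible (BH-adjusted per-gene
  two-group tests), not bit-identical to any particular external run.
* ENC's missing-family handling (drop n < 2 families; recover F3 from F2
  and F4) is one of several conventions in circulation; alternatives move
  Nc only in genes with unusually skewed amino-acid usage.
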