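---
title: "Exome read-depth deletion discovery: models, parameters and design choices"
author: "exodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome read-depth deletion discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exodel)
library(dplyr)
```

# The problem

Exome sequencing of disease cohorts is usually mined for single-nucleotide
variants, but the same per-target read depth carries copy-number
information: a heterozygous deletion halves the expected depth over the
exons it spans. `exodel` implements a complete deletion-discovery and
interpretation pipeline for case-control exome cohorts, of the kind used to
survey rare genic deletions in common genetic epilepsies (generalized and
Rolandic):

1. depth normalization and a hidden Markov model caller,
2. deletion filtering against in-house controls and population CNV maps,
3. a large/rare-deletion burden test by phenotype-label permutation,
4. variant QC plus a composite deleterious-variant classifier,
5. a compound-heterozygote screen extended to first-order
   protein-interaction partners on a brain-specific network, and
6. hypergeometric gene-set over-representation against a brain-expressed
   background.

Because patient exomes cannot be redistributed, the package ships a seeded
synthetic-cohort generator that reproduces the statistical structure each
stage assumes; all tests run without any external data.

# The depth model and the caller

## Normalization

Let $X$ be the samples-by-targets matrix of mean per-target read depth.
After excluding samples with mean depth < 30x or with fewer than 70% of
targets covered at >= 20x, each target column is mean-centred and a singular
value decomposition is taken. Components whose variance exceeds
`rel_var_threshold` (default 0.7) times the *mean* component variance are
subtracted — the "PVE-mean" criterion of the published PCA+HMM exome CNV
method this caller re-implements. These top components absorb capture batch
effects, per-sample library size and other latent structure; a sparse
deletion (a handful of carriers over tens of targets) contributes far less
variance than one principal component and survives. Each residual row is
finally divided by its own standard deviation, giving per-sample z-scores
with unit row variance.

Two numerical facts shaped the defaults of the *generator* (not the
caller): the PVE-mean cut only separates structure from noise when the
structured components dominate the Marchenko-Pastur noise bulk, and a
deletion spanning a large fraction of the target space is diluted by the
per-row standardization. Both are properties of the real method that the
synthetic data must respect, and they are discussed under the generator
below.

## The hidden Markov model

Per sample and chromosome the z-scores are decoded with a 3-state HMM
(diploid, deletion, duplication) with Gaussian emissions
$\mathcal N(0, 1)$, $\mathcal N(-3, 1)$, $\mathcal N(+3, 1)$ and
distance-dependent transitions. With CNV entry probability $p$ (default
$10^{-8}$), per-target exit rate $q = 1/t$ (expected CNV length $t = 6$
targets) and attrition factor $f = e^{-d/D}$ for inter-target gap $d$ and
attrition distance $D = 70\,000$ bp, the transition matrix from a CNV state
is

$$P(\text{CNV} \to \text{CNV}) = f(1-q) + (1-f)\,p, \qquad
  P(\text{CNV} \to \text{DIP}) = fq + (1-f)(1-2p),$$

so distant targets relax toward the diploid stationary distribution. These
are the published defaults of the re-implemented method; the source study
names only the tool, so all of them are exposed as `hmm_params()`
arguments. Viterbi decoding uses log-space arithmetic with deterministic
tie-breaking (lowest state index wins), and maximal non-diploid runs become
calls.

Each call is scored with `q_some`, the phred-scaled posterior probability
that at least one target in the segment is non-diploid, computed from a
forward-backward pass plus a state-restricted forward recursion — entirely
in log space, so $q_{some} = -10(\log P_{\text{none}} - \log P_{\text{data}})/\ln 10$
never underflows. Following the original tool's convention it is rounded
and capped at 99. `z_mean` is the arithmetic mean z over the call's
targets. The test suite checks Viterbi likelihoods, decoded paths,
posterior normalization and `q_some` against exhaustive enumeration of all
$3^n$ state paths on instances of up to 8 targets.

## Deletion filtering

Deletions are retained when `z_mean` < -3 (strict) and `q_some` >= 60;
duplications are always dropped, as their false-positive rate under
read-depth calling is too high for meaningful interpretation. Case-only
deletions additionally require: no control carries a matching call, at most
2 distinct case carriers, and no reference-map interval with frequency
above 1% matches. "Matching" is 70% *reciprocal* overlap
($\min(|a\cap b|/|a|, |a\cap b|/|b|)$) throughout; the source study sets
the 0.7 fraction without specifying one-way versus reciprocal, and the
reciprocal form was chosen because it is symmetric and stricter. All
coordinates use 1-based inclusive starts with exclusive ends, so
`length = end - start` — the convention under which every row of the
bundled table of 104 published microdeletions reproduces its printed length
exactly.

# Burden testing

Large (> 400 kb, strict) deletions with internal carrier frequency below
0.5% enter four statistics per phenotype group: deletion rate per person,
proportion of samples with at least one deletion, total deleted length per
person, and average deletion length (0 for a group without calls). The
observed case-minus-control difference of each statistic is referred to its
permutation distribution under random relabeling, one-sided (cases higher).
With at most `exhaustive_limit` (default 5000) distinct labelings the
enumeration is exact and $p = \#\{\Delta^* \ge \Delta\}/n_{\text{labelings}}$;
otherwise `n_perm` (default 10,000) seeded relabelings are drawn and the
add-one estimator $p = (1 + \#\{\Delta^* \ge \Delta\})/(1 + n_{\text{perm}})$
is used, which is unbiased-in-spirit and never zero. On the worked
4-case/4-control instance with one deletion per case, exact enumeration
over $\binom{8}{4} = 70$ labelings gives $p = 1/70$ for the rate statistic,
which the acceptance suite asserts. Because count-based statistics are
discrete, the permutation test is mildly conservative; the calibration
test (500 null cohorts of 300 cases / 300 controls with Poisson(1)
deletion counts, 200 permutations each) checks that the rejection rate at
$\alpha = 0.05$ stays in the 3-7% band for all four statistics.

# Variant pipeline

Genotypes with DP < 10 or GQ < 20 are masked to missing and site
missingness recomputed. Site-level predicates follow GATK-style hard
filters (SNVs: QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
ReadPosRankSum < -8, DP < 10, GQ_MEAN < 20, VQSLOD < 0, missingness > 5%,
ABHet outside [0.25, 0.75], Hardy-Weinberg phred > 20, i.e. HWE p < 0.01;
INDELs: FS > 200 and ReadPosRankSum < -20 instead, without the
MQ/ABHet predicates). Missing annotations pass by default (filter on
evidence present); `strict_missing = TRUE` inverts that. The INDEL VQSLOD
clause is direction-ambiguous in common practice, so it is an explicit
configuration choice (`indel_vqslod_rule`), defaulting to failing negative
values symmetrically with SNVs.

Multi-allelic records are decomposed to biallelic ones and left-normalized
by the standard trim-and-shift algorithm (trim shared trailing bases,
extending left from the reference when an allele would empty; then trim
shared leading bases). The operation is idempotent, which the property
suite checks on randomized indels.

A variant is *rare* when its minor allele frequency is strictly below
0.005 in every population database column; an absent entry counts as
frequency zero. A variant is *deleterious* when any of three criteria
fires: (1) it is not synonymous and has >= 5 "deleterious" calls among the
missense predictor panel, or CADD > 4.5, or at least 2 of
{GERP > 3, PhyloP > 0.95, SiPhy > 10}; (2) it is splicing, stop-gain or
stop-loss; (3) it is any insertion or deletion. The source description
says "5 out of 8" while listing nine predictors; the panel here defaults
to all nine with a quorum of 5, and both are configurable. Missing
predictor calls never count toward the quorum, and synonymous variants
never qualify through criterion 1 regardless of their scores. The
classifier is verified against an independent truth-table oracle over the
full predicate space (effect class x hit count x CADD side x conservation
pattern).

The CADD threshold of 4.5 is applied to whichever CADD column the input
provides; the source does not state whether it is raw or phred-scaled, so
the threshold is configurable rather than reinterpreted.

# Compound heterozygotes on a brain network

The interaction network is restricted to nomenclature-valid,
brain-expressed genes (edges survive only if both endpoints do; no
transitive closure). For each sample, a *same-gene* hit is a case-only
deleted gene that also carries a rare deleterious variant in that sample;
a *first-order* hit is a deleterious-variant gene adjacent in the filtered
network to one of the sample's deleted genes. Phasing is unavailable at
this resolution, so "deletion on one allele, variant on the other" is
operationalized as co-occurrence in the same sample — a deliberate,
documented over-approximation. Genes absent from the network remain
eligible for same-gene hits. The screen is checked against a brute-force
triple loop over (sample, deleted gene, variant) on random instances.

# Over-representation and score comparisons

Gene-set over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for $X \sim \text{Hypergeom}(N, K, n)$ with a brain-expressed
background universe. The three published deleted-gene versus epilepsy-gene
analyses — overlaps of 13/134, 7/49 and 6/85 deleted genes against 674
epilepsy-associated genes in a background of 14,177 — are recomputed by the
acceptance suite and agree with the printed values to within 0.002 before
rounding. The source labels those p-values "empirical" while citing an
exact-test implementation; the exact tail is used here, with the small
tolerance absorbing that ambiguity. Per-gene score comparisons (e.g. CNV
tolerance scores between phenotypes) use the Wilcoxon rank-sum test: exact
when both groups have <= 20 observations without ties, mid-rank normal
approximation with tie-corrected variance otherwise, and p = 1 by
convention for fully degenerate data.

# The synthetic cohort generator

The generator is a first-class module: every downstream stage is tested
against cohorts it produces. Defaults emulate the post-QC cohort scale of
the motivating study — 196 GGE-like cases, 194 RE-like cases, 572
controls — with the following depth model per cell:

$$X_{ij} \sim \text{NB}\!\left(\mu_{ij},\ \phi\right), \qquad
\mu_{ij} = \bar\mu\, s_i\, t_j\, b_{ij}\, c_{ij}$$

* $\bar\mu$ = 100x mean depth; $\phi = 0.005$ dispersion, giving a
  per-target coefficient of variation of ~12% at 100x, typical of exome
  capture;
* $s_i$: log-normal per-sample size factors (sd 0.1 on the log scale,
  i.e. ±10% library-size spread);
* $t_j$: log-normal per-target capture efficiencies (sd 0.3);
* $b_{ij} = \exp(\sigma_b \sum_r a_{ir} g_{jr})$: multiplicative low-rank
  batch structure, rank 3 with $\sigma_b = 0.15$;
* $c_{ij}$: the injected copy ratio (0.5 for heterozygous deletions over
  carrier-by-locus cells, 1 elsewhere).

Two generator choices deserve their variance analysis on record. First,
the batch amplitude: with weak batch structure the PVE-mean 0.7 threshold
lands inside the Marchenko-Pastur noise bulk, and the normalization either
strips dozens of noise components (attenuating every deletion) or, worse,
removes single-sample components and collapses individual samples.
Real multi-center exome cohorts have dominant batch structure — that is the
premise of PCA normalization — and $\sigma_b = 0.15$ places the structured
components roughly an order of magnitude above the noise bulk for cohorts
from 60 to 1000 samples, so the published criterion behaves as designed.
Second, target density: targets are tiled with ~12 kb mean inter-target
gaps, matching the density of a real exome (~30 Mb of targets in a 3 Gb
genome). Density matters because a >400 kb deletion then spans ~40 targets,
a small fraction of the target space; on an unrealistically dense grid the
same deletion would cover several percent of all targets and the per-row
standardization would dilute its z-scores.

Chromosomes are synthetic (`chr1`..`chr4` by default, 1-based
coordinates); deletion loci are placed on non-overlapping target runs
(largest first, uniformly among feasible starts), and carriers are drawn
from the configured phenotype groups. Reference CNV maps plant the loci
flagged `common_in_reference` at >1% frequency so case-only filtering has
true positives to remove, while keeping accidental overlaps of background
intervals with other truth loci rare. The variant generator emits the nine
predictor calls, CADD, three conservation scores, four database allele
frequencies, GATK-style site annotations and heterozygous genotypes with
DP/GQ; a configured fraction of missense sites is generated "deleterious"
(predictor consensus, high CADD, high conservation) so classifier rates are
testable binomially. Networks are Erdős–Rényi $G(n, m)$ graphs with a
configured mean degree and brain-expression flag rate (default 0.78,
matching the proportion observed when a curated interaction network is
restricted to brain-expressed genes).

All randomness flows from one global seed through named child streams
(`child_seed(seed, "depth")`, `"variants"`, `"network"`, ...), so adding a
generator never perturbs another and any stage is replayable in isolation.

## What the generator does *not* emulate

No GC-content or mappability bias, no raw reads or alignment artifacts, no
duplications, no population structure or relatedness, no linkage between
variants, and no exclusion modelling for the (unstated) difference between
recruited and analysed sample counts in the motivating cohort. Passing
tests on synthetic cohorts therefore demonstrate the statistical machinery
under the stated depth model — not robustness to every failure mode of real
capture data.

# Problem sizes used by the test and acceptance suites

The recovery analysis uses 100 cases + 100 controls over 5,000 targets at
100x with heterozygous deletions spanning 12-18 targets — large enough for
stable PCA spectra, small enough to iterate comfortably. Deletions of
exactly 10 targets are detected too, but sit closer to the z < -3 filter
boundary (mean segment z scales with the locus-average capture efficiency),
so the quoted sensitivity condition uses the 12-18 target range; boundary
targets with weak capture efficiency are occasionally trimmed by the
Viterbi path, which is the caller's resolution limit, not a defect. HMM
enumeration oracles run at up to 8 targets ($3^8$ paths); burden
calibration uses 500 replicate null cohorts with 200 permutations each.

# Known limitations

* Breakpoints are target-resolution only; lengths are exon-span lengths.
* `q_some` is the only genotype-quality score carried; no per-sample
  re-genotyping quality is computed.
* The burden module's statistics are the four published ones; covariate
  adjustment is out of scope.
* Hemizygous-variant phasing is not modelled in the compound-het screen.
* Whether the published per-call "Z-score" is the mean normalized z or the
  tool's mean-read-depth field is not stated in the source; `z_mean` (mean
  normalized z) is used and named accordingly.
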