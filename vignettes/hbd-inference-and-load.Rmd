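---
title: "Model-based autozygosity inference and minor-allele load statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based autozygosity inference and minor-allele load statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdload)
```

`hbdload` infers homozygosity-by-descent (HBD) segments from unphased
biallelic SNP genotypes, quantifies the amount and the *age structure* of
individual inbreeding, and compares the burden of (putatively deleterious)
minor alleles between groups of populations. This vignette is the package's
account of the underlying models, the tunable parameters, and the design
choices made where the design was genuinely open.

## The multi-class HBD hidden Markov model

Within an individual, a genomic position is homozygous-by-descent when both
copies coalesce in a single recent ancestor. Segments created by a
coalescence about `g` generations back have exponentially distributed
genetic lengths with mean `1/(2g)` Morgans. The model therefore runs a
hidden Markov chain along the ordered markers of each individual with `K`
HBD classes of increasing *rate* `R_k` (default the ladder 2, 4, ..., 8192)
plus one non-HBD class (rate 8192). A class of rate `R` collects segments
whose ancestry lies about `R/2` generations back; its segments have mean
length `1/R` Morgans.

* **Transitions.** Across a genetic distance `d` (Morgans) the chain stays
  in state `k` with probability `exp(-R_k d)`; otherwise the segment ends
  and a new state is entered with probability given by the mixing
  coefficients `M` (re-entry into the same class is allowed). The initial
  distribution is `M`. Scaffolds are decoded as independent chains: the
  implementation inserts an effectively infinite inter-scaffold distance,
  which makes the transition collapse exactly to `M`.
* **Emissions.** With alternate-allele frequency `f` at a marker, the
  non-HBD state emits genotypes by Hardy-Weinberg
  (`(1-f)^2, 2f(1-f), f^2`). An HBD state is homozygous for a single
  founder allele sampled with probability equal to its frequency, so it
  emits `(1-f, 0, f)`; a genotyping-error rate `e` (default 0.001) mixes
  in the Hardy-Weinberg law so that isolated heterozygous calls do not
  veto a segment. Missing genotypes emit likelihood 1 in every state.
* **Estimation.** Rates are fixed; only the mixing coefficients are fitted
  per individual by EM, re-estimating `M` from the expected number of
  state *entries* (initial state plus posterior-weighted jump events) on
  each forward-backward pass. This update provably does not decrease the
  likelihood; iteration stops when the log-likelihood improves by less
  than `tol` (default 1e-4) or after `max_iter` (default 100) iterations,
  in which case the fit is flagged, not rejected. Uniform initialisation
  is used; the likelihood ridge between neighbouring old classes means
  individual class weights are less identifiable than their sums, which
  is why downstream quantities aggregate classes.
* **Numerics.** Forward and backward variables are rescaled at every
  marker, so panels of millions of markers stay in range; the per-marker
  stay probabilities are precomputed once per individual and shared
  across EM iterations. Both passes exploit the rank-one structure of the
  transition matrix and run in `O(markers x states)`.

`F_HBD` is the mean over markers of the posterior probability of the
autozygous classes — those with rate at most `T`. The default `T = 1024`
declares segments coalescing up to 512 generations back autozygous. The
threshold is implemented as `rate <= T` so that the rate-1024 class (512
generations) is included, matching the stated 512-generation horizon; a
strict-inequality variant is available via `strict = TRUE`. Viterbi
decoding provides discrete segments, from which `N_HBD` (count) and
`S_HBD` (mean length, 0 for an empty set so summaries stay total) are
computed per individual over the autozygous classes.

Emission allele frequencies default to the individual's population
(`freq_scope = "population"`); `"global"` reproduces the common practice
of running the model on a pooled multi-population panel.

## Allele-sharing inbreeding and the origin contrast

The matching between individuals `i` and `j` at a locus with dosages
`x_i`, `x_j` is `(x_i x_j + (2 - x_i)(2 - x_j))/4` — the probability that
one random allele from each matches. Within an individual this is 1 at a
homozygous and 0.5 at a heterozygous locus. Averaging over loci gives the
matrix `M`. With `Mbar_B` the mean between-individual matching of a
reference set, the self-kinship `beta_ii = (M_ii - Mbar_B)/(1 - Mbar_B)`
estimates `(1 + F_i)/2`, so the package reports

`F_AS,i = 2 beta_ii - 1`.

The transformation matters: the raw scaled diagonal has expectation 0.5,
not 0, under random mating, because the within-individual baseline
`1 - f(1-f)` differs from the between-pair baseline `1 - 2f(1-f)`. The
reported `F_AS` is zero-centred under random mating, 1 for a fully
homozygous genome, and negative for individuals who match alleles less
than random pairs of their population — the hallmark of sampled sib
groups, whose mutual relatedness inflates `Mbar_B`.

Pairwise relatedness for the unrelated-reference filter is the analogous
off-diagonal standardisation `(M_ij - Mbar_B)/(1 - Mbar_B)`; individuals
are removed greedily (most violating pairs first, ties broken by lowest
id) until all pairs sit below the threshold (default 0.05 — full sibs
score about 0.25, so families are reliably split).

Because `F_HBD` measures IBD against the allele-frequency reference while
`F_AS` measures it against the *current population's* sharing, their
contrast dates the inbreeding: `F_HBD` clearly above `F_AS` indicates
ancient coalescence (small historical population size); the reverse
indicates structure or recent consanguinity. The `origin` label uses a
reporting band `delta` (default 0.01) around the identity line; the raw
coefficients remain the quantitative output.

## Diversity and effective size

Per-site diversity is the unbiased pairwise difference
`2 d (m - d)/(m (m - 1))` over the `m` non-missing allele copies.
Averaging uses either the number of sites in the analysed panel (the
default; comparable across SNP panels but *inflated* relative to per-bp
diversity, since monomorphic genome positions are absent) or a supplied
callable length in bp. Reports always state which denominator was used.
`Ne = pi / (4 mu)` with `mu` defaulting to 4.6e-9 per site per
generation, a passerine pedigree estimate; `Ne` is exactly linear in `pi`
and inversely proportional to `mu`, so a different mutation rate rescales
but never reorders populations. Uncertainty comes from a block bootstrap:
1 Mb physical blocks resampled with replacement, 1000 replicates by
default, replicate SD reported as SE.

## The autozygosity landscape

Per-SNP HBD probability (the posterior mass of all HBD classes, averaged
across individuals; a `limit_T` option restricts to the autozygous
classes) is summarised in sliding physical windows — 100 kb width, 20 kb
step by default, left-aligned at the scaffold start, last partial window
kept. Scaffolds with fewer than `min_scaffold_snps` markers (default
10,000) are dropped wholesale; windows without SNPs are emitted with a
missing value so gaps stay visible. Windows in the upper and lower
`tail = 2.5%` of probabilities are flagged islands and deserts. When ties
would over-fill a tail beyond `ceiling(tail x n)` windows, only strictly
extreme windows are flagged (a constant track flags nothing) and any
residue is resolved by genomic order — reproducibility over completeness.
Gene density per window counts every gene touching the window (half-open
overlap, so a boundary-spanning gene counts in both windows); the
association with window HBD probability is a Spearman rank correlation
with a seeded permutation p-value (10,000 shuffles by default).

## Minor-allele load and the R_XY family

Minor alleles proxy derived (and enriched-for-deleterious) alleles.
Because the rarer allele at a site depends on who is sampled, minor
alleles are called *globally* by bootstrap: each of 1000 replicates draws,
with replacement, an equal number of unrelated individuals per population
(the smallest unrelated-set size, so no population dominates), and votes
for the rarer allele; exact ties vote for the alternate allele, and the
across-replicate majority is the call. The equal-draw balancing and the
tie direction are deliberate fixed conventions; the tie rule is the one
place where the call depends on the ref/alt labelling.

For two disjoint groups `X` and `Y` and a functional category, with
`d/n` the minor-allele fraction at a site in a group,

* `L_XnotY = sum_i (d_X/n_X)(1 - d_Y/n_Y)` and `R_XY = L_XnotY / L_YnotX`;
* the homozygous analogue `R2_XY` uses expected-homozygote terms. The
  printed form of that term reduces algebraically to `2d/n` (its
  common factors cancel), which the default `l2_form = "literal"`
  evaluates; `l2_form = "dodds"` substitutes the unbiased homozygosity
  `d(d-1)/(n(n-1))`. Both are reported because the literal form is
  unlikely to be the intended statistic, yet is what the defining
  equations say.
* `R'` ratios divide the category ratio by the intergenic ratio,
  cancelling demography shared across categories; `R' = 1` means
  selection has been equally efficient in both groups.

Standard errors come from a delete-one block jackknife over contiguous
5 Mb physical blocks (at least 10 blocks required; the block length is an
argument). A ratio is flagged significant when the interval
`ratio +- SE` excludes 1 — under the null this flags roughly a third of
replicates, which is the convention's known permissiveness, so the flag
is a screen, not a test. Group-level count comparisons use the two-sided
Wilcoxon rank-sum test (normal approximation, tie-corrected) with effect
size `r = |Z|/sqrt(n)` labelled at the conventional 0.1/0.3/0.5 cut-offs.

## The synthetic-data generator

Every stage is testable by parameter recovery on panels with known truth.
Per individual and scaffold, the autozygous mosaic is an alternating
renewal process: non-HBD gaps are exponential with mean
`w_0 / sum(w_k R_k)` Morgans, a tract picks class `k` with probability
proportional to `w_k R_k` and has exponential length with mean `1/R_k` —
so the expected genome fraction in class `k` is exactly the configured
weight `w_k`. Genotypes are Hardy-Weinberg outside tracts; inside, the
individual is homozygous for one founder allele drawn with probability
equal to its population frequency, heterozygous only with the
genotyping-error probability. Population structure uses the
Balding-Nichols construction (a Beta distribution around the ancestral
frequency with one divergence knob per population); ancestral frequencies
are uniform by default, mimicking a panel already filtered on minor
allele count. Full-sib pairs are two offspring of simulated parents,
appended after the unrelated individuals and flagged in metadata. Load
asymmetry multiplies the minor-allele frequencies of chosen categories in
one group by a factor, clamped to `[0, 1]`; intergenic sites are never
shifted, preserving the normalising reference.

**What the generator does not emulate — and what that implies.** Sites
are independent: there is no linkage disequilibrium, no shared haplotype
blocks between individuals, and no evolved selection (load asymmetry is
imposed, not evolved). Consequently:

* parameter-recovery results certify the *estimators* under the model's
  own assumptions, not robustness to real LD structure;
* drift-induced excess homozygosity is sitewise-independent, and the HMM
  correctly refuses to call it recent autozygosity — it lands in the
  oldest (excluded) classes. Real panels, where ancient co-ancestry
  arrives in linked blocks, are *easier* for the model than this
  simulation, not harder.

The second point has a concrete consequence for the classic island
signature (`F_HBD` above `F_AS`). In real island populations the shared
ancient co-ancestry inflates the between-individual reference of `F_AS`
while the HBD model, fed pooled allele frequencies, still sees the
corresponding linked homozygosity as segments. The generator cannot
reproduce that configuration: planted tracts are independent across
individuals, so they raise `F_AS` by exactly the planted fraction — the
same quantity `F_HBD` estimates with a small detection loss. A strict
`mean F_HBD > mean F_AS` under planting alone is therefore not expected
to hold here, and the corresponding calibration check documents this
limitation rather than papering over it. Diagnosing inbreeding origin on
real data is unaffected; it is the synthetic emulation of *shared*
ancestry that is out of scope.

## Reference study conditions used by the test suite

Analytic toys aside, the property checks run at desk scale, chosen once:

* parameter recovery: 30 individuals, 15 scaffolds of 100 Mb at 2e-8
  Morgans/bp (30 Morgans total), 1500 markers per scaffold, planted
  fractions 0.05/0.10/0.30 in the rate-64 class;
* calibration of `R'`: 200 replicate panels, two populations of 12 with
  equal divergence 0.05, 4000 sites over ten 5 Mb scaffolds, 100-replicate
  minor-allele bootstraps;
* load-shift detection: 100 replicates of the same layout with a 0.5
  frequency shift on the deleterious categories of one group;
* the island-signature check: 100 seeds of a two-population panel
  (divergence 0.02 vs 0.10) with ancient-class planting (rates 16-128,
  total 0.10) and pooled emission frequencies.

Larger genomes tighten every recovery; these sizes keep the full suite in
the minutes range on a single core.

## Known limitations

* Mixing-coefficient EM is per individual; no information is shared
  across individuals, matching standard practice but costing precision
  for very sparse panels.
* The emission model assumes known allele frequencies; they are estimated
  from the panel, and in small populations the focal individual's own
  genotypes bias its frequencies slightly toward itself, giving `F_HBD` a
  small downward bias that shrinks with sample size.
* The non-HBD state shares its rate with the oldest HBD class, so
  genome-wide heterozygosity deficits spread over unlinked sites are
  absorbed by old classes, by design.
* Significance flags on `R'` ratios are SE-overlap screens, not
  calibrated hypothesis tests.
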