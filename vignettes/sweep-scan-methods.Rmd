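---
title: "Methods: detecting directional selection in domesticated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting directional selection in domesticated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem

Domestication and breed formation leave two complementary footprints in a
genome. A *completed* sweep shifts allele frequencies along one breed's
lineage, depressing diversity locally; an *ongoing* sweep carries a selected
allele to intermediate frequency on an unusually long haplotype. `sweepscan`
implements the corresponding three-population scan design — two domesticated
breeds (the package's examples call them Yorkshire and Landrace, sampled as
16 and 14 diploids) against a wild outgroup (10 diploid wild boar) — with
the population branch statistic (PBS) for the first footprint, the
integrated haplotype score (iHS) for the second, a distinct-haplotype-count
statistic (H) describing the strong linkage disequilibrium typical of modern
breeds, gene-level outlier calling, and QTL-overlap enrichment.

# Statistics

## Nucleotide diversity and Hudson's K_ST

For `n` haplotypes, `pi` is the mean number of pairwise differences,
computed per site as `c (n - c) / choose(n, 2)` and summed over a window
(identical to enumerating all pairs; the unit tests verify this identity
exhaustively). For two populations,

    F_ST = 1 - pi_w / pi_t,   pi_w = (n1 pi1 + n2 pi2) / (n1 + n2)

with `pi_t` the pooled diversity. Negative estimates (sampling noise around
zero differentiation) are clamped to 0 before the time transform, because a
negative "divergence time" is meaningless; the raw estimate is kept in the
output. A window monomorphic across a pair leaves F_ST undefined and flags
the window.

## PBS

Each pairwise F_ST is mapped to an effective divergence time
`T = -ln(1 - F_ST)`. `F_ST = 1` (all diversity between populations) is
capped in a sample-size-aware way by substituting `1 - 1/(2 n_total)`, so a
fixed difference contributes `ln(2 n_total)` rather than infinity. The three
branch lengths are

    PBS_1 = (T_1w + T_12 - T_2w) / 2   (and cyclically),

reported for both breeds and the outgroup; by construction the three
branches sum to half the sum of the three times, which every scan asserts to
machine precision. Windows hold exactly 200 SNPs and advance by 50 (the
scan's canonical values, both configurable); the SNP set is the sites
variable in the *combined* three-population sample so the three pairwise
F_ST values of a window share identical sites, and trailing partial windows
are dropped — a chromosome with `N >= 200` such SNPs yields
`floor((N - 200)/50) + 1` windows. Downstream outlier calling uses the two
breed branches; the outgroup branch is diagnostic.

## iHS

For one breed, the derived allele at a site is defined *operationally*
against the outgroup: the allele minor, or absent, in the wild sample. A
site with outgroup frequency exactly 0.5 cannot be polarized; rather than
break the tie arbitrarily (mis-polarization flips the sign of the score) the
site is flagged ambiguous and excluded from cores. Cores require breed MAF
strictly above 0.2 — the statistic has maximal power for intermediate
frequencies — and at least two carriers of each allele; EHH extension uses
*every* SNP whatever its frequency. EHH at a span S among the `n_c` carriers
of the core allele is the probability that two random carriers are identical
over S. Each flank is truncated at the first site where EHH drops below
0.05, and the trapezoidal integral `iHH` is taken up to the linearly
interpolated 0.05 crossing; a flank that hits the chromosome end first
produces a biased integral, so edge-truncated cores are reported but
excluded from ranking unless `keep_truncated = TRUE`. The raw score is
`ln(iHH_A / iHH_D)`.

The standardization contract is mean 0, variance 1 within each
derived-allele-frequency class (20 equal-width bins by default, classes
under 10 records merged with the nearest class). One wording ambiguity had
to be resolved: standardizing a folded statistic "to mean 0" is
self-contradictory, so the *signed* score is standardized per class and the
ranking statistic is the absolute standardized score. Integration is over
physical distance; a genetic-map hook would slot in at the offset
computation.

## The H statistic

H is the number of distinct haplotype strings in a bin of 30 sites variable
*within the focal population* (sites fixed in that population are skipped
when composing bins, following the per-breed reading); bins are
non-overlapping by default so the histogram does not double-count, a
step option allows sliding. Low H (2–4) over many bins is the signature of
near-complete LD from inbreeding and admixture between divergent inbred
lines, and is not reproduced by neutral no-recombination simulation under a
simple two-bottleneck demography — the acceptance suite reproduces that gap
qualitatively (see below).

## Gene outliers and QTL enrichment

A site belongs to a gene if it falls within 1 kb upstream of the
transcription start to 1 kb downstream of the stop; since both flanks are
1 kb the assignment region is the span padded by 1 kb on each side whatever
the strand (the flank is closed at exactly 1,000 bp). Window signals attach
by >= 1 bp overlap with that padded span — the most inclusive reading, and
configurable in spirit by passing midpoints as site signals. Each gene keeps
its strongest signal; genes are ranked and the top 1% *of the full annotated
universe* is called outliers (19,990 genes give exactly 200 per breed and
method), with cutoff ties broken deterministically by genomic position.

QTL-candidate genes are genes whose unpadded span overlaps a QTL interval
(< 5 cM, roughly < 5 Mbp, with redundant loci collapsed) by >= 1 bp.
Enrichment of an outlier set against any QTL gene set is assessed by drawing
`B` uniform same-size gene sets without replacement (the field's
"bootstrap" overlap test; this null is exactly hypergeometric, which the
tests use as a closed-form cross-check) with `p = (#{null >= observed} + 1)/(B + 1)`.
Subcategory tests are Bonferroni-corrected within one (breed, method) scan
family. The between-breed outlier-overlap test resamples *both* sets; the
expected null overlap of two independent size-k sets from a universe of G
genes is k^2/G.

# Synthetic data: the stated world

## Neutral coalescent mode

The structured coalescent without recombination mirrors classic ms usage:
lineages coalesce through breed-formation bottlenecks, the breed split
(after which the two breed demes exchange migrants at probability `m` per
lineage per generation), the domestication bottleneck and the wild/domestic
split; mutations fall on the realized genealogy under infinite sites. The
default parameterization is *illustrative of the model class, not a fitted
estimate* — the package simulates under a stated model and does not infer
one: wild ancestor Ne = 10,000; domestication 2,000 generations
ago (10 ky at a 5-year generation time, inside the 5–15 ky window usually
quoted) through a 250-diploid bottleneck lasting 200 generations; breed
formation 40 generations ago (about 200 years) through 50-diploid
bottlenecks of 10 generations; present breed size 1,000; `m = 0.001`;
`mu = 2.5e-8` per site per generation. The domestic lineage between the two
bottlenecks is held at the breed size — the model's field list carries no
separate parameter for it. Collapsed splits (`T_dom = T_split = 0`) give a
single panmictic population, the regime where `E(pi) = theta` and
`E(S) = theta * sum(1/i)` are verified against 10,000 replicates.

Under these defaults the breeds' diversity sits well below the outgroup's
(checked per breed per replicate), the direction the real data show
(0.0029/0.0028 vs 0.0036); the magnitudes are not calibration targets.

## Forward Wright–Fisher mode

The forward simulator is a literal discrete-generation diploid
Wright–Fisher model (implemented in C++; all randomness flows through R's
RNG so a single `set.seed`-style integer governs every run): random mating
with fitness-weighted parent sampling, per-gamete crossover count
Poisson(`r` x region length), finite-sites biallelic mutation with recurrent
hits rejected, migration as a per-gamete probability of drawing a parent
from the other breed, and the same two-split/two-bottleneck timeline.
Desk-scale runs use rescaled parameters (sizes and times divided by Q; `mu`,
`r`, `s` multiplied by Q — [scale_demography()]), and an ancestral burn-in
of `4 N_anc` generations by default (some heavy acceptance worlds shorten
this to ~2 N_anc and say so; standing diversity is then ~80–90% of
equilibrium, which the relevant tests do not depend on).

Sweeps apply additive viability selection (1, 1+s, 1+2s) in one breed from a
configurable onset. `complete` mode conditions on fixation at sampling;
`partial` mode conditions on the frequency *among the sampled haplotypes*
falling in a band around the target (the most literal reading of "frequency
at which sampling occurs", and the variant that keeps the sampled carrier
counts in the intended regime); conditioning is by rejection-resampling of
the post-onset segment only, with fresh randomness, a 1,000-attempt cap and
the rejection count reported in the ground truth. A diagnostic `track` mode
plants an allele without conditioning and records its trajectory — that is
how the `s = 0` neutrality of the machinery is tested.

## What a green test does and does not establish

The generators reproduce the *statistical structure* the scans assume:
phased biallelic haplotypes, three populations with the right topology,
reduced breed diversity, LD governed by recombination and demography, and
planted selection with known ground truth. They do not emulate sequencing
error, genotype-likelihood filtering, phasing switch error, variable
mutation/recombination maps, or reference bias; green sweep-recovery tests
therefore speak to the statistics, not to robustness against upstream
artefacts. Two desk-scale artefacts deserve explicit mention, because the
acceptance experiments quantify them. First, with rescaled breed sizes
N <= 500 a non-trivial fraction of ancestral haplotype pairs coalesce within
the last ~0.1 N generations, which fattens the ancestral iHH of even a
perfectly planted partial sweep — at real scale those pairs are rare.
Second, a swept haplotype block carries several statistically equivalent
"clone" cores (founder-private alleles dragged together), so the *nearest*
core competes with its own family for the handful of top-1% slots a small
genome affords. Both effects cap the literal nearest-core-in-top-1%
recovery rate at desk scale; the acceptance suite reports the measured rate
against the stated threshold rather than substituting a weaker criterion.

## Annotation toys

`make_toy_annotations()` lays non-overlapping genes into equal slots (so
overlap is impossible by construction) and drops QTL intervals of 2–10% of
the region with one of the four AnimalQTLdb-style categories (production,
reproduction, exterior, health) and a subcategory label, converting width to
cM at the conventional ~1 cM per Mbp.

# Numerical choices

* Coordinates are 0-based half-open internally; VCF converts at the
  boundary; the 1 kb flank is closed at exactly 1,000 bp.
* `-ln(1 - F_ST)` caps `F_ST = 1` via `1 - 1/(2 n_total)`; negative F_ST
  clamps to 0 (raw value retained).
* EHH integration interpolates linearly to the 0.05 crossing; flanks that
  reach the chromosome edge are integrated as-is but flagged, and such cores
  are excluded from ranking by default.
* Frequency classes with fewer than 10 records merge into the nearest
  occupied class (bin-centre distance, ties to the lower class); a class
  with zero score variance yields NA scores and a warning rather than a
  division by zero.
* Outlier-rank ties at the percentile cutoff break by (chromosome, start).
* All stochastic entry points take one integer seed; internal stages derive
  independent seeds through a documented Lehmer step ([derive_seed()]), and
  every simulator is byte-identical under a fixed seed.
* Config files are JSON (no YAML parser is assumed on the deployment image).

# Limitations

* The demography defaults are illustrative; nothing in the package
  re-estimates demographic parameters.
* iHS uses physical distance in place of a genetic map.
* The enrichment null resamples gene labels; intervals are not rotated, so
  gene-length and clustering biases are not modelled.
* Desk-scale forward simulation caps populations at ~2,000 diploids; larger
  worlds must be rescaled, with the artefacts described above.
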