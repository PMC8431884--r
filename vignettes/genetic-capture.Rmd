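---
title: "Measuring genetic capture in ex situ seed collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genetic capture in ex situ seed collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcapture)
library(dplyr)
```

## The problem

Seed banks conserve wild plant populations ex situ, but how much of a
population's genetic variation actually ends up in a seed collection is
rarely measured. For wild banana relatives (genus *Musa*), collectors
typically obtain one infructescence ("bunch") per local population — all
seeds of a bunch share one mother — and a region is sampled as a handful of
local populations. The question this package answers quantitatively: **what
fraction of the alleles segregating in the source populations is captured
by the seeds, and how many collection units (populations, bunches, seeds)
are needed to reach a target such as the 70% benchmark of the Global
Strategy for Plant Conservation?**

The answer depends strongly on the mating system. Under self-fertilization
a bunch is little more than a resampling of its mother's genotype: seeds
are near-identical, a single seed holds most of the bunch's alleles, and
many bunches from different mothers are needed to represent the region.
Under outcrossing every seed carries a different father's gamete, so a
bunch samples the whole neighbourhood's allele pool and few bunches
suffice — but many seeds per bunch are needed to exhaust a bunch.

## Data model

The universal input is a tibble with one row per sample: `sample_id`,
`population`, `role` (`"population"` plant or `"seed"`), `bunch` (required
for seeds), optional `lat`/`lon`, then two integer columns per
microsatellite locus (`<locus>_1`, `<locus>_2`, e.g. fragment lengths in
bp; 0 or empty = missing). Allele order within a call is meaningless; a
call with either allele unscored is treated as missing entirely, and
half-calls are normalised to missing on input with a warning.

Before analysis, `filter_missing()` applies the conventional quality rule:
loci with more than 25% missing calls are dropped first, then samples with
more than 25% missing calls across the remaining loci. The order matters
and is a deliberate choice — the worst loci usually reflect assay failure,
and removing them first rescues samples. One consequence worth knowing:
because dropping a dirty locus can rescue a sample, the number of retained
*samples* is not monotone in the threshold (the number of retained loci
is). The removal report records every fraction so the filter can be
audited.

## Diversity indices

`diversity_summary()` produces the standard description of each grouping:

* **AR**, rarefied allelic richness: allele counts standardised to a common
  number of gene copies `g` by hypergeometric rarefaction,
  $AR_\ell = \sum_i \left[1 - \binom{N-N_i}{g}\big/\binom{N}{g}\right]$,
  summed over loci (so AR scales with panel size). With `g = "auto"` the
  depth is the per-locus minimum copy count across the groups being
  compared, the usual El Mousadik–Petit convention.
* **PA**, private alleles: alleles observed in one grouping and absent from
  the other.
* **MLG**, multilocus genotypes, the clonality indicator. Two samples
  differing only in missingness are counted as distinct MLGs by default
  (missing is a state); a wildcard mode that lets missing calls match
  anything is available and documented as greedy in sample order.
* **H′, λ, E5** on MLG abundances: Shannon–Wiener (natural log), Simpson
  (`1 - Σp²`), and evenness `E5 = (1/Σp² − 1)/(e^{H′} − 1)` with `E5 = 1`
  when all abundances are equal (the formula is evaluated exactly there to
  avoid rounding past the upper bound).
* **Ho, Hexp**: observed heterozygosity and Nei's gene diversity with the
  small-sample correction `n_c/(n_c − 1)` (a flag disables it), averaged
  unweighted over loci with data.
* **Fis** as a ratio of averages, `1 − mean(Ho_ℓ)/mean(Hexp_ℓ)` over loci
  with `Hexp_ℓ > 0`, matching hierarchical-F practice; per-locus values are
  attached. Negative Fis indicates heterozygote excess.

Seed-vs-population comparisons of per-locality index values use Welch's
unequal-variance t test (`welch_t_test()`), which is how small numbers of
localities (five per region here) are honestly compared.

## Accumulation curves and capture targets

The core procedure works on **incidence**: presence/absence of each
(locus, allele) pair across collection units (`build_incidence()`), where a
unit is a local population, a bunch, or a single seed within one bunch.

Because the sampled units never contain every regional allele, observed
richness is first extrapolated (`extrapolate_total_richness()`):

* `bootstrap` — `S_obs + Σ_i (1 − p_i)^n`, `p_i` the fraction of units
  containing allele `i` (the regional default);
* `chao2` — classic form `S_obs + q1²/(2 q2)`, falling back to the
  bias-corrected `S_obs + q1(q1−1)/2` when no doubletons exist (the
  within-bunch default, robust at ~16 units);
* `jackknife1` — `S_obs + q1 (n−1)/n`.

`accumulation_curve()` then gives the expected cumulative distinct-allele
count as units are added in random order: analytically
(`method = "exact"`, the mean over all orderings,
$E[S_k] = \sum_i 1 - \binom{n-f_i}{k}/\binom{n}{k}$) or by resampling
orderings (`method = "random"`, permutations without replacement, which
also yields the per-step SD band shown by `autoplot()`; sampling with
replacement is available behind `replace = TRUE` for strict bootstrap
semantics). Curves are normalised as percentages of the extrapolated
total. Two normalisations matter:

* population and bunch curves are normalised against the extrapolated
  **total regional richness of the population samples**, so that bunch
  curves answer "how much of the region do my bunches capture";
* seed-within-bunch curves are normalised against that bunch's own
  extrapolated total.

`units_to_threshold()` reports the smallest number of units whose expected
curve reaches each target (70% and 90% by default). When even all observed
units fall short, a two-parameter Michaelis–Menten curve `V·k/(K + k)` is
least-squares fitted to the mean curve (starting values `V = S_hat`,
`K = n/2`) and the extrapolated unit count is reported, always flagged
`"extrapolated"` — saturating extrapolation far beyond the data is an
informed guess, not a measurement.

## Genetic structure

`amova()` partitions molecular variance among/within populations from
squared inter-individual distances (Excoffier-style, unequal group sizes).
The distance is the allele-mismatch count per locus (0/1/2), the common
codominant default; squared Euclidean distance on allele dosages is
available as an alternative. Loci with a missing call in either sample are
skipped pairwise and the distance rescaled by `L/L_compared` (pairs
compared on fewer than half the loci are flagged). Negative among-group
variance components are truncated to zero and flagged. Significance comes
from permuting individuals among populations with group sizes fixed, with
the plus-one correction `p = (#{φ* ≥ φ} + 1)/(n + 1)` — p can never be 0.

`nei_distance()` implements Nei's (1972) standard distance
`D = −ln I`, `I = J_{XY}/√(J_X J_Y)` with sums over loci taken before the
ratio; disjoint allele profiles give `D = ∞`, which is kept and flagged
rather than silently capped, and `hierarchical_clustering()` (complete
linkage, deterministic label-order tie-break, Newick export via
`as_newick()`) refuses infinite entries. `mantel_test()` correlates
geographic and genetic distances under simultaneous row/column
permutations (one-sided, plus-one corrected); geographic distance is plain
Euclidean on raw coordinates (`geo_distance()`), the convention for local
scales, with no great-circle correction.

## The simulator

The published genotypes behind this analysis are not deposited, so the
package carries a generative model that reproduces the *statistical
structure* the method consumes, with every observable signal mapped to one
parameter:

1. regional allele frequencies per locus ~ symmetric
   Dirichlet(`regional_alpha`) — small `alpha` gives the rare-allele-heavy
   spectra typical of microsatellite panels;
2. local population frequencies ~ Dirichlet with mean = regional and
   concentration `(1−θ)/θ` (Balding–Nichols), so `theta` controls
   differentiation; an optional 1-D spatial gradient interpolates local
   means along a transect to induce isolation by distance;
3. adult genotypes drawn with inbreeding coefficient `F`
   (`P(hom_i) = p_i² + F p_i(1−p_i)`);
4. seeds from one uniformly chosen mother per population, through a
   hierarchical cascade evaluated in this order: apomixis `a` (clonal copy
   of the mother), else a Mendelian maternal gamete plus a paternal gamete
   from the mother (selfing `s`), from a regional-frequency migrant (`m`),
   or from a uniformly chosen other adult;
5. per-call missing-data masking.

`TruthRecord`-style output (true frequencies, per-seed parentage) makes
parameter-recovery tests possible: estimated Fis of simulated adults
recovers `F` within ±0.05, and AMOVA φ is monotone in `theta`.

### Presets and their calibration

Three shipped presets (`sim_preset()`) emulate the three study species.
Parameters were fixed once against the published summary statistics —
panel sizes after filtering (19/10/14 loci), missing rates
(3.9/8.1/4.7%), mean locus polymorphism (3.8/6.2/18.6), local
heterozygosities and Fis, the reported φ levels, and the qualitative
capture pattern (a selfer whose five bunches stall below the 70% regional
target while one seed holds ≥90% of its bunch; an outcrosser that reaches
70% within three bunches while one seed holds only ~35% of its bunch):

| preset | loci | k | alpha | theta | F | s | a | m | missing |
|---|---|---|---|---|---|---|---|---|---|
| `acuminata_like` (selfer) | 19 | 24 | 0.035 | 0.29 | 0.8 | 0.99 | 0.1 | 0.005 | 0.039 |
| `balbisiana_like` (mixed) | 10 | 8 | 0.15 | 0.25 | 0 | 0.4 | 0.05 | 0.05 | 0.081 |
| `maclayi_like` (outcrosser) | 14 | 20 | 0.5 | 0.2 | 0 | 0 | 0 | 0.05 | 0.047 |

`k` is the *latent* allele space per locus; with a skewed frequency
spectrum only 3–4 alleles per locus are typically observed in a 75-plant
regional sample of the selfer. The selfing rate of the selfer preset is
0.99 rather than a milder 0.95: at 0.95 a 16-seed bunch contains on
average ~0.7 outcrossed seeds, which would scatter dozens of private
alleles through the seed pool and break the near-clonal bunch structure
the species actually shows (only two private seed alleles in >100 seeds);
0.99 reproduces that observation. Default design sizes mirror the study:
5 populations × 15 adults, one 16-seed bunch per population.

### What the simulator does not emulate

No genotyping error, null alleles, allele-size homoplasy or stutter; no
linkage or physical map; a single non-overlapping generation (no
pedigree depth); migrant pollen drawn from the *regional* pool rather
than from unmodelled external populations; populations on a 1-D transect
with all samples of a population at one coordinate. Passing tests
therefore show the statistics and sampling machinery are correct under a
faithful null model of mixed mating — not that any particular field
dataset is free of marker artefacts.

## Numerical and design choices

* Rarefaction uses `lchoose` differences, exact for the small copy numbers
  involved; terms with `N − N_i < g` contribute 0.
* `g = "auto"` drops loci lacking two gene copies in some compared group
  and records them.
* Frequencies always renormalise over non-missing copies; every frequency
  table satisfies `Σp = 1 ± 1e-9` per locus.
* Permutation p-values are plus-one corrected and one-sided (greater).
* All stochastic stages take explicit seeds; `run_full_analysis()` derives
  per-stage child seeds deterministically from the single `rng_seed`, so
  reruns are byte-identical apart from the manifest timestamp.
* The pipeline degrades gracefully: single-population datasets skip AMOVA,
  Mantel and population accumulation with logged reasons instead of
  failing.

## Validation strategy and problem sizes

The test suite checks each computational primitive against an independent
oracle at a size where brute force is exact: rarefaction against
exhaustive enumeration of all `C(N, g)` subsamples (copies ≤ 10);
exact accumulation curves against the average over all `n!` orderings
(`n ≤ 6`); the richness estimators against hand-evaluated closed forms and
against vegan's `specpool` where the formulas coincide; AMOVA against a
definitional double-loop sums-of-squares computation (≤ 12 individuals)
plus a 200-dataset type-I-error calibration of the permutation test; the
Mantel statistic against vegan's `mantel`. Simulation-level properties
(parameter recovery, the selfing/outcrossing capture contrast) use 10–20
seeded replicates at the study's own design size. The whole suite and the
acceptance script each run in a few minutes on one CPU.

## Limitations

One bunch per population (as in the study design) confounds bunch and
population effects; the package measures capture for that design rather
than optimising collecting strategies with multiple mothers per
population. AR comparisons across species with different marker panels
are not meaningful — the indices condition on the panel. Extrapolated
unit counts beyond the observed range inherit the saturating-curve
assumption and are flagged accordingly.
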