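---
title: "Trio-structured introgression tests: models, statistics and design choices"
author: "Dtrio maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-structured introgression tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Dtrio)
```

## The problem

When two populations of the same species differ in their exposure to a
heterospecific lineage — one grows next to it, the other far away; one shares
its mating system, the other does not — any *recent* introgression from that
lineage should leave an asymmetric footprint in their genomes. Dtrio
implements a hypothesis-testing framework built on this idea: four-taxon
ABBA–BABA tests in which the two conspecific accessions are deliberately
placed so that P2 is the "matched" accession (spatially closer to P3, or
sharing its mating system) and P1 the unmatched one. Under the hypothesis
that the matching factor promotes gene flow, the genome-wide D statistic is
predicted to be positive, and a battery of such trios can be interrogated
with sign tests, regressions on genetic or geographic distance, and
direction-of-introgression statistics.

## Site patterns and the statistics

Sites are polarized against the outgroup: the outgroup allele is the
ancestral state "A" (by fiat, even where the outgroup carries the rarer
allele), the other allele is derived, "B". Over the ordered quartet
(P1, P2, P3, O), three biallelic patterns are informative:

* **BBAA** — P1 and P2 share the derived allele: concordant with the
  species tree.
* **ABBA** — P2 and P3 share it; **BABA** — P1 and P3 share it. Under
  incomplete lineage sorting alone these two are equally frequent.

Patterson's D contrasts them,

$$D = \frac{\mathrm{ABBA} - \mathrm{BABA}}{\mathrm{ABBA} + \mathrm{BABA}},$$

while the admixture-proportion statistic normalises the same excess by all
informative sites,

$$D_p = \frac{|\mathrm{ABBA} - \mathrm{BABA}|}
             {\mathrm{ABBA} + \mathrm{BABA} + \mathrm{BBAA}},$$

and is read as the net fraction of the genome differentially introgressed.
$D_p \le |D|$ always, with equality only when BBAA is absent, and $D_p$ is
invariant to swapping P1 and P2 while D changes sign — properties the test
suite asserts directly.

```{r}
cnt <- PatternCounts(abba = 179196, baba = 167118, bbaa = 676317)
c(D = computeD(cnt), Dp = computeDp(cnt))
```

## Inference: block bootstrap over windows

Linkage makes per-site resampling invalid, so significance comes from a
block bootstrap: the genome is tiled into non-overlapping windows (100 kb by
default; chromosome tails are kept as shorter terminal windows), and each
replicate redraws windows with replacement, pools their counts and
recomputes D. The reported `pRaw` follows the overlap-with-zero rule: for an
empirical D > 0, the fraction of replicates with D ≤ 0. Two details deserve
emphasis:

* `pRaw` is a one-sided overlap probability and is uniform on (0, 0.5)
  under the null, so rejecting at `pRaw < α` has twice the nominal type-I
  error. `BootstrapResult` therefore also carries `pTwo = min(1, 2·pRaw)`,
  which is the calibrated two-sided p-value; the package's calibration test
  operates on `pTwo`. `pRaw` is retained as the historically reported
  quantity, and Bonferroni adjustment (`adjustPvalues()`, `min(1, p·n)`) is
  applied to it for battery significance calls.
* The default replicate size is 1000 windows regardless of how many windows
  the data contain, reproducing a fixed-size (100 Mb) resample design. A
  bootstrap is only variance-calibrated when the resample size equals the
  universe size, so calibration studies should pass
  `nWindowsPerRep = <number of windows>` and `universe = "all"`; with the
  default against a larger universe the test is conservative. When no
  replicate falls on the opposite side of zero, `pRaw` is reported as
  `1/(nReps + 1)` rather than a literal zero.

The resampling universe defaults to windows containing at least one
informative site; empty windows only dilute the resample and are excluded
(configurable via `universe = "all"`).

Per-window D values (`windowScan()`) use the strict SNP filter — a window
enters the outlier scan only with *more than* `minSnps = 20` informative
sites — and a window is an outlier when
$z_w = |d_w - \overline{d}| / \mathrm{sd}(d) > 3$. The z-score is computed
per window against the mean and standard deviation over retained windows;
the threshold of 3 is configurable and recorded in the output.

## The coalescent simulator

`simulateDataset()` draws, for each non-recombining locus, a four-tip
genealogy under the multispecies coalescent with a single instantaneous
introgression pulse, then evolves Jukes–Cantor sequences along it. The
default scenario: P1–P2 split at 1.2N generations, P3 at 2.4N, outgroup at
16N, pulse at 0.2N (or 0.04N), θ = 0.001, 10-kb loci. Printed "xN
generations" values are interpreted literally as numbers of generations and
halved into 2N-scaled coalescent units (pairwise coalescence rate 1). We
examined the alternative readings in which those values are ms-style time
arguments (doubling or quadrupling all times): both make mean $D_p$
*overestimate* the admixture proportion for P3 → P2 introgression, the
opposite of the consistent slight underestimation the statistic is known
for, so the literal reading is used throughout and is not configurable.

Mechanically, a mutation under Jukes–Cantor maps base $b$ to
$(b + \delta) \bmod 4$ with $\delta$ uniform on {1, 2, 3}; offsets along a
root-to-tip path are additive, so per-site tip states follow from summed
offsets without tracking mutation times, which keeps the simulator fully
vectorised across loci while remaining an exact JC process (multiple hits
included). Per-site expected substitutions on a branch are its length in 2N
units times θ/2; $D$, $D_p$ and $D_2$ are count ratios and are insensitive
to this overall scale. Sites left with more than two alleles by multiple
hits are removed, matching the biallelic contract of the empirical readers.

The simulator is validated three ways: closed-form MSC topology
probabilities at γ ∈ {0, 1} (e.g. $P(\mathrm{P1P2}) = 1 - \tfrac23
e^{-\Delta}$ with Δ the internal branch in 2N units), the JC distance
closed form $p = \tfrac34(1 - e^{-4d/3})$, and a cross-check of topology
frequencies against an independent coalescent implementation (msprime) at
three parameter points including pulses in both directions.

What the generator deliberately does not emulate: recombination within
loci, more than one sample per taxon, selection, mutation-model complexity
beyond JC, and missing data. Passing tests on simulated data therefore
demonstrate the statistical machinery under the stated model, not
robustness to those real-data complications.

## Accuracy of D_p

`runDpValidation()` reruns the simulation study of $D_p$ as an estimator of
γ over direction × timing × γ. At full size (100 replicates of 10,000
loci) this is expensive; the shipped tests use a documented reduction:
20 replicates of 2,000 10-kb loci for the γ = 0.05 and γ = 0.10 cells, and
10 replicates of 2,500 4-kb loci for the full 10-γ grid. The latter trades
locus length for locus count at a fixed sequence budget: cell means are
unaffected by locus length (the statistics are ratios of pattern counts,
and loci are exchangeable), while between-replicate variance scales with
the number of independent genealogies, so shorter-but-more loci give
tighter cell means per CPU second.

Under the default scenario, mean $D_p$ is monotone in γ in every condition
and slightly conservative; the underestimation for P3 → P2 introgression
stays under one percentage point at γ ≤ 0.10, while for P2 → P3 it is
larger (2–3+ percentage points at small γ, growing with γ), because
introgression in that direction shortens the internal branches on which
ABBA substitutions accrue. The D statistic itself overestimates γ severely
in the P3 → P2 direction and is non-linear in γ throughout — the motivation
for preferring $D_p$ as a proportion estimate.

## Direction of introgression: D2

For trios with significant D, the direction of exchange is assessed with
$D_2 = d_{AC|AB} - d_{AC|BC}$: the mean P1–P3 divergence over windows whose
genealogy matches the species branching order minus the same mean over
windows matching the introgression topology. Windows are labelled by their
smallest ingroup pairwise p-distance (differing sites over the window span;
exact ties, including empty windows, are unresolved — `tieTolerance`
widens the tie margin if desired). No gene-tree inference program is
involved; with the long internal branches typical of resolvable windows the
minimal-divergence label recovers the simulator's true topology in well
over 95% of resolvable windows, a property the tests check against the
simulator's recorded truth.

$D_2 > 0$ indicates introgression primarily P2 → P3, but lineage-specific
population sizes and admixture proportions away from one half shift its
null value, so significance is assessed against a simulated null of P3 → P2
introgression at the trio's own estimated admixture proportion (its $D_p$),
with split times converted from years via
`years / (generationTime · Ne)` (defaults: Ne = 10⁶, two years per
generation) and per-lineage heterozygosity proxies entering as
tip-branch θ scaling. The p-value is
$(\#\{D_2^{null} \ge D_2^{obs}\} + 1)/(n + 1)$, one-sided toward the
P2 → P3 signature ("at least as extreme" is read directionally; a
two-sided option exists). Null replicates with an undefined $D_2$ (an empty
topology class) are dropped from the denominator.

## The battery

`runBattery()` chains the pipeline over a trio configuration (YAML or data
frame): polarize → count → D, $D_p$ → block bootstrap → Bonferroni over the
family of trios (the family size defaults to the number of trios and is
configurable) → optional D2 direction calls → battery-level inference:

* an exact two-sided sign test (`signTest()`, the doubled smaller binomial
  tail) of observed D signs against each trio's `expected_sign`;
* a sign test of SC → SI versus SI → SC direction calls among
  cross-mating-system exchanges;
* OLS regressions of $D_p$ on mean (P1P3, P2P3) genetic distance and on
  relative geographic proximity (`relativeProximity()`: the difference of
  the two accessions' great-circle distances to the nearest P3 population;
  haversine on a 6371-km sphere);
* maximum accession-disjoint subsets of the significant trios (exact
  enumeration over the P1/P2/P3 triples; the shared outgroup is ignored),
  each re-tested, to gauge sensitivity to accession reuse.

Per-trio failures are isolated and surfaced as `status = "error"` rows so a
single misconfigured trio cannot abort a clade-wide run. Every input trio
appears exactly once in the report.

## Degenerate inputs and numerical conventions

* D is undefined (NA with a warning) when ABBA + BABA = 0; $D_p$ when all
  three counts are zero — never silently 0.
* Heterozygous diploid VCF genotypes: `"strict"` (default) records them as
  missing, so any trio containing the site drops it — deterministic and
  conservative; `"random"` draws one allele under a seed.
* Coordinates are 1-based closed internally (the `GRanges` convention);
  BED exports convert to 0-based half-open.
* Sites where the outgroup carries the minor allele are still polarized —
  the outgroup defines ancestral by fiat.
* All Monte-Carlo functions take explicit seeds, restore the caller's RNG
  state, and derive per-replicate child seeds below 2³¹ from a single
  master seed.

## Known limitations

One haploid sequence per taxon end to end: allele-frequency-based D
estimators, f4-ratio or $f_d$ statistics, jackknife variants and sliding
windows are out of scope. The D2 null simulation inherits the simulator's
single-pulse, no-recombination model, and its per-lineage θ proxies scale
only the pre-merge portion of tip branches. Genome-scale empirical results
(bootstrap SDs over ~10⁸ sites, distance regressions over a full accession
panel) require the corresponding genome data and are not reproduced by the
bundled examples.
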