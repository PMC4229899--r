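---
title: "Haplotype motifs as ancestry markers: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype motifs as ancestry markers: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifscan)
```

## The problem

Short combinations of allele states on the uniparental genomes — a 6- or
12-locus Y-STR haplotype, or a handful of HVS-I substitutions on the
mitochondrial control region — have repeatedly been proposed as
*diagnostic motifs* of Jewish patrilineal or matrilineal ancestry: the
Cohen and Levite Modal Haplotypes (CMH/LMH) and their extended 12-locus
versions (eCMH/eLMH), two Arabic counterparts (GAL, IP), and four
Ashkenazi founder mtDNA lineages (K1, K2, K3, N). `motifscan`
re-implements, as a tested pipeline, the quantitative machinery needed to
evaluate that claim on large genetic-genealogical databases: filtering
raw repository exports, matching motifs, testing motif-by-group
association, converting carrier frequencies into an assignment
probability, and dating the carriers' common ancestors from haplotype
networks under explicit mutation-rate models.

## Data model and filtering

A Y-STR record is a kit id, a self-reported ancestry-group label, a
haplogroup with its evidence flag (direct SNP typing vs prediction from
≥25-locus STR profiles), and a locus → repeat-count map. An mtDNA record
carries an HVS-I substitution set in `"16093C"` notation (rCRS
coordinates) and the covered interval. Two normalizations matter before
any comparison and are easy to get wrong:

* **DYS439**: raw exports from the major testing company sit 4 repeats
  above standard forensic nomenclature; `normalize_dys439()` subtracts 4
  (idempotently) so alleles are comparable with published motifs.
* **DYS389**: DYS389II is a compound allele containing DYS389I;
  mutational-distance work uses `DYS389b = DYS389II − DYS389I`
  (`derive_dys389b()`), and DYS385 is dropped from networks because its
  two alleles cannot be assigned to a specific copy of the duplicated
  region. DYS385 is stored and compared as an unordered pair throughout.

`filter_records()` applies the double admission criterion in a fixed
order (dedup by kit id, first occurrence wins → typing density/coverage →
haplogroup evidence), so every removed record is counted exactly once and
the report satisfies a conservation invariant that is property-tested on
random databases. Y records need ≥ 12 typed loci; mtDNA records need full
coverage of 16,024–16,569 and SNP-confirmed haplogroups. Heteroplasmies
and indels are dropped at parse time with a warning: all published motifs
are plain substitutions, and including unstable length variants would
only add noise to set comparisons.

## Motif matching

Matching is deliberately dumb: every panel locus typed and equal to the
motif allele (Y), or the substitution set equal to the motif set (mtDNA).
Haplogroup context is *not* enforced — the published count tables list
CMH matches inside R1b and eLMH matches across several R1a sub-clades,
which is evidence the original tabulation stratified by haplogroup after
matching, and that polyphyly is itself a finding. Records untyped at a
panel locus return `NA` and are excluded from that motif's denominator
rather than silently counted as mismatches.

mtDNA matching defaults to **exact-set** comparison. K3's substitution
set is a subset of both K1's and K2's, yet the published counts are
disjoint; only exact-set matching reproduces that. Subset containment is
available as an explicit mode for sensitivity analysis.

## Association statistics

`chi_square_yates()` implements the k×2 chi-square with the continuity
correction applied cell-wise and floored at zero — the behaviour of the
legacy contingency-table software generation this analysis came from —
with classic Pearson available by flag. Sparse categories (any expected
count < 5) are merged into an `"others"` row before testing, repeatedly
until stable. For the published tables the tested matrix appends a
non-carrier remainder row (`as_contingency(..., include_noncarriers =
TRUE)`), so the columns sum to the group sizes: the 2×2 collapse of that
construction reproduces the magnitude of the printed statistics (e.g.
~1340 for CMH), which the carriers-only table cannot reach. The exact
category merging behind the printed degrees of freedom is not stated in
the source and is not recoverable; `reproduce_summary_tables()` therefore
prints our statistic and df *beside* the printed ones and flags
differences instead of tuning the collapsing until they agree.

The same report recomputes the percentage rows. The mtDNA table's
printed percentages only reproduce when divided by the **Y-DNA** group
sizes (e.g. 47/5281 ≈ 0.9 rather than 47/2818 ≈ 1.7); the report shows
both denominators and flags the discrepancy. Percentages round half-up to
one decimal, matching the printed rows; p-values below 0.001 are reported
as `< 0.001` rather than `0.000`.

## Bayesian assignment

For a motif with frequency $p_1$ among Jews and $p_0$ among non-Jews, and
a prior proportion $\pi$ of Jewish individuals in the population, the
posterior probability that a motif carrier is Jewish is

$$P(J \mid \text{motif}) = \frac{p_1 \pi}{p_1 \pi + p_0 (1 - \pi)}.$$

`posterior_curve()` evaluates this on a log-spaced grid of priors plus a
point estimate at the worldwide proportion (13 million of 7.2 billion,
both configuration constants). Frequencies are plug-in ratios; a Jeffreys
adjustment (add ½) is offered for zero-count cells, where the plug-in
posterior is degenerate at 0 or 1 — it is flagged, never applied
silently. With the published CMH counts the point estimate is ≈ 0.016:
even the most Jewish-enriched motif is overwhelmingly more likely to be
carried by a non-Jewish individual, which is the core negative result the
statistics support.

## Mutation-rate models

Four calibrations ship as YAML resources, plus a per-site NRY SNP model
for interval arithmetic:

| model | rate | units | source of calibration |
|---|---|---|---|
| genealogical | 0.00166 (→ 0.020/haplotype) | mut/marker/25-y gen | documented family genealogies |
| germline | 2.113×10⁻³ ± 1.369×10⁻³ (→ 0.025) | mut/marker/gen | 126,873 father–son meioses |
| hvs1_pedigree | 1.06×10⁻² | mut/segment/gen | pooled mother–child HVS-I studies (28/2633) |
| hvs1_fossil | 1.42×10⁻³ | mut/segment/gen | phylogenetic calibration, 16,051–16,400 |

The stored per-haplotype rates are the *printed* roundings of per-marker
× 12 (0.01992 → 0.020; 0.025356 → 0.025), flagged as such, because the
downstream interval and dating arithmetic in the source uses the printed
constants (1/0.025 → one mutation per 40 transmissions; 2633/28 → one
HVS-I mutation per 94 generations; 3×10⁻⁸ × 10.15 Mb → one NRY mutation
per ~3 generations). The pedigree HVS-I rate exceeds the fossil-calibrated
one about 7.5-fold — the choice of calibration alone moves TMRCAs by
close to an order of magnitude, which is why every dating function takes
the rate model as an explicit argument.

`aggregate_germline()` pools per-locus father–son counts across studies
(rates = Σ mutations / Σ meioses; invariant to splitting a study with the
same totals). Loci with no observed mutation take an explicit fallback
rate — the trimeric DYS426 is the motivating case, with a
population-model regression value of 0.458×10⁻³ — rather than a silent
zero that would bias the haplotype sum downward.

### Back mutations

Under a symmetric single-step mutation model, a marker that accumulates
$\lambda t$ mutation events performs a ±1 random walk, so the *observed*
net displacement is the absolute value of a Skellam variable (difference
of two Poissons with mean $\lambda t/2$):

$$E|X| = 2\sum_{k\ge 1} k\, e^{-\lambda t} I_k(\lambda t) < \lambda t ,$$

computed exactly via modified Bessel functions. `back_correct()` inverts
this expectation by monotone bisection (tolerance 10⁻¹⁰), so
`back_correct(smm_expected_observed(x)) = x` to 10⁻⁸ across the working
range; the corrected load is always ≥ the observed displacement and the
two agree in the small-load limit. The published calibration-plot slope
(0.00166) is consumed as a given constant; the correction implemented
here is the exact inversion, derivable and testable from first
principles, rather than a re-derivation of that plot.

## Networks and dating

`median_joining()` follows the classic scheme: build the minimum spanning
network at tolerance ε (ε = 0, the common software default, keeps the
union of all minimum spanning trees), let every connected triplet propose
its cell-wise median as an unsampled intermediate, insert the candidate
that most reduces total spanning cost, repeat to a fixed point, and prune
medians that ended up redundant. Ties are broken lexicographically so
construction is deterministic. On every enumerable 3-haplotype instance
the result provably attains the optimal single-Steiner-point cost
(checked against brute force in the test suite), and median insertion
never increases cost relative to the observed-haplotype MST.

Per-locus weights follow the inverse-variance scoring rule
`round(10 × mean variance / locus variance)` — fast loci are
down-weighted so they do not dominate topology. "Total variance over all
loci" is read as the *mean*, so equal-variance loci all get weight 10,
consistent with the default weight of 10 given to each HVS-I site;
constant loci take the cap (default 99). Weights guide topology only:
`rho_tmrca()` always counts **unweighted** mutational steps, because rho
calibrates against mutations per haplotype.

The rho statistic is the multiplicity-weighted mean step count from a
root to every sampled haplotype; its standard error is the classical
estimator $\sigma = \sqrt{\sum_b l_b n_b^2}/n$ over the shortest-path
tree branches. The source never states its rooting rule, so rooting is
explicit: the default is the modal (highest-multiplicity) node with a
documented lexicographic tie-break, and any node can be specified.
Dating divides rho by the model's per-haplotype rate, optionally after
back-correcting the per-marker displacement; with the genealogical rate
a rho of 0.94 dates to 0.94/0.020 × 25 = 1175 years, the arithmetic that
underlies the published clade ages. Because the haplotypes behind the
published R1a/J1 networks are not available, those point estimates are
validated here by *parameter recovery*: on 200 simulated star genealogies
(50 tips, 12 loci, 0.025 mutations/haplotype/generation, true age 40
generations) the mean rho matches the Skellam expectation and the mean
back-corrected age covers 1000 years within Monte-Carlo error.

## The synthetic-data generator

`simulate_database()` emulates a genealogical-repository snapshot: two
ancestry groups (default sizes 5281 and 57,639, the published database
composition), haplogroup labels drawn from per-group mixtures typical of
European/Middle-Eastern testing pools, motif carriers planted at the
published per-group carrier frequencies, background haplotypes built as
founder-plus-noise and *post-checked never to collide with a motif
state*, and an exact truth ledger (extended-motif carriers also match
their nested 6-locus motif; the ledger accounts for that). With mutation
disabled the ledger matches the matcher's counts exactly — the basis of
the end-to-end smoke test. A configurable fraction of deliberately
failing records (short typing, missing coverage, duplicate kits,
unconfirmed haplogroups) exercises the filter.

What the generator does **not** emulate: real haplotype phylogenies
(haplogroup labels are independent of haplotype content apart from
planted mt carriers), multi-step STR mutations, population structure
within groups, or self-report error in the group labels. Passing tests
therefore demonstrate correctness of the machinery under the stated
models, not robustness of the original study's self-reported labels.
Star genealogies (`simulate_star_genealogy()`) implement exactly the
symmetric single-step model the back-correction assumes;
`simulate_hvs1()` adds finite-sites recurrence with hotspot multipliers
(default 5× at 16,311 and 16,519, the fast sites that make haplogroup-K
motif matching fragile).

The packaged HVS-I reference slice used by the FASTA importer and the
sequence simulator is a **synthetic stand-in** with correct coordinates
(`hvs1_reference_synthetic.fasta`); supply the real rCRS 16,024–16,569
slice when importing real data.

## Numerical and design choices

* Rounding: percentages half-up to 1 decimal (printed convention); locus
  weights use R's round-half-even; displayed rates 3 significant figures,
  full precision internally.
* Bisection tolerance 10⁻¹⁰ for back-correction; Skellam sums truncated
  adaptively far past the distribution's tail.
* Degenerate inputs fail loudly: empty contingency tables, zero group
  sizes, saturated displacements, disconnected roots, DYS439 corrections
  below the plausible allele range.
* Problem sizes in the test suite (databases of a few hundred records,
  200 dating replicates, symmetry-reduced enumeration of the 3-haplotype
  space) are chosen to give tight Monte-Carlo checks while keeping the
  default test run fast; the full published database sizes are the
  generator defaults and run in seconds.

## Known limitations

The printed chi-square degrees of freedom cannot be reproduced without
knowing the original category merging; we report our own deterministic
rule beside the printed values. The relatedness-screening procedure
behind the "known common ancestor" fractions is undescribed and not
implemented (its printed fraction for non-Jewish projects, 606/48,006,
also does not equal the printed 1.5%). Haplogroup prediction from STR
profiles is out of scope — records carry the typed/predicted flag as
input. Rho dating assumes the root is the founder haplotype; choosing a
non-ancestral modal node biases ages downward, which is why rooting is
surfaced rather than hidden.
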