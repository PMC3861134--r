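---
title: "Methods: hotspots, matched controls, and GC-biased gene conversion in a PRDM9-free landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspots, matched controls, and GC-biased gene conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(recland)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The scientific setting

In PRDM9-bearing mammals, hotspot positions are dictated by the protein's
zinc-finger motif recognition and move rapidly in evolution. Canids lack
a functional PRDM9, and their crossovers concentrate instead on CpG-rich
sequence — promoter CpG islands above all. Two consequences organize the
package:

1. *Composition is a confounder everywhere.* Hotspots sit on CpG-rich
   DNA, so any naive comparison of hotspot sequence against genome
   background rediscovers CpG content rather than a recombination
   signal. Case/control designs must match composition first
   (`match_coldspots()`), and motif claims are made only relative to
   matched controls.
2. *Recombination writes back into the sequence.* Repair of W/S
   heteroduplexes during recombination favours the strong (C/G) allele
   — GC-biased gene conversion (BGC). Around active hotspots, derived
   AT→GC polymorphisms therefore outnumber GC→AT ones, measurable as
   the skew ratio `n(AT→GC)/n(GC→AT)` per distance bin
   (`skew_profile()`).

## 2. The rate track and the hotspot caller

A genetic map is a piecewise-constant track: boundaries in bp (1-based
in the TSV interchange format) and one cM/Mb rate per interval. All
interval algebra inside the package is 0-based half-open (BED
convention); the conversion happens exactly once, in I/O.

`call_hotspots()` proceeds in two stages:

* **Seeding.** Intervals with rate ≥ `fold` × the chromosome's
  length-weighted median rate are candidate peaks; candidates closer
  than `merge_gap` (500 bp) merge.
* **Local re-test.** Each candidate must reach `fold` × the
  length-weighted *median* rate of its two `flank` (100 kb) flanks,
  from which **all** candidate intervals are first excised — not only
  the candidate under test. At realistic densities (one hotspot per
  ~100 kb) neighbouring peaks would otherwise contaminate the
  background; the median makes the remainder robust. Widths outside
  `[min_width, max_width]` = [1, 20] kb are rejected, and `flank` must
  exceed `max_width` or the caller refuses to run.

Defaults (`fold = 5`, 100 kb flanks, 1–20 kb widths, 500 bp merge) are
package choices: the source analysis describes "hotspot-like peaks"
without publishing its caller's thresholds, so the defaults were chosen
to reproduce that qualitative behaviour and are all exposed as
parameters. Strength classes (`classify_strength()`) default to
peak-rate tertiles for the same reason — the published strong /
intermediate / weak cutpoints are not in the text; all-equal peaks fall
into the lowest class (documented tie-break).

`lorenz_curve()` sorts intervals by rate (descending) and accumulates
physical against genetic fraction; Gini is twice the area between the
curve and the diagonal. It is invariant under uniform rescaling of the
rates, 0 for a uniform map, and → 1 under complete concentration.

## 3. Interval statistics

`overlap_randomization_test()` repositions each query interval uniformly
within its own chromosome, preserving widths and per-chromosome counts —
deliberately conservative; reshuffling across chromosomes would change
the null in ways the data cannot justify. The p-value uses the add-one
convention `(1 + #{rand ≥ obs})/(n_rand + 1)`, which is valid for any
`n_rand`; with discrete overlap counts it is slightly conservative,
which the calibration test accounts for by checking the empirical CDF at
0.05 against binomial 99% bounds. An exhaustive mode enumerates all
integer placements of a single interval and serves as the small-case
oracle.

`compare_peak_sets()` needs care with "shared": per-peak any-overlap
counts are *not* symmetric between the two sets (many-to-one overlaps),
so the symmetric quantity reported as `shared_pairs` is the number of
overlapping pairs, while the per-set unique counts/percentages use the
per-peak definition (that is the arithmetic behind published
uniqueness percentages). Percentages round half away from zero.

## 4. Matched coldspots

For each hotspot, processed in descending peak-rate order so strong
hotspots claim controls first, the candidate pool is the grid of
non-overlapping same-width windows tiling its chromosome. A window is
eligible iff it

* overlaps no called hotspot and no already-assigned coldspot (each
  window is consumed once, so the returned coldspots are mutually
  disjoint — enforced and tested);
* has maximum rate ≤ 2× the chromosome's length-weighted median ("no
  local rate elevation"; the source gives no number, 2× is the package
  default and configurable);
* has N-fraction ≤ `max_missing` (default 0);
* matches the hotspot's GC within 0.5 and CpG within 0.1 *percentage
  points* — absolute, not relative: a relative 0.1% CpG tolerance would
  be near-unsatisfiable, and absolute points are the standard usage in
  composition matching.

Among eligible windows, the one minimizing |Δ SNP density| wins. The
argmin is evaluated on the integer SNP-count scale (all candidates share
the hotspot's width), because dividing by width first introduces
last-ulp float noise that destroys exact ties; ties break to the
leftmost genomic coordinate, making the matcher fully deterministic.
Unmatched hotspots are counted, not errored — the source analysis
itself matched only 4,759 of 6,228 candidate hotspots.

## 5. Motif enrichment

Presence/absence per sequence (not occurrence counts) is the tested
statistic, mirroring how such motif tables are reported. The scan tests
every k-mer for k = 6…9; the Bonferroni denominator is the total number
of distinct motifs actually scanned — the source is silent on its
denominator, and this is the most conservative defensible choice. By
default a sequence "contains" a motif if either strand matches, and
reverse-complement pairs collapse onto the lexicographically smaller
k-mer (their presence vectors are identical under double-strand
counting); most CG-rich motifs of interest are near-palindromic, so the
choice is low-impact, and a single-strand mode exists for oracle tests.
Repeat and non-repeat partitions are produced by hard-masking
(`mask_intervals()`); N-containing windows can never match a motif.

Fisher's exact test is two-sided; inside a scan, p-values are memoized
on the 2×2 table so the ~350k-motif full scan stays tractable. At small
sample sizes Fisher is conservative — the permutation calibration test
asserts the attained type-I rate does not exceed the nominal level,
rather than that it equals it.

## 6. Polarization and the skew statistic

`polarize()` implements outgroup parsimony: if the outgroup allele
equals exactly one ingroup allele, that allele is ancestral; anything
else (no shared allele, missing outgroup, invalid alleles) is rejected
with a reason. No likelihood-based ancestral reconstruction is
attempted — the single-outgroup parsimony rule is the method being
reproduced. Classes: W = {A, T}, S = {C, G}; W→W and S→S changes are
tallied but excluded from the ratio.

`flag_cpg_creating()` marks sites where either allele would create a CpG
(left flank C with a G allele, or right flank G with a C allele); N
flanks make the flag `NA` and such sites are excluded *conservatively*
when `exclude_cpg = TRUE`. CpG hypermutability (deamination) otherwise
couples composition to apparent skew.

`skew_profile()`:

* **Anchor**: distance to the hotspot *center* (the published figures
  plot "around hotspots" without stating an anchor; the center is the
  symmetric choice). Default bins of 1 kb over ±25 kb.
* **Localization**: only hotspots ≤ 5 kb wide enter (the figure caption
  restricts to hotspots "localized to within 5 kb"); parameterized via
  `max_hotspot_width`.
* **Uncertainty**: the bootstrap resamples *hotspots* with their
  attached SNPs (each SNP attaches to its nearest center), preserving
  within-hotspot correlation; a per-SNP bootstrap would understate the
  variance. Percentile 2.5/97.5 bands; an exhaustive enumeration mode
  over all `n^n` resamples is the oracle at tiny n. Bins with zero
  GC→AT counts get a flagged `NA` ratio and no CI.

`stratified_skew()` runs the same machinery per strength class, each
class's SNPs re-attached to that class's nearest hotspot.

## 7. Feature profiles and composition regressions

`profile_around()` averages the map over signed distance bins across
anchors; width-1 intervals are point anchors (a TSS is a position, and
treating it as a half-open interval's midpoint would shift every
profile by 0.5 bp — a real bug the tests caught at step-change
boundaries), wider intervals contribute midpoints, and minus-strand
anchors flip so negative distance is always upstream. Bins partially
outside the mapped extent use the covered part; fully-outside anchors
are skipped with a warning. Repeat-family profiling uses
`thin_intervals()` (greedy left-to-right, 10 kb midpoint spacing, 5 kb
windows by default, matching the published procedure);
`gene_body_profile()` rescales each gene to 50 proportional bins.

`windowed_correlation()` tiles chromosomes per scale and reports Pearson
r of rate against GC and against CpG. The zero-variance guard is
tolerance-based (sd ≤ 1e-10·(|mean|+1)) because rates reconstructed
from a cumulative integral carry ~1e-16 float noise — exact-zero tests
never fire. `composition_regression()` fits OLS on standardized
predictors and reports signs with 95% CIs, refusing |r| > 0.999
collinearity; it exists to check the sign flip (CpG positive, GC
negative once both enter jointly). `flanking_composition_compare()`
uses a Wilcoxon rank-sum test — the source names no test, and
composition fractions are bounded and non-normal, so a rank test is the
defensible default.

## 8. The synthetic world

The generator is first-class, tested code, and its defaults are the
stated toy-world conditions used throughout the acceptance criteria
(20 Mb chromosome scale, 10× peak folds, 4.3 kb hotspot widths matching
the published median, 5 kb bias kernels, 500-hotspot worlds).

* **Genome.** Background i.i.d. at `base_comp` (default uniform — see
  §9 on why). Islands are first-order Markov segments with GC
  `island_gc` (0.6) and a C→G transition solved by fixed-point
  iteration so the realized CpG fraction hits `island_cpg_mult` ×
  `P(C)P(G)` despite the stationary-distribution shift that a naive
  boost induces (the naive construction undershoots by ~10–15%).
  Infeasible targets (CpG beyond what the island GC allows, or island
  mass beyond ~80% of the genome) error at config time. A configurable
  fraction of TSS sit on island centers; repeats are labelled AT-rich /
  GC-rich i.i.d. segments placed off-island.
* **Map.** Constant background plus rectangular (default) or Gaussian
  rate bumps; `island_coloc_frac` of bumps center on distinct islands.
  Overlapping bumps merge in the truth set, with the strongest
  constituent supplying the merged record's fold *and center* — using
  the merged midpoint would break island colocalization for merged
  clusters, since the midpoint of two island-centered bumps lies
  between islands.
* **Polymorphisms.** Two lineages diverge from the genome as common
  ancestor; mutations are Poisson in position with a uniform choice
  among the three alternative bases. Every mutation is *retained* as a
  segregating variant with baseline probability 1/2; within the bias
  kernel, W→S mutations are retained with probability `b` and S→W with
  `1 − b`. This retention-thinning model reproduces neutrality exactly
  at b = 0.5 and gives a central skew elevation of `b/(1 − b)` under a
  rectangular kernel — sufficient for every statistic the pipeline
  computes, none of which uses linkage disequilibrium. No coalescent is
  simulated, deliberately: LD-based rate estimation is out of scope,
  and a per-locus tree would buy realism the statistics never see. The
  outgroup lineage evolves without bias (the published comparison found
  no skew in the outgroup lineage at the ingroup's hotspots, which is
  the discriminating prediction). The outgroup allele at ingroup SNPs
  is the ancestral base flipped with probability `divergence` (0.01),
  generating realistic polarization failures. Mutation densities
  (0.004/0.0015 per bp pre-retention) are toy-scale choices set once so
  per-bin counts support ratio estimation on megabase fixtures; they
  are ~2–3× the real per-bp SNP densities, compensating for genomes
  ~100× smaller.
* **Peaks.** Two stages share a configurable fraction of identical
  intervals; all distinct peaks are placed disjointly so the realized
  unique fractions equal `1 − sharing` exactly.
* **Determinism.** Each generator seeds `set.seed(cfg$seed + offset)`
  (genome +0, map +1, polymorphisms +2, peaks +3), so stages are
  independently reproducible and byte-identical under a fixed seed.

## 9. Calibration, composition, and what a green test establishes

The skew ratio's neutral expectation is `n_W/n_S`, the ratio of W to S
*sites* in the surveyed sequence — 1 only when GC content is 50%. Two
consequences:

* The neutral-calibration worlds (b = 0.5, CI covers 1) use uniform
  base composition and **no CpG islands**: with island-colocated
  hotspots the central bins sit on GC-rich sequence, the neutral ratio
  centers near 0.67, and a correct CI rightly excludes 1 — a
  composition effect, not BGC. The real analysis handles the same
  confounder with matched controls and CpG exclusions; the simulator
  handles it by removing composition structure from the calibration
  world. A green calibration therefore establishes that the estimator
  and its bootstrap are unbiased and well-covered *given neutral
  composition*, not that composition effects are absent in real data.
* The genome-wide mean-zero property of the log ratio is asserted
  against `log(n_W/n_S)` of the actual simulated genome, not against 0.

Scaling decisions, stated once: the planted-motif recovery test uses
3,000 matched pairs (not the published 4,759) and k = 7 only; the
neutral-calibration replicates run on 2 Mb / 50-hotspot worlds with
polymorphisms redrawn over a fixed genome and map (the polymorphism
noise dominates); the permutation type-I check uses k = 6 on 120
sequences with a shared Fisher memo. Each choice trades nothing but
statistical headroom, which was computed a priori, for runtime.

Known limitations: no LD structure, so nothing here validates
LD-based map estimation; single-outgroup parsimony misassigns ancestry
at back-mutated or parallel sites (the `divergence` parameter produces
rejections, not misassignments beyond outgroup-allele flips onto the
derived state, which occur at rate ~`divergence`/3 and slightly dilute
true skew); hotspot "width" in the caller is the width of the
above-threshold run, which for Gaussian bumps depends on the threshold;
and the i.i.d. background lacks the CpG depletion of real mammalian
genomes, so absolute CpG fractions are higher than in real data while
island/background *ratios* are realistic.
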