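---
title: "Methods: co-occurrence network ensembles from dilution-series cultivation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence network ensembles from dilution-series cultivation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellnets)
```

## The problem and the procedure

Microbial co-occurrence networks predict pairwise taxon associations from
abundance data, but almost none of those predictions are ever tested with
cultures. `wellnets` implements an end-to-end desk version of a
cultivation-based validation workflow. Environmental homogenates (plant,
root, sediment) are serially diluted (10^-1^..10^-7^) and dispensed into
96-well plates across two media, so that wells at the deeper dilutions are
founded by few cells and harbor simplified communities. Amplicon feature
tables per well then support one co-occurrence network *per plate*, and the
ensemble of plate networks is mined for taxon pairs that recur.

The analysis chain is:

1. **Growth filter.** A plate enters the analysis only if strictly more
   than 30% of its wells grew ("effective plate"). In silico, a well grew
   iff its total read count reaches `min_reads` (default 100) — the only
   proxy available from a feature table for what is scored visually at the
   bench. The denominator is the designed well count.
2. **Prevalence filter.** Within a plate, Zotus present in fewer than 30%
   of the growing wells are discarded; correlations are computed on the
   growing wells only. Whether the 30% denominator should be all wells or
   growing wells is not determined by the source protocol; we use growing
   wells (the community actually observed) and expose
   `denominator = "all"` as an option.
3. **Edges.** All pairwise Spearman rank correlations (mid-ranks for ties)
   between retained Zotus, computed by default on per-well relative
   abundances (total-sum scaling; raw-count mode available). The p-value
   uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
   df. P-values are Benjamini–Hochberg adjusted over all pairs tested
   *within that plate* (each plate is an independent inference), and an
   edge is kept iff `|rho| > 0.6` **and** `q < 0.01`, both strict.
4. **Degree filter.** To keep validation experiments tractable, only nodes
   with degree centrality < 5 are retained, in a single pass (degrees are
   not recomputed iteratively), edges surviving iff both endpoints survive.
5. **Pair prevalence.** For each pair and each (sample type, medium) group
   — dilution level and replicate are pooled on purpose — the occurrence
   frequency is `FO = Np / Ng`, with `Np` the number of group networks
   containing the edge and `Ng` the group's network count. Robust pairs
   satisfy `FO > 0.30` (strict); the top-3 report per group is ranked by
   FO with ties broken by mean `|rho|`, then lexicographic pair id, and is
   deliberately *not* restricted to the robust list (the two outputs serve
   different purposes and are kept separate).
6. **Ensemble comparison.** Networks are compared by Jaccard similarity of
   their unordered edge sets; two empty edge sets compare as 0 (0/0 is
   undefined; the choice is logged).
7. **Isolate matching.** Cultured-isolate 16S sequences have their V4
   region excised between the 515F/806R primer sites (IUPAC-aware search,
   one mismatch allowed per site, leftmost forward hit on duplicates). An
   isolate matches a Zotu when their V4 identity reaches 1.0 (identical V4
   region); otherwise it may fall back to the nearest Zotu leaf on a
   neighbor-joining tree of all V4 sequences, accepted only below a path
   distance cap of 0.03 (roughly 3% divergence — a guard against matching
   across genera, and a deliberate artifact decision flagged in the
   output). Identity ties break by tree distance, then remain unmatched.
8. **Co-culture classification.** For every isolate combination
   representing a pair, mono- and co-culture growth curves are compared by
   the difference in trapezoidal area under log10 density,
   `delta = auc_log(co) - auc_log(mono)`, per partner and per time window.
   Thresholding at `epsilon` (log10-units per hour, default 0.2) maps the
   two signs onto the standard taxonomy: (+,+) mutualism, (+,0)
   commensalism, (+,-) exploitation, (-,0) amensalism, (-,-) competition,
   (0,0) neutralism. A `collapse` mode folds these onto the three-way
   plate readout (mutual / competitive / neutral). Since no quantitative
   criterion for these calls exists at the bench, `epsilon` is reported
   with every call.

## The synthetic plate-array generator

No raw sequencing data are required: the `simulate_*` family generates the
whole study design with known ground truth.

* **Source community**: normalized log-normal abundances over `n_species`
  taxa; `cells_per_ul` sets the homogenate density. No reference value for
  homogenate cell density exists for these samples, so it is a free
  parameter; the default 1e6 cells/µl is a realistic density for
  environmental homogenates and puts the informative occupancy range at
  dilution levels 3–5 for a 40-taxon community.
* **Seeding**: each well receives Poisson numbers of cells per taxon at
  rate `cells_per_ul x inoculum_volume_ul x abundance x
  10^-dilution_level`; the expected load decays exactly 10x per level.
* **Growth + interactions**: seeded taxa reach a per-well equilibrium in
  which each taxon's share is its seeded share times `exp(sign x effect)`
  for every co-seeded interaction partner, renormalized. This endpoint
  model (rather than integrating community dynamics) is sufficient because
  the inference consumes endpoint abundances only.
* **Reads**: multinomial at `read_depth` for occupied wells; empty wells
  keep all-zero rows (growth scoring happens downstream).
* **Co-colonization mode**: with `co_colonization = TRUE`, positively
  interacting partners additionally share a per-well log-normal seeding
  factor (`co_seed_sd`). This matters: with growth coupling alone, the
  across-well rank correlation of a planted pair is structurally capped
  near 0.65 — the alignment contributed by presence/absence mismatch wells
  is diluted by independent Poisson seeding noise within co-seeded wells,
  and large effects add compositional anti-correlation. Positive
  co-occurrence at the `|rho| > 0.6` level is, in this generator as in
  nature, chiefly a co-*colonization* signal. The pipeline's default study
  condition (`run_config()`) therefore plants positive pairs as
  co-colonizers (`co_seed_sd = 1`, `effect_size = 1`), which yields
  within-plate rho of about 0.75–0.90 at the informative dilutions;
  `simulate_plate()` itself defaults to `co_colonization = FALSE`.
* **Planted-pair placement**: pairs are drawn among taxa whose expected
  per-well occupancy at the central dilution lies in [0.80, 0.95] —
  taxa that are nearly ubiquitous or mostly absent cannot carry an
  identifiable co-occurrence signal at any effect size.
* **Growth curves**: logistic growth per partner (defaults: r 0.5–0.6/h,
  K ~1e9 cells/ml, 0–48 h sampled every 2 h), with the co-culture carrying
  capacity scaled by `k_up = 30` (benefit) or `k_down = 1/30` (harm) so a
  real effect moves log10 density by ~1.5 at saturation — comfortably
  beyond the `epsilon = 0.2` call threshold — plus optional post-peak
  exponential decline for biphasic trajectories and multiplicative
  log-normal noise (default sd 0.1).
* **Sequences**: random V4-length Zotu sequences; synthetic isolate 16S
  records embed a (possibly mutated) copy of a Zotu's V4 between concrete
  instantiations of the degenerate primers, with random flanks.

What the generator does **not** emulate: sequencing error, chimeras,
primer-amplification bias, taxon-specific growth bias across media, spatial
structure on agar, and mechanistic (e.g. Lotka–Volterra or chemostat)
community dynamics. Passing tests therefore demonstrate that the inference
machinery recovers planted signal under idealized sampling noise — not that
it would be equally reliable against real sequencing artifacts.

## Numerical choices

* All threshold comparisons follow the stated inequalities exactly: growth
  fraction and FO are strict `>`, prevalence is `>=`, edge thresholds are
  strict, degree is strict `<`. 29/96 growing wells retains a plate;
  28/96 does not.
* FDR is Benjamini–Hochberg (the conventional default of the R ecosystem
  the thresholds come from) via `p.adjust`, applied per plate.
* `|rho| = 1` maps to `p = 0`. Pairs with constant ranks are skipped and
  logged, never assigned `rho = 0`. Zotus absent from every retained well
  are dropped before pair enumeration.
* The t-approximation p-value is accurate to well within 0.05 of the exact
  permutation p for n >= 6 wells; at n = 4–5 its error can reach ~0.15.
  Networks are only ever built on >= 4 wells and in practice on dozens, so
  this small-n regime does not arise in the pipeline; the test suite
  characterizes it explicitly.
* Neighbor joining minimizes the Q criterion, with the first minimum in
  column-major order on ties (deterministic); negative branch lengths are
  clamped to zero with the deficit shifted to the sister branch so the
  joined pair's distance is preserved, and the event is logged. On
  additive matrices the reconstruction is exact to < 1e-9.
* Global-alignment identity uses match +1 / mismatch -1 / linear gap -2;
  identity = matched columns / total alignment columns.
* Log-scale AUC floors densities at a detection limit of 1 cell/ml before
  the log transform.
* Well ordering is fixed row-major A1..H12 for 96-well plates and stable
  zero-padded otherwise; all stages are deterministic given a seed, and
  every stage can be re-run from its persisted TSV/JSON intermediates.

## Problem sizes

The shipped tests and the acceptance script run the ensemble condition at
2 groups x 9 plates (3 dilution levels x 3 replicates) x 96 wells x 40
taxa with 3 planted positive pairs per sample type; the oracle suites use
200 random vectors (n = 6–8) against exhaustive permutation null
distributions, 1,000 random p-vectors against the step-up FDR definition,
20 random additive trees of up to 12 taxa, and 120 simulator-labelled
growth-curve sets (6 labels x 20 replicates, noise sd 0.1). These sizes
were chosen as the smallest at which every property is sharply testable.

## Limitations

* FO is estimated from few networks per group (9 here, a handful in any
  real array), so FO resolution is coarse (multiples of 1/Ng) and the
  strict `FO > 0.30` boundary can hinge on a single network.
* The identity-1.0 matching rule mirrors the "identical V4" criterion, but
  one Zotu can absorb several strains; the tree fallback cap (0.03) is an
  artifact decision, not a biological constant.
* The interaction taxonomy is an endpoint description over a chosen
  window; biphasic pairs get different labels in different windows by
  design, and `epsilon` has no bench-side calibration.
* Compositional closure biases relative-abundance correlations negative by
  roughly -1/(k-1) for k retained taxa; at the 40-taxon scale this is
  ~-0.03 and immaterial against the 0.6 edge threshold, but raw-count mode
  exists for sensitivity checks.
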