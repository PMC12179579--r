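---
title: "Dissecting gene-tree discordance and genome-trait evolution with endophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting gene-tree discordance and genome-trait evolution with endophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endophylo)
```

## What this package models

`endophylo` bundles the bespoke computations of a phylogenomic study of
epiphytic orchids (Pleurothallidinae-type data): hundreds of nuclear
gene trees against a coalescent species tree, flow-cytometric genome
traits (genome size, partial-endoreplication fraction, GC content),
pseudo-occurrence range maps, and phylogenetic comparative statistics.
Every analysis can be exercised end to end on synthetic data generated
in-package, which is how the test suite works.

## Concordance accounting

For each internal node of a rooted species tree, every gene tree is
classified against the bipartition (split) the node defines:

* **uninformative** when the split restricted to the gene tree's taxa is
  trivial (one side lost, or fewer than three shared taxa), or when the
  gene tree neither contains nor contradicts the restricted split
  (e.g. the relevant branches were collapsed into a polytomy);
* **concordant** when one of the gene tree's own splits equals the
  restricted split;
* **conflicting** when some gene-tree split is incompatible with it —
  two splits conflict exactly when all four pairwise side intersections
  are non-empty.

The three counts partition the gene-tree set at every node, and the most
frequent conflicting split is tracked as the node's top alternative
(ties broken lexicographically so output is deterministic). Collapsing
weakly supported gene-tree branches (`collapse_low_support()`, strict
`< threshold`) moves gene trees from the conflict column to the
uninformative column, never into concordance: a polytomy is compatible
with everything but witnesses nothing.

The taxon jackknife (`taxon_jackknife()`) removes chosen taxa from the
species tree and every gene tree, recounts, and reports per-node deltas.
Nodes are matched across the removal by restricting the original node's
split to the surviving taxa; a node whose split becomes trivial has no
counterpart and carries `NA` after-counts. Removal sets are taken
jointly, so synergistic multi-taxon removals are a single set.

## The alternative-topology scenario test

The scenario test asks which clade-level topologies the gene trees
actually support. With k tips after reduction (one representative per
clade plus the fixed taxa), the space of rooted binary topologies is
\((2k-3)!!\) — about \(3.2\times10^{11}\) at k = 13 — far too many to
score, so candidates are restricted to the fully resolved topologies
*observed* among the pruned, relabeled gene trees (or, alternatively,
their majority-rule consensus; `mode = "consensus"`). A fully resolved
rooted candidate on k tips has k − 1 internal nodes (12 at k = 13).

Each candidate is scored by running the concordance machinery with the
candidate in the species-tree position: the **support score** is the
mean concordant count over the candidate's internal nodes, excluding
the root (which defines no bipartition; its two child nodes are scored
as ordinary nodes, so 11 node values enter the k = 13 average).
Scores are averaged over representative draws — every candidate is
scored against every draw's pruned gene set, so candidates observed in
only some draws remain comparable — and ranked, with ties broken on
the canonical newick string.

Two design points deserve emphasis:

* **Rooting.** Split support is invariant to rooting, so two candidates
  that differ only in root placement cannot be distinguished by the
  score, and coalescent noise on the root branch can even favour the
  wrong rooted variant. Passing `outgroup=` to `rank_scenarios()`
  re-roots every pruned gene tree on the study outgroup before
  candidate enumeration, which removes rooted duplicates from the
  candidate set. This mirrors the usual practice of outgroup-rooting
  gene trees before concordance analysis, and we consider it essential
  whenever candidates are to be read as rooted scenarios.
* **"Observed" candidates.** Reading candidate topologies directly off
  the pruned gene trees biases the candidate set toward topologies with
  non-negligible gene-tree frequency; this is intentional — the point
  of the test is to rank scenarios the data actually display.

Representative draws are uniform within each clade, processed in
alphabetical clade order under a single seeded generator, so a draw
sequence is a pure function of the seed.

## Flow-cytometry trait derivation

Genome size is the classic internal-standard ratio: the sample's 2C
peak position under propidium iodide (the stoichiometric, base-neutral
stain) divided by the standard's, times the standard's 2C size in Mbp.

Under **partial endoreplication** only a fraction \(P\) of the genome
participates in each endocycle, so the expected peak series is
\(F_r = F_0\,(1 + (2^r - 1)P)\), \(r = 0, 1, 2, \dots\) — successive
peaks less than two-fold apart. `replicated_fraction()` fits \(P\) by
least squares on the log scale, which is maximum likelihood under the
multiplicative (log-normal) noise that flow cytometers produce, using a
grid scan over \((0, 1]\) refined by bounded optimization plus the
closed-form solutions of each consecutive peak pair (these make the
estimator exact on noise-free series). Accessions with
\(P \ge 0.95\) are classified as conventional endoreplication (CE),
below as partial (PE); the threshold is inclusive on the CE side
because it exists to absorb measurement error around complete
replication. At 2 % peak-position noise the estimator is unbiased to
within about 0.005, but no estimator can push single-run CE/PE
misclassification below roughly 3 % with four or five observable
peaks — the information simply is not in the series — which is why the
95 % threshold, not a sharper one, is the field's convention.

GC content uses the **dye factor** DF = DAPI/PI of the same 2C peak.
DAPI binds AT runs of length \(n\) (default 4), so fluorescence scales
as the AT fraction to the \(n\)-th power and
\(AT_s = AT_{std}\,(DF_s/DF_{std})^{1/n}\), GC = 100 − AT. The binding
length is a configurable calibration knob; alternative calibrations
drop in by changing `binding_length`. A mass-balance inversion
(`infer_fraction_gc()`) recovers the GC content of the replicated
fraction from the 2C and first-endocycle GC values.

## Pseudo-occurrence ranges and trait surfaces

Without reliable point occurrences, a taxon's range is reconstructed as
the intersection of (i) membership in its recorded botanical regions
and (ii) an inclusive elevation band on a DEM (reported minima and
maxima are attained values, hence inclusive). Fine in-range cells are
aggregated onto a coarse grid (default 0.5°) with areas weighted by
\(\cos(\text{latitude})\) — adequate at 30-arc-second scale and free of
geodesy dependencies — and a taxon is *present* in a coarse cell only
when its occupied area strictly exceeds 5 % of the cell's area. Trait
surfaces are occupied-area-weighted means over the present taxa;
species-density layers count presences by endoreplication mode, with
the PE:CE ratio undefined (nodata) where no CE species occurs. Cells
lacking region or elevation data are out of range by construction.
Rasters travel as plain headered ASCII grids; percentile statistics use
R's default (type 7) quantile convention, and the 47.5–52.5 % and
45–55 % percentile pairs around the median feed the PGLS uncertainty
analysis.

## Comparative statistics

The Brownian covariance of tip values is the matrix of shared
root-to-tip path lengths; Pagel's λ multiplies its off-diagonals.
`pagel_lambda_ml()` profiles the likelihood over λ ∈ [0, 1] (coarse
grid, then golden-section refinement, tolerance 1e−6) and reports a
likelihood-ratio 95 % CI; when λ̂ sits at 1 and the χ²(1) cutoff cannot
exclude the boundary the upper limit is reported as `NA`, matching the
conventional "CI = 0.96–NA" notation. `pgls()` fits GLS regressions
under the λ-transformed covariance (λ = 0 is exactly OLS) and reports
explained variance as the GLS R² computed in the whitened space, in
percent. Predictor uncertainty (`pgls_with_uncertainty()`) redraws each
taxon's predictor uniformly between per-taxon bounds — order-statistic
bounds, hence uniform rather than Gaussian sampling — refits `n_intra`
times, and summarizes replicates as "median p (min–max)".

Phylogenetic ANOVA simulates the trait under Brownian motion (rate and
mean estimated from the data) and compares the classical F statistic
with its simulated null; the p-value uses add-one smoothing, so its
floor is \(1/(n_{sim}+1)\). Ancestral states are GLS estimates whose
variances include the uncertainty of the estimated phylogenetic mean;
the root estimate equals that mean. Branch-wise change detection flags
an edge when the reconstructed change exceeds the two-sided
\((1-\alpha)\) quantile of a normal null with variance
\(\hat\sigma^2 t\) plus both endpoint estimation variances — including
the endpoint variances makes the test mildly conservative, which keeps
its false-positive rate below α under pure Brownian motion. A constant
trait has zero Brownian rate and flags nothing.

## The synthetic-data generator

* **Gene trees** come from a bespoke multispecies-coalescent sampler:
  within each species-tree branch (lengths in coalescent units of 2N
  generations), j lineages coalesce at rate j(j−1)/2; remaining
  lineages coalesce above the root. The sampler reproduces the analytic
  rooted-triplet law \(1 - \tfrac{2}{3}e^{-t}\), which the tests check
  at t ∈ {0, 0.5, 1, 2} with 20 000 genes each.
* **Hybrid signal** is injected topologically: in a Bernoulli-γ subset
  of gene trees the target clade is pruned and regrafted at an
  alternative attachment, producing the two-dominant-topology signature
  that motivates hybridization hypotheses. Trees where the clade is not
  monophyletic are skipped with a warning.
* **Traits** are multivariate-normal draws under the λ-transformed
  Brownian covariance.
* **Flow-cytometry runs** place PI peaks on the partial-endoreplication
  series, scale DAPI by the dye factor implied by the requested GC, and
  apply independent multiplicative log-normal noise per peak position.
  Defaults describe a realistic accession: four observable peaks
  (2C–16C′), a large plant internal standard (9090 Mbp 2C, 38.5 % GC),
  and noise-free unless asked otherwise. The per-peak-independent noise
  is deliberately pessimistic — real instruments share gain drift
  across peaks of one run — so parameter-recovery results here are
  conservative.
* **Landscapes** are seeded smooth random fields (sums of random
  low-frequency plane waves) rescaled to 0–4000 m, nearest-centre
  mosaics for regions and ecoregions, and environmental layers built
  with a chosen correlation to the DEM.

`make_fixture_suite()` writes a complete miniature study (species tree
with five two-member clades plus an outgroup, 200 coalescent gene trees
carrying one γ = 0.3 hybrid signal, trait and peak tables, landscape,
ranges) whose truth is known, so pipeline-level tests can assert
recovery rather than just execution.

## What the synthetic tests do and do not show

The generator reproduces the statistical structure the analyses assume:
coalescent discordance, Brownian traits with tunable signal,
multiplicative flow-cytometry noise, smooth spatial fields. It does not
emulate gene-tree estimation error, alignment artefacts, non-Brownian
trait evolution, instrument drift, or the spatial autocorrelation of
real checklist data. Passing tests therefore demonstrate correctness of
the computations and calibration under the stated models, not
robustness to every feature of real data.

## Problem sizes and numerical choices

The test suite runs the concordance oracle on 500 random instances of
up to 8 taxa, scenario recovery on 100 seeds × 200 genes, triplet-law
checks with 20 000 genes per branch depth, 1000-replicate PGLS
calibration, 200-seed λ recovery on a 200-tip tree, 500-dataset
phylogenetic-ANOVA calibration, and a 1000 × 1000-cell landscape —
sizes at which the statistical assertions have narrow Monte-Carlo
error yet the whole suite stays comfortably inside a coffee break.
Random-tree and random-instance counts in unit tests are smaller, since
they guard logic rather than calibration. All stochastic procedures
take explicit seeds and are bit-reproducible; optimizer tolerances are
1e−6 (λ) and 1e−10 (P), and boundary optima are snapped exactly to the
boundary when the likelihood there is at least as good.

## Known limitations

* Split-based concordance cannot express rooted-clade conflict; with a
  declared outgroup this rarely matters, but analyses of root-adjacent
  nodes should be read with the rooting caveat above.
* `count_rooted_topologies()` is exact up to k = 16 (the double
  factorial stays below 2^53); beyond that it returns a correctly
  rounded double.
* The GC model assumes a single effective binding length for the
  AT-preferential stain; organisms with unusual AT-run length
  distributions would need a recalibrated `binding_length`.
* Exhaustive scoring of all \((2k-3)!!\) topologies is intentionally
  unsupported for k > 9; candidate enumeration from the gene trees is
  the supported route.
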