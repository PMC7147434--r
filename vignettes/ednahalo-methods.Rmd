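---
title: "ednahalo: models and methods for occupancy-filtered eDNA transect analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ednahalo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednahalo)
```

## The problem

Environmental DNA (eDNA) metabarcoding of seawater yields a table of amplicon
sequence variant (ASV) read counts per PCR replicate. Before any ecological
question can be asked of such a table — here, whether dinoflagellate abundance
is depressed inside and immediately outside eelgrass (*Zostera marina*) beds —
four sources of error have to be dealt with:

1. **cross-sample contamination** (tag jumping), estimated from positive
   sequencing controls of tissue that cannot occur in the samples (kangaroo,
   ostrich);
2. **false detections**, ASVs that appear in a PCR replicate without the taxon
   being present in the bottle of water;
3. **failed replicates**, PCRs whose community profile bears little relation
   to the other replicates of the same bottle;
4. **uneven read depth and amplification efficiency**, which make raw counts
   incomparable across replicates and across taxa.

`ednahalo` implements the corresponding pipeline — positive-control
decontamination, Bayesian site-occupancy filtering, replicate quality
control, and eDNA abundance indexing — followed by the community-level
analyses (Bray–Curtis distances, nMDS, PERMANOVA), phylum-level habitat
association tests between the eelgrass (`Eg`) and bare-substrate (`Ba`)
transect extremes, and a spatial "halo" detector for depletion of a focal
phylum along transects. A synthetic-study generator with full ground truth
makes every stage testable without sequencing data.

The central container is `EdnaExperiment`, a `SummarizedExperiment` whose
`counts` assay is ASVs × PCR replicates, with the sampling design (site,
month, ordered transect position `Eg < 1 < 3 < 6 < 10 < 15 < Ba`, bottle,
replicate, run, sample class) in `colData` and the taxonomy in `rowData`.
Sample names encode the design as underscore-delimited fields
(`WB_Al_1_July_2_run1`); `parseSampleName()` documents the dialect and
`defaultDialect()` makes the vocabularies extensible.

## Decontamination

For each ASV, `maxControlProportion()` computes its proportion within every
positive-control replicate and keeps the maximum. `subtractContamination()`
then reduces each ASV's within-replicate proportion in every environmental
sample by that value, floors at zero, and maps back to counts at the
replicate's original read total. Two deliberate choices:

* **No renormalization after flooring.** The eDNA index renormalizes later;
  normalizing twice would distort the subtraction.
* **Depth preserved.** Keeping the original replicate total (at the price of
  fractional counts) keeps the subsequent low-read filter
  (`dropLowReadReplicates()`, default `min_reads = 1000`) meaningful. The
  threshold is a config parameter because "extremely low" depends on the run;
  1000 reads is roughly 5% of the simulated mean depth.

ASVs assigned to the control tissues themselves are removed outright.
Flooring at zero is the only coherent treatment of proportions that would
otherwise go negative.

## The occupancy model

Detections are summarized per (ASV, bottle) as `y` detections out of `K`
replicate trials (`buildDetectionHistories()`; one post-decontamination read
counts as a detection by default). The model has three parameters:
commonness `psi` (probability the taxon truly occupies a bottle), the
per-replicate true-positive detection rate `p11`, and the false-positive rate
`p10`. The likelihood marginalizes the latent occupancy state `z` of each
bottle:

$$
L(\psi, p_{11}, p_{10}) \;=\; \prod_b \Big[ \psi\,\mathrm{Bin}(y_b \mid K_b, p_{11})
 + (1-\psi)\,\mathrm{Bin}(y_b \mid K_b, p_{10}) \Big].
$$

Priors are independent uniform(0,1) truncated to `p10 < p11`, the standard
identifiability constraint that breaks label switching in false-positive
occupancy models. `fitOccupancyModel()` samples the posterior with
componentwise random-walk Metropolis on the probability scale; proposal
scales adapt toward ~40% acceptance during burn-in only and are frozen for
the sampling phase, so the retained chain has a fixed kernel. Defaults are 2
chains × 5000 draws after 2000 burn-in; split-R̂ < 1.05 on all three
parameters is reported as convergence, and non-converged ASVs are retained
conservatively rather than culled.

Given a fitted posterior, the probability a bottle with history `(y, K)` is
truly occupied is the closed form

$$
P(z=1 \mid y) = \frac{\psi\, p_{11}^{y} (1-p_{11})^{K-y}}
{\psi\, p_{11}^{y} (1-p_{11})^{K-y} + (1-\psi)\, p_{10}^{y} (1-p_{10})^{K-y}},
$$

averaged over posterior draws (`presenceProbability()`; `presenceProb()`
exposes the plug-in form). An ASV's overall presence probability is the
**maximum** over its bottles — an ASV genuinely present somewhere should not
be culled because it is absent elsewhere; the mean is available via
`aggregate = "mean"`. `cullAsvs()` removes ASVs with overall probability
strictly below 0.2 (the "< 20%" rule; configurable).

Per-ASV fits are independent (no hierarchical pooling). Since the posterior
depends on the histories only through the multiset of `(y, K)` pairs,
`fitOccupancyAll()` fits once per unique pattern and reuses the result
(`collapsePatterns = TRUE`), which is exact by construction.

Validation anchors the sampler to a brute-force oracle: grid integration
over a 51³ midpoint grid of the unit cube (with the ordering constraint).
Posterior means agree within |Δ| ≤ 0.02 on random small instances, and
parameters simulated at (psi, p11, p10) = (0.6, 0.85, 0.05) over 300 bottles
are recovered within ±0.07 with ≥ 85% credible-interval coverage. The grid
itself becomes unreliable in one corner: when every bottle is saturated
(y = K everywhere) the posterior rides a boundary ridge (the data are also
consistent with small `psi` and large `p10`), and the 51³ grid overstates
the `psi` mean by ~0.04; the tests therefore use non-degenerate histories
for oracle comparisons.

## Replicate quality control

`replicateDistances()` computes, per bottle, the arithmetic-mean centroid of
its replicates' eDNA-index vectors and each replicate's Bray–Curtis
dissimilarity to it. The "95% confidence interval" discard rule is
implemented as a pooled one-sided empirical 95th percentile of all centroid
distances (`flagOutlierReplicates()`, `qc_alpha = 0.05`): with only ~3
replicates per bottle, a per-bottle interval has no power, so pooling borrows
strength across the dataset. Centroids live in index space (not
principal-coordinate space), the pass is single-shot (no recomputation after
discards), replicates with zero reads have undefined distance and are always
discarded, singleton bottles get distance 0 by convention, and bottles may
drop to zero survivors. With fewer than 10 pooled distances a normal
approximation to the cutoff is used, with a warning.

## eDNA abundance index and community analyses

`ednaIndex()` is the two-step transform: counts → proportions within each
replicate, then each taxon's proportions divided by that taxon's maximum over
all replicates. Values lie in [0, 1]; every non-zero taxon attains 1
somewhere; the index is invariant to per-replicate depth rescaling. Counts
can be aggregated to `taxon_unit` or `phylum` (summed) before indexing.

Distances, ordination and variance partitioning are delegated to vegan:
`brayCurtis()` wraps `vegdist` (with all-zero pairs set to distance 0, with a
warning), `runNmds()` wraps `metaMDS` (Kruskal stress-1, monotone regression,
up to `nmds_max_starts` random starts, deterministic seeding), and
`runPermanova()` wraps `adonis2` with sequential (Type-I) sums of squares in
the order given — site, month, transect position by default, so later terms
are adjusted for earlier ones; order sensitivity is inherent to Type-I and
intentional. Transect position enters as a 7-level categorical factor since
no parametrization of distance is assumed. Permutation p-values are
`(#{F* ≥ F} + 1)/(n_perm + 1)` under free row permutation; single-level
factors are dropped with `R2 = 0, p = 1` and a warning; R² terms plus
residual sum to 1 exactly.

## Habitat association

`relativeAbundance()` computes, per phylum and site-month with both transect
extremes sampled, the mean phylum index over `Eg` replicates minus the mean
over `Ba` replicates (positive = more abundant in eelgrass).
`habitatAssociation()` runs a two-sided paired Wilcoxon signed-rank test per
phylum across site-months, Bonferroni-corrected over the number of phyla
actually tested (not a fixed 13, since other datasets carry other phyla).
The exact null is used whenever the differences are untied and few; ties take
a tie-corrected normal approximation without continuity correction, so
all-zero differences give p = 1 exactly.

## Halo detection

1. `transectEvents()`: one event per (taxon unit, site-month) where the taxon
   occurs — the grand mean of its index over the transect's replicates.
2. `splitHighLow()`: events are split into high- and low-abundance classes by
   the globally optimal two-cluster k-means of the 1-D values. Optimality is
   exact and deterministic: the optimal 1-D two-cluster partition is
   contiguous in sorted order, so all n−1 cut points are scored by
   within-cluster SS; no random initialization, no seed sensitivity. The
   between/total SS ratio is reported.
3. `gmmTwoGroup()`: the high events' per-position index values (pooled across
   transects, following the combined-sites-and-months framing) are fit with a
   univariate two-component Gaussian mixture — equal- and unequal-variance
   models, the better chosen by BIC, via mclust with the conjugate variance
   prior (`priorControl()`). The prior matters: unregularized, the
   unequal-variance model habitually collapses one component onto a spike of
   near-identical low values (the classic 1-D mixture degeneracy) and the
   spatial grouping dissolves. Each transect position is assigned to the
   component holding the majority of its values' posterior memberships; group
   "A" is the component of the most shoreward position, "B" the other. A
   Wilcoxon rank-sum test (exact when small and untied) compares the two
   groups' values, and the between/total SS of the grouping is reported.
   Fewer than 4 values is an error; identical values yield a flagged
   degenerate result.
4. `adjacentDissimilarityCheck()`: to rule out plain spatial autocorrelation,
   all-ASV Bray–Curtis dissimilarities between adjacent alongshore positions
   (Eg and Ba are excluded — their metric distance to the transect varies by
   site) are grouped by spacing in meters and tested with Kruskal–Wallis.
   All-equal dissimilarities short-circuit to p = 1 (the rank test is
   undefined on full ties).

## The synthetic generator

`simulateStudy()` emulates the survey that motivates the package: 5 sites ×
3 months × 7 transect positions × 3 PCR replicates = 105 bottles / 315
environmental replicates (a superset of the 84 bottles a real field season
yields), plus positive controls (tissue-dominated, in triplicate) and
negative controls. Its data model, per bottle: Dirichlet-like base
composition (gamma shape 0.3, giving the skewed rank-abundance curves
typical of metabarcoding), log-normal site and month effects (SD 0.5 on the
log scale — modest, realistic spatial/temporal turnover), episodic blooms
(probability 0.13 per taxon-unit × site-month, ×25 abundance), and an
optional halo: the focal phylum's abundance divided by `haloFactor` at every
position except `Ba`. Occupancy is Bernoulli(`psiTrue`) per (ASV, bottle)
— except that a blooming taxon is forced present throughout its site-month,
because a taxon at 25× abundance is in the water column by construction;
`psiTrue` governs background occupancy only. Replicates detect present ASVs
with `p11True`, absent ones with `p10True`, and detected ASVs receive
multinomial reads at negative-binomial depth (mean 20 000, size 5).
Defaults: 6 phyla × 4 taxon units × 3 ASVs = 72 environmental ASVs;
(psi, p11, p10) = (0.6, 0.85, 0.05); contamination into positive controls at
rate 10⁻³ and control-tissue leakage into field samples at 5×10⁻⁴ — the
leakage rates are order-of-magnitude choices, flagged in the manifest, since
no quantitative rates are established. `bloomProb = 0.13` is calibrated to
the design: 4 focal taxon units × 15 site-months = 60 candidate events,
yielding ~8 high-abundance events per run, the scale at which the halo
analysis is meant to operate.

What the generator does **not** emulate: sequence-level error (no FASTQ,
chimeras, or index-hopping mechanics — contamination is injected directly as
proportions), taxonomic misassignment, between-run batch effects, uneven
realized sampling (all 105 bottles exist), compositional interactions beyond
closure, and abundance-dependent detection (detection is gated by `p11`
regardless of how many reads a taxon would receive). Passing tests therefore
demonstrate that the pipeline recovers structure *of the kind it assumes*,
at field-realistic noise levels — not that it is robust to every artifact of
real libraries.

One compositional effect is worth knowing about: when a bloom dominates a
community, closure compresses the *index* contrast of the halo below the
injected abundance factor (proportions saturate at the undepleted position).
The halo detector is validated against exactly this realistic attenuation.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds; `runAll()` derives fixed
  per-stage seeds from the master seed, so skipping a stage does not shift
  downstream randomness, and repeated runs are byte-identical. Run manifests
  omit timestamps by default (`timestamps: false`) for exactly this reason.
* Validation problem sizes (the package's own choices): oracle agreement on
  20 instances of ≤ 30 bottles; recovery at 300 bottles × 10 seeds;
  calibration at 200 PERMANOVA / 500 Kruskal–Wallis null simulations with 99
  permutations each; end-to-end halo recovery over 50 seeded studies per arm.
* Ties: monotone-regression ties in nMDS follow vegan's primary treatment;
  rank tests switch to tie-corrected normal approximations when exactness is
  unavailable; the 1-D split breaks WSS ties at the first optimal cut.
* Degenerate inputs fail loudly and early (no positive controls, all-zero
  controls, single-level PERMANOVA factors, all-identical cluster values),
  or degrade with a warning where a convention exists (singleton bottles,
  all-zero taxa, all-equal distances).

## Limitations

Per-ASV occupancy fits assume bottles are exchangeable (no covariates, no
site-level hierarchy). The pooled 95th-percentile QC rule assumes replicate
noise is comparable across bottles. The halo analysis assumes the focal
phylum's spatial signal is shared across high-abundance events; events with a
lost `Ba` bottle (replicate QC can empty a bottle) cannot contribute a
bare-substrate contrast, and runs with very few high events are intrinsically
noisy. PERMANOVA R² values depend on term order. None of the stages model
abundance-dependent detection, which real metabarcoding exhibits.
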