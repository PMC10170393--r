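---
title: "Methods: multi-marker fecal metabarcoding diet analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-marker fecal metabarcoding diet analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spraintR implements a complete presence–absence dietary analysis for a
generalist predator (the Eurasian otter, *Lutra lutra*) sampled by fecal
("spraint") collection, combining two DNA metabarcoding markers with
morphological identification of undigested hard parts. This vignette is the
package's account of the science: the models and rules it implements, the
decisions taken where the design was genuinely open, and what the synthetic
data can and cannot tell you about real data.

## The analysis problem

Fecal metabarcoding yields, per marker, a samples × taxa table of read
counts contaminated by tag jumping, cross-contamination and host DNA.
Morphological analysis of the same feces yields sparser detections at
coarser, sometimes ambiguous resolution ("rudd/roach"). The pipeline turns
these channels into one binary prey matrix and asks how diet composition
varies with individual covariates (sex, size, body condition) and spatial
gradients (longitude, distance from the coast, water habitat type).

## Read filtering

Two filters are applied per marker, in this order:

1. **Proportional filter.** Within each fecal sample, a taxon contributing
   strictly less than a marker-specific fraction of the sample's *raw*
   total reads is zeroed (defaults 0.5% for 16S, 0.3% for COI). A count
   exactly at the threshold is kept. Control libraries are never altered.
2. **Control filter.** For each taxon, the maximum read count observed in
   any extraction negative, PCR negative or unused tag combination becomes
   its contamination threshold; fecal counts less than or equal to the
   threshold are zeroed (a fecal count merely tying the worst control is
   not trusted).

Open choices, fixed here: the proportional denominator is the raw sample
total (whether it should instead exclude non-target reads is not decidable
from first principles; the raw convention is simple and conservative), the
proportional filter is not re-applied after the control filter, repeat
libraries are collapsed by per-cell maximum before filtering (preserving
every detection), and control thresholds are computed per marker because
libraries are sequenced independently. Mock-community libraries pass
through the filters but are excluded from diet statistics; they exist for
validation only.

After filtering, presence is `count > 0`. Non-food records are then
removed: taxa outside Animalia (diatoms, fungi), the consumer's own reads,
taxa listed as too coarsely resolved to analyse, and taxa flagged with
maximum body size below 3 mm (assumed secondary or accidental ingestion).
Every removal class is tallied.

## Taxonomy-aware reconciliation

Taxa live on a fixed seven-rank Linnaean ladder (kingdom … species);
intermediate ranks must be attached at the nearest coarser ladder rank
before import. "Finer" always means strictly greater depth on the root
path, not rank-label comparison — this is robust to ragged trees where
ranks are skipped.

**Across markers** the per-sample union is taken; when one marker's taxon
is an ancestor of the other's, only the descendant survives (the coarser
record is the same prey seen at lower resolution). Detections on disjoint
lineages are both kept: multi-prey samples are real.

**Across methods** (molecular vs morphological) the same principle applies
with three refinements for ambiguous morphology:

* a composite category (e.g. "rudd/roach") whose member set contains the
  DNA taxon resolves to the DNA taxon;
* a single-member morphological identification that is strictly finer than
  the DNA taxon (a descendant) wins instead;
* a partial overlap between a composite and the DNA taxon's subtree is
  recorded at the lowest common ancestor — the most specific taxon that is
  certainly correct.

Every combined record carries a provenance label (`only_A`, `only_B`,
`both_same_rank`, `both_diff_rank`), labelled relative to argument order.
The provenance partition is disjoint and conserves totals, which is the
backbone of the method-comparison statistics. Morphological labels judged
to reflect secondary predation (insect, beetle, mollusk, snail) or the
otter grooming itself (mammal, identified from fur) are removed before
comparison; the blocklist is configuration, not algorithm.

## Covariates

**Scaled mass index.** Body condition is `SMI = M (L0/L)^b`, with `L0` the
population mean length and `b` the standardised major axis slope of
log-mass on log-length, `b = sign(r)·sd(log M)/sd(log L)`. SMA is the
appropriate line because both morphometrics carry measurement error. The
exponent is fitted on the full reference population supplied, not the
analysis subset.

**Size classes.** Per sex, body lengths are partitioned into three classes
by Jenks natural breaks — the exact Fisher dynamic-programming minimiser of
within-class sum of squares, deterministic with ties broken toward the
lowest feasible break. The medium interval is closed on both ends, so an
individual exactly at a break falls in the class whose printed interval
contains it.

**Spatial covariates.** River distance to the coast is the mean over
candidate rivers (carcass locations do not always pin down the river
travelled); individuals within 1 km of the coast and closer to the coast
than any river get distance zero. Habitat assignment: transitional water
if within 2.5 km (half a 10-km buffer radius), else lake under the same
rule (transitional takes precedence as the rarer, more specific
condition), else the buffer's river network decides with main-channel
length weighted 10× against tributary length; the main channel wins only
with a weighted share strictly above 50% (ties to tributary). Season is
meteorological quarters (Dec–Feb winter, …) — the choice is a documented
default, configurable, since no canonical definition exists for this kind
of survey. GIS extraction itself (routing, buffers, land cover) is out of
scope; the pipeline consumes its outputs.

## Prey groups and occurrence statistics

Taxa are aggregated into analyst-defined prey groups; a group is present
iff any member taxon is present. Coarse taxa that cannot be assigned
(e.g. Salmonidae, ambiguous between trout and salmon groups) are dropped
with a tally. Groups present in fewer than three samples are removed as
rare. Frequency of occurrence is the percentage of analysed samples
containing the group; the denominator is samples with any dietary data
(configurable to all screened samples — the choice matters when many
samples yield nothing).

## The multivariate model

The response is the binary samples × prey-groups matrix. The model is a
stack of independent per-group binomial GLMs with complementary log-log
link `g(p) = log(−log(1−p))` over one shared design matrix — the
model-based alternative to distance-based community analysis, robust to
mean–variance artefacts in presence–absence data. The cloglog link is the
natural choice for presence arising from an underlying encounter process.

* **Fitting** is iteratively reweighted least squares with step-halving;
  convergence when the deviance changes by less than 1e-8, at most 100
  iterations; fitted probabilities clamped to [1e-10, 1−1e-10]. Separated
  responses return flagged non-convergent fits rather than errors so
  resampling never dies on a degenerate draw. Rank-deficient designs error
  naming the aliased columns. AIC per fit is `deviance + 2·(coefficients)`.
* **Community statistic**: the sum over groups of per-group
  likelihood-ratio deviances between nested models — additive by
  construction, which every test asserts exactly.
* **Inference** is a parametric bootstrap from the reduced model: each
  group's response is simulated from its reduced-model fitted
  probabilities, both models refitted, the statistic recomputed. The
  multivariate p-value uses the add-one convention `(1+#{sim ≥ obs})/(B+1)`
  and can never be exactly zero. The resampling scheme is a design choice:
  among Monte-Carlo schemes valid under the binomial model this is the
  simplest, and it is exact under the null model being tested.
* **Per-group p-values** are adjusted by free step-down (Westfall–Young)
  resampling over the same simulated statistics — the correction family
  associated with resampling-based multivariate tests, monotone along the
  significance ordering.
* **Model selection** is greedy stepwise on the sum of per-group AICs,
  starting from the global model, with marginality respected (interactions
  require and protect their main effects). Terms are then tested
  sequentially (type-I order) in the order listed.
* Categorical covariates use treatment coding with lexically sorted levels
  (determinism); rows with any missing covariate are dropped with a
  logged count.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's statistical properties are demonstrated.

True diets follow the *same* cloglog model the analysis fits: group
presence probability `1−exp(−exp(α_g + β_lon·z(lon) + β_coast·z(coast)))`,
so parameter recovery is well-posed. Effect sizes act on z-standardised
covariates, making link-scale magnitudes comparable across covariates.
Default intercepts span realistic prevalences for a generalist otter diet
(a few dominant fish groups at 0.24–0.39, a tail of rarer groups at
0.04–0.15); default gradients lean salmonids, amphibians and
marine/estuarine groups west, cyprinids and percids east, eels and
flatfish coastal, bullhead inland.

Detection channels emulate the study structure rather than sequence-level
reality: per-marker, per-clade detection probabilities (16S
vertebrate-leaning at 0.85, COI invertebrate-leaning at 0.8 with reduced
0.45 vertebrate coverage and family-level resolution ceilings for some
vertebrates); log-normal read depths (meanlog 8, sdlog 1 — library totals
in the tens of thousands); host reads in most libraries; Poisson
contamination with mean 0.3 reads per cell reaching fecal and control
libraries alike; donor-proportional tag jumping into unused tag
combinations; morphological detection at 0.45 per true prey with
species-to-family/composite coarsening and injected secondary-prey labels.
Contamination magnitudes are chosen for testability — the filters must see
realistic, removable noise — not calibrated to any sequencing platform.
All randomness flows from one seed through fixed per-stage substreams, so
every stage is independently reproducible.

What passing tests show, and what they do not: the generator produces
independent samples, honest binomial noise, and contamination that behaves
like the filters assume. Real spraint data have between-sample dependence
(shared sites), taxon-specific amplification bias, and contamination that
correlates with plate layout — none of which is emulated. Calibration and
recovery results here validate the pipeline's statistics under its own
model, not the field behaviour of any marker.

## Problem sizes and numerical choices

The simulation-based properties are demonstrated at the sizes a desk
analysis supports: null calibration with 200 replicates of n = 200 samples
× 10 groups at B = 199 resamples (rejection rate at α = 0.05 expected in
[0.02, 0.08]); end-to-end effect recovery with 50 replicates of the full
pipeline at n = 250 and B = 499, requiring the planted coast-distance
effect (β = 1.0 on the link scale, one group) to be detected with adjusted
p ≤ 0.05 in at least 80% of runs. Exhaustive oracles back the
combinatorial components: Jenks partitions are checked against full
enumeration for n ≤ 12, k ≤ 4; marker reconciliation against a brute-force
union-minus-dominated-ancestors reduction on random 30-node trees; the
IRLS fitter against an independent BFGS optimiser of the same likelihood
to 1e-6 in deviance.

Known limitations: presence–absence only (read counts are never treated as
abundance); no spatial autocorrelation in the model; the stepwise search
is greedy, not exhaustive; composite morphological categories must share
an ancestor below kingdom; and the provenance partition counts records,
not individuals, so taxa detected at two resolutions appear once per
resolution in taxon tallies — both tallies are reported rather than forced
to agree.
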