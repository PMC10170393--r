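# spraintR

Presence–absence dietary analysis of a generalist predator from
multi-marker fecal DNA metabarcoding and morphological prey remains,
built around the Eurasian otter (*Lutra lutra*) and its spraint samples.

Metabarcoding read tables are noisy (tag jumping, cross-contamination,
host DNA) and multi-channel (two markers with different taxonomic
coverage, plus microscopy of undigested hard parts at coarser, sometimes
ambiguous resolution). spraintR turns these channels into one binary prey
matrix and models how diet composition varies across individuals and
space:

* **Read filtering** — per fecal sample, taxa below a marker-specific
  fraction of the raw sample total (0.5% for 16S, 0.3% for COI) are
  removed, then any count less than or equal to the per-taxon maximum
  observed in negative controls and unused tag combinations.
* **Taxonomy-aware reconciliation** — detections are merged across
  markers and methods on a rank-ladder taxonomy: lineage-related
  detections keep the finer taxon, composite morphological categories
  ("rudd/roach") resolve toward the certain taxon, ambiguous overlaps
  fall back to the lowest common ancestor, and every combined record
  carries provenance (`only_A`, `only_B`, `both_same_rank`,
  `both_diff_rank`).
* **Covariates** — scaled mass index `SMI = M·(L0/L)^b` with the
  standardised major axis exponent `b = sign(r)·sd(log M)/sd(log L)`;
  sex-specific Jenks natural-breaks size classes (exact Fisher dynamic
  programming); river distance to the coast; water-habitat assignment
  with 10× main-channel weighting.
* **Diet statistics** — prey-group aggregation (logical OR over member
  taxa), rarity filtering (< 3 samples), frequency of occurrence, mean
  prey groups per sample.
* **Multivariate model** — independent binomial GLMs with complementary
  log-log link per prey group over a shared design; community
  likelihood-ratio statistic = sum of per-group deviances; inference by
  parametric bootstrap from the reduced model with add-one p-values
  `(1+#{sim ≥ obs})/(B+1)`; per-group p-values adjusted by free step-down
  (Westfall–Young) resampling; stepwise sum-AIC term selection. The IRLS
  and bootstrap core is compiled (Rcpp/Armadillo).
* **Synthetic-data generator** — a first-class module producing taxonomy,
  otter metadata, true diets on longitude/coast-distance gradients (same
  cloglog link as the analysis), per-marker read tables with labelled
  contamination and controls, and coarsened morphology, all reproducible
  from one seed.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data with known truth; each writes its tables under `results/`. Running
`analysis/04_diet_summaries.R` prints:

```
Unassigned coarse presences dropped: 4
632 occurrences of 15 prey groups across 281 otters; mean 2.25 groups per otter.
Most frequent prey groups:
stickleback brown_trout         eel    bullhead       perch   amphibian
       37.7        37.0        31.0        26.7        13.2        12.8
```

i.e. after filtering, reconciliation and grouping, 281 of 300 simulated
otters retain dietary data, averaging 2.25 prey groups each; stickleback
occurs in 37.7% of samples, brown trout in 37.0%, and so on — the
frequency-of-occurrence ranking the generator's prevalences imply.
`analysis/05_mglm.R` then selects terms by sum-AIC and prints the
sequential analysis of deviance with resampled p-values, flagging the
prey groups driving each spatial association.

Equivalent calls in R:

```r
library(spraintR)
res <- run_pipeline(pipeline_config(seed = 1, n_otters = 250, B = 199))
res$anova          # community deviance and p per term
res$fo             # frequency of occurrence per prey group
res$manifest$hash  # bit-reproducible run fingerprint
```

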