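# PartnerTraj

Partnership trajectories, polygenic scores and later-life health.

People's marital histories unfold over decades, and single-time-point
marital status misses most of that variation. PartnerTraj implements a
life-course pipeline for researchers in social epidemiology and
sociogenomics who want to (1) turn retrospective marriage/dissolution
reports into yearly partnership-state sequences for ages 15–50, (2)
summarize how trajectories differ with optimal-matching (OM) edit
distances, (3) cluster them into a small typology with Ward's linkage,
and (4) relate the typology — together with polygenic scores (PGSs) and
socioeconomic background — to health outcomes measured after age 50.

## The methods in brief

* **Sequences.** Each person-year gets one of five states
  (`N` not married, `M` married, `R` remarried, `D` divorced,
  `W` widowed). Interior gaps are imputed by last observation carried
  forward; illegal transitions (e.g. `M → N`) are detected and offending
  histories excluded with logged reasons.
* **OM distance.** Substitution costs follow the transition-rate scheme
  `sub(a,b) = 2 − p(b|a) − p(a|b)` with indel cost fixed at 1; the edit
  distance is the usual dynamic program (C++ core, deduplicated pairwise
  matrix).
* **Clustering.** Ward linkage (`ward.D2` by default) on the dissimilarity
  matrix, cut at `k = 6`, with the standard quality-index suite: average
  silhouette width (ASW), pseudo-R², Calinski–Harabasz (CH), Hubert's
  Gamma (HG) and Hubert's C (HC).
* **PGS.** `PGS_i = Σ_j W_j G_ij` over effect-allele dosages, with
  negative weights resolved by allele flipping and scores standardized
  within the scored sample.
* **Models.** Multinomial logit for cluster membership, proportional-odds
  ordered logit for self-rated health (1 = poor … 5 = excellent), NB2
  negative binomial for the CESD count (0–8), a five-stage specification
  series with pooled and gender-stratified fits, gender × cluster and
  gender × cluster × PGS interactions, and inverse-probability weights
  for selection sensitivity.
* **Synthetic cohorts.** `simulateCohort()` draws six archetypal
  trajectories, class-correlated PGSs/SES, and outcomes from
  known-coefficient models, with full ground truth — the whole pipeline
  is testable without access-restricted survey data.

## Worked example

```r
library(PartnerTraj)

res <- runPipeline(pipelineConfig(seed = 3, n = 200))
res$quality
#> QualityReport (k = 6, n = 200)
#>   ASW 0.7880 | R2 0.9760 | CH 1580.3 | HG 0.9934 | HC 0.0031

adjustedRand(res$sim$truth$class, clusterLabels(res$clusters))
#> [1] 1
```

The quality report says the six-cluster Ward solution on this simulated
cohort is extremely clean: silhouettes average 0.79 (well-separated
clusters), 98% of the squared-dissimilarity discrepancy is between
clusters, nearly every within-cluster distance is smaller than every
between-cluster distance (HG ≈ 1, HC ≈ 0) — and the adjusted Rand index
of 1 confirms the cut reproduces the generator's latent classes exactly.
Real survey sequences are much noisier; on the motivating data this
index suite sits near ASW ≈ 0.45.

Fitting the staged outcome models on the simulated analytic table:

```r
sim <- simulateCohort(generatorConfig(n = 2000), seed = 11)
ms  <- runModelSeries(sim$analytic)
subset(ms$table, outcome == "srh" & stratum == "all" & stage == 5 &
               term == "pgs_wellbeing")
#>   outcome stratum stage          model          term estimate     se    z     p stars ratio
#>       srh     all     5 srh.all.stage5 pgs_wellbeing   0.0992 0.0412 2.41 0.016     *   1.1
```

A one-SD higher well-being PGS multiplies the odds of better self-rated
health by about 1.1 in the fully adjusted specification — the estimate
(0.099, SE 0.041) sits essentially on the generator's true coefficient of
0.10 on the log-odds scale.

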