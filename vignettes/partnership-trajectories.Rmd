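---
title: "Partnership trajectories, polygenic scores and later-life health: methods"
author: "PartnerTraj authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partnership trajectories, polygenic scores and later-life health: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PartnerTraj)
```

## The analysis

PartnerTraj implements a life-course analysis in two stages. The first
stage turns retrospective marriage and dissolution reports into yearly
partnership-state sequences for ages 15–50, measures pairwise
dissimilarity between sequences by optimal matching (OM), and clusters the
dissimilarity matrix with Ward's linkage into a small typology of
partnership trajectories. The second stage uses the typology, together
with polygenic scores (PGSs) and socioeconomic background, in regression
models of two later-life health outcomes: self-rated health (ordered
logit) and the CESD depressive-symptom count (NB2 negative binomial).

## Sequences

Each person-year between ages 15 and 50 is assigned one of five states:
`N` not married, `M` married (first marriage), `R` remarried (any marriage
of order two or higher, regardless of how the prior marriage ended), `D`
divorced, `W` widowed. The year of an event takes the *new* state: the
marriage year is coded `M`/`R` and the dissolution year `D`/`W`; when two
events fall in the same calendar year the later-ordered event wins. The
source reports do not resolve event timing below the year, so the package
makes no attempt at month-level coding, and age is simply
`year − birth year`.

Interior gaps (years whose state cannot be determined, e.g. after a closed
marriage with no recorded end reason) are filled by carrying the most
recent observed state forward (LOCF). Leading gaps cannot be invented, so
such persons are excluded and logged, as are persons with overlapping
marriage records or sequences that violate the legality rules: a married
or remarried person can never return directly to `N`; `N → D` and `N → W`
are accepted only after a prior marriage. `buildCohort()` applies the full
chain — state assignment, imputation, validation — and guarantees that
every retained sequence is legal.

## Dissimilarities

Substitution costs follow the transition-rate (TRATE) scheme: with pooled
empirical transition probabilities $p(b \mid a)$ between states in
adjacent years,

$$\mathrm{sub}(a, b) = 2 - p(b \mid a) - p(a \mid b), \qquad a \neq b,$$

so substitutions between states that frequently follow one another are
cheap and never-observed transitions cost the maximum of 2. Rates are
pooled over all ages (the common time-invariant form of the scheme) and
estimated on the same sequence set being compared. States never observed
as a transition source get the maximum cost — absent evidence of
commonness, the scheme treats them as rare. Insertion and deletion cost 1.

The OM distance is the minimum total edit cost transforming one sequence
into another, computed by the standard dynamic program (implemented in
C++; identical sequences are deduplicated before the $O(n^2 L^2)$ pairwise
computation). Because all sequences are exactly 36 positions long, no
length normalization is applied. The package's tests verify the dynamic
program against an independent oracle that exhaustively enumerates all
monotone alignments for short sequences, plus symmetry, the triangle
inequality under estimated costs, the position-wise substitution upper
bound, and cost-scaling linearity.

## Clustering and quality indices

Ward's linkage is applied to the OM dissimilarity matrix. The default
variant is `ward.D2` (Lance–Williams updates on squared dissimilarities,
heights reported on the distance scale); the original source cites Ward's
criterion without naming a variant, so `ward.D` is exposed as a
configuration alternative and cluster solutions may differ slightly
between the two conventions. The tree is cut at a configured `k`
(default 6); an index-versus-k scan table is produced by `qualityScan()`
but no automatic selection is performed.

Five quality indices are reported, using a discrepancy-based sum of
squares $SS(A) = \frac{1}{2|A|}\sum_{i,j \in A} d_{ij}^2$ (the
pseudo-variance appropriate for dissimilarity data, mirroring the
variance decomposition Ward optimizes):

* **ASW** — average silhouette width;
* **R²** — $1 - W/T$ with $W$ the pooled within-cluster and $T$ the total
  discrepancy;
* **CH** — Calinski–Harabasz pseudo-F, $\frac{B/(k-1)}{W/(n-k)}$;
* **HG** — Hubert's Gamma, the Goodman–Kruskal concordance between
  within/between pair membership and the distances (ties dropped). It is
  computed exactly at any $n$ by sorting the between-cluster distances and
  rank-counting, rather than by the quadratic pair-by-pair comparison;
* **HC** — the Hubert–Levin C index,
  $(S - S_{\min})/(S_{\max} - S_{\min})$, lower is better.

All five are verified to ten decimal places against hand computation on a
four-point, two-pair fixture, and are invariant to cluster relabeling and
to consistent row/column permutation of the matrix.

Cluster summaries (sizes, shares, per-cluster state distributions, mean
and median age at first marriage over ever-married members) support
labelling the typology; never-married members are counted separately
because an age at first marriage is undefined for them.

## Polygenic scores

$PGS_i = \sum_j W_j G_{ij}$ over effect-allele dosages
$G_{ij} \in \{0, 1, 2\}$. SNPs with negative GWAS weights are flipped
(alleles swapped, $W_j \to -W_j$, $G \to 2 - G$) so all effect sizes are
positive; standardized scores are invariant to the flip. Scores are
standardized within the scored (complete-case) sample, which is why their
means deviate slightly from zero in restricted analytic subsamples.
Fractional imputed dosages are accepted with a warning; LD handling and
summary-statistic QC are out of scope.

## Outcome models

Self-rated health (reverse-coded 1 = poor … 5 = excellent) is modelled by
proportional-odds ordered logit, $P(Y \le m \mid x) =
\operatorname{logistic}(\kappa_m - x'\beta)$; the CESD count (0–8) by NB2,
$\mu = e^{x'\beta}$, $\operatorname{Var} = \mu + \alpha\mu^2$, with the
dispersion reported as $\ln\alpha$; cluster membership by multinomial
logit with "Married in 20s and Continuously Married" as the reference
cluster. Fitting uses established maximum-likelihood routines with
tightened convergence tolerances; the wrappers are validated against
closed forms (2×2 log odds ratio, null-model intercepts, intercept-only
cutpoints), structural equivalences (multinomial $k = 2$ ≡ logistic, NB2
$\alpha \to 0$ ≡ Poisson, 2-category ordered logit ≡ binary logistic) and
simulation-based coverage calibration.

The staged series fits, per outcome and stratum (pooled, male, female),
five specifications: clusters only; PGSs only; clusters + PGSs;
clusters + SES + controls; clusters + PGSs + SES + controls. Controls are
gender (pooled fits only), birth year, the three-level birth cohort
(< 1948, 1948–1959, ≥ 1960), and the outcome-specific offset between age
50 and the measurement year. The ten ancestry principal components enter
every stage containing PGSs by default — the source is ambiguous on
whether they enter all stages, so a toggle (`includePCsAllStages`) covers
the other reading. Both McFadden and Cox–Snell pseudo-R² are emitted
because the reported flavor is unstated; McFadden is the default display.
Significance stars follow the conventional 0.05/0.01/0.001 two-sided Wald
thresholds with no multiple-testing correction. Missing data are handled
by listwise deletion, with inverse-probability weights
(`computeIPW()`: logistic inclusion model on birth year, cohort and
gender; weights $1/\hat p$ normalized to mean one, probabilities
winsorized at 0.01) as the sensitivity path.

Two numerical choices matter here. Birth year is centered (at 1944)
before fitting: the slope is invariant, but the uncentred scale
ill-conditions the finite-difference Hessians and can corrupt standard
errors. And interaction designs are checked for rank deficiency up front,
with aliased columns named in the error, because empty gender × cluster
cells silently destroy interpretability otherwise.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with full ground truth for recovery testing:

* **Six archetypes** named after the motivating typology (Never Married;
  Married in 30s and Widowed; Married and Divorced; Married in 20s and
  Continuously Married; Married by 20 and Continuously Married; Married
  and Remarried), with shares defaulting to the published cluster shares
  (0.057/0.055/0.037/0.360/0.442/0.048, renormalized from their printed
  rounding). Timing laws are truncated-normal ages chosen so archetypes
  are well separated (e.g. first marriage at 15–20 for the "by 20" class
  versus 21–29 for the "in 20s" class) and all events stay inside ages
  15–50; they reproduce the qualitative shapes of the published state
  distributions and are documented defaults, not estimates of any real
  cohort.
* **Membership model**: the latent class is drawn from a multinomial
  logit whose default coefficients follow the published sign pattern
  (e.g. negative education effects on early-marriage classes) at
  magnitudes detectable at $n = 5000$. The intercepts are calibrated by a
  deterministic fixed-point iteration so that the *marginal* class shares
  equal the configured shares under those covariate effects (exactly the
  configured softmax when all coefficients are zero); without the
  calibration, uncentred covariates such as the 60% female share would
  silently inflate the female-leaning classes.
* **Genotypes** are independent binomial(2, $f_j$) dosages over four
  disjoint SNP panels (no LD); PGSs are computed through the package's own
  scoring path.
* **Outcomes** are drawn from the ordered-logit and NB2 models above with
  known coefficients ($\alpha = 1.5$, near the published dispersion).
* **Interior gaps**, when requested, are masked only at positions whose
  left neighbour belongs to the same spell, so LOCF provably reconstructs
  the truth — the generator guarantees repairable gaps by construction.
  The default missingness rate is 0, which makes the record-to-sequence
  round trip exact: `assignStates()` applied to the generated marriage
  records reproduces the latent state matrix identically, and the latent
  matrix is built by an independent code path precisely so that equality
  is a meaningful test.

What passing tests on this generator do *not* show: robustness to recall
error, cohabitation (out of scope by design), month-level timing, LD
structure, or the missingness mechanisms of real surveys — the generator
is a calibration instrument, not a survey emulator.

## Problem sizes and determinism

The shipped tests exercise the oracle on all pairs of sequences up to
length 4 over a 3-state alphabet (7260 pairs per cost draw, five draws),
distance properties on 200 random sequences (10⁴ random triples for the
triangle inequality), cluster recovery on ten cohorts of $n = 1000$, and
coverage calibration with 100 replications per model family at
$n = 5000$ — sizes chosen to make Monte-Carlo bands tight while keeping a
full run inside a coffee break. All simulations are seeded; the pipeline
writes a manifest (config snapshot, artifact checksums, stage timings)
and identical configs yield byte-identical artifacts.

## Known limitations

* Only legal marriage histories are modelled; cohabitation and nonmarital
  partnerships are out of scope.
* The Ward variant and squared-versus-raw distance convention behind the
  published index values is not stated in the source; both conventions
  are exposed, and index values can shift between them.
* OM with unit indels emphasizes marriage timing and spell durations;
  alternative dissimilarities (Hamming, LCS, spell-sensitive variants)
  are deliberately not implemented beyond the cost-scheme hooks.
* The exact filters behind the motivating study's trajectory-construction
  sample are unstated; the exclusion log records this package's own
  policy (missing birth year, overlapping records, leading missingness,
  unrepairable illegal transitions).
* Whether a dissolution and a new marriage can share a calendar year in
  the source data is unknown; the package logs such records and applies
  the later-event-wins rule without claiming fidelity to the source.
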