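---
title: "Separating maternal and social microbiota transmission with dyadic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating maternal and social microbiota transmission with dyadic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtrans)
```

## The question and the data structure

In wild mammal populations, gut microbes reach a host along two main
conspecific routes: vertically, from the mother around birth and during
early care, and horizontally, from social contacts throughout life. The two
routes leave the same footprint — shared taxa between hosts — so separating
them requires modelling *pairs* of samples: each observation is a dyad
(sample A, sample B) whose response is a microbiota similarity and whose
predictors describe the pair (is this a mother and her offspring? how
strongly are the two individuals socially associated? how far apart do they
live? how far apart in time were the samples taken?). `dyadtrans`
implements this dyadic workflow end to end for ASV-level 16S data, together
with a synthetic-study generator that plants known transmission effects so
the whole chain can be validated by parameter recovery.

The expected inputs are the five files a field study of this kind produces:
an ASV count table (samples x ASVs), a taxonomy table, sample metadata
(individual, date, age class, sex), a pedigree (mother/father per
individual), and nightly logger detection records.

## From counts to dyads

**Taxon filtering.** Non-gut contaminants (by default any lineage
containing *Cyanobacteria* or *Mitochondria*, matched case-insensitively at
any rank) are removed first, then singleton ASVs, then counts are
normalised to within-sample proportions. The order is fixed and recorded in
a filter log: removing contaminant reads first means the singleton
threshold acts on true gut counts. A singleton is an ASV with total count
across the dataset of at most one — the convention of the main ASV-calling
community — because presence in a single read is indistinguishable from
error; the alternative definition (present in exactly one sample) is
available behind a flag. Jaccard similarity is unaffected by the
normalisation step since it only uses presence (abundance strictly greater
than zero; no minimum-abundance cut is applied).

**Similarity.** The primary response is the Jaccard Index — the proportion
of ASVs shared by two samples, the natural currency of a transmission
question — with Bray-Curtis similarity (abundance-weighted) as a
sensitivity metric. Matrices are computed through `vegan::vegdist` and
returned as similarities with unit diagonal; the package's own pairwise
implementations and a naive brute-force loop serve as cross-checks in the
test suite.

**Social association.** Two individuals are co-detected when PIT-tag
loggers record them at the same station on the same 12-hour night. The
adjusted Simple Ratio Index restricts both numerator (nights co-detected)
and denominator (nights either is detected) to the overlap of the pair's
logger lifespans — the window between each individual's first and last
detection — so pairs monitored over barely-overlapping periods are not
diluted by nights when one of them was absent altogether. Co-detection
requires the same station id, not coordinate proximity (loggers are
discrete stations), and multiple reads of a pair at one station in one
night count once. One caveat is documented rather than guessed: whether the
denominator should additionally discount nights when no logger was
deployed inside an individual's range is not decidable from the data model
used here; the index implements the lifespan-overlap correction only.
Restricting records to the overlap window can itself shift the window
(an individual's first in-window detection may come later), so the window
rule is applied once, internally; applying it twice changes nothing.

**Kinship.** Pedigree relatedness uses the standard first-degree coding:
parent-offspring and full siblings 0.5, half-siblings (exactly one shared
recorded parent) 0.25, all else 0. Missing parents are distinct unknowns.
Mother-offspring status is the binary of interest: 1 only when one member
is the *recorded mother* of the other; father-offspring pairs are 0 and are
controlled through the relatedness covariate instead. Deeper pedigree
arithmetic (grandparents, cousins) is deliberately out of scope of the
four-value scheme.

**Dyad assembly and filters.** One row per unordered pair of samples from
different individuals; within-individual pairs are excluded. Covariates:
age-class similarity and sex similarity (1 if equal), spatial distance
between logger centroids, sampling interval in whole days, adjusted SRI,
relatedness, mother-offspring status. Two exclusion rules are applied
jointly: (i) pairs where both samples are immature, and (ii)
mother-offspring pairs where the *mother's* sample is immature. Rule (ii)
makes age-class similarity within mother-offspring dyads a pure function of
offspring age, which is what lets the mother-offspring x age-class
interaction read as "does the maternal signal fade as offspring mature".
The two removal sets can overlap, so the filter report always lists both
sets and their intersection alongside the stage counts, rather than
assuming disjointness.

**Response transform and scaling.** The Beta likelihood is undefined at 0
and 1, so similarities are compressed once, after filtering, with the
Smithson-Verkuilen transform `(y (n - 1) + 0.5) / n` using the final row
count. Continuous covariates (SRI, relatedness, spatial distance, sampling
interval) are centred and scaled to unit SD so the posterior effect sizes
are directly comparable; binary covariates stay on 0/1 so that main effects
remain interpretable as stratum effects at level 0. Standardisation is the
default but optional; the centre/scale pairs are stored for
back-transformation.

## The model

The response is modelled as Beta with logit link and precision phi:

$$y_d \sim \mathrm{Beta}(\mu_d\,\phi,\ (1-\mu_d)\,\phi), \qquad
\mathrm{logit}(\mu_d) = \mathbf{x}_d^\top \boldsymbol\beta
 + u_{A(d)} + u_{B(d)} + w_{sA(d)} + w_{sB(d)}$$

with two *multi-membership* random intercepts: one effect per individual
(`u`, entering once for each of the dyad's two individuals) and one per
sample (`w`, likewise). These absorb the massive non-independence of
dyadic data — every individual and every sample appears in many rows — and
each effect enters additively with equal weight. Fixed effects are
mother-offspring status, SRI, relatedness, age similarity, sex similarity,
spatial distance, sampling interval, and optionally the
mother-offspring x age-similarity and SRI x age-similarity interactions.

**Priors** (documented and configurable): Normal(0, 2.5) on coefficients
of the standardized design, half-Student-t(3, 0, 2.5) on both
random-effect SDs, Gamma(0.01, 0.01) on phi. These are weakly informative
on the logit scale; with tens of thousands of rows the likelihood
dominates.

**Sampler.** Gradient-based MCMC (Hamiltonian Monte Carlo) written for
this likelihood: dual-averaging step-size adaptation targeting 0.8
acceptance, a diagonal mass matrix estimated during warmup, jittered
trajectory lengths, and two reparameterisations chosen for this data
regime. First, the fixed-effects block is thin-QR-rotated (the sampler
works on the orthogonalised design and the Normal prior is mapped through
the rotation exactly), which decorrelates the intercept from the binary
covariates and interactions. Second, the random effects are *centred*:
dyadic data informs each individual effect through hundreds of rows, which
is the regime where the centred parameterisation mixes well and the
non-centred one funnels — the opposite of the sparse-data default. Both
choices were verified empirically against an independent Gibbs sampler
(JAGS) fit of the identical model, which the test suite retains as a
cross-check: posterior means and SDs of slopes, random-effect SDs and phi
agree to within Monte-Carlo error. Default settings are 4 chains of 1,000
warmup + 1,000 kept draws; the reduced preset (2 chains of 500 + 500,
shorter trajectories) is used where many models are fitted (the family
scan and simulation studies). Seeded fits are bit-reproducible.

**Diagnostics.** Split-Rhat per parameter (threshold 1.05 by default) with
optional trace-plot files, and an autocorrelation-based effective sample
size. Slope parameters mix well under both presets; the random-effect SDs
mix more slowly at the reduced preset when their posteriors are very small
— acceptable for the scan, where only the two maternal terms are read off,
and resolved by the full preset for headline fits.

**Stratum effects.** With a binary modifier, the effect of a term at
modifier level m is `beta_main + m * beta_interaction`, composed draw-wise
so the credible interval is a true posterior interval. The same
composition applied to published point estimates (0.17 maternal effect
among adult-immature pairs, -0.13 interaction) reproduces the adult-adult
stratum effect (0.04).

## Attribution: which family carries the maternal signal?

The leave-one-family-out scan recomputes the Jaccard response with each
bacterial family excluded in turn and refits the interaction model with
the reduced sampler, recording the mother-offspring main effect and its
age interaction, plus deltas against the full-table reference fit. Because
the exclusion filters depend only on metadata, the dyad rows are built
once and only the response column is swapped — the scan therefore cannot
change the number of rows, which is asserted as an invariant. Per-family
fits use derived seeds (base seed + family index), making the scan
reproducible and trivially parallel. ASVs without family assignment are
never excluded (excluding an undefined group is meaningless) and appear as
an `Unassigned` pseudo-row; a family whose exclusion would empty a sample
is flagged and skipped with its reason. The richness diagnostic reports
the rank correlation between each family's logged ASV count and its
deltas, and whether the top attenuator is also the richest family — the
check that influence is not a trivial function of how many ASVs the
exclusion removes. A single engine (this package's Beta multi-membership
model) is used for both the headline fits and the scan, for internal
consistency; analyses that use a different engine for the scan will print
effects on a different scale.

## The Mantel confound check

Before interpreting maternal and social coefficients from one model, the
package checks that mother-offspring status and social association are not
themselves confounded: a Mantel permutation test correlates the
individual-level mother-offspring indicator matrix with the SRI matrix,
permuting row/column labels jointly. The test is two-sided with the
add-one convention `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)` and 9,999
permutations by default (the permutation count and sidedness are design
choices of this package); an exact enumeration mode exists for small
matrices and is used as the oracle in tests.

## The synthetic-study generator

No generative model is given by field data, so all distributional choices
here are artifact-level, made once and documented; the generator's role is
to create data whose *transmission structure* is known exactly.

* **Population.** `n_mothers` breeding females each receive a litter of
  `1 + Poisson(litter_size_mean - 1)` offspring (guaranteeing at least one,
  with the exact stated mean); each litter is sired by one male drawn from
  the non-offspring males, so full- and paternal-half-siblings occur.
  Offspring settle near the maternal home centre (Normal dispersal, SD =
  arena/10). Offspring are sampled immature for the first half of their
  occasions and adult later; a fraction `p_young` of other individuals
  also enter young, providing immature-immature pairs for the filters to
  act on. Defaults (70 individuals, 6 mothers, ~3 samples each, two age
  classes) mirror a typical small-rodent study of ~220 samples.
* **Logger records.** Stations on a regular grid; each individual is
  detected with probability `detection_rate` per 12-h night at a station
  chosen by a Gaussian kernel around its home centre (SD = arena/8), so
  neighbours share stations and the SRI decays with home-range distance.
* **Microbiota.** ASV `j` of family `f` is present in a sample of
  individual `i` at age class `a` with probability
  `plogis(alpha_j + B_mat(a, f) M_ij + beta_soc S_ij)`, where
  `alpha_j ~ Normal(-2, 1.25)` (baseline prevalence ~12%, heavy tails),
  `M_ij` indicates maternal availability, and `S_ij` is the SRI-weighted
  carrier prevalence among contacts. `B_mat` is `beta_mat` while immature,
  decays by `adult_decay` in adulthood, and is multiplied by
  `1 + focal_family_boost` for one designated high-transmission family
  (named *Muribaculaceae* after the anaerobic, non-spore-forming family
  that cannot persist environmentally and is therefore the canonical
  transmission candidate in wild mice). The maternal repertoire is the
  union of the mother's own realised samples, generated before any
  offspring sample, so "maternally available" is fixed and well defined;
  a contact's carrier status is read from its most recent earlier sample,
  falling back to a latent baseline repertoire — no information travels
  backwards in time. Present ASVs get symmetric-Dirichlet weights scaled
  to a 10,000-read multinomial, producing realistic integer tables for
  the singleton filter; a few Cyanobacteria/Mitochondria ASVs are
  appended outside the transmission model to exercise the contaminant
  filter. Default planted effects `beta_mat = beta_soc = 1.5` on the logit
  scale are strong but realistic boosts (odds ratio ~4.5 for a maternally
  available taxon in an immature sample).

What the generator deliberately does **not** emulate: sequence-level error
(no reads, chimeras or taxonomy mistakes), trap-capture processes,
paternity uncertainty, seasonal turnover, or within-host dynamics beyond
the repertoire construction. Passing recovery tests therefore demonstrates
that the *statistical chain* — similarity, network, dyads, filters, model
— detects and localises transmission structure of realistic magnitude;
it does not validate the upstream bioinformatics of real studies.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to keep the full test
suite within a routine CI run: parameter recovery uses 60 individuals / 6
mothers / ~150 samples (about 10,000 dyads) over 10 seeds with the reduced
sampler; null calibration uses 20 replicates of 40 individuals; the
attribution recovery uses 10 families over 10 seeds with ~26 individuals
per study. Degenerate inputs fail loudly and early: empty samples cannot
be normalised or compared, proportions-mode tables cannot be
singleton-filtered, responses outside (0,1) instruct the caller to apply
the squeeze, a rank-deficient design stops before sampling, and single
chains refuse to compute Rhat. Ties in the Mantel permutation count are
resolved conservatively (`|r*| >= |r|` with a 1e-12 slack towards
counting).

## Orchestration

`run_pipeline()` drives the whole analysis from a YAML or list config
(either the five input files or a `simulate` block), writes every artefact
(filtered table, similarity and SRI matrices, dyad table with its filter
report, posterior summaries, convergence report, optional Mantel and scan
outputs) plus a `provenance.json` with the config hash, seed, sampler
settings and the filter log. The package deliberately ships no shell
executable: the exported functions and this orchestrator are the
interface, and `scripts/acceptance.R` shows the headless usage pattern.

## Known limitations

* The adjusted SRI implements the lifespan-overlap correction as defined
  above; studies using rotating logger deployments may want an additional
  availability correction that this package does not attempt.
* The Beta likelihood treats the squeezed response as continuous; with
  very small ASV universes the Jaccard Index is coarsely discrete and the
  model is an approximation.
* Effects are reported on the logit (linear-predictor) scale of the
  standardized design; they are comparable within a fit, and
  back-transformation helpers are provided, but scales differ across
  engines and response codings, so cross-study comparison of raw
  magnitudes needs care.
* At the reduced sampler preset the random-effect SDs can show elevated
  Rhat when their posteriors are tiny; headline inference should use the
  default preset and the convergence checker.
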