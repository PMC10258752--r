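---
title: "Repertoire metrics, infection episodes, and their association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire metrics, infection episodes, and their association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repari)
```

# Scope

`repari` implements a cohort analysis that links the breadth of the infant
T-cell receptor repertoire, measured by AIRR-seq at a single time point, to
the number of acute respiratory infections (ARI) recorded in daily symptom
diaries over the first years of life. The pipeline has three arms that meet
in a regression:

1. **Repertoire arm** — clonotype tables are filtered, rarefied to a common
   read depth, and summarised per subject (clonality, Shannon and Simpson
   diversity, richness, CDR3 length, somatic hypermutation, V-gene usage,
   generation probability).
2. **Diary arm** — daily A/B-symptom grids are turned into discrete ARI
   episodes and cumulative counts per year of life.
3. **Association arm** — cumulative counts are regressed on each
   standardized repertoire metric with an older-sibling adjustment, by
   ordinary least squares (additional infections per SD) and by Poisson
   regression (relative risk per SD).

A synthetic-data module generates all three inputs with known ground truth,
so every stage is testable without access to cohort data.

# Repertoire model and preprocessing

A **clonotype** is a unique CDR3 nucleotide sequence; reads sharing the
CDR3 belong to one clone. Rows of a clonotype table that share a CDR3 are
merged by summing read counts; the merged clone keeps the read-count
majority V/J call, with lexicographic tie-break so results never depend on
row order.

Preprocessing applies two rules, in this order:

* **Filter** (`filter_repertoire`): non-productive clones and clones with
  fewer than `min_count = 2` reads are removed. Singletons are dominated by
  PCR/sequencing artefacts at typical error rates, and non-productive
  rearrangements do not contribute to the expressed repertoire.
* **Rarefy** (`downsample_reads`): repertoires are subsampled *without
  replacement* to a fixed depth — 50,000 reads for within-cohort analyses,
  30,000 when including shallower control repertoires. Filtering precedes
  rarefaction; reversing the order would let singleton artefacts enter the
  subsampled pool and inflate richness.

Rarefaction is read-level: each clone contributes `read_count`
indistinguishable reads to an urn and `target` reads are drawn without
replacement, so per-clone sampled counts are multivariate hypergeometric.
The implementation draws clones sequentially with conditional univariate
hypergeometric draws, which is exact and O(S). The tests verify the law by
a chi-square goodness-of-fit against the closed-form joint pmf on a
three-clone toy over 2000 seeds. Sampling with replacement (multinomial) is
available behind `replace = TRUE` but is not the default, because
"normalising to a read count" conventionally means rarefaction. Repertoires
shallower than the target raise an error rather than being silently
dropped: exclusion is a cohort-level decision and is handled (and recorded
in the manifest) by the pipeline driver.

# Repertoire statistics

All diversity statistics operate on the read-frequency vector
$p_i = n_i / N$ over the $S$ clones of a filtered, rarefied repertoire.
Logarithms are base 2 throughout (fixed by the evenness definition), so
Shannon diversity is in bits:

$$H' = -\sum_i p_i \log_2 p_i, \qquad
  J = \frac{H'}{\log_2 S}, \qquad
  \text{clonality} = 1 - J, \qquad
  D_{\text{Simpson}} = 1 - \sum_i p_i^2 .$$

Clonality is 1 for a monoclonal sample and 0 for a perfectly even one. At
$S = 1$ Pielou's $J$ is undefined ($\log_2 1 = 0$); clonality is defined as
1 there, the monoclonal limit. Simpson diversity is reported in its
diversity form $1 - \sum p_i^2$ (rising with evenness); the concentration
form is available via a flag.

Further per-repertoire statistics:

* **Richness** $S$ — distinct clonotypes; only meaningful across subjects
  at a common depth, so a warning is emitted on raw repertoires.
* **Mean CDR3 length** (amino acids) — unweighted over unique clonotypes by
  default. Whether published means weight by clone or by read is usually
  unstated; the clonotype-weighted choice treats each rearrangement as one
  observation of the junctional machinery, and a read-weighted variant is a
  flag away.
* **SHM fraction** (IGH only) — fraction of unique clonotypes with
  V-segment germline identity strictly below 98%. The threshold is strict:
  a clone at exactly 98.0% is *not* called mutated. The denominator is
  unique clonotypes (read weighting available), since SHM is a property of
  the clone, not of its expansion.
* **V-gene usage and PCA** — per-subject V-gene frequency vectors (rows sum
  to 1), decomposed by column-centred PCA via eigendecomposition of the
  covariance matrix. The per-gene `contribution` output reproduces the
  usual "genes contributing most to repertoire skewing" ranking; the even
  reference level is $1/\#\text{genes}$.

# Generation probability

The probability that V(D)J recombination produces a given CDR3 nucleotide
sequence (Pgen) separates *public* clonotypes (high Pgen, frequently shared
between individuals; threshold $10^{-9}$) from *private* ones. Full Pgen
machinery marginalises over an IGoR-parameterised event space including D
segments and context-dependent insertions. `repari` substitutes a
deliberately simplified generative model — V suffix, 3' V trimming, i.i.d.
untemplated insertion, 5' J trimming, J prefix — for three reasons: the
downstream claims are threshold classifications and repertoire means, not
per-sequence parity with reference tools; the simplified model is *exactly*
enumerable, so the implementation can be verified against brute-force
enumeration to machine precision; and the same model powers the forward
sampler of the synthetic module, so every simulated sequence has a
computable Pgen.

`pgen_nt` sums, over all event tuples whose concatenation equals the query,
the product of event probabilities. It is computed by dynamic programming
over the (V piece, insertion, J piece) split positions with prefix products
for insertion bases — exact, no Monte Carlo. Pgen is computed at the
nucleotide level, matching the clone definition (amino-acid marginalisation
is out of scope). Trimming removes `min(t, segment length)` bases, so
extreme trims yield an empty piece; the enumeration oracle in the test
suite applies the identical rule.

Two consequences of the simplification to keep in mind: absolute Pgen
values are not comparable to values from full IGoR-class models, and
sequences outside the toy model's space receive Pgen 0 (these are counted
and reported when annotating a repertoire).

# Episode calling

Diary day 0 is the date of birth; year $n$ ends at day $365n - 1$ (leap
days ignored). A recorded day **qualifies** as an ARI day when it has at
least one A-symptom (fever, wheezing, wet cough, diagnosed pneumonia or
otitis media) or at least two B-symptoms (dry cough, chills, sore throat,
runny/blocked nose, increased sleep need, appetite loss, increased
attachment).

The diary convention fixes only the *start* rule. Termination is a
convention: an episode ends on its last qualifying day once `gap_days`
consecutive non-qualifying days have passed. The default gap of 3 days is a
deliberate middle ground — short enough that distinct infections a week
apart are not merged, long enough that a one-day symptom lull inside an
episode does not split it — and is configurable (1–14) and surfaced in every
output, since the authoritative rule lives with the cohort's published
diary analyses. A single qualifying day constitutes an episode.

Missing diary days default to non-qualifying (`asymptomatic` policy): the
completeness filter, not the episode caller, guards against sparsely
recorded diaries. The alternative `censor` policy pauses the gap counter on
unrecorded days, never letting missingness terminate an episode.
Cumulative counts attribute an episode to the interval containing its
*start* day. Subjects enter the association only when diary completeness
exceeds 0.8 over the observation window.

# Association models

For each repertoire metric separately (the metrics are strongly mutually
correlated, so they are never entered jointly), with the metric
standardized to SD 1 *after* the completeness filter so that "per SD"
refers to the analysed subset:

* **Linear**: $\text{ARI}_{4y} = \beta_0 + \beta_m z + \beta_s
  \mathbb{1}[\text{older siblings}] + \varepsilon$, by OLS with
  normal-theory Wald 95% CIs. $\beta_m$ is the number of additional
  infections per SD.
* **Poisson**: $\log E[\text{ARI}_{ty}] = \beta_0 + \beta_m z + \beta_s
  \mathbb{1}[\cdot]$ at each interval end $t$, giving relative risks
  $e^{\beta}$ with exponentiated Wald CIs, comparable across intervals.

Wald intervals were chosen because no interval type is mandated by the
reporting convention and they are the default in the field. Overdispersion
is not modelled (plain Poisson), but the Pearson dispersion statistic is
attached to every fit so a reader can judge the assumption. A constant
sibling covariate is dropped with a warning rather than an error, so small
simulated cohorts remain analysable. Squared Pearson correlations between
metrics and counts are available as a descriptive companion
(`metric_ari_r2`).

# The synthetic cohort: what it emulates and what it does not

`simulate_cohort` generates the statistical structure the analysis
*assumes*:

* A latent per-subject trait $z \sim N(0,1)$ scales the Dirichlet
  concentration $\alpha_i = \alpha\, e^{z_i}$ of clone abundances
  (Dirichlet–multinomial; two parameters map cleanly onto
  clonality/richness, with a log-normal alternative deliberately left out
  of scope) and simultaneously sets the infection rate
  $\lambda_i = \exp(\beta_0 + \beta_m z_i + \beta_s \text{sib}_i)$, so
  diversity and infection counts are causally coupled with a known sign.
* Defaults state the emulated world: 120 subjects, 50,000 reads,
  $\beta_0 = 3.4$ (about 30 cumulative episodes by age 4),
  $\beta_m = -0.1$ per SD, $\beta_s = 0.15$, 5-day episodes, 10% diary
  missingness, 40% of children with older siblings. `clone_concentration
  = 2` puts baseline clonality near the low values typical of infant TRB
  repertoires. `n_clones = 2000` is a desk-scale stand-in for real
  repertoires (tens of thousands of clones), bounded by the sequence space
  of the toy recombination model; tests scale it down further for speed.
* Episodes are planted with separation greater than `gap_days`, the first
  episode day carrying one A-symptom and the rest two B-symptoms — so both
  halves of the qualification rule are exercised, and with no missingness
  the episode caller must recover the planted episodes *exactly*.
* 5% of clones are injected as out-of-frame, non-productive rearrangements
  to exercise the productivity filter; for IGH, a configurable fraction of
  clones receives germline identity uniform on [90, 98), the rest 100.

What it does **not** emulate: HLA-driven sharing of public clonotypes
between subjects, infection seasonality, age-dependent V-usage drift,
sequencing error (singletons arise only from sampling), and realistic
repertoire sizes. A green end-to-end test therefore establishes that the
pipeline recovers the structure it assumes, at desk scale, with the correct
direction and calibrated uncertainty — not that the biological effect size
in any real cohort is reproduced.

# Numerical choices

* Probability vectors are validated to sum to 1 within $10^{-9}$; diversity
  oracle agreement is tested at $10^{-12}$ (Kahan-compensated summation as
  the independent reference).
* Clonality at the uniform boundary can land a few ulps below 0; residues
  larger than $-10^{-9}$ are clamped to 0, anything worse is a bug and is
  allowed to surface.
* All seeded operations save and restore the caller's RNG state; the
  pipeline derives per-subject rarefaction seeds from the master seed by a
  single `sample.int`, making outputs byte-identical across reruns.
* Tables are written with 17 significant digits so read→write→read
  round-trips are bit-exact.
* Serialized configs and models use JSON (the environment's guaranteed
  structured-text format).

# Known limitations

* The episode termination gap is a convention; sensitivity to `gap_days`
  should accompany any substantive result (episode counts are monotone
  non-increasing in the gap, which the tests verify).
* Pgen values are model-relative; only threshold classifications and
  within-model comparisons are meaningful.
* Plain Poisson will understate uncertainty under real-world
  overdispersion; inspect the reported dispersion statistic.
* The CDR3-length and SHM weighting conventions (clonotype vs read) change
  numbers slightly; both are exposed, defaults documented above.
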