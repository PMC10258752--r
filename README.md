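# repari

Immune **rep**ertoire metrics and **a**cute **r**espiratory **i**nfection
episodes in infant cohorts.

## The problem

Birth-cohort studies that pair AIRR-seq of the T- and B-cell receptor
repertoire with daily infection symptom diaries ask a simple question with
a lot of machinery behind it: *is a narrow antigen-receptor repertoire in
infancy associated with more respiratory infections?* Answering it
requires three analysis arms that are usually stitched together ad hoc:

1. **Repertoire summarisation.** Clonotype tables (AIRR rearrangement TSV,
   one row per unique CDR3 nucleotide sequence) are filtered — clones with
   fewer than 2 reads and non-productive rearrangements removed — and
   rarefied without replacement to a common depth (50,000 reads
   within-cohort; 30,000 against shallower controls). Per repertoire the
   package computes clonality, Shannon and Simpson diversity, richness,
   mean CDR3 length, somatic hypermutation (IGH), V-gene usage with PCA,
   and V(D)J generation probability (Pgen) under an exactly enumerable
   generative model, with public clonotypes called at Pgen > 10⁻⁹.
2. **Episode calling.** A diary day is an ARI day when it has ≥ 1
   A-symptom (fever, wheezing, wet cough, diagnosed pneumonia/otitis
   media) or ≥ 2 B-symptoms (dry cough, chills, sore throat, runny/blocked
   nose, increased sleep need, appetite loss, increased attachment).
   Episodes end after a configurable gap (default 3) of non-qualifying
   days; subjects need > 80% diary completeness to enter the association.
3. **Association.** Cumulative ARI counts are regressed on each
   standardized repertoire metric with an older-sibling adjustment:
   OLS (additional infections per SD) and Poisson regression (relative
   risk per SD, across yearly intervals), both with Wald 95% CIs.

The core statistics, with `p_i` the read frequency of clone `i` among `S`
clones:

    H' = −Σ p_i log₂ p_i          (Shannon diversity, bits)
    J  = H' / log₂(S)             (Pielou's evenness)
    clonality = 1 − J             (1 = monoclonal, 0 = perfectly even)
    Simpson diversity = 1 − Σ p_i²

A synthetic-data module (`cohort_scenario`, `simulate_cohort`) generates
repertoires, diaries and covariates with known ground truth — a latent
trait couples repertoire evenness to the infection rate
`λ = exp(β₀ + β_metric·z + β_sib·sib)` — so every pipeline stage has an
oracle. See the methods vignette
(`vignettes/repertoire-infection-analysis.Rmd`) for the model, parameter
defaults and limitations.

## Worked example

```r
library(repari)
sc  <- cohort_scenario(n_subjects = 40, n_clones = 300,
                       reads_per_subject = 6000,
                       diary_missing_prob = 0.05, seed = 7)
sim <- simulate_cohort(sc)
write_cohort(sim, "demo")

cfg <- run_config(repertoire_dir  = "demo/repertoires",
                  diary_path      = "demo/diary.tsv",
                  covariates_path = "demo/covariates.tsv",
                  out_dir         = "demo/out",
                  normalize_target = 4000L, seed = 99L)
res <- run_pipeline(cfg)

head(res$metrics[, c("subject_id", "clonality", "shannon_bits",
                     "simpson_diversity", "richness")], 4)
#>   subject_id clonality shannon_bits simpson_diversity richness
#> 1       S001    0.0110         8.14             0.996      300
#> 2       S002    0.0906         7.21             0.990      243
#> 3       S003    0.0698         7.50             0.993      268
#> 4       S004    0.0540         7.68             0.994      277

fit_linear_ari(res$analysed, "shannon_bits")
#>             term estimate ci_low ci_high                 scale
#> 1       metric_z    -2.57  -4.35  -0.785 additional_infections
#> 2 older_siblings     7.02   3.48  10.555 additional_infections

fit_poisson_ari(res$analysed, "shannon_bits", interval_years = 4)
#>             term estimate ci_low ci_high         scale interval_year
#> 1       metric_z    0.925  0.876   0.976 relative_risk             4
#> 2 older_siblings    1.245  1.116   1.390 relative_risk             4
```

Reading the output: each SD of Shannon diversity is associated with about
2.6 *fewer* cumulative infections by age 4 (relative risk 0.93 per SD),
while having older siblings adds about 7 — the directions and magnitudes
planted in the generator (`β_metric = −0.1`, `β_sib = 0.15`, mean
cumulative count ≈ 31). `res$manifest` records seeds, parameters and
per-stage subject exclusions; outputs land in `demo/out/` as
`metrics.tsv`, `episodes.tsv`, `effects.json`, `run_manifest.json`.

The same stages are scriptable via the CLI wrapper
(`inst/cli/repari`): subcommands `simulate`, `metrics`, `pgen`,
`episodes`, `associate`, `run`.

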