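# langmarker

Identify and internally validate smartphone-keyboard **language markers**
of posttraumatic symptom severity. The package is aimed at digital
phenotyping and psychiatric epidemiology analysts who have (or must
simulate) two data streams from trauma survivors followed for six months:

* **daily word bags** — per participant-day, an unordered list of typed
  words with frequencies (no text is ever reconstructable), and
* **flash surveys** — brief planned-missing symptom questionnaires at
  roughly ten scheduled timepoints covering ten symptom domains.

## What it computes

1. **Lexicon features.** Category lexicons (literal words plus
   `prefix*` patterns) score the percent of a day's words matched;
   weighted lexicons score `intercept + Σ wᵗ·(countᵗ/total)`. Features are
   z-scored on the identification half only.
2. **Factor scores.** Per domain, a pooled one-factor model
   `x_k = ν_k + λ_k η + ε_k` with `Var(η) = 1` is fitted by
   full-information maximum likelihood over each row's observed items;
   regression-method scores summarize severity per participant-timepoint.
3. **The bivariate linear mixed model** — the statistical core. For each
   (feature, domain) pair, with correlated random intercepts
   `(b_s, b_f) ~ N₂(0, D)` and correlated occasion residuals
   `(e_s, e_f) ~ N₂(0, Σ)`:

   * cross-sectional (between-subject) correlation
     `ρ_b = D_sf / √(D_ss D_ff)`
   * longitudinal (within-subject) correlation
     `ρ_w = Σ_sf / √(Σ_ss Σ_ff)`

   estimated by FIML over whichever of the two values each occasion
   observed, with delta-method Wald inference (and a likelihood-ratio
   alternative). The likelihood is compiled and structure-exploiting; a
   dense brute-force oracle (`loglik_direct()`) must agree to 1e-8 in the
   tests.
4. **Split-half selection.** Participants are halved; all
   feature × domain × type tests are FDR (Benjamini–Hochberg) screened on
   the identification half, and candidates are Bonferroni-confirmed on the
   validation half.
5. **Change prediction.** Validated longitudinal markers predict strict
   sign-of-change worsening vs improvement between the first and last
   timepoints; sensitivity, specificity, PPV and NPV are reported, with
   direction inversion for negatively correlated markers.
6. **Synthetic cohorts.** A generator with planted `(ρ_b, ρ_w)` pairs,
   one-factor items, softmax-linked word bags, device logs and completion
   tables makes the entire pipeline testable without restricted data.

## Worked example

```r
library(langmarker)

# a panel with known truth: rho_b = 0.4, rho_w = 0.2, 15% missing cells
pan <- simulate_blmm_panel(200, 8, rho_b = 0.4, rho_w = 0.2,
                           missing_rate = 0.15, seed = 42)
fit_blmm(pan)
#> Bivariate linear mixed model (FIML)
#>   participants: 200, occasions: 1559, logLik: -4189.804
#>   between-subject rho_b = 0.3830 (se 0.0716, p 8.92e-08)
#>   within-subject  rho_w = 0.2133 (se 0.0313, p 9.87e-12)
```

Both planted correlations are recovered within one standard error, and
both Wald tests reject zero association. End to end, from word bags to a
marker table:

```r
cfg <- pipeline_config(
  outdir = tempfile("demo"),
  sim = sim_config(n_participants = 60,
                   planted_pairs = list(list(feature = 3, domain = 2,
                                             rho_b = 0.6, rho_w = 0.4)),
                   seed = 11),
  n_starts = 2)
run_all(cfg)
mk <- read.csv(file.path(cfg$outdir, "marker_table.csv"))
subset(mk, status != "rejected")[, c(1:3, 9, 11)]
#>    feature   domain association_type p_adj_identification    status
#> 43  negemo domain02  cross_sectional              0.00344 candidate
```

The planted pair (the `negemo` word category against domain 2) is the one
surviving the FDR screen; at only 30 participants per half it remains a
candidate rather than a validated marker — a faithful illustration of why
the split-half design needs cohort-scale samples. `run_all()` also writes
factor scores, the aligned panel, per-pair fits, change metrics, a
missingness diagnostic and a manifest to `cfg$outdir`. The same stages are
scriptable via `inst/exec/langmarker run --config config.yaml`.

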