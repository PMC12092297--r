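---
title: "Deriving and validating smartphone language markers of posttraumatic symptom severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating smartphone language markers of posttraumatic symptom severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a traumatic event, survivors develop adverse posttraumatic
neuropsychiatric symptoms (pain, depression, nightmares, somatic symptoms,
avoidance, anxiety, hyperarousal, and related domains) whose severity waxes
and wanes over the following months. Passive smartphone keyboard data — an
unordered daily bag of typed words with frequencies, from which no message
can ever be reconstructed — offers a privacy-preserving window on language
use during that period. `langmarker` implements the full analysis chain
that turns such word bags plus brief "flash" symptom surveys into
*validated language markers*: lexicon features whose association with a
symptom domain survives a split-half discovery/confirmation workflow.

The chain is: word bags → normalized lexicon features; survey items →
per-domain factor scores; day-level features aligned with survey
timepoints; a bivariate linear mixed model per (feature, domain) pair;
FDR screening on one half of the participants and Bonferroni confirmation
on the other; and finally a sign-of-change evaluation of the validated
longitudinal markers as predictors of symptom worsening.

## The measurement model

Each symptom domain is measured by a small set of survey items
administered at scheduled timepoints, with planned missingness. Pooling
all participant-timepoints, the package fits a one-factor confirmatory
model per domain,

$$x_k = \nu_k + \lambda_k\,\eta + \varepsilon_k,\qquad
  \eta \sim N(0, 1),\quad \varepsilon_k \sim N(0, \theta_k),$$

by full-information maximum likelihood: each row contributes the marginal
Gaussian likelihood of whatever items it observed, grouped by missingness
pattern for speed. The factor variance is fixed at 1 (rather than fixing a
loading), which keeps factor scores on a common standardized scale across
domains; the first loading is reported positive. Scores are
regression-method scores using only the row's observed items,

$$\hat\eta = \frac{\sum_{k \in o} \lambda_k (x_k - \nu_k)/\theta_k}
                 {1 + \sum_{k \in o} \lambda_k^2/\theta_k},$$

which are shrunken: their variance never exceeds 1, and their correlation
with the true latent has the closed-form ceiling
$\sqrt{s/(1+s)}$ with $s = \sum_k \lambda_k^2/\theta_k$. With three
standardized items loading 0.8/0.7/0.6 that ceiling is about 0.88 — a
useful reminder that short planned-missing scales bound the attainable
score validity regardless of sample size. The estimator (maximum
likelihood with regression scores) is the standard default; an ordinal or
weighted-least-squares variant is out of scope.

## The bivariate linear mixed model

The statistical core treats each (feature, domain) pair symmetrically.
For participant $i$ at survey occasion $j$,

$$s_{ij} = \mu_s + b_{si} + e_{sij}, \qquad
  f_{ij} = \mu_f + b_{fi} + e_{fij},$$

with correlated random intercepts
$(b_{si}, b_{fi}) \sim N_2(0, D)$ and correlated occasion residuals
$(e_{sij}, e_{fij}) \sim N_2(0, \Sigma)$, independent across occasions.
The two derived quantities are the *between-subject (cross-sectional)
correlation* $\rho_b = D_{sf}/\sqrt{D_{ss}D_{ff}}$ — do participants with
stably higher feature levels carry stably higher severity? — and the
*within-subject (longitudinal) correlation*
$\rho_w = \Sigma_{sf}/\sqrt{\Sigma_{ss}\Sigma_{ff}}$ — do occasion-to-
occasion deviations move together? Because random intercepts cancel in
differences, $\rho_w$ is exactly the model-implied correlation of
endpoint-to-endpoint changes, which is why longitudinal markers predict
worsening versus improvement.

Estimation is full-information maximum likelihood: an occasion may
contribute the symptom only, the feature only, or both, and each
participant's observed stack is jointly normal with covariance
$Z_i D Z_i' + \mathrm{blockdiag}(\Sigma_{o})$. The implementation exploits
the Woodbury identity so every evaluation reduces to 2×2 algebra, runs in
compiled code, and — with a single mean per series — depends on the data
only through per-participant sufficient statistics, which makes the
large replication studies below affordable. A deliberately naive oracle,
`loglik_direct()`, rebuilds each participant's dense covariance matrix and
is required by the test suite to agree with the optimized likelihood to
within 10⁻⁸.

Numerical choices:

* both covariance matrices are optimized on the log-Cholesky scale
  (unconstrained, always positive definite);
* starts are method-of-moments estimates of $D$ and $\Sigma$ from
  between/within sample covariances, plus deterministically jittered
  restarts (default 5), keeping the best log-likelihood;
* standard errors come from the observed information matrix, propagated to
  the correlations by an analytic delta-method gradient; p-values are
  two-sided Wald;
* estimates with $|\rho| \ge 0.999$ are flagged as boundary cases and
  their standard errors suppressed rather than reported from an invalid
  quadratic approximation;
* a likelihood-ratio alternative (`lrt_rho()`) refits with the selected
  cross-covariance pinned to zero;
* the default mean structure is a single mean per series, matching the
  bivariate correlation formulation; occasion-specific symptom means are
  available (`t_means = TRUE`) because severity declines over follow-up,
  and with them $\rho_w$ describes deviations around the trend rather
  than around a flat mean. Neither choice is asserted as the original
  study's; the flag exists so both are reproducible.
* residuals are independent across occasions; serial correlation is not
  modelled, but the generator has an autoregressive hook (`ar_rho`) to
  probe the cost of that assumption.

## Preprocessing rules

The filters are applied exactly as stated, with strict inequalities:
features whose share of zeros among non-missing cells exceeds 90% are
dropped; daily word counts above 10,000 are set missing (the count only —
category percentages for the day are kept); participants whose device log
shows two operating systems within their first six months are removed.
Redundant features (pairwise Spearman correlation above 0.85,
pairwise-complete) form components from which one representative survives:
the feature with the strongest mean absolute Spearman association with the
domain scores, ties broken lexicographically, with an explicit priority
list available where interpretability should override the statistic.
Marker values are the mean of the feature on the day before and the day of
each survey; if one of the two days is missing the available day is used
(discarding it would waste data and bias the panel toward heavy typists),
and only when both are missing is the marker missing. Zero percentages are
computed over non-missing cells because a no-typing day carries no
evidence of zero category usage.

A missingness diagnostic correlates per-participant mean factor scores
with activity completion rates; when every correlation is weak (|r| <
0.1) the missing-at-random assumption behind the full-information
likelihood is considered plausible.

## Split-half selection

Participants — not observations — are randomly halved: repeated measures
within a participant are dependent, and an observation-level split would
leak identification information into validation. On the identification
half, every (feature, domain, association-type) test enters one
Benjamini–Hochberg family (both association types of all pairs jointly);
tests with adjusted p below α = 0.05 become candidates. On the validation
half, candidates alone form the Bonferroni family, and survivors are
validated markers, reported with validation-half estimates. Cross-
sectional and longitudinal p-values from one fit count as two tests.

## Change evaluation

Worsening is strictly `score(last) − score(first) > 0`, improvement
strictly `< 0`; exact zeros and incomplete endpoints are excluded on both
the truth and prediction side. Validated longitudinal markers predict the
change class from the sign of their own change; a marker with a negative
validated correlation has its prediction inverted, so reported
sensitivity/specificity/PPV/NPV always refer to predicting worsening. The
identity $\mathrm{PPV} = \mathrm{sens}\,\pi /
(\mathrm{sens}\,\pi + (1-\mathrm{spec})(1-\pi))$, with $\pi$ the worsening
prevalence, holds exactly for every reported row and is asserted in the
tests.

## The synthetic cohort

Because the motivating study's data are restricted, the package ships a
generator that emulates the *statistical* structure the analysis assumes,
not realistic language: ten survey timepoints spanning days 7–180 with a
linearly declining severity trend; one-factor item responses per domain
(default loadings 0.8/0.7/0.6, uniquenesses $1-\lambda^2$); latent
language features following the same random-intercept model as the
analysis, with configurable planted $(\rho_b, \rho_w)$ per
(feature, domain) pair; and daily word bags drawn from a multinomial whose
category emission weights follow a log-linear (softmax) link in the
latent feature value — the simplest monotone link that exercises the
lexicon stage. Word bags are generated for the survey-adjacent days plus a
few random extra days per participant, which keeps fixtures small without
affecting any aligned observation. Missingness is MCAR by default (the
diagnostic above is the in-model justification); an optional MAR mode ties
dropout to current severity for robustness experiments. A single master
seed drives fixed-offset streams for latents, items, words, missingness
and device logs, so adding features does not perturb earlier draws.
Ground truth is returned (and written as a clearly named `truth.json`)
but never read by the pipeline.

Defaults aim at a plausible mid-size cohort: 200 participants, six word
categories mirroring the bundled toy lexicons, ~300 words per day, 15%
survey and 20% word-day missingness, between-participant share (ICC) 0.55
of unit latent variance, and a 2% operating-system switch rate.

## What the validation studies show

The test suite and `scripts/acceptance.R` recompute, from scratch:

* recovery of planted $\rho_b = 0.30$, $\rho_w = 0.15$ with 20% missing
  cells across 100 replicates of 400 participants × 8 occasions (mean bias
  well under 0.02; ~94% coverage of nominal 95% intervals);
* exact agreement (≤ 10⁻⁸) between the structured likelihood and the dense
  oracle;
* Wald-test size for $\rho_w = 0$ near 0.05 over 1000 null replicates of
  200 × 6;
* the change-correlation identity at n = 2000;
* measurement-model loading recovery under planned missingness, and the
  factor-score validity ceiling discussed above;
* bit-exact agreement of the BH and Bonferroni adjustments with
  brute-force definitions, and, over replicated split-half studies of
  40 features × 10 domains with three planted pairs
  ($\rho_b = 0.5$, $\rho_w = 0.3$, 160 participants × 6 occasions — sizes
  chosen once for near-unit power at split-half scale), recovery of all
  planted markers with the familywise false-validation rate held at or
  below 5%;
* byte-identical pipeline reruns and equality of `run_all()` with its
  stage-by-stage composition.

Passing these says the machinery is correct and calibrated *under the
generator's assumptions*: Gaussian latents, linear links, independent
occasions, ignorable missingness. It does not certify performance on real
keyboard data, where features are skewed and zero-inflated, severity
trajectories are heterogeneous, and missingness may be informative — the
MAR generator mode and the occasion-mean flag exist precisely to explore
those departures.

## Known limitations

* One factor per domain; no measurement invariance testing, no ordinal
  estimation.
* No random slopes or covariate adjustment in the bivariate model;
  associations are unadjusted by design.
* Spearman pruning and zero-percentage rules are threshold rules; results
  near the thresholds are sensitive to sampling noise.
* The change evaluation uses single first/last endpoints and a sign rule;
  no clinically anchored change thresholds and no multivariable
  combination of markers.
* Weighted lexicons are linear in relative frequencies; no pretrained
  trait models are shipped, only a toy example of the interface.
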