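---
title: "Simulating and evaluating an abstaining diagnostic classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating an abstaining diagnostic classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abstaindx)
```

## The problem

Screening aids for autism spectrum disorder (ASD) in primary care face a
population in which most referred children have *some* developmental or
behavioral condition, but only a minority have ASD. The hard cases are not
ASD-versus-neurotypical; they are ASD versus phenotypically overlapping
conditions (language disorder, global developmental delay, ADHD, anxiety).
A device that must answer on every child will either miss ASD cases or
over-call them.

`abstaindx` studies the selective-classification answer to this problem: a
device that outputs **ASD positive**, **ASD negative**, or **indeterminate**
("no result"). The indeterminate output is a risk control: when the inputs
are not granular enough for a confident call, the device abstains and the
child is referred onward as usual. The price of abstention is coverage — the
*determinate rate* — and the regulatory contract is that, among determinate
outputs, positive predictive value (PPV) and negative predictive value (NPV)
stay above negotiated floors (0.65 and 0.85 by default here).

The package provides four computational stages, usable separately or
end-to-end:

1. **Cohort synthesis** — 18–72-month-olds with three latent classes
   (ASD / non-ASD condition / neurotypical), covariates, DSM-5 severity
   levels, comorbidity sets, and age-banded 64-item ordinal questionnaires.
2. **Reference-standard simulation** — a diagnosing specialist, a blinded
   reviewing specialist, a tie-breaking third on disagreement, majority
   adjudication, and a diagnostic-certainty Likert score.
3. **Abstention classifier** — a probabilistic score model over the 64-item
   vector plus dual thresholds `(t_neg, t_pos)` calibrated by
   cross-validation to maximize the determinate rate subject to the PPV and
   NPV floors.
4. **Exact evaluation** — 3×3 confusion matrices, determinate-subset and
   no-abstention metrics with exact Clopper–Pearson intervals, Boschloo's
   unconditional exact test for subgroup contrasts, and covariate-stratified
   reports.

## The cohort model

Each subject carries a scalar latent severity trait $z$ with
class-conditional normal distributions. Defaults:

| class | probability | $z$ mean | $z$ sd |
|---|---|---|---|
| ASD | 0.287 | 1.5 | 1 |
| non-ASD condition ("comorbid_only") | 0.619 | 0.0 | 1 |
| neurotypical | 0.094 | −2.5 | 1 |

The class mix matches a large multi-site primary-care referral cohort
(28.7% ASD, 61.9% other conditions, 9.4% neurotypical). The latent means are
a modeling choice — real questionnaire distributions are proprietary — made
once, with two deliberate properties: the comorbid class sits *between*
neurotypical and ASD, and it overlaps the ASD class substantially (1.5 SD
apart). That overlap is what generates the central phenomenon of interest:
children with non-ASD conditions dominate the indeterminate zone, so
abstention concentrates exactly where clinical complexity does.

Item responses follow a graded (ordinal logistic) response model with K = 5
levels: item $j$ has discrimination $a_j$ and thresholds
$b_{j1} < \dots < b_{j,K-1}$, and
$P(\text{level} \ge k \mid z) = \mathrm{logit}^{-1}(a_j (z - b_{jk}))$.
Default discriminations ramp over $[0.8, 2]$ and item locations sweep
$[-1, 1]$; items are exchangeable within channel because the real item
content and its mapping to the published core-behavior list are not
disclosed. Two age bands mirror the real device's questionnaire versions:
18–47 months (18 caregiver + 33 video-analyst + 13 clinician items) and
48–72 months (21 + 28 + 15); both total 64.

Covariates (sex, non-exclusive race/ethnicity, parental income and
education) are sampled independently of the clinical class by default. The
study this package emulates found no performance differences by covariate,
so independence is the matching null; dependence can be introduced by
editing `covariate_probs`. ASD subjects receive social-communication and
restricted/repetitive-behavior severity levels 1–3 from the within-class
tertile of $z$, independently jittered by ±1 with probability 0.2, which
qualitatively reproduces severity skewing toward levels 2–3 among
device-positive children. Comorbid-class subjects draw each condition label
independently at published marginal rates and are guaranteed at least one;
ASD subjects draw at half rates. Item responses are complete by default; a
per-item missingness probability exists because insufficiently granular
inputs are precisely the abstention trigger in the real device.

## The consensus reference standard

Two simulation modes are exposed because published studies report
*agreement marginals*, not a generative error model:

* **Agreement mode** (default): the first reviewer agrees with the
  diagnosing specialist with probability 0.79; on disagreement (21% of
  subjects, matching the published second-review rate) the tie-breaker sides
  with the diagnosing specialist with probability 0.43. The final label
  therefore equals the diagnosing call with probability
  $0.79 + 0.21 \times 0.43 = 0.8803$.
* **Error-model mode**: every specialist errs independently of the others
  with per-class probability $\varepsilon$; majority voting reduces the
  reference error to $\varepsilon^2(3 - 2\varepsilon)$. Individual
  specialist accuracy against truth is unobservable in a real trial, so the
  defaults (0.05 per class) are placeholders for sensitivity analyses, not
  estimates.

Non-ASD final diagnoses split into "other condition" versus "neurotypical"
by the subject's own record (the panel is assumed to identify comorbid
conditions without error, since no error rate for that subclassification is
published). Certainty Likert distributions are solved from published
marginals: every category places 95% mass on "somewhat" or "completely
certain", with the completely-certain share at 0.67 (ASD), 0.74 (other
condition) and 0.95 (neurotypical).

An important consequence of agreement mode, worth stating plainly: because
reviewer behavior is drawn from agreement probabilities rather than from
truth, about 12% of final labels flip away from the diagnosing call
*independently of the subject's presentation*. Combined with the diagnosing
specialist's own error this puts a ceiling of roughly 0.84 on the NPV any
score model can achieve against the simulated reference standard — just
below the default 0.85 floor. In a real trial, device scores and consensus
labels err on the *same* ambiguous children, which is why the real device
could clear the floor comfortably. The synthetic pipeline's independent
label noise is the harsher null; end-to-end runs at the default panel
settings therefore calibrate to low determinate rates or fail, and users
studying calibration behavior in isolation should either pass true class
labels to `calibrate_thresholds()` or reduce the panel noise.

## Threshold calibration

Scores come from a pluggable learner (`fit_score_model()`): gradient-boosted
trees (xgboost, the model class the real device deploys) by default, with a
logistic fallback. Calibration operates on *out-of-fold* scores from
class-stratified cross-validation (`cv_oof_scores()`); scores computed on a
model's own training data are tagged and refused, since in-fold scores
overstate attainable PPV/NPV.

The search space is finite and sufficient: candidate thresholds are the
midpoints between consecutive sorted unique out-of-fold scores, plus 0 and
1 — the induced partition of subjects only changes at observed scores. Among
all pairs $t_{neg} \le t_{pos}$, `calibrate_thresholds()` returns the pair
maximizing the determinate rate subject to PPV ≥ 0.65 and NPV ≥ 0.85. The
published account states the floors and "variable abstention rates" but not
the objective; maximizing coverage is the standard selective-classification
choice and is recorded here as an assumption.

Numerical and boundary conventions, fixed once:

* **Output rule**: negative iff `score < t_neg`, positive iff
  `score >= t_pos`, indeterminate otherwise. `t_neg = t_pos` reduces to an
  ordinary binary classifier.
* **Feasibility**: a pair must emit at least one positive and one negative
  output overall, with floors met where evaluated. In `per_fold` mode
  (constraints enforced inside every fold rather than pooled) a fold whose
  region is empty contributes no constraint for that region.
* **Tie-break**: among determinate-rate maximizers, the widest abstention
  band wins, then the lowest `t_neg` — a deterministic, conservative choice
  consistent with a device designed to minimize false negatives.
* **Failure is a value, not an exception**: overlapping populations may
  admit no feasible pair, and that outcome is scientifically meaningful.

A known limitation of the default pooled constraint evaluation: because the
search maximizes over on the order of $n$ candidate pairs, a small score
region can satisfy a floor by chance. With labels drawn independently of
scores at prevalence 0.29 (so no genuine operating point exists against a
0.65 PPV floor), roughly 7% of replicates at n = 400 still return a
"feasible" pair covering 5–10% of subjects — a pooled point-estimate
overfit, not signal. Per-fold constraint evaluation suppresses these flukes
and is the recommended mode when the feasible region is expected to be
marginal.

## Exact statistics

All interval estimates are exact Clopper–Pearson bounds computed by the
beta-quantile identity (`qbeta(α/2, x, n−x+1)` and
`qbeta(1−α/2, x+1, n−x)`), with `lo = 0` at `x = 0` and `hi = 1` at `x = n`.
The test suite checks them against direct bisection of the binomial tail
conditions for every `x ≤ n ≤ 25` and verifies ≥95% empirical coverage.

Subgroup contrasts use Boschloo's unconditional exact test: the Fisher
exact p-value orders the joint outcome space of the two independent
binomials, and the p-value is the supremum over the nuisance success
probability of the rejection-region probability. The supremum is evaluated
on 1000 equally spaced interior points followed by two local 10× refinement
passes, bounding grid error far below reporting precision. The two-sided
version orders outcomes by the two-sided Fisher p-value; published p-values
for the age contrasts do not state sidedness, and the two-sided convention
reproduces both printed values (0.006 and 0.03).

Abstention-aware metric conventions: PPV, NPV, sensitivity and specificity
are computed on the determinate subset, pooling both non-ASD reference
categories into the negative class; the *no-abstention counterfactual*
instead counts every indeterminate output as a failure for its reference
class, which is what forces the published denominators (all 122 ASD and all
303 non-ASD completers). Metrics with empty denominators carry an explicit
`undefined` flag. No multiple-testing correction is applied across strata,
matching the practice of reporting separate CIs per stratum and checking
their overlap; that is a faithful-reproduction choice, not an endorsement.

## What the synthetic generator does and does not emulate

Passing tests on synthetic cohorts demonstrate that the pipeline's
machinery is correct under the stated generative assumptions: a
one-dimensional severity trait, conditionally independent graded items,
covariates independent of class, and reference noise independent of device
scores. Real questionnaire data are multidimensional, items are not
exchangeable, covariates correlate with referral patterns, and specialist
disagreement concentrates on genuinely ambiguous children. None of those
features are claimed; results on synthetic data bound what the code does,
not what any real device would achieve.

## Problem sizes used by the test suite

Monte-Carlo checks run at sizes chosen to keep the default suite fast while
leaving comfortable statistical margins: panel marginals at $10^5$ subjects
(3 Monte-Carlo SEs ≈ 0.4 percentage points), class-mix goodness of fit over
300 replicate cohorts of 150, prevalence centering over 400 replicate
cohorts of 425, calibration-versus-oracle equivalence on grids of ≤ 20
scores, Boschloo enumeration on group sizes ≤ 8, and the
separation-monotonicity sweep over five latent separations × 10 replicate
cohorts of 300 with the default gradient-boosted learner.

## End-to-end runs

```r
cfg <- run_config("simulate_full", seed = 7,
                  cohort = list(n_subjects = 425))
res <- run_pipeline(cfg, "run7")
res$calibration
res$metrics
```

Every artifact (cohort CSV with adjudication trail, scores and outputs;
confusion CSV; metrics JSON; stratified tables; Markdown report; log with
config hash and calibration decisions) is reproducible from the
configuration and seed: all randomness flows from one seed through named
substreams (cohort, panel, learner, folds), so regenerating one stage does
not perturb another. Typed confusion matrices can also be analyzed directly
(`run_config("evaluate_confusion", input = ...)`), which is how the
published 3×3 table shipped in `inst/extdata/pivotal_confusion.csv` is
processed.
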