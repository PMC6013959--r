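---
title: "Predicting 30-day readmission risk with deep unified networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 30-day readmission risk with deep unified networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

About one in four heart-failure patients returns to hospital within 30 days
of discharge. Telemonitoring programs can prevent a fraction of those
readmissions, but enrolling every discharged patient is not economical, so
hospitals want a per-admission risk score computed at discharge from
electronic medical record (EMR) data: demographics, utilization history,
diagnoses, procedures, labs, medications, and clinician notes. `readmitnet`
implements a complete modelling stack for this task — cohort labeling,
feature engineering, a deep architecture with per-sample layer attention,
reference baselines, threshold-sweep evaluation, and a cost model that turns
an ROC curve into projected program savings — together with a synthetic EMR
generator so every stage is testable without access to protected health
data.

## Outcome definition

Every hospitalization is an *index admission*. An index is flagged with a
30-day readmission when the same patient's next countable admission begins
no more than 30 days after the index discharge; a readmission is itself
evaluated as an index for the following stay. Planned admissions (e.g.
chemotherapy, dialysis), within-hospital transfers, and discharges against
medical advice are not countable: they are never flagged, never serve as the
readmission of an earlier stay, and are invisible to the gap computation —
the gap runs from an index's discharge to the patient's next *countable*
admission.

Two readings of the rules are genuinely open and were fixed as package
design choices: the day count is `next admit − this discharge` in whole
days with a same-day return (gap 0) counting, and an intervening excluded
admission does not interrupt the gap. Ties between admissions starting the
same day are broken by discharge date and then input order.
`cumulative_prior_30day_readmissions` — the running count of a patient's
earlier flagged stays — is carried as a feature because prior readmission
history is consistently among the strongest predictors in this literature.

## Feature engineering

Each data type contributes variables from a fixed window around the
admission, with a fixed value expression:

| data type    | window                               | expression                |
|--------------|--------------------------------------|---------------------------|
| demographics | patient level                        | 1-of-K / continuous       |
| admissions   | admit → discharge                    | continuous (length of stay, age, prior readmissions) |
| diagnoses    | discharge − 2 years → discharge      | binary occurrence         |
| labs         | admit → admit + 7 d; discharge − 7 d → discharge | abnormal-result counts (two variables per code) |
| medications  | admit → discharge                    | occurrence counts         |
| procedures   | admit → discharge                    | occurrence counts         |
| notes        | admit → discharge                    | bag-of-words binary, counts for allergies |

Medication and diagnosis codes can be passed through user-supplied
two-column lookup tables (e.g. drug name → ATC level 5, diagnosis →
well-known-factor group); unmapped codes pass through under their raw
identity and the mapping coverage is reported rather than asserted, since
real vocabularies are not shipped with the package.

Note sections are retained when they appear in at least 50% of the notes of
their note type. Retained sections are tokenized (any deterministic
token normalizer can be plugged in; the default lowercases — full
lemmatization and part-of-speech filtering are out of scope), and words
appearing five times or fewer in the whole corpus are dropped. Each
surviving word yields a per-document count and a binary presence variable;
the windowed extractor then keeps the binary variant for all sections
except allergies, which uses counts.

Categorical variables are 1-of-K expanded; this package deliberately does
*not* bin continuous variables, which are instead min–max scaled — the
choice between those two readings of "1-of-K coding of quantitative
variables" is ambiguous in the source literature and binning would discard
resolution without a stated K. Missing values are treated as zero before
scaling. Min–max parameters are always fit on training data only and
applied to held-out data with clipping into [0, 1].

### Variable filtering by total KL divergence

For each variable the class-conditional distributions `P` (readmitted) and
`Q` (not readmitted) are estimated — Bernoulli cell counts for binary
columns, a 10-bin equal-width histogram over the pooled range otherwise —
with an additive pseudo-mass of `eps = 1e-9` per cell so that empty cells do
not produce infinite divergences. The score is the total (symmetrized)
divergence

$$D_j = \mathrm{KL}(P_j \| Q_j) + \mathrm{KL}(Q_j \| P_j),$$

and variables with $D_j \ge \bar D + \tfrac12 \mathrm{sd}(D)$ are retained.
The divergence is estimated on the scaled values; the bin count, the
smoothing mass and the scale were fixed once as package defaults (the
source method does not state them) and are exposed as arguments. Because
the filter is supervised it must be fit inside each training fold — the
cross-validation harness does exactly that.

## Deep unified networks

DUNs are vertically deep but horizontally shallow. With input
$x \in [0,1]^p$, $K$ data-unit layers of $m$ neurons are produced by
*harmonizing units* that fuse the raw input with the previous layer:

$$h_1 = \sigma(V_1 x + c_1), \qquad
  h_k = \sigma(U_k h_{k-1} + V_k x + c_k), \quad k = 2, \dots, K.$$

A per-sample *attention unit* places a weight vector on the $K$-simplex,

$$a(x) = \mathrm{softmax}(W_a x + b_a), \qquad
  \textstyle\sum_k a_k(x) = 1,\; a_k(x) \in [0,1],$$

the layers are mixed as $z = \sum_k a_k(x)\, h_k$, and a single *decision
unit* produces the risk $\hat y = \mathrm{sigmoid}(w \cdot z + b)$. From
any data unit there are only two horizontal hops to the output (mix, then
decide), so gradient paths stay short regardless of depth; the attention
weights report, per admission, how much nonlinearity the prediction drew
on — a linear-explainable case concentrates weight on shallow layers.

The published description of this architecture leaves the exact equations
to supplementary material that is not redistributable, so the equations
above are this package's reconstruction, fixed by three commitments: the
harmonizing unit sees both $x$ and $h_{k-1}$ (dropping $x$ would collapse
the mesh into a plain DNN), the attention unit is a single linear map of
$x$ followed by a normalized exponential (trained jointly, bookkept with
the decision unit), and the loss is mean binary cross-entropy, which the
sigmoid output implies. The gradient of every parameter is derived
analytically and verified against central finite differences in the test
suite.

Training is mini-batch SGD with classical momentum (defaults: learning rate
0.01, momentum 0.9, batch size 100), inverted dropout on the input and on
every data unit (defaults ≈ 0.4, active only during training; inference
uses expectation scaling), and fan-scaled symmetric uniform weight
initialization. Weight init, epoch shuffling and dropout masks all derive
from one seed, so a fixed seed reproduces the training trajectory exactly.
Default architecture: $K = 5$ layers of $m = 759$ sigmoid neurons, the
tuned operating point reported for this method on real EMR data; the tests
use far smaller nets.

## Baselines

*Maxout networks* share the training loop: each inner-layer neuron takes
the maximum of its affine pieces before the layer activation, and with one
piece per neuron the network is numerically identical to a plain DNN — a
stated property the suite checks to 1e-10. *Logistic regression* delegates
to glmnet (L1 or L2, default L2 with $\lambda = 6.931 \times 10^{-6}$) and
reports feature importance as $|w_j|$ ranked descending. *Gradient
boosting* is a thin adapter over xgboost, present for comparison tables
only; it skips with a warning when the library is absent.

## Evaluation

`roc_curve()` sweeps the threshold over every distinct score (ties enter
together) and keeps raw TP/FP/predicted-positive counts at each point, so
downstream consumers never re-score. `auc()` is the trapezoidal area,
equal to pairwise concordance with half credit for ties. The operating
point minimizes the distance to the ideal corner,
$\sqrt{\mathrm{FP}^2 + (1-\mathrm{TP})^2}$, with ties broken toward higher
TP rate then lower threshold. Prediction at threshold $t$ is
$\text{score} \ge t$; precision with zero predicted positives is reported
as 0 with a warning. Cross-validation uses stratified folds (both classes
guaranteed per fold — plain folds risk degenerate test folds at a 23%
event rate), refits the encoder/scaler and the KL filter inside each
training fold, and selects the operating point on each held-out curve.
The hyper-parameter harness draws one random 10% subset, then runs seeded
random search over the declared distributions, scoring each candidate by
mean k-fold AUC on the subset; a sequential model-based optimizer could be
slotted in, but no tree-structured Parzen estimator implementation is
available to R here, and the harness states which strategy it used.

## Cost model

With per-readmission cost $C_r$ (default \$9655), per-enrollee program
cost $C_p$ (default \$1500) and response rate $r$ (default 50%), the net
savings at a threshold with TP true positives and PP predicted positives is

$$S = C_r \cdot \mathrm{TP} \cdot r - C_p \cdot \mathrm{PP}.$$

`savings_sweep()` evaluates $S$ at every ROC point (the all-negative point
makes 0 attainable, so the maximum is never negative), breaking ties toward
the smaller program, and `savings_summary()` reports the mean ± sd of the
per-fold maxima and of the accuracy at the corresponding thresholds,
computed on held-out-fold counts.

## The synthetic cohort generator

No public EMR extract exists for this problem, so the generator emulates
the statistical structure the method assumes: patients with
`1 + Poisson(mean − 1)` chained admissions (default mean 2.4 per patient);
per-admission planned/transfer/against-medical-advice flags at configured
fractions (defaults 5%/3%/2%); and a logistic risk model over latent
admission-level covariates with both linear effects and XOR/product
interactions plus Gaussian noise. The intercept is calibrated by root
finding so the realized flagged fraction of countable admissions converges
to the target rate (default 23.3%, the published cohort rate). Gaps are a
mixture of truncated-geometric short gaps (readmissions, 0–30 days) and
uniform long gaps (31–365 days); dates live on an integer-day axis because
the method consumes only day differences. Event tables are tied to the
covariates — an active binary covariate plants its diagnosis code within
two years of discharge, each continuous covariate drives the abnormal-lab
intensity of one lab code in both lab windows, and note tokens follow a
Zipf distribution whose head shifts toward a 20-word high-risk
sub-vocabulary as the risk score grows, so bag-of-words features carry
signal. The true per-admission probability is stored alongside the records
for testing only and is never visible to the feature extractor.

What the generator does *not* emulate: real ICD-9/ATC semantics, clinically
plausible individual trajectories, free text (tokens only), informative
missingness, or secular drift across facilities. Passing tests therefore
demonstrate that the pipeline recovers structure it is pointed at — not
that the shipped defaults would reach any particular accuracy on real EMR
data, where published AUCs for this task sit near 0.7.

## Numerical choices and degenerate inputs

- Constant columns min–max scale to all zeros; held-out values outside the
  training range clip into [0, 1].
- KL smoothing `eps = 1e-9` per cell; 10 equal-width histogram bins.
- Softmax logits are max-shifted before exponentiation; softplus is
  linearized above 30 to avoid overflow.
- Training aborts with a diagnostic (suggesting a smaller learning rate)
  if the loss goes non-finite; zero epochs return the parameters unchanged.
- Degenerate single-class labels error in the KL filter, the logistic
  baseline, and `roc_curve()`.
- Note features are keyed to the admission a note belongs to rather than
  re-windowed by note date; in particular the social-history window
  ("penultimate to admission date") collapses to that admission linkage —
  an interpretation, since the exact window is not recoverable from the
  source description.

## Problem sizes used by the test suite

The suite exercises the stack at deliberately small scale: gradient checks
on a p = 5, m = 4, K = 3 network; the model-ordering experiment on a
seeded XOR-plus-linear cohort of ≈ 3500 eligible admissions with p = 20
covariates (DUNs K = 3, m = 32 tanh vs maxout 2 × 32 with 3 pieces vs
ridge logistic, mean 5-fold AUC over 5 seeds — mirroring the tuned depth
relation in which the unified network is the deepest model); rate
calibration on a 10,000-patient cohort; weight recovery on ≈ 20,000
noise-free admissions; and an end-to-end pipeline (generate → label →
featurize → cross-validate a small DUNs → cost summary) on ≈ 5000
admissions.

## Known limitations

The architecture is a reconstruction (see above); the attention
parameterization in particular could differ from the original. The KL
filter's bin scheme for continuous variables is a package choice. The
package does not implement mortality censoring, payer-specific planned
readmission algorithms, de-identification, or terminology services, and
the gradient-boosting baseline is intentionally a wrapper, not a
reimplementation.
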