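# readmitnet

Risk prediction for 30-day hospital readmission from electronic medical
record (EMR) data, built around **deep unified networks (DUNs)** — a
mesh-like feed-forward architecture for tabular clinical data — with the
full modelling stack around it: cohort labeling, windowed feature
extraction with bag-of-words note features, total-KL-divergence variable
filtering, maxout / logistic-regression / gradient-boosting baselines,
threshold-sweep ROC evaluation under stratified k-fold cross-validation,
and a telemonitoring cost-savings model. A seeded synthetic EMR cohort
generator makes every stage testable without protected health data.

## The model

With admission feature vector $x \in [0,1]^p$, DUNs stack $K$ *data units*
produced by *harmonizing units* that fuse the raw input with the previous
layer,

$$h_1 = \sigma(V_1 x + c_1), \qquad h_k = \sigma(U_k h_{k-1} + V_k x + c_k),$$

weight them with a per-sample *attention unit* on the probability simplex,
$a(x) = \mathrm{softmax}(W_a x + b_a)$, and pass the mixture
$z = \sum_k a_k(x) h_k$ through a single *decision unit*,
$\hat y = \mathrm{sigmoid}(w \cdot z + b)$. The stack is vertically deep
but horizontally shallow — two hops from any data unit to the output — and
the attention weights show, per admission, how much nonlinearity the
prediction used. Training is mini-batch SGD with momentum on binary
cross-entropy, with inverted dropout; all gradients are derived
analytically and checked against finite differences in the test suite.

Candidate admissions are scored at discharge. An admission is labeled with
a 30-day readmission when the patient's next countable admission starts
within 30 days of its discharge; planned admissions, transfers, and
discharges against medical advice are excluded from counting. The
operating threshold is chosen on the ROC curve either at the point closest
to the ideal corner ($\min \sqrt{FP^2 + (1-TP)^2}$) or at the point
maximizing projected program savings
$C_r \cdot TP \cdot r - C_p \cdot PP$ (defaults: readmission cost
$C_r = \$9655$, program cost $C_p = \$1500$, response rate $r = 50\%$).

See `vignettes/readmission-risk-methods.Rmd` for the full methods account.

## Worked example

```r
library(readmitnet)

cfg    <- cohort_config(n_patients = 1000, seed = 42)
cohort <- generate_cohort(cfg)
labeled <- label_readmissions(cohort)
summ    <- cohort_summary(labeled)

feats <- extract_features(cohort, labeled)
x     <- encode_and_scale(feats$data)
kl    <- total_kl_divergence(x, feats$labels)

net    <- duns_config(n_layers = 3, n_neurons = 32, activation = "tanh",
                      dropout_input = 0.05, dropout_inner = 0.05,
                      n_epochs = 10, seed = 1)
report <- kfold_cv(duns_factory(net), feats$data, feats$labels,
                   k = 5, seed = 7, kl_filter = TRUE)
savings <- savings_summary(report, cost_params())
```

This prints, in order:

```
Synthetic EMR cohort: 1000 patients, 2332 admissions
30-day readmission rate: 23.4% (490 of 2092 countable admissions)
Total KL divergence filter: kept 137 of 1515 variables (threshold 0.01381)
5-fold cross-validation (mean ± sd):
  auc       0.629 ± 0.030
  accuracy  0.631 ± 0.008
  precision 0.333 ± 0.009
  recall    0.573 ± 0.052
  f1        0.421 ± 0.020
max net savings: $48052 +/- 18404 per fold (accuracy there: 73.5%)
```

The generator hit its calibrated 23.3% readmission-rate target (23.4%
realized at this cohort size); the supervised KL filter cut 1515 encoded
variables down to 137, refit inside each training fold during
cross-validation; a small 3-layer DUNs then separates held-out readmissions
at AUC ≈ 0.63 on this 1000-patient cohort — the synthetic risk signal is
deliberately modest — and sweeping the savings equation along each held-out
fold's ROC curve locates the enrollment threshold that maximizes projected
net savings, with the classification accuracy at that threshold.

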