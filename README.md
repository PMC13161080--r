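# tsnaffect

Predicting student affective state from passively sensed behavior.

Periodic mental-health surveys catch distress late. Passive sensing —
accelerometer activity states, microphone acoustic states, Wi-Fi location
traces, internet session logs — tracks the behavioral correlates of affect
continuously. `tsnaffect` implements a two-phase method over
StudentLife-style sensing streams for researchers in digital phenotyping
and campus mental-health analytics:

1. **Feature extraction + association screening.** Per-student behavioral
   aggregates — routine-regularity entropy
   `R_f = (T_d/D) · (−Σ p_i ln p_i)` over 30-minute activity bins, mean
   morning-onset time `R_wh`, Wi-Fi co-location social-episode count,
   mean daily online time `R_dt` (weekday/weekend), mean adjusted
   last-logout `R_nt` (01:00 counts as 25:00 on the previous day), and
   daily traffic `R_fr` — are discretized with **exact Jenks natural
   breaks** (dynamic programming, not heuristics) and mined with
   **Apriori** for rules linking behavior classes to affect levels.
2. **Temporal sensitive network (TSN).** A compact classifier embeds each
   day's feature vector, scores history days with a tanh attention head
   (`I_k = tanh(W_d S_k + b_d)`, softmax to weights `α_k`), pools them
   into a long-term habit `L = Σ α_k S_k`, and fuses it with the
   short-term state `S` through a learned gate
   `G = σ(W_e S + W_f L + b_g)`, `P = G ⊙ S + (1 − G) ⊙ L`, ending in a
   4-class softmax over the valence–arousal quadrants of the Photographic
   Affect Meter (1 high stress, 2 depressive mood, 3 calmness, 4 high
   energy). Training is Adam + cross-entropy with early stopping; the
   backward pass is hand-derived and finite-difference verified.

A seeded synthetic cohort generator with planted behavior–affect rules
("high entropy + late logout → stress risk", "low social contact + late
onset → depressive risk") makes every stage testable without real data.
Evaluation ships student-grouped stratified k-fold CV, support-weighted
metrics, paired t-tests, the four-variant ablation, and a latent-dimension
sweep.

## Worked example

```r
library(tsnaffect)

spec   <- cohort_spec(n_students = 40, n_days = 30,
                      rule_strength = 0.8, noise = 0.1, seed = 42)
cohort <- generate_cohort(spec)
fx     <- extract_features(cohort$streams)

mined <- mine_rules(fx$students, min_support = 0.15, min_confidence = 0.5)
subset(mined$rules, antecedent %in% c("r_f=High & r_nt=High",
                                      "r_wh=High & social=Low"))
#>              antecedent consequent support confidence     lift
#>  r_wh=High & social=Low    level=2   0.225        0.9 3.272727
#>    r_f=High & r_nt=High    level=1   0.200        0.8 4.000000
```

Both planted rules are recovered: 22.5 % of students are late-onset,
low-social *and* labeled depressive-mood, and among all late-onset
low-social students 90 % carry that label — 3.3× the base rate (lift).
Confidences sit near the planted `rule_strength` of 0.8.

```r
daily   <- build_daily_vectors(fx$daily)
samples <- build_samples(daily, attr(daily, "feature_cols"), t_window = 3)
samples
#> <tsn_samples> 1080 samples, 40 students, T = 3, 6 features
#>   level counts: 237/296/287/260

fit <- tsn(samples, "full", tsn_config(d = 32, max_epochs = 60,
                                       patience = 10, seed = 1))
fit
#> <tsn> variant 'full', d = 32, T = 3
#>   trained 29 epochs (best 19), train n = 971, val n = 109
#>   best validation loss 0.7054

plan <- stratified_kfold(samples$y, k = 5, seed = 1,
                         groups = samples$student)
run_cv(samples, plan, "full", tsn_config(d = 32, max_epochs = 60,
                                         patience = 10, seed = 1))
#> <cv_result> variant 'full' over 5 folds
#>   accuracy     0.802 +/- 0.078
#>   precision_w  0.838 +/- 0.048
#>   recall_w     0.802 +/- 0.078
#>   f1_w         0.797 +/- 0.081
```

Held-out accuracy of 0.80 against a 0.25 chance level, on *unseen
students* (folds are grouped by student so sliding windows never leak
identity across the split). `predict(fit, samples, type = "trace")` and
`attention_report()` expose the per-day attention weights and gate
activations behind any prediction; `plot(fit)` shows the loss trajectory,
and `run_ablation()` / `sweep_dimension()` reproduce the variant table and
the accuracy-versus-`d` curve.

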