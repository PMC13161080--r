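---
title: "Predicting student affect from behavioral sensing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting student affect from behavioral sensing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsnaffect)
```

## The problem

Campus mental-health screening by periodic questionnaires misses the onset
of distress between surveys. Digital phenotyping offers a complement:
passively sensed behavior — movement, acoustic environment, location, and
internet use — carries signal about affective state. `tsnaffect`
implements a two-phase pipeline over StudentLife-style sensing streams:

1. **Feature engineering and association screening.** Six behavioral
   aggregates are extracted per student, discretized with exact Jenks
   natural breaks, and mined with Apriori for association rules linking
   behavior classes to affect levels. The rules act as an interpretable
   screen for which features carry signal.
2. **Temporal sensitive network (TSN).** A small neural classifier maps a
   window of daily behavior vectors to one of four affect levels (the
   valence–arousal quadrants of the Photographic Affect Meter, PAM),
   fusing an attention-pooled *long-term habit* representation with the
   *short-term state* of the most recent day through a learned gate.

Everything runs on plain CSV streams, and a seeded synthetic cohort
generator with planted behavior–affect rules makes the whole pipeline
testable without access to a real sensing study.

## Behavioral features

All wall-clock logic uses a single fixed UTC offset (the data are from one
campus; no time-zone database is involved), and logical days are the
half-open intervals `[00:00, 24:00)` — a record exactly at midnight
belongs to the later day. A student-day enters the analysis only if the
union of spans covered by its accelerometer and Wi-Fi records (spans break
at gaps longer than 10 minutes) reaches 6 hours; days below that are kept
only as imputation context. Missing per-day metrics are median-filled from
the student's valid days; categorical day states are forward-filled.

**Routine regularity (`r_f`).** The 06:00–22:00 window is cut into 30-minute
bins. Each non-stationary accelerometer record (Walking/Running) and each
Wi-Fi location transition is one activity event. Pooling a student's valid
days gives a bin distribution $p$, and

$$R_f = \frac{T_d}{D}\left(-\sum_{i=1}^{n} p_i \ln p_i\right),$$

where $D$ counts valid sensing days and $T_d$ the whole observation span.
Concentrated routines give low entropy; the $T_d/D$ factor inflates the
score when participation is sparse, so "irregular" and "barely observed"
both push the score up. Two bin-count conventions circulate for this
window: 06:00–22:00 at 30 minutes yields $n = 32$ bins, while the
commonly quoted $n = 48$ corresponds to binning the full day. The package
defaults to the stated wall-clock window (32 bins) and offers
`binning_scheme(0, 24, 30)` for the 48-bin variant; entropies are in nats
(natural log), the usual convention for this form.

**Morning onset (`r_wh`).** The day's onset is the earlier of (i) the start
of the first run of non-stationary activity sustained for 5 minutes
(interruptions up to 60 s tolerated) and (ii) the first Wi-Fi record away
from the student's nighttime residence cluster — the modal location over
00:00–05:00 scans, ties broken lexicographically. `r_wh` is the mean onset
in seconds-of-day over days where either criterion fires; "normalized
timestamp" is read as seconds-of-day, which keeps the unit interpretable
(07:30 = 27 000 s).

**Social interaction.** A social episode is a temporal intersection of two
students' Wi-Fi location segments (runs of identical consecutive location
ids, closed by a location change or a 10-minute stale gap, extended by
half the median scan interval) that survives four fidelity filters: at
least 5 minutes long; at least 3 Wi-Fi scans per participant inside the
overlap; at most 50 % `Unknown` microphone labels for any participant with
microphone data there; and at least one `Speaking`/`Noisy` record from
either side. Candidate pairs are found through a (location id, 15-minute
bucket) hash index rather than an all-pairs scan, so cohort-level cost is
near-linear in the total number of segments; the tests verify exact
agreement with a brute-force all-pairs oracle. The per-student feature is
the episode count over valid days.

**Internet usage.** Session duration is averaged per observed *day* (not
per session), separately for weekdays and weekends — the metric is mean
daily online time. Late-night behavior uses a logical day shift: a logout
between 00:00 and 05:00 extends the previous day (01:00 becomes 25:00 =
90 000 s), and `r_nt` is the mean shifted time of each day's final logout.
`r_fr` is mean daily traffic in MB. The weekday/weekend split applies to
duration only; the late-night and traffic metrics pool all days.

## Phase 1: discretization and rule mining

`jenks_breaks()` computes the exact optimum of the within-class sum of
squared deviations (SDCM) over all contiguous partitions of the sorted
sample, by dynamic programming with prefix-sum segment costs — not the
usual heuristic reseeding. Ties break toward the smaller upper class, so
results are deterministic; reported breakpoints are midpoints between
boundary values, and `gvf = 1 − SDCM/SDAM` summarizes fit. Tests check
equivalence with exhaustive enumeration for every input up to length 12.

Each student becomes one mining transaction: a `"feature=Class"` token per
aggregate feature (default three classes, Low/Medium/High) plus a single
label token — the student's modal daily affect level, ties toward the more
severe level. `apriori()` enumerates frequent itemsets level-wise with
downward-closure pruning and exact rational supports; `generate_rules()`
keeps only rules whose consequent is a label token. The canonical
thresholds are support 0.5 and confidence 0.5; both are arguments, since
planted-rule studies on four-level cohorts need a lower support floor (a
rule's support cannot exceed its level's prevalence). `select_features()`
turns surviving rules into an advisory feature shortlist.

## Phase 2: the temporal sensitive network

Each day's six-feature vector is standardized (training-split statistics
only — the fit object stores the centering so held-out data never leaks
into the scaling) and embedded by a shared affine-tanh map into
$\mathbb{R}^d$. For a sample predicting day $t$, the history block holds
days $t-T, \dots, t-1$ and the short-term state $S_u$ is the embedded day
$t$ (configurable to a mean over the last few days; the horizon is a
package choice, defaulting to 1). Then

$$I_u^k = \tanh(W_d S_u^k + b_d), \qquad
  \alpha_u^k = \frac{e^{I_u^k}}{\sum_j e^{I_u^j}}, \qquad
  L_u = \sum_k \alpha_u^k S_u^k,$$

$$G_u = \sigma(W_e S_u + W_f L_u + b_g), \qquad
  P_u = G_u \odot S_u + (1 - G_u) \odot L_u,$$

with a final affine-softmax layer over the four levels trained by
cross-entropy. The softmax over days requires scalar scores, so $W_d$ is a
single row; the alternative (vector scores with a learned context vector)
adds parameters without an identified benefit at this scale. The attention
sum gives every history day a direct gradient path into the loss, and the
gate lets the model interpolate continuously between "trust the habit"
($G \to 0$) and "trust today" ($G \to 1$).

Training uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), learning rate $10^{-3}$, shuffled minibatches of
64, at most 300 epochs, early stopping on a stratified 10 % validation
split with patience 20 and best-weight restoration. Initialization is
uniform scaled by $1/\sqrt{\text{fan-in}}$. Every stochastic step (init,
shuffling, split) derives from the config seed, so trajectories are
bit-reproducible on one platform. The backward pass is derived by hand and
verified against central finite differences to below $10^{-4}$ relative
error; probabilities are clamped at $10^{-12}$ before the log. Class
weighting is available behind a flag but off by default — plain
cross-entropy already penalizes confident mistakes on minority levels.

Four ablation variants share one interface: `baseline` (short-term only),
`baseline_ltm` (concatenation with a uniform $1/T$ history mean),
`baseline_fm` (gate over the uniform mean), and `full` (attention plus
gate).

### Key tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 32 | latent dimension; the sweep utility covers 8–256 |
| `t_window` | 3 days | history length feeding attention |
| `short_term_span` | 1 day | days averaged into $S_u$ |
| `lr`, `batch` | 1e-3, 64 | Adam step and minibatch size |
| `max_epochs`, `patience` | 300, 20 | epoch cap and early-stopping patience |
| `min_hours` | 6 h | coverage floor for a valid student-day |
| `min_support`, `min_confidence` | 0.5, 0.5 | mining thresholds |

## Evaluation harness

`stratified_kfold()` does per-class round-robin assignment after a seeded
shuffle, so fold class counts stay within one unit of balance. By default
folds are **student-grouped**: sliding windows from one student never span
folds. Plain "stratified 5-fold" over windows would leak identity — a
student's adjacent windows share most of their days — so grouping is the
honest default, and it makes held-out accuracy a claim about *unseen
students*; a flag restores sample-level stratification. Metrics are
support-weighted precision/recall/F1 plus accuracy, reported fold-wise as
mean ± sd, and variant comparisons use the classical paired t-test on
per-fold differences (zero-variance differences are flagged as degenerate
rather than silently producing `NaN`).

## The synthetic cohort generator

`generate_cohort()` realizes four behavioral archetypes, one per affect
level: *anxious-irregular* (dispersed activity, post-midnight logouts →
level 1), *withdrawn* (few co-location episodes, late onset → level 2),
*healthy-regular* (concentrated routine, early onset, sociable → level 3),
and *high-energy* (very active and sociable → level 4). The first two
mirror the mined rule structure — high entropy + late logout → stress risk;
low social contact + low diligence → depressive risk — and the other two
populate the remaining levels so stratified CV is well-defined.

Per student, a symmetric Dirichlet draw (concentration = the archetype's
`activity_concentration`; small values concentrate mass in few bins, large
values disperse it) fixes the bin distribution of scattered walking
events; a sustained morning walk and a Wi-Fi departure from a personal
home cluster realize the onset; co-location episodes are synchronized
scans of both participants at a shared fresh location id with `Speaking`
records from one side, laid on a half-hour grid so one student's episodes
never interleave; sessions have log-normal durations (capped at 4 h),
gamma traffic, and a Gaussian final-logout hour that may cross midnight.
Labels are planted per student: with probability `rule_strength` the
student conforms to their archetype's level, otherwise a random other
level is substituted; each day's label then flips with probability
`noise`. Consequently the *daily* frequency of an archetype's level is
about `rule_strength · (1 − noise)`, while the *student-level* mining
confidence sits near `rule_strength` (the modal label washes out daily
noise). Session-duration and traffic distributions are chosen for
positivity and right skew, not fitted to any real dataset.

What the generator does **not** emulate: sensor dropout and battery gaps,
within-day label drift (labels are day-constant up to noise), shared
public locations (non-episode scans use personal location ids, so
co-location precision is exact by construction), behavioral
autocorrelation beyond the archetype, and any attempt to match real
StudentLife marginals. Passing the planted-signal tests therefore shows
the pipeline recovers structure it is pointed at — not that real-world
accuracy would match.

## Validation scale and numerical choices

The checks in `tests/` and `scripts/acceptance.R` run at sizes chosen to
exercise the full method while staying desk-scale: oracle equivalences use
≥ 500 Jenks cases (length ≤ 12), ≥ 200 Apriori transaction sets (≤ 6
items), and ≥ 100 random co-location cohorts (≤ 10 students); the
planted-signal study uses 200 students × 60 days with `rule_strength`
0.8 and `noise` 0.1, student-grouped 5-fold CV at `d = 32`, and a 60-epoch
cap with patience 10 (the validation loss plateaus well before that at
this sample size). Degenerate inputs are defined rather than left to
chance: zero activity events give `r_f = 0` with a warning; a student with
no nighttime scans simply loses onset criterion (ii); all-zero confusion
matrices and sub-`k` classes raise errors; Jenks ties break toward the
smaller upper class; values at a breakpoint go to the lower class.

## Limitations

Affect labels are self-reported momentary states, not clinical outcomes;
the four-level PAM discretization ships as an explicit, overridable lookup
because the instrument's exact score-to-quadrant table is a protocol
detail. The feature set is deliberately small and interpretable; richer
modalities (GPS, app-level logs, Bluetooth) are out of scope. The network
is intentionally compact — its value is the attention-plus-gate structure,
not capacity — and all conclusions from synthetic cohorts carry the
caveats listed above.
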