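---
title: "Methods: studying foundation-model adaptability across hospital sites at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: studying foundation-model adaptability across hospital sites at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package studies

Structured-EHR foundation models are decoder-only transformers pretrained
with a next-code objective: a patient's record is a time-ordered sequence
of clinical codes $X = (x_1, \dots, x_n)$, and the model is trained to
predict $x_{t+1}$ from the prefix, exactly as in GPT-style language
modelling. Once pretrained, the model is used as a *frozen feature
encoder*: the hidden state summarizing a patient's history up to a
prediction time, $R = f_\theta(X)$, feeds a small supervised head (a
linear probe) for each clinical prediction task.

The question the package operationalizes is whether such a model
pretrained at one hospital transfers to another: used off the shelf, or
adapted by *continued pretraining* (resuming the same self-supervised
objective on the new site's records), and how these options compare with
training conventional baselines — gradient-boosted trees on count
features — or a local foundation model from scratch. The three
experiment families are (1) an overall comparison with a cross-site
ablation, (2) a few-shot label-efficiency grid, and (3) pretraining
sample-size (subsample) curves. All of it runs at desk scale on
synthetic two-site data with known generative structure, so every
quantitative claim in the test suite has a computable oracle.

## The synthetic two-site EHR generator

Each patient carries a day-granular latent health state (4 states,
"healthy" through "critical") evolving as a first-order Markov chain.
Each admitted day the state emits Poisson-many coded events from a
site-specific categorical distribution and lab events with
state-dependent Gaussian values; at day end the stay terminates through
state-dependent discharge and death hazards; discharged patients may be
readmitted within 30 days with a probability depending on their last
state. Outcomes are therefore *emergent* — a hypoglycemia label exists
because a generated glucose value crossed 3 mmol/L inside the outcome
window — never painted-on labels, so the cohort-labelling code is the
single source of truth for both synthetic and real data.

Key design choices:

* **First-order, day-granular latent dynamics.** This buys closed-form
  oracles: task prevalences conditional on the cohort's eligibility and
  exclusion rules are computed exactly by iterating the chain with its
  hazards and crossing probabilities (`analyticTaskRates()`), code
  marginals and entropies analytically (`analyticCodeMarginals()`,
  `analyticEntropies()`). The test suite checks the generator against
  these oracles with exact binomial intervals, and checks the
  transformer's converged loss against the entropy sandwich.
* **A sticky chain.** Self-transition probabilities are high
  (0.70–0.92/day), so the admission-day state strongly shapes the rest
  of the stay. This is what makes outcomes predictable from history
  available at the prediction time — the analogue of chronic severity in
  real inpatient populations. With a fast-mixing chain, outcomes several
  days out are nearly independent of everything observable at
  prediction time and every model collapses toward AUROC 0.5.
* **Two sites with a material but survivable shift.** Sites share 72
  "core" diagnosis codes plus the lab codes (over 80% of each site's
  vocabulary) and own 18 exclusive codes each; shared-code frequencies
  are tilted in opposite directions on a log scale (±0.6), and the
  initial-state mix differs (site A pediatric-like and healthier, site B
  adult/ICU-like and sicker). Site-exclusive codes are state-neutral —
  administrative/coding-practice codes that shift the marginal without
  carrying patient-state information — so cross-site vocabulary drops
  cost information only through sequence shortening, not label signal.
  The default configuration yields an analytic total-variation distance
  between site code marginals of roughly 0.43.
* **Outcome skew.** Hazards and lab means were chosen once so the eight
  task prevalences span roughly 1.5%–30% across the two sites, with the
  sicker site higher on every task — the kind of skewed, site-dependent
  prevalence profile multi-center inpatient studies report.
* **Scale.** The default site size is 2,000 patients
  (`synthConfig()`), and the benchmark plan (`experimentPlan()`) uses
  1,500 per site so that a full five-replicate study fits in minutes on
  one CPU. These are the package's study conditions; tests that need
  tighter binomial intervals generate 5,000-patient populations.

What the generator does *not* emulate: real clinical semantics of
individual codes, irregular visit cadence, measurement artifacts,
informative missingness, or temporal non-stationarity. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that
its comparative claims hold under a controlled, favourable shift — not
that the same margins would appear on any particular pair of hospitals.

## Cohort, tasks and splits

Admissions are eligible if the patient meets the site's age floor (28
days for the pediatric-like site, 18 years for the adult-like site) and
the stay did not end before the earliest prediction time. One admission
per patient is selected uniformly at random. Eight binary tasks are
labelled: in-hospital mortality, long length of stay (≥ 7 days), 30-day
readmission, and five abnormal-lab tasks with strict thresholds (glucose
< 3 mmol/L, sodium < 125 mmol/L, potassium > 7 mmol/L, hemoglobin
< 70 g/L, platelets < 50×10⁹/L; boundary values never fire). The
prediction time is midnight closing the admission day — implemented
exactly as 00:00 of the following calendar day on an integer-minute
timeline — except readmission, which predicts at midnight closing the
discharge day with a 30-day post-discharge window. Admissions whose
outcome occurred before the prediction time are excluded from that task;
for readmission this also removes in-hospital deaths, which precede the
prediction time by construction (we label post-discharge death-free
non-readmissions 0 rather than censoring). Events timestamped at or
after the prediction time are excluded from model input (strict `<`),
avoiding label leakage. Readmission is ascertained against *any* later
admission, including ones not selected into the cohort.

Patients are split 70/15/15 into global train/validation/test folds by
largest-remainder rounding over a seeded permutation; task-specific
folds inherit the patient's global fold, so no patient ever appears in
two folds of any task.

## The miniature foundation model

`pretrainFM()` trains a decoder-only transformer with pre-LayerNorm
residual blocks, learned positional embeddings, GELU feed-forward
layers, and *causal sliding-window attention*: position $i$ attends to
positions $[\max(1, i-w+1), i]$. The local window is the configurable
reading of a "local attention mechanism"; the benchmark uses $w = 16$
with 2 layers and hidden size 32 (the package default `fmConfig()` is
2×64). Numeric lab values are not tokenized — codes only enter the
stream; values drive labels. Long histories are chunked to
`max_seq_len` for pretraining and truncated to the most recent
`max_seq_len` tokens for encoding, on the view that
prediction-time-adjacent history matters most.

Optimization is Adam with global gradient-norm clipping, a fixed token
budget per step (so "steps" are optimizer updates of comparable size),
early stopping when validation loss has not improved for `patience`
steps, and return of the best-validation checkpoint. The learning rate
is selected from `lr_candidates` by validation loss (default grid
1e-3/3e-4/1e-4; the benchmark fixes 1e-3 to keep five replicates cheap).
The implementation is hand-written RcppArmadillo with manual
backpropagation; tests verify the analytic gradients against finite
differences at 1e-4 relative tolerance and verify causality by
perturbing future tokens.

Continued pretraining (`continuePretrainFM()`) resumes the same
objective from the parent's parameters on a new corpus tokenized with
the *parent's vocabulary* (inherited, never rebuilt — so codes unknown
to the parent are dropped, reproducing the reduced cross-site code
coverage phenomenon), with a fresh optimizer state and the same early
stopping.

Representations are the final-LayerNorm hidden states. The package
exposes both the last-token state and the mean over positions
(`representation = "last"` / `"mean"`); the benchmark uses mean pooling.
With a hidden size this small and desk-scale pretraining, the last-token
state is dominated by the identity of the final token and is too noisy
for k≤64-shot probes, while mean pooling aggregates state evidence over
the whole window; at full scale the distinction matters much less. An
empty tokenized history encodes to the zero vector.

## Task heads

The baseline is the conventional count featurization — per-code event
counts over the full observation window plus age in days and a sex
indicator, with the code feature space restricted to codes seen in the
task training fold — feeding a gradient-boosted tree classifier
(xgboost). The tuning grid crosses learning rate {0.1, 0.03}, leaf count
{15, 31} and the boosting-algorithm variant {gbtree, dart} — the
"optimization algorithm as a hyperparameter" axis — each with
early-stopped rounds (≤ 500) on the task validation fold, selected by
validation log loss. No time-binning, ontology rollup, or class
reweighting is applied anywhere; prevalences stay skewed and tuning is
plain log loss.

The foundation-model heads are L2-regularized logistic probes on frozen
representations, minimized by L-BFGS with the intercept unpenalized;
the inverse-regularization grid C ∈ {0.01, 0.1, 1, 10} (penalty
$\tfrac{1}{2C}\lVert w\rVert^2$) is selected on the validation fold by
log loss. A training fold containing a single class yields a flagged
constant-rate head. Hyperparameters never see the test fold.

## Few-shot protocol

For k in an ascending powers-of-two grid (the full design is
2–1024; the benchmark uses {16, 64}), each iteration draws k/2 positives
and k/2 negatives without replacement from the task training fold. When
only $k_p < k/2$ positives exist, all $k_p$ enter and negatives fill the
draw back to k — keeping k the draw's total size; the alternative
reading (fill only to k/2) is available as `fill = "to_half"`. The
validation fold is never subsampled. Per-cell seeds derive
deterministically from (seed, task, k, iteration). Crucially, the
continued checkpoint used for few-shot features is retrained with every
task-train patient removed from its adaptation corpus, so pretraining
never sees few-shot candidates' records; the leakage audit enforces
this. Because balanced sampling distorts the base rate, predicted risks
are mapped back to the deployment prevalence before calibration is
measured, using
$$p' = \frac{p}{p + (1-p)\,(1-b')/b'},$$
with $b'$ estimated as the task training-fold prevalence. The map fixes
0 and 1, is the identity at $b' = 0.5$, and is inverted exactly by
swapping the roles of $b'$ and the balanced prior.

## Evaluation and inference

Discrimination is AUROC with midrank tie handling (verified against
exhaustive pair counting). Calibration is expected calibration error
over 10 quantile bins of predicted risk (type-7 quantile edges;
duplicate edges from tied risks are merged; if all risks fall in one
bin the degenerate value $|\bar p - \bar y|$ is returned).

Model comparisons use a hierarchical bootstrap: each replicate resamples
tasks with replacement (the outer "outcomes" level), then patients with
replacement within each resampled task, and recomputes the mean metric
difference; 1,000 replicates by default (500 in the benchmark plan), CI
from the 2.5/97.5 percentiles, and a two-tailed p-value equal to twice
the smaller tail proportion of replicate differences around zero
(replicates exactly at zero count half in each tail; capped at 1). The
flat patient-only variant is available via `nested = FALSE`, and is also
what a single-task comparison degenerates to. Within-resample AUROC
requires both classes; degenerate resamples are redrawn. The test suite
checks type-I error of the patient-resampling p-value at the nominal 5%
level (within ±2 points over 500 null simulations) and power against a
0.15 AUROC gap at n = 2,000. One property of the nested variant worth
knowing: resampling tasks treats the task set as drawn from a population
of outcomes, so with only a handful of homogeneous tasks the resulting
p-values are *conservative* (null rejection well below 5%); type-I error
is controlled, and the scheme pays for its robustness to between-task
heterogeneity with power when tasks are exchangeable.

## The benchmark and its directional claims

`runBenchmark()` executes the full study once per seed: generate both
sites; build cohorts, labels and splits; pretrain local models on each
site's global training fold; continue-pretrain each model on the other
site; evaluate per-task AUROC/ECE of every arm on the test folds; run
the few-shot grid (FM⁺ probes vs full-grid count-GBM, on the four most
prevalent tasks so balanced draws at k = 64 are fillable); and run the
subsample curves (continued arms at fractions {0.05, 0.2, 1} of the
adaptation site's training patients, against the fully trained local
model). Its three directional indicators, each required in at least 4
of 5 seeded replicates, are the toy analogues of the study's headline
findings:

* (a) continued pretraining does not hurt — the adapted external model's
  mean test AUROC is at least the off-the-shelf external model's,
  averaged over both transfer directions;
* (b) in the few-shot regime (k ≤ 64), FM⁺ linear probes beat the
  fully tuned count-GBM's mean AUROC;
* (c) continued pretraining reaches the from-scratch local model's mean
  AUROC using a strictly smaller fraction of pretraining patients.

An automated leakage audit runs with every benchmark: no test- or
validation-fold patient may appear in any pretraining corpus, task folds
must be patient-disjoint, and few-shot checkpoints must exclude
task-train patients; corrupted provenance makes the audit fail loudly.

## Numerical and degenerate-input conventions

Timestamps are integer minutes from the Unix epoch (UTC), making
"midnight" arithmetic exact. Vocabulary ties at equal counts break
lexicographically by code string. LayerNorm uses ε = 1e-5; training
aborts with a diagnostic on non-finite loss; sequences shorter than two
tokens carry no training signal and are dropped. The probe clips
probabilities only inside log-loss computations (1e-12), never in
reported predictions. Bootstrap replicates that cannot produce a
two-class resample after 1,000 attempts are dropped from the replicate
set. Single-bin ECE, empty-history representations, single-class
training folds, and fraction-1 subsample arms all have the documented
behaviours above rather than errors.

## Known limitations

The generator's latent process is far simpler than real EHR dynamics;
the transformer is orders of magnitude smaller than production
foundation models, and the absolute AUROC levels (≈0.6–0.8) reflect the
synthetic ceiling, not clinical performance. The directional indicators
are majority-vote claims over five replicates at desk scale, with
margins of a few AUROC points; they demonstrate the machinery and the
direction of the effects, not their real-world magnitude. Wall-clock
efficiency comparisons between continued and from-scratch pretraining
are out of scope, as are fairness analyses, ontology harmonization, and
fine-tuning of foundation-model parameters (probes only).
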