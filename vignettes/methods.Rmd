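---
title: "Model, losses and protocols in mmdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, losses and protocols in mmdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdx)
```

## The problem

Differential dementia diagnosis asks, for one person at a time, which of
thirteen partially co-occurring diagnostic statements hold: normal cognition
(NC), mild cognitive impairment (MCI), dementia (DE), and — when dementia is
present — any of ten contributing etiologies (AD, LBD, VD, PRD, FTD, NPH,
SEF, PSY, TBI, ODE). Real clinical cohorts are radically incomplete: a
memory-clinic visit may carry a full neuropsychological battery but no MRI,
a population study may carry little beyond demographics, and many subjects
were simply never assessed for particular etiologies. `mmdx` implements a
model family built around that incompleteness rather than around imputation:
missing features are masked out of the computation entirely, and missing
labels are masked out of the loss.

## Model

Each catalog feature is embedded into a `d_model`-width token by a
modality-specific map: a single linear layer for standardized numeric
values, a lookup table for categorical codes (one independent row per
code), and, for imaging, a linear projection of a precomputed embedding
vector. A learnable downsampling adapter (four convolutional blocks — two
stride-2 kernel-2 convolutions collapsing a 768-channel 4×4×4 encoder grid
to a single position, then two 1×1×1 blocks) reduces an external encoder's
output grid to a 256-vector; the encoder itself (a pretrained 3D
transformer over skull-stripped volumes) is deliberately outside the
package and is treated as a pluggable producer of grids or vectors.

The tokens form an unordered set — there is no positional encoding, because
features are identified by their own embedding parameters and the input has
no meaningful order. A transformer encoder (pre-normalization layers,
multi-head self-attention, ReLU feed-forward blocks) aggregates the set. A
learned classification token pools the output by attending to the visible
tokens (a masked mean is available behind `model_config(pooling =
"masked_mean")`), and an affine head maps the pooled state to 13 logits
with elementwise sigmoids — the heads are independent because the labels
are not mutually exclusive (mixed dementia is common).

**Masking is the load-bearing mechanism.** A feature that is missing — or
deliberately dropped during training — contributes a `-Inf` additive bias to
every attention score in which it would serve as key, in every layer, and
is excluded from pooling. No value stored at a masked position can
therefore influence any output; the test suite asserts this as exact
(bit-identical) invariance under arbitrary perturbation of masked values,
for random weights. Masked token slots are zero-filled rather than
NaN-filled so downstream numerics stay finite even though the slots are
contractually unread.

## Training

The loss is `L = L_FL + λ·L_RL + β·‖w‖²` with λ = 0.005 and β = 0.0005.

`L_FL` is a class-balanced focal loss over all subjects and heads, with
focusing exponent γ = 2 and per-label balance weight `α_i = (1 − f_i)²`,
where `f_i` is the positive fraction among known training labels — rare
etiologies get weights near 1. `L_RL` is a pairwise hinge within each
subject: a head labelled 0 must score below a head labelled 1 by a margin
ε = 0.25. Pairs with equal labels contribute the constant ε exactly as the
defining formula reads; the constant carries no gradient, and
`ranking_loss(include_constant = FALSE)` reports the interpretable
constant-free value. Both sums are normalized by the batch size N (default
128), not by the number of unmasked terms — masked terms are zeroed inside
the sum, again following the formulas literally.

Unknown labels are handled by a loss mask: terms (and, for the ranking
loss, pairs) touching an unknown label contribute zero loss and provably
zero gradient (a finite-difference audit is part of the test suite).
Missing-data robustness is trained in by random feature masking: for each
record in each batch, the observed feature set S is permuted, an index i is
drawn uniformly from {1..|S|}, and all but the first i permuted features
are dropped — so the number of surviving features is uniform on {1..|S|}
and at least one always survives. Structural missingness and simulated
dropout compose into one mask; only observed features are ever permuted.

Optimization is AdamW at learning rate 0.001 with a cosine schedule with
warm restarts (first restart after 64 epochs, period doubling), the
default budget being 256 epochs. The L2 term is applied as decoupled
weight decay at rate 2β over exactly the weight set the `‖w‖²` term covers
— all weight matrices, embedding tables and projections and the
classification token, excluding biases and layer-norm parameters — so the
reported loss and the applied regularization agree. Validation is scored
at every epoch end and the best epoch's weights are returned; the
selection metric is the micro-averaged AUROC over the 13 heads (which
specific validation score is maximized was an open choice; micro-AUROC is
the package's default because it is the primary reported metric, and it is
configurable). Probabilities are clamped to [1e-7, 1−1e-7] before logs.
Feature masks are redrawn per batch (the alternative, per epoch, would
merely slow the diversity of masks seen per sample). A non-finite loss
aborts training with the epoch and learning rate in the error message.

Two choices deserve emphasis because the source description leaves them
open. First, pooling: a learned classification token is the default since
it is standard for set-shaped transformer inputs and interacts cleanly
with masking; depth and width (4 layers, 4 heads, feed-forward 4·d_model)
are likewise configuration defaults, not claims about the original
architecture. Second, the imaging adapter sits outside the optimizer:
cohort tables carry precomputed embedding vectors, so the trainable
imaging path is the linear projection; the adapter remains a
deterministic, parameterized module usable for preprocessing encoder
grids.

## Interpretability

Shapley attribution treats each record as a cooperative game whose players
are its observed features and whose payoff is the model output for one
label with a coalition revealed through the attention mask — no surrogate
model, no imputation, no retraining. Permutation sampling averages
marginal contributions over uniformly drawn orderings; it is unbiased, and
with full enumeration it reproduces the exact Shapley value (the tests
check this against a 2^F brute-force computation). Absent features receive
exactly 0. The payoff defaults to the predicted probability
(`payoff = "logit"` is available); the empty coalition is evaluated with
only the classification token active, which makes its payoff a model
constant, identical across records — the consistent completion of the
masking semantics at the empty set. The global ranking protocol for a
diagnostic group filters to cases with positive logit, keeps the `n_cases`
(default 500) with the most observed features (ties broken by subject_id
order), includes the zeros of absent features in the per-feature means,
and ranks descending.

## Evaluation

AUROC uses the midrank convention, making it identical to the
tie-corrected Mann–Whitney statistic; AUPR is step-wise average precision.
Averaging across heads: micro pools all (score, label) pairs into one
curve; macro is the unweighted mean; weighted weights each label by its
positive count. Confusion statistics (accuracy, sensitivity, specificity,
MCC) are computed at a configurable threshold, default 0.5; degenerate
margins yield `NA` rather than 0. Subgroup reports stratify by age bin,
gender and race — metadata that never enters the model unless declared as
features.

The co-occurrence evaluation scores etiology combinations (size ≥ 2) with
at least `min_positive_samples(bound)` jointly positive subjects, where
`ceil(1/(4·bound))` inverts the distribution-free maximum variance `1/(4n)`
of an empirical AUROC; at the default bound 0.01 the floor is 25. A
combination's positives are subjects positive for *all* its labels,
negatives are everyone else, and subjects with an unknown label in the
combination are dropped. How to collapse a multi-label combination's
probabilities into one score was an open choice; the default is the mean
of the member probabilities (min and product are flags), and the report
records which statistic was used.

The missingness sweep re-scores a cohort with whole feature groups masked
(MRI, FAQ, GDS, NPIQ, UPDRS, NP tests, …) and reports per-label AUROC per
scenario; the scenario grid is caller-supplied. Clinician fusion rescales
a 0–100 confidence score by 1/100 and averages it with the model
probability — symmetric and idempotent by construction.

## The synthetic cohort generator

Restricted clinical cohorts cannot ship with a package, so every protocol
above is exercised on simulated data whose *structure* — not whose
marginal distributions — mirrors the real setting. Labels are drawn
hierarchically: cognitive status with prevalences NC 0.35 / MCI 0.25 /
DE 0.40 (a dementia-enriched referral-style mix), then etiologies
conditional on DE (AD 0.60 dominating, as in real registries, down to PRD
0.02), with pairwise co-occurrence boosts (AD∧VD, LBD∧PSY) and the
constraints that every DE case carries at least one etiology and NC cases
carry none. Features follow label-dependent distributions driven by a
single effect matrix on the standardized scale: cognitive scores (MMSE,
MoCA) fall with MCI/DE, functional and behavioural scales (FAQ, NPI-Q,
GDS) rise with DE and specific etiologies, UPDRS rises with LBD, apoe4
loads on AD through a logistic link, and the synthetic MRI embedding
carries DE/AD/VD shifts on its leading block. The dedicated etiology
markers are planted at 2.5–3 standardized units: a single marker at
effect d with unit noise caps the achievable AUROC at Φ(d/√2), so 2 SD
(ceiling ≈ 0.92, further eroded by marker missingness) would leave a rare
etiology undetectable at the ≥ 0.9 level the recovery experiments demand,
while 3 SD (ceiling ≈ 0.98) leaves honest headroom. UPDRS in parkinsonian
dementia and GDS in psychiatric-origin impairment genuinely are elevated
by this order of magnitude. These sizes are deliberately optimistic
relative to subtler real-world signals, so a passing recovery test
demonstrates correctness of the pipeline, not clinical performance. Missingness is MCAR by default (matching how the sweep masks
features irrespective of values; an MAR hook conditioned on labels exists
but is off), with named sparsity profiles — NACC-like 10%, ADNI-like 69%,
FHS-like 94% — reproducing the sparsity contrast between a reference
cohort and external validation cohorts without claiming to reproduce those
cohorts. A subject's last observed feature is never removed, and the
realized rate is logged.

What the generator does *not* emulate: measurement floors/ceilings beyond
simple clipping, site effects, longitudinal structure, label noise, and
informative missingness. Passing tests therefore show that the machinery —
masking, losses, optimization, attribution, metrics — does what it claims
under known conditions; they say nothing about accuracy on real patients.

## Numerical choices and scales

Numeric features are z-scored with training-split statistics frozen at fit
time (affine embeddings are scale-sensitive); constant features
standardize to zero with a unit-sd fallback. Layer norm uses eps 1e-5;
attention scores are scaled by `1/sqrt(d_head)`. Weight init is Xavier for
the backbone, `1/sqrt(d_model)`-scaled normals for embeddings, small
normals for the head. The test and example experiments run at desk scale —
d_model 16–32, 1–2 layers, cohorts of 700–4,000 subjects, 10–48 epochs —
sizes at which the planted-signal cohort is comfortably learnable; the
configuration defaults (d_model 256, 4 layers, 256 epochs) are the
reference settings for full-scale use.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(synthetic_config(n_subjects = 2000, seed = 1))
x <- apply_missingness(sim$cohort, 0.15,
                       label_rates = c(rep(0, 3), rep(0.1, 10)))
ck <- train_model(x[1:1400], x[1401:1700],
                  model_config(d_model = 32, n_layers = 2, n_heads = 2,
                               ff_width = 64),
                  loss_config(),
                  train_config(epochs = 20, seed = 7))
te <- x[1701:2000]
pr <- predict_cohort(ck, te)
metric_report(pr$probs, te$labels, strata = te$strata)
```

## Known limitations

The backbone is pure R; it is fast enough for thousands of subjects and
tens of features, not for hundreds of thousands. Only MCAR missingness is
generated by default, so robustness conclusions transfer to informative
missingness only with care. The imaging encoder is out of scope: the
package consumes its outputs. Exact Shapley enumeration is limited to ten
observed features; beyond that, permutation sampling with its `1/sqrt(n)`
error is the tool.
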