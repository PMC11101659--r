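---
title: "Prototype-based interpretable classification of multimodal lesion images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-based interpretable classification of multimodal lesion images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mupnet)
```

## The model

`mupnet` implements a multimodal prototype network for binary risk
prediction from paired lesion images — the setting is breast ultrasound,
where each lesion is imaged in three modalities (grayscale B-mode, colour
Doppler showing vascularity, and elastography showing tissue stiffness) and
carries a biopsy-confirmed benign/malignant label plus an ordinal BI-RADS
assessment (3, 4a, 4b, 4c, 5). The network is *inherently* interpretable:
every prediction is, by construction, a weighted sum of similarities to a
small set of prototypes, and after training each prototype *is* a latent
patch of a real training image, so the evidence behind a prediction can be
shown to a radiologist as actual prior cases.

The forward computation has four parts.

**Per-modality feature extraction.** One independent convolutional
extractor per modality $m$ maps the image $x^m$ to a latent feature map
$z^m = f^m(x^m; w^m) \in \mathbb{R}^{H_f \times W_f \times C}$. The default
desk-scale backbone is a three-block stack (3×3 convolution, ReLU, 2×2 max
pooling; spatial downsampling 8) followed by a 1×1 "add-on" convolution to
the shared channel count $C = 128$ with a logistic squashing, so latent
features lie in $(0,1)^C$ — the same range on which prototypes are
uniformly initialised. Deeper or wider stacks are configured through
`backbone_config(channels = ...)`; a residual ImageNet-pretrained backbone
is out of scope at desk scale.

**Prototype similarity.** Each modality owns $N$ (default 10) single-pixel
prototypes $p_j^m \in \mathbb{R}^{1\times 1\times C}$, allocated half to
each class. For each prototype, squared Euclidean distances
$d = \lVert p_j^m - \mathrm{pixels}(z^m)\rVert_2^2$ to every feature-map
position are mapped through the activation

$$s_{j}^m = \mathrm{avg}\,\mathrm{top}_k\!\left(\log\frac{d+1}{d+\varepsilon}\right),$$

i.e. top-$k$ average pooling of a log-distance similarity. The activation
is strictly decreasing in $d$ and bounded by $\log(1/\varepsilon)$ at
$d = 0$. Defaults: $\varepsilon = 10^{-4}$ (a standard stabiliser
magnitude; the published description leaves the value open) and $k = 3$
($k = 1$ is exactly max pooling; the pooling is named top-$k$ without a
stated $k$, and 3 averages the activation over a few positions without
washing out localisation).

**Structured linear head.** The $M\cdot N$ similarity scores, flattened
modality-major (index $(m-1)N + j$), feed a bias-free linear layer
$w_h \in \mathbb{R}^{MN \times K}$ with softmax output. The head is not
randomly initialised: entry $((m-1)N+j,\,k)$ is $1$ when prototype $j$ of
modality $m$ belongs to class $k$ and $-0.5$ otherwise, so each class
logit starts as (own-class evidence) $- \tfrac12$ (other-class evidence).
The malignancy probability is the softmax coordinate of the malignant
class.

**Contribution scores.** The contribution of prototype $(m,j)$ to class
$k$ is $s_{j}^m \cdot w_h[(m-1)N+j,\,k]$; contributions sum exactly to the
class logit, which is the faithfulness property the explanation report
relies on (tested to $10^{-6}$).

## Objective and the sign-convention ambiguity

Training combines cross-entropy with two prototype-shaping terms computed
per modality and batch sample: the *clustering* loss (minimum squared
distance from any feature-map position to an own-class prototype, a
non-negative value) and the *separation* loss (the negative of the
analogous other-class minimum, a non-positive value), plus an L1 penalty on
$w_h$. The published composition is

$$L = L_{ce} + \alpha L_{sep} + \beta L_{clu} + \gamma L_{reg},
\qquad \alpha = 0.8,\ \beta = -0.08,\ \gamma = 10^{-4},$$

which `loss_weights()`/`total_loss()` reproduce verbatim. Composed this
way, however, *both* distance terms are rewarded for growing: minimising
$\alpha L_{sep}$ maximises the other-class minimum distance (correct for
separation) while minimising $\beta L_{clu}$ with $\beta < 0$ *also*
maximises the own-class minimum distance — the opposite of clustering. In
practice the two terms dominate the objective (they are unbounded while
cross-entropy is not), the prototypes drift away from the feature
distribution, and representation learning stalls; at the package's
reference conditions (300 synthetic lesions, 2 cycles) the literal
composition reaches held-out AUC ≈ 0.65, no better than its starting
point, while the canonical prototype-network convention — weight 0.8
*rewarding* proximity to own-class prototypes and weight 0.08 rewarding
distance from other-class prototypes — reaches ≈ 0.97 under identical
conditions. Since the method demonstrably works in its original setting,
the coefficients as printed are best read as a transcription slip
(swapped relative to the prototype-network lineage the method builds on).
`mupnet_train()` therefore defaults to `loss_convention = "canonical"` and
keeps `"as_published"` selectable for comparison; nothing is silently
rewritten — the objective functions themselves compute the printed
formulas exactly, and both compositions are tested.

The L1 penalty applies by default to the off-class head entries (those
initialised at $-0.5$), encouraging sparse negative reasoning;
`l1_mode = "full"` penalises the whole matrix (the published description says only that
the L1 norm is applied to $w_h$).

## Three-stage optimisation

Training repeats a three-stage cycle until the epoch budget is used:

1. **Joint stage** (default 10 epochs/cycle): extractors and prototypes are
   optimised by Adam; the head stays frozen at its structured
   initialisation.
2. **Projection**: every prototype is replaced by its nearest latent patch
   (squared L2) among *policy-eligible* training lesions of its class, and
   the source lesion, position and grade are recorded as provenance. Ties
   break on the lowest (lesion id, position) in canonical order. Only
   original images — not augmented copies — donate patches.
3. **Last-layer stage** (default 5 epochs/cycle): only $w_h$ is tuned
   (cross-entropy + L1).

A final projection runs at the end if the budget expires mid-cycle, so a
returned model always satisfies the projection postcondition: each
prototype equals, exactly at stored precision, a training patch of its
class with a policy-allowed grade (`check_projection()` re-derives this
from provenance). The cycle cadence (10 + 5) is a package choice; the
published description states the stages repeat but not the cadence.

Optimisation details: Adam (`lr` 0.001, batch 40, 80 epochs by default, all
randomness from one run seed). The learning-rate wording "decreased by 90%
every 5 epochs" admits two readings: literal ×0.1 per 5 epochs, or a
milder ×0.9 step. The literal schedule freezes all learning after roughly
the first cycle, which a pretrained backbone may tolerate but a
from-scratch backbone does not: at the reference conditions it turns the
outcome into an initialisation lottery (held-out AUC between 0.47 and 0.97
across seeds), whereas ×0.9 trains every cycle and reaches AUC ≥ 0.99 on
the same seeds. The package default is therefore `lr_decay_factor = 0.9`,
with `0.1` selectable for the literal reading. The published description
applies weight decay 0.001 to batch-normalisation parameters; the desk-scale
backbone has no normalisation layers, so that mode is a no-op here, and
`weight_decay_mode = "conv"` applies it conventionally to convolution
weights instead.

Class imbalance is handled before training by oversampling the minority
class with offline flip/rotation/blur copies to a 1:1 ratio (originals
retained, copies flagged and excluded from projection); on-the-fly
augmentation applies the same jointly-drawn transform to all modalities of
a sample: horizontal flip (p = 0.5), brightness and contrast factors in
[0.9, 1.1], central crop fraction in [0.9, 1] resized back, rotation in
[−10°, 10°].

## Domain-knowledge candidate policy

Projection candidates are restricted per modality and class on the ordinal
scale: B-mode and Doppler prototypes come from grades {3, 4a} (benign)
versus {4c, 5} (malignant); elastography — the most operator-sensitive
modality — only from the extremes {3} versus {5}; borderline 4b never
donates a prototype. The policy is data (`candidate_policy()`), fully
overridable for other ordinal schemes, and `allow_all_policy()` reduces
projection to plain nearest-patch-of-class (tested as an equivalence).

## Synthetic data generator

`simulate_lesions()` emulates the *structure* of a multimodal
lesion dataset so every module is testable without clinical data: per
lesion, three paired 64×64 images with shared geometry, a label
(malignant prevalence 0.4), and a grade drawn from a class-conditional
distribution (benign mass on {3, 4a, 4b}, malignant on {4b, 4c, 5}; both
give 4b weight, so the policy always has something to exclude). Appearance
cues follow the standard clinical descriptors:

* **B-mode** — multiplicative log-normal speckle (log-sd 0.25) over a
  darker lesion whose polar boundary is an ellipse perturbed by random
  harmonics with class-conditional amplitude (benign 0.04 ± 0.02,
  malignant 0.22 ± 0.06): malignant boundaries are measurably more
  irregular (isoperimetric ratio).
* **Doppler** — the B-mode base plus Poisson-many coloured flow blobs near
  the boundary (mean 0.8 benign, 4 malignant).
* **Elastography** — a stiffness overlay whose high-intensity core area
  fraction equals the stiffness parameter (Beta(2,9) benign vs Beta(7,3)
  malignant).

Grades are *sampled*, not thresholded from rendering parameters, so any
grade/appearance correlation is induced only through the class. Splits are
70/10/20 train/val/test in generation order, mirroring a chronological
cohort split. What the generator does **not** emulate: physical wave
propagation, scanner/operator variability, annotation noise, or lesions
whose appearance contradicts their label — so a high AUC here demonstrates
that the pipeline learns and explains as designed, not that it would reach
the same accuracy on clinical images.

The reference desk-scale configuration used by the acceptance script and
the end-to-end tests is 300 lesions, the default backbone, and two
training cycles (30 epochs) — chosen as the smallest setting at which the
three modality cues are all clearly learned.

## Numerical and degenerate-input choices

* The similarity stabiliser $\varepsilon$ appears only in the denominator,
  as printed.
* Feature maps pass through the 1×1 sigmoid add-on layer (the published description is
  silent on channel matching); a zeroed final layer therefore yields a
  constant map at 1/2, the squashing's zero-input fixed point.
* Distance maps are clamped at 0 before the log activation to absorb
  floating-point cancellation.
* Projection and the min-distance losses share one tie rule: `which.min`
  order, i.e. lowest position then lowest prototype; projection
  additionally orders candidates by lesion id.
* `bootstrap_ci()` redraws resamples on which the statistic is undefined
  (e.g. single-class resamples for an AUC), with a capped redraw budget;
  intervals are percentile intervals at the lesion level.
* `mcnemar_test()` uses the exact two-sided binomial for discordant counts
  below 25 and the continuity-corrected chi-square otherwise; zero
  discordance returns p = 1, flagged degenerate.
* `delong_test()` returns p = 1 for identical score vectors (zero variance
  of a zero difference).
* Explanation percentages are normalised over the six displayed
  representatives (not all $M \cdot N$ prototypes) with negative
  contributions clipped at zero and a uniform split when everything is
  non-positive; the report states this rule alongside the scores. Matching
  regions are the 95th-percentile level set of the bilinearly upsampled
  activation map, returned as a tight bounding box.

## Known limitations

* The backbone is a small plain conv stack; no normalisation layers,
  residual connections or pretraining, so absolute accuracy on real
  ultrasound is not expected to transfer.
* Under the literal ×0.1/5-epoch decay option, effective learning happens
  in the first cycle only; longer budgets mostly add projection/tuning
  passes.
* Prototype allocation per class is an equal split by default; the
  per-modality allocation actually used in the original setting is not
  stated anywhere and may differ.
* The reader-study module computes arithmetic on decision tables; it does
  not model multi-reader multi-case variance.
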