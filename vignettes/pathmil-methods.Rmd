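---
title: "Weakly supervised colon histopathology with pathmil: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised colon histopathology with pathmil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Training image classifiers for digital pathology normally requires experts to
annotate slides, which does not scale. `pathmil` implements an
annotation-free alternative for colon histopathology built from two
components:

1. a **report labeler** that extracts a weak multilabel diagnosis from the
   free-text pathology report paired with each whole-slide image (WSI), and
2. a **multiple-instance-learning (MIL) classifier** that learns to predict
   that diagnosis from the image alone, using the extracted labels as weak
   supervision.

The label space is five colon diagnoses in a fixed canonical order: cancer,
high-grade dysplasia (HGD), low-grade dysplasia (LGD), hyperplastic polyp,
and normal. A case may carry several labels at once (a polyp can harbour both
dysplasia grades), so every slide-level quantity in the package is a
five-element 0/1 indicator vector.

## Report labeling

The labeler is a deliberately auditable rule pipeline:

* **Normalization** lowercases, folds Unicode to ASCII where possible and
  collapses whitespace, keeping an offset map back to the original text.
  Newlines survive as sentence boundaries.
* **Recognition** is greedy longest-match, left to right, over token n-grams
  of a gazetteer (a flat concept table with synonyms). Tokenization splits on
  hyphens as well as whitespace, so "high-grade" and "high grade" are the
  same token stream. Matches never overlap and never cross a sentence
  boundary.
* **Linking** tries exact term equality first, then a small set of curated
  rewrite patterns (shorthand such as "adeno carcinoma"), then fuzzy matching
  by normalized Levenshtein ratio with threshold 0.85. Ties break by higher
  score, then lexicographically smallest concept id, so linking is
  deterministic. The threshold is configurable; 0.85 tolerates one or two
  keystroke errors in typical term lengths without linking unrelated words.
* **Negation** marks a mention negated when a cue ("no", "not", "without",
  "absence of", "free of", "negative for") starts within five tokens before
  it with no intervening sentence boundary. Rule-based labelers without
  negation handling systematically convert phrases like "NO high-grade
  dysplasia" into false positives; negation detection is therefore on by
  default, and switching it off reproduces that documented failure mode for
  study.
* **Grade resolution**: bare "dysplasia" is ambiguous. Adjectives within a
  four-token lookback decide the grade (severe/marked/high → HGD,
  mild/moderate/slight/low → LGD); an unqualified mention falls back to a
  configurable default, LGD, the far more prevalent grade in screening
  corpora. The default is declared rather than silently assumed.
* **Context suppression**: the clause "margin of resection on
  hyperplasia-adenomatous mucosa" describes a margin, not a hyperplastic
  polyp, and is a known trap for keyword labelers. A context rule suppresses
  hyperplasia mentions within five tokens after a resection-margin trigger.
  Like negation, it can be disabled to reproduce the trap.
* **Fallback**: a report in which no diagnostic class survives is labeled
  `normal`. A finalized label is therefore never the all-zero vector.

The ad-hoc rule set is a reconstruction, versioned with the package; it makes
no claim of completeness for any particular hospital's phrasing. Machine
translation and neural recognizers are out of scope — the recognizer is an
interface with the gazetteer matcher as its shipped default, and input is
asserted to be English.

## Slide preprocessing

Slides are tiled into 224 x 224 patches at 10x magnification (both
configurable). Tissue is separated from glass by Otsu-thresholding the HSV
saturation channel, followed by morphological opening, closing (disk radius
2) and hole filling; stained tissue is saturated while background is nearly
grey, so this is a deterministic, dependency-light stand-in for heavier
quality-control tooling. A patch is kept when at least half of its pixels are
tissue (`tissue_threshold = 0.5`, a sensitivity knob). The grid is
non-overlapping and border cells smaller than a patch are dropped, never
padded — padding would fabricate tissue.

Training-time augmentation happens at WSI level: per slide, three operations
are each included with probability 0.5 — rotation by 90/180/270 degrees,
horizontal or vertical flip, and bounded HSV colour jitter (hue ±20,
saturation ±30, value ±20 on the 8-bit scale) — and the one sampled pipeline
is applied to every patch of the bag, preserving within-slide consistency.
For efficiency the package applies the transform to tiles already downscaled
to the backbone input size; flips and right-angle rotations commute exactly
with block-mean downscaling, and the colour jitter very nearly so.

## The MIL model

A slide is a bag \(X_n\) of \(p\) patch instances. The classifier is
instance-level MIL with attention pooling:

* a **frozen backbone** maps each patch to a feature vector. The default
  "resnet34" preset is a 34-layer residual network producing 512 features from
  224 x 224 tiles; a "tiny" two-layer convolutional preset (64 features from
  32 x 32 tiles) exists for desk-scale experiments and tests. Backbone
  weights are random (seeded) or loaded from file; pretraining them is
  outside the package. Because no deep-learning framework is available to R
  here, the forward passes are implemented directly with im2col convolution
  and BLAS matrix products; with random weights, activations are
  channel-standardized so the residual stack stays well-scaled. The tiny
  preset additionally appends the tile's per-channel colour mean and
  standard deviation to its random conv features — the colour statistics
  carry the stain signal that a pretrained backbone would encode.
* an **embedding layer** reduces features to 128 dimensions (grid-searchable
  over 32/64/128/256) with a ReLU before the classifier;
* a **patch classifier** produces 5 logits per patch; patch predictions are
  multiclass (softmax, argmax with lowest-index tie-break);
* an **attention network** scores each patch per class. For class \(c\) the
  weights \(a_{c,\cdot}\) are the softmax over patches of those scores, so
  each class row sums to 1 by construction. The WSI logit of class \(c\) is
  \(\sum_p a_{c,p} z_{p,c}\), the attention-weighted sum of that class's
  patch logits, and the WSI probability is its logistic transform — a
  multilabel slide prediction.

Two compositional details are genuinely open in the source formulation and
are fixed here behind one function (`attention_pool()`): attention acts on
the embeddings (scores are linear in the embedding) and aggregates *logits*,
not probabilities, before a sigmoid. Weighted-logit aggregation keeps the
instance-level contract — patch predictions exist independently of the
pooling — while yielding calibrated-ish multilabel WSI probabilities.
Per-class attention heads are the default ("the network weighs the patches
for each class"); a shared-attention variant is a config switch.

A class is predicted when its probability exceeds 0.5; if nothing clears the
threshold the argmax class is emitted, because a diagnosis must never be
empty.

### Training

The loss is the unweighted mean over the five classes of binary
cross-entropy between WSI probabilities and the weak label (no class
re-weighting, despite imbalance). Optimization is Adam, learning rate 1e-3,
weight decay 1e-3, 15 epochs, one bag per gradient step (batch construction
is otherwise unspecified, and one-bag steps are the simplest faithful
choice). The backbone stays frozen — tests assert its weights are
bit-identical before and after training. The returned checkpoint is the
epoch with the lowest validation loss, the same criterion the grid search
uses. Gradients for the embedding/classifier/attention stack are derived by
hand (the softmax-over-patches backward pass is the only subtle step) and
verified against loss decrease and seeded reproducibility.

Cross-validation is k = 10 by default, split at **patient** level so slides
of one patient never straddle training and validation; fold sizes differ by
at most one patient. Metrics are reported as mean ± sample standard
deviation over the k fold models. One master seed fans out per-fold and
per-epoch streams, so each fold is independently reproducible.

## Evaluation protocol

* **WSI level (multilabel)**: micro-accuracy pooled over all
  (sample, class) indicator cells — the headline metric; support-weighted
  macro F1 (zero-support classes carry no weight; F1 of a present-but-never-
  predicted class is 0); per-class precision/recall; one-vs-rest ROC with
  trapezoidal AUC (degenerate classes flagged undefined, never scored 0). A
  per-sample exact-match accuracy is computed but never headlined.
* **Patch level (multiclass)**: Cohen's kappa against pixel-derived patch
  ground truth; 0.40–0.60 is conventionally "moderate" agreement.
* **Label sources** are compared with a two-sided Wilcoxon rank-sum test:
  the null is enumerated exactly up to a combined n of 12 (factorially cheap
  and exact for the k ≤ 10 fold comparisons this package makes) and
  approximated normally with tie and continuity corrections above that; the
  two branches agree within 0.02 at the switch point.
* **Mislabeled-subset analysis**: `find_mislabeled()` returns the cases
  whose automatic label differs from ground truth in any indicator; metrics
  restricted to that subset quantify robustness to weak-label noise.
* **External schemes**: public datasets use coarser label sets (e.g.
  "Benign" = hyperplastic + normal; "High-risk" = cancer + HGD; "Dysplasia"
  = both grades). Predictions and ground truth are aggregated by OR over
  each external class's members; internal classes a scheme does not map are
  dropped. Schemes ship as data (TSV) so users can add their own. A case
  whose mapped prediction is empty simply scores wrong against any positive
  ground truth — the least charitable, most conservative convention.
* **Interpretability**: attention weights render as heatmaps (min-max
  normalized per slide, painted into patch footprints only, ranking
  preserved), and the embedding layer's output can be exported for 2-D
  t-SNE projection of patches whose top probability exceeds 0.5. The
  projection uses a compact exact t-SNE implemented in the package
  (quadratic in the number of points, seeded) — plotting plumbing, not a
  methodological contribution.

## The synthetic benchmark

Real paired WSI/report corpora are hospital-private, so the package ships a
generator that emulates the *structure* of such data:

* **Slides**: white background with one elliptical tissue region per set
  class, painted with a gland-like periodic texture. Deformation amplitude
  and fill solidity are strictly ordered from normal (regular, sparse) to
  cancer (deformed, solid), echoing the morphology gradient pathologists
  describe, and each class has a distinct stain-like base colour spaced
  widely enough in hue to survive the bounded colour jitter. Per-pixel and
  per-cell ground truth are emitted; a cell's class is the one covering at
  least half of its tissue. The default slide is 1120 x 1120 (a 5 x 5 grid
  of 224-pixel patches) for desk-scale speed, configurable upward. Textures
  are evaluated on a half-resolution lattice and pixel-replicated — the ring
  spacings (22 px and up) are far coarser than the 2-px lattice, so no class
  structure is lost.
* **Reports**: template phrases per class, drawn from wording the bundled
  gazetteer covers. Pure-normal cases omit findings entirely with
  probability 0.5 so both the explicit-mention and fallback paths of the
  labeler are exercised. Optional noise: a negated phrase for an unset class
  ("no high-grade dysplasia") with probability `negation_rate`, and the
  hyperplasia-margin trap clause with probability `distractor_rate`.
* **Label noise**: exactly `floor(mislabel_rate * n)` cases get one
  uniformly chosen indicator flipped (re-asserting at least one set class) —
  the minimal corruption matching the "one or more classes differ"
  definition of a mislabeled sample. Rates of 0.15–0.25 emulate the error
  levels reported for automatic report labeling at scale; the manifest
  records every corruption so noise recovery can be checked exactly.
* **Prevalence** defaults to a screening-like mixture dominated by normal
  (0.30) and LGD (0.22), with co-occurring dysplasia grades (0.08) and
  cancer+HGD (0.06) present because multilabel cases are what distinguish
  this problem; patients receive two slides each, round-robin.

What the generator deliberately does **not** emulate: photorealistic gland
morphology, stain physics, scanner variation, multi-magnification pyramids
beyond two levels, or report language beyond the template families. Passing
the synthetic recovery tests therefore shows the *pipeline* is correct and
the MIL machinery can localize and aggregate class evidence — it does not
certify clinical performance on real slides, whose headline numbers were
obtained at hospital scale with pretrained backbones and are out of reach of
a CPU-scale rebuild.

## Problem sizes used by the test suite

The suite exercises label recovery with 160 training + 40 held-out bags on
5 x 5 patch grids with the tiny backbone and k = 2 folds (held-out
micro-accuracy ≥ 0.9, patch kappa in the "moderate" band), noise robustness
with a 100-case corpus at `mislabel_rate = 0.2` (clean vs 20%-noisy vs fully
random training labels must degrade monotonically), attention localization
on 50 two-class slides with a model trained on the standard screening
mixture (mixed single- and multi-class bags are what teach each per-class
attention head its own class; a trainer fed only two-class bags localizes
visibly worse between hue-adjacent classes), and the labeler round trip on
200-report corpora. These sizes were chosen as the smallest at which the
statistical properties under test are stable across seeds.

## Known limitations

* Random-weight backbones are far weaker than pretrained ones; on real
  histology the tiny preset's colour statistics would be confounded by stain
  variation. The backbone contract accepts file-loaded weights for that
  reason.
* The labeler's rules are a reconstruction tuned on synthetic phrasing plus
  the documented failure cases; real hospital reports will need gazetteer
  and rule extensions (block-splitting of multi-specimen reports is
  explicitly not handled).
* The exact t-SNE is quadratic in the number of exported patches; export a
  sample for corpora beyond a few thousand patches.
* Grid search trains (configurations x folds) models; with the full default
  grid this is meant for the tiny backbone at desk scale.
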