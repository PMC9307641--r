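# pathmil

Annotation-free weak supervision for colon histopathology in R: extract
multilabel diagnoses from free-text pathology reports with a rule-based
concept recognizer/linker, and train an attention-pooling, instance-level
multiple-instance-learning (MIL) classifier on whole-slide-image (WSI) patch
bags using those extracted labels — no pixel-wise or manual image annotation
anywhere in the loop.

The package is aimed at computational-pathology researchers who want a fully
inspectable, CPU-scale implementation of this weak-supervision recipe,
together with the evaluation protocol and a synthetic paired report/slide
benchmark that makes every stage testable without clinical data.

## The model

The label space is five colon diagnoses in fixed order: cancer, high-grade
dysplasia, low-grade dysplasia, hyperplastic polyp, normal; a case may carry
several at once.

**Report labeling.** Mentions are recognized by greedy longest match over a
gazetteer, linked by exact match → curated rewrite rules → normalized
Levenshtein similarity (threshold 0.85), filtered by negation detection
("no high-grade dysplasia") and context rules (the hyperplasia-as-margin
trap), with grade adjectives (severe/mild/…) resolving bare "dysplasia".
Reports with no surviving diagnostic concept are labeled `normal`.

**MIL classification.** A slide is a bag *Xₙ* of *p* 224×224 patches taken
at 10× from tissue regions (Otsu saturation masking). A frozen backbone maps
each patch to a feature vector (512-d for the 34-layer residual preset), an
embedding layer reduces it to 128-d (ReLU), a classifier yields per-patch
5-class logits *z*, and a per-class attention network produces weights
*a₍c,p₎* ≥ 0 with Σₚ *a₍c,p₎* = 1. The slide-level probability of class *c*
is

&nbsp;&nbsp;&nbsp;&nbsp;P(c | Xₙ) = σ( Σₚ a₍c,p₎ · z₍p,c₎ ),

trained with mean per-class binary cross-entropy against the report-derived
weak label (Adam, lr 1e-3, 15 epochs, WSI-level augmentation, patient-level
10-fold cross-validation, grid search by lowest validation loss). Evaluation
covers multilabel micro-accuracy, support-weighted F1, per-class
precision/recall, ROC/AUC, patch-level Cohen's κ, Wilcoxon rank-sum
comparisons of label sources, mislabeled-subset analysis, attention heatmaps
and t-SNE latent exports, plus aggregation onto public datasets' coarser
label schemes (e.g. "Benign" = hyperplastic ∪ normal).

## Worked example

Label a report:

```r
library(pathmil)
gaz <- read_gazetteer()   # bundled colon concept table
res <- label_report(
  "tubulovillous adenoma with severe dysplasia; no evidence of adenocarcinoma.",
  gaz)
label_classes(res$label)
#> [1] "high_grade_dysplasia"
res$concepts[, c("surface", "method", "score", "negated", "class")]
#>                 surface method score negated                class
#> 1 tubulovillous adenoma  exact     1   FALSE                 <NA>
#> 2      severe dysplasia  exact     1   FALSE high_grade_dysplasia
#> 3        adenocarcinoma  exact     1    TRUE               cancer
```

"severe" promotes the dysplasia to high grade; the negated adenocarcinoma is
recognized, linked, and discarded, so cancer is *not* in the label.

Run the whole pipeline on a synthetic corpus (40 paired reports + slides,
tiny backbone, 2-fold cross-validation):

```r
cfg <- pipeline_config(
  out_dir = "demo_run",
  corpus  = corpus_config(n_cases = 40, seed = 1),
  train   = train_config(seed = 1),
  k = 2, seed = 1)
out <- run_pipeline(cfg)
glance(out$cv)
#>   micro_accuracy_mean val_loss_mean weighted_f1_mean micro_accuracy_sd ... k
#> 1               0.845         0.424            0.541            0.0212 ... 2
```

`demo_run/summary.json` collates the stages:

```json
{"seed":1,"version":"0.1.0",
 "labeler":{"micro_accuracy":1,"weighted_f1":1},
 "wsi":{"micro_accuracy":"0.845 ± 0.021","weighted_f1":"0.541 ± 0.014",
        "val_loss":"0.424 ± 0.060"},
 "patch_kappa":0.5403}
```

Read: the labeler recovered every planted report label
(`labeler.micro_accuracy = 1`); the MIL model, trained only on those weak
labels, reaches 0.845 ± 0.021 validation micro-accuracy over the five
indicator cells per slide at this tiny corpus size (it passes 0.9 at the
160-bag scale the test suite uses), and its patch-level agreement with the
per-patch ground truth is κ ≈ 0.54 — "moderate", which is the expected band
for a model never shown a single patch label. A command-line front-end with
the same stages ships at `inst/cli/pathmil`.

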