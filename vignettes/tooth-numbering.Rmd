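---
title: "Correcting tooth numbers on periapical films: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting tooth numbers on periapical films: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothnum)
```

## The problem

An object detector run on a dental periapical radiograph produces a set of
bounding boxes, each with an FDI tooth number (ISO-3950: first digit the
quadrant, second the position 1--8) and a confidence score. Detectors
localize teeth very well but number them poorly: teeth of the same
morphological category look alike, so a second premolar is easily called a
first premolar, and left/right mirror teeth (25 vs 15) are
near-indistinguishable from a single tooth's appearance. What the detector
cannot see locally, the arrangement of the dentition supplies globally: all
teeth in one periapical film belong to one arch, and their numbers must
form a contiguous, ordered window of that arch's fixed 16-slot sequence.
`toothnum` implements this arrangement-based correction as a staged
post-processing pipeline, together with the evaluation metrics used to
measure it, and a synthetic data generator so the whole system can be
exercised without clinical data.

The pipeline stages are:

1. **Stage 1** -- the raw detector output.
2. **Stage 2** -- overlap filtering. Standard per-label non-maximum
   suppression (IOU > 0.6 deletes all but the highest-score box) cannot
   remove duplicate boxes that carry *different* labels, so a second pass
   repeatedly finds the pair with the largest IOU regardless of label and,
   while it exceeds 0.7, deletes the lower-score member.
3. **Stage 3** -- template matching. The surviving labels, ordered left to
   right by box center, are slid along both 16-slot arrangement templates
   (`18,17,...,11,21,...,28` upper; `48,...,41,31,...,38` lower) and the
   boxes are relabeled from the best-scoring alignment.
4. **Stage 4** -- missing teeth. A small classifier predicts, for each gap
   between adjacent boxes, how many teeth (0--3) are missing there;
   placeholder `"M"` elements are inserted into the sequence before
   template matching, so an edentulous gap consumes template slots without
   forcing the downstream teeth onto wrong numbers.

## The comparison score

An alignment places the ordered label sequence $X_1, \dots, X_n$ (possibly
containing placeholders) at consecutive template slots $T_1, \dots, T_n$.
Its score is

$$\mathrm{Comparison} \;=\;
  \underbrace{\sum_{i:\,X_i = T_i} s_i}_{\text{match score}}
  \;+\;
  \underbrace{\sum_{i:\,X_i \ne T_i} s_i \cdot
     \mathrm{sim}\big(\mathrm{cat}(X_i), \mathrm{cat}(T_i)\big)}_{\text{mismatch score}},$$

where $s_i$ is the detector's confidence for box $i$. A matched position
contributes its full score; a mismatched one contributes its score
discounted by the similarity of the two tooth *categories* (wisdom, molar,
premolar, canine, and the incisor categories), encoded in per-dentition
symmetric matrices with diagonal 0.9 and zero blocks between the
molar-type and anterior categories. The placeholder has similarity 0
everywhere: it buys slot occupancy, never score. The maximizing
(dentition, offset, direction) triple wins, and the template labels at the
aligned slots replace the predicted labels. Because the correction is a
template window read-off, the corrected numbering is guaranteed to be a
strictly ordered, duplicate-free window of one arch -- the property the
raw detector output lacks.

Two details are worth stating precisely:

* **Both directions are scored.** Intraoral films can be mirrored, so the
  reversed sequence is scored as well (disable with
  `pipeline_config(enable_reversal = FALSE)`). The FDI system is
  bilaterally symmetric -- the upper template reversed is its own
  contralateral mirror, and mirror teeth share a category. A consequence
  is that an alignment with *no* exact label match is exactly tied with
  its mirrored, reversed counterpart. Ties (scores within 1e-9, so that
  floating-point summation order cannot flip them) are resolved by a fixed
  priority: upper before lower, forward before reversed, smaller offset
  first.
* **Cross-dentition lookups.** A noisy detection can carry a label from
  the opposite arch, and the similarity matrices are per-dentition. The
  lookup translates the predicted category into the template dentition's
  category set -- the upper lateral/central incisor categories pool into
  the lower incisor category, and the lower incisor category widens to the
  upper lateral-incisor column. This is the minimal rule that makes the
  lookup total; the matrices themselves are never altered.

The matrices ship as data but are deliberately user-replaceable
(`write_similarity_config()` / `read_similarity_config()`): they encode
expert judgment, not measurement, and better values may exist.

## Missing-teeth prediction

The gap classifier uses exactly two features per adjacent box pair: the
horizontal margin distance (right box's `xmin` minus left box's `xmax`;
negative when inclined neighbors overlap) and the horizontal center
distance. The margin alone fails precisely in the clinically interesting
case -- neighbors tipping into an extraction gap close the margin -- but
tipping moves each box center only about half as far as it moves the
facing edge, so the center distance retains the signal. Both features are
divided by the image's mean detected-box width before classification.
This normalization is a package choice: films vary in scale, and the
mean box width is a film-intrinsic yardstick; the raw pixel values are
kept alongside. The center distance is horizontal rather than Euclidean
because teeth are arranged along the roughly horizontal arch in a
periapical view.

The classifier is a feed-forward network with two fully connected hidden
layers of 10 rectified-linear units, a softmax over the four classes
0--3, cross-entropy loss, and Adam updates (step size 0.01, mini-batches
of 32) for 100 epochs, seeded and exactly reproducible. The architecture
and label range are fixed design points of the method; the activation,
optimizer and learning rate are conventional defaults, chosen once. No
installed R package provides a two-hidden-layer perceptron of this shape,
so the forward/backward pass is implemented directly in `R/mlp.R`
(~100 lines of matrix algebra); `nnet`, the usual single-hidden-layer
choice, would change the stated architecture.

Predicted counts above 3 never occur (the softmax has four classes); at
insertion time counts are nevertheless clamped to 3 defensively. If an
augmented sequence would exceed 16 slots, placeholders are shed from the
widest predicted gaps first -- a pathological case that clean inputs
cannot reach.

## Evaluation metrics

Detections are matched to ground truth per image by greedy selection on
the full IOU matrix: take the global maximum entry, and while it exceeds
0.7 record the pair and delete its row and column. Matching is therefore
order-independent, one-to-one, and every matched pair has IOU > 0.7
(all thresholds in the package are strict inequalities). From the pooled
counts over a dataset (micro-average; a film with more teeth weighs
more):

* detection precision = matches / detected boxes, detection recall =
  matches / ground-truth boxes;
* numbering precision and recall replace matches by the matched pairs
  whose labels also agree, so numbering can never exceed detection;
* mean IOU averages the matched pairs' IOUs (reported with SD).

Per-class average precision follows the 11-point interpolation
convention: detections of a class, pooled over the dataset and ranked by
descending score, greedily claim the highest-IOU unclaimed ground-truth
box of their image at IOU > 0.5 (duplicates and low-IOU detections are
false positives); AP is the mean over recall points $0.0, 0.1, \dots,
1.0$ of the maximum precision at or beyond each recall. mAP averages AP
over classes with at least one ground-truth instance -- classes that
appear only as false positives would otherwise make the average
ill-defined. Empty denominators anywhere yield 0 plus an explicit
`*_defined = FALSE` flag rather than an error.

## What the synthetic generator emulates

`generate_film()` draws a dentition, a contiguous template window, and
per-gap missing counts, then lays out boxes left to right with
category-specific nominal widths (wisdom 10.0, molar 10.5, premolar 7.0,
canine 7.5, upper lateral incisor 6.5, upper central incisor 8.5, lower
incisor 5.5 mm, all at 12.5 px/mm, width CV 6%). These widths are
plausibility choices of this package, not measurements. Missing-tooth
gaps are as wide as the absent teeth; with probability `p_incline` the
flanking boxes extend 20--42% of the gap toward each other, reproducing
the margin-closing incline case. `corrupt_detections()` then applies
dropout, corner jitter (SD 1.5 px), label confusion (contralateral /
adjacent-position / same-category modes in proportion 5:3:2), and
duplicate boxes at IOU > 0.7 with a different label and a reduced score;
correct labels draw scores from U(0.75, 0.98), confused ones from
U(0.40, 0.80). Every corruption is logged, so tests can assert exact
expected outcomes per film.

Two default rates deserve justification:

* **Label confusion 0.25 per box** puts raw numbering precision near
  0.75 after overlap filtering -- the regime in which arrangement-based
  correction is the binding constraint.
* **Missing-tooth probability 0.05 per gap** (roughly one film in seven
  shows a gap) reflects that most periapical windows in an ordinary adult
  clinical population show an intact run of teeth. This prevalence
  matters: rigid stage-3 matching provably mislabels the short side of
  any missing-tooth film, so the stage-2 to stage-3 improvement holds
  when intact films, where matching repairs confusions, dominate. At
  much higher prevalence stage 3 would be net harmful and only the
  placeholder-aware stage 4 would help -- a regime the staged design is
  explicitly not aimed at.

The generator does *not* emulate: image pixels (the tool operates purely
on boxes), truncated edge teeth, deciduous or supernumerary teeth,
vertical arch curvature beyond small jitter, inter-film variation in
detector quality, or correlated errors between neighboring teeth.
Passing tests on synthetic films therefore demonstrate the correctness
and internal consistency of the post-processing machinery under the
stated noise model -- not clinical performance, which depends on a real
detector's error structure.

For gap-classifier *training* the package uses a missing-enriched
configuration (`p_missing = 0.30`) so that all four classes are well
represented -- ordinary class rebalancing; evaluation films always use
the defaults.

## Problem sizes and numerical choices

The shipped tests train the gap classifier on sets of 500--2,000 gaps and
evaluate the pipeline on benchmarks of up to 200 films (about 1,000
boxes), sizes at which every reported proportion is stable to a few
hundredths; randomized operator checks run 300--1,000 trials against
brute-force reference implementations. Other numeric choices: IOU uses
the continuous area convention (width = `xmax - xmin`), degenerate
zero-area boxes are rejected at validation; all suppression, matching and
AP thresholds are strict; score ties in suppression keep the earlier
input row, IOU ties process the lowest pair index first; alignment ties
follow the priority order above; argmax ties in the gap classifier
resolve toward the smaller count. Coordinates are written to disk as
integer pixels (rounded half-up), matching the pixel-distance annotation
convention; scores keep full precision.

## Known limitations

* The arrangement correction assumes a single dentition per film and at
  most 16 boxes after filtering; longer sequences are an error by design.
* Template matching is rigid: placeholders are the only gap mechanism,
  and a wrong missing-count prediction shifts every tooth on the short
  side of the gap.
* The similarity matrices are expert priors with one-decimal resolution;
  ties they induce are resolved by convention, not evidence.
* Metrics follow the strict-inequality conventions stated above; suites
  using `>=` at thresholds will differ on boundary cases.
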