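---
title: "Reverse active learning for noisy-label histopathology patches"
author: "dralnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse active learning for noisy-label histopathology patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A digitised pathology slide carries one diagnostic label — *normal*,
*benign*, *carcinoma in situ*, and so on — but it is far too large to feed
to a convolutional classifier.  The standard workaround crops the slide
into fixed-size square patches and propagates the slide label to every
patch.  That propagation is wrong wherever a cancerous slide contains
normal tissue: those patches are normal tissue wearing a cancer label.
A classifier trained on such a pool learns from partly corrupted
supervision, and its patch-level accuracy suffers.

`dralnet` implements a data-cleaning procedure for exactly this setting
— **deep-reverse active learning (DRAL)** — together with the two
network architectures it is designed around, the patch-extraction
pipeline that produces the (noisy) training pool, patch-to-slide voting
fusion, and a synthetic-slide generator that makes the whole chain
testable: on synthetic slides the tumor mask is known exactly, so the
set of mislabeled patches is known exactly, and the cleaning step can be
scored like a detector.

## Deep-reverse active learning

Classical active learning selects the *least certain* samples and sends
them to an annotator.  DRAL runs the idea in reverse: samples the model
cannot become confident about are likely to carry a wrong propagated
label, and instead of being annotated they are *expelled* from the
training pool.

The loop, as implemented in `run_dral()`:

1. Train a deliberately small confidence network — **RefineNet**, six
   3×3 convolutions with 2×2 max pools, an average pool, and two fully
   connected layers — on the propagated-label pool.  Low capacity is the
   point: the network underfits patches whose labels conflict with
   their appearance, so its softmax confidence stays low on them.
2. Predict on every training patch.  Flag every patch whose maximum
   class probability is **strictly below 0.5** (`flag_low_confidence()`).
3. Apply the augmentation-group consensus (`consensus_removal()`): every
   patch exists in 8 orientation variants (4 rotations × optional
   vertical flip).  If **more than four of the eight** are flagged, the
   whole group is removed; otherwise only the flagged members go.
4. Fine-tune the same weights on the reduced pool (warm start, no
   re-initialisation — the incremental accuracy gains across iterations
   only make sense with warm starts).
5. Evaluate accuracy on a fixed validation set with trusted labels, and
   stop when it stops improving (patience 1 by default), when an
   optional target accuracy is reached, or after `max_iterations`.

Two consequences of the *confidence-only* flagging rule are worth
spelling out.  First, removal does not require the model to *disagree*
with the label — only to be unsure.  A patch whose appearance is shared
by several label populations (normal tissue labeled four different
ways) keeps a split posterior and is flagged; a patch the model
confidently assigns to the *wrong* class is kept.  Second, with two
classes the maximum softmax probability is ≥ 0.5 by construction, so
the default threshold can never fire; `dral_config()` warns loudly and
the threshold must be raised deliberately for binary problems.  The
removal decision itself is a pure function of the predicted
probabilities, so the selection stage is exactly reproducible.

Because emptying the training pool is a degenerate fixed point of the
rules (a uniform predictor flags everything), `dral_iteration()` aborts
with a diagnostic rather than return an empty pool, and an optional
per-iteration `removal_cap` is available (off by default).

## The classifier: atrous DenseNet (ADN)

The final classifier is a DenseNet-style network rebuilt around two
ideas: *wide, shallow* dense blocks, and *dilated (atrous) convolutions*
for multiscale context.

* A dense block concatenates the outputs of all previous layers, so
  layer *l* receives `k0 + k(l-1)` channels where `k` is the growth
  rate.  `dense_input_channels()` is that arithmetic; the builders
  assert it structurally at every concatenation node.
* An **atrous dense connection (ADC)** block replaces each ordinary
  dense layer with a pair: a dilated 3×3 convolution (dilation
  alternating 2, 3, 2, 3 across layers) followed by an ordinary 3×3
  convolution that fuses the multiscale features.  A dilated kernel
  spans `kernel + (kernel-1)(dilation-1)` pixels at the same parameter
  count (`effective_kernel_extent()`), which is why small dilation
  rates (2 and 3) are used — larger ones outgrow the patch itself.
* The reference configuration (`adn_config()`) uses three ADC blocks of
  four dense layers with growth rates **8, 16, 32**, a stem convolution
  with max pool, average-pool transitions, a network-in-network head of
  two 1×1 convolutions, global average pooling and one fully connected
  output: 1 + 3·4·2 + 2 + 1 = **28 weighted layers**
  (`count_weighted_layers()`).

One design point was genuinely open: block transitions.  DenseNet-style
transitions carry a 1×1 compression convolution, but any transition
convolution would raise the weighted-layer count to 30 and break the
reference 28-layer budget that the rest of the architecture pins down.
The transitions here are therefore average-pool only; compression is
unnecessary anyway at these widths (48/112/240 channels).  Similarly,
the head's internals are fixed only by the layer budget: two 1×1
convolutions (128 and 64 channels) meet it.  The exact wiring of the
dilated pair (parallel branches vs. the sequential alternation used
here) is a second open point; the alternating-sequential reading keeps
the paired-convolution design and the channel arithmetic consistent.

Every weighted layer except the output is followed by batch
normalisation and PReLU.  Batch normalisation is also what licenses the
large initial learning rate in the schedule below.

## Training

`fit()` runs plain mini-batch SGD with momentum 0.9 — the conventional
optimizer for this schedule style — with batch size 16 and the staged
learning rate of `lr_at()`: 0.05 to start (viable because of batch
normalisation), then 0.01, then ×0.1 per subsequent stage.  Stage
lengths are configurable (`epochs_per_stage`); nothing in the method
fixes them, and the desk-scale defaults here are short.  Loss is the
softmax cross-entropy (`softmax_loss()`), computed with log-sum-exp
stabilisation and tested to 1e-8 against the direct formula.

Training runs on a purpose-built CPU engine (`src/nn.cpp`):
im2col/GEMM convolutions in single precision on top of the BLAS R is
linked against, with batch norm, PReLU and pooling kernels alongside,
and a whole-epoch driver that avoids per-layer R round trips.  A
per-layer R-orchestrated path with the same kernels is kept as the
reference implementation; the test suite checks the two against each
other and checks backpropagation against central finite differences.

One numerical behaviour deserves its own paragraph, because it is easy
to trip over in *short* trainings.  Eval-mode batch normalisation uses
exponential running averages of the batch statistics; when the weights
move quickly (large learning rate, few epochs) those averages lag the
weights they are supposed to describe, and every confidence estimate
downstream — including the DRAL flagging rule — inherits the bias.
After each epoch the engine therefore recalibrates: it resets the
running statistics and rebuilds them with a forward-only sweep over a
class-spanning sample of the training inputs (up to 4096 patches) at
the final weights.  Reproducibility is statistical, not bitwise: a
fixed seed fixes initialisation and batch order, but the engine's
single-precision arithmetic may differ in the last bits across BLAS
builds.

Because the networks have fixed input sizes, patches whose side is an
integer multiple of the model input are downscaled by exact block
averaging; other ratios use bilinear resampling.

## The synthetic testbed

`generate_corpus()` builds slides from band-limited Gaussian noise
textures: each class has its own spatial frequency band (geometric
spacing from 0.035 cycles/pixel) and its own palette.  Class 0 is a
pale-pink "normal tissue"; the tumor classes use neighbouring
violet/mauve hues, deliberately close together — real tissue categories
differ subtly, and a trivially separable task would make label noise
harmless and the cleaning step untestable.  A per-slide brightness
jitter (±0.05) emulates scanner and staining variation.  Non-normal
slides accrete random ellipses of the class texture until the tumor
mask covers the target area fraction (±0.05); the lesion radius cap
(0.11 of the slide side) was calibrated once so that the default
corpus — 4 classes, 256×256 slides, tumor fraction 0.3 — induces
roughly 20% patch-label noise under 64-pixel/50%-overlap extraction
with purity threshold 0.1, and was not revisited.

Ground truth follows a mask-arithmetic rule replacing pathologist
review: a patch's true label is the slide label if its tumor-pixel
fraction reaches the purity threshold (default 0.1), else class 0.
`expected_noise_rate()` turns that rule into the corpus's injected
noise rate, the base rate against which removal precision is scored.

What the generator does **not** emulate: H&E stain chemistry and colour
deconvolution, scanner artifacts, pyramid/tiled slide formats, spatial
correlation between lesions, or class-dependent lesion morphology.
Passing tests on this testbed show that the pipeline's *mechanics* are
right — extraction arithmetic, propagation, flagging, consensus,
training, fusion — and that the cleaning signal is recoverable when
label noise has the assumed structure (normal tissue inside cancer
slides).  They do not show that the specific accuracies transfer to
real stained tissue.

## Reference experiment and problem sizes

`run_experiment()` chains the stages and writes every artifact
(manifests, per-iteration removal logs, metrics for both arms) into a
versioned run directory.  The packaged reference conditions are: 4
classes, 8 training slides per class of 256×256 pixels, tumor fraction
0.3, 64-pixel patches at 50% overlap (49 per slide), 8-fold dihedral
augmentation — a pool of 12,544 patches — and 4 validation slides per
class with mask-derived trusted labels.  At desk scale the confidence
network trains for one epoch before flagging and a single removal
iteration runs (the refined pool is fixed at the moment of removal, so
the fine-tuning epoch that the default configuration retains is skipped
in the battery); each classifier arm then trains through the first two
schedule stages — one epoch at 0.05 and one at 0.01 — at 32×32 input
(patches block-averaged down).  Completing the schedule matters: a
single epoch at the large rate leaves the arm comparison dominated by
optimisation noise, while the rate drop lets both arms settle close to
their pool-optimal solutions so the comparison reflects the pools.
These sizes keep a full five-seed battery to roughly twenty minutes of
CPU time.  The two classifier arms share one initialisation seed so the
noisy-vs-refined comparison is paired; only the training pool differs.

The slide-level label is fused from patch predictions by majority vote;
ties break by the higher mean probability over the slide's patches,
then by the lower class index, making fusion deterministic and
order-invariant.

## Known limitations

* The 0.5 confidence threshold is vacuous for binary problems (see
  above); threshold semantics for K = 2 are exposed but have no
  principled default.
* Removal is confidence-only by design; a confidently *mis*classified
  mislabeled patch is never removed.  Recall of the injected-noise
  detector is accordingly modest — precision is the designed-for
  quantity.
* The engine is CPU-only and single-threaded beyond the BLAS; it is
  sized for the synthetic testbed, not for gigapixel corpora.
* Whether multi-class F-measures should be micro- or macro-averaged is
  convention-dependent; `classification_metrics()` reports both.
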