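---
title: "Methods: A-line plaque classification for intravascular OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-line plaque classification for intravascular OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the unit of analysis

Intravascular optical coherence tomography (IVOCT) acquires depth profiles
of backscattered near-infrared light — A-lines — one angular position at a
time while the catheter is pulled back through a coronary artery. A single
pullback yields hundreds of polar-domain frames (rows = depth $r$, columns
= angle $\theta$), far more than a cardiologist can read during an
intervention. `octaline` classifies every A-line into one of three
clinically meaningful categories:

* **fibrocalcific** — a bright, homogeneous fibrous layer followed by a
  signal-poor calcific core with sharply delineated front and/or back
  borders;
* **fibrolipidic** — a fibrous layer followed by a fast, diffuse signal
  drop-off characteristic of a lipid pool or necrotic core;
* **other** — everything else, including normal three-layered wall
  (intima / media / adventitia).

The A-line is the right unit because tissue is naturally ordered with
depth from the lumen, and the discriminative features (a sharp calcium
edge, the attenuation rate in lipid) live along that axis.

## Preprocessing

Each frame passes through six steps, in order:

1. **Lumen detection.** Edge strength is the positive part of the radial
   derivative of the Gaussian-smoothed frame (bright tissue above dark
   lumen). Dynamic programming finds the contour $r(\theta)$ maximising
   summed edge strength subject to $|r(\theta+1) - r(\theta)| \le
   \Delta_{max}$ (default 2 px) *with circular closure*. Exact circular DP
   requires anchoring the start state; the implementation anchors on all
   depths for shallow frames and on a ±16 px window around the open-chain
   optimum for deep frames (exact whenever the open optimum already
   closes). The edge operator and $\Delta_{max}$ are design choices — the
   reference pipeline delegates them to earlier work that is out of scope
   here.
2. **Guidewire zeroing.** Shadowed columns are set to zero. The bundled
   detector (columns whose post-lumen intensity falls below 10% of the
   frame median, dilated by 2) is a deliberately simple stand-in; the
   simulator's exact masks are preferred wherever available.
3. **Pixel shifting.** Column $\theta$ is shifted so depth index 0 is the
   *first sample after* the lumen boundary (read literally as radius + 1);
   vacated deep samples are zero-filled. A contour value of −1 is the
   sentinel for "boundary before the first sample".
4. **Crop** to the first 200 px (≈ 1 mm at 5 µm/px — the same sampling
   that makes a 65 µm thin cap ≈ 13 px).
5. **Log compression** as $\log(1+x)$: a bare logarithm is undefined at
   the zeros introduced by steps 2–3; post-log the fill value contributes
   $\log 1 = 0$.
6. **Smoothing** with a unit-sum 7×7, σ = 1 Gaussian kernel — circular
   along θ (the vessel is a closed tube) and replicate along r (the paper
   behind this pipeline is silent on boundary handling; these are the
   choices that respect the geometry).

All indices are 0-based in interfaces that expose radial positions; r
increases away from the catheter.

## Classifiers

The CNN is the seven-layer architecture: replicate-pad 5 px per edge (so
the first valid convolution returns a map the same length as the input),
conv 32×11, max-pool 2/2, conv 64×9, max-pool 2/2, dense 100 (ReLU),
dense 3 (softmax). Along r the lengths run 200 → 210 → 200 → 100 → 92 →
46 → 2944 → 100 → 3. The ANN baseline is 200 → 100 → 50 → 3 with ReLU
hidden layers (25,303 parameters). The source architecture table states
ReLU only for the dense layer; ReLU after each convolution is this
package's (standard) choice.

Because no deep-learning framework exists in the supported R stack, the
engine is implemented here: im2col convolutions on BLAS matrix products,
argmax-routed max-pooling (ties to the first index), Glorot-uniform
initialisation, Adam (lr 1e-4), and class-weighted categorical
cross-entropy. The analytic backward pass is verified against central
finite differences to 1e-5 in the test suite.

Training details:

* **Class weights** are inverse class proportions of the training set,
  normalised so the most frequent class has weight 1 — proportions
  (1/6, 1/6, 2/3) give the canonical (4, 4, 1). The normalisation is a
  convention; the un-normalised variant differs only by a global scale
  absorbed into the learning rate.
* **Early stopping**: training stops when the validation loss fails to
  improve on the running best by more than 0.01% *relative* for 5
  consecutive epochs, or at epoch 100; the returned parameters are those
  of the best validation epoch. The relative reading is forced: losses
  are scale-dependent, so an absolute 0.01% threshold would be
  meaningless. The validation loss uses the same weighted objective as
  training (the unweighted alternative is equally defensible; this one
  keeps a single objective).
* **Standardization**: none / samplewise / featurewise, with featurewise
  statistics computed on the training set only and zero standard
  deviations floored at 1. The default is none.
* Batch size 256 (unspecified upstream; config-exposed), fully seeded
  shuffling, guidewire A-lines never enter batches.

## En-face cleaning

Per-A-line classifications are noisy when viewed in the en-face (θ, z)
plane. A fully connected CRF with the appearance kernel dropped
($w_1 = 0$) is minimised by synchronous mean-field iteration:

$$E(l) = \sum_i -\log P_i(l_i) + \sum_{i<j} \mu(l_i,l_j)\, w_2
  \exp\!\left(-\tfrac{1}{2}\left[\tfrac{\Delta\theta^2}{\sigma_\theta^2} +
  \tfrac{\Delta z^2}{\sigma_z^2}\right]\right)$$

with $\mu = 1$ iff the labels differ and $\Delta\theta$ the circular
angular difference. Message passing is realised as separable truncated
Gaussian filtering of the marginals (ring-distance kernel along θ so wide
windows never double-count a neighbour; self-contribution subtracted;
truncation at ±2σ by default). Guidewire pixels are removed from the
graph entirely and re-inserted as guidewire labels afterwards — giving
them uniform unaries instead would fabricate evidence. The pairwise sum
is counted once per unordered pair, in both the energy function and the
inference.

Numerical choices: marginals initialised to the input probabilities
(equivalently, softmax of the negated unaries with an $\varepsilon =
10^{-12}$ floor), synchronous updates, softmax renormalisation each
iteration, no damping, argmax ties broken toward fibrocalcific. A dense
all-pairs reference implementation (`mean_field_dense`) ships with the
package; the filtered implementation matches it to better than 1e-6 on
random grids, and on two-pixel toys the argmax agrees with exhaustive MAP
enumeration in the regimes where mean field is exact (one term dominant).
On *frustrated* toys — conflicting confident unaries at intermediate
coupling — synchronous mean field need not reach the exact MAP; this is a
property of the algorithm, not a defect of the implementation.

**Parameter defaults.** The kernel scale derives from the reference
window of (19, 5) en-face pixels in (θ, z), read as a ±2σ truncated
extent: $\sigma_\theta = 4.75$, $\sigma_z = 1.25$; 5 iterations. The
smoothness weight is left free upstream ("optimized ad hoc"); the default
$w_2 = 0.25$ balances a confident unary gap ($\log(0.8/0.1) \approx 2.1$)
against the ~8 neighbours within one σ, so isolated errors flip while
lesion-scale regions survive. Empirically (and reproducibly in the test
suite), $w_2 = 2$ already over-smooths at desk scale. Note that θ pixels
are *per-rotation A-lines*: on grids with fewer A-lines per rotation than
the clinical 448, the equivalent window shrinks proportionally
(19 × 64/448 ≈ 2.7 for a 64-A-line grid).

**Area opening.** Three serial passes with threshold 10: each pass takes
one class as background (order: other, fibrocalcific, fibrolipidic —
config-exposed; the order is unspecified upstream) and relabels
8-connected foreground components (θ wrap-aware) smaller than 10 pixels.
One design decision matters in practice: the drifting guidewire shadow
can slice a true lesion into sub-threshold slivers. Since tissue
continues behind an occluded sector, guidewire pixels *bridge
connectivity* while contributing no area and never being relabeled
(`bridge_invalid`, on by default). Without bridging, area opening
measurably deletes correct lesion fragments at desk scale.

## Saliency

Guided backpropagation: the backward pass starts from the chosen class's
**pre-softmax** activation (standard for class saliency and better
conditioned than differentiating the probability); at each ReLU the
gradient is zeroed where the forward input was negative *or* the flowing
gradient is negative; max-pool routes gradient to the forward argmax
(ties to the first index). Maps are rectified to magnitudes by default
(signed maps via `rectify = FALSE`). For a ReLU-free model the guided map
equals the plain input gradient — the basis of the exactness tests. On
CNNs trained on synthetic data, saliency concentrates within ±5 px of the
true calcium borders, mirroring the qualitative finding that border
pixels drive the fibrocalcific call.

## Evaluation

Cross-validation is pullback-held-out: with 48 ids and 10 folds the plan
is 9 × (38 train / 5 val / 5 test) + 1 × (40/5/3), every pullback tested
exactly once; for other n, test sets take round(n/folds) ids (remainder
in the last fold) and validation max(1, round(n/10)) ids. Disjointness is
asserted at runtime. Class-wise accuracy is the row-normalised diagonal
of the confusion matrix (recall); sensitivity, specificity and F1 are
one-vs-rest; zero-support classes report NA rather than 0. Both pooled
counts and per-fold mean ± standard error are emitted, since the
upstream tables print both. The paired two-tailed t-test operates on
per-fold overall error rates by default.

## The simulator: a stated world

No clinical accession accompanies the source work, so every stage is
tested against a synthetic pullback generator with exact per-A-line
ground truth. It emulates: an eccentric lumen varying smoothly in θ and
slowly in z; a guidewire shadow of fixed angular width drifting across
frames; lesions as rectangles-with-jitter in (θ, z) (blocky en-face
structure); class-conditional profiles built directly from the
qualitative tissue definitions — plateau + step (transition ≤ 2 px) for
fibrocalcific, plateau + diffuse (≥ 10 px) exponential drop-off for
fibrolipidic, moderate decay with optional three-layer banding for other;
and unit-mean multiplicative gamma speckle (default shape 2: fully
developed speckle is shape 1, clinical systems average several sweeps).
Labels are generated per A-line directly, never recovered from rendered
intensities, so ground truth is exact by construction.

What the simulator does **not** model: the confocal/roll-off response,
attenuation-coefficient physics, macrophages, thrombus, side branches,
stents, label noise, or inter-observer ambiguity. A green end-to-end test
therefore establishes that the pipeline recovers a *stated, separable*
world — not clinical performance. The reference accuracies (printed on a
non-public 48-pullback clinical dataset) are explicitly out of scope.

## Desk-scale acceptance world

The end-to-end acceptance test trains the CNN on 30 synthetic pullbacks
and tests on 10, on one CPU. To fit the budget the geometry is reduced to
40 frames × 64 A-lines × 300 px with a training cap of 10k A-lines and 10
epochs. Two constants are paper-fixed in *absolute pixel units* and are
therefore not scaled down with the grid: the area-opening threshold (10
en-face pixels) — so lesion arcs stay at clinical absolute scale (12–30
A-lines) rather than scaling with the 64-A-line circumference — and the
smoothness window, which *is* angular and is scaled to 19 × 64/448 pixels
accordingly. With these choices, at seed 1 the classifier reaches 99.6%
held-out A-line accuracy pre-cleaning and cleaning adds a further net
improvement.

## Known limitations

* The circular-DP anchor window makes deep-frame lumen detection
  approximate when the open-chain optimum violates closure badly; on
  simulated frames the error is ≪ 1 px on average.
* Mean field is an approximation; no MAP guarantee outside the dominant
  regimes discussed above.
* The training engine is CPU-bound R; it is sized for the desk-scale
  problems here, not for clinical-volume training.
* The guidewire detector is a stand-in and is not tuned; supply masks
  from upstream hardware metadata where they exist.
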