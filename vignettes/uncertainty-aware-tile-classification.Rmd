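---
title: "Uncertainty-aware classification of tissue tiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware classification of tissue tiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histopathology pipelines classify small square crops ("tiles" or "patches")
of H&E-stained whole-slide images into tissue classes — tumour epithelium,
simple and complex stroma, immune infiltrate, debris, mucosa, adipose
tissue, background. Clinical use puts two extra demands on such a
classifier beyond raw accuracy: it should say *how sure it is* about each
tile, so that ambiguous cases can be routed to a pathologist, and it should
make the most of scarce expert annotation. `tilebayes` implements a single
model that serves both ends, plus the three workflows the uncertainty
unlocks: annotation-efficient active learning, detection of mislabelled
training tiles, and tile-based whole-slide segmentation.

## Model

The classifier (`build_classifier()`) is a compact residual convolutional
network: a 3x3 convolution stem (batch normalisation, ReLU, 2x2 max-pool),
`n_blocks` residual blocks (two 3x3 convolutions with batch normalisation
and an identity skip, each block followed by a 2x2 max-pool), global
average pooling, and then two fully connected hidden layers of 32 units.
Both hidden layers carry dropout at rate 0.5, so on average half their
units are switched off in every stochastic pass. The first hidden layer
feeds an *auxiliary* softmax head, the second the *final* softmax head.
Training minimises the weighted natural-log cross-entropy

$$L = 0.9\,\mathrm{CE}(\text{final}) + 0.1\,\mathrm{CE}(\text{aux}),$$

which regularises the shared trunk through the auxiliary gradient while
keeping the final head dominant. The loss is zero exactly when both heads
are one-hot at the true label; probabilities are clamped at $10^{-12}$ so
it is always finite.

Optimisation is mini-batch Adam (batches of 32; evaluation in batches of
128) with an initial learning rate of $10^{-3}$ and a plateau rule: a
stratified validation split is carved out of the training set
(`val_fraction`, 0.1 by default, 0.3 in active-learning mode where the
labelled set is small), validation accuracy is monitored, and whenever it
fails to improve for `lr_patience` consecutive epochs the learning rate is
multiplied by 0.1.

The network engine itself (convolutions as im2col GEMMs, batch
normalisation, max-pooling, dropout, backpropagation, Adam) is implemented
in vectorised base R on top of BLAS and is validated against central finite
differences to $10^{-9}$ relative error in the test suite.

### Two deliberate numerical choices in the training loop

* **Near-zero head initialisation.** The two softmax heads start with
  weights of SD 0.01, so the initial predictive distribution is close to
  uniform and the initial loss close to $\log M$. With conventionally
  He-scaled heads the random initial network is *confidently wrong*
  (initial loss 3-5 nats), the plateau rule sees no validation improvement
  while optimisation digs itself out, and the learning rate can be
  annihilated before learning starts. Near-zero heads are the standard
  remedy and made every reduced-scale run in this package stable.
* **Plateau patience at small scale.** With a validation split of only a
  few dozen tiles, validation accuracy moves in coarse jumps and can sit
  flat while the model is still improving. The full-scale default patience
  is 5 epochs; the reduced-scale configurations (`toy_train_config()`) use
  8. The active-learning benchmark trains every step for 30 epochs under
  this setting — i.e. to convergence at its scale — because acquisition
  quality is only as good as the model doing the scoring.

## Monte-Carlo dropout and the two uncertainty measures

At prediction time dropout is kept active and the tile is passed through
the network $T$ times (default $T = 50$); batch-normalisation always uses
its frozen running statistics, so the dropout masks are the *only*
stochastic element. Each pass is one sample $\hat\omega_t$ from the
variational posterior over weights, and the predictive posterior is the
average of the per-pass class distributions:

$$P(y \mid o, D) \approx \frac{1}{T}\sum_{t=1}^{T} P(y \mid o, \hat\omega_t).$$

`mc_predict()` returns the full $T \times M$ sample matrix and its mean;
`classify()` takes the argmax of the mean (ties broken toward the lowest
class index). Two uncertainty summaries are computed in nats:

* **Predictive entropy** $H = -\sum_y \bar p_y \log \bar p_y$ — total
  uncertainty, both epistemic (reducible with data) and aleatoric
  (inherent ambiguity).
* **BALD** $= H - \frac{1}{T}\sum_t H[P(y \mid o, \hat\omega_t)]$ — the
  mutual information between the label and the weights; large when the
  passes disagree confidently (epistemic), near zero when every pass
  returns the same possibly-flat distribution (aleatoric).

These satisfy $0 \le \mathrm{BALD} \le H \le \log M$ exactly; the package
clips the occasional $-10^{-16}$ floating-point BALD to zero. Because the
scale of entropy thresholds in the literature is often left implicit, the
records report both raw $H$ and $H_{\mathrm{norm}} = H / \log M \in [0,1]$.

**Seeding of the MC stream.** `score_dataset()` draws one per-unit dropout
mask pair per pass, derived from `(seed, t)`, and applies it to every tile
in the dataset — one weight sample per pass, shared across observations,
which is the literal variational reading of the approximation above. A
welcome consequence is that two pixel-identical tiles always receive
identical records. The alternative (independent masks per tile) would make
records depend on a tile's position in the dataset.

## Active learning

`run_active_learning()` implements pool-based acquisition. Step 0 trains on
a stratified seed set of `seed_per_class` tiles per class (default 40, so
320 for eight classes); each subsequent step scores the *remaining* pool
with the chosen acquisition function — `random`, `entropy_H` or `bald`,
the uncertainty measures sorted descending with lexicographic-id
tie-breaks — acquires `step_size` tiles (default 160; the final step takes
whatever remains), and retrains *from a fresh initialisation* on the grown
labelled set. With a 4496-tile pool this yields 28 steps (0–27), the last
one partial (320 + 26x160 + 16). Per-step test accuracy is measured with
the MC-posterior mean, and `al_compare()` / `al_benchmark()` average traces
over repeats. Traces are compared by the size-normalised trapezoidal area
under the accuracy-vs-size curve (`trace_auc()`), a size-averaged accuracy
in [0, 1].

## Mislabelled-tile detection

Region-level annotation inevitably mislabels some tiles. The detector
(`identify_mislabelled()`) exploits a signature of such tiles: a
well-trained model misclassifies them (relative to their assigned label)
*confidently*, i.e. with low $H$. Given an expected mislabelled percentage
$p_m$, the threshold for class $c$ is the $p_m$-th percentile of the
empirical $H$ distribution among tiles assigned to $c$ (type-7 linear
interpolation between closest ranks — the specific percentile convention
matters for reproducibility, so it is fixed and oracle-tested). Candidates
are the misclassified tiles with $H$ strictly below their class threshold,
unioned over classes. Thresholds are monotone in $p_m$, so candidate sets
nest.

The planted-noise protocol (`plant_label_noise()`,
`evaluate_identification()`) relabels a known fraction $p_m$ of training
tiles to a uniformly drawn *different* class, retrains, runs the detector
at the same $p_m$, and scores it. Following the planted-noise bookkeeping
convention used in this line of work, `sensitivity` is
$|planted \cap P|/|P|$ with $P$ the candidate set (the fraction of flagged
tiles that are truly corrupted — a precision-style quantity) and
`specificity` is the clean fraction of unflagged tiles. Because that
"sensitivity" differs from the usual epidemiological definition, the
standard recall $|planted \cap P|/|planted|$ is always reported alongside.

## Segmentation

`segment_slide()` cuts a slide into non-overlapping `tile_size` squares
(default 50 px; partial edge tiles are dropped — at the canonical
5000x5000/50 geometry nothing is dropped and the grid is exactly 100x100 =
10000 tiles), bilinearly upscales each tile to the model input (128x128 at
full scale), classifies it by the argmax of the MC-posterior mean and
records $H$ per tile. The uncertainty grid is reported for inspection but
never alters a class decision. `render_segmentation()` paints tiles in
class colours and smooths region edges with a Gaussian filter (sigma
defaults to `tile_size/4`; `replicate` boundary handling so image borders
are not contaminated). The blur is cosmetic: `class_area_statistics()`
(percent of tiles per class, always summing to 100) is computed from the
raw class grid before any blurring.

## The synthetic data generator

`generate_dataset()` / `generate_slide()` produce the package's benchmark
data: oriented sinusoidal gratings with class-specific two-colour palettes,
Gaussian blob perturbations and additive pixel noise (SD 12 intensity
units by default). One master seed draws a per-patch seed table up-front,
so every patch is reproducible independently of generation order.

The *confusability* dial emulates a genuinely ambiguous class pair (the
way complex stroma shades into simple stroma): a patch of class $A$ with
confusability $\rho$ draws $\lambda \sim U(0, \rho)$ and renders the
texture with parameters $(1-\lambda)A + \lambda B$. At $\rho = 1$ the two
classes' patch distributions coincide exactly; at $\rho = 0.6$ (the
benchmark setting) about a sixth of each class's mass falls in the overlap
region, leaving a few percent of irreducible (aleatoric) error — enough
for the confusable classes to carry visibly higher mean $H$ and for the
$H$-vs-BALD contrast to be observable.

What the generator deliberately does **not** emulate: H&E stain variation,
pyramidal slide formats, spatial correlation between neighbouring tiles,
class imbalance, and the sheer visual diversity of real tissue. Passing the
reduced-scale benchmarks therefore demonstrates that the machinery is
correct and that the qualitative orderings hold on controllable data — it
does not certify full-scale histopathology accuracy.

## Reduced-scale study conditions

All training-based checks run on one CPU in minutes, at sizes chosen once:

| condition | value |
|---|---|
| tiles | 24x24 px, 4 classes |
| trunk | 8 filters, 1 residual block (~3k parameters) |
| toy convergence / noise benchmark | 120 train + 50 test per class, 20 epochs, T = 25 |
| planted-noise rates | $p_m \in \{0, 10, 30, 50\}\%$, 3 seeds |
| active-learning benchmark | pool 600 (150/class), seed 40/class, +160/step (4 steps), 30 epochs/step, T = 20, 3 seeds |
| cross-validation check | 100/class, k = 2, 40 epochs |

The acceptance script (`scripts/acceptance.R`) re-runs all of the above
from scratch under a caller-supplied seed.

Two of these checks are genuinely stochastic and their margins at desk
scale are small. Occasional training runs collapse the confusable pair
into a single class (test accuracy drops to 0.75) and the plateau rule
then locks the learning rate in that basin; this per-run noise of up to
~0.17 accuracy is larger than the true entropy-vs-random acquisition
effect at a single seed. Averaged over the benchmark's three internal
seeds at its documented conditions the expected orderings hold
(entropy-H acquisition at least matches random; accuracy is non-increasing
in the planted-noise rate), but an individual reseeded run can flip
either — a limitation of the reduced scale, not of the machinery, and one
reason the full-scale protocol averages eight initialisations per
acquisition step.

## Numerical conventions

* Natural logarithms everywhere; $0 \log 0 := 0$.
* Probability clamping at $10^{-12}$ in cross-entropy; BALD clipped at 0.
* Argmax ties break toward the lowest class index; uncertainty-ranking
  ties break by lexicographic id (stable acquisition).
* Percentiles: type-7 (linear interpolation, inclusive endpoints).
* Stratified holdout draws $\lceil n_c/k \rceil$ test tiles per class —
  the only rounding consistent with a 504/4496 split of 8x625 tiles — and
  the $k$ "folds" are independent seeded draws, not a partition (504-tile
  test sets are incompatible with strictly partitioning 5000 tiles into
  ten folds).
* ROC AUC is trapezoidal (equals the Mann-Whitney pair statistic);
  precision-recall area uses the step-wise average-precision convention.
  Both conventions are fixed so results are reproducible, and both are
  cross-checked against independent oracles in the test suite.
* PNG/TIFF IO, bilinear resizing and Gaussian blurring delegate to
  EBImage.

## Known limitations

* The convolutional trunk is a compact residual approximation; no claim is
  made that it reproduces any particular published architecture's
  layer-for-layer behaviour, only the stated structural properties (batch
  norm, residual connections, dropout-bearing dual 32-unit heads).
* MC-dropout is one approximation to Bayesian inference; deep ensembles or
  calibration post-processing are out of scope.
* Max-entropy acquisition is known to chase aleatoric noise when ambiguity
  is strong; the benchmark's confusability setting keeps that regime
  visible without letting it dominate.
* Edge tiles are dropped, not padded; overlapping-tile voting and
  pixel-level segmentation are out of scope.
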