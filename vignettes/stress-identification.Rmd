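---
title: "Identifying stress sources and anxiety states in athlete cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying stress sources and anxiety states in athlete cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressid)
```

## The problem

Athletes under competitive pressure develop anxiety whose *source* matters
for intervention: anxiety rooted in physical condition (body balance,
injury history, muscle strength, exercise load), in the competition
environment (technical errors, track comfort, site humidity, competition
scale), or in cognition (opponent strength, self-regulation, match score,
audience atmosphere) each calls for different counseling. The measurement
instrument is a 12-factor questionnaire, standardized to scores on
$[0, 10]$, with the factors grouped in three blocks of four (A1--A4
physical, B1--B4 competition, C1--C4 cognitive).

`stressid` provides two complementary engines over such score tables:

1. an **unsupervised** two-phase hierarchical clustering that partitions a
   cohort into groups with similar stress profiles, and
2. a **supervised** Gaussian radial-basis-function (RBF) network that maps
   a score vector to one of the three anxiety classes / risk levels.

A synthetic cohort generator, a weighted scoring utility and a small CLI
round out the toolkit.

## Two-phase clustering

### Dividing phase

The cohort $D = \{P_1,\dots,P_n\}$, $P_i \in \mathbb{R}^d$, starts as a
single class. For each class and each dimension $i$ the algorithm builds an
equal-width histogram over the class's own range and looks for a **valley**
— an interior local minimum of the (moving-average smoothed) bin counts. A
valley bin $b$ with threshold $h$ (the median of the values inside the bin,
or the bin midpoint if it is empty) defines the candidate split

$$C_1 = \{P_j : p_i^j \le h\}, \qquad C_2 = \{P_j : p_i^j > h\},$$

which is accepted only if **both** subclasses, counted under the parent's
binning of dimension $i$, retain a (smoothed) peak above the parent's mean
per-bin count $n/B$ — i.e. the split separates two genuine modes. Among
valid candidates the deepest valley wins (ties: lowest dimension, then
lowest bin). Splitting recurses on both children until no class admits a
valid split. The phase deliberately over-segments relative to the true
cluster count; repairs happen bottom-up afterwards.

Three guards keep the valley search statistically honest; all three were
forced by observed failures, and all three are mirrored in the exhaustive
test oracle:

* **Valley significance.** A candidate's smoothed count must fall below
  $n/B - 2\sqrt{n/B}$, roughly two Poisson standard deviations below the
  structureless-bin mean. Without this, flat (uniform) histograms — where
  every bin hovers at the mean — split at routine noise dips; with only a
  plain "below the mean" rule a $300 \times 4$ uniform cloud still
  shattered into 9 clusters.
* **Size-scaled bins.** The effective bin count is
  $\min(B, \lceil\sqrt{n}\rceil)$. At the configured $B = 16$ a class of
  50 points averages 3 samples per bin, and sampling noise fabricates
  "valid" valleys wholesale (two clean 2-D blobs of 100 points dissolved
  into 44 clusters before this guard).
* **Positive depth.** A plateau (valley exactly level with a flank) is not
  a valley.

Tunable parameters, all in `clus_config()`:

| parameter | default | meaning |
|---|---|---|
| `bins` | 16 | maximum histogram bins per dimension |
| `min_cluster_size` | 2 | never produce a subclass smaller than this; classes below twice this size are never split |
| `smoothing_window` | 3 | odd moving-average window on bin counts (1 = off) |

### Agglomerating phase

The dividing tree is walked deepest level first. Two sibling subclasses are
examined once each side has itself collapsed to a single cluster; they merge
if and only if the dividing criterion cannot re-split their pooled members
(`find_split` on the union returns nothing). A merged pair is replaced by
its parent one level up; a refused pair stands, and because only siblings
are ever compared, its ancestors can then never merge across that boundary.

One structural consequence deserves honesty: because `find_split` is
deterministic and the union of two siblings is exactly the node the
dividing phase split, a tree produced by `dividing_phase` *with the same
configuration* is never modified by `agglomerating_phase` — the phase
functions as a consistency check there. It does real work on trees built
otherwise: manually constructed or over-segmented trees (as in the test
suite's artificial-split cases) are repaired to the coarsest partition the
dividing criterion cannot refine. Running the two phases with different
configurations (e.g. dividing with `smoothing_window = 1`, agglomerating
with the default) realizes the over-segment-then-repair dynamic explicitly.

### What a green clustering test establishes

On planted 12-dimensional three-blob cohorts with block-mean separation 5
and spread 0.8 ($\approx 6\sigma$), the algorithm recovers the three
classes at ARI $\ge 0.95$ (the acceptance suite measures $\approx 0.99$
over fixed seeds). Every split is a single-dimension threshold, so
resolution is bounded by one-dimensional mode overlap: at the generator's
default 3$\sigma$ block separation the inter-mode dip is not significant at
two Poisson standard deviations and cohorts cluster as a single class. That
is a property of histogram-valley splitting in general, not of this
implementation; cohorts separated at $\ge 5\sigma$ per coordinate are
recovered reliably (ARI 0.95--0.98 at spread 0.6 in the test suite).

## Weighted scoring and factor grouping

The composite stress score of a profile $e = (e_1,\dots,e_m)$ under
non-negative weights $w$ is the weight-normalized mean

$$Q = \frac{\sum_{i=1}^m w_i e_i}{\sum_{i=1}^m w_i},$$

bounded by the range of $e$, invariant under rescaling of $w$, and equal to
the arithmetic mean under uniform weights (the default — no canonical
factor weighting is built in).

`column_summary()` reports per-factor cohort means **floor-truncated** to
two decimals rather than rounded. The convention is forensic: in the
embedded worked-example table the column means 5.428 and 6.477 print as
5.42 and 6.47, which only truncation produces. Two printed entries of that
table's average row (C3 = 7.47, C4 = 8.42) match neither truncation nor
rounding of their columns (recomputed 6.477 and 7.228) and are treated as
typographical errors; tests assert the ten verifiable factors.

`factor_grouping()` clusters factor *columns* by average-linkage
agglomeration under correlation distance $1 - r$ and cuts the dendrogram at
a height (default 0.90), keeping merges at height $\le$ the cut. Distance
and linkage are package choices: a cut value like 0.90 is only meaningful
on a normalized similarity scale, and $1 - r$ with average linkage is the
standard such scale. Zero-variance columns have undefined correlations and
are isolated as singletons with a warning. Note that the 10-athlete
embedded table alone does *not* reproduce a clean A/B/C block structure at
the 0.90 cut — ten rows are far too few to pin 66 correlations — so no test
asserts it.

## The RBF anxiety classifier

### Model

Three Gaussian hidden units, one per anxiety class, and a single linear
output:

$$y(x) = \sum_{j=1}^{3} w_j R_j(x), \qquad
R_j(x) = \exp\!\left(-\frac{\lVert x - c_j\rVert^2}{2\sigma_j^2}\right).$$

Targets are integer class codes $d_q \in \{1,2,3\}$; by convention physical
anxiety carries code 3, competition 1, cognitive 2 (configurable, but the
physical = 3 anchor is fixed by the method's specification). The scalar
output doubles as a risk score: `predict_risk()` rounds $y$ half-up and
clips to $\{1,2,3\}$ (low / medium / high), and `predict_class()` inverts
the code mapping. The conflation of *class* and *risk level* is inherited
from the method as published; both readings are exposed and the caller
chooses.

### Initialization and training

Initialization uses class statistics: $c_j(1)$ is the mean of class $j$'s
samples, $\sigma_j(1)$ their mean Euclidean distance to that center
(floored at $\sigma_{\min} = 10^{-3}$), and the output weights solve the
$3\times 3$ system $R\,w = d$ built from one representative per class (the
sample nearest its class mean), with a ridge-regularized least-squares
fallback if singular.

Training minimizes the batch error
$\xi = \tfrac12 \sum_q (d_q - y(x_q))^2$ by full-batch gradient descent
with analytic gradients

$$\frac{\partial\xi}{\partial w_j} = -\sum_q e_q R_j(x_q), \qquad
\frac{\partial\xi}{\partial c_j} = -\sum_q e_q \frac{w_j}{\sigma_j^2}
R_j(x_q)\,(x_q - c_j), \qquad
\frac{\partial\xi}{\partial \sigma_j} = -\sum_q e_q \frac{w_j}{\sigma_j^3}
\lVert x_q - c_j\rVert^2 R_j(x_q),$$

each verified against central finite differences on randomized instances
(the published form of the center gradient is typographically corrupted;
the formula above is the unique reading consistent with the error function
and the other two gradients). One iteration is one epoch — the gradient
formulas sum over all samples — and training stops when $\xi < \varepsilon$
(default $0.01N$, i.e. a mean squared residual of 0.02) or after `max_iter`
(default 5000) epochs. Widths are floored at $\sigma_{\min}$ after every
update so no step can produce a non-positive Gaussian.

### Why three learning rates

The defaults are $\eta_w = 5\cdot 10^{-3}$, $\eta_s = 2\cdot 10^{-3}$,
$\eta_c = 5\cdot 10^{-5}$. Batch gradients scale with $N$, and the three
parameter families differ sharply in sensitivity: the output weights are
linear parameters with the widest stable range; widths reshape the
activations more gently; center displacement changes every activation and
directly erodes the interpretability of the units as class prototypes. A
single shared rate large enough to train the weights (e.g. 0.01 for all
three families) makes the error trace oscillate in early epochs and drags
the centers several score units away from the class means — on default
synthetic cohorts the learned "prototypes" ended up to 4 units (Euclidean)
from their classes. With the per-family defaults, training on $n = 500$
default cohorts reaches $\ge 97\%$ training accuracy with centers within
0.42 spread units of the true class means (acceptance suite, five seeds).

### Degenerate inputs and numerical choices

* A class with a single sample gets width $\sigma_{\min}$ (zero mean
  distance, floored).
* `max_iter = 0` returns the initialized network with `converged = FALSE`
  when $\xi \ge \varepsilon$; a network whose initialization already
  satisfies $\xi < \varepsilon$ returns at iteration 0, converged.
* Squared distances are clamped at 0 before exponentiation to absorb
  floating-point cancellation.
* Model JSON is written with 17 significant digits, which round-trips IEEE
  doubles exactly (`jsonlite`'s full-precision default of 15 does not).

## The synthetic generator

`generate_cohort()` emulates the structure the method's original training
cohort is described to have, none of which is deposited: $n = 500$ athletes
(default), three anxiety classes in proportions 0.30 / 0.40 / 0.30
(physical / competition / cognitive — the only class split documented for
such a cohort), and for each athlete four in-block factor scores drawn from
$\mathcal{N}(7.5, 1)$ and eight off-block scores from
$\mathcal{N}(4.5, 1)$, all clipped to $[0,10]$. The block means mirror the
visible pattern of the embedded worked-example table (in-block scores
$\approx$ 7--9, off-block $\approx$ 3--6); the spread of 1.0 is a
realistic questionnaire noise level chosen once.

What the generator does **not** emulate: inter-factor correlation inside a
block beyond the shared mean shift, athlete-level response styles
(acquiescence, extreme responding), integer-valued or skewed score
distributions, and class-mixture profiles (an athlete with two stress
sources). A green end-to-end test therefore establishes that the algorithms
recover clean block structure — not that they are robust to real
questionnaire pathology.

Class counts are `round(n * proportions)` with any rounding remainder
absorbed by the largest class, so counts always sum to `n`. Generation is
byte-reproducible per seed and restores the caller's RNG state.

The two worked-example fixtures are embedded verbatim: the
$10 \times 12$ score table (`table3_fixture()`; its last row is printed
with a duplicated "M1" label in the source and is stored as M10, consistent
with the companion assignment table) and the model-vs-manual assignment
table (`table4_fixture()`), which agree on 9 of 10 athletes (M10: model
competition, manual cognitive).

## Known limitations

* Splits are axis-parallel thresholds; clusters separated only by oblique
  or multivariate structure, or by less than $\approx 4$--$5\sigma$ in
  every single coordinate, are not resolved.
* The sibling-only merge scheme cannot reunite a cluster that an early
  split divided across the tree's top branches; the deepest-valley-first
  selection makes this rare but not impossible.
* The scalar-output RBF imposes an artificial ordering on the three
  classes (the class coded 2 sits "between" 1 and 3 on the output axis);
  with well-separated prototypes this is immaterial, but a one-hot output
  would remove it at the cost of departing from the published design.
* Factor grouping on small cohorts is unstable; treat the 0.90 cut as
  exploratory unless $n$ is comfortably larger than the number of factors.
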