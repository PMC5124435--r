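---
title: "Learning a stochastic edit distance for symbolized physiological time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning a stochastic edit distance for symbolized physiological time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedsax)
```

## The problem

Bedside monitors in intensive care produce univariate vital-sign streams
(here: heart rate, one value per minute) that are discarded after display,
yet carry information about imminent deterioration. sedsax implements a
pipeline that predicts a binary patient outcome — whether an acute
hypotensive episode follows the observed window — from such a stream, by

1. compressing each series into a short **symbol string** (SAX),
2. **learning** how strings of the same cohort relate to each other, as the
   operation probabilities of a stochastic edit distance, and
3. classifying new series by the **1-nearest-neighbour** rule under the
   learned distance.

The learned distance replaces the unit-cost Levenshtein distance: instead
of every insertion, deletion and substitution costing 1, each operation has
a probability estimated from data, and the dissimilarity of `y` given `x`
is `-log p(y | x)`.

## Symbolization (SAX)

Each record is cut into fully overlapping sliding windows of
`window_size` raw values (default 120 — two hours at one sample per
minute, the shortest span over which a stark clinical decline is expected
to be visible). Every window is z-normalized (population standard
deviation; a window with zero variance is replaced by all zeros rather
than dividing by zero), averaged into `symbols` equal segments (PAA;
default 24, i.e. one symbol per 5 minutes), and each segment mean is
mapped to a letter through the standard-normal quantiles that split the
line into `alphabet_size` equiprobable regions (default 3: low / average /
high). A value exactly on a breakpoint takes the higher letter; this
tie-break is arbitrary but fixed.

Two reductions keep strings short enough for the transducer:

* **Run collapse** — consecutive identical words count once. Operating on
  whole words (not single letters) preserves within-word structure.
* **Systematic group sampling** — if the concatenated words still exceed
  `target_length` characters (default 1020), every k-th *word* is kept,
  `k = ceiling(n_words / floor(target_length / word_length))`. An even
  stride preserves temporal patterns better than a simple random sample,
  and sampling whole words never splits the unit that encodes one
  subsequence. With 2,000 five-letter groups (10,000 characters) and a
  1,000-character target the stride is 10 groups (50 characters), leaving
  200 groups and exactly 1,000 characters. We state the stride in words:
  the equivalent character stride is `k * word_length`, and this form
  guarantees the cap for every input size, including those where rounding
  a character stride would overshoot.

Sampling groups are identified with SAX words, so `group_size` defaults to
`symbols`; it is exposed separately for experimentation. Windows are
assumed uniformly sampled at one value per minute; the reader does no
resampling. The final artifact per record is one labeled line,
`1 abbaccabcaba...` or `0 abaacbabcaaa...`.

## The conditional memoryless transducer

The distance model is a single-state two-tape automaton. Conditioned on
the input string, the generative process is: while input remains, with `a`
the next input letter, choose to **insert** letter `b` (probability
`ins[b]`), **substitute** `a` by `b` (`sub[a,b]`; `b = a` included), or
**delete** `a` (`del[a]`); once the input is exhausted, choose between
insertions and **stop** (`gamma`). Memorylessness means these
probabilities do not depend on position or history. Two normalization
constraints follow:

* `sum_b ins[b] + gamma = 1` (end-of-input context), and
* `sum_b ins[b] + sum_b sub[a,b] + del[a] = 1` for every input letter `a`.

The conditional parameterization models `p(y | x)` directly, which is what
a distance for nearest-neighbour classification needs; no joint model over
`(x, y)` is estimated.

`p(y | x)` sums over all edit paths via the forward lattice

```
alpha[i, j] = ins[y_j]   * alpha[i, j-1]
            + del[x_i]   * alpha[i-1, j]
            + sub[x_i,y_j] * alpha[i-1, j-1],    p(y|x) = gamma * alpha[|x|, |y|]
```

with the mirrored backward recursion supplying suffix probabilities. The
E-step reads posterior expected operation counts off the two lattices
(e.g. a substitution at `(i, j)` contributes
`alpha[i-1,j-1] * sub[x_i,y_j] * beta[i,j] / p(y|x)`); the M-step is the
closed-form constrained maximizer: insertions are pooled across contexts,
`ins[b] = n_ins[b] / T` with
`T = sum n_ins + n_end + sum_a (n_sub[a,.] + n_del[a])`, the remaining
mass `M = 1 - sum(ins)` becomes `gamma`, and each input letter's
substitution/deletion counts are scaled to share `M`. A letter never seen
on the input tape receives the uniform conditional share — the only
smoothing anywhere; elsewhere the alphabet is closed and unexplainable
pairs error loudly rather than being silently smoothed.

### Training pairs

The transducer is trained on the **pairdataset**: each training string `x`
paired with its nearest neighbour `NN(x)` under the classic edit distance,
self excluded, ties to the earliest index. By default the neighbour search
stays within the string's own outcome class (`scope = "same_class"`), so
EM concentrates probability on the operations that relate strings of the
same class and the learned distance contracts within-class variation; the
all-classes variant is a flag. Similarly, classification scores
`-log p(train | test)` with the test string on the input tape
(`direction = "input_test"`); the opposite orientation is available since
the asymmetric model makes the choice substantive.

## Numerical choices

* Production lattices are computed in scaled probability space: each row
  of the forward/backward matrices is rescaled by its maximum and the log
  scales accumulated separately, so strings at the 1020-character cap stay
  within double range without a log-sum-exp per cell. A per-row factor
  turns scaled products back into posterior counts; a guard falls back to
  per-cell log accumulation in the (rare) case the factor would overflow.
* `sed_forward()`/`sed_backward()` retain a plain-probability reference
  implementation used by the small-string oracle tests.
* EM defaults: uniform initialization (all end-of-input outcomes
  equiprobable), tolerance `1e-6` on the total log-likelihood, `max_iter
  100`; a Dirichlet random initialization with a seed is available for
  multi-starts. The log-likelihood trace is checked non-decreasing in the
  tests.
* Zero-variance windows are detected at standard deviation `< 1e-12`.
* Metrics with zero denominators (no predicted positives, or no true
  positives) are reported as `NaN`, never coerced to 0.
* A pair with `p(y|x) = 0` yields distance `+Inf` inside classification
  (so other candidates win) but errors inside fitting, where it indicates
  an initialization without full support.

## The synthetic cohort

No clinical recordings ship with the package; `generate_cohort()` emulates
the study layout instead: 58 training patients (28 positive), 10 test
patients (5 positive), 600 minutes per record at one sample per minute.
Signals are AR(1) around a per-patient baseline — the simplest process
with the within-window autocorrelation that SAX words discretize —
with defaults baseline 80 ± 5 beats/min between patients, AR coefficient
0.9, innovation sd 2 beats/min. Positive records add a linear drift
(default −0.15 beats/min per minute) over their final 120 minutes,
mirroring the two-hour clinical horizon; the task predicts hypotension
from heart rate alone, with no generative link between the two specified,
so the direction and size of this proxy effect are free choices, fixed
once and documented here. Setting the drift to 0 yields a null model
with no class signal.

What the generator does **not** emulate: real heart-rate nonstationarity,
circadian and treatment effects, measurement artifacts and gaps, multi-day
records, or actual hypotension physiology. Passing the end-to-end tests
therefore shows that the pipeline extracts a class-correlated temporal
pattern when one exists and finds none when none exists — not that it
reproduces clinical performance figures, which depend on the real
recordings and are out of scope here.

## Problem sizes used by the tests and the acceptance script

Fast checks run on strings of length ≤ 8 against a brute-force edit-path
enumerator (every script enumerated explicitly, tolerance `1e-10`).
Parameter recovery fits 200 and 2,000 sampled pairs of 10-letter inputs
from an identity-leaning ground truth (summed conditional KL below 0.05
at n = 2,000). Sampler-model agreement uses 100,000 Monte-Carlo draws
compared to forward probabilities within three standard errors. End-to-end
cohort runs use the full 58/10-patient layout with EM capped at 12–15
iterations — by then the likelihood gains per iteration are far below the
scale that changes any nearest-neighbour decision, and the cap keeps a
full cohort fit to roughly a minute; null-model accuracy is pooled over a
few seeds and checked against a 99% binomial band around 0.5, and the
drifted power check uses a 0.2 beats/min-per-minute decline.

## Known limitations

* The memoryless model cannot represent position- or context-dependent
  edit costs; contextual (n-gram) transducers and transducer-kernel
  methods are out of scope.
* Only univariate series are handled; no multivariate representation is
  provided.
* `k = 1` nearest neighbour only, matching the method; no voting or
  cross-validation harness.
* EM converges to a local maximum; the uniform initialization is
  deterministic and worked well in recovery simulations, with random
  multi-starts available when it does not.
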