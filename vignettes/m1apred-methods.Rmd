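---
title: "Moment-based encoding and ensemble classification of m1A sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based encoding and ensemble classification of m1A sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

1-methyladenosine (m1A) is a post-transcriptional RNA modification: a
methyl group attached at position 1 of an adenosine base. It is common
at tRNA position 58 and occurs in mRNA and rRNA, and its misregulation
has been linked to mitochondrial defects and several neurological
conditions. Experimental mapping of m1A sites is expensive, so sequence-
based classifiers are used to triage candidate adenosines.

`m1apred` treats the task as binary classification of a fixed-length
window: 41 nucleotides over \{A,C,G,U\} with the candidate adenosine at
the centre (position 21). Everything downstream — feature encoding,
model training, evaluation — consumes such windows.

## The feature encoding

Each window is mapped to a 522-dimensional numeric vector built from
six groups:

| group  | width | content |
|--------|------:|---------|
| PRIM   | 90    | moments of the mono/di/tri position-relative incidence matrices |
| RPRIM  | 90    | the same on the reversed sequence |
| FV     | 84    | overlapping k-mer counts, k = 1, 2, 3 |
| AAPIV  | 84    | per-k-mer sums of occurrence start positions |
| RAAPIV | 84    | the same on the reversed sequence |
| SEQMAT | 90    | moments of the row-major folded token matrix |

Bases are coded A=1, C=2, G=3, U=4 (alphabetical over the RNA
alphabet). No mapping is canonical for this kind of encoding; what
matters is that one bijection is frozen, because every moment value
depends on it. k-mers are indexed lexicographically with the first base
most significant, so the code of a k-mer of all A's is always 1.

### Incidence matrices

The position-relative incidence matrix (PRIM) at level k is a
4^k × 4^k matrix summarising where k-mers sit relative to one another.
The accumulation rule frozen here is

> cell (i, j) = sum of (q − p) over all ordered stream positions
> p < q with token i at p and token j at q.

Other accumulation rules preserving relative-position information would
be admissible; this one is simple, order-sensitive (PRIM of a sequence
and of its reversal differ), and easy to verify against brute-force
pair enumeration, which the test suite does. RPRIM applies the same
rule after reversing the symbols (plain reversal — the input is RNA, so
no complementation is involved).

The sequence matrix (SEQMAT group) folds the token stream row-major
into the smallest square that holds it, zero-padding the tail: 41 mono
tokens become a 7 × 7 matrix with 8 trailing zeros.

### Statistical moments

Matrix-valued groups enter the feature vector through 30 coefficients
rather than raw cells (a tri-nucleotide PRIM alone would otherwise
contribute 4096 features): the 10 raw moments
$N_{jk} = \sum_{c,d} c^j d^k \beta_{cd}$, the 10 central moments taken
about the mass centroid, and the 10 discrete Hahn moments, each at the
order pairs $(j,k)$ with $j + k \le 3$ in a fixed order. Raw moments
are location-sensitive; central moments are translation-invariant
(verified in the tests by embedding a matrix inside a larger zero
matrix); Hahn moments project onto a discrete orthogonal polynomial
family with shape parameters $(u, v)$.

Numerical choices:

* Hahn moments use the separable two-dimensional form
  $H_{ij} = \sum_{p,q} \beta_{pq}\, h_i^{u,v}(p, N)\, h_j^{u,v}(q, N)$
  — one polynomial per axis, which is what makes $H_{ij}$ depend on
  both orders.
* `u = v = 0` by default; both are exposed (`assemble_features(w, u, v)`)
  since they are shape knobs, not fitted quantities.
* The polynomials are used as defined, without norm-based
  normalisation; coefficients at side 64 reach magnitudes around
  10^13–10^14, which double precision carries exactly enough for the
  standard-scaling step that follows.
* Pochhammer symbols are rising factorials computed as direct products;
  for the matrix sides used here (≤ 64) no log-domain evaluation is
  needed.
* A matrix with zero total mass has no centroid; central moments raise
  an error rather than guessing. Valid windows can never produce such a
  matrix (a 41-nt window always yields ≥ 39 tokens).

## The classifiers

Nine configurations across three ensemble families, all retrievable
from `model_registry()` and trainable through `m1a_fit()`:

* **Blending** — four base learners (feed-forward neural network,
  3-nearest-neighbour, RBF-kernel SVM with C = 10 and γ = 10⁻⁴, and a
  deep decision tree) feed a gradient-boosted meta-learner with 100
  estimators. The meta-learner is trained on base-learner scores for an
  inner 20% holdout of the training partition, never on scores the
  bases produced for their own training rows; the bases are then refit
  on the full training partition for prediction. This protocol detail
  is a design choice to prevent meta-learner leakage.
* **Bagging** — random forest (200 trees, depth 50), extremely
  randomized trees (100 trees, depth 40), a single deep decision tree,
  and bootstrap aggregation of 100 trees with out-of-bag scoring
  (reported by `summary()` on the fit). Probability aggregation is the
  mean of member scores; label ties at exactly 0.5 resolve to the
  positive side of the ≥ threshold, applied uniformly everywhere.
* **Boosting** — gradient boosting (learning rate 0.1, 100 rounds,
  squared-error split criterion), histogram-based gradient boosting
  (200 iterations, depth 40) — the strongest configuration and the
  default — AdaBoost (50 rounds of the SAMME weight-update over
  depth-1 trees), and XGBoost (100 iterations, depth 40).

Implementation mapping, for readers comparing with Python ecosystems:
the gradient-boosted models run on `xgboost` (exact tree method for the
plain gradient booster, histogram method for the histogram variant);
forests on `ranger`; single trees on `rpart`; SVM on `e1071`; the
neural base learner on `nnet`. Two deliberate translations: `nnet`
fits a single hidden layer, so the two-layer (5, 2) network becomes a
single hidden layer of 5 units with weight decay 10⁻⁴; and `rpart`
caps tree depth at 30, so nominal depths of 80 saturate at 30 with the
complexity penalty disabled (`cp = 0`), which grows the tree to purity
on these data — the depth cap is not the binding constraint.
The AdaBoost and bagging aggregation loops are written in the package.

Preprocessing is standard scaling (per-feature mean 0, sd 1), fitted on
the training partition only; constant columns pass through as zeros.
Scores are class-1 probabilities in [0, 1]; calls threshold at 0.5 by
default (exposed as `threshold`).

Every training path is deterministic given `seed`: single-threaded
tree learners, seeded forests and boosters, seeded splits.

## Evaluation protocols

`split_70_30()` draws a stratified independent split (train size
round(0.7 n), per-class allocation by largest remainder, so class
proportions in the train partition track the full set to within one
sample per class — the stratification is an interpretation choice made
for variance control). `kfold_plan()` gives k disjoint folds with sizes
differing by at most one. Metrics are sensitivity, specificity,
accuracy, MCC, F1 and AUROC; MCC returns 0 when any denominator factor
vanishes (the standard degenerate-table convention), and AUROC is the
Mann–Whitney rank statistic with ties counted one half.

Three significance tests compare classifiers: the pooled two-proportion
z test on test-set accuracies; McNemar's test on discordant calls
(exact binomial below 25 discordant pairs, continuity-corrected
chi-square above, with the statistic floored at zero so equal
discordant counts give p = 1); and a resampled paired t test over
repeated 70/30 resplits with accuracy as the paired statistic and
trials − 1 degrees of freedom. With zero variance across trials the t
statistic degenerates; the guard returns p = 1 for a zero mean
difference and p → 0 otherwise.

## The synthetic generator

Real m1A training data derive from transcriptome-wide resources that
this package does not ship or download. `synth_windows()` instead
generates labelled windows reproducing the qualitative compositional
structure of that data: a U/A-rich background with G flat; C confined
to a narrow band two positions either side of the centre (positions
19–23 at W = 41); the centre forced to A. The profile probabilities
(background A/C/G/U = .35/0/.20/.45; band = .30/.25/.15/.30) are
toolkit choices — the real position-specific probabilities are not
published — and can be replaced via the `profile` argument.

The class signal is a planted dinucleotide ("AG" by default) inserted
at six disjoint anchor slots upstream of the centre (positions 9 to 19
in steps of two), each independently with probability
1 − exp(−effect/2). A positional dinucleotide enrichment, rather than
a single-base frequency shift, was chosen deliberately so the
incidence-matrix and position-sum groups — not just the frequency
vector — carry discriminative information. `effect = 0` makes the two
classes exchangeable by construction.

What the generator does **not** emulate: homology structure between
windows, species mixture, genuine motif grammar around m1A sites, or
class imbalance. Passing the recovery tests therefore demonstrates
that the encoding and models can extract a planted positional signal
end-to-end — not that they attain any particular accuracy on real
transcriptome data.

## Problem sizes and tolerances in the checks

The test suite verifies the moment engine against independent
brute-force double-sum oracles at 10⁻⁹ relative tolerance on 200
random matrices of sides 2–16, the metrics against the direct formulas
on every confusion table with at most 20 samples, and signal recovery
with 2000 windows (held-out AUROC ≥ 0.90 at effect 3, and within
[0.45, 0.55] at effect 0); the nine-model sweep runs on a 400-window
set. These sizes keep a full run of the suite in the minutes range on
one core while leaving the statistical assertions comfortably away
from their thresholds.

## Known limitations

* The registry freezes the published hyperparameters; there is no
  tuning machinery, by design.
* `rpart`'s depth-30 cap and `nnet`'s single hidden layer are the two
  places the configurations are approximated rather than reproduced
  exactly (see above).
* Feature encoding is ~20 ms per window single-threaded; encoding
  millions of scanned sites would call for chunking by the caller.
* The 0.5 call threshold is a convention, not a calibrated operating
  point; `run_predict()` exposes it.
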