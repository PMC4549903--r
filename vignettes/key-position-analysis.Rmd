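---
title: "Key-position analysis of nucleosome formation affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key-position analysis of nucleosome formation affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleokey)
```

## The data model

The unit of analysis is a pool of fixed-length (150 bp) DNA oligos, each
carrying a measured nucleosome-formation affinity: the log-ratio of the
sequence's abundance after competitive nucleosome reconstitution over its
abundance in the initial pool. Positive affinity means the sequence
out-competed the pool for histone octamers.

`filter_by_affinity()` discards the weakly informative middle of the
affinity distribution: only records with affinity strictly above 1 (labeled
positive) or strictly below 0 (labeled negative) are kept. The strictness
is deliberate — affinity exactly 0 or 1 is dropped — because the class
definition ("clearly forms" vs "clearly resists" nucleosomes) should not
depend on boundary ties; the filter is idempotent and order-preserving.

Coordinates are 1-based and inclusive throughout the user-facing layer. A
*diad* (dinucleotide) "at position p" starts at base p, so a 150 bp oligo
has 149 diad positions. This convention is chosen so that reported
key-position lists (which reach position 132 for 20-position sets) fit
naturally in 1..149.

## Diad partitions and the per-sequence weight

An experiment is defined by a *diad partition*: a nucleosome-favouring
positive set and a disfavouring negative set. The three standard
experiments differ only here:

```{r partitions}
standard_partitions()
```

The rationale: position-wise frequency profiles (`position_frequency()`)
show CC/CG/GC/GG enriched in positive-affinity sequences and AA/AT/TT in
negative ones; TA separates the classes poorly (hence `4-3` drops it) while
AC separates them well (hence `5-4` adds it).

Each record gets the scalar weight

$$ w = \begin{cases} af\,(n_1 - n_2), & af \ge 0 \\ af\,(n_2 - n_1), & af < 0 \end{cases} \;=\; |af|\,(n_1 - n_2), $$

with $n_1$/$n_2$ its positive/negative diad counts (overlapping
occurrences counted, the standard k-mer convention). The two branches are
algebraically one formula, $|af|(n_1-n_2)$ — a property-tested identity in
the suite. Because the sign of $w$ always points along the diad excess, the
package reads $|w|$ as a per-record *confidence* (sample weight) and
carries the class in the sign of the affinity. The alternative reading of
$w$ as a regression target is implemented only in the single-class
profiler (below), where no classification target exists.

## The single-layer network

Each sequence is encoded as $x \in \{+1, 0, -1\}^{149}$: $x_p = +1$ if the
diad at $p$ is in the positive set, $-1$ if in the negative set, else 0.
The learner is a single-layer network — a linear score
$s = \sum_p \beta_p x_p + b$ with logistic output — because the method's
product is exactly one weight per position; a hidden layer would not yield
per-position weights directly.

Fitting minimizes the sample-weighted **mean** logistic loss plus a ridge
penalty $\tfrac{\lambda}{2}\lVert\beta\rVert^2$ (bias unpenalized) by
damped Newton iterations (IRLS with step halving). Numerical choices:

* **Weighted mean, not sum.** Sample weights are normalized to sum 1, so
  duplicating every record leaves the optimum unchanged (a tested
  invariant) and $\lambda$ means the same thing at every pool size.
* **Ridge $\lambda = 10^{-3}$** (default). The ternary features are
  near-separable when the planted or biological signal is strong; the
  ridge keeps the optimum finite and suppresses the variance of the 139
  signal-free positions without disturbing the ranking of the informative
  ones. Values within an order of magnitude behave equivalently for
  position *ranking*, which is all that downstream selection consumes.
* **Zero initialization, damped steps, relative-loss tolerance
  $10^{-10}$, at most 50 iterations.** Newton from zero is deterministic,
  so identical data and config give bit-identical weights; the seed in
  `training_config()` exists for fold derivation, not the optimizer.
* **Degenerate inputs.** Single-class input is rejected with a pointer to
  the single-class profiler; all-zero sample weights are an error; the
  IRLS working weights are floored at $10^{-15}$ to keep the Hessian
  solvable under perfect fits.

"Divide all data into 10 parts equally" with a "9-1" protocol is read as
10-fold cross-validation: `make_folds()` assigns folds deterministically
from a seed, stratified by label, sizes differing by at most one. For each
fold the network trains on the other nine parts; held-out confusion counts
are recorded per fold and the per-position weights are aggregated across
folds by the arithmetic mean.

## Key positions and the restricted classifier

`select_key_positions()` ranks positions by $|\beta_p|$ — magnitude, not
signed value, because positions with strong *negative* effect are as
informative about binding as positive ones; a `signed = TRUE` switch
exists for sensitivity analysis. Ties break toward the smaller index,
making selection deterministic and the top-$k$ set monotone in $k$.

The classifier then scores a sequence from the key positions only,
$s = \sum_{p \in K} \beta_p x_p + b$, i.e. the full score with non-key
weights zeroed (a tested masking identity). Key weights are reused from
training by default — the leaner choice given that nothing in the protocol
mandates refitting; `cv_keypos_evaluation(refit = TRUE)` instead retrains
the network per fold on the key features alone for comparison. The
decision threshold defaults to 0 (score exactly 0 classifies negative);
nothing in the protocol suggests a tuned threshold.

Metrics are computed from the *mean* of the per-fold confusion quadruples
(which is why fractional counts such as TP = 786.3 are legal inputs — all
four metrics are invariant to a common positive rescaling of the counts)
and reported ×100 at one decimal. MCC equals the phi coefficient, the
Pearson correlation of the binary prediction and label vectors; the suite
verifies this against brute-force enumeration of every integer confusion
table of total ≤ 20. Zero denominators flag the affected metric as
undefined instead of erroring.

## The single-class profiler

For a positive-only or negative-only subset no classification target
exists, so `profile_weights_single_class()` fits the linear score to the
affinity value by ridge least squares. This is a design decision: it is
the simplest model producing a per-position profile comparable in shape to
the logistic one, and on synthetic subsets it recovers planted positions'
extreme weights. Ridge normal equations are used instead of a
rank-revealing least squares so that positions never touched by the
partition's diads receive weight ~0 rather than an undefined coefficient.

## The synthetic generator

`synthetic_spec()` / `generate_pool()` emulate exactly the structure the
analysis assumes: independent background bases; a class per record; a
class-conditional Gaussian affinity; and, at each planted position, with
probability $\Delta$ (the effect size), the diad overwritten by a uniform
draw from the class-consistent diad set, overlaps resolved left to right.

Defaults are the package's desk-scale study conditions, fixed once:

* **2000 sequences** — large enough for stable 10-fold training on 149
  features, small enough that the full recovery harness runs in seconds.
* **10 planted positions, evenly spread** (10, 25, ..., 145) — mirrors the
  10-position key sets and avoids overlap artifacts.
* **Effect size Δ = 0.30** — a moderate, partly masked signal: at a
  planted position the class-consistent diad probability rises from the
  background 4/16 to 0.475.
* **Class balance 0.573** — the positive fraction of the real ~43,800-oligo
  microarray pool.
* **Affinity ~ N(1.5, 0.5) / N(−1, 0.5)** — chosen so the strict filter
  keeps most records (a few percent fall in [0, 1] and are dropped) and so
  affinity sign almost always agrees with the class, as in a clean
  measurement.

What the generator does **not** emulate: dinucleotide periodicity
(~10 bp helical phasing), composition heterogeneity, measurement error
structure of the microarray, PCR bias, read-count filtering, or any
mechanistic link from sequence to affinity (affinity is drawn, not
computed). Passing recovery tests therefore demonstrates that the
estimator finds *planted position-specific diad biases of the stated
size*; they do not certify performance on real pools, where the signal is
weaker, periodic, and entangled with base composition.

Under these conditions the cross-validated top-10 selection recovers ≥ 8
of the 10 planted positions in ≥ 90% of seeds, and under Δ = 0 the
selection is unstable across seeds (near-chance pairwise overlap), the
null control.

## The pipeline

`run_experiment()` chains input (files or generator) → filter → profiles →
CV training → key selection → key-restricted held-out classification →
metrics, writing plot-ready TSV tables, a `run.log` with per-stage record
counts, and a `manifest.json` carrying the config, seed and md5 hashes of
inputs and outputs. All randomness flows from the single run seed through
derived per-stage seeds; two runs with the same config are byte-identical
outside the timestamped log. `run_standard_experiments()` fans out over
the three standard partitions and writes a key-set comparison
(`compare_key_sets()`: exact, ±1-tolerant one-to-one, and Jaccard
overlap).

## Known limitations

* The pool must be fixed-length, single-strand, A/C/G/T only; no
  reverse-complement augmentation or symmetrization is performed.
* Only diads (k = 2) are modelled; no gapped or phased k-mer scoring.
* The learner is linear in the ternary encoding; interactions between
  positions are invisible to it by construction.
* No periodicity statistic is computed for the key-position spacing, and
  no ROC/threshold calibration beyond the fixed cut at 0.
* Real-pool reference quantities (dataset counts, published key-position
  lists) require the external affinity download and are used only as
  comparison inputs, never re-derived here.
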