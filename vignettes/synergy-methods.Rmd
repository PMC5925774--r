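---
title: "Scoring and predicting drug-combination synergy with synscreen"
author: "synscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and predicting drug-combination synergy with synscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

# The problem

High-throughput combination screens measure two-drug checkerboards —
factorial dose grids of two compounds on one cancer cell line, read out
as percent of untreated control growth. A combination is *synergistic*
when it inhibits growth more than an additivity null model predicts from
the two single agents alone. `synscreen` covers the full path from raw
screen tables to benchmarked synergy predictors:

1. score every checkerboard against its Loewe-additivity reference;
2. featurise drugs (chemistry) and cell lines (expression);
3. train a symmetric feed-forward network to regress synergy from those
   features, against bespoke baselines;
4. evaluate everything under stratified nested cross-validation in four
   generalisation regimes.

# Loewe scoring

## The single-agent model

Each (drug, cell line) single-agent screen is summarised by a
four-parameter Hill curve

$$E(c) \;=\; E_\infty + (E_0 - E_\infty)\,
  \frac{\mathrm{EC}_{50}^{\,h}}{\mathrm{EC}_{50}^{\,h} + c^{\,h}},$$

with `e0` the zero-dose response (% of control, typically near 100),
`einf` the asymptote at infinite dose, `ec50` the half-effect
concentration in µM and `h` the slope. Responses are *never clipped*:
values above 100 (growth stimulation) or below 0 (cytotoxic readouts)
are legitimate assay output. `fitHill()` averages replicates per dose and
runs bounded Levenberg–Marquardt least squares (`minpack.lm`), with
`ec50` initialised at the geometric mean of the nonzero doses, `h = 1`,
and `e0`/`einf` from the extreme-dose responses; bounds are
`h ∈ [0.1, 10]` and `ec50` within two decades of the dose ladder, with
three restarts a decade apart in `ec50`. A fit to constant responses (an
inactive agent — common in real screens) returns a *flat fallback curve*
with `e0 = einf` and a classed warning rather than an error, so
screen-scale pipelines keep running.

## The additivity reference and the score

Under Loewe additivity the combination behaves as if each drug were a
dilution of the other: the expected response $E$ at doses $(a, b)$
solves

$$\frac{a}{A(E)} + \frac{b}{B(E)} = 1,$$

where $A$ and $B$ invert the two Hill curves. `loeweReference()` solves
this by bisection on $E$ over the overlap of the two curves' attainable
response ranges, to an absolute tolerance of $10^{-6}$ (well below assay
noise) in at most 200 iterations. Three edge cases are defined
explicitly: both doses zero returns the mean of the two `e0` values; a
single zero dose returns the other agent's Hill response exactly; and
when the index equation has no root in the overlap — one drug simply
cannot reach the other's effect level — $E$ is clipped to the nearest
jointly attainable boundary instead of erroring, because inactive and
weakly potent agents are routine. A flat single-agent curve degrades the
reference to the highest-single-agent response, with a warning.

A measured 4×4 checkerboard is embedded by `assembleSurface()` into a
5×5 surface whose zero-dose edges are Hill predictions and whose corner
is the mean of the two fitted `e0` values (both should be ≈ 100; the
mean is our choice of tie-break). `synergyScore()` then sums, over the
16 nonzero-dose wells, the deviation

$$\text{reference} - \text{observed},$$

so positive scores mean more inhibition than additivity, i.e. synergy.
The **sum** over wells (in %-of-control points) is the default
aggregation: screen-scale score distributions span roughly −300 to +180,
a range only a summed deviation can produce; a per-well `mean` is
available via the `aggregation` flag. Replicates are always averaged
before scoring. Sham consistency — a drug combined with itself under
dose addition scores 0 — holds by construction and is enforced by tests
to `1e-3`.

# Featurisation

Drugs are described by three typed blocks, concatenated with per-column
kind tags (`count`, `continuous`, `binary`) that survive filtering and
concatenation because the MinMax kernel downstream needs them:

* **Circular fingerprint counts** (`ecfpCounts()`): Morgan-style
  atom-environment counts of radius 3 (diameter 6), folded by a 32-bit
  FNV-1a hash into 2048 columns (the pre-filter width is our choice; the
  variance filter prunes it per training set). SMILES are canonicalised
  through OpenBabel first, so any spelling of a structure yields the
  identical vector. Environments covering the same atom set at different
  radii are de-duplicated, as in standard extended-connectivity
  fingerprinting.
* **Physico-chemical descriptors** (`physchemDescriptors()`): a fixed,
  documented list of 16 — OpenBabel's MW, logP, MR, TPSA, HBD, HBA and
  fluorine count, plus graph-derived heavy-atom, ring, ring-atom,
  ring-bond, rotatable-bond, N, O, S/halogen and formal-charge counts.
  Descriptor failures surface as `NA`, never as silent zeros.
* **Toxicophore flags** (`toxicophoreFlags()`): one 0/1 flag per SMARTS
  structural alert. The package ships a small literature-derived default
  set (nitroaromatics, aromatic amines, epoxides, Michael acceptors,
  quinones, …) in `inst/extdata/toxicophores.smarts`; the file format is
  `name<TAB>pattern` and users substitute their own curated set. Invalid
  patterns are rejected when the set is loaded, not per molecule.

Salt handling and pH-specific protonation are *not* re-implemented;
structures are consumed as given (canonicalisation aside). Cell lines
are described by a post-summarisation expression matrix
(`loadExpression()`), optionally restricted to an informative-gene mask
file; no re-normalisation happens at load time, because summarisation
belongs upstream. `zeroVarianceFilter()` drops exactly the columns with
zero variance over a reference (training) row set and returns a
replayable column mask, so held-out entities are always projected into
the training feature space.

# Input normalisation

Three strategies, fitted strictly on training rows
(`fitNormalizer()` / `applyNormalizer()`):

| strategy         | transform                                             |
|------------------|-------------------------------------------------------|
| `norm`           | standardise per column                                |
| `norm_tanh`      | standardise, then `tanh` (bounded in (−1, 1))         |
| `norm_tanh_norm` | standardise, `tanh`, standardise again (second pass fitted on the tanh-transformed training values) |

All feature columns — both drugs' chemistry and the expression block —
are transformed uniformly; zero-variance columns store a standard
deviation of 1 so the transform stays defined when a fold split
reintroduces a constant column after variance filtering. Tests mutate
held-out rows and assert the normaliser state is untouched; no statistic
ever sees validation or test rows.

# The symmetric network

`trainSynergyNet()` trains a fully connected network on the
concatenation (drug A ‖ drug B ‖ cell line): ReLU hidden layers (two or
three; *conic* when widths halve, e.g. 64→32, *rectangular* when
constant), a single linear output, mean-squared-error loss, plain SGD
(no momentum, no schedule — none is part of the method), optional
inverted dropout (the screen-scale setting is input 0.2 / hidden 0.5),
and Glorot-style variance-scaled uniform initialisation from the config
seed. Because a combination must not depend on the order its drugs are
written down, the training set is **doubled** — each sample appears as
A‖B‖cell and B‖A‖cell with the target duplicated (fold assignment
happens *before* doubling, so the two orderings never straddle folds) —
and prediction propagates both orderings and averages, which makes
`predictSymmetric()` exactly order-invariant, bit for bit. A flag
disables the averaging for ablation.

Early stopping follows the moving-average rule: after each epoch the
validation MSE enters a trailing moving average over 25 epochs, and the
weights kept are those of the epoch minimising that average — not the
final epoch. The per-epoch log (`epoch, train_mse, val_mse,
val_mse_ma25`) is saved with the model so the stopping decision can be
re-derived; with identical seeds and configs the log is identical (the
implementation is single-threaded base R matrix code, so determinism is
exact). Non-finite losses abort with a classed error recommending a
lower learning rate (at screen scale the method's preferred rate is
small, $10^{-5}$; the reduced worlds here train well at $10^{-2}$ to
$5 \times 10^{-3}$).

# Baselines

**Median polish** (`medianPolishFit()` / `medianPolishPredict()`): each
prediction is the mean of the two drug medians and the cell-line median
of the training synergy scores; unseen entities fall back to the global
median. It uses no features at all, which is exactly what makes it the
right floor for the benchmark.

**Modified MinMax kernel** (`minmaxKernel()`): for nonnegative vectors,

$$K(\mathbf x, \mathbf z) =
  \frac{\sum_{p:\,x_p + z_p > 0} \min(x_p, z_p)/\max(x_p, z_p)}
       {\#\{p : x_p + z_p > 0\}},$$

a Tanimoto/Jaccard generalisation to counts and continuous values, in
[0, 1], symmetric, and 1 on identical nonzero vectors. Signed continuous
columns are routed through `posNegSplit()` first (each column `f`
becomes `max(f, 0)` and `max(−f, 0)`; counts and binaries pass through),
which is why kind tags exist. For a pair of all-zero vectors both
conventions are selectable — similarity 1 ("identical objects", the
default) or 0 ("no shared features") — since the definition's fallback
denominator of 1 is ambiguous on empty support. The kernel feeds any
kernelised regressor that accepts a precomputed matrix (e.g. a ν-SVR);
regressor internals are deliberately out of scope and enter through the
pluggable learner interface (`synergyLearner()`).

# Cross-validation regimes

`makeFolds()` implements four schemes (k = 5 by default):

* `random` — shuffled samples; the optimistic regime.
* `leave_combination` — every *unordered drug pair* confined to one
  fold: test combinations are novel, their drugs and cell lines are not.
  This is the headline regime.
* `leave_drug` / `leave_cell_line` — entities partitioned across folds;
  a fold's test set is every quartet touching a held-out entity, and its
  training set every quartet touching none of them. Quartets whose two
  drugs are held out in *different* folds go to the test fold of the
  lexicographically smaller drug identifier (deterministic, audit-
  flagged via `crossFold`) and are excluded from both folds' training
  sets.

Groups are shuffled with the seed and assigned greedily to the smallest
fold by sample count. The inner split carves roughly a quarter of each
outer training set — by the same scheme — as the validation set; we use
one validation split per outer fold rather than a full inner k-fold,
matching the single-validation-set construction of the early-stopping
rule, and the choice is switchable in principle by re-carving.
`auditFolds()` re-derives the defining properties (coverage,
disjointness, pair/entity leakage; size balance only for the
sample-level schemes, since entity-held-out test sets legitimately vary
with entity connectivity), and `nestedCV()` selects each fold's
hyperparameters by inner-validation MSE before applying the refitted
winner exactly once to the outer test fold. One refit subtlety: learners
that need a held-out monitor (the network's early stopping) refit on the
inner-training set keeping the validation monitor; closed-form learners
(median polish, penalised linear models) refit on the full outer
training set. The distinction is the learner's `usesValidation` flag.

# Metrics

`regressionMetrics()` reports MSE, RMSE (= √MSE by construction) and
Pearson's r (undefined — `NA`, never 0 — under zero variance).
`classificationMetrics()` thresholds *measured* scores at 30 (the heavy
right tail, roughly the top decile of a screen-shaped distribution) to
define positives, computes ROC AUC by the rank (Mann–Whitney) formula
and PR AUC by a descending-score sweep from the continuous predictions,
and accuracy, balanced accuracy, precision, sensitivity, specificity and
Cohen's κ from predictions thresholded at a cut chosen by
`selectThreshold()`: the midpoint between sorted unique predicted values
maximising balanced accuracy on a validation set, ties broken toward the
lower cut (predictions concentrate near zero, so a deliberate threshold
choice matters). Method pairs are compared by the Wilcoxon signed-rank
test on per-sample squared errors over identical test points
(`pairedMethodTest()`; zero differences dropped per the standard
convention, all-tied inputs reported as undefined).
`groupwiseCorrelation()` gives the per-drug / per-cell-line
applicability-domain summary, flagging undersized or zero-variance
groups instead of dropping them. Fold reports carry mean ± sd rows; we
do not construct parametric confidence intervals for fold means, and the
bootstrap is left to the user — the per-fold table is returned whole.

# The synthetic world

Real screens of this shape (tens of drugs, tens of cell lines, hundreds
of combinations) are external data; the generator gives every module a
self-contained test surface with *known* ground truth.

* `generateDesign()` reproduces the screen layout: an exhaustive set
  combined all-vs-all plus a supplemental set combined only against it.
  At full scale (22 + 16 drugs, 39 cell lines) this enumerates 583
  pairs — 83% of the 703 possible — and 22 737 quartets.
* `generateWorld()` plants structure featurisation can recover: drugs
  carry a latent mechanism class expressed through count/continuous/
  binary features; cell lines carry latent pathway activities expressed
  through a quarter of the expression genes; true synergy is a
  heavy-tailed symmetric class-pair interaction modulated by a
  pathway activity, plus Gaussian noise (sd 5 by default). Labels are
  rescaled to sd 23 and median 4.4 — the shape of screen-scale Loewe
  score distributions: mass near zero, heavy tails. Because the signal
  is a pure interaction, the feature-free median-polish baseline cannot
  express it while a network can — which is precisely the contrast the
  benchmark probes.
* `generateSurfaces()` inverts the scoring pipeline: Hill curves drawn
  per (drug, cell line) (`e0 ~ N(100, 2)`, `einf ~ U(0, 50)`, log-
  uniform `ec50` inside the ladder, `h ~ U(0.8, 2.5)`), single-agent
  tables at 8 log-spaced doses × 6 replicates, checkerboards at 4×4
  doses × 4 replicates equal to the Loewe reference minus a planted
  deviation, plus measurement noise (2% of control by default). The
  deviation pattern is a smooth mid-dose bump by default — so recovery
  tests exercise interpolation, not just constants — with a uniform
  option for exact linearity checks (per-well δ on 16 wells recovers
  16·δ under sum aggregation).

What the generator does *not* emulate: real compound structures or
expression values, plate/batch effects, dose-ladder misalignment,
heteroscedastic assay noise, or the correlation structure of real
pharmacology. Green tests therefore demonstrate the *machinery* —
scoring identities, leakage-free splitting, learnability of planted
interactions — not predictive performance on any real screen.

# Problem sizes and numerical choices

The test and acceptance suites run on reduced worlds chosen as the
package's own working sizes: an 8-drug × 6-cell-line world (150
quartets) for fast module tests, a 16-drug × 12-cell-line world (1 260
quartets) for the network-vs-baseline benchmark, and the full 38 × 39
design for pure arithmetic and split audits. The benchmark network is
conic [64, 32], learning rate 5 × 10⁻³, 150 epochs, batch 64, no
dropout (at 10³ samples the early-stopping regulariser suffices; dropout
earns its keep at 10⁴⁺ samples and 10³⁺-unit layers). Bisection
tolerance 10⁻⁶; Hill-fit restarts 3; all RNG flows from explicit seeds
and every simulated quantity is a pure function of them.

# Limitations

* Loewe scores depend on the fitted Hill curves; strongly non-sigmoidal
  single agents degrade the reference before any learning happens.
* The bisection-based reference assumes both curves are monotone in the
  same direction; mixed-direction pairs are rejected rather than
  guessed.
* The network implementation is plain R matrix code: exactly
  reproducible and fast at reduced scale, but not intended for
  10⁸-parameter screen-scale training.
* The empty-support kernel convention and the sum-over-wells score
  aggregation are documented choices where the underlying definitions
  are ambiguous; both have switches.
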