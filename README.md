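# synscreen

Analysis of two-drug combination screens in cancer cell lines: Loewe
synergy scoring of dose–response checkerboards, drug and cell-line
featurisation, and machine-learned synergy prediction with leakage-free
benchmarking.

## Who this is for

Groups running (or reanalysing) combination high-throughput screens of
the common design — separate single-agent screens (8 concentrations, 6
replicates) plus 4×4 combination checkerboards in quadruplicate across a
cell-line panel — who want (i) principled synergy scores per
(drugA, drugB, cellLine) and (ii) predictive models that are evaluated
honestly for *novel combinations*, *novel drugs* and *novel cell lines*,
not just random holdout.

## The core quantities

**Single agents** are summarised by four-parameter Hill curves
`E(c) = E∞ + (E0 − E∞)·EC50^h / (EC50^h + c^h)` (percent of control,
never clipped). **The additivity null** is Loewe: the expected
combination response `E` at doses `(a, b)` solves

```
a / A(E) + b / B(E) = 1
```

with `A`, `B` the inverse Hill curves (solved by bisection to 1e-6; a
drug combined with itself scores exactly zero under this null). Each
measured 4×4 checkerboard is embedded in a 5×5 surface whose zero-dose
edges come from the Hill fits, and the **synergy score** is the sum over
the 16 nonzero-dose wells of `reference − observed` (%-of-control
points; positive = synergistic).

**The predictor** is a symmetric feed-forward network on the
concatenation (drug A features ‖ drug B features ‖ cell-line
expression): ReLU hidden layers, linear output, MSE loss, plain SGD,
optional dropout, and early stopping at the epoch minimising the
25-epoch moving average of validation MSE. Each training sample enters
in both drug orders and prediction averages both orders, so outputs are
exactly order-invariant. Baselines: median polish (mean of the two drug
medians and the cell-line median) and a modified MinMax kernel
`K(x, z) = Σ min(x_p, z_p)/max(x_p, z_p) / #{p active}` for mixed
count/binary/continuous features (after positive/negative splitting),
for use with any precomputed-kernel regressor. Evaluation is stratified
nested 5-fold cross-validation in four regimes (random,
leave-combination-out, leave-drug-out, leave-cell-line-out) with a
regression and classification metric panel (MSE/RMSE/Pearson r; ROC and
PR AUC, ACC, BACC, PREC, TPR, TNR, Cohen's κ at a balanced-accuracy-
optimised threshold, positives = measured score > 30).

## Worked example

Simulate a small screen with planted synergy, score it, and benchmark
the network against the median-polish baseline under
leave-combination-out cross-validation:

```r
library(synscreen)

## a reduced screen: 5 exhaustive + 3 supplemental drugs, 6 cell lines
design <- generateDesign(5L, 3L, 6L)
nrow(design$pairs)      # 25 drug pairs
nrow(design$quartets)   # 150 (pair, cell line) samples

## synthetic world with latent drug classes and cell pathways
world <- generateWorld(design, seed = 7)
round(sd(world$quartets$synergy), 1)      # 22.4  (screen-shaped labels)
round(median(world$quartets$synergy), 1)  # 4.5

## dose-response surfaces carrying the planted synergy, then re-score
surf <- generateSurfaces(design$quartets,
                         plantedScore = world$quartets$synergy,
                         noiseSd = 0, pattern = "uniform", seed = 1)
scored <- scoreSurfaces(surf$singleAgent, surf$checkerboards)
m <- merge(scored, world$quartets,
           by = c("drug_a", "drug_b", "cell_line"),
           suffixes = c(".scored", ".planted"))
max(abs(m$synergy.scored - m$synergy.planted))
## 3.1e-13: the pipeline recovers the planted scores exactly at zero noise

## leakage-free benchmark
folds <- makeFolds(world$quartets, "leave_combination", k = 5, seed = 3)
all(auditFolds(folds, world$quartets))    # TRUE
cv <- nestedCV(world$quartets, folds, synergyLearner("medianPolish"))
regressionMetrics(cv$predictions$y, cv$predictions$yhat)$mse
## 511.2  (the feature-free floor on this world)
```

At this miniature scale the baseline is hard to beat; on the larger
synthetic world used by `scripts/acceptance.R` (16 drugs × 12 cell
lines, 1 260 quartets) the symmetric network reaches a cross-validated
MSE about 80% below median polish with Pearson r ≈ 0.93 for novel
combinations.

A command-line wrapper for the whole pipeline lives at
`inst/cli/synscreen.R` (`score-surfaces`, `featurize`, `simulate`,
`train`, `predict`, `evaluate`).

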