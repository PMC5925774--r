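## Stratified nested cross-validation in four generalisation regimes,
## plus the regression/classification metric panel.

## shuffle groups with the seed, then assign each (largest pending first
## after shuffling) to the currently smallest fold by sample count
greedyAssign <- function(groupSizes, k) {
  load <- numeric(k)
  fold <- integer(length(groupSizes))
  for (i in seq_along(groupSizes)) {
    f <- which.min(load)
    fold[i] <- f
    load[f] <- load[f] + groupSizes[i]
  }
  fold
}

#' Assign quartets to cross-validation folds
#'
#' Builds the outer test folds and per-fold inner train/validation split
#' under one of four schemes:
#' \describe{
#'   \item{`random`}{samples shuffled into `k` balanced folds.}
#'   \item{`leave_combination`}{every unordered drug pair is confined to
#'     one fold, so test combinations are never seen in training (the
#'     "novel combination" regime).}
#'   \item{`leave_drug`}{drugs are partitioned into `k` groups; fold
#'     `f`'s test set is every quartet touching a held-out drug of `f`,
#'     and its training set every quartet touching none of them.}
#'   \item{`leave_cell_line`}{same, partitioning cell lines.}
#' }
#' Groups are shuffled with the seed, then assigned greedily to the
#' smallest fold by sample count. Quartets whose two drugs fall into two
#' different held-out groups are assigned to the test fold of the
#' lexicographically smaller drug and flagged `crossFold`; they are
#' excluded from the training sets of both folds involved. The inner
#' validation split carves roughly a quarter of each outer training set
#' by the same scheme.
#'
#' @param quartets data.frame with `drug_a`, `drug_b`, `cell_line`.
#' @param scheme split scheme (see above).
#' @param k number of outer folds (default 5).
#' @param seed integer seed; identical seeds give identical assignments.
#' @return A [FoldAssignment-class].
#' @export
makeFolds <- function(quartets,
                      scheme = c("random", "leave_combination",
                                 "leave_drug", "leave_cell_line"),
                      k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(quartets)
  if (k < 2L) stopf("synscreen_invalid_input", "k must be >= 2")
  set.seed(as.integer(seed))
  crossFold <- rep(FALSE, n)

  groupOf <- switch(scheme,
    random = as.character(seq_len(n)),
    leave_combination = pairKey(quartets$drug_a, quartets$drug_b),
    leave_drug = NULL, leave_cell_line = NULL)

  if (scheme %in% c("random", "leave_combination")) {
    groups <- unique(groupOf)
    if (length(groups) < k)
      stopf("synscreen_invalid_input",
            "scheme '%s' needs >= %d groups, found %d",
            scheme, k, length(groups))
    groups <- sample(groups)
    sizes <- as.numeric(table(groupOf)[groups])
    gf <- greedyAssign(sizes, k)
    names(gf) <- groups
    outer <- gf[groupOf]
  } else {
    entCols <- if (scheme == "leave_drug") c("drug_a", "drug_b")
               else "cell_line"
    ents <- unique(unlist(quartets[entCols]))
    if (length(ents) < k)
      stopf("synscreen_invalid_input",
            "scheme '%s' needs >= %d entities, found %d",
            scheme, k, length(ents))
    ents <- sample(ents)
    ## size of an entity = number of quartets touching it
    touch <- function(e) {
      if (scheme == "leave_drug")
        quartets$drug_a == e | quartets$drug_b == e
      else quartets$cell_line == e
    }
    sizes <- vapply(ents, function(e) sum(touch(e)), numeric(1))
    ef <- greedyAssign(sizes, k)
    names(ef) <- ents
    if (scheme == "leave_cell_line") {
      outer <- ef[quartets$cell_line]
    } else {
      fa <- ef[quartets$drug_a]; fb <- ef[quartets$drug_b]
      crossFold <- fa != fb
      ## tie-break: fold of the lexicographically smaller drug id
      smallerIsA <- quartets$drug_a <= quartets$drug_b
      outer <- ifelse(crossFold, ifelse(smallerIsA, fa, fb), fa)
    }
  }
  outer <- as.integer(unname(outer))

  entityFoldOf <- if (scheme == "leave_drug") {
    ef
  } else if (scheme == "leave_cell_line") ef else NULL

  ## roles per outer fold: test = outer fold; excluded = quartets touching
  ## a held-out entity of this fold without being in its test set; the
  ## remainder is split train/validation (~3:1) by the same scheme
  roles <- matrix("train", n, k)
  for (f in seq_len(k)) {
    test <- outer == f
    roles[test, f] <- "test"
    if (scheme == "leave_drug") {
      held <- names(entityFoldOf)[entityFoldOf == f]
      touches <- quartets$drug_a %in% held | quartets$drug_b %in% held
      roles[touches & !test, f] <- "excluded"
    } else if (scheme == "leave_cell_line") {
      held <- names(entityFoldOf)[entityFoldOf == f]
      touches <- quartets$cell_line %in% held
      roles[touches & !test, f] <- "excluded"
    }
    trainIdx <- which(roles[, f] == "train")
    if (length(trainIdx) == 0L) next
    valGroups <- switch(scheme,
      random = as.character(trainIdx),
      leave_combination = pairKey(quartets$drug_a[trainIdx],
                                  quartets$drug_b[trainIdx]),
      leave_drug = NULL, leave_cell_line = NULL)
    if (!is.null(valGroups)) {
      ug <- sample(unique(valGroups))
      nval <- if (length(ug) < 2L) 0L else
        min(max(1L, round(length(ug) / 4)), length(ug) - 1L)
      hold <- ug[seq_len(nval)]
      roles[trainIdx[valGroups %in% hold], f] <- "validation"
    } else if (scheme == "leave_drug") {
      trDrugs <- sample(setdiff(
        unique(c(quartets$drug_a[trainIdx], quartets$drug_b[trainIdx])),
        character()))
      hold <- trDrugs[seq_len(max(1L, round(length(trDrugs) / 4)))]
      tIdx <- trainIdx[quartets$drug_a[trainIdx] %in% hold |
                         quartets$drug_b[trainIdx] %in% hold]
      roles[tIdx, f] <- "validation"
    } else {
      trCells <- sample(unique(quartets$cell_line[trainIdx]))
      hold <- trCells[seq_len(max(1L, round(length(trCells) / 4)))]
      roles[trainIdx[quartets$cell_line[trainIdx] %in% hold], f] <-
        "validation"
    }
    ## tiny designs: never let the validation carve empty the train set
    if (!any(roles[, f] == "train"))
      roles[roles[, f] == "validation", f] <- "train"
  }
  new("FoldAssignment", scheme = scheme, k = as.integer(k),
      outerFold = outer, roles = roles, crossFold = crossFold,
      entityFold = if (is.null(entityFoldOf)) integer()
                   else setNames(as.integer(entityFoldOf),
                                 names(entityFoldOf)),
      seed = as.integer(seed))
}

#' Write / read a fold assignment as CSV
#'
#' Long format: one row per (quartet, outer fold) with columns
#' `drug_a,drug_b,cell_line,outer_fold,role`.
#'
#' @param folds a [FoldAssignment-class].
#' @param quartets the quartet data.frame the assignment refers to.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFolds <- function(folds, quartets, path) {
  rows <- do.call(rbind, lapply(seq_len(folds@k), function(f)
    data.frame(quartets[, c("drug_a", "drug_b", "cell_line")],
               outer_fold = f, role = folds@roles[, f])))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Audit a fold assignment for leakage
#'
#' Checks the defining properties of the scheme: outer test folds are
#' disjoint and cover all samples; under `leave_combination` no unordered
#' drug pair occurs in both a training and the test set of any fold;
#' under `leave_drug`/`leave_cell_line` no training quartet touches a
#' held-out entity of its fold.
#'
#' @param folds a [FoldAssignment-class].
#' @param quartets the quartet data.frame.
#' @return Named logical vector of audit results (all `TRUE` when
#'   clean).
#' @export
auditFolds <- function(folds, quartets) {
  n <- nrow(quartets)
  res <- c(covers = all(folds@outerFold %in% seq_len(folds@k)) &&
             length(folds@outerFold) == n)
  ## fold-size balance is a defining property only of the sample/pair
  ## schemes; entity-held-out test sets vary with entity connectivity
  if (folds@scheme %in% c("random", "leave_combination"))
    res <- c(res,
             balanced = diff(range(tabulate(folds@outerFold, folds@k))) <=
               max(1, 0.5 * n / folds@k))
  if (folds@scheme == "leave_combination") {
    ok <- TRUE
    pk <- pairKey(quartets$drug_a, quartets$drug_b)
    for (f in seq_len(folds@k)) {
      test <- folds@roles[, f] == "test"
      trainish <- folds@roles[, f] %in% c("train", "validation")
      if (length(intersect(pk[test], pk[trainish]))) ok <- FALSE
    }
    res <- c(res, no_pair_leak = ok)
  }
  if (folds@scheme %in% c("leave_drug", "leave_cell_line")) {
    ok <- TRUE
    for (f in seq_len(folds@k)) {
      held <- names(folds@entityFold)[folds@entityFold == f]
      trainish <- folds@roles[, f] %in% c("train", "validation")
      touches <- if (folds@scheme == "leave_drug")
        quartets$drug_a %in% held | quartets$drug_b %in% held
      else quartets$cell_line %in% held
      if (any(touches & trainish)) ok <- FALSE
      ## every quartet touching a held-out entity is test or excluded here
      if (!all(folds@roles[touches, f] %in% c("test", "excluded")))
        ok <- FALSE
    }
    res <- c(res, no_entity_leak = ok)
  }
  res
}

#' Nested cross-validation over a hyperparameter grid
#'
#' For each outer fold, every grid point is trained on the fold's inner
#' training set and scored by MSE on the inner validation set; the best
#' grid point is refitted on the full outer training set (learners that
#' need a held-out monitor keep the inner validation split for early
#' stopping) and applied exactly once to the outer test fold. Grid
#' points whose training fails are logged and skipped unless all fail.
#'
#' @param quartets data.frame with `synergy`.
#' @param folds a [FoldAssignment-class] over `quartets`.
#' @param learner a learner from [synergyLearner()] (or the same shape).
#' @param grid nonempty list of hyperparameter lists.
#' @param features `list(drug = , cell = )` feature matrices or `NULL`.
#' @return List with `predictions` (data.frame `fold`, `index`, `y`,
#'   `yhat`), `chosen` (per-fold winning grid index) and `innerMSE`
#'   (folds x grid matrix).
#' @export
nestedCV <- function(quartets, folds, learner, grid = list(list()),
                     features = NULL) {
  if (length(grid) == 0L)
    stopf("synscreen_invalid_input", "hyperparameter grid is empty")
  k <- folds@k
  innerMSE <- matrix(NA_real_, k, length(grid))
  chosen <- integer(k)
  preds <- NULL
  for (f in seq_len(k)) {
    r <- folds@roles[, f]
    trQ <- quartets[r == "train", , drop = FALSE]
    vaQ <- quartets[r == "validation", , drop = FALSE]
    teQ <- quartets[r == "test", , drop = FALSE]
    for (g in seq_along(grid)) {
      m <- tryCatch(learner$fit(trQ, vaQ, features, grid[[g]]),
                    error = function(e) {
                      message(sprintf("fold %d grid %d failed: %s",
                                      f, g, conditionMessage(e)))
                      NULL
                    })
      if (is.null(m)) next
      yh <- learner$predict(m, vaQ, features)
      innerMSE[f, g] <- mean((vaQ$synergy - yh)^2)
    }
    if (all(is.na(innerMSE[f, ])))
      stopf("synscreen_learner_failure",
            "all grid points failed on fold %d", f)
    chosen[f] <- which.min(innerMSE[f, ])
    ## refit on the full outer training set
    refitTrain <- if (isTRUE(learner$usesValidation)) trQ
                  else rbind(trQ, vaQ)
    best <- learner$fit(refitTrain, vaQ, features, grid[[chosen[f]]])
    yh <- learner$predict(best, teQ, features)
    preds <- rbind(preds, data.frame(fold = f, index = which(r == "test"),
                                     y = teQ$synergy, yhat = yh))
  }
  list(predictions = preds, chosen = chosen, innerMSE = innerMSE)
}

## ---------------------------------------------------------------------------
## Metric panel
## ---------------------------------------------------------------------------

#' Regression metrics: MSE, RMSE, Pearson r
#'
#' Standard definitions with `rmse = sqrt(mse)`. When either vector has
#' zero variance, the correlation is reported as `NA` (undefined), never
#' coerced to 0.
#'
#' @param y,yhat numeric vectors of equal length `>= 2`.
#' @return Named list `mse`, `rmse`, `pearson_r`, `n`.
#' @export
regressionMetrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stopf("synscreen_invalid_input", "need equal-length vectors, n >= 2")
  mse <- mean((y - yhat)^2)
  r <- if (sd(y) == 0 || sd(yhat) == 0) NA_real_ else cor(y, yhat)
  list(mse = mse, rmse = sqrt(mse), pearson_r = r, n = length(y))
}

## rank-based ROC AUC (Mann-Whitney with tie correction)
rocAUC <- function(labels, scores) {
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

## PR AUC by descending-score sweep (step integration over recall)
prAUC <- function(labels, scores) {
  np <- sum(labels)
  if (np == 0L || all(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(rev(sc)) # keep last index of each tied block
  keep <- rev(last)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Classification metric panel for thresholded synergy
#'
#' Measured scores above `measuredThreshold` (default 30, the top ~10%
#' of a screen-shaped score distribution) define the positive class.
#' ROC and precision-recall AUCs are computed from the continuous
#' predictions; accuracy, balanced accuracy, precision, sensitivity,
#' specificity and Cohen's kappa from predictions thresholded at
#' `predictedThreshold`. With a single-class `y` the AUCs are `NA`
#' (undefined) while the thresholded metrics are still computed.
#'
#' @param y measured synergy scores.
#' @param yhat predicted synergy scores.
#' @param measuredThreshold cut on `y` defining positives.
#' @param predictedThreshold cut on `yhat` (see [selectThreshold()]).
#' @return Named list with `roc_auc`, `pr_auc`, `acc`, `bacc`, `prec`,
#'   `tpr`, `tnr`, `kappa`, `threshold_used`, `n`.
#' @export
classificationMetrics <- function(y, yhat, measuredThreshold = 30,
                                  predictedThreshold) {
  lab <- y > measuredThreshold
  pred <- yhat > predictedThreshold
  tp <- sum(lab & pred); fp <- sum(!lab & pred)
  fn <- sum(lab & !pred); tn <- sum(!lab & !pred)
  n <- length(y)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(roc_auc = rocAUC(lab, yhat), pr_auc = prAUC(lab, yhat),
       acc = po, bacc = mean(c(tpr, tnr)), prec = prec,
       tpr = tpr, tnr = tnr, kappa = kappa,
       threshold_used = predictedThreshold, n = n)
}

#' Select the prediction threshold maximising balanced accuracy
#'
#' Scans candidate cuts at the midpoints of sorted unique predicted
#' scores on a validation set and returns the cut with maximal balanced
#' accuracy; ties break toward the lower threshold. With fewer than two
#' distinct predictions the single value itself is returned (every cut
#' is equivalent).
#'
#' @param y validation measured scores (both classes must be present).
#' @param yhat validation predicted scores.
#' @param measuredThreshold cut on `y` defining positives (default 30).
#' @return The selected cut on `yhat`.
#' @export
selectThreshold <- function(y, yhat, measuredThreshold = 30) {
  lab <- y > measuredThreshold
  if (all(lab) || !any(lab))
    stopf("synscreen_invalid_input",
          "validation set must contain both classes")
  u <- sort(unique(yhat))
  if (length(u) < 2L) return(u[1])
  cand <- (u[-1] + u[-length(u)]) / 2
  bacc <- vapply(cand, function(cut) {
    pred <- yhat > cut
    tpr <- sum(lab & pred) / sum(lab)
    tnr <- sum(!lab & !pred) / sum(!lab)
    (tpr + tnr) / 2
  }, numeric(1))
  cand[which.max(bacc)]  # which.max takes the first (lowest) maximiser
}

#' Paired Wilcoxon signed-rank comparison of per-sample squared errors
#'
#' Tests whether two methods' squared errors on identical test points
#' differ, via the Wilcoxon signed-rank test on the paired differences
#' (zero differences dropped per the standard convention). When every
#' pair is tied the statistic is undefined and reported as `NA`.
#'
#' @param errors1,errors2 equal-length vectors of per-sample squared
#'   errors on the same test points.
#' @param alternative passed to [stats::wilcox.test()].
#' @return List with `statistic`, `p_value`, `n_effective`.
#' @export
pairedMethodTest <- function(errors1, errors2,
                             alternative = "two.sided") {
  if (length(errors1) != length(errors2))
    stopf("synscreen_invalid_input", "paired samples must align")
  d <- errors1 - errors2
  eff <- sum(d != 0)
  if (eff == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_effective = 0L))
  wt <- suppressWarnings(
    stats::wilcox.test(errors1, errors2, paired = TRUE,
                       alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = eff)
}

#' Per-drug or per-cell-line prediction quality
#'
#' Pearson correlation between measured and predicted synergy over all
#' quartets involving each entity — the applicability-domain summary.
#' Groups with fewer than `minN` samples or without variance are
#' flagged (`ok = FALSE`, `r = NA`), not silently dropped.
#'
#' @param quartets data.frame with `synergy`.
#' @param predictions numeric vector aligned with `quartets`.
#' @param groupBy `"drug"` or `"cell_line"`.
#' @param minN minimum group size for a correlation (default 3).
#' @return data.frame with `entity`, `n`, `r`, `ok`.
#' @export
groupwiseCorrelation <- function(quartets, predictions,
                                 groupBy = c("drug", "cell_line"),
                                 minN = 3L) {
  groupBy <- match.arg(groupBy)
  ents <- if (groupBy == "drug")
    sort(unique(c(quartets$drug_a, quartets$drug_b)))
  else sort(unique(quartets$cell_line))
  rows <- lapply(ents, function(e) {
    idx <- if (groupBy == "drug")
      which(quartets$drug_a == e | quartets$drug_b == e)
    else which(quartets$cell_line == e)
    y <- quartets$synergy[idx]; yh <- predictions[idx]
    ok <- length(idx) >= minN && sd(y) > 0 && sd(yh) > 0
    data.frame(entity = e, n = length(idx),
               r = if (ok) cor(y, yh) else NA_real_, ok = ok)
  })
  do.call(rbind, rows)
}

#' Per-fold metric report
#'
#' Computes the full regression + classification panel per outer fold of
#' a [nestedCV()] result, selecting the classification threshold on each
#' fold's validation predictions would require refitting; instead the
#' threshold is selected on the pooled out-of-fold predictions of the
#' other folds (documented choice). Returns per-fold rows plus a
#' mean ± sd summary row.
#'
#' @param cvResult result of [nestedCV()].
#' @param measuredThreshold positive-class cut on measured scores.
#' @return data.frame, one row per fold plus `mean` and `sd` rows.
#' @export
metricReport <- function(cvResult, measuredThreshold = 30) {
  pr <- cvResult$predictions
  folds <- sort(unique(pr$fold))
  rows <- lapply(folds, function(f) {
    own <- pr[pr$fold == f, ]
    rest <- pr[pr$fold != f, ]
    thr <- tryCatch(
      selectThreshold(rest$y, rest$yhat, measuredThreshold),
      error = function(e) measuredThreshold)
    rm <- regressionMetrics(own$y, own$yhat)
    cm <- classificationMetrics(own$y, own$yhat, measuredThreshold, thr)
    data.frame(fold = as.character(f), mse = rm$mse, rmse = rm$rmse,
               pearson_r = rm$pearson_r, roc_auc = cm$roc_auc,
               pr_auc = cm$pr_auc, acc = cm$acc, bacc = cm$bacc,
               prec = cm$prec, tpr = cm$tpr, tnr = cm$tnr,
               kappa = cm$kappa, threshold_used = cm$threshold_used,
               n = rm$n)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1]
  summ <- rbind(colMeans(num, na.rm = TRUE),
                apply(num, 2, sd, na.rm = TRUE))
  tab <- rbind(tab, data.frame(fold = c("mean", "sd"), summ))
  rownames(tab) <- NULL
  tab
}
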