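#' Fit the median-polish baseline
#'
#' Computes, over the training quartets only, the median synergy score of
#' every drug (counting quartets where it appears in either position), of
#' every cell line, and the global median as fallback for unseen
#' entities.
#'
#' @param quartets training data.frame with `drug_a`, `drug_b`,
#'   `cell_line`, `synergy`.
#' @return A [MedianTables-class].
#' @export
medianPolishFit <- function(quartets) {
  if (nrow(quartets) == 0L)
    stopf("synscreen_invalid_input", "empty training set")
  drugs <- unique(c(quartets$drug_a, quartets$drug_b))
  dm <- vapply(drugs, function(d) {
    median(quartets$synergy[quartets$drug_a == d | quartets$drug_b == d])
  }, numeric(1))
  names(dm) <- drugs
  cm <- vapply(split(quartets$synergy, quartets$cell_line), median,
               numeric(1))
  new("MedianTables", drugMedians = dm, cellMedians = cm,
      globalMedian = median(quartets$synergy))
}

#' Predict synergy with the median-polish baseline
#'
#' The prediction for a quartet is the mean of the two drug medians and
#' the cell-line median; any entity unseen in training contributes the
#' global median instead.
#'
#' @param tables a fitted [MedianTables-class].
#' @param quartets data.frame of quartet keys.
#' @return Numeric vector of predictions.
#' @export
medianPolishPredict <- function(tables, quartets) {
  stopifnot(is(tables, "MedianTables"))
  look <- function(tab, keys) {
    v <- tab[keys]
    v[is.na(v)] <- tables@globalMedian
    unname(v)
  }
  (look(tables@drugMedians, quartets$drug_a) +
     look(tables@drugMedians, quartets$drug_b) +
     look(tables@cellMedians, quartets$cell_line)) / 3
}

#' Split signed continuous features into nonnegative parts
#'
#' The MinMax kernel is defined on nonnegative values only, so each
#' continuous column `f` becomes the pair `max(f, 0)` and `max(-f, 0)`
#' (suffixes `.pos` / `.neg`); count and binary columns pass through
#' untouched. The original continuous block is exactly `pos - neg`.
#'
#' @param block a [FeatureBlock-class] (or plain matrix, treated as all
#'   continuous).
#' @return A [FeatureBlock-class] with only nonnegative entries.
#' @export
posNegSplit <- function(block) {
  if (!is(block, "FeatureBlock")) block <- FeatureBlock(as.matrix(block))
  v <- block@values
  cols <- list(); kinds <- character()
  for (j in seq_len(ncol(v))) {
    if (block@kinds[j] == "continuous" && any(v[, j] < 0)) {
      pos <- pmax(v[, j], 0); neg <- pmax(-v[, j], 0)
      cols[[length(cols) + 1L]] <- setNames(
        list(pos, neg), paste0(colnames(v)[j], c(".pos", ".neg")))
      kinds <- c(kinds, "continuous", "continuous")
    } else {
      cols[[length(cols) + 1L]] <- setNames(list(v[, j]), colnames(v)[j])
      kinds <- c(kinds, block@kinds[j])
    }
  }
  flat <- unlist(cols, recursive = FALSE)
  out <- do.call(cbind, flat)
  colnames(out) <- names(flat)
  FeatureBlock(out, kinds)
}

#' Modified MinMax kernel for mixed nonnegative features
#'
#' For nonnegative vectors `x`, `z` the similarity is the mean of
#' `min(x_p, z_p) / max(x_p, z_p)` over the features `p` active in either
#' vector (`x_p + z_p > 0`):
#' `K(x, z) = sum_p min/max / #\{p : x_p + z_p > 0\}`.
#' It generalises the Tanimoto/Jaccard similarity to counts and
#' continuous values, lies in `[0, 1]`, is symmetric, and equals 1 on
#' identical nonzero vectors. Signed continuous columns must be routed
#' through [posNegSplit()] first. The behaviour for a pair of all-zero
#' vectors is selectable: `"one"` (identical objects, the default) or
#' `"zero"` (no shared active features).
#'
#' @param X,Z nonnegative matrices (rows = entities) over the same
#'   columns; `Z` defaults to `X`.
#' @param emptyPair similarity assigned when no feature is active in
#'   either vector.
#' @return `nrow(X)` x `nrow(Z)` kernel matrix.
#' @export
minmaxKernel <- function(X, Z = X, emptyPair = c("one", "zero")) {
  emptyPair <- match.arg(emptyPair)
  if (is(X, "FeatureBlock")) X <- X@values
  if (is(Z, "FeatureBlock")) Z <- Z@values
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z))
    stopf("synscreen_invalid_input", "column mismatch")
  if (any(X < 0) || any(Z < 0))
    stopf("synscreen_invalid_input",
          "negative entries: apply posNegSplit() before the kernel")
  K <- matrix(NA_real_, nrow(X), nrow(Z))
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    for (j in seq_len(nrow(Z))) {
      zj <- Z[j, ]
      active <- (xi + zj) > 0
      na <- sum(active)
      K[i, j] <- if (na == 0L) {
        if (emptyPair == "one") 1 else 0
      } else {
        sum(pmin(xi[active], zj[active]) / pmax(xi[active], zj[active])) / na
      }
    }
  }
  dimnames(K) <- list(rownames(X), rownames(Z))
  K
}

## ---------------------------------------------------------------------------
## Pluggable learner interface
## ---------------------------------------------------------------------------

#' Pluggable synergy learners
#'
#' A learner is a list with functions `fit(trainQuartets, valQuartets,
#' features, hyper)` returning an opaque model, and `predict(model,
#' quartets, features)` returning numeric scores, where `features` is a
#' `list(drug = , cell = )` of feature matrices (possibly `NULL` for
#' feature-free learners). `valQuartets` may only be used for monitoring
#' (early stopping), never for parameter fitting; the flag
#' `usesValidation` tells the cross-validation harness whether the
#' learner needs a held-out monitor when refitting on a full outer
#' training fold. This is the surface through which the harness drives
#' both the bundled learners and any off-the-shelf regressor.
#'
#' Bundled learners:
#' \describe{
#'   \item{`"medianPolish"`}{the feature-free baseline; ignores `hyper`.}
#'   \item{`"network"`}{the symmetric feed-forward regressor; `hyper` is
#'     a list of [NetworkConfig()] arguments plus optional `strategy`.}
#'   \item{`"elasticNet"`}{example off-the-shelf wrapper (glmnet) over
#'     the doubled, normalised features; `hyper` takes `alpha` and
#'     `lambda`. Requires the `glmnet` package.}
#' }
#'
#' @param name learner name.
#' @return A learner list with `fit` and `predict`.
#' @export
synergyLearner <- function(name = c("medianPolish", "network",
                                    "elasticNet")) {
  name <- match.arg(name)
  switch(name,
    medianPolish = list(
      name = name, usesValidation = FALSE,
      fit = function(trainQuartets, valQuartets, features, hyper)
        medianPolishFit(trainQuartets),
      predict = function(model, quartets, features)
        medianPolishPredict(model, quartets)),
    network = list(
      name = name, usesValidation = TRUE,
      fit = function(trainQuartets, valQuartets, features, hyper) {
        strategy <- hyper$strategy %||% "norm_tanh_norm"
        hyper$strategy <- NULL
        cfg <- do.call(NetworkConfig, hyper)
        trainSynergyNet(trainQuartets, valQuartets, features$drug,
                        features$cell, cfg, strategy)
      },
      predict = function(model, quartets, features)
        predictSymmetric(model, quartets, features$drug, features$cell)),
    elasticNet = list(
      name = name, usesValidation = FALSE,
      fit = function(trainQuartets, valQuartets, features, hyper) {
        if (!requireNamespace("glmnet", quietly = TRUE))
          stopf("synscreen_missing_dep", "learner 'elasticNet' needs glmnet")
        tr <- doubleTrainingSet(
          makeTriplets(trainQuartets, features$drug, features$cell))
        norm <- fitNormalizer(tr$X, hyper$strategy %||% "norm")
        fit <- glmnet::glmnet(applyNormalizer(norm, tr$X), tr$y,
                              alpha = hyper$alpha %||% 0.5,
                              lambda = hyper$lambda %||% 0.1)
        list(fit = fit, norm = norm)
      },
      predict = function(model, quartets, features) {
        tri <- makeTriplets(quartets, features$drug, features$cell)
        pr <- function(X) as.numeric(stats::predict(
          model$fit, applyNormalizer(model$norm, X)))
        (pr(cbind(tri$Xa, tri$Xb, tri$Xc)) +
           pr(cbind(tri$Xb, tri$Xa, tri$Xc))) / 2
      }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
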