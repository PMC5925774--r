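#' @import methods
NULL

## ---------------------------------------------------------------------------
## Dose-response surfaces
## ---------------------------------------------------------------------------

#' Four-parameter Hill dose-response curve
#'
#' Represents a fitted single-agent dose-response model for one
#' (drug, cell line) pair. The response at concentration `c` (in µM) is
#' `E(c) = einf + (e0 - einf) * ec50^h / (ec50^h + c^h)`, expressed in
#' percent of untreated control. Responses may exceed 100 or drop below 0
#' (cytotoxicity) and are never clipped.
#'
#' @slot e0 numeric, response at zero dose (% of control).
#' @slot einf numeric, asymptotic response at infinite dose (% of control).
#' @slot ec50 numeric, half-effect concentration in µM, strictly positive.
#' @slot h numeric, Hill slope, strictly positive.
#' @slot residual numeric, residual sum of squares of the fit (NA when the
#'   curve was constructed rather than fitted).
#' @slot degenerate logical, TRUE when the curve is a flat fallback from a
#'   degenerate fit (`e0 == einf`).
#'
#' @seealso [fitHill()], [hillResponse()], [loeweReference()]
#' @export
setClass("HillCurve",
  representation(e0 = "numeric", einf = "numeric", ec50 = "numeric",
                 h = "numeric", residual = "numeric", degenerate = "logical"),
  prototype(residual = NA_real_, degenerate = FALSE))

setValidity("HillCurve", function(object) {
  msg <- character()
  for (s in c("e0", "einf", "ec50", "h")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("slot '%s' must be a finite scalar", s))
  }
  if (length(msg) == 0L) {
    if (object@ec50 <= 0) msg <- c(msg, "ec50 must be > 0")
    if (object@h <= 0) msg <- c(msg, "h must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Constructor for [HillCurve-class] objects
#'
#' @param e0,einf,ec50,h curve parameters; see [HillCurve-class].
#' @param residual optional residual sum of squares.
#' @param degenerate logical flag for flat fallback curves.
#' @return A validated `HillCurve`.
#' @examples
#' hc <- HillCurve(e0 = 100, einf = 10, ec50 = 1, h = 2)
#' hillResponse(hc, 1)  # 55, halfway between e0 and einf
#' @export
HillCurve <- function(e0, einf, ec50, h, residual = NA_real_,
                      degenerate = FALSE) {
  new("HillCurve", e0 = as.numeric(e0), einf = as.numeric(einf),
      ec50 = as.numeric(ec50), h = as.numeric(h),
      residual = as.numeric(residual), degenerate = degenerate)
}

setMethod("show", "HillCurve", function(object) {
  cat(sprintf(
    "HillCurve: e0=%.4g einf=%.4g ec50=%.4g uM h=%.4g%s%s\n",
    object@e0, object@einf, object@ec50, object@h,
    if (is.na(object@residual)) "" else sprintf(" (RSS %.4g)", object@residual),
    if (object@degenerate) " [degenerate/flat]" else ""))
})

#' Measured 4x4 combination checkerboard
#'
#' A factorial dose grid of two drugs on one cell line, at four strictly
#' ascending nonzero concentrations per drug, with responses in percent of
#' control already averaged over replicates.
#'
#' @slot drugADoses,drugBDoses numeric(4), strictly positive ascending µM.
#' @slot response 4x4 numeric matrix, rows indexed by drug-A dose, columns
#'   by drug-B dose.
#' @slot replicateCount positive integer, replicates averaged per well.
#' @export
setClass("Checkerboard",
  representation(drugADoses = "numeric", drugBDoses = "numeric",
                 response = "matrix", replicateCount = "integer"),
  prototype(replicateCount = 1L))

setValidity("Checkerboard", function(object) {
  msg <- character()
  for (s in c("drugADoses", "drugBDoses")) {
    d <- slot(object, s)
    if (length(d) != 4L || any(!is.finite(d)) || any(d <= 0))
      msg <- c(msg, sprintf("%s must be 4 finite positive doses", s))
    else if (any(diff(d) <= 0))
      msg <- c(msg, sprintf("%s must be strictly ascending", s))
  }
  if (!all(dim(object@response) == c(4L, 4L)))
    msg <- c(msg, "response must be a 4x4 matrix")
  if (any(!is.finite(object@response)))
    msg <- c(msg, "response entries must be finite")
  if (length(object@replicateCount) != 1L || object@replicateCount < 1L)
    msg <- c(msg, "replicateCount must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Constructor for [Checkerboard-class] objects
#' @param drugADoses,drugBDoses numeric(4) positive ascending doses (µM).
#' @param response 4x4 response matrix (% of control), replicate-averaged.
#' @param replicateCount number of replicates that were averaged.
#' @return A validated `Checkerboard`.
#' @export
Checkerboard <- function(drugADoses, drugBDoses, response,
                         replicateCount = 1L) {
  new("Checkerboard", drugADoses = as.numeric(drugADoses),
      drugBDoses = as.numeric(drugBDoses),
      response = as.matrix(response),
      replicateCount = as.integer(replicateCount))
}

setMethod("show", "Checkerboard", function(object) {
  cat(sprintf("Checkerboard 4x4 (%d replicate%s averaged)\n",
              object@replicateCount,
              if (object@replicateCount > 1L) "s" else ""))
  m <- round(object@response, 2)
  dimnames(m) <- list(paste0("A:", signif(object@drugADoses, 3)),
                      paste0("B:", signif(object@drugBDoses, 3)))
  print(m)
})

#' Assembled 5x5 dose-response surface
#'
#' A combination surface over two dose ladders that each start at zero.
#' The zero-dose row and column carry single-agent Hill-curve predictions,
#' the interior 4x4 block carries the measured checkerboard, and the
#' `[1, 1]` corner is the mean of the two fitted zero-dose responses.
#'
#' @slot drugADoses,drugBDoses numeric(5), ascending, first element 0.
#' @slot response 5x5 numeric matrix (% of control).
#' @export
setClass("DoseSurface",
  representation(drugADoses = "numeric", drugBDoses = "numeric",
                 response = "matrix"))

setValidity("DoseSurface", function(object) {
  msg <- character()
  for (s in c("drugADoses", "drugBDoses")) {
    d <- slot(object, s)
    if (length(d) != 5L || d[1] != 0 || any(diff(d) <= 0))
      msg <- c(msg, sprintf("%s must be 5 ascending doses starting at 0", s))
  }
  if (!all(dim(object@response) == c(5L, 5L)))
    msg <- c(msg, "response must be a 5x5 matrix")
  if (any(!is.finite(object@response)))
    msg <- c(msg, "response entries must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DoseSurface", function(object) {
  cat("DoseSurface 5x5 (% of control)\n")
  m <- round(object@response, 2)
  dimnames(m) <- list(paste0("A:", signif(object@drugADoses, 3)),
                      paste0("B:", signif(object@drugBDoses, 3)))
  print(m)
})

## ---------------------------------------------------------------------------
## Features
## ---------------------------------------------------------------------------

#' Typed feature block
#'
#' An entity-by-feature numeric matrix in which every column carries a kind
#' tag: `"count"` (nonnegative integers), `"binary"` (0/1) or
#' `"continuous"`. Kind tags are preserved through filtering and
#' concatenation; the MinMax kernel's positive/negative split relies on
#' them downstream.
#'
#' @slot values numeric matrix, entities in rows, features in columns, with
#'   unique column names.
#' @slot kinds character vector, one tag per column.
#' @export
setClass("FeatureBlock",
  representation(values = "matrix", kinds = "character"))

setValidity("FeatureBlock", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "values must have unique column names")
  if (length(object@kinds) != ncol(v))
    msg <- c(msg, "one kind tag per column required")
  bad <- setdiff(unique(object@kinds), c("count", "binary", "continuous"))
  if (length(bad))
    msg <- c(msg, paste("unknown kind tag:", paste(bad, collapse = ", ")))
  ck <- which(object@kinds == "count")
  if (length(ck) && ncol(v) && nrow(v)) {
    cv <- v[, ck, drop = FALSE]
    if (any(is.finite(cv) & (cv < 0 | cv != round(cv))))
      msg <- c(msg, "count columns must be nonnegative integers")
  }
  bk <- which(object@kinds == "binary")
  if (length(bk) && nrow(v)) {
    bv <- v[, bk, drop = FALSE]
    if (any(is.finite(bv) & !(bv %in% c(0, 1))))
      msg <- c(msg, "binary columns must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Constructor for [FeatureBlock-class] objects
#' @param values numeric matrix with unique column names.
#' @param kinds per-column kind tags (`"count"`, `"binary"`,
#'   `"continuous"`); a single tag is recycled.
#' @return A validated `FeatureBlock`.
#' @export
FeatureBlock <- function(values, kinds = "continuous") {
  values <- as.matrix(values)
  if (length(kinds) == 1L) kinds <- rep(kinds, ncol(values))
  new("FeatureBlock", values = values, kinds = as.character(kinds))
}

setMethod("show", "FeatureBlock", function(object) {
  tab <- table(factor(object@kinds,
                      levels = c("count", "binary", "continuous")))
  cat(sprintf("FeatureBlock: %d entities x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%d %s", tab, names(tab))[tab > 0],
                    collapse = ", ")))
})

#' @describeIn FeatureBlock-class number of entities (rows).
#' @param x a `FeatureBlock`.
#' @export
setMethod("nrow", "FeatureBlock", function(x) nrow(x@values))

#' @describeIn FeatureBlock-class number of features (columns).
#' @export
setMethod("ncol", "FeatureBlock", function(x) ncol(x@values))

#' Accessors for FeatureBlock
#'
#' `featureValues()` returns the numeric matrix, `featureKinds()` the
#' per-column kind tags.
#' @param x a [FeatureBlock-class].
#' @return A matrix, or a character vector of kind tags.
#' @export
featureValues <- function(x) x@values

#' @rdname featureValues
#' @export
featureKinds <- function(x) x@kinds

#' Bind feature blocks column-wise
#'
#' Concatenates blocks over the same entities, keeping kind tags. Column
#' names are prefixed when `prefixes` is given to keep them unique.
#' @param ... [FeatureBlock-class] objects with equal row counts.
#' @param prefixes optional character vector, one prefix per block.
#' @return A combined `FeatureBlock`.
#' @export
cbindBlocks <- function(..., prefixes = NULL) {
  blocks <- list(...)
  if (!is.null(prefixes)) {
    stopifnot(length(prefixes) == length(blocks))
    blocks <- mapply(function(b, p) {
      colnames(b@values) <- paste0(p, colnames(b@values))
      b
    }, blocks, prefixes)
  }
  FeatureBlock(do.call(cbind, lapply(blocks, featureValues)),
               unlist(lapply(blocks, featureKinds)))
}

## ---------------------------------------------------------------------------
## Normalisation
## ---------------------------------------------------------------------------

#' Input normaliser with train-fold-only statistics
#'
#' Holds column-wise statistics for one of three strategies:
#' `"norm"` (standardise), `"norm_tanh"` (standardise then hyperbolic
#' tangent) and `"norm_tanh_norm"` (standardise, tanh, standardise again,
#' the second pass fitted on the tanh-transformed training values).
#' Standard deviations of zero-variance columns are stored as 1 so the
#' transform stays defined.
#'
#' @slot strategy one of `"norm"`, `"norm_tanh"`, `"norm_tanh_norm"`.
#' @slot mean1,sd1 first-pass column statistics.
#' @slot mean2,sd2 second-pass statistics (length 0 unless
#'   `norm_tanh_norm`).
#' @seealso [fitNormalizer()], [applyNormalizer()]
#' @export
setClass("Normalizer",
  representation(strategy = "character", mean1 = "numeric", sd1 = "numeric",
                 mean2 = "numeric", sd2 = "numeric"),
  prototype(mean2 = numeric(), sd2 = numeric()))

setValidity("Normalizer", function(object) {
  msg <- character()
  if (!object@strategy %in% c("norm", "norm_tanh", "norm_tanh_norm"))
    msg <- c(msg, "unknown strategy")
  if (length(object@mean1) != length(object@sd1))
    msg <- c(msg, "mean1/sd1 length mismatch")
  if (any(object@sd1 <= 0) || any(object@sd2 <= 0))
    msg <- c(msg, "stored standard deviations must be strictly positive")
  if (object@strategy == "norm_tanh_norm" &&
      length(object@mean2) != length(object@mean1))
    msg <- c(msg, "norm_tanh_norm requires second-pass statistics")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Normalizer", function(object) {
  cat(sprintf("Normalizer[%s] over %d columns\n",
              object@strategy, length(object@mean1)))
})

## ---------------------------------------------------------------------------
## Models
## ---------------------------------------------------------------------------

#' Feed-forward network configuration
#'
#' Architecture and optimisation settings for the synergy regression
#' network. `hiddenSizes` of two or three layers; a conic architecture
#' halves the width at each depth (e.g. `c(64, 32)`), a rectangular one
#' keeps it constant.
#'
#' @slot hiddenSizes integer vector of 2 or 3 positive layer widths.
#' @slot learningRate positive numeric, plain SGD step size.
#' @slot inputDropout,hiddenDropout dropout rates in `[0, 1)`.
#' @slot maxEpochs positive integer.
#' @slot earlyStopWindow width of the validation-MSE moving average used
#'   for early stopping (default 25 epochs).
#' @slot batchSize minibatch size.
#' @slot seed integer RNG seed; fixes initial weights, shuffling and
#'   dropout masks.
#' @export
setClass("NetworkConfig",
  representation(hiddenSizes = "integer", learningRate = "numeric",
                 inputDropout = "numeric", hiddenDropout = "numeric",
                 maxEpochs = "integer", earlyStopWindow = "integer",
                 batchSize = "integer", seed = "integer"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (!length(object@hiddenSizes) %in% c(2L, 3L) ||
      any(object@hiddenSizes < 1L))
    msg <- c(msg, "hiddenSizes must be 2 or 3 positive integers")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@inputDropout < 0 || object@inputDropout >= 1 ||
      object@hiddenDropout < 0 || object@hiddenDropout >= 1)
    msg <- c(msg, "dropout rates must lie in [0, 1)")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be positive")
  if (object@earlyStopWindow < 1L)
    msg <- c(msg, "earlyStopWindow must be positive")
  if (length(msg)) msg else TRUE
})

#' Constructor for [NetworkConfig-class] objects
#' @param hiddenSizes 2 or 3 hidden-layer widths.
#' @param learningRate SGD learning rate.
#' @param inputDropout,hiddenDropout dropout rates in `[0, 1)`; the screen
#'   configuration of the reference grid is input 0.2 / hidden 0.5.
#' @param maxEpochs training epoch budget.
#' @param earlyStopWindow moving-average window for early stopping.
#' @param batchSize minibatch size.
#' @param seed RNG seed.
#' @return A validated `NetworkConfig`.
#' @export
NetworkConfig <- function(hiddenSizes = c(64L, 32L), learningRate = 1e-2,
                          inputDropout = 0, hiddenDropout = 0,
                          maxEpochs = 200L, earlyStopWindow = 25L,
                          batchSize = 64L, seed = 1L) {
  new("NetworkConfig", hiddenSizes = as.integer(hiddenSizes),
      learningRate = as.numeric(learningRate),
      inputDropout = as.numeric(inputDropout),
      hiddenDropout = as.numeric(hiddenDropout),
      maxEpochs = as.integer(maxEpochs),
      earlyStopWindow = as.integer(earlyStopWindow),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: hidden [%s], lr %.2g, dropout in/hid %.2g/%.2g, %d epochs (MA%d stop), batch %d, seed %d\n",
    paste(object@hiddenSizes, collapse = ", "), object@learningRate,
    object@inputDropout, object@hiddenDropout, object@maxEpochs,
    object@earlyStopWindow, object@batchSize, object@seed))
})

#' Trained symmetric synergy network
#'
#' Weights, configuration, fitted input normaliser and the per-epoch
#' training log of a feed-forward synergy regressor. Predictions average
#' the two drug orderings, so they are exactly invariant to swapping the
#' drugs.
#'
#' @slot weights list of layer weight matrices.
#' @slot biases list of layer bias vectors.
#' @slot config the [NetworkConfig-class] used.
#' @slot normalizer fitted [Normalizer-class] (input side).
#' @slot dims named integer vector with `drug` and `cell` feature widths.
#' @slot log data.frame with columns `epoch`, `train_mse`, `val_mse`,
#'   `val_mse_ma25`.
#' @slot bestEpoch epoch whose weights are stored (moving-average
#'   early-stopping choice).
#' @export
setClass("SynergyNet",
  representation(weights = "list", biases = "list", config = "NetworkConfig",
                 normalizer = "Normalizer", dims = "integer",
                 log = "data.frame", bestEpoch = "integer"))

setMethod("show", "SynergyNet", function(object) {
  cat(sprintf(
    "SynergyNet: layers [%s] -> 1, best epoch %d/%d, final val MSE %.4g\n",
    paste(object@config@hiddenSizes, collapse = ", "), object@bestEpoch,
    nrow(object@log), object@log$val_mse[object@bestEpoch]))
})

#' Median-polish lookup tables
#'
#' Per-drug and per-cell-line training-set medians of synergy scores plus
#' a global fallback median; the baseline predictor averages the two drug
#' medians and the cell-line median.
#'
#' @slot drugMedians,cellMedians named numeric vectors.
#' @slot globalMedian numeric fallback for unseen entities.
#' @export
setClass("MedianTables",
  representation(drugMedians = "numeric", cellMedians = "numeric",
                 globalMedian = "numeric"))

setMethod("show", "MedianTables", function(object) {
  cat(sprintf("MedianTables: %d drugs, %d cell lines, global median %.3g\n",
              length(object@drugMedians), length(object@cellMedians),
              object@globalMedian))
})

## ---------------------------------------------------------------------------
## Evaluation
## ---------------------------------------------------------------------------

#' Cross-validation fold assignment
#'
#' Maps every synergy quartet to an outer test fold under one of four
#' split schemes, together with the per-fold inner train/validation split.
#' Schemes: `"random"` shuffles samples; `"leave_combination"` confines
#' every unordered drug pair to a single fold; `"leave_drug"`
#' (`"leave_cell_line"`) assigns each drug (cell line) to one fold, a
#' fold's test set being every quartet touching a held-out entity.
#'
#' @slot scheme split scheme name.
#' @slot k number of outer folds.
#' @slot outerFold integer vector, test-fold index per quartet.
#' @slot roles character matrix, quartets x folds, entries in
#'   `"train"`, `"validation"`, `"test"`, `"excluded"`.
#' @slot crossFold logical vector flagging quartets whose two entities are
#'   held out in different folds (audit trail for the deterministic
#'   tie-break that assigned them).
#' @slot entityFold named integer vector mapping each drug (cell line) to
#'   its fold under `leave_drug` (`leave_cell_line`); empty otherwise.
#' @slot seed integer seed that produced the assignment.
#' @seealso [makeFolds()]
#' @export
setClass("FoldAssignment",
  representation(scheme = "character", k = "integer", outerFold = "integer",
                 roles = "matrix", crossFold = "logical",
                 entityFold = "integer", seed = "integer"),
  prototype(entityFold = integer()))

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment[%s]: %d samples in %d folds (sizes %s)%s\n",
              object@scheme, length(object@outerFold), object@k,
              paste(tabulate(object@outerFold, object@k), collapse = "/"),
              if (any(object@crossFold))
                sprintf(", %d cross-fold", sum(object@crossFold)) else ""))
})
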