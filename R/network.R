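#' Build (drug, drug, cell line) sample triplets
#'
#' Looks up feature rows for every quartet and returns the three feature
#' matrices in the fixed concatenation order (drug A, drug B, cell line)
#' together with the targets.
#'
#' @param quartets data.frame with columns `drug_a`, `drug_b`,
#'   `cell_line` and optionally `synergy`.
#' @param drugFeatures numeric matrix (or [FeatureBlock-class]) with one
#'   row per drug, rownames = drug identifiers.
#' @param cellFeatures numeric matrix (or [FeatureBlock-class]) with one
#'   row per cell line.
#' @return List with matrices `Xa`, `Xb`, `Xc`, numeric `y` (NA when no
#'   `synergy` column) and the `quartets` themselves.
#' @export
makeTriplets <- function(quartets, drugFeatures, cellFeatures) {
  if (is(drugFeatures, "FeatureBlock")) drugFeatures <- drugFeatures@values
  if (is(cellFeatures, "FeatureBlock")) cellFeatures <- cellFeatures@values
  missD <- setdiff(unique(c(quartets$drug_a, quartets$drug_b)),
                   rownames(drugFeatures))
  if (length(missD))
    stopf("synscreen_invalid_input", "drugs without features: %s",
          paste(missD, collapse = ", "))
  missC <- setdiff(unique(quartets$cell_line), rownames(cellFeatures))
  if (length(missC))
    stopf("synscreen_invalid_input", "cell lines without features: %s",
          paste(missC, collapse = ", "))
  list(Xa = drugFeatures[quartets$drug_a, , drop = FALSE],
       Xb = drugFeatures[quartets$drug_b, , drop = FALSE],
       Xc = cellFeatures[quartets$cell_line, , drop = FALSE],
       y = if ("synergy" %in% names(quartets)) quartets$synergy
           else rep(NA_real_, nrow(quartets)),
       quartets = quartets)
}

#' Symmetric doubling of the training set
#'
#' Presents each sample twice, once in the A-B and once in the B-A drug
#' order, so the regressor need not distinguish the orderings. Output has
#' exactly `2n` rows; rows `2i - 1` and `2i` are the two orderings of
#' sample `i` (the cell-line segment is identical, the drug segments are
#' swapped), with the target duplicated.
#'
#' @param triplets list as returned by [makeTriplets()].
#' @return List with matrix `X` (`2n` rows) and numeric `y` (length
#'   `2n`).
#' @export
doubleTrainingSet <- function(triplets) {
  n <- nrow(triplets$Xa)
  dA <- ncol(triplets$Xa); dC <- ncol(triplets$Xc)
  X <- matrix(NA_real_, 2L * n, 2L * dA + dC)
  if (n > 0L) {
    odd <- seq(1L, 2L * n, by = 2L)
    X[odd, ] <- cbind(triplets$Xa, triplets$Xb, triplets$Xc)
    X[odd + 1L, ] <- cbind(triplets$Xb, triplets$Xa, triplets$Xc)
  }
  list(X = X, y = rep(triplets$y, each = 2L))
}

## Glorot-style variance-scaled uniform initialisation.
initLayers <- function(sizes) {
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    weights[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                           sizes[l], sizes[l + 1L])
    biases[[l]] <- numeric(sizes[l + 1L])
  }
  list(weights = weights, biases = biases)
}

## Forward pass without dropout (inference).
forwardPass <- function(weights, biases, X) {
  L <- length(weights)
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- pmax(A %*% weights[[l]] +
                rep(biases[[l]], each = nrow(A)), 0)
  }
  unname(drop(A %*% weights[[L]] + rep(biases[[L]], each = nrow(A))))
}

#' Train the feed-forward synergy regressor
#'
#' A fully connected network with 2-3 ReLU hidden layers and a single
#' linear output, minimising mean squared error by plain stochastic
#' gradient descent (no momentum, no schedule) with optional inverted
#' dropout on the input and hidden layers. Early stopping follows the
#' moving-average rule: after each epoch the validation MSE enters a
#' trailing moving average over `earlyStopWindow` epochs (default 25),
#' and the weights returned are those of the epoch that minimised this
#' average, not the last epoch. The per-epoch log allows the stopping
#' decision to be re-derived.
#'
#' @param X normalised training matrix (rows = samples, already doubled
#'   when symmetry is wanted).
#' @param y numeric targets.
#' @param config a [NetworkConfig-class]; its seed fixes weights,
#'   shuffling and dropout, so identical seeds give identical logs.
#' @param Xval,yval validation set (disjoint from training) driving early
#'   stopping.
#' @return List with `weights`, `biases`, `log` (data.frame `epoch`,
#'   `train_mse`, `val_mse`, `val_mse_ma25`) and `bestEpoch`.
#' @export
trainNetwork <- function(X, y, config, Xval, yval) {
  stopifnot(is(config, "NetworkConfig"))
  X <- as.matrix(X); Xval <- as.matrix(Xval)
  n <- nrow(X)
  sizes <- c(ncol(X), config@hiddenSizes, 1L)
  set.seed(config@seed)
  net <- initLayers(sizes)
  W <- net$weights; b <- net$biases
  L <- length(W)
  keepIn <- 1 - config@inputDropout
  keepHid <- 1 - config@hiddenDropout
  lr <- config@learningRate
  win <- config@earlyStopWindow

  log <- data.frame(epoch = integer(), train_mse = numeric(),
                    val_mse = numeric(), val_mse_ma25 = numeric())
  bestMA <- Inf; bestEpoch <- NA_integer_
  bestW <- W; bestB <- b
  valHist <- numeric()

  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, n)]
      A <- X[idx, , drop = FALSE]
      m <- length(idx)
      ## forward with dropout masks
      if (keepIn < 1) {
        mask0 <- matrix(rbinom(m * ncol(A), 1L, keepIn) / keepIn,
                        m, ncol(A))
        A <- A * mask0
      }
      acts <- vector("list", L + 1L); acts[[1L]] <- A
      zs <- vector("list", L)
      masks <- vector("list", L)
      for (l in seq_len(L - 1L)) {
        Z <- acts[[l]] %*% W[[l]] + rep(b[[l]], each = m)
        H <- pmax(Z, 0)
        if (keepHid < 1) {
          masks[[l]] <- matrix(rbinom(m * ncol(H), 1L, keepHid) / keepHid,
                               m, ncol(H))
          H <- H * masks[[l]]
        }
        zs[[l]] <- Z
        acts[[l + 1L]] <- H
      }
      out <- acts[[L]] %*% W[[L]] + rep(b[[L]], each = m)
      err <- out - y[idx]
      if (any(!is.finite(err)))
        stopf("synscreen_nan_loss",
              "training diverged (non-finite loss at epoch %d); try a lower learning rate (e.g. 1e-5)",
              epoch)
      delta <- 2 * err / m
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gB <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
          delta <- delta * (zs[[l - 1L]] > 0)
        }
        W[[l]] <- W[[l]] - lr * gW
        b[[l]] <- b[[l]] - lr * gB
      }
    }
    trainMSE <- mean((forwardPass(W, b, X) - y)^2)
    valMSE <- mean((forwardPass(W, b, Xval) - yval)^2)
    if (!is.finite(trainMSE) || !is.finite(valMSE))
      stopf("synscreen_nan_loss",
            "training diverged (non-finite loss at epoch %d); try a lower learning rate (e.g. 1e-5)",
            epoch)
    valHist <- c(valHist, valMSE)
    ma <- mean(valHist[max(1L, epoch - win + 1L):epoch])
    log <- rbind(log, data.frame(epoch = epoch, train_mse = trainMSE,
                                 val_mse = valMSE, val_mse_ma25 = ma))
    if (ma < bestMA) {
      bestMA <- ma; bestEpoch <- epoch
      bestW <- W; bestB <- b
    }
  }
  list(weights = bestW, biases = bestB, log = log, bestEpoch = bestEpoch)
}

#' Train a symmetric synergy network end to end
#'
#' High-level wrapper: builds triplets, doubles the training set (both
#' drug orders), fits the input normaliser on the doubled training rows
#' only, and trains the network with moving-average early stopping
#' monitored on the (equally doubled and train-normalised) validation
#' quartets.
#'
#' @param trainQuartets,valQuartets quartet data.frames with `synergy`.
#' @param drugFeatures,cellFeatures feature matrices/blocks, rownames =
#'   entity ids.
#' @param config a [NetworkConfig-class].
#' @param strategy normalisation strategy (see [fitNormalizer()]).
#' @return A [SynergyNet-class].
#' @export
trainSynergyNet <- function(trainQuartets, valQuartets, drugFeatures,
                            cellFeatures, config = NetworkConfig(),
                            strategy = "norm_tanh_norm") {
  tr <- doubleTrainingSet(
    makeTriplets(trainQuartets, drugFeatures, cellFeatures))
  va <- doubleTrainingSet(
    makeTriplets(valQuartets, drugFeatures, cellFeatures))
  norm <- fitNormalizer(tr$X, strategy)
  fit <- trainNetwork(applyNormalizer(norm, tr$X), tr$y, config,
                      applyNormalizer(norm, va$X), va$y)
  dims <- c(drug = ncol(as.matrix(
    if (is(drugFeatures, "FeatureBlock")) drugFeatures@values
    else drugFeatures)),
    cell = ncol(as.matrix(
      if (is(cellFeatures, "FeatureBlock")) cellFeatures@values
      else cellFeatures)))
  new("SynergyNet", weights = fit$weights, biases = fit$biases,
      config = config, normalizer = norm, dims = dims,
      log = fit$log, bestEpoch = fit$bestEpoch)
}

#' Order-invariant prediction by two-way averaging
#'
#' Propagates each sample through the network in both drug orderings
#' (A-B-cell and B-A-cell) and averages, so the output is exactly
#' invariant to swapping the two drugs. Set `symmetric = FALSE` to ablate
#' and use only the A-B order.
#'
#' @param model a [SynergyNet-class].
#' @param quartets quartet data.frame to predict for.
#' @param drugFeatures,cellFeatures feature matrices/blocks matching the
#'   training dimensions.
#' @param symmetric average both orderings (default TRUE).
#' @return Numeric vector of predicted synergy scores.
#' @export
predictSymmetric <- function(model, quartets, drugFeatures, cellFeatures,
                             symmetric = TRUE) {
  stopifnot(is(model, "SynergyNet"))
  tri <- makeTriplets(quartets, drugFeatures, cellFeatures)
  if (ncol(tri$Xa) != model@dims[["drug"]] ||
      ncol(tri$Xc) != model@dims[["cell"]])
    stopf("synscreen_invalid_input",
          "feature dimensions do not match training (drug %d/%d, cell %d/%d)",
          ncol(tri$Xa), model@dims[["drug"]],
          ncol(tri$Xc), model@dims[["cell"]])
  fwd <- function(X) forwardPass(model@weights, model@biases,
                                 applyNormalizer(model@normalizer, X))
  ab <- fwd(cbind(tri$Xa, tri$Xb, tri$Xc))
  if (!symmetric) return(ab)
  ba <- fwd(cbind(tri$Xb, tri$Xa, tri$Xc))
  (ab + ba) / 2
}

#' Save / load a trained synergy network
#'
#' The saved-model directory holds a YAML config, the normaliser state as
#' a flat key-value file, one CSV per weight layer plus a biases CSV, and
#' the training log as `log.csv` with columns
#' `epoch,train_mse,val_mse,val_mse_ma25`.
#'
#' @param model a [SynergyNet-class].
#' @param dir directory to create/populate.
#' @return `loadSynergyNet()` returns the restored model;
#'   `saveSynergyNet()` returns `dir` invisibly.
#' @export
saveSynergyNet <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  yaml::write_yaml(list(
    hiddenSizes = as.integer(cfg@hiddenSizes),
    learningRate = cfg@learningRate, inputDropout = cfg@inputDropout,
    hiddenDropout = cfg@hiddenDropout, maxEpochs = cfg@maxEpochs,
    earlyStopWindow = cfg@earlyStopWindow, batchSize = cfg@batchSize,
    seed = cfg@seed, dims = as.list(model@dims),
    bestEpoch = model@bestEpoch), file.path(dir, "config.yaml"))
  writeNormalizer(model@normalizer, file.path(dir, "normalizer.txt"))
  for (l in seq_along(model@weights)) {
    write.csv(model@weights[[l]],
              file.path(dir, sprintf("weights_%d.csv", l)),
              row.names = FALSE)
    write.csv(data.frame(bias = model@biases[[l]]),
              file.path(dir, sprintf("biases_%d.csv", l)),
              row.names = FALSE)
  }
  write.csv(model@log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname saveSynergyNet
#' @export
loadSynergyNet <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  nlayers <- length(list.files(dir, pattern = "^weights_"))
  weights <- lapply(seq_len(nlayers), function(l)
    as.matrix(read.csv(file.path(dir, sprintf("weights_%d.csv", l)))))
  biases <- lapply(seq_len(nlayers), function(l)
    read.csv(file.path(dir, sprintf("biases_%d.csv", l)))$bias)
  weights <- lapply(weights, function(w) { dimnames(w) <- NULL; w })
  new("SynergyNet",
      weights = weights, biases = biases,
      config = NetworkConfig(cfg$hiddenSizes, cfg$learningRate,
                             cfg$inputDropout, cfg$hiddenDropout,
                             cfg$maxEpochs, cfg$earlyStopWindow,
                             cfg$batchSize, cfg$seed),
      normalizer = readNormalizer(file.path(dir, "normalizer.txt")),
      dims = c(drug = as.integer(cfg$dims$drug),
               cell = as.integer(cfg$dims$cell)),
      log = read.csv(file.path(dir, "log.csv")),
      bestEpoch = as.integer(cfg$bestEpoch))
}
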