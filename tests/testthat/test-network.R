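test_that("doubleTrainingSet emits both orderings of every sample", {
  q <- data.frame(drug_a = c("A", "B", "A", "C", "B"),
                  drug_b = c("B", "C", "C", "D", "D"),
                  cell_line = "c1",
                  synergy = 1:5)
  drugs <- matrix(seq_len(8), 4, 2,
                  dimnames = list(c("A", "B", "C", "D"), c("f1", "f2")))
  cells <- matrix(99, 1, 1, dimnames = list("c1", "g1"))
  tri <- makeTriplets(q, drugs, cells)
  dbl <- doubleTrainingSet(tri)
  expect_equal(dim(dbl$X), c(10L, 5L))
  expect_equal(dbl$y, rep(1:5, each = 2))
  dA <- 2L
  for (i in seq_len(5)) {
    r1 <- dbl$X[2 * i - 1, ]; r2 <- dbl$X[2 * i, ]
    # drug blocks swapped, cell block identical
    expect_equal(r1[1:dA], r2[dA + 1:dA], ignore_attr = TRUE)
    expect_equal(r1[dA + 1:dA], r2[1:dA], ignore_attr = TRUE)
    expect_equal(r1[5], r2[5])
  }
  # empty input gives an empty matrix
  empty <- doubleTrainingSet(makeTriplets(q[0, ], drugs, cells))
  expect_equal(nrow(empty$X), 0L)
})

test_that("a tiny network fits a realizable linear target", {
  set.seed(31)
  X <- matrix(rnorm(500 * 6), 500)
  w <- rnorm(6)
  y <- as.numeric(X %*% w)
  cfg <- NetworkConfig(hiddenSizes = c(16L, 8L), learningRate = 1e-2,
                       maxEpochs = 150L, seed = 9L)
  fit <- trainNetwork(X[1:400, ], y[1:400], cfg, X[401:500, ], y[401:500])
  expect_lt(min(fit$log$train_mse), 0.01 * var(y))
})

test_that("training is deterministic and the stopping rule is re-derivable", {
  set.seed(32)
  X <- matrix(rnorm(200 * 4), 200)
  y <- rnorm(200)
  cfg <- NetworkConfig(hiddenSizes = c(8L, 4L), learningRate = 5e-3,
                       maxEpochs = 40L, earlyStopWindow = 10L, seed = 5L)
  f1 <- trainNetwork(X[1:150, ], y[1:150], cfg, X[151:200, ], y[151:200])
  f2 <- trainNetwork(X[1:150, ], y[1:150], cfg, X[151:200, ], y[151:200])
  expect_identical(f1$log, f2$log)
  expect_identical(f1$weights, f2$weights)
  # the logged moving average is the trailing mean of val_mse
  ma <- vapply(seq_len(nrow(f1$log)), function(e)
    mean(f1$log$val_mse[max(1, e - 9):e]), numeric(1))
  expect_equal(f1$log$val_mse_ma25, ma, tolerance = 1e-12)
  # the chosen epoch minimises it
  expect_equal(f1$bestEpoch, which.min(ma))
})

test_that("divergent training aborts with a diagnostic", {
  set.seed(33)
  X <- matrix(rnorm(100 * 4, sd = 50), 100)
  y <- rnorm(100, sd = 1000)
  cfg <- NetworkConfig(hiddenSizes = c(16L, 8L), learningRate = 10,
                       maxEpochs = 50L, seed = 1L)
  expect_error(trainNetwork(X, y, cfg, X, y),
               "lower learning rate", class = "synscreen_nan_loss")
})

test_that("dropout training still learns and stays reproducible", {
  set.seed(34)
  X <- matrix(rnorm(300 * 5), 300)
  y <- as.numeric(X %*% rnorm(5))
  cfg <- NetworkConfig(hiddenSizes = c(32L, 16L), learningRate = 1e-2,
                       inputDropout = 0.2, hiddenDropout = 0.5,
                       maxEpochs = 60L, seed = 2L)
  f1 <- trainNetwork(X[1:250, ], y[1:250], cfg, X[251:300, ], y[251:300])
  f2 <- trainNetwork(X[1:250, ], y[1:250], cfg, X[251:300, ], y[251:300])
  expect_identical(f1$log$train_mse[1], f2$log$train_mse[1])
  expect_lt(min(f1$log$val_mse), var(y))
})

test_that("symmetric prediction is exactly order-invariant", {
  world <- tinyWorld()
  q <- world$quartets
  feats <- worldFeatures(world)
  cfg <- NetworkConfig(hiddenSizes = c(8L, 4L), maxEpochs = 5L, seed = 3L)
  model <- trainSynergyNet(q[1:100, ], q[101:150, ], feats$drug,
                           feats$cell, cfg, "norm")
  fwd <- predictSymmetric(model, q[1:20, ], feats$drug, feats$cell)
  swapped <- q[1:20, ]
  tmp <- swapped$drug_a; swapped$drug_a <- swapped$drug_b
  swapped$drug_b <- tmp
  rev <- predictSymmetric(model, swapped, feats$drug, feats$cell)
  expect_identical(fwd, rev)   # bit-for-bit
  # the one-sided ablation is NOT invariant in general
  oneway <- predictSymmetric(model, q[1:20, ], feats$drug, feats$cell,
                             symmetric = FALSE)
  onewayRev <- predictSymmetric(model, swapped, feats$drug, feats$cell,
                                symmetric = FALSE)
  expect_false(identical(oneway, onewayRev))
})

test_that("prediction equals a hand-propagated forward pass", {
  # 2-dim drug blocks, 1-dim cell block, hand-set weights
  drugs <- matrix(c(1, 0, 0, 2), 2, 2,
                  dimnames = list(c("A", "B"), c("u", "v")))
  cells <- matrix(3, 1, 1, dimnames = list("c1", "g"))
  q <- data.frame(drug_a = "A", drug_b = "B", cell_line = "c1")
  W1 <- matrix(0.1 * seq_len(5 * 4), 5, 4)
  W2 <- matrix(0.05 * seq_len(4 * 2), 4, 2)
  W3 <- matrix(c(1, -1), 2, 1)
  ident <- fitNormalizer(rbind(diag(5), -diag(5)), "norm")
  ident@mean1[] <- 0; ident@sd1[] <- 1   # identity transform
  model <- new("SynergyNet", weights = list(W1, W2, W3),
               biases = list(rep(0.1, 4), rep(-0.2, 2), 0.5),
               config = NetworkConfig(hiddenSizes = c(4L, 2L)),
               normalizer = ident, dims = c(drug = 2L, cell = 1L),
               log = data.frame(epoch = 1L, train_mse = 0, val_mse = 0,
                                val_mse_ma25 = 0),
               bestEpoch = 1L)
  hand <- function(x) {
    h1 <- pmax(as.numeric(x %*% W1) + 0.1, 0)
    h2 <- pmax(as.numeric(h1 %*% W2) - 0.2, 0)
    sum(h2 * W3) + 0.5
  }
  want <- (hand(c(1, 0, 0, 2, 3)) + hand(c(0, 2, 1, 0, 3))) / 2
  got <- predictSymmetric(model, q, drugs, cells)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("a saved model reloads to identical predictions", {
  world <- tinyWorld(seed = 12)
  q <- world$quartets
  feats <- worldFeatures(world)
  cfg <- NetworkConfig(hiddenSizes = c(8L, 4L), maxEpochs = 4L, seed = 6L)
  model <- trainSynergyNet(q[1:100, ], q[101:150, ], feats$drug,
                           feats$cell, cfg)
  d <- withr::local_tempdir()
  saveSynergyNet(model, d)
  back <- loadSynergyNet(d)
  expect_equal(predictSymmetric(back, q[1:30, ], feats$drug, feats$cell),
               predictSymmetric(model, q[1:30, ], feats$drug, feats$cell),
               tolerance = 1e-12)
  # training log round-trips with the stopping column intact
  expect_equal(back@log$val_mse_ma25, model@log$val_mse_ma25,
               tolerance = 1e-12)
})
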