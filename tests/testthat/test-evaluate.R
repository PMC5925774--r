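test_that("random folds balance sizes and partition the samples", {
  q <- data.frame(drug_a = rep("A", 100), drug_b = rep("B", 100),
                  cell_line = sprintf("c%03d", 1:100))
  f <- makeFolds(q, "random", k = 5, seed = 1)
  expect_equal(unname(tabulate(f@outerFold, 5)), rep(20L, 5))
  expect_true(all(auditFolds(f, q)))
  # identical seed, identical assignment
  f2 <- makeFolds(q, "random", k = 5, seed = 1)
  expect_identical(f@outerFold, f2@outerFold)
  expect_identical(f@roles, f2@roles)
})

test_that("leave-combination folds confine every unordered pair", {
  world <- tinyWorld()
  q <- world$quartets
  f <- makeFolds(q, "leave_combination", k = 5, seed = 2)
  pk <- pairKey(q$drug_a, q$drug_b)
  # exhaustive check: no pair occurs in two outer folds
  expect_true(all(vapply(split(f@outerFold, pk),
                         function(x) length(unique(x)) == 1L, logical(1))))
  expect_true(all(auditFolds(f, q)))
  # validation never shares a pair with its fold's training set? They may
  # share pairs with each other but not with test; the audit covers test
  for (fold in 1:5) {
    test <- f@roles[, fold] == "test"
    notTest <- f@roles[, fold] != "test"
    expect_length(intersect(pk[test], pk[notTest]), 0L)
  }
})

test_that("leave-drug and leave-cell-line folds exclude held-out entities", {
  world <- tinyWorld()
  q <- world$quartets
  for (scheme in c("leave_drug", "leave_cell_line")) {
    f <- makeFolds(q, scheme, k = 3, seed = 4)
    audit <- auditFolds(f, q)
    expect_true(all(audit), label = scheme)
    # exhaustive scan: training quartets touch no held-out entity
    for (fold in 1:3) {
      held <- names(f@entityFold)[f@entityFold == fold]
      trainish <- f@roles[, fold] %in% c("train", "validation")
      touch <- if (scheme == "leave_drug")
        q$drug_a %in% held | q$drug_b %in% held
      else q$cell_line %in% held
      expect_equal(sum(touch & trainish), 0L)
    }
  }
  # cross-fold quartets are flagged and sit in the lexicographically
  # smaller drug's fold
  f <- makeFolds(q, "leave_drug", k = 3, seed = 4)
  if (any(f@crossFold)) {
    i <- which(f@crossFold)[1]
    smaller <- min(q$drug_a[i], q$drug_b[i])
    expect_equal(f@outerFold[i], unname(f@entityFold[smaller]))
  }
})

test_that("fold construction rejects undersized designs", {
  q <- tinyQuartets()
  expect_error(makeFolds(q, "leave_cell_line", k = 5),
               class = "synscreen_invalid_input")
  expect_error(makeFolds(q[1:3, ], "random", k = 5),
               class = "synscreen_invalid_input")
})

test_that("nested CV with a degenerate grid equals a plain CV loop", {
  world <- tinyWorld()
  q <- world$quartets
  f <- makeFolds(q, "leave_combination", k = 4, seed = 6)
  cv <- nestedCV(q, f, synergyLearner("medianPolish"))
  # independent hand-rolled loop over the same folds
  handErr <- numeric(0); cvErr <- numeric(0)
  for (fold in 1:4) {
    r <- f@roles[, fold]
    fit <- medianPolishFit(q[r %in% c("train", "validation"), ])
    pred <- medianPolishPredict(fit, q[r == "test", ])
    handErr <- c(handErr, (q$synergy[r == "test"] - pred)^2)
    own <- cv$predictions[cv$predictions$fold == fold, ]
    cvErr <- c(cvErr, (own$y - own$yhat)^2)
  }
  expect_equal(mean(cvErr), mean(handErr), tolerance = 1e-12)
  # every test sample predicted exactly once
  expect_equal(sort(cv$predictions$index), seq_len(nrow(q)))
})

test_that("inner validation error, not training error, drives selection", {
  # learner that memorises training targets when told to overfit:
  # perfect on train, useless on validation
  memoriser <- list(
    name = "memoriser", usesValidation = FALSE,
    fit = function(tr, va, features, hyper) {
      if (isTRUE(hyper$overfit)) {
        list(mode = "memo", keys = paste(tr$drug_a, tr$drug_b,
                                         tr$cell_line),
             vals = tr$synergy)
      } else list(mode = "mean", mu = mean(tr$synergy))
    },
    predict = function(model, quartets, features) {
      if (model$mode == "memo") {
        hit <- match(paste(quartets$drug_a, quartets$drug_b,
                           quartets$cell_line), model$keys)
        out <- model$vals[hit]
        out[is.na(out)] <- 1e6   # memoriser is lost off its table
        out
      } else rep(model$mu, nrow(quartets))
    })
  world <- tinyWorld()
  q <- world$quartets
  f <- makeFolds(q, "leave_combination", k = 3, seed = 8)
  cv <- nestedCV(q, f, memoriser,
                 grid = list(list(overfit = TRUE), list(overfit = FALSE)))
  # the overfitting grid point is never chosen
  expect_true(all(cv$chosen == 2L))
})

test_that("regression metrics match their definitions", {
  expect_equal(regressionMetrics(1:5, 1:5)$mse, 0)
  expect_equal(regressionMetrics(1:5, 1:5)$pearson_r, 1)
  m <- regressionMetrics(c(0, 2), c(1, 1))
  expect_equal(m$mse, 1); expect_equal(m$rmse, 1)
  # formula oracle on a random fixture
  set.seed(50)
  y <- rnorm(50); yh <- rnorm(50)
  m <- regressionMetrics(y, yh)
  expect_equal(m$mse, sum((y - yh)^2) / 50, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(m$mse), tolerance = 1e-12)
  expect_equal(m$pearson_r,
               sum((y - mean(y)) * (yh - mean(yh))) /
                 sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2)),
               tolerance = 1e-12)
  # zero variance -> undefined, not 0
  expect_true(is.na(regressionMetrics(c(1, 1), c(1, 2))$pearson_r))
})

test_that("classification panel reproduces a hand-computed table", {
  # contingency TP=5 FP=5 FN=5 TN=85 at both thresholds = 30
  y <- c(rep(40, 10), rep(0, 90))
  yhat <- c(rep(40, 5), rep(0, 5), rep(40, 5), rep(0, 85))
  m <- classificationMetrics(y, yhat, 30, 30)
  expect_equal(m$prec, 0.5, tolerance = 1e-12)
  expect_equal(m$tpr, 0.5, tolerance = 1e-12)
  expect_equal(m$tnr, 85 / 90, tolerance = 1e-12)
  expect_equal(m$bacc, (0.5 + 85 / 90) / 2, tolerance = 1e-12)
  # Cohen's kappa per definition: po = 0.9, pe = (10*10 + 90*90)/100^2
  po <- 0.9; pe <- (100 + 8100) / 1e4
  expect_equal(m$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(m$acc, po, tolerance = 1e-12)
  # perfect ranking
  expect_equal(classificationMetrics(y, y, 30, 30)$roc_auc, 1)
})

test_that("ROC AUC sits near 0.5 for random scores and matches pROC", {
  set.seed(51)
  y <- ifelse(runif(2000) < 0.1, 40, 0)
  yhat <- rnorm(2000)
  m <- classificationMetrics(y, yhat, 30, 0)
  expect_gt(m$roc_auc, 0.47); expect_lt(m$roc_auc, 0.53)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y > 30, yhat, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$roc_auc, ref, tolerance = 1e-10)
})

test_that("single-class labels yield NA AUCs but thresholded metrics", {
  y <- rep(0, 10); yhat <- rnorm(10)
  m <- classificationMetrics(y, yhat, 30, 0)
  expect_true(is.na(m$roc_auc)); expect_true(is.na(m$pr_auc))
  expect_false(is.na(m$acc))
})

test_that("threshold selection maximises balanced accuracy exhaustively", {
  # perfectly separated: any cut in the gap works; ours lies there
  y <- c(rep(50, 5), rep(0, 5))
  yhat <- c(6:10, 1:5)
  cut <- selectThreshold(y, yhat, 30)
  expect_gt(cut, 5); expect_lt(cut, 6)
  # constant predictions: single candidate returned
  expect_equal(selectThreshold(y, rep(2, 10), 30), 2)
  # exhaustive-search oracle on 20 random scores
  set.seed(52)
  y20 <- ifelse(runif(20) < 0.4, 40, 0)
  yh20 <- rnorm(20)
  u <- sort(unique(yh20))
  cand <- (u[-1] + u[-length(u)]) / 2
  bacc <- vapply(cand, function(ct) {
    lab <- y20 > 30; pred <- yh20 > ct
    mean(c(sum(lab & pred) / sum(lab), sum(!lab & !pred) / sum(!lab)))
  }, numeric(1))
  expect_equal(selectThreshold(y20, yh20, 30), cand[which.max(bacc)])
  expect_error(selectThreshold(rep(0, 5), rnorm(5)),
               class = "synscreen_invalid_input")
})

test_that("paired error comparison follows the signed-rank construction", {
  # identical errors: no decision
  r <- pairedMethodTest(1:5, 1:5)
  expect_true(is.na(r$statistic)); expect_equal(r$n_effective, 0L)
  # uniformly larger method-2 errors on n=30: exact one-sided null is
  # 2^-30 for all-positive differences
  set.seed(53)
  e1 <- runif(30); e2 <- e1 + 1
  r <- pairedMethodTest(e2, e1, alternative = "greater")
  expect_lt(r$p_value, 0.001)
  # statistic equals the brute-force sum of positive signed ranks
  d <- rnorm(12)
  e1 <- runif(12); e2 <- e1 - d
  want <- sum(rank(abs(d))[d > 0])
  expect_equal(pairedMethodTest(e1, e2)$statistic, want)
})

test_that("groupwise correlations match per-group recomputation", {
  set.seed(54)
  world <- tinyWorld()
  q <- world$quartets
  pred <- q$synergy + rnorm(nrow(q), sd = 5)
  gc <- groupwiseCorrelation(q, pred, "drug")
  for (i in seq_len(nrow(gc))) {
    idx <- q$drug_a == gc$entity[i] | q$drug_b == gc$entity[i]
    expect_equal(gc$r[i], cor(q$synergy[idx], pred[idx]),
                 tolerance = 1e-12)
  }
  # perfect predictions give r = 1 everywhere
  gp <- groupwiseCorrelation(q, q$synergy, "cell_line")
  expect_equal(gp$r, rep(1, nrow(gp)), tolerance = 1e-12)
  # constant measured scores are flagged undefined, not dropped
  qq <- q; qq$synergy[qq$drug_a == "D01" | qq$drug_b == "D01"] <- 5
  gf <- groupwiseCorrelation(qq, pred, "drug")
  row <- gf[gf$entity == "D01", ]
  expect_false(row$ok); expect_true(is.na(row$r))
})

test_that("the metric report keeps rmse = sqrt(mse) per fold", {
  world <- tinyWorld()
  q <- world$quartets
  f <- makeFolds(q, "leave_combination", k = 4, seed = 10)
  cv <- nestedCV(q, f, synergyLearner("medianPolish"))
  rep <- metricReport(cv)
  perFold <- rep[!(rep$fold %in% c("mean", "sd")), ]
  expect_equal(perFold$rmse, sqrt(perFold$mse), tolerance = 1e-12)
  expect_equal(nrow(rep), 6L)   # 4 folds + mean + sd
})
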