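test_that("circular fingerprint counts behave on micro-molecules", {
  # methane at radius 0: exactly one environment, count 1
  v <- ecfpCounts("C", radius = 0)
  expect_equal(sum(v > 0), 1L)
  expect_equal(sum(v), 1L)
  # SMILES spelling cannot matter
  expect_identical(ecfpCounts("CCO", radius = 1),
                   ecfpCounts("OCC", radius = 1))
  # purity: repeated calls agree exactly
  expect_identical(ecfpCounts("c1ccccc1O"), ecfpCounts("c1ccccc1O"))
})

test_that("environment totals match a neighbourhood-enumeration oracle", {
  # independent oracle: enumerate atom-centred neighbourhoods of radius
  # <= r as atom-index sets and count the distinct sets; the fingerprint
  # de-duplicates environments on exactly these sets, so its total count
  # must agree
  enumerate <- function(adjacency, radius) {
    n <- length(adjacency)
    sets <- character()
    for (atom in seq_len(n)) {
      seen <- atom
      frontier <- atom
      sets <- c(sets, paste(sort(seen), collapse = ","))
      for (r in seq_len(radius)) {
        if (radius == 0) break
        frontier <- setdiff(unlist(adjacency[frontier]), seen)
        seen <- sort(c(seen, frontier))
        sets <- c(sets, paste(seen, collapse = ","))
      }
    }
    length(unique(sets))
  }
  # ethanol heavy-atom graph: C1-C2-O3 (3 atoms, up to 2 radii each)
  ccoAdj <- list(2L, c(1L, 3L), 2L)
  expect_equal(sum(ecfpCounts("CCO", radius = 1)), enumerate(ccoAdj, 1L))
  expect_equal(sum(ecfpCounts("CCO", radius = 2)), enumerate(ccoAdj, 2L))
  # isobutane: central C bonded to three methyls
  isoAdj <- list(c(2L, 3L, 4L), 1L, 1L, 1L)
  expect_equal(sum(ecfpCounts("CC(C)C", radius = 1)), enumerate(isoAdj, 1L))
})

test_that("unparseable SMILES raise a parse error naming the input", {
  expect_error(ecfpCounts("not-a-molecule(("),
               class = "synscreen_parse_error")
  expect_error(molFromSmiles("C1CC"), class = "synscreen_parse_error")
})

test_that("toxicophore flags match per-pair substructure truth", {
  patterns <- c(nitroaromatic = "[c][N+](=O)[O-]",
                aromatic_ring = "c1ccccc1",
                epoxide = "C1OC1",
                aldehyde = "[CX3H1](=O)[#6]",
                hydroxyl = "[OX2H]")
  mols <- c(benzene = "c1ccccc1",
            nitrobenzene = "c1ccccc1[N+](=O)[O-]",
            ethylene_oxide = "C1CO1",
            acetaldehyde = "CC=O",
            ethanol = "CCO")
  # hand-derived presence matrix (molecules x patterns)
  truth <- rbind(
    benzene        = c(0, 1, 0, 0, 0),
    nitrobenzene   = c(1, 1, 0, 0, 0),
    ethylene_oxide = c(0, 0, 1, 0, 0),
    acetaldehyde   = c(0, 0, 0, 1, 0),
    ethanol        = c(0, 0, 0, 0, 1))
  got <- t(vapply(mols, toxicophoreFlags, integer(5), patterns = patterns))
  expect_equal(unname(got), unname(truth))
  # self-match and absent-substructure edges
  expect_equal(unname(toxicophoreFlags("c1ccccc1",
                                       c(p = "c1ccccc1"))), 1L)
  expect_equal(unname(toxicophoreFlags("CCO",
                                       c(p = "[c][N+](=O)[O-]"))), 0L)
})

test_that("invalid SMARTS are rejected at set-load time", {
  f <- withr::local_tempfile(lines = c("ok\tc1ccccc1", "broken\t[[["))
  expect_error(readSmarts(f), class = "synscreen_invalid_input")
  # the shipped default set parses
  expect_gt(length(readSmarts()), 5L)
})

test_that("physico-chemical descriptors match known values and hand counts", {
  w <- physchemDescriptors("O")
  expect_equal(w[["MW"]], 18.02, tolerance = 0.01)
  expect_equal(physchemDescriptors("CCO")[["HBD"]], 1)
  # hand enumeration of graph-derived counts
  tol <- physchemDescriptors("Cc1ccccc1")     # toluene
  expect_equal(tol[["heavyAtoms"]], 7)
  expect_equal(tol[["rings"]], 1)
  expect_equal(tol[["ringAtoms"]], 6)
  expect_equal(tol[["ringBonds"]], 6)
  expect_equal(tol[["rotatableBonds"]], 0)    # methyl is terminal
  ea <- physchemDescriptors("CCOC(=O)C")      # ethyl acetate
  expect_equal(ea[["heavyAtoms"]], 6)
  expect_equal(ea[["rotatableBonds"]], 2)     # C-O and O-C(=O)
  expect_equal(ea[["nO"]], 2)
  # determinism
  expect_identical(physchemDescriptors("CCN(CC)CC"),
                   physchemDescriptors("CCN(CC)CC"))
})

test_that("zero-variance filtering drops exactly the constant columns", {
  set.seed(11)
  m <- matrix(rnorm(10 * 13), 10)
  m <- cbind(m, matrix(rep(c(1, 0, 7, 7, 2, 2, 3), each = 10), 10))
  colnames(m) <- sprintf("f%02d", 1:20)
  m <- m[, sample(20)]
  block <- FeatureBlock(m)
  res <- zeroVarianceFilter(block)
  expect_equal(ncol(res$block), 13L)
  expect_equal(sum(res$mask), 13L)
  # an all-distinct column is retained; a constant one dropped
  expect_true(all(apply(featureValues(res$block), 2, var) > 0))
  # all-constant block errors explicitly
  expect_error(zeroVarianceFilter(FeatureBlock(matrix(1, 5, 3,
    dimnames = list(NULL, c("a", "b", "c"))))),
    class = "synscreen_empty_block")
})

test_that("the retained-column mask replays on new entities", {
  m <- matrix(c(1, 1, 1, 2, 5, 9, 0, 0, 0), 3,
              dimnames = list(NULL, c("k1", "k2", "k3")))
  block <- FeatureBlock(m, c("count", "count", "binary"))
  res <- zeroVarianceFilter(block)
  fresh <- FeatureBlock(matrix(c(9, 4, 1), 1,
                               dimnames = list(NULL, c("k1", "k2", "k3"))),
                        c("count", "count", "binary"))
  out <- applyColumnMask(fresh, res$mask)
  expect_equal(colnames(featureValues(out)),
               colnames(featureValues(res$block)))
  expect_equal(featureKinds(out), featureKinds(res$block))
  # kind tags survive filtering
  expect_equal(featureKinds(res$block), "count")
})

test_that("expression loading honours the informative-gene mask order", {
  d <- withr::local_tempdir()
  genes <- sprintf("G%02d", 1:10)
  expr <- matrix(seq_len(40), 10, 4,
                 dimnames = list(genes, paste0("c", 1:4)))
  mf <- file.path(d, "expr.csv")
  write.csv(data.frame(gene = genes, expr), mf, row.names = FALSE)
  # mask restricted and reordered
  maskFile <- file.path(d, "mask.txt")
  writeLines(c("G07", "G02", "G05", "G01", "G09", "G03"), maskFile)
  fb <- loadExpression(mf, maskFile)
  expect_equal(dim(featureValues(fb)), c(4L, 6L))
  expect_equal(colnames(featureValues(fb)),
               c("G07", "G02", "G05", "G01", "G09", "G03"))
  expect_equal(featureValues(fb)["c1", "G07"], 7)
  # no mask keeps all genes; missing mask genes are named in the error
  expect_equal(ncol(loadExpression(mf)), 10L)
  writeLines(c("G01", "GX1"), maskFile)
  expect_error(loadExpression(mf, maskFile), "GX1",
               class = "synscreen_invalid_input")
})

test_that("featurizeDrugs concatenates typed blocks with stable kinds", {
  fb <- featurizeDrugs(c(a = "CCO", b = "c1ccccc1"), foldSize = 64,
                       patterns = c(ring = "c1ccccc1"))
  expect_equal(nrow(fb), 2L)
  expect_equal(sum(featureKinds(fb) == "count"), 64L)
  expect_equal(sum(featureKinds(fb) == "continuous"), 16L)
  expect_equal(sum(featureKinds(fb) == "binary"), 1L)
  expect_equal(unname(featureValues(fb)[, "tox_ring"]), c(0, 1))
})
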