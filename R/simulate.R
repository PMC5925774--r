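## Synthetic-data generator: combination designs, worlds with latent drug
## mechanism classes and cell-line pathway structure, and dose-response
## surfaces with planted Loewe deviations. Everything is a pure function
## of its seed so tests and the acceptance pipeline are reproducible
## without external data.

#' Generate a combination-screen design
#'
#' An "exhaustive" drug set combined all-vs-all plus a "supplemental"
#' set combined only against the exhaustive drugs (never with each other
#' and never with itself), crossed with a panel of cell lines. The
#' default sizes (22 exhaustive, 16 supplemental, 39 cell lines) give
#' `C(22,2) + 16*22 = 583` distinct pairs — 83% of all `C(38,2)` possible
#' pairs — and `583 * 39 = 22737` quartets.
#'
#' @param nExhaustive drugs combined all-vs-all (default 22).
#' @param nSupplemental drugs combined only against the exhaustive set
#'   (default 16).
#' @param nCellLines cell-line panel size (default 39).
#' @return List with `drugs` (ids and set membership), `cellLines`,
#'   `pairs` (data.frame `drug_a`, `drug_b`) and `quartets` (the pair x
#'   cell-line skeleton).
#' @export
generateDesign <- function(nExhaustive = 22L, nSupplemental = 16L,
                           nCellLines = 39L) {
  stopifnot(nExhaustive >= 1L, nSupplemental >= 0L, nCellLines >= 1L)
  exh <- sprintf("D%02d", seq_len(nExhaustive))
  sup <- if (nSupplemental > 0L)
    sprintf("S%02d", seq_len(nSupplemental)) else character()
  cells <- sprintf("C%02d", seq_len(nCellLines))
  pairsEE <- if (nExhaustive >= 2L) t(utils::combn(exh, 2L)) else
    matrix(character(), 0L, 2L)
  pairsSE <- if (length(sup)) cbind(rep(sup, each = length(exh)),
                                    rep(exh, length(sup))) else
    matrix(character(), 0L, 2L)
  pairs <- data.frame(drug_a = c(pairsEE[, 1], pairsSE[, 1]),
                      drug_b = c(pairsEE[, 2], pairsSE[, 2]))
  quartets <- data.frame(
    drug_a = rep(pairs$drug_a, times = nCellLines),
    drug_b = rep(pairs$drug_b, times = nCellLines),
    cell_line = rep(cells, each = nrow(pairs)))
  list(drugs = data.frame(drug = c(exh, sup),
                          set = rep(c("exhaustive", "supplemental"),
                                    c(length(exh), length(sup)))),
       cellLines = cells, pairs = pairs, quartets = quartets)
}

#' Generate a synthetic world: features and ground-truth synergy
#'
#' Every drug gets a latent mechanism class and feature blocks that are
#' informative of it: sparse nonnegative counts (class-prototype Poisson
#' rates), continuous columns (class-shifted Gaussians) and binary
#' columns (class-dependent Bernoulli flags). Every cell line gets a
#' latent pathway-activity vector; a known subset of expression "genes"
#' loads on the pathways while the remainder is noise. Ground-truth
#' synergy is an interaction term: a symmetric heavy-tailed class-pair
#' effect, modulated by the activity of a pathway associated with the
#' class pair, plus zero-centred Gaussian noise. The label distribution
#' is rescaled to a configurable standard deviation (default 23) and
#' shifted so the median sits at a small positive value (default 4.4),
#' the shape of screen-scale Loewe score distributions (mass near zero,
#' heavy tails).
#'
#' @param design a design from [generateDesign()].
#' @param nClasses number of latent drug mechanism classes (default 4).
#' @param nPathways number of latent cell pathways (default 4).
#' @param nCounts,nContinuous,nBinary drug feature block widths.
#' @param nGenes expression genes (a quarter load on pathways).
#' @param labelSd target standard deviation of synergy labels.
#' @param labelMedian target median of synergy labels.
#' @param noiseSd sd of the irreducible label noise (part of `labelSd`).
#' @param seed RNG seed; identical seeds give identical worlds.
#' @return List with `drugFeatures` and `cellFeatures`
#'   ([FeatureBlock-class]), `drugClass`, `pathways`, `quartets` (the
#'   skeleton with a `synergy` column), `truth` (noise-free scores) and
#'   the parameters.
#' @export
generateWorld <- function(design, nClasses = 4L, nPathways = 4L,
                          nCounts = 32L, nContinuous = 8L, nBinary = 8L,
                          nGenes = 40L, labelSd = 23, labelMedian = 4.4,
                          noiseSd = 5, seed = 1L) {
  set.seed(as.integer(seed))
  drugs <- design$drugs$drug
  cells <- design$cellLines
  nd <- length(drugs); nc <- length(cells)
  cls <- sample(rep_len(seq_len(nClasses), nd))
  names(cls) <- drugs

  ## drug features: class prototypes + per-drug jitter
  protoRate <- matrix(runif(nClasses * nCounts, 0, 3), nClasses)
  counts <- matrix(rpois(nd * nCounts, protoRate[cls, ]), nd)
  protoMu <- matrix(rnorm(nClasses * nContinuous, sd = 2), nClasses)
  contin <- protoMu[cls, ] + matrix(rnorm(nd * nContinuous, sd = 0.5), nd)
  protoP <- matrix(runif(nClasses * nBinary, 0.1, 0.9), nClasses)
  binar <- matrix(rbinom(nd * nBinary, 1L, protoP[cls, ]), nd)
  dimnames(counts) <- list(drugs, sprintf("cnt%03d", seq_len(nCounts)))
  dimnames(contin) <- list(drugs, sprintf("con%02d", seq_len(nContinuous)))
  dimnames(binar) <- list(drugs, sprintf("bin%02d", seq_len(nBinary)))
  drugFeatures <- cbindBlocks(FeatureBlock(counts, "count"),
                              FeatureBlock(contin, "continuous"),
                              FeatureBlock(binar, "binary"))

  ## cell lines: pathway activities and expression with latent structure
  path <- matrix(rnorm(nc * nPathways), nc,
                 dimnames = list(cells, sprintf("P%d", seq_len(nPathways))))
  nInf <- max(nPathways, floor(nGenes / 4))
  load <- matrix(rnorm(nInf * nPathways, sd = 1.5), nPathways, nInf)
  expr <- cbind(path %*% load + matrix(rnorm(nc * nInf, sd = 0.3), nc),
                matrix(rnorm(nc * (nGenes - nInf)), nc))
  colnames(expr) <- sprintf("G%03d", seq_len(nGenes))
  rownames(expr) <- cells
  cellFeatures <- FeatureBlock(expr, "continuous")

  ## heavy-tailed symmetric class-pair interaction, pathway-modulated
  inter <- matrix(rt(nClasses^2, df = 3), nClasses)
  inter <- (inter + t(inter)) / 2
  pathOf <- matrix(sample.int(nPathways, nClasses^2, replace = TRUE),
                   nClasses)
  pathOf[lower.tri(pathOf)] <- t(pathOf)[lower.tri(pathOf)]
  q <- design$quartets
  ca <- cls[q$drug_a]; cb <- cls[q$drug_b]
  g <- inter[cbind(ca, cb)] *
    path[cbind(match(q$cell_line, cells), pathOf[cbind(ca, cb)])]
  ## rescale so that signal + noise hits the target sd, then centre the
  ## median at a small positive value
  sigSd <- sqrt(max(labelSd^2 - noiseSd^2, 1e-6))
  g <- g / max(sd(g), 1e-12) * sigSd
  g <- g - median(g) + labelMedian
  noise <- rnorm(length(g), sd = noiseSd)
  q$synergy <- g + noise
  list(drugFeatures = drugFeatures, cellFeatures = cellFeatures,
       drugClass = cls, pathways = path, quartets = q, truth = g,
       params = list(nClasses = nClasses, nPathways = nPathways,
                     labelSd = labelSd, labelMedian = labelMedian,
                     noiseSd = noiseSd, seed = seed))
}

#' Generate single-agent screens and checkerboards with planted synergy
#'
#' Draws a Hill curve per (drug, cell line), emits a single-agent table
#' (8 log-spaced concentrations, 6 replicates) and, per quartet, a 4x4
#' checkerboard (4 replicates) whose wells equal the Loewe-additive
#' reference minus a planted deviation pattern, plus measurement noise.
#' The planted per-quartet total is recovered by the scoring pipeline as
#' the synergy score (sum aggregation), making end-to-end round trips
#' exact at zero noise. The deviation pattern is either a smooth bump
#' centred at mid-doses (default; exercises interpolation) or uniform
#' across the 16 wells (exact linearity checks).
#'
#' @param quartets quartet skeleton (`drug_a`, `drug_b`, `cell_line`).
#' @param plantedScore numeric vector (recycled) of per-quartet total
#'   synergy scores to plant, in %-of-control points.
#' @param noiseSd measurement noise sd in % of control (default 2).
#' @param pattern `"bump"` or `"uniform"` per-well deviation pattern.
#' @param doseRange range (µM) spanned by the 8-point single-agent
#'   ladder.
#' @param seed RNG seed.
#' @return List with `singleAgent` and `checkerboards` data.frames in
#'   the standard long CSV layouts, plus `curves` (the true
#'   [HillCurve-class] objects, named `"drug|cell"`).
#' @export
generateSurfaces <- function(quartets, plantedScore = 0, noiseSd = 2,
                             pattern = c("bump", "uniform"),
                             doseRange = c(0.01, 10), seed = 1L) {
  pattern <- match.arg(pattern)
  set.seed(as.integer(seed))
  plantedScore <- rep_len(plantedScore, nrow(quartets))
  saDoses <- 10^seq(log10(doseRange[1]), log10(doseRange[2]),
                    length.out = 8L)
  cbDoses <- saDoses[c(2L, 4L, 5L, 7L)]

  ## per-well weights summing to 1
  w <- if (pattern == "uniform") matrix(1 / 16, 4L, 4L) else {
    b <- outer(dnorm(seq_len(4L), 2.5, 1), dnorm(seq_len(4L), 2.5, 1))
    b / sum(b)
  }

  need <- unique(rbind(
    setNames(quartets[, c("drug_a", "cell_line")], c("drug", "cell_line")),
    setNames(quartets[, c("drug_b", "cell_line")], c("drug", "cell_line"))))
  curves <- list()
  saRows <- vector("list", nrow(need))
  for (i in seq_len(nrow(need))) {
    cv <- HillCurve(e0 = rnorm(1, 100, 2),
                    einf = runif(1, 0, 50),
                    ec50 = 10^runif(1, log10(doseRange[1] * 10),
                                    log10(doseRange[2] / 10)),
                    h = runif(1, 0.8, 2.5))
    key <- paste(need$drug[i], need$cell_line[i], sep = "|")
    curves[[key]] <- cv
    resp <- rep(hillResponse(cv, saDoses), times = 6L) +
      rnorm(8L * 6L, sd = noiseSd)
    saRows[[i]] <- data.frame(
      drug = need$drug[i], cell_line = need$cell_line[i],
      dose_uM = rep(saDoses, times = 6L),
      response_pct = resp, replicate = rep(seq_len(6L), each = 8L))
  }
  singleAgent <- do.call(rbind, saRows)

  cbRows <- vector("list", nrow(quartets))
  for (i in seq_len(nrow(quartets))) {
    ca <- curves[[paste(quartets$drug_a[i], quartets$cell_line[i],
                        sep = "|")]]
    cb <- curves[[paste(quartets$drug_b[i], quartets$cell_line[i],
                        sep = "|")]]
    ref <- matrix(NA_real_, 4L, 4L)
    for (a in seq_len(4L)) for (b in seq_len(4L))
      ref[a, b] <- loeweReference(cbDoses[a], cbDoses[b], ca, cb)
    clean <- ref - plantedScore[i] * w   # deviation = reference - observed
    grid <- expand.grid(a = seq_len(4L), b = seq_len(4L),
                        replicate = seq_len(4L))
    cbRows[[i]] <- data.frame(
      drug_a = quartets$drug_a[i], drug_b = quartets$drug_b[i],
      cell_line = quartets$cell_line[i],
      dose_a_uM = cbDoses[grid$a], dose_b_uM = cbDoses[grid$b],
      response_pct = clean[cbind(grid$a, grid$b)] +
        rnorm(nrow(grid), sd = noiseSd),
      replicate = grid$replicate)
  }
  list(singleAgent = singleAgent,
       checkerboards = do.call(rbind, cbRows),
       curves = curves)
}

#' Write a synthetic corpus to disk
#'
#' Emits the single-agent, checkerboard and quartet CSVs in the standard
#' dialects plus a YAML manifest recording seeds and parameters.
#'
#' @param world a world from [generateWorld()].
#' @param surfaces optional result of [generateSurfaces()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSyntheticCorpus <- function(world, surfaces = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(world$quartets, file.path(dir, "quartets.csv"),
            row.names = FALSE)
  write.csv(data.frame(entity = rownames(world$drugFeatures@values),
                       world$drugFeatures@values, check.names = FALSE),
            file.path(dir, "drug_features.csv"), row.names = FALSE)
  ## expression in the genes x cell-lines on-disk layout
  expr <- t(world$cellFeatures@values)
  write.csv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
            file.path(dir, "expression.csv"), row.names = FALSE)
  if (!is.null(surfaces)) {
    write.csv(surfaces$singleAgent, file.path(dir, "single_agent.csv"),
              row.names = FALSE)
    write.csv(surfaces$checkerboards,
              file.path(dir, "checkerboards.csv"), row.names = FALSE)
  }
  yaml::write_yaml(c(world$params,
                     list(generated = "synthetic", package = "synscreen",
                          version = as.character(
                            utils::packageVersion("synscreen")))),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
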