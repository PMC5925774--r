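#' Circular-fingerprint substructure counts
#'
#' Computes extended-connectivity (Morgan-style) atom-environment counts
#' for a structure: every atom contributes one environment per radius
#' from 0 up to `radius`, environments covering an identical atom set are
#' de-duplicated, and the surviving environment identifiers are hashed
#' into `foldSize` columns whose entries count occurrences. A radius of 3
#' corresponds to diameter-6 fingerprints (ECFP_6). Identical structures
#' (any SMILES spelling) yield identical vectors because parsing
#' canonicalises first.
#'
#' @param smiles a single SMILES string.
#' @param radius neighbourhood radius (default 3, i.e. diameter 6).
#' @param foldSize number of hashed columns (default 2048).
#' @return Named integer vector of length `foldSize`
#'   (`ecfp0001`...`ecfpNNNN`).
#' @examples
#' sum(ecfpCounts("C", radius = 0) > 0)  # one atom environment
#' @export
ecfpCounts <- function(smiles, radius = 3L, foldSize = 2048L) {
  stopifnot(radius >= 0, foldSize >= 1)
  mol <- molFromSmiles(smiles)
  env <- morganEnvironments(mol, radius)
  v <- integer(foldSize)
  idx <- (env$id %% foldSize) + 1L
  for (i in idx) v[i] <- v[i] + 1L
  names(v) <- sprintf("ecfp%04d", seq_len(foldSize))
  v
}

#' Load a named SMARTS pattern set
#'
#' Reads a tab-separated file of `name<TAB>pattern` lines (lines starting
#' with `#` ignored) and validates every pattern by attempting a match
#' against benzene; invalid patterns are reported at load time with their
#' names, not later per molecule.
#'
#' @param path SMARTS file; default is the toxicophore set shipped with
#'   the package, a small literature-derived collection of structural
#'   alerts (nitroaromatics, aromatic amines, epoxides, Michael
#'   acceptors, ...).
#' @return Named character vector of SMARTS patterns.
#' @export
readSmarts <- function(path = system.file("extdata", "toxicophores.smarts",
                                          package = "synscreen")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) != 2L
  if (any(bad))
    stopf("synscreen_invalid_input", "malformed SMARTS line(s): %s",
          paste(which(bad), collapse = ", "))
  pat <- vapply(parts, `[`, "", 2L)
  names(pat) <- vapply(parts, `[`, "", 1L)
  ok <- withOBMol("c1ccccc1", function(m) {
    vapply(pat, function(p) {
      !inherits(tryCatch(ChemmineOB::smartsSearch_OB(list(m), p),
                         error = function(e) e), "error")
    }, logical(1))
  })[[1]]
  if (!all(ok))
    stopf("synscreen_invalid_input", "invalid SMARTS pattern(s): %s",
          paste(names(pat)[!ok], collapse = ", "))
  pat
}

#' Binary toxicophore flags
#'
#' One flag per SMARTS pattern: 1 iff the pattern matches the structure
#' at least once.
#'
#' @param smiles a single SMILES string.
#' @param patterns named character vector of SMARTS (see [readSmarts()]).
#' @return Named 0/1 integer vector, one entry per pattern.
#' @export
toxicophoreFlags <- function(smiles, patterns = readSmarts()) {
  can <- canonicalSmiles(smiles)
  flags <- withOBMol(can, function(m) {
    vapply(patterns, function(p)
      as.integer(ChemmineOB::smartsSearch_OB(list(m), p) > 0), integer(1))
  })[[1]]
  names(flags) <- names(patterns)
  flags
}

#' Physico-chemical descriptor vector
#'
#' A fixed, documented list of 16 standard descriptors per structure:
#' OpenBabel-derived molecular weight, logP, molar refractivity, TPSA,
#' H-bond donors and acceptors and fluorine count, plus graph-derived
#' heavy-atom, ring-bond, ring, rotatable-bond, heteroatom (N, O, S,
#' halogen) counts and the formal-charge sum. Rotatable bonds are
#' acyclic single bonds between two non-terminal heavy atoms. Descriptor
#' failures yield `NA` (flagged missing), never a silent zero.
#'
#' @param smiles a single SMILES string.
#' @return Named numeric vector of length 16.
#' @examples
#' physchemDescriptors("O")[["MW"]]  # 18.02
#' @export
physchemDescriptors <- function(smiles) {
  mol <- molFromSmiles(smiles)
  ob <- tryCatch(withOBMol(mol$cansmi, function(m)
    ChemmineOB::prop_OB(list(m)))[[1]],
    error = function(e) NULL)
  pick <- function(col) {
    if (is.null(ob) || !col %in% colnames(ob)) NA_real_
    else as.numeric(ob[1, col])
  }
  b <- mol$bonds
  deg <- vapply(seq_along(mol$element), function(i)
    if (is.null(mol$adj[[i]])) 0L else nrow(mol$adj[[i]]), integer(1))
  rotatable <- if (nrow(b) == 0L) 0L else
    sum(b$order == 1 & !b$inRing & deg[b$a1] > 1 & deg[b$a2] > 1)
  nRingBonds <- sum(b$inRing)
  nRingAtoms <- sum(mol$inRing)
  ## circuit rank = independent rings
  nRings <- nrow(b) - length(mol$element) + nComponents(mol)
  c(MW = pick("MW"), logP = pick("logP"), MR = pick("MR"),
    TPSA = pick("TPSA"), HBD = pick("HBD"), HBA = pick("HBA1"),
    nF = pick("nF"),
    heavyAtoms = length(mol$element),
    rings = nRings, ringAtoms = nRingAtoms, ringBonds = nRingBonds,
    rotatableBonds = rotatable,
    nN = sum(mol$element == "N"), nO = sum(mol$element == "O"),
    nSHal = sum(mol$element %in% c("S", "F", "Cl", "Br", "I")),
    chargeSum = sum(mol$charge))
}

## number of connected components of the heavy-atom graph
nComponents <- function(mol) {
  n <- length(mol$element)
  if (n == 0L) return(0L)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- mol$adj[[v]]
      if (!is.null(nb)) for (w in nb[, 1]) if (comp[w] == 0L) {
        comp[w] <- cur; queue <- c(queue, w)
      }
    }
  }
  cur
}

#' Drop zero-variance feature columns
#'
#' Removes every column whose variance over a set of reference rows
#' (typically the training entities) is exactly zero, and returns the
#' retained-column mask so the identical selection can be replayed on new
#' entities.
#'
#' @param block a [FeatureBlock-class].
#' @param referenceRows row indices (or names) defining the variance
#'   reference; defaults to all rows.
#' @return List with `block` (filtered [FeatureBlock-class]) and `mask`
#'   (named logical vector over the original columns).
#' @export
zeroVarianceFilter <- function(block, referenceRows = seq_len(nrow(block))) {
  stopifnot(is(block, "FeatureBlock"))
  if (length(referenceRows) == 0L)
    stopf("synscreen_invalid_input", "referenceRows must be nonempty")
  v <- block@values[referenceRows, , drop = FALSE]
  keep <- apply(v, 2L, function(x) var(x) > 0)
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stopf("synscreen_empty_block", "all %d columns have zero variance",
          ncol(block))
  names(keep) <- colnames(block@values)
  list(block = FeatureBlock(block@values[, keep, drop = FALSE],
                            block@kinds[keep]),
       mask = keep)
}

#' Apply a retained-column mask to a feature block
#'
#' @param block a [FeatureBlock-class] over the original column space.
#' @param mask logical mask as returned by [zeroVarianceFilter()].
#' @return The filtered [FeatureBlock-class], columns in training order.
#' @export
applyColumnMask <- function(block, mask) {
  stopifnot(is(block, "FeatureBlock"))
  if (!identical(names(mask), colnames(block@values)))
    stopf("synscreen_invalid_input",
          "mask columns do not match block columns")
  FeatureBlock(block@values[, mask, drop = FALSE], block@kinds[mask])
}

#' Load a gene-expression feature block for cell lines
#'
#' Reads a genes x cell-lines matrix (CSV or TSV, header row of cell-line
#' identifiers, first column gene identifiers) and returns the transposed
#' cell-line x gene [FeatureBlock-class], optionally restricted to an
#' informative-gene mask (one identifier per line; column order follows
#' the mask order). No re-normalisation is performed — summarisation is
#' assumed to have happened upstream.
#'
#' @param matrixFile path to the expression matrix.
#' @param maskFile optional path to the informative-gene list.
#' @return A continuous [FeatureBlock-class], cell lines in rows.
#' @export
loadExpression <- function(matrixFile, maskFile = NULL) {
  tab <- readDelimAuto(matrixFile)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  if (!is.null(maskFile)) {
    mask <- trimws(readLines(maskFile))
    mask <- mask[nzchar(mask)]
    missing <- setdiff(mask, genes)
    if (length(missing))
      stopf("synscreen_invalid_input",
            "mask genes absent from matrix: %s",
            paste(missing, collapse = ", "))
    m <- m[mask, , drop = FALSE]
  }
  FeatureBlock(t(m), "continuous")
}

#' Featurize a set of drugs
#'
#' Builds the combined per-drug feature block: circular-fingerprint
#' counts, physico-chemical descriptors and toxicophore flags, with kind
#' tags `count` / `continuous` / `binary` respectively.
#'
#' @param smiles named character vector of SMILES (names = drug ids).
#' @param radius,foldSize passed to [ecfpCounts()].
#' @param patterns SMARTS set for [toxicophoreFlags()].
#' @return A [FeatureBlock-class] with one row per drug.
#' @export
featurizeDrugs <- function(smiles, radius = 3L, foldSize = 2048L,
                           patterns = readSmarts()) {
  stopifnot(!is.null(names(smiles)), all(nzchar(names(smiles))))
  asRows <- function(f) {
    m <- do.call(rbind, lapply(smiles, f))
    rownames(m) <- names(smiles)
    m
  }
  fp <- asRows(function(s) ecfpCounts(s, radius, foldSize))
  pc <- asRows(physchemDescriptors)
  tox <- asRows(function(s) toxicophoreFlags(s, patterns))
  colnames(tox) <- paste0("tox_", names(patterns))
  cbindBlocks(FeatureBlock(fp, "count"),
              FeatureBlock(pc, "continuous"),
              FeatureBlock(tox, "binary"))
}

#' Read a SMILES file
#'
#' One structure per line, optionally followed by a tab-separated
#' identifier; unnamed entries get `mol<N>` identifiers.
#'
#' @param path SMILES file path.
#' @return Named character vector of SMILES.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  smi <- vapply(parts, `[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else sprintf("mol%d", i),
    "")
  names(smi) <- ids
  smi
}
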