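## Molecular graph utilities on top of ChemmineOB (OpenBabel bindings).
## SMILES are canonicalised through OpenBabel before use so that any two
## SMILES of the same structure map to one graph; the heavy-atom graph is
## read from OpenBabel's V2000 molfile rendering of the canonical SMILES
## (atom block, bond block, M CHG charge lines), which also covers
## single-atom molecules that higher-level SDF containers reject.

## Standard valences used to infer implicit hydrogen counts from heavy
## bond orders (fallback 0 for elements not listed).
.STD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                  S = 2, Cl = 1, Br = 1, I = 1)

## run f over the single OBMol parsed from a SMILES string
withOBMol <- function(smiles, f) {
  ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), f)
}

canonicalSmiles <- function(smiles) {
  can <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = paste0(smiles, "\n")),
    error = function(e) "")
  can <- sub("[\t ].*$", "", trimws(can))
  if (!nzchar(can))
    stopf("synscreen_parse_error", "unparseable SMILES: '%s'", smiles)
  can
}

#' Parse a SMILES string into a molecular graph
#'
#' Canonicalises through OpenBabel and returns the heavy-atom graph:
#' elements, formal charges, bond list with orders, ring membership and
#' implicit hydrogen counts (standard valence minus the sum of heavy
#' bond orders, adjusted by charge). A bond is in a ring iff its
#' endpoints stay connected after its removal.
#'
#' @param smiles a single SMILES string.
#' @return A list with elements `element` (character), `charge`
#'   (integer), `nH` (integer), `inRing` (logical), `bonds` (data.frame
#'   `a1`, `a2`, `order`, `inRing`), `adj` (per-atom matrix of
#'   neighbour index and bond order) and `cansmi` (the canonical SMILES
#'   used).
#' @export
molFromSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonicalSmiles(smiles)
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(can, "\n")),
    error = function(e) "")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L)
    stopf("synscreen_parse_error", "unparseable SMILES: '%s'", smiles)
  counts <- lines[4]
  nAtoms <- as.integer(substr(counts, 1L, 3L))
  nBonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(nAtoms) || nAtoms < 1L)
    stopf("synscreen_parse_error", "unparseable SMILES: '%s'", smiles)
  atomLines <- lines[4L + seq_len(nAtoms)]
  element <- trimws(substr(atomLines, 32L, 34L))
  bondLines <- if (nBonds > 0L) lines[4L + nAtoms + seq_len(nBonds)]
               else character()
  bonds <- data.frame(
    a1 = as.integer(substr(bondLines, 1L, 3L)),
    a2 = as.integer(substr(bondLines, 4L, 6L)),
    order = as.integer(substr(bondLines, 7L, 9L)))
  ## formal charges from "M  CHG" property lines
  charge <- integer(nAtoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    nPairs <- f[1]
    for (p in seq_len(nPairs))
      charge[f[2 * p]] <- f[2 * p + 1L]
  }
  bonds$inRing <- vapply(seq_len(nrow(bonds)), function(k)
    connectedWithout(nAtoms, bonds, k), logical(1))
  inRing <- rep(FALSE, nAtoms)
  if (nrow(bonds))
    inRing[unique(c(bonds$a1[bonds$inRing], bonds$a2[bonds$inRing]))] <- TRUE
  adj <- vector("list", nAtoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- rbind(adj[[bonds$a1[k]]],
                                c(bonds$a2[k], bonds$order[k]))
    adj[[bonds$a2[k]]] <- rbind(adj[[bonds$a2[k]]],
                                c(bonds$a1[k], bonds$order[k]))
  }
  heavyVal <- vapply(seq_len(nAtoms), function(i)
    if (is.null(adj[[i]])) 0 else sum(adj[[i]][, 2]), numeric(1))
  std <- .STD_VALENCE[element]
  std[is.na(std)] <- 0
  nH <- pmax(0L, as.integer(std + charge - heavyVal))
  list(element = element, charge = charge, nH = nH, inRing = inRing,
       bonds = bonds, adj = adj, cansmi = can)
}

## endpoints of bond k still connected when k is removed?
connectedWithout <- function(n, bonds, k) {
  src <- bonds$a1[k]; dst <- bonds$a2[k]
  seen <- rep(FALSE, n); seen[src] <- TRUE
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (j in seq_len(nrow(bonds))) {
      if (j == k) next
      w <- if (bonds$a1[j] == v) bonds$a2[j]
           else if (bonds$a2[j] == v) bonds$a1[j] else next
      if (!seen[w]) {
        if (w == dst) return(TRUE)
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

## Circular (Morgan-style) atom environments. Returns one surviving
## environment per row: identifier (32-bit hash), radius, central atom.
## Initial atom invariant: element, heavy degree, formal charge, implicit
## H count, ring membership; iteration hashes the previous invariant with
## the sorted (bond order, neighbour invariant) list. Environments whose
## covered atom set duplicates a previously generated one are removed,
## mirroring the de-duplication stage of extended-connectivity
## fingerprinting.
morganEnvironments <- function(mol, radius) {
  n <- length(mol$element)
  inv <- vapply(seq_len(n), function(i) {
    deg <- if (is.null(mol$adj[[i]])) 0L else nrow(mol$adj[[i]])
    fnv1a32(paste(mol$element[i], deg, mol$charge[i], mol$nH[i],
                  as.integer(mol$inRing[i]), sep = ":"))
  }, numeric(1))
  ids <- inv
  out <- data.frame(id = inv, radius = 0L, atom = seq_len(n))
  if (radius > 0) {
    for (r in seq_len(radius)) {
      newInv <- numeric(n)
      for (i in seq_len(n)) {
        nb <- mol$adj[[i]]
        newInv[i] <- if (is.null(nb)) {
          fnv1a32(paste("r", r, ids[i], sep = ":"))
        } else {
          parts <- paste(nb[, 2], ids[nb[, 1]], sep = "-")
          fnv1a32(paste("r", r, ids[i],
                        paste(sort(parts), collapse = "|"), sep = ":"))
        }
      }
      ids <- newInv
      out <- rbind(out, data.frame(id = ids, radius = r, atom = seq_len(n)))
    }
  }
  ## de-duplicate on covered atom set: two environments spanning the same
  ## atoms describe the same substructure; the smaller radius wins (rows
  ## are ordered by radius)
  keyOf <- function(atom, r) {
    seen <- atom
    frontier <- atom
    if (r > 0) for (s in seq_len(r)) {
      nxt <- unlist(lapply(frontier, function(v)
        if (is.null(mol$adj[[v]])) integer() else mol$adj[[v]][, 1]))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    paste(sort(seen), collapse = ",")
  }
  keys <- mapply(keyOf, out$atom, out$radius)
  out[!duplicated(keys), , drop = FALSE]
}
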