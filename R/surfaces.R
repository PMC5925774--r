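#' Loewe-additivity expected response for a dose pair
#'
#' Under Loewe additivity a combination behaves as if each drug were a
#' dilution of the other: the expected response `E` at doses `(a, b)`
#' solves the index equation `a / A(E) + b / B(E) = 1`, where `A` and `B`
#' are the inverse single-agent Hill curves. The root is located by
#' bisection on `E` over the overlap of the two curves' attainable
#' response ranges, to an absolute tolerance of 1e-6 (at most 200
#' iterations). When no root exists in the overlap — one drug cannot reach
#' the other's effect level — `E` is clipped to the nearest jointly
#' attainable boundary.
#'
#' Edge cases: both doses zero returns `mean(e0_a, e0_b)`; a single zero
#' dose returns the other drug's Hill response exactly; a degenerate
#' (flat) curve makes the additivity reference fall back to the
#' highest-single-agent response of the pair, with a warning.
#'
#' @param doseA,doseB nonnegative doses in µM (scalars).
#' @param curveA,curveB [HillCurve-class] objects, monotone in the same
#'   direction.
#' @param tol absolute bisection tolerance on the response.
#' @return Expected combination response (% of control).
#' @examples
#' hc <- HillCurve(100, 0, ec50 = 1, h = 1)
#' loeweReference(0.5, 0.5, hc, hc)  # sham: equals hillResponse(hc, 1)
#' @export
loeweReference <- function(doseA, doseB, curveA, curveB, tol = 1e-6) {
  stopifnot(is(curveA, "HillCurve"), is(curveB, "HillCurve"))
  if (doseA < 0 || doseB < 0)
    stopf("synscreen_invalid_input", "doses must be nonnegative")
  if (doseA == 0 && doseB == 0) return(mean(c(curveA@e0, curveB@e0)))
  if (doseB == 0) return(hillResponse(curveA, doseA))
  if (doseA == 0) return(hillResponse(curveB, doseB))

  flatA <- curveA@degenerate || curveA@e0 == curveA@einf
  flatB <- curveB@degenerate || curveB@e0 == curveB@einf
  if (flatA || flatB) {
    ra <- hillResponse(curveA, doseA); rb <- hillResponse(curveB, doseB)
    warnf("synscreen_flat_curve",
          "flat single-agent curve: using highest-single-agent reference")
    ## HSA: the stronger of the two single-agent effects (further from e0)
    e0m <- mean(c(curveA@e0, curveB@e0))
    return(if (abs(ra - e0m) >= abs(rb - e0m)) ra else rb)
  }

  dirA <- sign(curveA@einf - curveA@e0)
  if (dirA != sign(curveB@einf - curveB@e0))
    stopf("synscreen_invalid_input",
          "curves must be monotone in the same direction")

  ## overlap of attainable (open) response ranges
  lo <- max(min(curveA@e0, curveA@einf), min(curveB@e0, curveB@einf))
  hi <- min(max(curveA@e0, curveA@einf), max(curveB@e0, curveB@einf))
  if (lo >= hi) { # ranges barely touch; only sensible for weird inputs
    return(mean(c(lo, hi)))
  }
  eps <- (hi - lo) * 1e-9
  index <- function(E) {
    doseA / hillInverse(curveA, E) + doseB / hillInverse(curveB, E) - 1
  }
  ## index() is monotone in E: for decreasing curves (e0 > einf) the
  ## required single-agent doses shrink as E rises toward e0, so the sum
  ## grows; for increasing curves the orientation flips.
  a <- lo + eps; b <- hi - eps
  fa <- index(a); fb <- index(b)
  decreasing <- curveA@e0 > curveA@einf
  if (decreasing) {
    ## f increasing in E: f(a) should be < 0 < f(b)
    if (fa >= 0) return(lo)   # doses exceed what reaches the overlap floor
    if (fb <= 0) return(hi)   # doses too small to pull below the ceiling
  } else {
    if (fb >= 0) return(hi)
    if (fa <= 0) return(lo)
  }
  for (i in seq_len(200L)) {
    m <- (a + b) / 2
    fm <- index(m)
    pos <- if (decreasing) fm > 0 else fm < 0
    if (pos) b <- m else a <- m
    if ((b - a) < tol) break
  }
  (a + b) / 2
}

#' Assemble a 5x5 dose-response surface
#'
#' Embeds a measured 4x4 checkerboard as the interior block of a 5x5
#' surface whose zero-dose edges are single-agent Hill predictions at the
#' corresponding nonzero doses, and whose `[1, 1]` corner is the mean of
#' the two fitted zero-dose responses. A warning (not an error) is issued
#' when checkerboard doses extrapolate beyond a curve's fitted bounds as
#' encoded in its `ec50` bounds — extrapolation is routine for inactive
#' agents.
#'
#' @param board a [Checkerboard-class] (replicate-averaged).
#' @param curveA,curveB fitted [HillCurve-class] objects for the two
#'   single agents on this cell line.
#' @return A [DoseSurface-class].
#' @export
assembleSurface <- function(board, curveA, curveB) {
  stopifnot(is(board, "Checkerboard"),
            is(curveA, "HillCurve"), is(curveB, "HillCurve"))
  da <- c(0, board@drugADoses)
  db <- c(0, board@drugBDoses)
  resp <- matrix(NA_real_, 5L, 5L)
  resp[1L, 1L] <- mean(c(curveA@e0, curveB@e0))
  resp[2:5, 1L] <- hillResponse(curveA, board@drugADoses)
  resp[1L, 2:5] <- hillResponse(curveB, board@drugBDoses)
  resp[2:5, 2:5] <- board@response
  new("DoseSurface", drugADoses = da, drugBDoses = db, response = resp)
}

#' Loewe synergy score of a dose-response surface
#'
#' Computes, for each of the 16 nonzero-dose wells, the deviation
#' `loeweReference - observed` (positive deviations mean more growth
#' inhibition than additivity predicts, i.e. synergy) and aggregates over
#' wells. The default aggregation is the sum of deviations in
#' %-of-control points; `"mean"` divides by 16. Replicates must have been
#' averaged before the surface was assembled.
#'
#' @param surface a [DoseSurface-class].
#' @param curveA,curveB the single-agent [HillCurve-class] objects used to
#'   build the Loewe reference.
#' @param aggregation `"sum"` (default) or `"mean"`.
#' @return A single synergy score; positive = synergistic.
#' @seealso [loeweReference()], [scoreSurfaces()]
#' @export
synergyScore <- function(surface, curveA, curveB,
                         aggregation = c("sum", "mean")) {
  stopifnot(is(surface, "DoseSurface"))
  aggregation <- match.arg(aggregation)
  dev <- matrix(NA_real_, 4L, 4L)
  for (i in 2:5) for (j in 2:5) {
    ref <- loeweReference(surface@drugADoses[i], surface@drugBDoses[j],
                          curveA, curveB)
    dev[i - 1L, j - 1L] <- ref - surface@response[i, j]
  }
  if (aggregation == "sum") sum(dev) else mean(dev)
}

#' Build replicate-averaged checkerboards from a long table
#'
#' @param tab data.frame with columns `drug_a`, `drug_b`, `cell_line`,
#'   `dose_a_uM`, `dose_b_uM`, `response_pct`, `replicate`.
#' @return Named list of [Checkerboard-class] objects, one per
#'   (drug_a, drug_b, cell_line), names `"A|B|cell"`.
#' @export
checkerboardsFromTable <- function(tab) {
  need <- c("drug_a", "drug_b", "cell_line", "dose_a_uM", "dose_b_uM",
            "response_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("synscreen_invalid_input", "checkerboard table lacks columns: %s",
          paste(miss, collapse = ", "))
  key <- paste(tab$drug_a, tab$drug_b, tab$cell_line, sep = "|")
  out <- lapply(split(tab, key), function(g) {
    da <- sort(unique(g$dose_a_uM)); db <- sort(unique(g$dose_b_uM))
    if (length(da) != 4L || length(db) != 4L)
      stopf("synscreen_invalid_input",
            "checkerboard for %s|%s|%s is not 4x4",
            g$drug_a[1], g$drug_b[1], g$cell_line[1])
    nrep <- max(table(paste(g$dose_a_uM, g$dose_b_uM)))
    m <- with(g, tapply(response_pct,
                        list(factor(dose_a_uM, levels = da),
                             factor(dose_b_uM, levels = db)),
                        mean))
    if (any(is.na(m)))
      stopf("synscreen_invalid_input",
            "missing wells in checkerboard %s|%s|%s",
            g$drug_a[1], g$drug_b[1], g$cell_line[1])
    Checkerboard(da, db, unclass(m), replicateCount = nrep)
  })
  out
}

#' Score every checkerboard in a screen against its Loewe reference
#'
#' End-to-end scoring pipeline: Hill curves are fitted to the single-agent
#' table per (drug, cell line), every checkerboard is replicate-averaged,
#' assembled into a 5x5 surface and scored. The result is the quartet
#' table consumed by the learning modules.
#'
#' @param singleAgent data.frame with columns `drug`, `cell_line`,
#'   `dose_uM`, `response_pct`, `replicate`.
#' @param checkerboards data.frame in the long checkerboard layout (see
#'   [checkerboardsFromTable()]).
#' @param aggregation passed to [synergyScore()].
#' @param verbose log one line per fitted curve (residuals) to stderr.
#' @return data.frame with columns `drug_a`, `drug_b`, `cell_line`,
#'   `synergy`.
#' @export
scoreSurfaces <- function(singleAgent, checkerboards,
                          aggregation = c("sum", "mean"), verbose = FALSE) {
  aggregation <- match.arg(aggregation)
  if (nrow(checkerboards) == 0L) {
    warnf("synscreen_empty_input", "no checkerboards to score")
    return(data.frame(drug_a = character(), drug_b = character(),
                      cell_line = character(), synergy = numeric()))
  }
  ## fit curves only for (drug, cell) pairs the checkerboards touch
  neededA <- unique(checkerboards[, c("drug_a", "cell_line")])
  neededB <- unique(checkerboards[, c("drug_b", "cell_line")])
  names(neededA) <- names(neededB) <- c("drug", "cell_line")
  needed <- unique(rbind(neededA, neededB))

  curves <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(needed))) {
    dr <- needed$drug[i]; cl <- needed$cell_line[i]
    sa <- singleAgent[singleAgent$drug == dr &
                        singleAgent$cell_line == cl, , drop = FALSE]
    if (nrow(sa) == 0L)
      stopf("synscreen_missing_single_agent",
            "no single-agent data for drug '%s' on cell line '%s'", dr, cl)
    avg <- tapply(sa$response_pct, sa$dose_uM, mean)
    cv <- withCallingHandlers(
      fitHill(as.numeric(names(avg)), as.numeric(avg)),
      synscreen_degenerate_fit = function(w) invokeRestart("muffleWarning"))
    if (verbose)
      message(sprintf("fit %s @ %s: ec50=%.3g h=%.3g RSS=%.3g%s",
                      dr, cl, cv@ec50, cv@h, cv@residual,
                      if (cv@degenerate) " [flat]" else ""))
    assign(paste(dr, cl, sep = "|"), cv, envir = curves)
  }

  boards <- checkerboardsFromTable(checkerboards)
  keys <- strsplit(names(boards), "|", fixed = TRUE)
  res <- data.frame(
    drug_a = vapply(keys, `[`, "", 1L),
    drug_b = vapply(keys, `[`, "", 2L),
    cell_line = vapply(keys, `[`, "", 3L),
    synergy = NA_real_)
  for (i in seq_along(boards)) {
    ca <- get(paste(res$drug_a[i], res$cell_line[i], sep = "|"),
              envir = curves)
    cb <- get(paste(res$drug_b[i], res$cell_line[i], sep = "|"),
              envir = curves)
    surf <- assembleSurface(boards[[i]], ca, cb)
    res$synergy[i] <- suppressWarnings(
      synergyScore(surf, ca, cb, aggregation))
  }
  rownames(res) <- NULL
  res
}
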