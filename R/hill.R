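#' Evaluate a Hill curve at given doses
#'
#' Computes `E(c) = einf + (e0 - einf) * ec50^h / (ec50^h + c^h)`, the
#' four-parameter log-logistic response in percent of control. `E(0) = e0`
#' exactly and `E(c) -> einf` as `c -> Inf`; the curve is monotone in
#' between.
#'
#' @param curve a [HillCurve-class].
#' @param dose numeric vector of concentrations in µM, all `>= 0`.
#' @return Numeric vector of responses (% of control).
#' @examples
#' hillResponse(HillCurve(100, 0, ec50 = 1, h = 1), c(0, 1, 1e6))
#' @export
hillResponse <- function(curve, dose) {
  stopifnot(is(curve, "HillCurve"))
  if (any(!is.finite(dose) & !is.infinite(dose)) || any(dose < 0))
    stopf("synscreen_invalid_input", "doses must be nonnegative")
  kh <- curve@ec50^curve@h
  r <- curve@einf + (curve@e0 - curve@einf) * kh / (kh + dose^curve@h)
  r[dose == 0] <- curve@e0       # exact, avoids 0^h edge cases for h < 1
  r[is.infinite(dose)] <- curve@einf
  r
}

#' Invert a Hill curve: dose that produces a given response
#'
#' Solves `E(c) = effect` for `c`. Defined only for effects strictly
#' inside the curve's attainable open range `(min(e0, einf), max(e0, einf))`.
#'
#' @param curve a [HillCurve-class].
#' @param effect response level (% of control).
#' @return Dose in µM (`Inf`/0 outside the attainable range is not
#'   returned; out-of-range effects give `NA`).
#' @keywords internal
hillInverse <- function(curve, effect) {
  lo <- min(curve@e0, curve@einf); hi <- max(curve@e0, curve@einf)
  out <- rep(NA_real_, length(effect))
  ok <- effect > lo & effect < hi
  ## c = ec50 * ((e0 - E)/(E - einf))^(1/h); the ratio is positive for
  ## E strictly between e0 and einf in either monotone direction
  ratio <- (curve@e0 - effect[ok]) / (effect[ok] - curve@einf)
  out[ok] <- curve@ec50 * ratio^(1 / curve@h)
  out
}

#' Fit a four-parameter Hill curve to single-agent responses
#'
#' Replicates are averaged per dose, then the model
#' `E(c) = einf + (e0 - einf) * ec50^h / (ec50^h + c^h)` is fitted by
#' bounded Levenberg-Marquardt least squares. Initial values: `ec50` at
#' the geometric mean of the nonzero doses, `h = 1`, `e0`/`einf` from the
#' responses at the dose extremes. Bounds: `h` in `[0.1, 10]`, `ec50` in
#' `[min dose / 100, max dose * 100]`. On failure the fit is restarted
#' (3 starts with `ec50` shifted a decade each way); if all starts fail,
#' or the averaged responses are constant, a flat fallback curve with
#' `e0 = einf = mean(response)` is returned and a classed warning
#' (`"synscreen_degenerate_fit"`) is signalled.
#'
#' @param doses numeric vector of `>= 4` distinct nonnegative doses (µM).
#' @param responses numeric matrix of % of control with one row per
#'   replicate and one column per dose, or a vector when a single
#'   replicate was run.
#' @return A [HillCurve-class] with the residual sum of squares in its
#'   `residual` slot.
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' y <- hillResponse(HillCurve(100, 10, 1, 2), d)
#' fitHill(d, y)
#' @export
fitHill <- function(doses, responses) {
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1L)
  if (!all(is.finite(responses)))
    stopf("synscreen_invalid_input", "responses must be finite")
  if (length(doses) != ncol(responses))
    stopf("synscreen_invalid_input",
          "need one response column per dose (%d doses, %d columns)",
          length(doses), ncol(responses))
  if (any(doses < 0))
    stopf("synscreen_invalid_input", "doses must be nonnegative")
  ## replicate-average, then pool duplicate doses
  ybar <- colMeans(responses)
  agg <- tapply(ybar, doses, mean)
  d <- as.numeric(names(agg)); y <- as.numeric(agg)
  if (sum(d > 0) < 4L)
    stopf("synscreen_invalid_input",
          "at least 4 distinct nonzero doses required (got %d)", sum(d > 0))

  flatFallback <- function() {
    m <- mean(y)
    warnf("synscreen_degenerate_fit",
          "degenerate Hill fit; returning flat curve at %.4g", m)
    HillCurve(e0 = m, einf = m, ec50 = exp(mean(log(d[d > 0]))), h = 1,
              residual = sum((y - m)^2), degenerate = TRUE)
  }
  if (sd(y) < 1e-9) return(flatFallback())

  dnz <- d[d > 0]
  ec50_0 <- exp(mean(log(dnz)))
  e0_0 <- y[which.min(d)]
  einf_0 <- y[which.max(d)]
  lower <- c(e0 = -Inf, einf = -Inf, lec50 = log(min(dnz) / 100), h = 0.1)
  upper <- c(e0 = Inf, einf = Inf, lec50 = log(max(dnz) * 100), h = 10)

  best <- NULL
  for (mult in c(1, 0.1, 10)) {
    start <- list(e0 = e0_0, einf = einf_0,
                  lec50 = min(max(log(ec50_0 * mult), lower["lec50"]),
                              upper["lec50"]),
                  h = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ einf + (e0 - einf) * exp(lec50 * h) /
          (exp(lec50 * h) + d^h),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(coef = coef(fit), rss = rss)
      if (best$rss < 1e-12) break
    }
  }
  if (is.null(best)) return(flatFallback())
  cf <- best$coef
  HillCurve(e0 = cf[["e0"]], einf = cf[["einf"]], ec50 = exp(cf[["lec50"]]),
            h = cf[["h"]], residual = best$rss)
}
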