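#' Fit an input normaliser on training rows only
#'
#' Computes column-wise statistics for one of three strategies:
#' \describe{
#'   \item{`norm`}{standardise to zero mean, unit variance}
#'   \item{`norm_tanh`}{standardise, then hyperbolic tangent (outputs
#'     bounded in `(-1, 1)`)}
#'   \item{`norm_tanh_norm`}{standardise, tanh, then standardise again;
#'     the second-pass statistics are computed on the tanh-transformed
#'     training values}
#' }
#' All feature columns are treated uniformly. Zero-variance columns store
#' a standard deviation of 1 so the transform stays defined (fold splits
#' can reintroduce constant columns after variance filtering).
#'
#' @param train numeric training matrix (rows = samples); validation and
#'   test rows must not be included.
#' @param strategy one of `"norm"`, `"norm_tanh"`, `"norm_tanh_norm"`.
#' @return A [Normalizer-class].
#' @export
fitNormalizer <- function(train,
                          strategy = c("norm", "norm_tanh",
                                       "norm_tanh_norm")) {
  strategy <- match.arg(strategy)
  train <- as.matrix(train)
  if (nrow(train) == 0L)
    stopf("synscreen_invalid_input", "training matrix is empty")
  if (any(!is.finite(train))) {
    idx <- which(!is.finite(train), arr.ind = TRUE)[1, ]
    stopf("synscreen_invalid_input",
          "non-finite entry at row %d, column %d", idx[1], idx[2])
  }
  guard <- function(s) ifelse(is.na(s) | s <= 0, 1, s)
  m1 <- colMeans(train)
  s1 <- guard(apply(train, 2L, sd))
  m2 <- numeric(); s2 <- numeric()
  if (strategy == "norm_tanh_norm") {
    z <- tanh(sweep(sweep(train, 2L, m1), 2L, s1, "/"))
    m2 <- colMeans(z)
    s2 <- guard(apply(z, 2L, sd))
  }
  new("Normalizer", strategy = strategy, mean1 = m1, sd1 = s1,
      mean2 = m2, sd2 = s2)
}

#' Apply a fitted normaliser
#'
#' Deterministic column-wise transform using the stored training
#' statistics; never refits, so held-out rows are transformed with
#' train-fold statistics only.
#'
#' @param normalizer a fitted [Normalizer-class].
#' @param x numeric matrix with the same column count as at fitting.
#' @return Transformed matrix of the same shape.
#' @export
applyNormalizer <- function(normalizer, x) {
  stopifnot(is(normalizer, "Normalizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(normalizer@mean1))
    stopf("synscreen_invalid_input",
          "column mismatch: normaliser fitted on %d columns, got %d",
          length(normalizer@mean1), ncol(x))
  z <- sweep(sweep(x, 2L, normalizer@mean1), 2L, normalizer@sd1, "/")
  if (normalizer@strategy == "norm") return(z)
  z <- tanh(z)
  if (normalizer@strategy == "norm_tanh") return(z)
  sweep(sweep(z, 2L, normalizer@mean2), 2L, normalizer@sd2, "/")
}

#' Serialise / restore normaliser state
#'
#' `writeNormalizer()` stores the strategy and column statistics in a
#' flat key-value text file inside a saved-model directory;
#' `readNormalizer()` restores it.
#'
#' @param normalizer a [Normalizer-class].
#' @param path file path.
#' @return `readNormalizer()` returns the restored [Normalizer-class];
#'   `writeNormalizer()` returns `path` invisibly.
#' @export
writeNormalizer <- function(normalizer, path) {
  num <- function(v) paste(format(v, digits = 17), collapse = ",")
  lines <- c(paste0("strategy=", normalizer@strategy),
             paste0("mean1=", num(normalizer@mean1)),
             paste0("sd1=", num(normalizer@sd1)),
             paste0("mean2=", num(normalizer@mean2)),
             paste0("sd2=", num(normalizer@sd2)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNormalizer
#' @export
readNormalizer <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(p)
    paste(p[-1], collapse = "="), ""), vapply(kv, `[`, "", 1L))
  num <- function(s) if (!nzchar(s)) numeric() else
    as.numeric(strsplit(s, ",")[[1]])
  new("Normalizer", strategy = vals[["strategy"]],
      mean1 = num(vals[["mean1"]]), sd1 = num(vals[["sd1"]]),
      mean2 = num(vals[["mean2"]]), sd2 = num(vals[["sd2"]]))
}
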