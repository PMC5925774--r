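## Internal helpers shared across modules.

#' @importFrom stats median sd var cor quantile rnorm runif rpois rbinom
#' @importFrom utils read.csv write.csv head
NULL

## 32-bit FNV-1a string hash. Used to fold circular-fingerprint environment
## identifiers and to fingerprint run configurations; must be stable across
## platforms, hence implemented on doubles with 16-bit split multiplication
## (a 32-bit product overflows R's integers and loses bits in a double).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- mulmod32(h, 16777619)
  }
  h
}

## (a * b) mod 2^32 exactly, for 0 <= a, b < 2^32.
mulmod32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  ## (a_hi*2^16 + a_lo) * b = a_hi*b*2^16 + a_lo*b; reduce term-wise so no
  ## intermediate exceeds 2^53
  hi_part <- ((a_hi * b) %% 65536) * 65536
  (hi_part + a_lo * b) %% 4294967296
}

## XOR for nonnegative doubles < 2^32 (bitwXor is 32-bit signed).
bitwXor64 <- function(a, b) {
  r <- 0
  bit <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + bit
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

## Canonical unordered-pair key for drug pairs.
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "synscreen_error")))
}

warnf <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "synscreen_warning")))
}

## Deterministic child seed derived from a user seed and a stream label;
## kept below 2^31 - 1.
childSeed <- function(seed, label) {
  (as.numeric(seed) * 7919 + fnv1a32(label) %% 100003) %% 2147483647
}

## Read a delimited table, sniffing comma vs tab from the header line.
readDelimAuto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}
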