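# Shared fixtures, generated in code (no data files).

# canonical unordered-pair key (independent of the package internals)
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")

# a small quartet table with explicit scores
tinyQuartets <- function() {
  data.frame(
    drug_a = c("A", "A", "A", "B", "B", "C"),
    drug_b = c("B", "C", "D", "C", "D", "D"),
    cell_line = rep(c("c1", "c2"), 3),
    synergy = c(1, 3, 5, 7, 9, 11))
}

# random Hill curve within screen-plausible ranges
randomHill <- function() {
  HillCurve(e0 = rnorm(1, 100, 2), einf = runif(1, 0, 60),
            ec50 = 10^runif(1, -1.5, 1), h = runif(1, 0.5, 3))
}

# dense-scan Loewe oracle: locate the index-sum root on an E grid
loeweOracle <- function(doseA, doseB, ca, cb, step = 1e-4) {
  lo <- max(min(ca@e0, ca@einf), min(cb@e0, cb@einf))
  hi <- min(max(ca@e0, ca@einf), max(cb@e0, cb@einf))
  E <- seq(lo + step, hi - step, by = step)
  invA <- ca@ec50 * ((ca@e0 - E) / (E - ca@einf))^(1 / ca@h)
  invB <- cb@ec50 * ((cb@e0 - E) / (E - cb@einf))^(1 / cb@h)
  idx <- doseA / invA + doseB / invB - 1
  E[which.min(abs(idx))]
}

# additive 4x4 checkerboard equal to the Loewe reference of two curves
additiveBoard <- function(ca, cb, doses = c(0.1, 0.5, 2, 5)) {
  ref <- outer(seq_along(doses), seq_along(doses),
               Vectorize(function(a, b)
                 loeweReference(doses[a], doses[b], ca, cb)))
  Checkerboard(doses, doses, ref)
}

# reduced synthetic world shared across learner tests
tinyWorld <- function(seed = 7) {
  design <- generateDesign(5L, 3L, 6L)
  generateWorld(design, seed = seed)
}

worldFeatures <- function(world) {
  list(drug = featureValues(world$drugFeatures),
       cell = featureValues(world$cellFeatures))
}
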