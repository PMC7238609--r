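# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the package's implementations.

# concordance by exhaustive enumeration of positive-negative pairs
concordanceEnum <- function(predicted, y) {
  pos <- predicted[y == 1]
  neg <- predicted[y == 0]
  wins <- ties <- 0
  for (a in pos) for (b in neg) {
    if (a > b) wins <- wins + 1
    else if (a == b) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Jaccard by explicit element counting
jaccardEnum <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  both <- 0
  for (el in s1) if (el %in% s2) both <- both + 1
  both / (length(s1) + length(s2) - both)
}

# brute-force criterion argmax over a path, first maximum = largest lambda
aicArgmaxEnum <- function(path) {
  vals <- vapply(path@fits, function(f) 2 * (f@loglik - f@nullLoglik) - 2 * f@k,
                 numeric(1))
  best <- 1L
  for (j in seq_along(vals)) if (vals[j] > vals[best]) best <- j
  best
}

# small signal dataset used by several fitting tests
signalDataset <- function(n = 120, p = 60, nSignal = 5, effectSize = 1,
                          seed = 42) {
  simulateDataset(SimulationConfig(n = n, p = p, nSignal = nSignal,
                                   effectSize = effectSize, seed = seed))
}
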