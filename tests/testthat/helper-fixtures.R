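# Small fixtures shared across test files; everything is generated in code.

makeTs <- function(data, compartment = "GM", tr = 3,
                   labels = sprintf("%s_%02d", compartment, seq_len(ncol(data)))) {
  RoiTimeSeriesSet(data, roiLabels = labels, compartment = compartment,
                   trSeconds = tr)
}

# A tiny effect-free cohort for smoke tests.
smallNullCohort <- function(nPerGroup = 5, nWm = 4, nGm = 6, nT = 80,
                            seed = 11) {
  generateCohort(CohortSpec(nPerGroup = nPerGroup, nWm = nWm, nGm = nGm,
                            nTimepoints = nT, seed = seed))
}

# Brute-force Pearson r via the textbook sum formula (independent of cor()).
pearsonByHand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
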