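## Shared fixtures: tiny configurations and datasets kept small enough for
## fast unit tests; built in code, never stored.

tinyConfig <- function(seed = 11L, ...) {
  modelConfig(L = 10L, embedDim = 6L, lstmUnits = 4L,
              cnnScales = c(3L, 5L), cnnFilters = 4L,
              denseSizes = c(8L, 4L, 1L), dropoutRate = 0,
              batchSize = 16L, epochs = 3L, seed = seed, ...)
}

## tiny fully-penetrant motif dataset encodable at L = 10
tinyMotifRecords <- function(n = 40L, seed = 3L) {
  generatePeptides(synthSpec(nPos = n %/% 2L, nNeg = n - n %/% 2L,
                             lengthRange = c(6L, 10L), motif = "CWK",
                             penetrance = 1, contamination = 0, seed = seed))
}

writeTempFasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}

## literal, loop-based evaluation of the attention equations: the oracle
## kept independent of the vectorised implementation under test
attentionOracle <- function(h, scoreFn) {
  T <- nrow(h)
  e <- numeric(T)
  for (t in seq_len(T)) e[t] <- scoreFn(h[t, ])
  denom <- 0
  for (k in seq_len(T)) denom <- denom + exp(e[k])
  alpha <- numeric(T)
  for (t in seq_len(T)) alpha[t] <- exp(e[t]) / denom
  ctx <- numeric(ncol(h))
  for (t in seq_len(T)) ctx <- ctx + alpha[t] * h[t, ]
  list(scores = e, weights = alpha, context = ctx)
}
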