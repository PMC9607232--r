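## shared test utilities: independent brute-force oracles and tiny fixtures

## naive sliding-dot-product correlation (double loop)
naiveCorrelate <- function(signal, kernel) {
  NS <- length(signal)
  NK <- length(kernel)
  out <- numeric(NS - NK + 1L)
  for (t in seq_along(out)) {
    acc <- 0
    for (j in seq_len(NK)) acc <- acc + signal[t + j - 1L] * kernel[j]
    out[t] <- acc
  }
  out
}

## naive peak normalized cross-correlation over all overlaps
naiveNcc <- function(a, b, minOverlap = 0.5) {
  la <- length(a)
  lb <- length(b)
  minLen <- max(1L, ceiling(minOverlap * min(la, lb)))
  best <- -1
  for (lag in -(lb - 1L):(la - 1L)) {
    ia <- max(1L, 1L + lag):min(la, lb + lag)
    if (length(ia) < minLen) next
    ib <- ia - lag
    den <- sqrt(sum(a[ia]^2) * sum(b[ib]^2))
    if (den == 0) next
    best <- max(best, abs(sum(a[ia] * b[ib]) / den))
  }
  best
}

## brute-force confusion tally
naiveConfusion <- function(pred, truth, NC) {
  M <- matrix(0L, NC, NC)
  for (i in seq_along(pred)) {
    M[truth[i], pred[i]] <- M[truth[i], pred[i]] + 1L
  }
  M
}

## small synthetic dataset reused by several training tests
smallDataset <- function(N = 2, NT = 400, P = 0.25, seed = 42) {
  buildDataset(SyntheticDatasetSpec(N = N, NT = NT, P = P, seed = seed))
}
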