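# Independent oracles, kept deliberately naive.

# Exhaustive without-replacement oracle: enumerate every N-subset of the F
# fragment designs (soluble designs are indices 1..f) and count those
# containing at least one soluble design. Feasible for F <= 12.
enum_P_N <- function(f, F, N) {
  subsets <- utils::combn(F, N)
  mean(apply(subsets, 2, function(s) any(s <= f)))
}

# Naive integer scan of the normalized yield, written from the defining
# formula rather than through the package's curve machinery.
naive_N_optimum <- function(q, r, N_max) {
  N <- seq_len(N_max)
  e <- (1 - (1 - q)^N) / (N + r)
  which.max(e)
}

expect_within_3se <- function(estimate, truth, n) {
  se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(estimate - truth), 3 * se + 1e-12)
}
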