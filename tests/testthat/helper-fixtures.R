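# Shared fixtures and independent oracles for the test suite.

# 31-repeat receptor with a loopout pseudo-unit between repeats 27 and 28,
# mirroring the packaged demo architecture.
demo_protein <- function() {
  repeat_protein("LeEIX2-demo", 31, loopout = list(after_repeat = 27))
}

# tiny protein with synthetic sequences for assembly/FASTA tests
toy_protein <- function(loopout = FALSE) {
  repeat_protein(
    "toy", 4,
    repeat_seqs = c("LRAL", "LKAL", "LNAL", "LQAL"),
    ncap_seq = "MNCAP",
    ccap_seq = "CCAPW",
    loopout = if (loopout) list(after_repeat = 2, seq = "GGSGG") else NULL
  )
}

# brute-force oracle: enumerate all L - n + 1 windows and count membership
oracle_inclusion_fractions <- function(L, n) {
  starts <- seq_len(L - n + 1)
  vapply(seq_len(L), function(i) {
    mean(vapply(starts, function(s) i >= s && i <= s + n - 1, logical(1)))
  }, numeric(1))
}

oracle_entropy <- function(L, n) {
  p <- oracle_inclusion_fractions(L, n)
  -sum(ifelse(p == 1, 0, p * log2(p)))
}

# ground truth matching the packaged demo
demo_truth <- function(...) {
  ground_truth(paratopes = data.frame(start = c(6, 22), end = c(10, 26)), ...)
}

# Jaccard index of two inclusive integer intervals
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}
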