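# Independent brute-force oracles the implementation is checked against.
# These deliberately use naive character loops / direct arithmetic and share
# no code with the package internals.

# AU fraction by explicit character loop (N stays in the denominator).
oracle_au_fraction <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  hits <- 0L
  for (ch in chars) if (ch == "A" || ch == "T") hits <- hits + 1L
  hits / length(chars)
}

# APS call by direct restatement of the rule: > threshold% AU in the first
# 100 bases, >= 300 nt length.
oracle_aps_positive <- function(utr3_seq, proximal_len = 100,
                                threshold = 50, min_len = 300) {
  n <- nchar(utr3_seq)
  head <- substr(utr3_seq, 1, min(proximal_len, n))
  au_pct <- 100 * oracle_au_fraction(head)
  (n >= min_len) && (au_pct > threshold)
}

# A random ACGT sequence of length n under the current RNG state.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Deterministic GC-only filler (0% AU), for building sequences whose AU
# statistics are fixed by construction.
random_seq_gc <- function(n) strrep("GC", ceiling(n / 2)) |> substr(1, n)
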