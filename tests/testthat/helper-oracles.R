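# Independent oracles and fixture builders shared across the suite.

# Semi-global edit distance (pattern global, text local), plain dynamic
# programming with unit costs. Row-wise vectorized; the insertion term is the
# min-plus prefix scan D[i,j] = j + cummin(D'[i,k] - k). Independent of the
# package's alignment engine.
oracle_semiglobal_dist <- function(pattern, text) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  m <- length(pc)
  n <- length(tc)
  prev <- rep(0, n + 1L)                      # row 0: free start in text
  for (i in seq_len(m)) {
    sub <- prev[seq_len(n)] + (pc[i] != tc)   # diagonal
    del <- prev[-1L] + 1                      # gap in text (pattern char dropped)
    vals <- c(i, pmin(sub, del)) - 0:n
    prev <- cummin(vals) + 0:n                # gap in pattern via prefix scan
  }
  min(prev)                                   # free end in text
}

# Two-sided Fisher p by direct enumeration over the margin-fixed table family,
# probabilities from binomial coefficients (no dhyper).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p0 <- pr[ks == a]
  min(sum(pr[pr <= p0 * (1 + 1e-7)]), 1)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Mutate a sequence with substitutions and optional indels (for stressing the
# caller against the DP oracle).
mutate_seq <- function(seq, n_sub = 0L, n_ins = 0L, n_del = 0L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0L) {
    pos <- sample(seq_along(chars), min(n_sub, length(chars)))
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  if (n_del > 0L && length(chars) > n_del) {
    chars <- chars[-sample(seq_along(chars), n_del)]
  }
  if (n_ins > 0L) {
    for (k in seq_len(n_ins)) {
      p <- sample(0:length(chars), 1L)
      chars <- append(chars, sample(bases, 1L), after = p)
    }
  }
  paste(chars, collapse = "")
}

# Small explicit design used where the full Kras window would be overkill:
# GTT (valine, 4 wobble options) + ATT (isoleucine, 3) + fixed TGG.
toy_design <- function() {
  barcode_design(
    window = codon_window("GTTATTTGG", first_codon_index = 1L),
    fixed = list(),
    variable_codons = c(1L, 2L),
    wobble_only = TRUE
  )
}
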