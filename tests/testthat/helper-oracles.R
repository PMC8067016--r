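# Independent oracles used across the suite. Each stays independent of
# the implementation path it checks.

# full (unbanded) affine dynamic-programming score, read global /
# reference local, via Biostrings; gap of length L costs 3 + 2L = the
# package convention 5 + 2*(L-1)
full_dp_score <- function(read, ref) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    read, ref, type = "global-local", substitutionMatrix = submat,
    gapOpening = 3, gapExtension = 2))
}

# exact two-sided rank-sum p by full enumeration of all C(nA+nB, nA)
# group assignments (Mann-Whitney U of the first sample)
perm_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  us <- apply(combos, 2, function(idx) {
    sum(r[idx]) - length(a) * (length(a) + 1) / 2
  })
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# random DNA / mutated copy helpers for alignment fixtures
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_read <- function(read, nmut) {
  ch <- strsplit(read, "")[[1]]
  idx <- sample(length(ch), nmut)
  ch[idx] <- vapply(ch[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

fixture_matrix <- function(name) {
  fx <- make_fixture(name)
  list(fx = fx,
       m = build_presence_matrix(fx$annotations,
                                 genome_ids = fx$metadata$genome_id))
}
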