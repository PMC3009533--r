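# Shared fixtures built in code; no binary or on-disk data.

# tiny FASTA writer for parser tests (deliberately independent of
# write_fasta so read/write tests are not circular)
write_fasta_lines <- function(lines, dir = withr_tempdir()) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

# a small, clearly separable 1-D training set: x < 0 -> c2, x >= 0 -> c1
separable_1d <- function(n_per_class = 10L) {
  X <- matrix(c(seq(1, 2, length.out = n_per_class),
                seq(-2, -1, length.out = n_per_class)), ncol = 1,
              dimnames = list(NULL, "x"))
  list(X = X, y = rep(c("c1", "c2"), each = n_per_class))
}

# small synthetic benchmark for fast PU tests
small_benchmark <- function(seed = 42L, gap = 0.15, n_pos = 60L,
                            n_unl = 200L) {
  generate_benchmark(benchmark_defaults(separation_gap = gap, seed = seed,
                                        n_pos = n_pos, n_unlabeled = n_unl))
}

# random valid sequences including ambiguity codes
random_seqs <- function(n, len_range = c(5L, 60L), p_ambig = 0.05,
                        seed = 1L) {
  set.seed(seed)
  alphabet <- c(amino_acids(), c("B", "Z", "X", "U", "O"))
  probs <- c(rep((1 - p_ambig) / 20, 20), rep(p_ambig / 5, 5))
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(alphabet, L, replace = TRUE, prob = probs), collapse = "")
  }, "")
  seq_records(sprintf("rs%04d", seq_len(n)), seqs)
}
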