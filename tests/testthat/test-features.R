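test_that("net_charge follows the default charge map", {
  expect_equal(net_charge("KRKR"), 4)
  expect_equal(net_charge("DEDE"), -4)
  expect_equal(net_charge("GGGG"), 0)
  expect_equal(net_charge("KXDH"), 0)  # H neutral, X unmapped
  # custom map: residues absent contribute 0
  expect_equal(net_charge("KRH", charge_map = c(H = 0.5)), 0.5)
})

test_that("scale_sum sums standard residues and skips ambiguity codes", {
  expect_equal(scale_sum("XXX", kyte_doolittle()), 0)
  # A = 1.42 on the helix scale
  expect_equal(scale_sum("AA", chou_fasman_helix()), 2.84)
  zeros <- propensity_scale(setNames(numeric(20), amino_acids()), "zeros")
  expect_equal(scale_sum("MKWYRDE", zeros), 0)
  expect_equal(scale_sum("AXA", chou_fasman_helix()), 2.84)
})

test_that("aa_composition normalizes over effective length", {
  comp <- aa_composition("AAAA")
  expect_equal(unname(comp["A"]), 1.0)
  expect_equal(sum(comp), 1.0)
  comp <- aa_composition("ACAC")
  expect_equal(unname(comp[c("A", "C")]), c(0.5, 0.5))
  # ambiguity codes excluded from both count and denominator
  comp <- aa_composition("AX")
  expect_equal(unname(comp["A"]), 1.0)
  # raw counts
  expect_equal(unname(aa_composition("ACAC", normalize = FALSE)[c("A", "C")]),
               c(2, 2))
})

test_that("local-environment encoder has 80 slots and classifies a homopolymer", {
  # poly-A: window means are exactly A's scale values (1.42 helix, 0.83
  # sheet) at every position including truncated ends, so every residue is
  # high-helix/low-sheet
  env <- local_env_composition("AAAAAAA")
  expect_length(env, 80L)
  expect_equal(unname(env["env_A_hiH_loS"]), 1.0)
  expect_equal(sum(env), 1.0)
  expect_true(all(env[names(env) != "env_A_hiH_loS"] == 0))

  # poly-V (helix 1.06, sheet 1.70): high-helix/high-sheet
  env <- local_env_composition("VVVV")
  expect_equal(unname(env["env_V_hiH_hiS"]), 1.0)

  # poly-G (0.57, 0.75): low/low
  env <- local_env_composition("GGGGG")
  expect_equal(unname(env["env_G_loH_loS"]), 1.0)
})

test_that("window means honor truncation and ambiguity exclusion", {
  # E (helix 1.51, sheet 0.37) then G's: at position 1 the window covers
  # positions 1..4 -> mean helix (1.51 + 3*0.57)/4 = 0.805 < 1 -> loH;
  # oracle computed by hand from the declared scale values
  env <- local_env_composition("EGGGGGGG", feature_config())
  expect_equal(unname(env["env_E_loH_loS"]), 1 / 8)
  # with window 1 the environment is the residue itself: E is hiH_loS
  env1 <- local_env_composition("EGGGGGGG", feature_config(env_window = 1L))
  expect_equal(unname(env1["env_E_hiH_loS"]), 1 / 8)
  # ambiguity codes drop out of the mean: X neighbors leave E alone in its
  # window, same as window 1
  envx <- local_env_composition("XXEXX", feature_config())
  expect_equal(unname(envx["env_E_hiH_loS"]), 1.0)
})

test_that("conservation law: environment marginals equal composition", {
  recs <- random_seqs(60, seed = 21)
  cfg <- feature_config()
  for (i in seq_len(nrow(recs))) {
    fv <- featurize(recs$seq[i], cfg)
    marg <- tapply(fv$local_env,
                   rep(amino_acids(), each = 4L), sum)[amino_acids()]
    expect_equal(as.numeric(marg), as.numeric(fv$composition),
                 tolerance = 1e-12)
  }
})

test_that("composition and charge are permutation-invariant; local_env is not", {
  # same multiset, different arrangement: E in the blocked string sits in
  # an all-E window (sheet mean 0.37, low), while in the alternating
  # string its windows mix in V (sheet 1.70), pushing the sheet mean over
  # the 1.0 threshold
  a <- "EEEEEVVVVV"
  b <- "EVEVEVEVEV"
  # same multiset of residues
  expect_equal(sort(strsplit(a, "")[[1]]), sort(strsplit(b, "")[[1]]))
  fa <- featurize(a)
  fb <- featurize(b)
  expect_equal(fa$charge, fb$charge)
  expect_equal(fa$composition, fb$composition)
  expect_equal(fa$hydro_sum, fb$hydro_sum)
  expect_false(isTRUE(all.equal(fa$local_env, fb$local_env)))
})

test_that("featurize layout is fixed and degenerate input yields no NaN", {
  fv <- featurize("KRKR")
  expect_length(fv$vector, 104L)
  expect_identical(names(fv$vector), feature_names())
  expect_equal(unname(fv$vector["charge"]), 4)
  expect_identical(featurize("KRKR")$vector, fv$vector)

  fx <- featurize("XXXX")
  expect_equal(fx$effective_length, 0L)
  expect_false(any(is.nan(fx$vector)))
  expect_true(all(fx$vector == 0))
})

test_that("featurize_matrix agrees with featurize and round-trips as TSV", {
  recs <- random_seqs(8, seed = 33)
  X <- featurize_matrix(recs)
  expect_equal(dim(X), c(8L, 104L))
  expect_identical(rownames(X), recs$id)
  for (i in c(1L, 5L)) {
    expect_equal(unname(X[i, ]), unname(featurize(recs$seq[i])$vector))
  }
  path <- tempfile(fileext = ".tsv")
  write_features(X, path)
  X2 <- read_features(path)
  expect_equal(X2, X, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(rownames(X2), rownames(X))
})

test_that("feature_config validates its inputs", {
  expect_error(feature_config(env_window = 4L), "odd")
  expect_error(feature_config(env_window = 0L), "odd")
  expect_error(propensity_scale(c(A = 1)), "missing residues")
})
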