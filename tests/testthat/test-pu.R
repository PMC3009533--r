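test_that("select_spies draws the rounded count, seeded", {
  P <- sprintf("p%03d", 1:200)
  sp <- select_spies(P, 0.15, seed = 3)
  expect_length(sp$S, 30L)
  expect_setequal(c(sp$S, sp$P_rest), P)
  expect_length(intersect(sp$S, sp$P_rest), 0L)

  expect_length(select_spies(sprintf("p%d", 1:4), 0.5, seed = 1)$S, 2L)
  # round-half-away-from-zero: 0.15 * 230 = 34.5 -> 35
  expect_length(select_spies(sprintf("p%d", 1:230), 0.15, seed = 1)$S, 35L)
  # explicit override reproduces a fixed historical configuration
  expect_length(select_spies(sprintf("p%d", 1:232), 0.15, seed = 1,
                             n_spies = 30)$S, 30L)

  expect_identical(select_spies(P, 0.15, seed = 7)$S,
                   select_spies(P, 0.15, seed = 7)$S)
  expect_error(select_spies(c("a", "b"), 0.1, seed = 1),
               "spy fraction degenerate")
})

test_that("spy_threshold is the minimum spy posterior", {
  expect_equal(spy_threshold(c(0.62, 0.81, 0.55)), 0.55)
  expect_equal(spy_threshold(0.9), 0.9)
  expect_error(spy_threshold(numeric(0)), "no spy")
  # strictness: with t = 0.55, only strictly-below examples drop
  t <- spy_threshold(c(0.62, 0.81, 0.55))
  u <- c(0.10, 0.55, 0.70)
  expect_equal(sum(u < t), 1L)
})

test_that("spy_threshold equals the brute-force largest-valid-threshold", {
  set.seed(101)
  for (i in 1:50) {
    probs <- runif(sample(1:20, 1))
    # oracle: largest candidate t with every spy >= t
    cand <- probs[vapply(probs, function(t) all(probs >= t), TRUE)]
    expect_equal(spy_threshold(probs), max(cand))
  }
})

test_that("a duplicate-only unlabeled pool yields the documented error", {
  P <- random_seqs(20, len_range = c(30L, 60L), p_ambig = 0, seed = 8)
  U <- seq_records(paste0("u_", P$id), P$seq)
  X_p <- featurize_matrix(P)
  X_u <- featurize_matrix(U)
  cfg <- spy_config(seed = 4, n_redraws = 3L)
  expect_error(extract_rn_spy(X_p, X_u, cfg), "no reliable negatives")
})

test_that("spy extraction separates the synthetic benchmark", {
  d <- small_benchmark()
  X_p <- featurize_matrix(d$P)
  X_u <- featurize_matrix(d$U)
  state <- extract_rn_spy(X_p, X_u, spy_config(seed = 2))
  # conservation + monotonicity
  expect_setequal(c(state$RN, state$Q), d$U$id)
  expect_length(intersect(state$RN, state$Q), 0L)
  h <- state$history
  expect_true(all(diff(h$n_rn) >= 0))
  expect_true(all(diff(h$n_q) <= 0))
  expect_true(all(h$n_rn + h$n_q == nrow(d$U)))
  # most true negatives extracted, hidden positives untouched
  tn <- names(d$truth)[d$truth == "negative"]
  hid <- names(d$truth)[d$truth == "positive"]
  expect_gt(mean(tn %in% state$RN), 0.9)
  expect_gt(mean(hid %in% state$Q), 0.9)
  # no spy ever enters RN
  expect_length(intersect(unlist(state$spies), state$RN), 0L)
})

test_that("expand_rn moves obvious negatives and conserves the pool", {
  d <- small_benchmark(seed = 13)
  X_p <- featurize_matrix(d$P)
  X_u <- featurize_matrix(d$U)
  state <- extract_rn_spy(X_p, X_u, spy_config(seed = 5))
  n_u <- nrow(d$U)
  # force three RN-identical examples back into Q: they must return to RN
  stopifnot(length(state$RN) > 3L)
  back <- state$RN[1:3]
  state$RN <- setdiff(state$RN, back)
  state$Q <- c(state$Q, back)
  out <- expand_rn(X_p, X_u, state, spy_config(seed = 5))
  expect_true(all(back %in% out$RN))
  expect_true(out$converged)
  h <- out$history
  expect_true(all(h$n_rn + h$n_q == n_u))
  # empty state errors
  empty <- out
  empty$RN <- character(0)
  expect_error(expand_rn(X_p, X_u, empty, spy_config()), "RN is empty")
})

test_that("run_pu is deterministic end to end and honors invariants", {
  d <- small_benchmark(seed = 3)
  ds <- pu_dataset(d$P, d$U, d$truth)
  m1 <- run_pu(ds, feature_config(), spy_config(seed = 9))
  m2 <- run_pu(ds, feature_config(), spy_config(seed = 9))
  expect_identical(m1$state$RN, m2$state$RN)
  expect_identical(predict(m1, d$P)$prob_positive,
                   predict(m2, d$P)$prob_positive)
  expect_setequal(c(m1$state$RN, m1$state$Q), d$U$id)
  expect_true(m1$converged)
  # training positives re-scored as positive on separable data
  pr <- predict(m1, d$P)
  expect_gt(mean(pr$label == "positive"), 0.95)
  expect_true(all(pr$prob_positive >= 0 & pr$prob_positive <= 1))
})

test_that("both variants run and converge on the same benchmark", {
  d <- small_benchmark(seed = 4)
  ds <- pu_dataset(d$P, d$U, d$truth)
  mo <- run_pu(ds, feature_config(), spy_config(seed = 2, variant = "original"))
  mm <- run_pu(ds, feature_config(), spy_config(seed = 2, variant = "modified"))
  expect_true(mo$converged)
  expect_true(mm$converged)
  # per-iteration thresholds recorded for the modified variant
  hm <- pu_history(mm)
  expect_true(all(hm$phase == "A"))
  expect_true(all(hm$n_spies > 0))
  tn <- names(d$truth)[d$truth == "negative"]
  expect_gt(mean(tn %in% mm$state$RN), 0.9)
})

test_that("predict flags zero-effective-length sequences", {
  d <- small_benchmark(seed = 6)
  m <- run_pu(pu_dataset(d$P, d$U), feature_config(), spy_config(seed = 1))
  pr <- predict(m, seq_records(c("ok", "weird"), c("KRKRKRDEDE", "XXXXX")))
  expect_false(pr$zero_length_flag[1])
  expect_true(pr$zero_length_flag[2])
  expect_true(all(pr$prob_positive >= 0 & pr$prob_positive <= 1))
})

test_that("model JSON round trip preserves predictions and membership", {
  d <- small_benchmark(seed = 10)
  m <- run_pu(pu_dataset(d$P, d$U), feature_config(), spy_config(seed = 3))
  path <- tempfile(fileext = ".json")
  save_pu_model(m, path)
  m2 <- load_pu_model(path)
  expect_identical(m2$state$RN, m$state$RN)
  expect_identical(m2$state$Q, m$state$Q)
  expect_equal(predict(m2, d$P), predict(m, d$P), tolerance = 1e-12)
  expect_equal(m2$feature_config$env_window, m$feature_config$env_window)
})

test_that("spy_config validates parameters", {
  expect_error(spy_config(s = 0), "s must be")
  expect_error(spy_config(s = 1), "s must be")
  expect_error(spy_config(max_iter = 0), "max_iter")
  expect_error(spy_config(n_redraws = -1), "n_redraws")
})
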