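# The PU-learning protocol.
#
# Phase A (spy technique): a random s-fraction of the positives is planted
# in the unlabeled pool with a negative label.  Because spies are genuine
# positives, the smallest spy posterior is the largest threshold at which
# every spy is still called positive; unlabeled examples strictly below it
# are reliable negatives (RN).  The loop re-trains on the shrinking pool
# until RN stops changing.
#
# Phase B: starting from the RN seed, train positives-vs-RN, move every
# undecided example classified negative (posterior < 0.5) into RN, repeat
# until no example moves.
#
# The modified variant draws a FRESH spy set each iteration and applies a
# per-iteration threshold; everything already in RN stays in the negative
# training side.
#
# The final classifier is trained on the full original positive set versus
# the converged RN set.

#' Spy / PU configuration
#'
#' @param s Spy fraction in (0, 1); default 0.15.
#' @param seed Integer seed; iteration i of the modified variant draws its
#'   spies with seed + i so runs are reproducible but draws distinct.
#' @param variant `"original"` (one spy draw, then expansion) or
#'   `"modified"` (fresh spies each iteration).
#' @param max_iter Iteration cap per phase; convergence is normally reached
#'   long before (the RN set is monotone and bounded).
#' @param n_spies Optional explicit spy count overriding `round(s * |P|)`;
#'   lets a specific historical configuration (e.g. 30 spies from 232
#'   positives) be reproduced exactly.
#' @param n_redraws Maximum number of fresh spy draws attempted when a draw
#'   yields an empty reliable-negative set (see Details).  Set to 0 to make
#'   an empty first pass an immediate error.
#' @param classifier [classifier_factory()] for the inner learner.
#'
#' @details
#' The min-over-spies threshold is sensitive to outlier spies: if the draw
#' happens to include a positive example lying inside the negative bulk,
#' the threshold collapses to the global minimum posterior and no unlabeled
#' example falls strictly below it.  Because spy selection is the
#' randomized element of the protocol, the implementation treats this as a
#' failed draw of a Las-Vegas procedure and redraws the spy set with the
#' next derived seed (draw r uses seed + r), still fully deterministic
#' given `seed`.  Only after `n_redraws` consecutive empty draws is the
#' documented "no reliable negatives" error raised — which is what happens,
#' for every draw, when the classes are genuinely inseparable.
#' @return A `spy_config`.
#' @export
spy_config <- function(s = 0.15, seed = 1L, variant = c("original", "modified"),
                       max_iter = 100L, n_spies = NULL, n_redraws = 10L,
                       classifier = classifier_factory()) {
  variant <- match.arg(variant)
  if (!is.numeric(s) || s <= 0 || s >= 1) stop("s must be in (0, 1)", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  n_redraws <- as.integer(n_redraws)
  if (is.na(n_redraws) || n_redraws < 0L) stop("n_redraws must be >= 0", call. = FALSE)
  stopifnot(inherits(classifier, "classifier_factory"))
  structure(list(s = s, seed = as.integer(seed), variant = variant,
                 max_iter = max_iter,
                 n_spies = if (!is.null(n_spies)) as.integer(n_spies),
                 n_redraws = n_redraws,
                 classifier = classifier),
            class = "spy_config")
}

#' Select spy examples from the positive set
#'
#' Draws `round(s * |P|)` ids (half-away-from-zero rounding, or the
#' explicit `n_spies` override) uniformly without replacement.
#'
#' @param P Character vector of positive ids.
#' @param s Spy fraction in (0, 1).
#' @param seed Integer seed.
#' @param n_spies Optional explicit count.
#' @return List with `S` (spy ids) and `P_rest` (the remaining ids).
#' @export
select_spies <- function(P, s, seed, n_spies = NULL) {
  n <- length(P)
  if (n < 2L) stop("need at least 2 positives to draw spies", call. = FALSE)
  k <- if (is.null(n_spies)) as.integer(.round_half_up(s * n)) else as.integer(n_spies)
  if (k < 1L || k >= n) {
    stop("spy fraction degenerate: ", k, " spies from ", n, " positives",
         call. = FALSE)
  }
  S <- .with_seed(seed, sample(P, k))
  list(S = S, P_rest = setdiff(P, S))
}

#' Spy-derived probability threshold
#'
#' The largest threshold t such that every spy is classified positive,
#' i.e. the minimum over the spies' Pr\[c1\].  Unlabeled examples with
#' Pr\[c1\] strictly below t become reliable negatives; ties at exactly t
#' stay undecided.
#'
#' @param spy_probs Numeric vector of spy posteriors (non-empty).
#' @return The threshold t.
#' @export
spy_threshold <- function(spy_probs) {
  if (!length(spy_probs)) stop("no spy probabilities", call. = FALSE)
  if (any(!is.finite(spy_probs))) stop("non-finite spy probability", call. = FALSE)
  min(spy_probs)
}

# internal: fresh history row
.hist_row <- function(phase, iteration, n_rn, n_q, threshold, n_spies) {
  data.frame(phase = phase, iteration = iteration, n_rn = n_rn, n_q = n_q,
             threshold = threshold, n_spies = n_spies,
             stringsAsFactors = FALSE)
}

.new_pu_state <- function(U_ids) {
  structure(list(RN = character(0), Q = U_ids, iteration = 0L,
                 history = .hist_row(character(0), integer(0), integer(0),
                                     integer(0), numeric(0), integer(0))[0, ],
                 spies = list(), converged = FALSE),
            class = "pu_state")
}

#' @export
print.pu_state <- function(x, ...) {
  cat("PU state: |RN| = ", length(x$RN), ", |Q| = ", length(x$Q),
      ", iterations = ", x$iteration,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Phase A: spy-based reliable-negative extraction (original variant)
#'
#' One spy draw; then repeatedly train (P \\ S as c1) against (remaining
#' unlabeled pool plus S as c2), score the pool, and move every example
#' with posterior strictly below the spy threshold into RN, until RN stops
#' changing or `max_iter` fires.  A draw whose first pass extracts nothing
#' is retried with a fresh seeded spy set, up to `cfg$n_redraws` times
#' (see [spy_config()] Details); the "no reliable negatives" error is
#' raised when every draw fails.
#'
#' @param X_p Feature matrix of the positive set (rownames = ids).
#' @param X_u Feature matrix of the unlabeled set (rownames = ids).
#' @param cfg A [spy_config()].
#' @return A `pu_state` with the RN/Q partition and per-iteration history;
#'   the number of discarded draws is recorded in `$redraws`.
#' @export
extract_rn_spy <- function(X_p, X_u, cfg = spy_config()) {
  P_ids <- rownames(X_p)
  fit <- cfg$classifier$train

  for (draw in 0:cfg$n_redraws) {
    spies <- select_spies(P_ids, cfg$s, cfg$seed + draw, cfg$n_spies)
    state <- .new_pu_state(rownames(X_u))
    state$redraws <- draw

    repeat {
      it <- state$iteration + 1L
      Xtr <- rbind(X_p[spies$P_rest, , drop = FALSE],
                   X_u[state$Q, , drop = FALSE],
                   X_p[spies$S, , drop = FALSE])
      ytr <- c(rep("c1", length(spies$P_rest)),
               rep("c2", length(state$Q) + length(spies$S)))
      clf <- fit(Xtr, ytr, seed = cfg$seed + it)
      p_spy <- predict_proba(clf, X_p[spies$S, , drop = FALSE])
      t <- spy_threshold(p_spy)
      p_q <- predict_proba(clf, X_u[state$Q, , drop = FALSE])
      move <- state$Q[p_q < t]

      state$RN <- c(state$RN, move)
      state$Q <- setdiff(state$Q, move)
      state$iteration <- it
      state$spies[[it]] <- spies$S
      state$history <- rbind(state$history,
                             .hist_row("A", it, length(state$RN),
                                       length(state$Q), t, length(spies$S)))

      if (it == 1L && !length(state$RN)) break  # failed draw, try a fresh one
      if (!length(move) || !length(state$Q)) { state$converged <- TRUE; break }
      if (it >= cfg$max_iter) {
        warning("extract_rn_spy: max_iter (", cfg$max_iter,
                ") reached before convergence")
        break
      }
    }
    if (length(state$RN)) {
      stopifnot(!any(unlist(state$spies) %in% state$RN))  # spy safety
      return(state)
    }
  }
  stop("no reliable negatives -- classes inseparable or spy fraction too small",
       call. = FALSE)
}

#' Phase B: iterative reliable-negative expansion
#'
#' Trains full-P-vs-RN, classifies the undecided set Q, and moves the
#' examples classified negative (posterior < 0.5) into RN, repeating until
#' no example moves or `max_iter` fires.
#'
#' @param X_p Feature matrix of the (full) positive set.
#' @param X_u Feature matrix of the unlabeled set.
#' @param state A `pu_state` with non-empty RN (from [extract_rn_spy()]).
#' @param cfg A [spy_config()].
#' @return The updated `pu_state`.
#' @export
expand_rn <- function(X_p, X_u, state, cfg = spy_config()) {
  stopifnot(inherits(state, "pu_state"))
  if (!length(state$RN)) stop("state$RN is empty", call. = FALSE)
  fit <- cfg$classifier$train
  P_ids <- rownames(X_p)
  it_b <- 0L

  repeat {
    it_b <- it_b + 1L
    if (!length(state$Q)) { state$converged <- TRUE; break }
    Xtr <- rbind(X_p, X_u[state$RN, , drop = FALSE])
    ytr <- c(rep("c1", length(P_ids)), rep("c2", length(state$RN)))
    clf <- fit(Xtr, ytr, seed = cfg$seed + state$iteration + it_b)
    p_q <- predict_proba(clf, X_u[state$Q, , drop = FALSE])
    W <- state$Q[p_q < 0.5]

    state$iteration <- state$iteration + 1L
    state$RN <- c(state$RN, W)
    state$Q <- setdiff(state$Q, W)
    state$history <- rbind(state$history,
                           .hist_row("B", it_b, length(state$RN),
                                     length(state$Q), 0.5, 0L))
    if (!length(W)) { state$converged <- TRUE; break }
    if (it_b >= cfg$max_iter) {
      warning("expand_rn: max_iter (", cfg$max_iter, ") reached before convergence")
      state$converged <- FALSE
      break
    }
  }
  state
}

# Modified spy variant: a fresh spy set each iteration; RN stays on the
# negative training side; per-iteration threshold.  An iteration that
# moves nothing while RN is still empty counts as a failed draw (the
# fresh-spies-per-iteration design makes the redraw implicit); once RN is
# non-empty, a no-move iteration is convergence.
.extract_rn_modified <- function(X_p, X_u, cfg) {
  P_ids <- rownames(X_p)
  state <- .new_pu_state(rownames(X_u))
  state$redraws <- 0L
  fit <- cfg$classifier$train

  repeat {
    it <- state$iteration + 1L
    spies <- select_spies(P_ids, cfg$s, cfg$seed + it, cfg$n_spies)
    Xtr <- rbind(X_p[spies$P_rest, , drop = FALSE],
                 X_u[c(state$RN, state$Q), , drop = FALSE],
                 X_p[spies$S, , drop = FALSE])
    ytr <- c(rep("c1", length(spies$P_rest)),
             rep("c2", length(state$RN) + length(state$Q) + length(spies$S)))
    clf <- fit(Xtr, ytr, seed = cfg$seed + it)
    t <- spy_threshold(predict_proba(clf, X_p[spies$S, , drop = FALSE]))
    p_q <- predict_proba(clf, X_u[state$Q, , drop = FALSE])
    move <- state$Q[p_q < t]

    state$RN <- c(state$RN, move)
    state$Q <- setdiff(state$Q, move)
    state$iteration <- it
    state$spies[[it]] <- spies$S
    state$history <- rbind(state$history,
                           .hist_row("A", it, length(state$RN),
                                     length(state$Q), t, length(spies$S)))

    if (!length(state$RN)) {
      state$redraws <- state$redraws + 1L
      if (state$redraws > cfg$n_redraws) {
        stop("no reliable negatives -- classes inseparable or spy fraction too small",
             call. = FALSE)
      }
    } else if (!length(move) || !length(state$Q)) {
      state$converged <- TRUE
      break
    }
    if (it >= cfg$max_iter + cfg$n_redraws) {
      warning("modified spy extraction: max_iter (", cfg$max_iter,
              ") reached before convergence")
      break
    }
  }
  stopifnot(!any(unlist(state$spies) %in% state$RN))
  state
}

#' Run the full PU-learning protocol
#'
#' Original variant: spy extraction ([extract_rn_spy()]) followed by RN
#' expansion ([expand_rn()]).  Modified variant: fresh spies each
#' iteration with per-iteration thresholds, run to convergence.  Either
#' way the final classifier is trained on the full original positive set
#' (spies included) versus the converged RN set.
#'
#' @param dataset A [pu_dataset()].
#' @param fcfg A [feature_config()].
#' @param cfg A [spy_config()].
#' @return A `pu_model`: list with `final_classifier`, `state`,
#'   `spy_config`, `feature_config`, `converged`.
#' @export
run_pu <- function(dataset, fcfg = feature_config(), cfg = spy_config()) {
  stopifnot(inherits(dataset, "pu_dataset"))
  X_p <- featurize_matrix(dataset$P, fcfg)
  X_u <- featurize_matrix(dataset$U, fcfg)

  state <- if (cfg$variant == "original") {
    expand_rn(X_p, X_u, extract_rn_spy(X_p, X_u, cfg), cfg)
  } else {
    .extract_rn_modified(X_p, X_u, cfg)
  }

  Xtr <- rbind(X_p, X_u[state$RN, , drop = FALSE])
  ytr <- c(rep("c1", nrow(X_p)), rep("c2", length(state$RN)))
  final <- cfg$classifier$train(Xtr, ytr, seed = cfg$seed)

  structure(list(final_classifier = final, state = state,
                 spy_config = cfg, feature_config = fcfg,
                 converged = state$converged),
            class = "pu_model")
}

#' @export
print.pu_model <- function(x, ...) {
  cat("PU model (", x$spy_config$variant, " spy variant)\n", sep = "")
  print(x$state)
  invisible(x)
}

#' Score sequences with a fitted PU model
#'
#' Features are computed with the model's embedded [feature_config()];
#' label is `"positive"` iff Pr\[c1\] >= 0.5.  Sequences with zero
#' effective length (no standard residues) are scored on the all-zero
#' vector and flagged.
#'
#' @param object A `pu_model`.
#' @param seqs Sequence records (or named character vector).
#' @param ... Unused.
#' @return Data frame with columns `id`, `prob_positive`, `label`,
#'   `zero_length_flag`.
#' @export
predict.pu_model <- function(object, seqs, ...) {
  records <- .as_records(seqs)
  X <- featurize_matrix(records, object$feature_config)
  eff <- attr(X, "effective_length")
  p <- predict_proba(object$final_classifier, X)
  data.frame(id = records$id,
             prob_positive = p,
             label = ifelse(p >= 0.5, "positive", "negative"),
             zero_length_flag = eff == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-iteration convergence history
#'
#' @param x A `pu_model` or `pu_state`.
#' @return Data frame with columns `phase`, `iteration`, `n_rn`, `n_q`,
#'   `threshold`, `n_spies` — the artifact for re-plotting RN/Q
#'   convergence curves.
#' @export
pu_history <- function(x) {
  if (inherits(x, "pu_model")) x <- x$state
  stopifnot(inherits(x, "pu_state"))
  x$history
}
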