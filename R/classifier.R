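# Inner binary classifier of the PU loop: a decision tree grown with the
# information-gain split criterion, pruned with the pessimistic
# (confidence-bound) rule, and reporting Laplace-smoothed class
# probabilities at the leaves.  Raw leaf frequencies would give near-0/1
# posteriors, which would make the min-over-spies threshold degenerate;
# Laplace smoothing is the standard fix for probability-estimation trees.
#
# Class labels are fixed as "c1" (positive) and "c2" (negative).

#' Decision-tree hyperparameters
#'
#' @param min_leaf Minimum number of training examples per leaf (default 2,
#'   the classic C4.5-style minimum branch size).
#' @param max_depth Maximum tree depth.
#' @param prune_cf Confidence level of the pessimistic-error pruning rule
#'   (default 0.25).  A subtree is collapsed when the upper-confidence-bound
#'   error estimate of the collapsed leaf does not exceed the summed
#'   estimates of its leaves; this is what stops the tree from fragmenting
#'   statistically inseparable regions, a property the spy threshold relies
#'   on.  Set to `NA` to disable pruning.
#' @param min_gain Smallest information gain (bits) accepted for a split.
#' @return A `tree_params` list.
#' @export
tree_params <- function(min_leaf = 2L, max_depth = 30L, prune_cf = 0.25,
                        min_gain = 1e-9) {
  stopifnot(min_leaf >= 1L, max_depth >= 1L)
  structure(list(min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 prune_cf = prune_cf, min_gain = min_gain),
            class = "tree_params")
}

# binary entropy in bits, vectorized over counts
.entropy2 <- function(a, b) {
  n <- a + b
  p <- ifelse(n > 0, a / n, 0)
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

# Clopper-Pearson upper confidence bound on the error rate of a leaf with
# e errors out of n, at confidence cf; multiplied by n this is the
# "predicted errors" quantity of pessimistic pruning.
.pessimistic_errors <- function(e, n, cf) {
  if (n == 0L) return(0)
  if (e >= n) return(n)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

# Recursive grow-then-prune.  y1 is logical (TRUE = class c1).  Returns a
# nested node list; each node carries the training class counts n1/n2 used
# later for Laplace probabilities.
.grow_node <- function(X, y1, idx, depth, params) {
  n1 <- sum(y1[idx])
  n2 <- length(idx) - n1
  n <- n1 + n2
  leaf <- list(n1 = n1, n2 = n2, feature = NA_integer_,
               threshold = NA_real_, left = NULL, right = NULL)
  if (n1 == 0L || n2 == 0L || n < 2L * params$min_leaf ||
      depth >= params$max_depth) {
    return(leaf)
  }

  parent_h <- .entropy2(n1, n2)
  best <- list(gain = params$min_gain, feature = NA_integer_,
               threshold = NA_real_)
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]
    cum1 <- cumsum(y1[idx][o])
    i <- seq_len(n - 1L)
    cut_ok <- xs[i] < xs[i + 1L] & i >= params$min_leaf &
      (n - i) >= params$min_leaf
    if (!any(cut_ok)) next
    i <- i[cut_ok]
    l1 <- cum1[i]
    l2 <- i - l1
    r1 <- n1 - l1
    r2 <- (n - i) - r1
    gain <- parent_h -
      (i * .entropy2(l1, l2) + (n - i) * .entropy2(r1, r2)) / n
    k <- which.max(gain)
    if (gain[k] > best$gain) {
      best <- list(gain = gain[k], feature = j,
                   threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2)
    }
  }
  if (is.na(best$feature)) return(leaf)

  x <- X[idx, best$feature]
  go_left <- x <= best$threshold
  left <- .grow_node(X, y1, idx[go_left], depth + 1L, params)
  right <- .grow_node(X, y1, idx[!go_left], depth + 1L, params)

  if (!is.na(params$prune_cf)) {
    subtree_err <- .subtree_pessimistic(left, params$prune_cf) +
      .subtree_pessimistic(right, params$prune_cf)
    leaf_err <- .pessimistic_errors(min(n1, n2), n, params$prune_cf)
    if (leaf_err <= subtree_err) return(leaf)
  }
  list(n1 = n1, n2 = n2, feature = best$feature, threshold = best$threshold,
       left = left, right = right)
}

.subtree_pessimistic <- function(node, cf) {
  if (is.na(node$feature)) {
    return(.pessimistic_errors(min(node$n1, node$n2), node$n1 + node$n2, cf))
  }
  .subtree_pessimistic(node$left, cf) + .subtree_pessimistic(node$right, cf)
}

# Flatten the nested node list into a table (preorder); left/right are row
# indices, NA feature marks a leaf.
.flatten_tree <- function(root) {
  rows <- list()
  add <- function(node) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(feature = node$feature,
                              threshold = node$threshold,
                              left = NA_integer_, right = NA_integer_,
                              n1 = node$n1, n2 = node$n2)
    if (!is.na(node$feature)) {
      rows[[id]]$left <<- add(node$left)
      rows[[id]]$right <<- add(node$right)
    }
    id
  }
  add(root)
  do.call(rbind, rows)
}

#' Train an information-gain decision tree
#'
#' Grows a binary CART-style tree using the information-gain (entropy)
#' split criterion, then applies pessimistic-error pruning.  Leaf class
#' probabilities are Laplace-smoothed: Pr\[c1\] = (n_c1 + 1) / (n + 2).
#' Training is fully deterministic (ties broken by lowest feature index,
#' then lowest threshold); `seed` is accepted for interface uniformity.
#'
#' @param X Numeric feature matrix (rows = examples).
#' @param y Character/factor labels, exactly the two classes `"c1"`
#'   (positive) and `"c2"` (negative), both present.
#' @param params [tree_params()].
#' @param seed Ignored (deterministic learner); present so any
#'   classifier factory shares one signature.
#' @return A `prob_tree` classifier.
#' @export
train_tree <- function(X, y, params = tree_params(), seed = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)", call. = FALSE)
  if (!all(y %in% c("c1", "c2"))) {
    stop("labels must be 'c1' or 'c2'", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  root <- .grow_node(X, y == "c1", seq_len(nrow(X)), 0L, params)
  structure(list(
    nodes = .flatten_tree(root),
    feature_dimension = ncol(X),
    feature_names = colnames(X),
    classes = c(positive = "c1", negative = "c2"),
    params = params
  ), class = "prob_tree")
}

#' Posterior probability of the positive class
#'
#' Routes each row of `X` down the tree and returns the Laplace-smoothed
#' leaf estimate of Pr\[c1\].
#'
#' @param clf A `prob_tree` from [train_tree()] (or any object with a
#'   `predict_proba` method).
#' @param X Feature matrix with `clf$feature_dimension` columns.
#' @return Numeric vector of Pr\[c1\] in \[0, 1\], one per row of `X`.
#' @export
predict_proba <- function(clf, X) UseMethod("predict_proba")

#' @export
predict_proba.prob_tree <- function(clf, X) {
  X <- as.matrix(X)
  if (ncol(X) != clf$feature_dimension) {
    stop("feature dimension mismatch: expected ", clf$feature_dimension,
         ", got ", ncol(X), call. = FALSE)
  }
  nd <- clf$nodes
  node <- rep(1L, nrow(X))
  repeat {
    f <- nd$feature[node]
    live <- which(!is.na(f))
    if (!length(live)) break
    go_left <- X[cbind(live, f[live])] <= nd$threshold[node[live]]
    node[live] <- ifelse(go_left, nd$left[node[live]], nd$right[node[live]])
  }
  (nd$n1[node] + 1) / (nd$n1[node] + nd$n2[node] + 2)
}

#' @export
print.prob_tree <- function(x, ...) {
  cat("prob_tree: ", sum(is.na(x$nodes$feature)), " leaves, ",
      x$feature_dimension, " features, n = ",
      x$nodes$n1[1L] + x$nodes$n2[1L], "\n", sep = "")
  invisible(x)
}

#' Classifier factory
#'
#' Names a conforming inner classifier for the PU loop.  The shipped
#' default is the information-gain decision tree; any factory whose
#' `train(X, y, seed)` returns an object with a [predict_proba()] method
#' over classes c1/c2 is accepted by [run_pu()].
#'
#' @param name Classifier name; `"tree"` is the only built-in.
#' @param params Passed to the trainer (see [tree_params()]).
#' @return A `classifier_factory` with elements `name`, `params`, `train`.
#' @export
classifier_factory <- function(name = "tree", params = list()) {
  if (identical(name, "tree")) {
    tp <- do.call(tree_params, params)
    train <- function(X, y, seed = NULL) train_tree(X, y, tp, seed)
  } else {
    stop("unknown classifier '", name, "'; supply a custom factory",
         call. = FALSE)
  }
  structure(list(name = name, params = params, train = train),
            class = "classifier_factory")
}
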