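# Sequence I/O, redundancy reduction and PU dataset assembly.

#' Read a FASTA file into sequence records
#'
#' Parses a FASTA file, taking the header token before the first space as
#' the record id, concatenating wrapped sequence lines and upper-casing
#' letters.  Validation is strict: duplicate ids and characters outside the
#' tolerated amino-acid alphabet are errors.
#'
#' @param path Path to a FASTA file.
#' @return A [seq_records()] data frame, one row per FASTA entry, input
#'   order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("[[:space:]].*$", "", names(set))
  seq_records(ids, as.character(set))
}

#' Write sequence records to a FASTA file
#'
#' @param records Sequence records (see [seq_records()]).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- .as_records(records)
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Identity between two sequences: number of identical aligned positions
# under global (Needleman-Wunsch) alignment with match = 1, mismatch = 0,
# gap = -1, divided by the length of the shorter sequence.  This mirrors
# the denominator convention of common redundancy-reduction tools.
.identity_matrix_cache <- new.env(parent = emptyenv())

.identity_submat <- function() {
  if (is.null(.identity_matrix_cache$mat)) {
    letters <- .AA_ALPHABET
    m <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 1
    .identity_matrix_cache$mat <- m
  }
  .identity_matrix_cache$mat
}

#' Pairwise sequence identity
#'
#' Globally aligns two sequences (match = 1, mismatch = 0, linear gap
#' penalty = -1) and returns the fraction of identical aligned positions
#' over the length of the shorter sequence.
#'
#' @param a,b Amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- .clean_seq(a)
  b <- .clean_seq(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "global",
    substitutionMatrix = .identity_submat(),
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy redundancy reduction
#'
#' Greedy longest-first clustering: records are sorted by decreasing
#' sequence length (ties broken by lexicographic id), and a record is kept
#' iff its [pairwise_identity()] to every already-kept record is at most
#' `max_identity`.  Intended as a desk-scale stand-in for CD-HIT-style
#' clustering on hundreds to a few thousand sequences.
#'
#' @param records Sequence records.
#' @param max_identity Maximum tolerated pairwise identity, in (0, 1].
#' @return The retained subset, in the greedy (longest-first) order.
#' @export
greedy_identity_reduce <- function(records, max_identity) {
  records <- .as_records(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (!is.numeric(max_identity) || length(max_identity) != 1L ||
      max_identity <= 0 || max_identity > 1) {
    stop("max_identity must be in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(records$seq), records$id)
  records <- records[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(records))) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(records$seq[i], records$seq[j]) > max_identity) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random holdout split of a positive set
#'
#' Uniform draw without replacement of `n_holdout` records to set aside for
#' final-model testing; the remainder is the training positive set.
#'
#' @param P Positive sequence records.
#' @param n_holdout Number of records to hold out (0 < n_holdout < nrow(P)).
#' @param seed Integer seed; the split is reproducible for a fixed seed.
#' @return List with elements `train` and `holdout` (both `seq_records`).
#' @export
holdout_split <- function(P, n_holdout, seed) {
  P <- .as_records(P)
  n <- nrow(P)
  if (!is.numeric(n_holdout) || n_holdout < 1 || n_holdout >= n) {
    stop("n_holdout must satisfy 0 < n_holdout < ", n, call. = FALSE)
  }
  idx <- .with_seed(seed, sample.int(n, as.integer(n_holdout)))
  hold <- P[sort(idx), , drop = FALSE]
  train <- P[-sort(idx), , drop = FALSE]
  rownames(hold) <- rownames(train) <- NULL
  list(train = train, holdout = hold)
}

#' Assemble a positive-unlabeled dataset
#'
#' @param P Positive sequence records.
#' @param U Unlabeled sequence records; ids must be disjoint from `P`.
#' @param truth Optional named character vector mapping every id in `U` to
#'   `"positive"` or `"negative"` (synthetic benchmarks only).
#' @return A list with elements `P`, `U` and `truth`, class `pu_dataset`.
#' @export
pu_dataset <- function(P, U, truth = NULL) {
  P <- .as_records(P)
  U <- .as_records(U)
  clash <- intersect(P$id, U$id)
  if (length(clash)) {
    stop("P and U share ids (e.g. ", clash[1L], ")", call. = FALSE)
  }
  if (!is.null(truth)) {
    if (!all(U$id %in% names(truth))) {
      stop("truth must cover every id in U", call. = FALSE)
    }
    truth <- truth[U$id]
    if (!all(truth %in% c("positive", "negative"))) {
      stop("truth labels must be 'positive' or 'negative'", call. = FALSE)
    }
  }
  structure(list(P = P, U = U, truth = truth), class = "pu_dataset")
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat("PU dataset: ", nrow(x$P), " positive, ", nrow(x$U), " unlabeled",
      if (!is.null(x$truth))
        paste0(" (", sum(x$truth == "positive"), " hidden positives)"),
      "\n", sep = "")
  invisible(x)
}

#' Write a set-membership manifest
#'
#' Records which set (P, U or holdout) each id belongs to as a two-column
#' TSV (`id`, `set`).
#'
#' @param dataset A [pu_dataset()].
#' @param path Output TSV path.
#' @param holdout Optional holdout sequence records.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path, holdout = NULL) {
  stopifnot(inherits(dataset, "pu_dataset"))
  df <- rbind(
    data.frame(id = dataset$P$id, set = "P", stringsAsFactors = FALSE),
    data.frame(id = dataset$U$id, set = "U", stringsAsFactors = FALSE)
  )
  if (!is.null(holdout)) {
    holdout <- .as_records(holdout)
    df <- rbind(df, data.frame(id = holdout$id, set = "holdout",
                               stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
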