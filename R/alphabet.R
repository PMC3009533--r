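# Amino-acid alphabet shared across the package.

# The 20 standard residues, alphabetical by one-letter code.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes tolerated on ingest but excluded from all
# counts and window statistics downstream.
.AA_AMBIG <- c("B", "Z", "X", "U", "O")

.AA_ALPHABET <- c(.AA20, .AA_AMBIG)

#' Standard amino-acid alphabet
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes,
#'   in alphabetical order.  This is the canonical feature ordering used by
#'   [aa_composition()] and [local_env_composition()].
#' @export
amino_acids <- function() .AA20

# Validate one amino-acid string.  Returns the cleaned (upper-cased,
# whitespace-stripped) sequence or throws with the 1-based position of the
# first offending character.
.clean_seq <- function(seq, id = NULL) {
  seq <- toupper(gsub("[[:space:]]+", "", seq))
  if (nchar(seq) < 1L) {
    stop("empty sequence", if (!is.null(id)) paste0(" for id '", id, "'"),
         call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .AA_ALPHABET))
  if (length(bad)) {
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         if (!is.null(id)) paste0(" in sequence '", id, "'"),
         call. = FALSE)
  }
  seq
}

#' Sequence record container
#'
#' Builds a validated data frame of sequence records, the atomic input of
#' every other module.  Identifiers must be unique, non-empty and free of
#' whitespace; sequences are upper-cased and must use the 20 standard
#' amino-acid letters plus the tolerated ambiguity codes B, Z, X, U, O.
#'
#' @param id Character vector of identifiers.
#' @param seq Character vector of amino-acid strings (same length as `id`).
#' @return A `data.frame` with columns `id` and `seq` and class
#'   `seq_records`.
#' @examples
#' seq_records(c("a", "b"), c("MKR", "acdw"))
#' @export
seq_records <- function(id, seq) {
  id <- as.character(id)
  seq <- as.character(seq)
  stopifnot(length(id) == length(seq))
  if (any(is.na(id)) || any(!nzchar(id)) || any(grepl("[[:space:]]", id))) {
    stop("ids must be non-empty and contain no whitespace", call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate id ", dup[1L], call. = FALSE)
  }
  seq <- vapply(seq_along(seq), function(i) .clean_seq(seq[i], id[i]), "")
  structure(data.frame(id = id, seq = seq, stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

# Coerce anything record-like (seq_records, data.frame, named character)
# to a validated seq_records data frame.
.as_records <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.data.frame(x)) return(seq_records(x$id, x$seq))
  if (is.character(x) && !is.null(names(x))) return(seq_records(names(x), x))
  stop("expected seq_records, a data.frame with id/seq, or a named character vector",
       call. = FALSE)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-away-from-zero (base round() is banker's rounding)
.round_half_up <- function(x) floor(abs(x) + 0.5) * sign(x)
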