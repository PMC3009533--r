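# Sequence featurization: each sequence is reduced to a fixed vector of
# 104 numbers:
#   [charge, hydro_sum, helix_sum, sheet_sum,
#    composition (20), local-environment composition (4 x 20 = 80)].
# Ambiguity codes (B, Z, X, U, O) are excluded from every count and from
# window means; "effective length" is the number of standard residues.

.ENV_CATS <- c("loH_loS", "loH_hiS", "hiH_loS", "hiH_hiS")

#' Feature configuration
#'
#' Bundles every tunable of the featurizer: the charge map, the three
#' residue scales, the local-environment window and thresholds, and the
#' composition normalization flag.
#'
#' @param charge_map Named numeric vector of per-residue charge
#'   contributions; residues absent from the map contribute 0.
#' @param hydrophobicity,helix,sheet [propensity_scale()] objects.
#' @param env_window Odd positive integer; width of the centered window
#'   over which helix/sheet propensity means are taken (truncated at
#'   sequence ends).
#' @param env_threshold_helix,env_threshold_sheet Window-mean cutoffs
#'   splitting "high" from "low" propensity environments.  1.0 is the
#'   natural former/breaker boundary of the Chou-Fasman scales.
#' @param normalize_composition If `TRUE` (default) composition and
#'   local-environment slots are fractions of the effective length;
#'   otherwise raw counts.
#' @param normalize_sums If `TRUE`, charge and the three propensity sums
#'   are divided by effective length.  Default `FALSE` (raw sums).
#' @return A `feature_config` object.
#' @export
feature_config <- function(charge_map = default_charge_map(),
                           hydrophobicity = kyte_doolittle(),
                           helix = chou_fasman_helix(),
                           sheet = chou_fasman_sheet(),
                           env_window = 7L,
                           env_threshold_helix = 1.0,
                           env_threshold_sheet = 1.0,
                           normalize_composition = TRUE,
                           normalize_sums = FALSE) {
  env_window <- as.integer(env_window)
  if (is.na(env_window) || env_window < 1L || env_window %% 2L == 0L) {
    stop("env_window must be an odd positive integer", call. = FALSE)
  }
  stopifnot(inherits(hydrophobicity, "propensity_scale"),
            inherits(helix, "propensity_scale"),
            inherits(sheet, "propensity_scale"),
            is.numeric(charge_map), !is.null(names(charge_map)))
  structure(list(
    charge_map = charge_map,
    hydrophobicity = hydrophobicity,
    helix = helix,
    sheet = sheet,
    env_window = env_window,
    env_threshold_helix = env_threshold_helix,
    env_threshold_sheet = env_threshold_sheet,
    normalize_composition = isTRUE(normalize_composition),
    normalize_sums = isTRUE(normalize_sums)
  ), class = "feature_config")
}

#' Feature names in canonical order
#'
#' @return Character vector of the 104 feature column names, in the fixed
#'   order used by [featurize()] and [featurize_matrix()].
#' @export
feature_names <- function() {
  c("charge", "hydro_sum", "helix_sum", "sheet_sum",
    paste0("comp_", .AA20),
    paste0("env_", rep(.AA20, each = 4L), "_", rep(.ENV_CATS, 20L)))
}

#' Net charge of a sequence
#'
#' Sum of per-residue charge contributions; residues absent from the map
#' (including ambiguity codes under the default map) contribute 0.
#'
#' @param seq Amino-acid string.
#' @param charge_map Named numeric vector (default: K/R = +1, D/E = -1).
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(seq, charge_map = default_charge_map()) {
  chars <- strsplit(.clean_seq(seq), "", fixed = TRUE)[[1L]]
  v <- charge_map[chars]
  sum(v, na.rm = TRUE)
}

#' Sum of a residue scale over a sequence
#'
#' @param seq Amino-acid string.
#' @param scale A [propensity_scale()].
#' @return Sum of scale values over standard residues; ambiguity codes are
#'   skipped.
#' @export
scale_sum <- function(seq, scale) {
  stopifnot(inherits(scale, "propensity_scale"))
  chars <- strsplit(.clean_seq(seq), "", fixed = TRUE)[[1L]]
  sum(scale$values[chars], na.rm = TRUE)
}

#' Amino-acid composition
#'
#' @param seq Amino-acid string.
#' @param normalize Divide counts by effective length (all-zero vector when
#'   the effective length is 0).
#' @return Named numeric vector of length 20 in [amino_acids()] order.
#' @export
aa_composition <- function(seq, normalize = TRUE) {
  chars <- strsplit(.clean_seq(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, .AA20)
  counts <- tabulate(idx[!is.na(idx)], nbins = 20L)
  eff <- sum(!is.na(idx))
  if (normalize && eff > 0L) counts <- counts / eff
  stats::setNames(as.numeric(counts), .AA20)
}

# Shared core: computes the full 104-vector plus effective length for one
# already-validated sequence string.  Window means use cumulative sums so
# the whole computation is vectorized over positions.
.featurize_core <- function(seq, cfg) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  idx <- match(chars, .AA20)        # NA at ambiguity codes
  std <- !is.na(idx)
  eff <- sum(std)

  charge <- {
    v <- cfg$charge_map[chars]
    sum(v, na.rm = TRUE)
  }
  hsum <- sum(cfg$hydrophobicity$values[idx[std]])
  asum <- sum(cfg$helix$values[idx[std]])
  bsum <- sum(cfg$sheet$values[idx[std]])

  comp <- tabulate(idx[std], nbins = 20L)

  env <- numeric(80L)
  if (eff > 0L) {
    half <- (cfg$env_window - 1L) %/% 2L
    pos <- seq_len(n)
    lo <- pmax(1L, pos - half)
    hi <- pmin(n, pos + half)
    hv <- ifelse(std, cfg$helix$values[idx], 0)
    sv <- ifelse(std, cfg$sheet$values[idx], 0)
    csh <- c(0, cumsum(hv))
    css <- c(0, cumsum(sv))
    csn <- c(0, cumsum(as.numeric(std)))
    nw <- csn[hi + 1L] - csn[lo]
    # every standard residue contributes itself, so nw >= 1 where std
    mh <- (csh[hi + 1L] - csh[lo])[std] / nw[std]
    ms <- (css[hi + 1L] - css[lo])[std] / nw[std]
    cat4 <- 2L * (mh >= cfg$env_threshold_helix) +
      (ms >= cfg$env_threshold_sheet) + 1L
    slot <- (idx[std] - 1L) * 4L + cat4
    env <- tabulate(slot, nbins = 80L)
  }

  if (cfg$normalize_composition && eff > 0L) {
    comp <- comp / eff
    env <- env / eff
  }
  if (cfg$normalize_sums && eff > 0L) {
    charge <- charge / eff
    hsum <- hsum / eff
    asum <- asum / eff
    bsum <- bsum / eff
  }
  list(vec = c(charge, hsum, asum, bsum, comp, env), eff = eff)
}

#' Local-environment amino-acid composition
#'
#' Counts each standard residue by its identity crossed with the
#' helix/sheet propensity regime of its sequence neighborhood.  For the
#' residue at position i, the mean helix propensity and mean sheet
#' propensity are taken over the window of `env_window` residues centered
#' at i (truncated at the ends; ambiguity codes excluded from the mean).
#' The environment is one of four kinds -- (low/high helix) x (low/high
#' sheet) against the configured thresholds -- giving 4 x 20 = 80 slots.
#'
#' @param seq Amino-acid string.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 80 (residue-major, the four
#'   environment kinds within each residue).
#' @export
local_env_composition <- function(seq, cfg = feature_config()) {
  core <- .featurize_core(.clean_seq(seq), cfg)
  stats::setNames(core$vec[25:104], feature_names()[25:104])
}

#' Featurize one sequence
#'
#' @param seq Amino-acid string.
#' @param cfg A [feature_config()].
#' @return A `feature_vector`: list with elements `charge`, `hydro_sum`,
#'   `helix_sum`, `sheet_sum`, `composition` (20), `local_env` (80),
#'   `effective_length`, and `vector` (the flat named 104-vector).
#' @export
featurize <- function(seq, cfg = feature_config()) {
  core <- .featurize_core(.clean_seq(seq), cfg)
  v <- stats::setNames(core$vec, feature_names())
  structure(list(
    charge = unname(v[1L]),
    hydro_sum = unname(v[2L]),
    helix_sum = unname(v[3L]),
    sheet_sum = unname(v[4L]),
    composition = v[5:24],
    local_env = v[25:104],
    effective_length = core$eff,
    vector = v
  ), class = "feature_vector")
}

#' Featurize a set of sequences into a matrix
#'
#' @param records Sequence records (or a named character vector).
#' @param cfg A [feature_config()].
#' @return Numeric matrix, one row per record (rownames = ids), 104 named
#'   columns, with an `effective_length` attribute (named integer vector).
#' @export
featurize_matrix <- function(records, cfg = feature_config()) {
  records <- .as_records(records)
  cores <- lapply(records$seq, .featurize_core, cfg = cfg)
  X <- do.call(rbind, lapply(cores, `[[`, "vec"))
  dimnames(X) <- list(records$id, feature_names())
  attr(X, "effective_length") <-
    stats::setNames(vapply(cores, `[[`, 0L, "eff"), records$id)
  X
}

#' Write / read a feature matrix as TSV
#'
#' The TSV has a header row with an `id` column followed by the 104 named
#' feature columns.
#'
#' @param X Feature matrix from [featurize_matrix()].
#' @param path TSV path.
#' @return `path` (write) or the feature matrix (read).
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df$id
  X
}
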