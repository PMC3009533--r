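# Residue-level scales: charge, hydrophobicity, secondary-structure
# propensities.  All three scales are injectable through feature_config(),
# so none of these defaults is load-bearing for the algorithm itself.

#' Propensity scale constructor
#'
#' @param values Named numeric vector with exactly one finite value per
#'   standard amino acid.
#' @param name Human-readable scale name.
#' @return A `propensity_scale` object.
#' @export
propensity_scale <- function(values, name = "custom") {
  if (!is.numeric(values) || is.null(names(values))) {
    stop("values must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(.AA20, names(values))
  if (length(missing)) {
    stop("scale '", name, "' missing residues: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- values[.AA20]
  if (any(!is.finite(values))) stop("scale values must be finite", call. = FALSE)
  structure(list(values = values, name = name), class = "propensity_scale")
}

#' Kyte-Doolittle hydrophobicity scale
#' @return A [propensity_scale()].
#' @export
kyte_doolittle <- function() {
  propensity_scale(c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  ), name = "Kyte-Doolittle hydrophobicity")
}

#' Chou-Fasman helix propensity (P-alpha)
#' @return A [propensity_scale()].  Values > 1 mark helix formers.
#' @export
chou_fasman_helix <- function() {
  propensity_scale(c(
    A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
    Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
    L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
    S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06
  ), name = "Chou-Fasman helix propensity")
}

#' Chou-Fasman sheet propensity (P-beta)
#' @return A [propensity_scale()].  Values > 1 mark sheet formers.
#' @export
chou_fasman_sheet <- function() {
  propensity_scale(c(
    A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
    Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
    L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
    S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
  ), name = "Chou-Fasman sheet propensity")
}

#' Default side-chain charge map
#'
#' Standard neutral-pH convention: K and R contribute +1, D and E -1,
#' histidine and all other residues 0.
#'
#' @return Named numeric vector over the 20 standard amino acids, in
#'   elementary-charge units.
#' @export
default_charge_map <- function() {
  v <- stats::setNames(numeric(20L), .AA20)
  v[c("K", "R")] <- 1
  v[c("D", "E")] <- -1
  v
}
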