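# Model persistence.  A fitted PU model is written as a single JSON
# artifact embedding the tree table, the feature configuration and the
# spy configuration, so predictions from a loaded model are self-contained
# and the artifact stays a plain text file.

.fcfg_to_list <- function(fcfg) {
  list(charge_map = as.list(fcfg$charge_map),
       hydrophobicity = list(name = fcfg$hydrophobicity$name,
                             values = as.list(fcfg$hydrophobicity$values)),
       helix = list(name = fcfg$helix$name,
                    values = as.list(fcfg$helix$values)),
       sheet = list(name = fcfg$sheet$name,
                    values = as.list(fcfg$sheet$values)),
       env_window = fcfg$env_window,
       env_threshold_helix = fcfg$env_threshold_helix,
       env_threshold_sheet = fcfg$env_threshold_sheet,
       normalize_composition = fcfg$normalize_composition,
       normalize_sums = fcfg$normalize_sums)
}

.fcfg_from_list <- function(x) {
  feature_config(
    charge_map = unlist(x$charge_map),
    hydrophobicity = propensity_scale(unlist(x$hydrophobicity$values),
                                      x$hydrophobicity$name),
    helix = propensity_scale(unlist(x$helix$values), x$helix$name),
    sheet = propensity_scale(unlist(x$sheet$values), x$sheet$name),
    env_window = x$env_window,
    env_threshold_helix = x$env_threshold_helix,
    env_threshold_sheet = x$env_threshold_sheet,
    normalize_composition = x$normalize_composition,
    normalize_sums = x$normalize_sums
  )
}

#' Save / load a fitted PU model
#'
#' @param model A `pu_model` from [run_pu()].
#' @param path JSON file path.
#' @return `path` (save) or the reconstructed `pu_model` (load).  Only the
#'   final classifier, converged RN/Q membership and configurations are
#'   persisted; per-iteration spy id lists are not.
#' @export
save_pu_model <- function(model, path) {
  stopifnot(inherits(model, "pu_model"))
  clf <- model$final_classifier
  stopifnot(inherits(clf, "prob_tree"))
  obj <- list(
    format = "pulearn-model",
    version = 1L,
    variant = model$spy_config$variant,
    spy = list(s = model$spy_config$s, seed = model$spy_config$seed,
               max_iter = model$spy_config$max_iter,
               n_spies = model$spy_config$n_spies,
               classifier = model$spy_config$classifier$name),
    feature_config = .fcfg_to_list(model$feature_config),
    converged = model$converged,
    rn = model$state$RN,
    q = model$state$Q,
    history = model$state$history,
    tree = list(nodes = clf$nodes,
                feature_dimension = clf$feature_dimension,
                feature_names = clf$feature_names)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_pu_model
#' @export
load_pu_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pulearn-model")) {
    stop("not a pulearn model artifact: ", path, call. = FALSE)
  }
  nodes <- as.data.frame(obj$tree$nodes)
  nodes$feature <- as.integer(nodes$feature)
  nodes$left <- as.integer(nodes$left)
  nodes$right <- as.integer(nodes$right)
  clf <- structure(list(nodes = nodes,
                        feature_dimension = as.integer(obj$tree$feature_dimension),
                        feature_names = obj$tree$feature_names,
                        classes = c(positive = "c1", negative = "c2"),
                        params = tree_params()),
                   class = "prob_tree")
  scfg <- spy_config(s = obj$spy$s, seed = obj$spy$seed,
                     variant = obj$variant, max_iter = obj$spy$max_iter,
                     n_spies = obj$spy$n_spies)
  hist <- as.data.frame(obj$history)
  state <- structure(list(RN = as.character(obj$rn), Q = as.character(obj$q),
                          iteration = if (nrow(hist)) max(hist$iteration) else 0L,
                          history = hist, spies = list(),
                          converged = isTRUE(obj$converged)),
                     class = "pu_state")
  structure(list(final_classifier = clf, state = state,
                 spy_config = scfg,
                 feature_config = .fcfg_from_list(obj$feature_config),
                 converged = isTRUE(obj$converged)),
            class = "pu_model")
}
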