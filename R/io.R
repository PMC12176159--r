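# File formats: labelled series as CSV, model specs as YAML, fit results and
# run manifests as JSON. All writes are atomic (temp file then rename) and
# all external step indices are 1-based.

write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read and write labelled series CSV files
#'
#' The on-disk schema is one row per time step: `series_id`, `t` (1-based
#' integer step), one numeric column per feature, and `label` (empty string
#' or missing = unlabelled, otherwise a state name). Reading checks for
#' duplicate `(series_id, t)` pairs, non-numeric features and (when a spec
#' is given) unknown label names.
#'
#' @param path CSV file path.
#' @param spec Optional [phmm_spec()] used to validate feature columns and
#'   label names on read.
#' @return `read_labelled_series()`: a tibble sorted by `series_id`, `t`.
#' @export
read_labelled_series <- function(path, spec = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"series_id" %in% names(d)) abort("missing 'series_id' column")
  if (!"t" %in% names(d)) abort("missing 't' column")
  if ("label" %in% names(d)) {
    d$label[!is.na(d$label) & d$label == ""] <- NA_character_
  }
  dup <- duplicated(d[, c("series_id", "t")])
  if (any(dup)) {
    abort(sprintf("duplicate (series_id, t) at row %d", which(dup)[1]))
  }
  feats <- setdiff(names(d), c("series_id", "t", "label"))
  for (f in feats) {
    if (!is.numeric(d[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[f]]))) & !is.na(d[[f]]))
      abort(sprintf("non-numeric feature '%s' (row %d)", f, bad[1]))
    }
  }
  if (!is.null(spec)) invisible(as_series_list(d, spec))  # full validation
  tibble::as_tibble(d[order(d$series_id, d$t), , drop = FALSE])
}

#' @param data Labelled-series data frame to write.
#' @rdname read_labelled_series
#' @export
write_labelled_series <- function(data, path) {
  d <- as.data.frame(data)
  if (!"series_id" %in% names(d)) d$series_id <- "series1"
  if (!"t" %in% names(d)) {
    d <- dplyr::mutate(dplyr::group_by(d, .data$series_id),
                       t = dplyr::row_number())
    d <- as.data.frame(dplyr::ungroup(d))
  }
  if ("label" %in% names(d)) d$label[is.na(d$label)] <- ""
  front <- intersect(c("series_id", "t"), names(d))
  d <- d[, c(front, setdiff(names(d), c(front, "label")),
             intersect("label", names(d)))]
  write_atomic(path, function(tmp) write.csv(d, tmp, row.names = FALSE))
}

#' Serialize a model specification to YAML
#'
#' @param spec A [phmm_spec()].
#' @param path YAML file path.
#' @return `read_model_spec()` reconstructs the `wlphmm_spec`.
#' @export
write_model_spec <- function(spec, path) {
  obj <- list(
    n_states = spec$n_states, state_names = spec$state_names,
    features = spec$emission$features,
    family = if (is.null(spec$emission$joint)) as.list(spec$emission$family) else NULL,
    joint = spec$emission$joint,
    label_mode = spec$label_mode, label_alphabet = spec$label_alphabet,
    support = apply(spec$support, 1, as.integer, simplify = FALSE),
    init_mode = spec$init$mode, init_vector = spec$init$vector,
    tie_groups = spec$tie_groups,
    fixed = spec$fixed)
  write_atomic(path, function(tmp) yaml::write_yaml(obj, tmp))
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  o <- yaml::read_yaml(path)
  phmm_spec(
    n_states = o$n_states,
    emission = emission_spec(o$features,
                             family = if (!is.null(o$family)) unlist(o$family),
                             joint = o$joint),
    state_names = o$state_names, label_mode = o$label_mode,
    label_alphabet = o$label_alphabet,
    support = matrix(as.logical(do.call(rbind, o$support)), o$n_states, o$n_states),
    init = if (o$init_mode == "fixed") as.numeric(o$init_vector) else o$init_mode,
    tie_groups = o$tie_groups %||% list(),
    fixed = o$fixed %||% list())
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted parameters, the per-restart table, the weight `alpha`
#' and the seed, so a run can be audited for multimodality and reproduced.
#'
#' @param fit A `wlphmm_fit`.
#' @param path JSON file path.
#' @return Invisibly, the path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    alpha = fit$alpha, loglik = fit$loglik, seed = fit$seed,
    converged = fit$converged, n_obs = fit$n_obs, n_labels = fit$n_labels,
    delta = fit$params$delta, Gamma = fit$params$Gamma,
    theta = fit$params$theta, beta = fit$params$beta,
    restarts = fit$restarts)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and timestamp of a run
#' so every output artifact can be reproduced from the manifest alone.
#'
#' @param path JSON file path.
#' @param config Named list of run configuration values.
#' @param seed The seed the run used.
#' @return Invisibly, the path.
#' @export
write_run_manifest <- function(path, config, seed) {
  obj <- list(
    config = config, seed = seed,
    tool = "wlphmm",
    version = as.character(utils::packageVersion("wlphmm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
}
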