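# Tabular <-> internal representation of labelled series.
#
# The tidy on-disk and in-memory format is one row per time step:
#   series_id (optional for a single series), t (1-based step, optional),
#   one numeric column per feature, label (NA / "" = unlabelled).

# Convert a data frame into a list of internal series:
# list(id, y = T x D matrix, z = integer labels with NA = unlabelled).
as_series_list <- function(data, spec) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) abort("data has no rows")
  feats <- spec$emission$features
  missing_cols <- setdiff(feats, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing feature columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"series_id" %in% names(data)) data$series_id <- "series1"
  ids <- unique(data$series_id)
  lapply(ids, function(id) {
    d <- data[data$series_id == id, , drop = FALSE]
    if ("t" %in% names(d)) {
      if (anyDuplicated(d$t)) abort(sprintf("duplicate (series_id, t) in series '%s'", id))
      d <- d[order(d$t), , drop = FALSE]
    }
    y <- as.matrix(d[, feats, drop = FALSE])
    if (!is.numeric(y)) abort(sprintf("non-numeric feature values in series '%s'", id))
    nmiss <- rowSums(is.na(y))
    if (any(nmiss > 0 & nmiss < length(feats))) {
      abort(sprintf("series '%s' has partially missing feature rows (row %d)",
                    id, which(nmiss > 0 & nmiss < length(feats))[1]))
    }
    z <- parse_labels(d[["label"]], spec, nrow(d))
    list(id = id, y = y, z = z, Tn = nrow(d))
  })
}

parse_labels <- function(lab, spec, Tn) {
  if (is.null(lab)) return(rep(NA_integer_, Tn))
  alphabet <- spec$label_alphabet
  if (is.factor(lab)) lab <- as.character(lab)
  if (is.numeric(lab)) {
    z <- as.integer(lab)
    bad <- !is.na(z) & (z < 1L | z > length(alphabet))
    if (any(bad)) abort(paste("labels out of range:", paste(unique(z[bad]), collapse = ", ")))
    return(z)
  }
  lab[!is.na(lab) & lab == ""] <- NA_character_
  z <- match(lab, alphabet)
  bad <- !is.na(lab) & is.na(z)
  if (any(bad)) {
    abort(paste("unknown labels:", paste(unique(lab[bad]), collapse = ", ")))
  }
  as.integer(z)
}

# Labelled index sets per state across a series list.
label_counts_by_state <- function(series_list, n_states) {
  counts <- integer(n_states)
  for (s in series_list) {
    tab <- tabulate(s$z[!is.na(s$z)], nbins = n_states)
    counts <- counts + tab
  }
  counts
}

#' Summarize label bookkeeping of a labelled data set
#'
#' Counts labelled steps per label class and overall, and reports the labelled
#' fraction of all time steps, in the tidy one-row-per-class form used for
#' sanity-checking sparse annotation campaigns.
#'
#' @param data A labelled-series data frame (columns `series_id`, features,
#'   `label`).
#' @param spec A [phmm_spec()] giving the label alphabet.
#' @return A tibble with columns `label`, `n`, `fraction_of_steps`, plus
#'   attributes `n_labels` (total labelled steps) and `n_steps`.
#' @export
label_summary <- function(data, spec) {
  sl <- as_series_list(data, spec)
  counts <- label_counts_by_state(sl, length(spec$label_alphabet))
  n_steps <- sum(vapply(sl, function(s) s$Tn, integer(1)))
  out <- tibble::tibble(
    label = spec$label_alphabet,
    n = counts,
    fraction_of_steps = counts / n_steps
  )
  attr(out, "n_labels") <- sum(counts)
  attr(out, "n_steps") <- n_steps
  out
}
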