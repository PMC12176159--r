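#' Split a series into two label-balanced subprofiles
#'
#' Divides each series at a random time point such that the two parts carry
#' an equal number of labels (difference at most 1 when the label count is
#' odd), mirroring the construction of cross-validation folds from long dive
#' profiles with unevenly distributed labels. The split point is drawn
#' uniformly among all time indices achieving the best possible balance; the
#' two subprofiles concatenate to the original series and are thereafter
#' treated as independent series.
#'
#' @param data Labelled-series data frame; every distinct `series_id` is
#'   split.
#' @param seed Integer seed (deterministic splits).
#' @param suffixes Two strings appended to `series_id` for the parts.
#' @return The same data frame with updated `series_id` and a `t` column
#'   renumbered within each subprofile.
#' @export
split_profile <- function(data, seed = 1, suffixes = c("_a", "_b")) {
  data <- as.data.frame(data)
  if (!"series_id" %in% names(data)) data$series_id <- "series1"
  set.seed(as.integer(seed) %% .Machine$integer.max)
  parts <- lapply(unique(data$series_id), function(id) {
    d <- data[data$series_id == id, , drop = FALSE]
    if ("t" %in% names(d)) d <- d[order(d$t), , drop = FALSE]
    Tn <- nrow(d)
    if (Tn < 2) abort(sprintf("series '%s' too short to split", id))
    lab <- if ("label" %in% names(d)) !is.na(d$label) & d$label != "" else rep(FALSE, Tn)
    pre <- cumsum(lab)
    total <- pre[Tn]
    k_cand <- seq_len(Tn - 1)
    imbalance <- abs(2 * pre[k_cand] - total)
    k_best <- k_cand[imbalance == min(imbalance)]
    k <- if (length(k_best) == 1) k_best else sample(k_best, 1)
    d$series_id <- paste0(id, ifelse(seq_len(Tn) <= k, suffixes[1], suffixes[2]))
    d$t <- c(seq_len(k), seq_len(Tn - k))
    d
  })
  tibble::as_tibble(dplyr::bind_rows(parts))
}

soft_reference <- function(posterior, labels, state) {
  if (is.data.frame(posterior)) {
    cols <- setdiff(names(posterior), c("series_id", "t"))
    posterior <- as.matrix(posterior[, cols, drop = FALSE])
    if (is.character(state)) state <- match(state, cols)
  }
  if (length(labels) != nrow(posterior)) abort("labels and posterior lengths differ")
  list(p = posterior[, state], state = state)
}

#' Soft (probability-averaged) sensitivity and specificity
#'
#' Soft sensitivity for state `i` is the mean posterior probability of `i`
#' over steps labelled `i`; soft specificity is the mean posterior
#' probability of *not* `i` over steps labelled as some other state.
#' Unlabelled steps are ignored. When the reference set is empty the metric
#' is undefined and `NA` is returned with a warning.
#'
#' @param posterior A posterior matrix / tibble from [phmm_posterior()]
#'   (state columns), aligned row-wise with `labels`.
#' @param labels Integer label vector (`NA` = unlabelled), aligned with the
#'   posterior rows.
#' @param state State index (or state-column name) the metric refers to.
#' @return A single value in `[0, 1]`, or `NA` if undefined.
#' @export
soft_sensitivity <- function(posterior, labels, state) {
  sr <- soft_reference(posterior, labels, state)
  idx <- which(!is.na(labels) & labels == sr$state)
  if (!length(idx)) {
    warn("soft_sensitivity undefined: no steps labelled with this state")
    return(NA_real_)
  }
  mean(sr$p[idx])
}

#' @rdname soft_sensitivity
#' @export
soft_specificity <- function(posterior, labels, state) {
  sr <- soft_reference(posterior, labels, state)
  idx <- which(!is.na(labels) & labels != sr$state)
  if (!length(idx)) {
    warn("soft_specificity undefined: no steps labelled with another state")
    return(NA_real_)
  }
  mean(1 - sr$p[idx])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly drawn positive item receives a higher
#' score than a randomly drawn negative item, ties counted one half;
#' algebraically identical to the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores (e.g. posterior probabilities).
#' @param truth Logical (or 0/1) indicator of the positive class.
#' @return AUC in `[0, 1]`, or `NA` with a warning if a class is absent.
#' @export
auc_score <- function(scores, truth) {
  truth <- as.logical(truth)
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]
  truth <- truth[keep]
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    warn("AUC undefined: one class is absent")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Candidate weights for cross-validated alpha selection
#'
#' The minimal candidate set `{0, |T_lab| / (T - |T_lab|), 1}`: the middle
#' value approximately balances the total contribution of labelled and
#' unlabelled observations in the weighted likelihood. Duplicates (e.g. when
#' half the steps are labelled) are removed. Callers may extend the set with
#' midpoints between neighbouring candidates.
#'
#' @param n_steps Total number of time steps `T` across the data set.
#' @param n_labels Number of labelled steps; must satisfy
#'   `0 < n_labels < n_steps`.
#' @return Sorted numeric vector of candidate weights.
#' @export
candidate_alphas <- function(n_steps, n_labels) {
  if (n_labels <= 0 || n_labels >= n_steps) {
    abort("n_labels must be strictly between 0 and n_steps")
  }
  sort(unique(c(0, n_labels / (n_steps - n_labels), 1)))
}

#' Cross-validated evaluation over a grid of weights
#'
#' For each candidate `alpha` and each fold: fit the PHMM on all series
#' outside the fold, run the forward-backward algorithm on the held-out
#' series with their labels excluded, and pool the held-out posteriors.
#' Metrics (per-state soft sensitivity, soft specificity and AUC against the
#' held-out labels) are computed either pooled over all held-out labels
#' (`metric_mode = "pooled"`) or per fold and then averaged
#' (`metric_mode = "per_fold_mean"`). Identifiability failures (e.g.
#' `alpha = 0` with a state unlabelled in some training complement) are
#' recorded per cell and do not abort the remaining cells.
#'
#' @param data Labelled-series data frame.
#' @param spec A [phmm_spec()].
#' @param alphas Numeric vector of candidate weights (see
#'   [candidate_alphas()]).
#' @param folds `"series"` (default: every series is its own fold) or a
#'   named vector / list mapping `series_id` to a fold id.
#' @param metric_mode `"pooled"` or `"per_fold_mean"`.
#' @param n_restarts,seed,control Passed to [phmm_fit()].
#' @return An object of class `wlphmm_cv` with elements `posteriors` (long
#'   tibble: `alpha`, `fold`, `series_id`, `t`, `state`, `posterior`,
#'   `label`), `metrics` (per alpha and state), `summary` (per alpha:
#'   mean AUC), `best_alpha`, `failures`. Supports [tidy()] and
#'   [autoplot()].
#' @export
phmm_cv <- function(data, spec, alphas, folds = "series",
                    metric_mode = c("pooled", "per_fold_mean"),
                    n_restarts = 10, seed = 1,
                    control = list(maxit = 500, reltol = 1e-9)) {
  metric_mode <- match.arg(metric_mode)
  data <- as.data.frame(data)
  if (!"series_id" %in% names(data)) data$series_id <- "series1"
  ids <- unique(data$series_id)
  fold_of <- if (identical(folds, "series")) {
    setNames(as.character(ids), ids)
  } else {
    unlist(folds)[ids]
  }
  if (anyNA(fold_of)) abort("every series_id needs a fold assignment")
  fold_levels <- unique(fold_of)
  if (length(fold_levels) < 2) abort("cross validation needs at least 2 folds")

  cell_seeds <- matrix(
    derive_seeds(seed, length(alphas) * length(fold_levels)),
    nrow = length(alphas))
  posts <- list()
  failures <- list()
  for (ai in seq_along(alphas)) {
    for (fi in seq_along(fold_levels)) {
      a <- alphas[ai]
      fl <- fold_levels[fi]
      held_ids <- ids[fold_of == fl]
      train <- data[!data$series_id %in% held_ids, , drop = FALSE]
      test <- data[data$series_id %in% held_ids, , drop = FALSE]
      res <- tryCatch({
        fit <- phmm_fit(train, spec, alpha = a, n_restarts = n_restarts,
                        seed = cell_seeds[ai, fi], control = control)
        post <- phmm_posterior(test, spec, fit$params, use_labels = FALSE)
        long <- tidyr::pivot_longer(post, cols = dplyr::all_of(spec$state_names),
                                    names_to = "state", values_to = "posterior")
        lab_tbl <- as_label_tbl(test, spec)
        dplyr::left_join(long, lab_tbl, by = c("series_id", "t")) |>
          dplyr::mutate(alpha = a, fold = fl, .before = 1)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          alpha = a, fold = fl, message = conditionMessage(res))
      } else {
        posts[[length(posts) + 1]] <- res
      }
    }
  }
  posteriors <- dplyr::bind_rows(posts)
  if (nrow(posteriors) == 0L) abort("every cross-validation cell failed")
  metrics <- cv_metrics(posteriors, spec, metric_mode)
  summary <- metrics |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(mean_auc = mean(.data$auc, na.rm = TRUE), .groups = "drop")
  structure(
    list(posteriors = posteriors, metrics = metrics, summary = summary,
         best_alpha = summary$alpha[which.max(summary$mean_auc)],
         failures = dplyr::bind_rows(failures), metric_mode = metric_mode,
         alphas = alphas, seed = seed),
    class = "wlphmm_cv")
}

as_label_tbl <- function(data, spec) {
  sl <- as_series_list(data, spec)
  dplyr::bind_rows(lapply(sl, function(s) {
    tibble::tibble(series_id = s$id, t = seq_len(s$Tn), label = s$z)
  }))
}

cv_metrics <- function(posteriors, spec, metric_mode) {
  one_block <- function(d) {
    wide <- tidyr::pivot_wider(d, names_from = "state", values_from = "posterior")
    pm <- as.matrix(wide[, spec$state_names, drop = FALSE])
    lab <- wide$label
    dplyr::bind_rows(lapply(seq_len(spec$n_states), function(i) {
      has_pos <- any(!is.na(lab) & lab == i)
      has_neg <- any(!is.na(lab) & lab != i)
      tibble::tibble(
        state = spec$state_names[i],
        sensitivity = if (has_pos) mean(pm[!is.na(lab) & lab == i, i]) else NA_real_,
        specificity = if (has_neg) mean(1 - pm[!is.na(lab) & lab != i, i]) else NA_real_,
        auc = if (has_pos && has_neg) {
          keep <- !is.na(lab)
          auc_score(pm[keep, i], lab[keep] == i)
        } else NA_real_)
    }))
  }
  if (metric_mode == "pooled") {
    posteriors |>
      dplyr::group_by(.data$alpha) |>
      dplyr::group_modify(~ one_block(.x)) |>
      dplyr::ungroup()
  } else {
    per_fold <- posteriors |>
      dplyr::group_by(.data$alpha, .data$fold) |>
      dplyr::group_modify(~ one_block(.x)) |>
      dplyr::ungroup()
    per_fold |>
      dplyr::group_by(.data$alpha, .data$state) |>
      dplyr::summarise(
        sensitivity = mean(.data$sensitivity, na.rm = TRUE),
        specificity = mean(.data$specificity, na.rm = TRUE),
        auc = mean(.data$auc, na.rm = TRUE), .groups = "drop")
  }
}

#' @export
print.wlphmm_cv <- function(x, ...) {
  cat(sprintf("PHMM cross validation over alpha = {%s} (%s metrics)\n",
              paste(signif(x$alphas, 3), collapse = ", "), x$metric_mode))
  print(x$summary)
  cat(sprintf("best alpha by mean AUC: %g\n", x$best_alpha))
  if (nrow(x$failures)) cat(sprintf("%d cell(s) failed\n", nrow(x$failures)))
  invisible(x)
}

#' @rdname phmm_cv
#' @param x A `wlphmm_cv`.
#' @param ... Unused.
#' @export
tidy.wlphmm_cv <- function(x, ...) x$metrics

#' Hard-label series by thresholding an event probability
#'
#' Reporting utility: flags each series whose event probability (e.g. the
#' terminal foraging probability) strictly exceeds a threshold.
#'
#' @param probabilities Tibble with columns `series_id`, `probability`
#'   (e.g. from [terminal_event_probability()]).
#' @param threshold Decision threshold, default 0.5 (strictly greater).
#' @return The input with an added logical column `flagged`.
#' @export
threshold_events <- function(probabilities, threshold = 0.5) {
  dplyr::mutate(probabilities, flagged = .data$probability > threshold)
}
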