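# Decoding is always unweighted: alpha influences estimation only. Posterior
# smoothing and Viterbi condition on the observations (and optionally the
# labels) under the plain model density.

# Scaled forward-backward for one internal series. Returns T x N posterior,
# the log-likelihood of the conditioning evidence, and the scaled forward
# variables (for diagnostics).
forward_backward_series <- function(params, spec, s, use_labels) {
  logb <- emission_logdens_matrix(spec$emission, params$theta, s$y)
  if (use_labels) logb <- logb + label_logmass_matrix(spec, s$z, params$beta)
  Tn <- nrow(logb)
  N <- ncol(logb)
  m <- apply(logb, 1, max)
  if (any(m == -Inf)) {
    abort(sprintf("series '%s': impossible evidence at step %d", s$id, which(m == -Inf)[1]))
  }
  e <- exp(logb - m)
  A <- matrix(0, Tn, N)
  cs <- numeric(Tn)
  a <- params$delta * e[1, ]
  cs[1] <- sum(a)
  if (cs[1] <= 0) abort(sprintf("series '%s': impossible evidence at step 1", s$id))
  A[1, ] <- a / cs[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- (A[t - 1, ] %*% params$Gamma) * e[t, ]
      cs[t] <- sum(a)
      if (cs[t] <= 0) abort(sprintf("series '%s': impossible evidence at step %d", s$id, t))
      A[t, ] <- a / cs[t]
    }
  }
  B <- matrix(0, Tn, N)
  B[Tn, ] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      B[t, ] <- (params$Gamma %*% (e[t + 1, ] * B[t + 1, ])) / cs[t + 1]
    }
  }
  post <- A * B
  post <- post / rowSums(post)
  list(posterior = post, loglik = sum(log(cs) + m))
}

#' Posterior state probabilities by the forward-backward algorithm
#'
#' Computes the smoothing probabilities `P(X_t = i | evidence)` for every
#' step of every series under a fitted (or any) parameter point. With
#' `use_labels = FALSE` (the default, and the convention for held-out
#' evaluation) the evidence is the observations only; with
#' `use_labels = TRUE` observed labels also condition the posterior, which
#' under the certain-label rule pins labelled steps to their labelled state.
#'
#' @param data Labelled-series data frame.
#' @param spec A [phmm_spec()].
#' @param params A [phmm_params()] point, or a `wlphmm_fit` (its parameters
#'   are used).
#' @param use_labels Condition on the labels as well as the observations.
#' @return A tibble with columns `series_id`, `t`, one posterior-probability
#'   column per state (named after the states), and attribute `"loglik"`, a
#'   per-series tibble of evidence log-likelihoods.
#' @export
phmm_posterior <- function(data, spec, params, use_labels = FALSE) {
  if (inherits(params, "wlphmm_fit")) {
    spec <- params$spec
    params <- params$params
  }
  sl <- as_series_list(data, spec)
  out <- vector("list", length(sl))
  ll <- numeric(length(sl))
  for (k in seq_along(sl)) {
    fb <- forward_backward_series(params, spec, sl[[k]], use_labels)
    post <- fb$posterior
    colnames(post) <- spec$state_names
    out[[k]] <- tibble::tibble(series_id = sl[[k]]$id, t = seq_len(sl[[k]]$Tn)) |>
      dplyr::bind_cols(tibble::as_tibble(post))
    ll[k] <- fb$loglik
  }
  res <- dplyr::bind_rows(out)
  attr(res, "loglik") <- tibble::tibble(
    series_id = vapply(sl, `[[`, "", "id"), loglik = ll)
  attr(res, "use_labels") <- use_labels
  res
}

#' Most probable state path by the Viterbi algorithm
#'
#' Returns the jointly most probable hidden-state path given the
#' observations (and, optionally, the labels). Ties are broken toward the
#' lower state index.
#'
#' @inheritParams phmm_posterior
#' @return A tibble with columns `series_id`, `t`, `state` (state name) and
#'   `state_index`, with attribute `"logp"`, a per-series tibble of the log
#'   joint probability of the returned path and the evidence.
#' @export
phmm_viterbi <- function(data, spec, params, use_labels = FALSE) {
  if (inherits(params, "wlphmm_fit")) {
    spec <- params$spec
    params <- params$params
  }
  sl <- as_series_list(data, spec)
  lG <- log(params$Gamma)
  out <- vector("list", length(sl))
  lp <- numeric(length(sl))
  for (k in seq_along(sl)) {
    s <- sl[[k]]
    logb <- emission_logdens_matrix(spec$emission, params$theta, s$y)
    if (use_labels) logb <- logb + label_logmass_matrix(spec, s$z, params$beta)
    Tn <- nrow(logb)
    N <- ncol(logb)
    V <- matrix(-Inf, Tn, N)
    bp <- matrix(0L, Tn, N)
    V[1, ] <- log(params$delta) + logb[1, ]
    if (Tn > 1) {
      for (t in 2:Tn) {
        for (j in seq_len(N)) {
          v <- V[t - 1, ] + lG[, j]
          bp[t, j] <- which.max(v)  # first max = lowest index on ties
          V[t, j] <- v[bp[t, j]] + logb[t, j]
        }
      }
    }
    path <- integer(Tn)
    path[Tn] <- which.max(V[Tn, ])
    lp[k] <- V[Tn, path[Tn]]
    if (!is.finite(lp[k])) {
      abort(sprintf("series '%s': impossible evidence, no admissible path", s$id))
    }
    if (Tn > 1) for (t in (Tn - 1):1) path[t] <- bp[t + 1, path[t + 1]]
    out[[k]] <- tibble::tibble(
      series_id = s$id, t = seq_len(Tn),
      state = spec$state_names[path], state_index = path)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "logp") <- tibble::tibble(
    series_id = vapply(sl, `[[`, "", "id"), logp = lp)
  res
}

#' Probability that a series ends in a given set of states
#'
#' Sums the final posterior row of each series over the given states. In the
#' foraging-dive model this is the probability that a dive ends in the
#' capture or ascent-with-fish state, i.e. that it was a successful foraging
#' dive.
#'
#' @param posterior A tibble from [phmm_posterior()].
#' @param states State names (or indices into the posterior's state columns).
#' @return A tibble with columns `series_id` and `probability`.
#' @export
terminal_event_probability <- function(posterior, states) {
  if (nrow(posterior) == 0L) abort("empty posterior")
  state_cols <- setdiff(names(posterior), c("series_id", "t"))
  if (is.numeric(states)) states <- state_cols[states]
  if (!all(states %in% state_cols)) abort("unknown state names")
  last <- posterior |>
    dplyr::group_by(.data$series_id) |>
    dplyr::slice_max(.data$t, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  prob <- if (!length(states)) {
    rep(0, nrow(last))
  } else {
    rowSums(as.matrix(last[, states, drop = FALSE]))
  }
  tibble::tibble(series_id = last$series_id, probability = prob)
}
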