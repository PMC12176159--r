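# Simulation-study machinery: a 2-state shifted-t generator with sparse
# exact labels, the 11-experiment one-setting-at-a-time grid, and
# misspecified Gaussian PHMM fitting with test-set AUC evaluation.

#' Generating model for the simulation study
#'
#' Builds the 2-state shifted-t PHMM used as the data-generating process:
#' transition matrix `rbind(c(0.99, 0.01), c(1 - gamma, gamma))`, initial
#' distribution equal to its stationary distribution, and state-dependent
#' shifted t(nu) emissions with unit scale whose locations are separated by
#' `kappa` standard deviations, i.e. `-/+ (kappa / 2) * sqrt(nu / (nu - 2))`.
#'
#' @param gamma Bottom-right transition entry (state-2 persistence), in
#'   (0, 1). Control value 0.95.
#' @param nu Degrees of freedom of the t emissions; must exceed 2 so the
#'   standard deviation `sqrt(nu / (nu - 2))` is finite. Control value 4.
#' @param kappa Separation between the state locations, in emission standard
#'   deviations. Control value 1.
#' @return A list with elements `spec` (a [phmm_spec()]) and `params` (a
#'   [phmm_params()]).
#' @examples
#' m <- build_sim_params()
#' m$params$Gamma
#' @export
build_sim_params <- function(gamma = 0.95, nu = 4, kappa = 1) {
  stopifnot(gamma > 0, gamma < 1, kappa > 0)
  if (nu <= 2) abort("nu must exceed 2 (finite emission standard deviation)")
  spec <- phmm_spec(2, emission_spec("y", family = c(y = "shifted_t")),
                    state_names = c("state1", "state2"), init = "stationary")
  half <- (kappa / 2) * sqrt(nu / (nu - 2))
  params <- phmm_params(
    spec,
    Gamma = rbind(c(0.99, 0.01), c(1 - gamma, gamma)),
    theta = list(list(y = c(location = -half, df = nu)),
                 list(y = c(location = half, df = nu))))
  list(spec = spec, params = params)
}

#' Simulate a hidden path and observations from a PHMM
#'
#' Draws `X_1` from `delta`, each subsequent state from the corresponding
#' transition row, and each observation from its state's emission.
#'
#' @param model A list with `spec` and `params` (e.g. from
#'   [build_sim_params()]), or a `wlphmm_fit`.
#' @param n_steps Series length `T`.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A tibble with columns `t`, the feature columns, and `state` (the
#'   true hidden path, an integer).
#' @export
sample_series <- function(model, n_steps, seed = 1) {
  if (inherits(model, "wlphmm_fit")) model <- list(spec = model$spec, params = model$params)
  spec <- model$spec
  params <- model$params
  set.seed(as.integer(seed) %% .Machine$integer.max)
  N <- spec$n_states
  x <- integer(n_steps)
  x[1] <- sample.int(N, 1, prob = params$delta)
  for (t in seq_len(n_steps)[-1]) {
    x[t] <- sample.int(N, 1, prob = params$Gamma[x[t - 1], ])
  }
  D <- emission_dim(spec$emission)
  Y <- matrix(NA_real_, n_steps, D, dimnames = list(NULL, spec$emission$features))
  for (i in seq_len(N)) {
    idx <- which(x == i)
    if (length(idx)) Y[idx, ] <- emission_sample(spec$emission, params$theta[[i]], length(idx))
  }
  dplyr::bind_cols(tibble::tibble(t = seq_len(n_steps)),
                   tibble::as_tibble(Y), tibble::tibble(state = x))
}

#' Sparsely label a hidden path
#'
#' Selects `round(ell * T)` time indices uniformly without replacement,
#' rejection-resampling the index set until every state carries at least two
#' labels, and sets each selected label equal to the true hidden state
#' (exact labels). Errors if some state occurs fewer than twice in `x` (the
#' caller should regenerate the series).
#'
#' @param x Integer hidden path.
#' @param ell Label proportion in (0, 1).
#' @param seed Integer seed.
#' @param min_per_state Minimum labels required per state (default 2).
#' @param n_states Number of states of the generating chain (default: at
#'   least 2, or the largest index seen in `x`).
#' @return Integer label vector with `NA` at unlabelled steps.
#' @export
sample_labels <- function(x, ell, seed = 1, min_per_state = 2L,
                          n_states = max(x, 2L)) {
  stopifnot(ell > 0, ell < 1)
  n_steps <- length(x)
  states <- seq_len(n_states)
  occ <- tabulate(x, nbins = n_states)
  if (any(occ < min_per_state)) {
    abort("some state occurs fewer than the required labels; regenerate the series")
  }
  n_lab <- max(round(ell * n_steps), length(states) * min_per_state)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (try in seq_len(10000L)) {
    idx <- sample.int(n_steps, n_lab)
    if (all(tabulate(x[idx], nbins = n_states) >= min_per_state)) {
      z <- rep(NA_integer_, n_steps)
      z[idx] <- x[idx]
      return(z)
    }
  }
  abort("could not draw a label set with the per-state minimum; increase ell")
}

#' The 11-experiment simulation grid
#'
#' The control configuration (`T = 2000`, `gamma = 0.95`, `nu = 4`,
#' `ell = 0.01`, `kappa = 1`) plus the ten perturbations that change exactly
#' one setting: `T` to 200 or 20000, `gamma` to 0.75 or 0.99, `nu` to 2.5 or
#' 100, `ell` to 0.001 or 0.1, and `kappa` to 0.5 or 2.
#'
#' @return A tibble with one row per experiment: `experiment`, `setting`
#'   (which knob was moved), `n_steps`, `gamma`, `nu`, `ell`, `kappa`.
#' @export
experiment_grid <- function() {
  base <- list(n_steps = 2000L, gamma = 0.95, nu = 4, ell = 0.01, kappa = 1)
  alt <- list(n_steps = c(200L, 20000L), gamma = c(0.75, 0.99),
              nu = c(2.5, 100), ell = c(0.001, 0.1), kappa = c(0.5, 2))
  rows <- list(tibble::tibble(experiment = "control", setting = "none",
                              !!!base))
  for (nm in names(alt)) {
    for (v in alt[[nm]]) {
      cfg <- base
      cfg[[nm]] <- v
      rows[[length(rows) + 1]] <- tibble::tibble(
        experiment = paste0(nm, "_", format(v, trim = TRUE, scientific = FALSE)),
        setting = nm, !!!cfg)
    }
  }
  dplyr::bind_rows(rows)
}

# 2-state Gaussian-emission fitting spec used on the simulated data
# (deliberately misspecified relative to the t-distributed generator).
gaussian_fit_spec <- function() {
  phmm_spec(2, emission_spec("y", family = c(y = "normal")),
            state_names = c("state1", "state2"), init = "free")
}

#' Run one simulation experiment
#'
#' For each replicate: simulate a training series and sparse exact labels
#' from the shifted-t generator (regenerating the hidden path if a state
#' occurs fewer than twice, which matters at short lengths with strong
#' persistence), simulate an independent test series from the same
#' mechanism, fit a 2-state Gaussian-emission PHMM for every `alpha` on the
#' grid, run the forward-backward algorithm on the test observations with
#' the test labels ignored, and score the state-2 posterior against the true
#' test states with AUC.
#'
#' @param config One row of [experiment_grid()] (or a list with `n_steps`,
#'   `gamma`, `nu`, `ell`, `kappa`).
#' @param n_reps Number of replicates.
#' @param seed Master seed; every replicate derives its own seeds.
#' @param alphas Weight grid (default `c(0, 0.001, 0.01, 0.1, 0.5, 1)`).
#' @param n_restarts Random restarts per fit (default 3).
#' @param replicates Subset of `1:n_reps` to run (default all). Replicate
#'   seeds depend only on `seed` and the replicate index, so a run can be
#'   extended incrementally: `replicates = 31:100` continues a 30-replicate
#'   run of the same seed.
#' @return A tibble with columns `replicate`, `alpha`, `auc`, `loglik`,
#'   `converged`, `failed`; fit failures are flagged per cell, not fatal.
#' @export
run_experiment <- function(config, n_reps = 30, seed = 1,
                           alphas = c(0, 0.001, 0.01, 0.1, 0.5, 1),
                           n_restarts = 3, replicates = seq_len(n_reps)) {
  config <- as.list(config)
  model <- build_sim_params(config$gamma, config$nu, config$kappa)
  fit_spec <- gaussian_fit_spec()
  seeds <- matrix(derive_seeds(seed, max(n_reps, max(replicates)) * 3L),
                  ncol = 3L, byrow = TRUE)
  out <- vector("list", length(replicates))
  for (j in seq_along(replicates)) {
    r <- as.integer(replicates[j])
    train <- regenerate_until_valid(model, config$n_steps, seeds[r, 1])
    z <- sample_labels(train$state, config$ell, seed = seeds[r, 2])
    train_df <- data.frame(t = train$t, y = train$y, label = z)
    test <- sample_series(model, config$n_steps, seed = seeds[r, 3])
    test_df <- data.frame(t = test$t, y = test$y)
    rows <- lapply(alphas, function(a) {
      res <- tryCatch({
        fit <- phmm_fit(train_df, fit_spec, alpha = a, n_restarts = n_restarts,
                        seed = seeds[r, 1])
        post <- phmm_posterior(test_df, fit_spec, fit$params, use_labels = FALSE)
        tibble::tibble(replicate = r, alpha = a,
                       auc = auc_score(post$state2, test$state == 2),
                       loglik = fit$loglik, converged = fit$converged,
                       failed = FALSE)
      }, error = function(e) {
        tibble::tibble(replicate = r, alpha = a, auc = NA_real_,
                       loglik = NA_real_, converged = FALSE, failed = TRUE)
      })
      res
    })
    out[[j]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

# Redraw the hidden path until every state occurs at least `min_per_state`
# times (relevant for short, highly persistent chains).
regenerate_until_valid <- function(model, n_steps, seed, min_per_state = 2L) {
  for (k in 0:1000) {
    s <- sample_series(model, n_steps, seed = (seed + k) %% .Machine$integer.max)
    if (all(tabulate(s$state, nbins = model$spec$n_states) >= min_per_state)) return(s)
  }
  abort("could not generate a series visiting every state")
}

#' Summarize an experiment by the best weight
#'
#' Median test-set AUC per `alpha` and the grid value maximizing it.
#'
#' @param results Output of [run_experiment()].
#' @return A list with `by_alpha` (tibble of `alpha`, `median_auc`, `n`) and
#'   `best_alpha`.
#' @export
summarize_experiment <- function(results) {
  by_alpha <- results |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(median_auc = median(.data$auc, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
  list(by_alpha = by_alpha,
       best_alpha = by_alpha$alpha[which.max(by_alpha$median_auc)])
}
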