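#' Check identifiability before an alpha = 0 fit
#'
#' At `alpha = 0` every unlabelled observation is dropped from the
#' likelihood, so a hidden state with no labels anywhere (and no tie to a
#' labelled state) has no data informing its emission parameters and the
#' model is unidentifiable. This guard errors in that situation and is run
#' automatically by [phmm_fit()].
#'
#' @param data Labelled-series data frame.
#' @param spec A [phmm_spec()].
#' @param alpha The weight about to be used.
#' @return Invisibly `TRUE` when the fit is identifiable.
#' @export
guard_identifiability <- function(data, spec, alpha) {
  if (alpha > 0) return(invisible(TRUE))
  sl <- as_series_list(data, spec)
  counts <- label_counts_by_state(sl, spec$n_states)
  rep_of <- tie_representative(spec)
  block_counts <- tapply(counts, rep_of, sum)
  bad <- names(block_counts)[block_counts == 0]
  if (length(bad)) {
    states <- spec$state_names[rep_of %in% as.integer(bad)]
    abort(paste0(
      "alpha = 0 is unidentifiable: no labels for state(s) ",
      paste(states, collapse = ", "),
      "; use alpha > 0 or supply labels for every state"))
  }
  invisible(TRUE)
}

#' Draw a random starting point for optimization
#'
#' Emission locations are spread across data quantiles (one per state, with
#' jitter), scale parameters drawn around the pooled data dispersion, and
#' supported transition rows Dirichlet-perturbed around a diagonally dominant
#' matrix. Deterministic given `seed`.
#'
#' @param data Labelled-series data frame.
#' @param spec A [phmm_spec()].
#' @param seed Integer seed.
#' @return A valid [phmm_params()] point.
#' @export
random_init <- function(data, spec, seed = 1) {
  sl <- as_series_list(data, spec)
  Y <- do.call(rbind, lapply(sl, `[[`, "y"))
  Y <- Y[complete.cases(Y), , drop = FALSE]
  if (nrow(Y) == 0L) abort("random_init needs at least one observation")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  N <- spec$n_states
  em <- spec$emission

  theta <- vector("list", N)
  for (i in seq_len(N)) {
    q <- if (N == 1) 0.5 else (i - 0.5) / N
    if (!is.null(em$joint)) {
      L <- log(pmax(Y, .Machine$double.eps))  # log scale for log-normal

      ml <- apply(L, 2, quantile, probs = q) + rnorm(ncol(L), 0, 0.25 * apply(L, 2, sd))
      sig <- diag(pmax(apply(L, 2, sd), 1e-3)^2 * runif(ncol(L), 0.5, 1.5), ncol(L))
      theta[[i]] <- list(meanlog = as.numeric(ml), sigmalog = sig)
    } else {
      th <- list()
      for (k in seq_along(em$features)) {
        f <- em$features[[k]]
        yk <- Y[, k]
        s_all <- max(sd(yk), 1e-3)
        th[[f]] <- switch(em$family[[f]],
          normal = c(mean = quantile(yk, q)[[1]] + rnorm(1, 0, 0.3 * s_all),
                     sd = s_all * runif(1, 0.5, 1.5)),
          gamma = {
            pos <- yk[yk > 0]
            if (!length(pos)) pos <- abs(yk) + 1e-3
            c(mean = quantile(pos, q)[[1]] * runif(1, 0.7, 1.4),
              sd = max(sd(pos), 1e-3) * runif(1, 0.5, 1.5))
          },
          shifted_t = c(location = quantile(yk, q)[[1]] + rnorm(1, 0, 0.3 * s_all),
                        df = 2 + abs(rnorm(1, 2, 1)))
        )
      }
      theta[[i]] <- th
    }
  }

  Gamma <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s <- which(spec$support[i, ])
    base <- rep(0.1 / max(length(s) - 1, 1), N)
    base[i] <- 0.9
    base <- base[s] / sum(base[s])
    g <- rgamma(length(s), shape = 30 * base + 0.5)
    Gamma[i, s] <- g / sum(g)
  }
  delta <- NULL
  if (spec$init$mode == "free") {
    g <- rgamma(N, shape = 2)
    delta <- g / sum(g)
  }
  beta <- NULL
  if (spec$label_mode == "categorical") {
    M <- length(spec$label_alphabet)
    beta <- matrix(0, N, M)
    for (i in seq_len(N)) {
      conc <- rep(1, M)
      if (i <= M) conc[i] <- 8
      g <- rgamma(M, shape = conc)
      beta[i, ] <- g / sum(g)
    }
  }
  phmm_params(spec, Gamma = Gamma, theta = theta, delta = delta, beta = beta)
}

#' Fit a weighted-likelihood PHMM by numerical maximum likelihood
#'
#' Maximizes the weighted log-likelihood over the unconstrained working
#' vector (see [pack()]) with BFGS, repeated from `n_restarts` random
#' starting points; the restart with the highest log-likelihood wins. All
#' structural constraints (transition support zeros, ties, fixed parameters,
#' the initial-distribution mode) hold exactly at every iterate.
#'
#' @param data Labelled-series data frame (multiple series allowed via
#'   `series_id`).
#' @param spec A [phmm_spec()].
#' @param alpha Weight in `[0, 1]` on unlabelled observations.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Seed for the restart stream.
#' @param init Optional [phmm_params()] used as the first starting point.
#' @param allow_alpha_gt1 Permit `alpha > 1`.
#' @param control Passed to [stats::optim()] (defaults: BFGS, `maxit = 500`,
#'   `reltol = 1e-9`).
#' @param sort_states When no labels are present and the states are fully
#'   exchangeable, reorder them by the location of the first feature for
#'   reporting (default `TRUE`).
#' @return An object of class `wlphmm_fit` with elements `params`, `loglik`,
#'   `alpha`, `restarts` (per-restart tibble), `spec`, `seed`,
#'   `converged`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' set.seed(1)
#' d <- data.frame(y = c(rnorm(60, -2), rnorm(60, 2)),
#'                 label = rep(NA_character_, 120))
#' spec <- phmm_spec(2, emission_spec("y", family = c(y = "normal")), init = "free")
#' fit <- phmm_fit(d, spec, alpha = 1, n_restarts = 2, seed = 7)
#' glance(fit)
#' @export
phmm_fit <- function(data, spec, alpha, n_restarts = 10, seed = 1,
                     init = NULL, allow_alpha_gt1 = FALSE,
                     control = list(maxit = 500, reltol = 1e-9),
                     sort_states = TRUE) {
  check_alpha(alpha, allow_alpha_gt1)
  guard_identifiability(data, spec, alpha)
  sl <- as_series_list(data, spec)
  n_labels <- sum(label_counts_by_state(sl, spec$n_states))

  negll <- function(w) {
    p <- tryCatch(unpack(w, spec), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    ll <- sum(vapply(sl, function(s) loglik_series(p, spec, s, alpha), numeric(1)))
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  seeds <- derive_seeds(seed, n_restarts + 50L)
  rows <- vector("list", n_restarts)
  best <- NULL
  extra <- n_restarts  # pool of fallback seeds for degenerate inits
  for (r in seq_len(n_restarts)) {
    if (r == 1L && !is.null(init)) {
      p0 <- init
      sd_r <- NA_integer_
    } else {
      sd_r <- seeds[r]
      p0 <- random_init(data, spec, seed = sd_r)
      tries <- 0L
      while (negll(pack(p0, spec)) >= 1e12 && tries < 25L) {
        extra <- extra + 1L
        sd_r <- seeds[extra]
        p0 <- random_init(data, spec, seed = sd_r)
        tries <- tries + 1L
      }
    }
    w0 <- pack(p0, spec)
    f0 <- negll(w0)
    if (f0 >= 1e12) {
      rows[[r]] <- tibble::tibble(restart = r, seed = sd_r, init_loglik = -Inf,
                                  loglik = -Inf, converged = FALSE)
      next
    }
    opt <- optim(w0, negll, method = "BFGS", control = control)
    rows[[r]] <- tibble::tibble(
      restart = r, seed = sd_r, init_loglik = -f0, loglik = -opt$value,
      converged = opt$convergence == 0)
    if (is.null(best) || -opt$value > best$loglik) {
      best <- list(w = opt$par, loglik = -opt$value, restart = r)
    }
  }
  restarts <- dplyr::bind_rows(rows)
  if (is.null(best)) {
    abort("all restarts produced a degenerate (-Inf) likelihood; check labels against the transition support")
  }
  params <- unpack(best$w, spec)
  if (sort_states && n_labels == 0L && states_exchangeable(spec)) {
    params <- canonical_order(params, spec)
  }
  structure(
    list(params = params, loglik = best$loglik, alpha = alpha,
         restarts = restarts, best_restart = best$restart, spec = spec,
         seed = seed, n_obs = sum(vapply(sl, `[[`, integer(1), "Tn")),
         n_series = length(sl), n_labels = n_labels,
         converged = any(restarts$converged),
         control = control),
    class = "wlphmm_fit"
  )
}

# States are exchangeable (reorderable for reporting) only with full support,
# no ties, no fixes, a non-fixed initial distribution and certain labels.
states_exchangeable <- function(spec) {
  all(spec$support) && !length(spec$tie_groups) && !length(spec$fixed) &&
    spec$init$mode != "fixed" && spec$label_mode == "certain"
}

state_location <- function(spec, th) {
  if (!is.null(spec$emission$joint)) return(th$meanlog[1])
  f <- spec$emission$features[[1]]
  p <- th[[f]]
  switch(spec$emission$family[[f]],
    normal = p[["mean"]], gamma = p[["mean"]], shifted_t = p[["location"]])
}

canonical_order <- function(params, spec) {
  loc <- vapply(params$theta, function(th) state_location(spec, th), numeric(1))
  o <- order(loc)
  if (identical(o, seq_along(o))) return(params)
  phmm_params(spec,
    Gamma = params$Gamma[o, o, drop = FALSE],
    theta = params$theta[o],
    delta = if (spec$init$mode == "free") params$delta[o] else NULL,
    beta = if (!is.null(params$beta)) params$beta[o, , drop = FALSE] else NULL)
}

#' @export
print.wlphmm_fit <- function(x, ...) {
  cat(sprintf("PHMM fit: %d states, alpha = %g, log-likelihood %.4f (%d/%d restarts converged)\n",
              x$spec$n_states, x$alpha, x$loglik, sum(x$restarts$converged),
              nrow(x$restarts)))
  print(x$params)
  invisible(x)
}

#' @rdname phmm_fit
#' @param x A `wlphmm_fit`.
#' @param ... Unused.
#' @export
tidy.wlphmm_fit <- function(x, ...) {
  spec <- x$spec
  p <- x$params
  N <- spec$n_states
  rows <- list()
  rows$delta <- tibble::tibble(
    component = "delta", state = spec$state_names, to_state = NA_character_,
    feature = NA_character_, term = "prob", estimate = p$delta)
  g <- expand.grid(i = seq_len(N), j = seq_len(N))
  rows$Gamma <- tibble::tibble(
    component = "Gamma", state = spec$state_names[g$i],
    to_state = spec$state_names[g$j], feature = NA_character_,
    term = "prob", estimate = p$Gamma[cbind(g$i, g$j)])
  em <- list()
  for (i in seq_len(N)) {
    th <- p$theta[[i]]
    if (!is.null(spec$emission$joint)) {
      D <- emission_dim(spec$emission)
      em[[length(em) + 1]] <- tibble::tibble(
        component = "emission", state = spec$state_names[i],
        to_state = NA_character_, feature = spec$emission$features,
        term = "meanlog", estimate = th$meanlog)
      idx <- which(upper.tri(th$sigmalog, diag = TRUE), arr.ind = TRUE)
      em[[length(em) + 1]] <- tibble::tibble(
        component = "emission", state = spec$state_names[i],
        to_state = NA_character_,
        feature = paste(spec$emission$features[idx[, 1]],
                        spec$emission$features[idx[, 2]], sep = ":"),
        term = "sigmalog", estimate = th$sigmalog[idx])
    } else {
      for (f in spec$emission$features) {
        em[[length(em) + 1]] <- tibble::tibble(
          component = "emission", state = spec$state_names[i],
          to_state = NA_character_, feature = f,
          term = names(th[[f]]), estimate = as.numeric(th[[f]]))
      }
    }
  }
  out <- dplyr::bind_rows(c(rows, em))
  if (!is.null(p$beta)) {
    g <- expand.grid(i = seq_len(N), j = seq_along(spec$label_alphabet))
    out <- dplyr::bind_rows(out, tibble::tibble(
      component = "beta", state = spec$state_names[g$i],
      to_state = spec$label_alphabet[g$j], feature = NA_character_,
      term = "prob", estimate = p$beta[cbind(g$i, g$j)]))
  }
  out
}

#' @rdname phmm_fit
#' @export
glance.wlphmm_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, alpha = x$alpha, n_states = x$spec$n_states,
    n_series = x$n_series, n_obs = x$n_obs, n_labels = x$n_labels,
    n_restarts = nrow(x$restarts), converged = x$converged)
}
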