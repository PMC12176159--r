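#' Declare state-dependent emission distributions
#'
#' An emission specification names the observed features and assigns each a
#' distribution family, either conditionally independent given the hidden
#' state (`family` mode) or a joint multivariate log-normal (`joint` mode).
#' Families available per feature:
#'
#' * `"normal"`: mean and standard deviation (`mean`, `sd`).
#' * `"gamma"`: parameterized by `mean` and `sd` (the convention common in
#'   movement ecology) and converted internally to shape/rate; support is
#'   strictly positive reals.
#' * `"shifted_t"`: a Student-t with unit scale shifted by `location`, with
#'   `df` degrees of freedom (`df > 2` so the standard deviation
#'   `sqrt(df / (df - 2))` is finite).
#'
#' Joint mode (`joint = "mvlognormal"`) models the feature vector as
#' multivariate log-normal with per-state mean vector `meanlog` and covariance
#' `sigmalog` on the log scale.
#'
#' @param features Character vector of feature (column) names, in order.
#' @param family Named character vector mapping each feature to a family;
#'   ignored when `joint` is given.
#' @param joint `NULL` (conditional independence across features) or
#'   `"mvlognormal"`.
#' @return An object of class `wlphmm_emission`.
#' @examples
#' emission_spec("y", family = c(y = "normal"))
#' emission_spec(c("max_depth", "duration"), joint = "mvlognormal")
#' @export
emission_spec <- function(features, family = NULL, joint = NULL) {
  stopifnot(is.character(features), length(features) >= 1L)
  if (!is.null(joint)) {
    joint <- match.arg(joint, "mvlognormal")
    family <- NULL
  } else {
    if (is.null(family)) family <- setNames(rep("normal", length(features)), features)
    if (is.null(names(family))) names(family) <- features
    family <- family[features]
    ok <- family %in% c("normal", "gamma", "shifted_t")
    if (any(!ok) || anyNA(family)) {
      abort("each feature needs a family in {'normal', 'gamma', 'shifted_t'}")
    }
  }
  structure(
    list(features = features, family = family, joint = joint),
    class = "wlphmm_emission"
  )
}

emission_dim <- function(emission) length(emission$features)

# Convert the user-facing gamma (mean, sd) parameterization to shape/rate.
# Exact and round-trips: shape = (mean/sd)^2, rate = mean/sd^2.
gamma_shape_rate <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) abort("gamma mean and sd must be strictly positive")
  c(shape = (mean / sd)^2, rate = mean / sd^2)
}

validate_theta_state <- function(emission, th) {
  if (!is.null(emission$joint)) {
    D <- emission_dim(emission)
    if (length(th$meanlog) != D) abort("meanlog has wrong length")
    S <- th$sigmalog
    if (!is.matrix(S) || any(dim(S) != D) || max(abs(S - t(S))) > 1e-8) {
      abort("sigmalog must be a symmetric D x D matrix")
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("sigmalog must be positive definite")
    return(invisible(TRUE))
  }
  for (f in emission$features) {
    p <- th[[f]]
    fam <- emission$family[[f]]
    if (fam == "normal") {
      if (!is.finite(p[["mean"]]) || !is.finite(p[["sd"]]) || p[["sd"]] <= 0) {
        abort(sprintf("normal feature '%s': sd must be positive and finite", f))
      }
    } else if (fam == "gamma") {
      if (p[["mean"]] <= 0 || p[["sd"]] <= 0) {
        abort(sprintf("gamma feature '%s': mean and sd must be positive", f))
      }
    } else {
      if (p[["df"]] <= 2) {
        abort(sprintf("shifted_t feature '%s': df must exceed 2", f))
      }
    }
  }
  invisible(TRUE)
}

#' State-dependent log density of one observation vector
#'
#' Evaluates `log f^(i)(y)` for one state's emission parameters. Returns
#' `-Inf` outside the support (e.g. non-positive values under gamma or
#' log-normal families).
#'
#' @param emission An [emission_spec()].
#' @param theta_state Parameter list for one state (see [emission_spec()] for
#'   the per-family parameter names).
#' @param y Numeric observation vector, one value per feature.
#' @return A single log density.
#' @export
emission_logdensity <- function(emission, theta_state, y) {
  D <- emission_dim(emission)
  if (length(y) != D) abort(sprintf("observation has length %d, expected %d", length(y), D))
  validate_theta_state(emission, theta_state)
  if (!is.null(emission$joint)) {
    if (any(y <= 0)) return(-Inf)
    return(dmvnorm_log(log(y), theta_state$meanlog, theta_state$sigmalog) - sum(log(y)))
  }
  ll <- 0
  for (k in seq_len(D)) {
    f <- emission$features[[k]]
    p <- theta_state[[f]]
    ll <- ll + switch(emission$family[[f]],
      normal = dnorm(y[k], p[["mean"]], p[["sd"]], log = TRUE),
      gamma = {
        sr <- gamma_shape_rate(p[["mean"]], p[["sd"]])
        if (y[k] <= 0) -Inf else dgamma(y[k], shape = sr[["shape"]], rate = sr[["rate"]], log = TRUE)
      },
      shifted_t = dt(y[k] - p[["location"]], df = p[["df"]], log = TRUE)
    )
  }
  ll
}

# Vectorized T x N matrix of log f^(i)(y_t); rows with all-NA observations
# (missing steps) get 0 so they contribute only transition/label factors.
emission_logdens_matrix <- function(emission, theta, Y) {
  Tn <- nrow(Y)
  N <- length(theta)
  out <- matrix(0, Tn, N)
  miss <- rowSums(!is.na(Y)) == 0L
  obs <- which(!miss)
  if (length(obs) == 0L) return(out)
  if (!is.null(emission$joint)) {
    for (i in seq_len(N)) {
      out[obs, i] <- vapply(obs, function(t) {
        emission_logdensity(emission, theta[[i]], Y[t, ])
      }, numeric(1))
    }
    return(out)
  }
  for (i in seq_len(N)) {
    acc <- numeric(length(obs))
    for (k in seq_along(emission$features)) {
      f <- emission$features[[k]]
      p <- theta[[i]][[f]]
      yk <- Y[obs, k]
      acc <- acc + switch(emission$family[[f]],
        normal = dnorm(yk, p[["mean"]], p[["sd"]], log = TRUE),
        gamma = {
          sr <- gamma_shape_rate(p[["mean"]], p[["sd"]])
          ifelse(yk <= 0, -Inf,
                 dgamma(pmax(yk, .Machine$double.xmin), shape = sr[["shape"]],
                        rate = sr[["rate"]], log = TRUE))
        },
        shifted_t = dt(yk - p[["location"]], df = p[["df"]], log = TRUE)
      )
    }
    out[obs, i] <- acc
  }
  out
}

# Draw n observations from one state's emission.
emission_sample <- function(emission, theta_state, n) {
  D <- emission_dim(emission)
  if (!is.null(emission$joint)) {
    Y <- t(vapply(seq_len(n), function(j) {
      exp(rmvnorm_one(theta_state$meanlog, theta_state$sigmalog))
    }, numeric(D)))
    colnames(Y) <- emission$features
    return(Y)
  }
  Y <- matrix(NA_real_, n, D, dimnames = list(NULL, emission$features))
  for (k in seq_len(D)) {
    f <- emission$features[[k]]
    p <- theta_state[[f]]
    Y[, k] <- switch(emission$family[[f]],
      normal = rnorm(n, p[["mean"]], p[["sd"]]),
      gamma = {
        sr <- gamma_shape_rate(p[["mean"]], p[["sd"]])
        rgamma(n, shape = sr[["shape"]], rate = sr[["rate"]])
      },
      shifted_t = p[["location"]] + rt(n, df = p[["df"]])
    )
  }
  Y
}
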