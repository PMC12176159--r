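#' Log mass of a label given the hidden state
#'
#' Under the certain-label rule a labelled step's label equals its hidden
#' state with probability 1, so the log mass is `0` when the label is absent
#' or equals the state and `-Inf` otherwise. Under the categorical rule an
#' absent label has mass 1 and an observed label `z` has mass
#' `beta[state, z]`.
#'
#' @param spec A [phmm_spec()].
#' @param state Hidden-state index in `1..N`.
#' @param z Label index in the alphabet, or `NA` for an unlabelled step.
#' @param beta Per-state label probability matrix (categorical mode).
#' @return A log probability mass.
#' @export
label_logmass <- function(spec, state, z, beta = NULL) {
  stopifnot(state >= 1L, state <= spec$n_states)
  if (is.na(z)) return(0)
  z <- as.integer(z)
  if (z < 1L || z > length(spec$label_alphabet)) abort("label out of alphabet")
  if (spec$label_mode == "certain") {
    if (z == state) 0 else -Inf
  } else {
    if (is.null(beta)) abort("categorical label mode needs beta")
    log(beta[state, z])
  }
}

# T x N matrix of log g^(i)(z_t).
label_logmass_matrix <- function(spec, z, beta = NULL) {
  Tn <- length(z)
  N <- spec$n_states
  out <- matrix(0, Tn, N)
  lab <- which(!is.na(z))
  if (!length(lab)) return(out)
  if (spec$label_mode == "certain") {
    for (t in lab) {
      out[t, ] <- -Inf
      out[t, z[t]] <- 0
    }
  } else {
    lb <- log(beta)
    for (t in lab) out[t, ] <- lb[, z[t]]
  }
  out
}

#' Likelihood weight of one time step
#'
#' Labelled steps always receive weight 1; unlabelled steps receive the
#' down-weighting factor `alpha`. Weights above 1 (more weight on unlabelled
#' than labelled data) are rejected unless explicitly allowed.
#'
#' @param z Label vector (`NA` = unlabelled); any type, only missingness is
#'   used.
#' @param alpha Weight in `[0, 1]` applied to unlabelled steps.
#' @param allow_alpha_gt1 Permit `alpha > 1` (advised against; off by
#'   default).
#' @return Numeric weight vector the same length as `z`.
#' @export
observation_weight <- function(z, alpha, allow_alpha_gt1 = FALSE) {
  check_alpha(alpha, allow_alpha_gt1)
  ifelse(is.na(z), alpha, 1)
}

check_alpha <- function(alpha, allow_alpha_gt1 = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    abort("alpha must be a single number in [0, 1]")
  }
  if (alpha > 1 && !allow_alpha_gt1) {
    abort("alpha > 1 gives unlabelled steps more weight than labelled ones; set allow_alpha_gt1 = TRUE to override")
  }
  invisible(alpha)
}

# Weighted per-step log emission+label terms: w_t * (log f + log g), with a
# zero weight producing exactly 0 (the step contributes only a Gamma factor).
weighted_logb <- function(spec, params, s, alpha) {
  lf <- emission_logdens_matrix(spec$emission, params$theta, s$y)
  lg <- label_logmass_matrix(spec, s$z, params$beta)
  w <- ifelse(is.na(s$z), alpha, 1)
  b <- lf + lg
  out <- b * w
  if (any(w == 0)) out[w == 0, ] <- 0
  out
}

# Pure-R log-space forward recursion (reference route; O(T N^2) logsumexp).
forward_loglik_r <- function(logwb, delta, Gamma) {
  Tn <- nrow(logwb)
  N <- ncol(logwb)
  lG <- log(Gamma)
  la <- log(delta) + logwb[1, ]
  if (Tn > 1) {
    for (t in 2:Tn) {
      la <- vapply(seq_len(N), function(j) {
        v <- la + lG[, j]
        m <- max(v)
        if (m == -Inf) -Inf else m + log(sum(exp(v - m)))
      }, numeric(1)) + logwb[t, ]
    }
  }
  m <- max(la)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(la - m)))
}

loglik_series <- function(params, spec, s, alpha, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  logwb <- weighted_logb(spec, params, s, alpha)
  if (engine == "cpp") {
    forward_loglik_cpp(logwb, params$delta, params$Gamma)
  } else {
    forward_loglik_r(logwb, params$delta, params$Gamma)
  }
}

#' Weighted PHMM log-likelihood of a labelled data set
#'
#' Computes the weighted log-likelihood in which every unlabelled time step's
#' emission term enters raised to the power `alpha` (labels, when present,
#' always at full weight), summed over independent series. At `alpha = 1` this
#' is the log of the joint density of observations and labels; at `alpha = 0`
#' it equals the log-likelihood of an HMM that treats all unlabelled
#' observations as totally missing; for a fully labelled series the value does
#' not depend on `alpha`.
#'
#' The recursion is scaled per step and accumulated in log space, so series of
#' length 20000 and more evaluate without underflow. A series whose labels are
#' jointly impossible under the transition support yields `-Inf` with a
#' warning rather than an error.
#'
#' @param data Labelled-series data frame (columns `series_id` (optional),
#'   `t` (optional), the spec's features, `label` with `NA`/`""` for
#'   unlabelled steps).
#' @param spec A [phmm_spec()].
#' @param params A [phmm_params()] point.
#' @param alpha Weight in `[0, 1]` on unlabelled steps.
#' @param allow_alpha_gt1 Permit `alpha > 1` (off by default).
#' @param engine `"cpp"` (scaled recursion, default) or `"r"` (log-space
#'   reference implementation).
#' @return Total log-likelihood (a single number), with attribute
#'   `"by_series"`, a tibble of per-series contributions.
#' @examples
#' spec <- phmm_spec(2, emission_spec("y", family = c(y = "normal")), init = "free")
#' pars <- phmm_params(spec,
#'   Gamma = matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
#'   theta = list(list(y = c(mean = -1, sd = 1)), list(y = c(mean = 1, sd = 1))),
#'   delta = c(.5, .5))
#' d <- data.frame(y = c(-1.2, 0.4, 1.1), label = c("state1", NA, NA))
#' phmm_loglik(d, spec, pars, alpha = 0.5)
#' @export
phmm_loglik <- function(data, spec, params, alpha,
                        allow_alpha_gt1 = FALSE, engine = c("cpp", "r")) {
  check_alpha(alpha, allow_alpha_gt1)
  engine <- match.arg(engine)
  sl <- as_series_list(data, spec)
  per <- vapply(sl, function(s) loglik_series(params, spec, s, alpha, engine), numeric(1))
  if (any(!is.finite(per))) {
    warn(sprintf(
      "series %s: labels are jointly impossible under the transition support (log-likelihood -Inf)",
      paste(vapply(sl[!is.finite(per)], `[[`, "", "id"), collapse = ", ")))
  }
  total <- sum(per)
  attr(total, "by_series") <- tibble::tibble(
    series_id = vapply(sl, `[[`, "", "id"), loglik = per)
  total
}
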