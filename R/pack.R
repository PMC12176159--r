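# Transform between constrained PHMM parameters and a flat unconstrained
# working vector for the optimizer.
#
# Layout (in order):
#   * each transition row: log-ratio logits over its supported entries,
#     reference = first supported entry (rows with one supported entry
#     contribute nothing, preserving structural zeros exactly);
#   * delta logits (free-initial-distribution mode only);
#   * one emission block per tie-group representative, per feature:
#       normal     mean (raw), log sd
#       gamma      log mean, log sd
#       shifted_t  location (raw), log(df - 2)
#       mvlognormal: meanlog (raw), log-Cholesky of sigmalog
#     with parameters pinned by `fixed` omitted;
#   * beta logits per state (categorical label mode only).

emission_blocks <- function(spec) sort(unique(tie_representative(spec)))

is_fixed_param <- function(spec, state, feature, param, index = 1L) {
  rep_of <- tie_representative(spec)
  for (fx in spec$fixed) {
    if (rep_of[fx$state] != rep_of[state]) next
    if (is.null(feature) && is.null(fx$feature)) {
      if (fx$param == param && (fx$index %||% 1L) == index) return(TRUE)
    } else if (!is.null(feature) && !is.null(fx$feature)) {
      if (fx$feature == feature && fx$param == param) return(TRUE)
    }
  }
  FALSE
}

#' Flatten PHMM parameters to an unconstrained working vector
#'
#' `pack()` and `unpack()` are exact inverses on valid parameter points;
#' `unpack()` always returns a parameter point satisfying every structural
#' constraint (row-stochastic rows via softmax over supported entries only,
#' positive scales via log transforms, ties and fixes re-applied).
#'
#' @param params A [phmm_params()] point.
#' @param spec The matching [phmm_spec()].
#' @return `pack()`: a named numeric vector; `unpack()`: a `wlphmm_params`.
#' @export
pack <- function(params, spec) {
  w <- numeric(0)
  nm <- character(0)
  N <- spec$n_states
  eps <- 1e-300
  for (i in seq_len(N)) {
    s <- which(spec$support[i, ])
    if (length(s) > 1) {
      v <- log(pmax(params$Gamma[i, s[-1]], eps) / pmax(params$Gamma[i, s[1]], eps))
      w <- c(w, v)
      nm <- c(nm, paste0("Gamma", i, ".", s[-1]))
    }
  }
  if (spec$init$mode == "free" && N > 1) {
    v <- log(pmax(params$delta[-1], eps) / pmax(params$delta[1], eps))
    w <- c(w, v)
    nm <- c(nm, paste0("delta", 2:N))
  }
  for (i in emission_blocks(spec)) {
    th <- params$theta[[i]]
    if (!is.null(spec$emission$joint)) {
      D <- emission_dim(spec$emission)
      for (k in seq_len(D)) {
        if (is_fixed_param(spec, i, NULL, "meanlog", k)) next
        w <- c(w, th$meanlog[k]); nm <- c(nm, sprintf("s%d.meanlog%d", i, k))
      }
      R <- chol(th$sigmalog)
      for (k in seq_len(D)) {
        w <- c(w, log(R[k, k])); nm <- c(nm, sprintf("s%d.lchol%d%d", i, k, k))
      }
      if (D > 1) {
        for (k in seq_len(D - 1)) for (l in (k + 1):D) {
          w <- c(w, R[k, l]); nm <- c(nm, sprintf("s%d.chol%d%d", i, k, l))
        }
      }
    } else {
      for (f in spec$emission$features) {
        p <- th[[f]]
        coords <- switch(spec$emission$family[[f]],
          normal = list(mean = p[["mean"]], sd = log(p[["sd"]])),
          gamma = list(mean = log(p[["mean"]]), sd = log(p[["sd"]])),
          shifted_t = list(location = p[["location"]], df = log(p[["df"]] - 2))
        )
        for (pn in names(coords)) {
          if (is_fixed_param(spec, i, f, pn)) next
          w <- c(w, coords[[pn]]); nm <- c(nm, sprintf("s%d.%s.%s", i, f, pn))
        }
      }
    }
  }
  if (spec$label_mode == "categorical") {
    M <- length(spec$label_alphabet)
    for (i in seq_len(N)) {
      v <- log(pmax(params$beta[i, -1], eps) / pmax(params$beta[i, 1], eps))
      w <- c(w, v); nm <- c(nm, paste0("beta", i, ".", 2:M))
    }
  }
  setNames(w, nm)
}

#' @param w A working vector produced by `pack()` (or any numeric vector of
#'   the same length).
#' @rdname pack
#' @export
unpack <- function(w, spec) {
  N <- spec$n_states
  pos <- 0L
  take <- function(k) {
    out <- w[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  Gamma <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s <- which(spec$support[i, ])
    if (length(s) == 1) {
      Gamma[i, s] <- 1
    } else {
      Gamma[i, s] <- softmax_ref(take(length(s) - 1))
    }
  }
  delta <- NULL
  if (spec$init$mode == "free" && N > 1) delta <- softmax_ref(take(N - 1))
  theta <- vector("list", N)
  for (i in emission_blocks(spec)) {
    if (!is.null(spec$emission$joint)) {
      D <- emission_dim(spec$emission)
      meanlog <- numeric(D)
      for (k in seq_len(D)) {
        meanlog[k] <- if (is_fixed_param(spec, i, NULL, "meanlog", k)) 0 else take(1)
      }
      R <- matrix(0, D, D)
      for (k in seq_len(D)) R[k, k] <- exp(take(1))
      if (D > 1) {
        for (k in seq_len(D - 1)) for (l in (k + 1):D) R[k, l] <- take(1)
      }
      theta[[i]] <- list(meanlog = meanlog, sigmalog = t(R) %*% R)
    } else {
      th <- list()
      for (f in spec$emission$features) {
        fam <- spec$emission$family[[f]]
        names_f <- switch(fam,
          normal = c("mean", "sd"), gamma = c("mean", "sd"),
          shifted_t = c("location", "df"))
        p <- setNames(numeric(2), names_f)
        for (pn in names_f) {
          raw <- if (is_fixed_param(spec, i, f, pn)) 0 else take(1)
          p[[pn]] <- switch(fam,
            normal = if (pn == "sd") exp(raw) else raw,
            gamma = exp(raw),
            shifted_t = if (pn == "df") 2 + exp(raw) else raw
          )
        }
        th[[f]] <- p
      }
      theta[[i]] <- th
    }
  }
  # non-representative states: filled from their representative by phmm_params
  rep_of <- tie_representative(spec)
  for (i in seq_len(N)) if (is.null(theta[[i]])) theta[[i]] <- theta[[rep_of[i]]]
  beta <- NULL
  if (spec$label_mode == "categorical") {
    M <- length(spec$label_alphabet)
    beta <- matrix(0, N, M)
    for (i in seq_len(N)) beta[i, ] <- softmax_ref(take(M - 1))
  }
  if (pos != length(w)) abort("working vector has wrong length for this spec")
  phmm_params(spec, Gamma = Gamma, theta = theta, delta = delta, beta = beta)
}
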