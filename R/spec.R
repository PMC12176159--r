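#' Specify the structure of a partially hidden Markov model
#'
#' A model specification collects everything structural about a PHMM: the
#' number of hidden states, their names, the emission families, the label
#' rule, the transition support mask (which entries of the transition matrix
#' may be nonzero), how the initial distribution is handled, and any parameter
#' ties or fixes.
#'
#' @param n_states Number of hidden states `N`.
#' @param emission An [emission_spec()].
#' @param state_names Character vector of length `N`; defaults to
#'   `"state1" ... "stateN"`.
#' @param label_mode `"certain"` (a labelled step's label equals its hidden
#'   state with probability 1) or `"categorical"` (per-state label probability
#'   vectors `beta` over `label_alphabet`, estimated from data).
#' @param label_alphabet Label values for categorical mode; defaults to the
#'   state names.
#' @param support `N x N` logical matrix, `TRUE` where the transition
#'   probability may be nonzero. Every row needs at least one `TRUE`. Default
#'   all `TRUE`.
#' @param init `"free"` (estimated), `"stationary"` (the stationary
#'   distribution of the fitted transition matrix), or a fixed probability
#'   vector of length `N`.
#' @param tie_groups List of integer vectors; states in one group share all
#'   emission parameters. Groups must be disjoint.
#' @param fixed List of fixes, each `list(state=, feature=, param=, value=)`,
#'   pinning one emission parameter (applied to the whole tie group of that
#'   state). Use `feature = NULL, param = "meanlog", index = k` style entries
#'   for joint emissions.
#' @return An object of class `wlphmm_spec`.
#' @examples
#' phmm_spec(2, emission_spec("y", family = c(y = "normal")))
#' @export
phmm_spec <- function(n_states, emission, state_names = NULL,
                      label_mode = c("certain", "categorical"),
                      label_alphabet = NULL, support = NULL,
                      init = "stationary", tie_groups = list(),
                      fixed = list()) {
  stopifnot(n_states >= 1L)
  label_mode <- match.arg(label_mode)
  if (!inherits(emission, "wlphmm_emission")) abort("emission must come from emission_spec()")
  if (is.null(state_names)) state_names <- paste0("state", seq_len(n_states))
  stopifnot(length(state_names) == n_states)
  if (is.null(support)) support <- matrix(TRUE, n_states, n_states)
  support <- matrix(as.logical(support), n_states, n_states)
  if (any(rowSums(support) < 1)) abort("every support row needs at least one TRUE entry")
  if (is.numeric(init)) {
    if (!is_prob_vector(init)) abort("fixed initial distribution must be a probability vector")
    init <- list(mode = "fixed", vector = init)
  } else {
    init <- list(mode = match.arg(init, c("free", "stationary", "fixed")), vector = NULL)
  }
  if (label_mode == "certain") {
    label_alphabet <- state_names
  } else if (is.null(label_alphabet)) {
    label_alphabet <- state_names
  }
  if (length(tie_groups)) {
    all_t <- unlist(tie_groups)
    if (anyDuplicated(all_t)) abort("tie groups must be disjoint")
    if (any(all_t < 1 | all_t > n_states)) abort("tie group state index out of range")
  }
  structure(
    list(
      n_states = as.integer(n_states), state_names = state_names,
      emission = emission, label_mode = label_mode,
      label_alphabet = label_alphabet, support = support, init = init,
      tie_groups = lapply(tie_groups, function(g) sort(as.integer(g))),
      fixed = fixed
    ),
    class = "wlphmm_spec"
  )
}

#' @export
print.wlphmm_spec <- function(x, ...) {
  cat(sprintf("PHMM specification: %d states (%s)\n", x$n_states,
              paste(x$state_names, collapse = ", ")))
  cat(sprintf("  emission: %s on (%s)\n",
              if (is.null(x$emission$joint)) paste(x$emission$family, collapse = " x ")
              else x$emission$joint,
              paste(x$emission$features, collapse = ", ")))
  cat(sprintf("  labels: %s; init: %s; %d structural zeros\n",
              x$label_mode, x$init$mode, sum(!x$support)))
  invisible(x)
}

# Map each state to its tie-group representative (the smallest member).
tie_representative <- function(spec) {
  rep_of <- seq_len(spec$n_states)
  for (g in spec$tie_groups) rep_of[g] <- min(g)
  rep_of
}

#' Assemble and validate a concrete PHMM parameter point
#'
#' @param spec A [phmm_spec()].
#' @param delta Initial distribution (ignored and recomputed when the spec
#'   says `"stationary"` or `"fixed"`).
#' @param Gamma `N x N` row-stochastic transition matrix honouring the
#'   support mask.
#' @param theta List of per-state emission parameter lists.
#' @param beta Per-state label probability rows (categorical mode only).
#' @return A validated object of class `wlphmm_params`.
#' @export
phmm_params <- function(spec, Gamma, theta, delta = NULL, beta = NULL) {
  N <- spec$n_states
  Gamma <- matrix(as.numeric(Gamma), N, N)
  if (any(abs(rowSums(Gamma) - 1) > 1e-10)) abort("Gamma rows must sum to 1")
  if (any(Gamma < 0)) abort("Gamma entries must be non-negative")
  if (any(Gamma[!spec$support] != 0)) abort("Gamma violates the support mask")
  if (spec$init$mode == "stationary") {
    delta <- stationary_dist(Gamma)
  } else if (spec$init$mode == "fixed") {
    delta <- spec$init$vector
  }
  if (is.null(delta)) delta <- rep(1 / N, N)
  if (!is_prob_vector(delta)) abort("delta must be a probability vector")
  if (length(theta) != N) abort("theta needs one entry per state")
  rep_of <- tie_representative(spec)
  theta <- theta[rep_of]  # enforce ties structurally
  theta <- apply_fixes(spec, theta)
  for (i in seq_len(N)) validate_theta_state(spec$emission, theta[[i]])
  if (spec$label_mode == "categorical") {
    if (is.null(beta)) abort("categorical label mode needs beta")
    beta <- matrix(as.numeric(beta), N, length(spec$label_alphabet))
    if (any(beta < 0) || any(abs(rowSums(beta) - 1) > 1e-8)) {
      abort("beta rows must be probability vectors")
    }
  } else {
    beta <- NULL
  }
  structure(
    list(delta = as.numeric(delta), Gamma = Gamma, theta = theta, beta = beta),
    class = "wlphmm_params"
  )
}

# Pin fixed parameters; a fix on any member of a tie group applies to all.
apply_fixes <- function(spec, theta) {
  if (!length(spec$fixed)) return(theta)
  rep_of <- tie_representative(spec)
  for (fx in spec$fixed) {
    states <- which(rep_of == rep_of[fx$state])
    for (i in states) {
      if (is.null(fx$feature)) {
        theta[[i]][[fx$param]][fx$index %||% 1L] <- fx$value
      } else {
        theta[[i]][[fx$feature]][[fx$param]] <- fx$value
      }
    }
  }
  theta
}

#' @export
print.wlphmm_params <- function(x, ...) {
  cat("PHMM parameters\n  delta:", round(x$delta, 4), "\n  Gamma:\n")
  print(round(x$Gamma, 4))
  invisible(x)
}
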