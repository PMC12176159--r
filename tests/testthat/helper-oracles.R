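# Independent oracles: brute-force path enumeration over all N^T hidden
# paths, used to check the recursive implementations on tiny instances.
# These never call the package's forward/backward/Viterbi code paths.

all_paths <- function(N, Tn) {
  as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
}

# Per-path log weight: log delta(x1) + sum log Gamma + sum w_t*(log f + log g).
path_logweights <- function(params, spec, y, z, alpha, use_labels = TRUE) {
  Tn <- nrow(y)
  N <- spec$n_states
  paths <- all_paths(N, Tn)
  lf <- sapply(seq_len(N), function(i) {
    sapply(seq_len(Tn), function(t) {
      emission_logdensity(spec$emission, params$theta[[i]], y[t, ])
    })
  })
  lf <- matrix(lf, Tn, N)
  lg <- matrix(0, Tn, N)
  if (use_labels) {
    for (t in seq_len(Tn)) {
      for (i in seq_len(N)) lg[t, i] <- label_logmass(spec, i, z[t], params$beta)
    }
  }
  w <- ifelse(is.na(z), alpha, 1)
  apply(paths, 1, function(x) {
    lp <- log(params$delta[x[1]])
    if (Tn > 1) {
      for (t in 2:Tn) lp <- lp + log(params$Gamma[x[t - 1], x[t]])
    }
    for (t in seq_len(Tn)) {
      b <- lf[t, x[t]] + lg[t, x[t]]
      lp <- lp + if (w[t] == 0) 0 else w[t] * b
    }
    lp
  })
}

brute_loglik <- function(params, spec, y, z, alpha) {
  lw <- path_logweights(params, spec, y, z, alpha)
  m <- max(lw)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(lw - m)))
}

brute_posterior <- function(params, spec, y, z, use_labels = FALSE) {
  Tn <- nrow(y)
  N <- spec$n_states
  lw <- path_logweights(params, spec, y, z, alpha = 1, use_labels = use_labels)
  paths <- all_paths(N, Tn)
  w <- exp(lw - max(lw))
  post <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) {
    for (i in seq_len(N)) post[t, i] <- sum(w[paths[, t] == i])
  }
  post / rowSums(post)
}

brute_viterbi <- function(params, spec, y, z, use_labels = FALSE) {
  lw <- path_logweights(params, spec, y, z, alpha = 1, use_labels = use_labels)
  paths <- all_paths(spec$n_states, nrow(y))
  k <- which.max(lw)
  list(path = as.integer(paths[k, ]), logp = lw[k])
}

# Independently coded missing-data HMM log-likelihood: unlabelled steps
# contribute a bare transition factor, labelled steps a diagonal f*g factor.
# Dense matrix products, no scaling (small instances only).
missing_data_loglik <- function(params, spec, y, z) {
  Tn <- nrow(y)
  N <- spec$n_states
  Pt <- function(t) {
    if (is.na(z[t])) return(diag(N))
    d <- vapply(seq_len(N), function(i) {
      exp(emission_logdensity(spec$emission, params$theta[[i]], y[t, ]) +
            label_logmass(spec, i, z[t], params$beta))
    }, numeric(1))
    diag(d, N)
  }
  v <- matrix(params$delta, 1) %*% Pt(1)
  if (Tn > 1) for (t in 2:Tn) v <- v %*% params$Gamma %*% Pt(t)
  log(sum(v))
}

# Trapezoidal ROC-area oracle, coded independently of auc_score().
trapezoid_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(c) mean(scores[truth] >= c), numeric(1))
  fpr <- vapply(th, function(c) mean(scores[!truth] >= c), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Random small PHMM instance for oracle comparisons.
random_instance <- function(seed, max_states = 3, max_T = 8, label_prob = 0.3) {
  set.seed(seed)
  N <- sample(2:max_states, 1)
  Tn <- sample(2:max_T, 1)
  spec <- phmm_spec(N, emission_spec("y", family = c(y = "normal")), init = "free")
  theta <- lapply(seq_len(N), function(i) {
    list(y = c(mean = rnorm(1, 0, 2), sd = runif(1, 0.5, 2)))
  })
  G <- matrix(rgamma(N * N, 1) + 0.05, N)
  G <- G / rowSums(G)
  delta <- rgamma(N, 1) + 0.05
  params <- phmm_params(spec, Gamma = G, theta = theta, delta = delta / sum(delta))
  x <- sample.int(N, Tn, replace = TRUE)
  y <- matrix(rnorm(Tn, c(-2, 0, 2)[x], 1), ncol = 1, dimnames = list(NULL, "y"))
  z <- ifelse(runif(Tn) < label_prob, x, NA_integer_)
  list(spec = spec, params = params, y = y, z = z,
       data = data.frame(y = y[, 1], label = z))
}
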