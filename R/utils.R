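# Internal helpers shared across modules.

# Draw `n` child seeds from a single user seed via a counter-based stream, so
# replicates / restarts are individually re-runnable.  Values stay below 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Wrap angular differences to (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Softmax with an implicit reference coordinate of 0 prepended.
softmax_ref <- function(free) {
  z <- c(0, free)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

is_prob_vector <- function(p, tol = 1e-10) {
  is.numeric(p) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_dist <- function(Gamma) {
  N <- nrow(Gamma)
  A <- t(diag(N) - Gamma)
  A <- rbind(A, rep(1, N))
  b <- c(rep(0, N), 1)
  qr.solve(A, b)
}

# Log density of a multivariate normal via Cholesky.
dmvnorm_log <- function(x, mean, sigma) {
  ch <- chol(sigma)
  d <- length(mean)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# One multivariate normal draw via Cholesky.
rmvnorm_one <- function(mean, sigma) {
  as.numeric(mean + t(chol(sigma)) %*% rnorm(length(mean)))
}
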