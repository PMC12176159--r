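test_that("certain-rule label mass follows the label-equals-state rule", {
  spec <- phmm_spec(3, emission_spec("y", family = c(y = "normal")))
  expect_identical(label_logmass(spec, 2, NA), 0)
  expect_identical(label_logmass(spec, 2, 2L), 0)
  expect_identical(label_logmass(spec, 2, 3L), -Inf)
  # categorical mode reads beta
  specc <- phmm_spec(2, emission_spec("y", family = c(y = "normal")),
                     label_mode = "categorical")
  beta <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  expect_identical(label_logmass(specc, 1, NA, beta), 0)
  expect_equal(label_logmass(specc, 2, 1L, beta), log(0.3))
})

test_that("observation weights are 1 on labels, alpha elsewhere", {
  expect_equal(observation_weight(c(3L, NA, 1L), 0.01), c(1, 0.01, 1))
  expect_equal(observation_weight(NA, 1), 1)
  expect_error(observation_weight(NA, -0.1), "alpha")
  expect_error(observation_weight(NA, 1.5), "alpha")
  expect_equal(observation_weight(NA, 1.5, allow_alpha_gt1 = TRUE), 1.5)
})

test_that("alpha = 0 with no labels gives log-likelihood 0 (row-stochastic collapse)", {
  p <- gauss2_params()
  d <- data.frame(y = rnorm(200))
  ll <- phmm_loglik(d, gauss2_spec(), p, alpha = 0)
  expect_equal(as.numeric(ll), 0, tolerance = 1e-12)
})

test_that("single-step half-weight likelihood matches the direct formula", {
  p <- gauss2_params(delta = c(0.3, 0.7))
  d <- data.frame(y = 0.4)
  ll <- phmm_loglik(d, gauss2_spec(), p, alpha = 0.5)
  direct <- log(0.3 * dnorm(0.4, -1.5, 1)^0.5 + 0.7 * dnorm(0.4, 1.5, 1)^0.5)
  expect_equal(as.numeric(ll), direct, tolerance = 1e-12)
})

test_that("weighted likelihood agrees with brute-force path enumeration", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    for (alpha in c(0, 0.3, 1)) {
      ll <- phmm_loglik(inst$data, inst$spec, inst$params, alpha = alpha)
      expect_equal(as.numeric(ll),
                   brute_loglik(inst$params, inst$spec, inst$y, inst$z, alpha),
                   tolerance = 1e-8)
    }
  }
})

test_that("alpha = 0 reduces to the independently coded missing-data HMM likelihood", {
  for (seed in 26:40) {
    inst <- random_instance(seed)
    ll <- phmm_loglik(inst$data, inst$spec, inst$params, alpha = 0)
    expect_equal(as.numeric(ll),
                 missing_data_loglik(inst$params, inst$spec, inst$y, inst$z),
                 tolerance = 1e-10)
  }
})

test_that("a fully labelled series has an alpha-invariant likelihood", {
  inst <- random_instance(41, label_prob = 1)
  ref <- as.numeric(phmm_loglik(inst$data, inst$spec, inst$params, alpha = 1))
  for (alpha in c(0, 0.2, 0.5, 0.8)) {
    expect_equal(as.numeric(phmm_loglik(inst$data, inst$spec, inst$params, alpha)),
                 ref, tolerance = 1e-10)
  }
})

test_that("alpha = 1 with no labels equals the classical HMM density", {
  p <- gauss2_params(delta = c(0.4, 0.6))
  set.seed(5)
  y <- rnorm(6)
  # dense matrix-product density: delta P(y1) prod Gamma P(yt) 1'
  P <- function(yt) diag(c(dnorm(yt, -1.5, 1), dnorm(yt, 1.5, 1)))
  v <- matrix(p$delta, 1) %*% P(y[1])
  for (t in 2:6) v <- v %*% p$Gamma %*% P(y[t])
  ll <- phmm_loglik(data.frame(y = y), gauss2_spec(), p, alpha = 1)
  expect_equal(exp(as.numeric(ll)), sum(v), tolerance = 1e-10)
})

test_that("scaled C++ and log-space R recursions agree", {
  for (seed in 42:52) {
    inst <- random_instance(seed)
    for (alpha in c(0.1, 1)) {
      expect_equal(
        as.numeric(phmm_loglik(inst$data, inst$spec, inst$params, alpha, engine = "cpp")),
        as.numeric(phmm_loglik(inst$data, inst$spec, inst$params, alpha, engine = "r")),
        tolerance = 1e-8)
    }
  }
})

test_that("the total likelihood is the sum over series, order-invariant", {
  i1 <- random_instance(60)
  i2 <- random_instance(61)
  # same spec shape is required across series; use instance 1's params
  d1 <- data.frame(series_id = "a", i1$data)
  d2 <- data.frame(series_id = "b", i2$data[, "y", drop = FALSE],
                   label = NA_integer_)
  spec <- i1$spec
  if (i2$spec$n_states != spec$n_states) d2$label <- NA_integer_
  both <- dplyr::bind_rows(d1, d2)
  ll_ab <- phmm_loglik(both, spec, i1$params, alpha = 0.5)
  ll_ba <- phmm_loglik(dplyr::bind_rows(d2, d1), spec, i1$params, alpha = 0.5)
  expect_equal(as.numeric(ll_ab),
               as.numeric(phmm_loglik(d1, spec, i1$params, 0.5)) +
                 as.numeric(phmm_loglik(d2, spec, i1$params, 0.5)))
  expect_equal(as.numeric(ll_ab), as.numeric(ll_ba))
  expect_error(phmm_loglik(both[0, ], spec, i1$params, 0.5), "rows")
})

test_that("no underflow on long series and impossible labels warn with -Inf", {
  p <- gauss2_params()
  d <- gauss2_data(20000, seed = 9)
  ll <- phmm_loglik(d[, c("y", "label")], gauss2_spec(), p, alpha = 1)
  expect_true(is.finite(ll))
  # labels impossible under a support mask that forbids leaving state 2
  spec <- phmm_spec(2, emission_spec("y", family = c(y = "normal")),
                    support = rbind(c(TRUE, TRUE), c(FALSE, TRUE)), init = "free")
  pars <- phmm_params(spec, Gamma = rbind(c(0.5, 0.5), c(0, 1)),
                      theta = list(list(y = c(mean = 0, sd = 1)),
                                   list(y = c(mean = 1, sd = 1))),
                      delta = c(0.5, 0.5))
  bad <- data.frame(y = rnorm(4), label = c(NA, 2L, 1L, NA))
  expect_warning(ll2 <- phmm_loglik(bad, spec, pars, alpha = 1), "impossible")
  expect_identical(as.numeric(ll2), -Inf)
})

test_that("missing observation steps contribute only transition and label factors", {
  p <- gauss2_params(delta = c(0.5, 0.5))
  spec <- gauss2_spec()
  d <- data.frame(y = c(0.2, NA, -0.5), label = c(NA, 2L, NA))
  ll <- phmm_loglik(d, spec, p, alpha = 1)
  # oracle: sum over paths, f-term of step 2 replaced by 1, g pins x2 = 2
  total <- 0
  for (x1 in 1:2) for (x3 in 1:2) {
    total <- total + p$delta[x1] * dnorm(0.2, c(-1.5, 1.5)[x1], 1) *
      p$Gamma[x1, 2] * p$Gamma[2, x3] * dnorm(-0.5, c(-1.5, 1.5)[x3], 1)
  }
  expect_equal(as.numeric(ll), log(total), tolerance = 1e-10)
})
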