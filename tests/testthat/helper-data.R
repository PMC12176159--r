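# Shared fixture builders (all generated in code at test time).

gauss2_spec <- function() {
  phmm_spec(2, emission_spec("y", family = c(y = "normal")),
            state_names = c("state1", "state2"), init = "free")
}

gauss2_params <- function(mu = c(-1.5, 1.5), sd = c(1, 1), diag_p = 0.95,
                          delta = c(0.5, 0.5)) {
  phmm_params(gauss2_spec(),
    Gamma = matrix(c(diag_p, 1 - diag_p, 1 - diag_p, diag_p), 2, byrow = TRUE),
    theta = list(list(y = c(mean = mu[1], sd = sd[1])),
                 list(y = c(mean = mu[2], sd = sd[2]))),
    delta = delta)
}

# Simulated labelled data from a well-separated 2-state Gaussian HMM.
gauss2_data <- function(n_steps, seed = 1, mu = c(-1.5, 1.5), diag_p = 0.95,
                        label_prob = 0, series_id = "s1") {
  model <- list(spec = gauss2_spec(), params = gauss2_params(mu = mu, diag_p = diag_p))
  d <- sample_series(model, n_steps, seed = seed)
  set.seed(seed + 7)
  lab <- ifelse(runif(n_steps) < label_prob, d$state, NA_integer_)
  data.frame(series_id = series_id, t = d$t, y = d$y, label = lab,
             state = d$state)
}

# A square-wave trace: 60 s at surface, one 45 s dive to 40 m, surface after.
square_dive_trace <- function(seed = 1) {
  synth_tag_trace(
    dives = data.frame(start_s = 60, duration_s = 45, max_depth = 40,
                       shape = "square"),
    total_s = 150, seed = seed)
}
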