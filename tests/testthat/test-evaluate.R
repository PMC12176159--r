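test_that("profile splits are label-balanced and concatenate to the original", {
  d <- data.frame(series_id = "w1", t = 1:10, y = rnorm(10),
                  label = c(NA, 1L, rep(NA, 6), 1L, NA))
  sp <- split_profile(d, seed = 3)
  expect_equal(nrow(sp), 10L)
  counts <- table(sp$series_id[!is.na(sp$label)])
  expect_equal(unname(sort(as.integer(counts))), c(1L, 1L))
  # parts concatenate to the original observations, in order
  expect_equal(sp$y, d$y)
  # the split point must lie in (2, 9]
  k <- sum(sp$series_id == "w1_a")
  expect_true(k >= 2 && k <= 8)
  # every admissible split point occurs across seeds (uniform choice)
  ks <- vapply(1:60, function(s) sum(split_profile(d, seed = s)$series_id == "w1_a"),
               numeric(1))
  expect_setequal(sort(unique(ks)), 2:8)

  # zero labels: any split valid, counts (0, 0)
  d0 <- data.frame(series_id = "w", t = 1:5, y = rnorm(5))
  s0 <- split_profile(d0, seed = 1)
  expect_equal(length(unique(s0$series_id)), 2L)

  # odd label count: difference exactly 1
  d3 <- data.frame(series_id = "w", t = 1:12, y = rnorm(12),
                   label = c(1L, NA, 1L, rep(NA, 7), 1L, NA))
  s3 <- split_profile(d3, seed = 2)
  c3 <- table(factor(s3$series_id[!is.na(s3$label)], unique(s3$series_id)))
  expect_equal(abs(diff(as.integer(c3))), 1)
  # determinism
  expect_identical(split_profile(d3, seed = 5), split_profile(d3, seed = 5))
})

test_that("soft sensitivity and specificity follow their closed forms", {
  post <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  lab <- c(1L, 2L, 3L, 1L)
  for (i in 1:3) {
    expect_equal(soft_sensitivity(post, lab, i), 1)
    expect_equal(soft_specificity(post, lab, i), 1)
  }
  unif <- matrix(1 / 3, 4, 3)
  expect_equal(soft_sensitivity(unif, lab, 1), 1 / 3)
  expect_equal(soft_specificity(unif, lab, 1), 2 / 3)
  p1 <- cbind(c(0.9, 0.8, 0.4), 1 - c(0.9, 0.8, 0.4))
  expect_equal(soft_sensitivity(p1, c(1L, 1L, 1L), 1), 0.7)
  expect_warning(res <- soft_specificity(p1, c(1L, 1L, 1L), 1), "undefined")
  expect_true(is.na(res))
})

test_that("AUC follows the Mann-Whitney form and the trapezoid oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # enumerate the 4 positive-negative pairs: 0.9 beats both negatives,
  # 0.35 loses to both -> 2/4
  expect_equal(auc_score(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4, 0.55, 0.8), c(1, 0, 1, 0)), 0.75)
  expect_warning(res <- auc_score(1:3, c(1, 1, 1)), "absent")
  expect_true(is.na(res))
  set.seed(99)
  for (k in 1:100) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    expect_equal(auc_score(scores, truth), trapezoid_auc(scores, truth),
                 tolerance = 1e-10)
  }
})

test_that("AUC agrees with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (k in 1:20) {
    scores <- runif(30)
    truth <- runif(30) < 0.4
    if (!any(truth) || all(truth)) next
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(scores, truth), ref, tolerance = 1e-10)
  }
})

test_that("candidate alpha sets follow the label-balance formula", {
  expect_equal(candidate_alphas(101, 1), c(0, 0.01, 1))
  expect_equal(candidate_alphas(2169, 106), c(0, 106 / 2063, 1))
  expect_equal(candidate_alphas(100, 50), c(0, 1))
  expect_error(candidate_alphas(100, 0), "strictly")
  expect_error(candidate_alphas(100, 100), "strictly")
})

test_that("cross validation pools held-out posteriors once per labelled step", {
  set.seed(1)
  d <- dplyr::bind_rows(
    gauss2_data(250, seed = 61, mu = c(-3, 3), label_prob = 0.2, series_id = "s1"),
    gauss2_data(250, seed = 62, mu = c(-3, 3), label_prob = 0.2, series_id = "s2"))
  d <- d[, c("series_id", "t", "y", "label")]
  cv <- phmm_cv(d, gauss2_spec(), alphas = c(0, 1), n_restarts = 2, seed = 3)
  # easy separation: both alphas decode well
  expect_true(all(cv$summary$mean_auc > 0.9))
  # every labelled step held out exactly once per alpha
  lab_steps <- d[!is.na(d$label), c("series_id", "t")]
  for (a in c(0, 1)) {
    held <- unique(cv$posteriors[cv$posteriors$alpha == a & !is.na(cv$posteriors$label),
                                 c("series_id", "t")])
    expect_equal(nrow(held), nrow(lab_steps))
  }
  # posterior rows sum to 1 after pivoting back
  wide <- tidyr::pivot_wider(cv$posteriors, names_from = "state",
                             values_from = "posterior")
  expect_equal(wide$state1 + wide$state2, rep(1, nrow(wide)), tolerance = 1e-8)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_identical(tidy(cv), cv$metrics)
})

test_that("guard failures are per-cell, and per-fold-mean metrics average folds", {
  # state 2 unlabelled in series s2: holding out s1 breaks alpha = 0 training
  d1 <- gauss2_data(150, seed = 71, mu = c(-3, 3), label_prob = 0.1, series_id = "s1")
  d2 <- gauss2_data(150, seed = 72, mu = c(-3, 3), label_prob = 0, series_id = "s2")
  d2$label[d2$state == 1][1:2] <- 1L
  d <- dplyr::bind_rows(d1, d2)[, c("series_id", "t", "y", "label")]
  cv <- phmm_cv(d, gauss2_spec(), alphas = c(0, 1), n_restarts = 2, seed = 5,
                metric_mode = "per_fold_mean")
  expect_true(nrow(cv$failures) >= 1)
  expect_true(all(cv$failures$alpha == 0))
  # the alpha = 1 cells all succeeded
  expect_equal(sort(unique(cv$posteriors$fold[cv$posteriors$alpha == 1])),
               c("s1", "s2"))
})

test_that("relabelling states permutes per-state metrics", {
  post <- rbind(c(0.7, 0.2, 0.1), c(0.2, 0.6, 0.2), c(0.1, 0.3, 0.6),
                c(0.5, 0.4, 0.1))
  lab <- c(1L, 2L, 3L, 2L)
  perm <- c(3L, 1L, 2L)  # new index of old state i is perm[i]
  post_p <- post[, order(perm)]
  lab_p <- perm[lab]
  for (i in 1:3) {
    expect_equal(soft_sensitivity(post, lab, i),
                 soft_sensitivity(post_p, lab_p, perm[i]))
    expect_equal(soft_specificity(post, lab, i),
                 soft_specificity(post_p, lab_p, perm[i]))
  }
})

test_that("event thresholding is strictly greater than the cutoff", {
  tbl <- tibble::tibble(series_id = c("a", "b", "c"),
                        probability = c(0.5, 0.51, 0.49))
  expect_equal(threshold_events(tbl)$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(threshold_events(tbl, 0.4)$flagged, c(TRUE, TRUE, TRUE))
})
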