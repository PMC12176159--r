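test_that("dive segmentation recovers scripted intervals exactly", {
  tr <- square_dive_trace()
  truth <- attr(tr, "truth")
  dives <- segment_dives(tr)
  expect_equal(nrow(dives), 1L)
  expect_equal(dives$start, truth$start)
  expect_equal(dives$end, truth$end)
  expect_equal(dives$max_depth, 40)
  expect_equal(dives$duration, 45)
  expect_equal(dive_summary(tr, dives$start, dives$end),
               c(max_depth = 40, duration = 45))

  # all-surface trace: no dives
  flat <- tag_trace(rep(0, 3000), rep(0, 3000), matrix(0, 3000, 3))
  expect_equal(nrow(segment_dives(flat)), 0L)

  # a 29-second excursion to 10 m is excluded
  short <- synth_tag_trace(
    data.frame(start_s = 10, duration_s = 29, max_depth = 10, shape = "v"),
    total_s = 60, seed = 2)
  expect_equal(nrow(segment_dives(short)), 0L)

  # multi-dive script recovered in order
  tr3 <- synth_tag_trace(
    data.frame(start_s = c(10, 120, 300), duration_s = c(60, 90, 40),
               max_depth = c(50, 80, 35), shape = c("square", "v", "square")),
    total_s = 400, seed = 3)
  d3 <- segment_dives(tr3)
  expect_equal(d3$start, attr(tr3, "truth")$start)
  expect_equal(d3$end, attr(tr3, "truth")$end)
})

test_that("the deep-dive filter is strict at the cutoff", {
  dives <- tibble::tibble(dive = 1:4, start = 1, end = 2,
                          max_depth = c(10, 30, 31, 95), duration = 60)
  kept <- filter_foraging_dives(dives)
  expect_equal(kept$max_depth, c(31, 95))
  expect_equal(nrow(filter_foraging_dives(dives[1:2, ])), 0L)
})

test_that("window features follow their definitions", {
  n <- 200
  tr <- tag_trace(depth = rep(35, n), heading = rep(0.4, n),
                  acc = matrix(1, n, 3))
  expect_equal(window_features(tr, 1, 100),
               c(ddepth = 0, htv = 0, jerk_peak = 0))
  # depth ramp 20 -> 24 across one window: last minus first
  ramp <- tag_trace(depth = seq(20, 24, length.out = 100), heading = rep(0, 100),
                    acc = matrix(0, 100, 3))
  expect_equal(window_features(ramp, 1, 100)[["ddepth"]], 4)
  # uniform rotation: 99 successive differences of 0.02 rad
  rot <- tag_trace(depth = rep(35, 100), heading = 0.02 * (0:99),
                   acc = matrix(0, 100, 3))
  expect_equal(window_features(rot, 1, 100)[["htv"]], 99 * 0.02, tolerance = 1e-12)
  # heading total variation is invariant to a global offset (wrap-around safe)
  rot2 <- tag_trace(depth = rep(35, 100), heading = wlphmm:::wrap_angle(0.02 * (0:99) + pi - 0.5),
                    acc = matrix(0, 100, 3))
  expect_equal(window_features(rot2, 1, 100)[["htv"]],
               window_features(rot, 1, 100)[["htv"]], tolerance = 1e-10)
  expect_error(window_features(tr, 5, 5), "2 samples")
})

test_that("jerk normalization uses the bottom-phase median and is scale invariant", {
  w <- tibble::tibble(window = 1:4, start = 1, end = 2,
                      jerk_peak = c(2, 4, 6, 8),
                      mean_depth = c(80, 75, 72, 20))  # max depth 100
  out <- normalize_jerk(w, max_depth = 100)
  # bottom windows are the first three (mean depth >= 70): median 4
  expect_equal(out$jerk_norm, c(0.5, 1, 1.5, 2))
  # constant bottom jerk normalizes to 1
  w2 <- dplyr::mutate(w, jerk_peak = 5)
  expect_equal(normalize_jerk(w2, 100)$jerk_norm, rep(1, 4))
  # global rescaling of accelerations cancels
  w3 <- dplyr::mutate(w, jerk_peak = jerk_peak * 7.3)
  expect_equal(normalize_jerk(w3, 100)$jerk_norm, out$jerk_norm, tolerance = 1e-12)
  expect_error(normalize_jerk(dplyr::mutate(w, jerk_peak = 0), 100), "motionless")
  expect_error(normalize_jerk(w, max_depth = 1000), "bottom")
})

test_that("ascent onset is the moment after the last deep sample", {
  # square dive: flat bottom at max depth, onset = first sample after the bottom
  tr <- square_dive_trace()
  truth <- attr(tr, "truth")
  onset <- ascent_onset(tr, truth$start, truth$end)
  d <- tr$depth[truth$start:truth$end]
  last_deep <- max(which(d >= 0.7 * max(d)))
  expect_equal(onset, truth$start + last_deep)
  expect_true(all(tr$depth[onset:truth$end] < 0.7 * 40))
  # v-dive: single crossing on the way up
  trv <- synth_tag_trace(
    data.frame(start_s = 5, duration_s = 60, max_depth = 50, shape = "v"),
    total_s = 80, seed = 4)
  tv <- attr(trv, "truth")
  onv <- ascent_onset(trv, tv$start, tv$end)
  thrv <- 0.7 * max(trv$depth[tv$start:tv$end])
  expect_true(trv$depth[onv - 1] >= thrv)
  expect_true(all(trv$depth[onv:tv$end] < thrv))
})

test_that("windows tile each dive with no gaps and a dropped partial tail", {
  tr <- square_dive_trace()
  d <- segment_dives(tr)
  w <- wlphmm:::dive_windows(tr, d$start, d$end)
  expect_equal(nrow(w), (d$end - d$start + 1) %/% 100)
  expect_equal(w$start, d$start + 100 * (seq_len(nrow(w)) - 1))
  expect_equal(w$end, w$start + 99)
  expect_true(all(diff(w$start) == 100))
})

test_that("crunch and video annotation rules label dives correctly", {
  base_dive <- data.frame(start_s = 10, duration_s = 120, max_depth = 60,
                          shape = "square")
  mk <- function(crunches = numeric(0), video = NULL) {
    tr <- synth_tag_trace(base_dive, total_s = 150, crunches = crunches,
                          video = video, seed = 6)
    d <- segment_dives(tr)
    w <- wlphmm:::dive_windows(tr, d$start, d$end)
    list(tr = tr, d = d, w = w,
         onset_s = (attr(tr, "truth")$ascent_onset - 1) / tr$fs)
  }
  s <- mk()
  # crunch 10 s before ascent onset -> its window labelled capture (4)
  cr <- s$onset_s - 10
  lab <- assign_labels(mk(crunches = cr)$tr, s$d$start, s$d$end, s$w)$label
  expect_equal(lab[1], 1L)  # first window always descent
  crunch_win <- which(s$w$start <= round(cr * 50) + 1 & s$w$end >= round(cr * 50) + 1)
  expect_equal(lab[crunch_win], 4L)
  expect_equal(sum(lab %in% c(4L, 5L, 6L), na.rm = TRUE), 1L)

  # crunch 45 s before ascent: ignored, no foraging label
  lab2 <- assign_labels(mk(crunches = s$onset_s - 45)$tr, s$d$start, s$d$end, s$w)$label
  expect_equal(sum(lab2 %in% c(4L, 5L, 6L), na.rm = TRUE), 0L)
  expect_equal(lab2[1], 1L)

  # crunch during ascent -> final window labelled ascent-with-fish (6)
  lab3 <- assign_labels(mk(crunches = s$onset_s + 5)$tr, s$d$start, s$d$end, s$w)$label
  expect_equal(lab3[length(lab3)], 6L)

  # full video coverage, no crunch -> final window ascent-without-fish (5)
  lab4 <- assign_labels(mk(video = rbind(c(0, 150)))$tr, s$d$start, s$d$end, s$w)$label
  expect_equal(lab4[length(lab4)], 5L)
  # partial coverage: no label
  lab5 <- assign_labels(mk(video = rbind(c(0, 60)))$tr, s$d$start, s$d$end, s$w)$label
  expect_equal(sum(lab5 %in% c(4L, 5L, 6L), na.rm = TRUE), 0L)
  # inconsistent annotation errors
  expect_error(
    assign_labels(mk(video = rbind(c(0, 150)))$tr, s$d$start, s$d$end, s$w,
                  foraging_seen = TRUE),
    "inconsistent")
})

test_that("the case-study model structures encode their constraints", {
  s1 <- case1_model_spec()
  expect_equal(s1$n_states, 3L)
  expect_true(all(s1$support))
  expect_equal(wlphmm:::emission_dim(s1$emission), 2L)
  expect_equal(s1$emission$joint, "mvlognormal")
  expect_equal(s1$label_alphabet, c("rest", "travel", "forage"))

  s2 <- case2_model_spec()
  expect_equal(s2$n_states, 6L)
  expect_equal(which(s2$support[1, ]), c(1L, 2L, 5L))
  expect_equal(which(s2$support[, 6]), c(4L, 6L))  # reachable only from 4 and itself
  expect_equal(s2$init$vector, c(1, 0, 0, 0, 0, 0))
  expect_equal(s2$tie_groups, list(c(5L, 6L)))
  expect_equal(unname(s2$emission$family), c("normal", "gamma", "gamma"))
  # rows 5 and 6 absorbing
  expect_equal(which(s2$support[5, ]), 5L)
})

test_that("the end-to-end feature pipeline yields a fit-ready labelled series", {
  dives <- data.frame(start_s = c(20, 220), duration_s = c(150, 120),
                      max_depth = c(60, 25), shape = "square")
  tr <- synth_tag_trace(dives, total_s = 400,
                        crunches = c(), video = rbind(c(0, 400)), seed = 9)
  feats <- dive_features(tr)
  # the 25 m dive is filtered out
  expect_equal(unique(feats$series_id), "dive1")
  expect_equal(nrow(feats), (150 * 50) %/% 100)
  expect_true(all(c("ddepth", "htv", "jerk", "label") %in% names(feats)))
  expect_equal(feats$label[1], "descent")
  expect_equal(feats$label[nrow(feats)], "ascent_nofish")
  expect_true(all(feats$htv >= 0) && all(feats$jerk > 0))
  # label bookkeeping through label_summary
  spec <- case2_model_spec()
  ls <- label_summary(feats, spec)
  expect_equal(sum(ls$n), 2L)
  expect_equal(attr(ls, "n_steps"), nrow(feats))
  # pipeline determinism
  tr2 <- synth_tag_trace(dives, total_s = 400, crunches = c(),
                         video = rbind(c(0, 400)), seed = 9)
  expect_identical(tr$depth, tr2$depth)
  expect_identical(dive_features(tr2), feats)
})

test_that("negative depth readings are clipped and counted", {
  tr <- tag_trace(c(-0.2, 0.1, 5), c(0, 0, 0), matrix(0, 3, 3))
  expect_equal(tr$depth[1], 0)
  expect_equal(tr$n_clipped, 1L)
})
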