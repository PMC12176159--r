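# Dive-scale data engineering for high-frequency tag records: dive
# segmentation, two-second window features, crunch-based labelling, the two
# case-study model structures, and a synthetic 50 Hz trace generator so the
# whole pipeline is testable without field data.

#' Construct a high-frequency tag trace
#'
#' Bundles the synchronized 50 Hz channels of a biologging tag: depth
#' (metres, positive down), heading (radians) and triaxial dynamic
#' acceleration (m/s^2), plus optional crunch-event timestamps (prey-handling
#' sounds identified on the hydrophone) and video-coverage intervals.
#' Above-surface depth readings (negative values) are clipped to 0 and
#' flagged.
#'
#' @param depth,heading Numeric vectors of equal length.
#' @param acc Matrix with one row per sample and 3 columns (x, y, z).
#' @param fs Sampling rate in Hz (default 50).
#' @param crunches Crunch timestamps in seconds from the start of the trace.
#' @param video Video-coverage intervals, a 2-column matrix of
#'   `(start_s, end_s)` rows (or `NULL`).
#' @return An object of class `wlphmm_trace`.
#' @export
tag_trace <- function(depth, heading, acc, fs = 50, crunches = numeric(0),
                      video = NULL) {
  stopifnot(fs > 0, length(depth) == length(heading), nrow(acc) == length(depth),
            ncol(acc) == 3)
  clipped <- depth < 0
  depth[clipped] <- 0
  if (!is.null(video)) video <- matrix(as.numeric(video), ncol = 2)
  structure(
    list(depth = as.numeric(depth), heading = as.numeric(heading),
         acc = acc, fs = fs, crunches = sort(as.numeric(crunches)),
         video = video, n = length(depth), n_clipped = sum(clipped)),
    class = "wlphmm_trace")
}

#' @export
print.wlphmm_trace <- function(x, ...) {
  cat(sprintf("tag trace: %d samples at %g Hz (%.1f s), %d crunch events\n",
              x$n, x$fs, x$n / x$fs, length(x$crunches)))
  invisible(x)
}

#' Segment a trace into dives
#'
#' A dive is a maximal contiguous run of samples deeper than
#' `depth_threshold` metres lasting at least `min_duration` seconds.
#'
#' @param trace A [tag_trace()].
#' @param depth_threshold Depth defining submerged samples (strictly
#'   greater), metres; default 0.5.
#' @param min_duration Minimum dive duration in seconds; default 30.
#' @return A tibble with columns `dive`, `start`, `end` (1-based sample
#'   indices, inclusive), `max_depth` (m) and `duration` (s), in time order.
#' @export
segment_dives <- function(trace, depth_threshold = 0.5, min_duration = 30) {
  under <- trace$depth > depth_threshold
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / trace$fs >= min_duration)
  if (!any(keep)) {
    return(tibble::tibble(dive = integer(0), start = integer(0), end = integer(0),
                          max_depth = numeric(0), duration = numeric(0)))
  }
  s <- starts[keep]
  e <- ends[keep]
  tibble::tibble(
    dive = seq_along(s), start = s, end = e,
    max_depth = vapply(seq_along(s), function(k) max(trace$depth[s[k]:e[k]]), numeric(1)),
    duration = (e - s + 1) / trace$fs)
}

#' Summarize one dive
#'
#' @param trace A [tag_trace()].
#' @param start,end Sample interval of the dive (from [segment_dives()]).
#' @return Named numeric vector `(max_depth, duration)` in metres / seconds.
#' @export
dive_summary <- function(trace, start, end) {
  c(max_depth = max(trace$depth[start:end]),
    duration = (end - start + 1) / trace$fs)
}

#' Keep only dives deep enough to be candidate foraging dives
#'
#' @param dives Tibble from [segment_dives()].
#' @param min_max_depth Depth cutoff in metres; dives with maximum depth
#'   strictly greater are kept. Default 30.
#' @return The filtered tibble.
#' @export
filter_foraging_dives <- function(dives, min_max_depth = 30) {
  dplyr::filter(dives, .data$max_depth > min_max_depth)
}

#' Two-second window summary features
#'
#' For one window of samples: change in depth (last reading minus first,
#' metres), heading total variation (sum of absolute successive heading
#' differences, each wrapped to `(-pi, pi]`, radians) and jerk peak (maximum
#' magnitude of successive acceleration-vector differences, m/s^2).
#'
#' @param trace A [tag_trace()].
#' @param start,end Sample interval of the window.
#' @return Named numeric vector `(ddepth, htv, jerk_peak)`.
#' @export
window_features <- function(trace, start, end) {
  if (end - start + 1 < 2) abort("a feature window needs at least 2 samples")
  idx <- start:end
  dd <- trace$depth[end] - trace$depth[start]
  htv <- sum(abs(wrap_angle(diff(trace$heading[idx]))))
  dacc <- diff(trace$acc[idx, , drop = FALSE])
  jerk <- max(sqrt(rowSums(dacc^2)))
  c(ddepth = dd, htv = htv, jerk_peak = jerk)
}

# Tile a dive with consecutive windows of `window_s` seconds; a final
# partial window is dropped.
dive_windows <- function(trace, start, end, window_s = 2) {
  len <- round(window_s * trace$fs)
  n_win <- (end - start + 1) %/% len
  if (n_win < 1) {
    return(tibble::tibble(window = integer(0), start = integer(0), end = integer(0),
                          ddepth = numeric(0), htv = numeric(0),
                          jerk_peak = numeric(0), mean_depth = numeric(0)))
  }
  ws <- start + (seq_len(n_win) - 1L) * len
  we <- ws + len - 1L
  feats <- t(vapply(seq_len(n_win), function(k) window_features(trace, ws[k], we[k]),
                    numeric(3)))
  tibble::tibble(
    window = seq_len(n_win), start = ws, end = we,
    ddepth = feats[, 1], htv = feats[, 2], jerk_peak = feats[, 3],
    mean_depth = vapply(seq_len(n_win), function(k) mean(trace$depth[ws[k]:we[k]]),
                        numeric(1)))
}

#' Normalize window jerk peaks by the dive's bottom-phase median
#'
#' Divides each window's jerk peak by the median jerk peak over the dive's
#' bottom windows (windows whose mean depth is at least `bottom_fraction`
#' of the dive's maximum depth), adjusting for variation between dives and
#' tags. Scale-invariant: rescaling all accelerations leaves the normalized
#' values unchanged.
#'
#' @param windows Tibble from the window-feature step (columns `jerk_peak`,
#'   `mean_depth`).
#' @param max_depth The dive's maximum depth (m).
#' @param bottom_fraction Fraction of maximum depth defining the bottom
#'   phase; default 0.7.
#' @return `windows` with an added `jerk_norm` column.
#' @export
normalize_jerk <- function(windows, max_depth, bottom_fraction = 0.7) {
  bottom <- windows$mean_depth >= bottom_fraction * max_depth
  if (!any(bottom)) abort("dive has no bottom windows; cannot normalize jerk")
  med <- median(windows$jerk_peak[bottom])
  if (med == 0) abort("degenerate (motionless) dive: bottom-phase median jerk is 0")
  dplyr::mutate(windows, jerk_norm = .data$jerk_peak / med)
}

#' Ascent-phase onset of a dive
#'
#' The ascent phase begins the moment after the animal was last at a depth
#' of at least `fraction` of its maximum dive depth (last-crossing rule, so
#' the onset sits on the final rise of the profile).
#'
#' @param trace A [tag_trace()].
#' @param start,end Sample interval of the dive.
#' @param fraction Fraction of maximum depth; default 0.7.
#' @return Absolute sample index of the first ascent sample.
#' @export
ascent_onset <- function(trace, start, end, fraction = 0.7) {
  d <- trace$depth[start:end]
  thr <- fraction * max(d)
  start + max(which(d >= thr))  # +0 local -> +1 past the last deep sample
}

#' Label a dive's windows from crunch and video annotations
#'
#' Applies the annotation rules for foraging dives, in order:
#' 1. the first window of every dive is labelled `descent`;
#' 2. crunches more than `ignore_before_s` seconds before the dive's ascent
#'    onset are ignored;
#' 3. if the first non-ignored crunch occurs before ascent, its window is
#'    labelled `capture`; if during ascent, the final window is labelled
#'    `ascent_fish` (the exact capture moment being ambiguous);
#' 4. if video covered the entire dive, no crunch was heard anywhere in the
#'    dive and no foraging was seen, the final window is labelled
#'    `ascent_nofish`.
#'
#' At most one foraging-related label is emitted per dive. A dive annotated
#' both as fully video-negative and as containing foraging evidence is an
#' inconsistent annotation and errors.
#'
#' @param trace A [tag_trace()] (supplies crunches, video coverage, `fs`).
#' @param start,end Sample interval of the dive.
#' @param windows Window tibble for this dive (from the window-feature
#'   step); labels attach to these windows.
#' @param onset Ascent onset sample (computed via [ascent_onset()] when
#'   `NULL`).
#' @param ignore_before_s Crunches earlier than this many seconds before
#'   ascent onset are ignored; default 30.
#' @param foraging_seen Was foraging observed on video without a crunch?
#'   (Blocks the `ascent_nofish` label.)
#' @return `windows` with an added integer `label` column on the 6-state
#'   alphabet (1 descent, 2 bottom, 3 chase, 4 capture, 5 ascent_nofish,
#'   6 ascent_fish); `NA` where unlabelled.
#' @export
assign_labels <- function(trace, start, end, windows, onset = NULL,
                          ignore_before_s = 30, foraging_seen = FALSE) {
  if (is.null(onset)) onset <- ascent_onset(trace, start, end)
  lab <- rep(NA_integer_, nrow(windows))
  if (nrow(windows) >= 1) lab[1] <- 1L  # descent
  cr_s <- trace$crunches
  cr <- round(cr_s * trace$fs) + 1L  # sample index of each crunch
  in_dive <- cr >= start & cr <= end
  cr_dive <- cr[in_dive]
  considered <- cr_dive[cr_dive >= onset - ignore_before_s * trace$fs]
  if (length(considered)) {
    first <- min(considered)
    if (first < onset) {
      w <- which(windows$start <= first & windows$end >= first)
      if (!length(w)) w <- nrow(windows)  # crunch in a dropped partial tail
      lab[max(w)] <- 4L  # capture
    } else {
      lab[nrow(windows)] <- 6L  # ascent with a fish
    }
  } else if (!length(cr_dive) && video_covers(trace, start, end)) {
    if (foraging_seen) {
      abort("inconsistent annotation: foraging seen on video but no crunch in a fully covered dive")
    }
    lab[nrow(windows)] <- 5L  # ascent without a fish
  }
  dplyr::mutate(windows, label = lab)
}

video_covers <- function(trace, start, end) {
  if (is.null(trace$video)) return(FALSE)
  s_s <- (start - 1) / trace$fs
  e_s <- end / trace$fs
  any(trace$video[, 1] <= s_s & trace$video[, 2] >= e_s)
}

#' Extract a labelled window series from a tag trace
#'
#' End-to-end feature pipeline for the foraging-dive model: segment dives,
#' keep those deeper than `min_max_depth`, tile each with two-second
#' windows, compute change in depth, heading total variation and normalized
#' jerk peak, and label windows from crunch and video annotations. Each dive
#' becomes one series.
#'
#' @param trace A [tag_trace()].
#' @param min_max_depth Dive depth cutoff (m), strictly greater; default 30.
#' @param window_s Window length in seconds; default 2.
#' @param bottom_fraction Bottom-phase fraction for jerk normalization and
#'   ascent onset; default 0.7.
#' @param id_prefix Series-id prefix, default `"dive"`.
#' @return A labelled-series tibble with columns `series_id`, `t`, `ddepth`,
#'   `htv`, `jerk`, `label` (state names of [case2_model_spec()], `NA` when
#'   unlabelled), ready for [phmm_fit()].
#' @export
dive_features <- function(trace, min_max_depth = 30, window_s = 2,
                          bottom_fraction = 0.7, id_prefix = "dive") {
  dives <- filter_foraging_dives(segment_dives(trace), min_max_depth)
  spec <- case2_model_spec()
  out <- lapply(seq_len(nrow(dives)), function(k) {
    d <- dives[k, ]
    w <- dive_windows(trace, d$start, d$end, window_s)
    if (nrow(w) == 0) return(NULL)
    w <- normalize_jerk(w, d$max_depth, bottom_fraction)
    w <- assign_labels(trace, d$start, d$end, w)
    tibble::tibble(
      series_id = paste0(id_prefix, d$dive), t = w$window,
      ddepth = w$ddepth, htv = w$htv, jerk = w$jerk_norm,
      label = spec$state_names[w$label])
  })
  dplyr::bind_rows(out)
}

#' Model structure for dive-type classification
#'
#' Three dive types (rest, travel, forage) observed through each dive's
#' maximum depth and duration, jointly bivariate log-normal per state; full
#' transition support, free initial distribution, certain labels.
#'
#' @return A [phmm_spec()].
#' @export
case1_model_spec <- function() {
  phmm_spec(
    3, emission_spec(c("max_depth", "duration"), joint = "mvlognormal"),
    state_names = c("rest", "travel", "forage"),
    label_mode = "certain", init = "free")
}

#' Model structure for within-dive foraging identification
#'
#' Six subdive states (descent, bottom, chase, capture, ascent without fish,
#' ascent with fish) observed through two-second window features: change in
#' depth (normal), heading total variation (gamma) and normalized jerk peak
#' (gamma), conditionally independent given the state. The transition
#' support encodes the dive phase structure (descent to bottom/chase to
#' capture, capture straight into ascent-with-fish, both ascent states
#' absorbing), the initial distribution is pinned to descent, the change in
#' depth means of the bottom, chase and capture states are fixed to 0, and
#' the two ascent states share one tied emission block.
#'
#' @return A [phmm_spec()].
#' @export
case2_model_spec <- function() {
  support <- matrix(FALSE, 6, 6)
  support[1, c(1, 2, 5)] <- TRUE
  support[2, c(2, 3, 5)] <- TRUE
  support[3, c(2, 3, 4, 5)] <- TRUE
  support[4, c(4, 6)] <- TRUE
  support[5, 5] <- TRUE
  support[6, 6] <- TRUE
  phmm_spec(
    6, emission_spec(c("ddepth", "htv", "jerk"),
                     family = c(ddepth = "normal", htv = "gamma", jerk = "gamma")),
    state_names = c("descent", "bottom", "chase", "capture",
                    "ascent_nofish", "ascent_fish"),
    label_mode = "certain",
    support = support,
    init = c(1, 0, 0, 0, 0, 0),
    tie_groups = list(c(5, 6)),
    fixed = list(
      list(state = 2, feature = "ddepth", param = "mean", value = 0),
      list(state = 3, feature = "ddepth", param = "mean", value = 0),
      list(state = 4, feature = "ddepth", param = "mean", value = 0)))
}

#' Generate a synthetic 50 Hz tag trace with scripted dives
#'
#' Builds a deterministic depth profile from a dive script (square or
#' v-shaped dives whose sample intervals are known exactly), a wrapped
#' random-walk heading, baseline acceleration noise with high-amplitude
#' bursts at scripted chase times, and optional crunch events and video
#' coverage. Ground truth (scripted dive intervals and ascent onsets) is
#' attached for oracle testing. The generator emulates the geometry and
#' annotation structure of real tag deployments, not their sensor noise.
#'
#' @param dives Tibble/data frame with columns `start_s`, `duration_s`,
#'   `max_depth`, `shape` (`"square"` or `"v"`).
#' @param total_s Total trace duration in seconds.
#' @param crunches Crunch timestamps (s).
#' @param video Video-coverage intervals, 2-column matrix of seconds.
#' @param chases Chase-burst timestamps (s); each adds 2 s of high-variance
#'   acceleration.
#' @param seed Integer seed (byte-identical traces for equal seeds).
#' @param fs Sampling rate; default 50.
#' @return A [tag_trace()] with attribute `"truth"`: a tibble of scripted
#'   dive sample intervals and ascent-onset samples.
#' @export
synth_tag_trace <- function(dives, total_s, crunches = numeric(0), video = NULL,
                            chases = numeric(0), seed = 1, fs = 50) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- round(total_s * fs)
  depth <- numeric(n)
  truth <- vector("list", nrow(dives))
  edge_depth <- 0.6  # just below the surface threshold, so intervals are exact
  for (k in seq_len(nrow(dives))) {
    d <- dives[k, ]
    s <- round(d$start_s * fs) + 1L
    len <- round(d$duration_s * fs)
    e <- s + len - 1L
    u <- seq(0, 1, length.out = len)
    prof <- if (d$shape == "square") {
      ifelse(u < 0.15, edge_depth + (d$max_depth - edge_depth) * u / 0.15,
             ifelse(u <= 0.85, d$max_depth,
                    d$max_depth - (d$max_depth - edge_depth) * (u - 0.85) / 0.15))
    } else {
      ifelse(u <= 0.5, edge_depth + (d$max_depth - edge_depth) * u / 0.5,
             d$max_depth - (d$max_depth - edge_depth) * (u - 0.5) / 0.5)
    }
    depth[s:e] <- prof
    truth[[k]] <- tibble::tibble(dive = k, start = s, end = e)
  }
  heading <- wrap_angle(cumsum(rnorm(n, 0, 0.05)))
  acc <- matrix(rnorm(3 * n, 0, 0.2), ncol = 3)
  for (cs in chases) {
    i0 <- round(cs * fs) + 1L
    idx <- i0:min(i0 + 2L * fs - 1L, n)
    acc[idx, ] <- acc[idx, ] + matrix(rnorm(3 * length(idx), 0, 3), ncol = 3)
  }
  tr <- tag_trace(depth, heading, acc, fs = fs, crunches = crunches, video = video)
  truth <- dplyr::bind_rows(truth)
  truth$ascent_onset <- vapply(seq_len(nrow(truth)), function(k) {
    ascent_onset(tr, truth$start[k], truth$end[k])
  }, numeric(1))
  attr(tr, "truth") <- truth
  tr
}
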