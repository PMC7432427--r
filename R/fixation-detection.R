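#' Detect fixations with a velocity threshold (I-VT)
#'
#' Classifies each inter-sample segment of a gaze stream as fixation-like or
#' saccade-like by its point-to-point velocity, then reports maximal
#' fixation-like runs as fixations. Velocity is computed between consecutive
#' valid samples in the stream's coordinate units per second; no
#' visual-angle conversion is attempted because it would require screen and
#' head geometry the stream does not carry.
#'
#' A candidate run is additionally split wherever the time between
#' consecutive valid samples exceeds `max_sample_gap` milliseconds
#' (tracking dropouts and blinks): bridging such a gap with one low-velocity
#' segment would hide exactly the sub-75 ms interruptions that
#' [merge_glances()] is designed to heal.
#'
#' @param stream a [gaze_stream()].
#' @param velocity_threshold saccade threshold in coordinate units per
#'   second; must be positive. The default of 2 is a conventional choice for
#'   normalized \[0,1\] coordinates, sitting well above typical
#'   within-fixation jitter velocities and well below saccadic sweeps; for
#'   pixel coordinates supply a value on the pixel scale.
#' @param min_duration minimum fixation duration in ms; shorter candidate
#'   runs are discarded. Default 60 ms: at 50 Hz anything shorter spans at
#'   most three samples and is noise-dominated.
#' @param max_sample_gap maximum time (ms) between consecutive valid samples
#'   within one fixation; defaults to 1.5 nominal sample intervals, so any
#'   dropout longer than a single missed frame splits the run.
#' @return a tibble of fixations with columns `t_start`, `duration` (ms),
#'   `cx`, `cy` (centroid), `n_samples`, ordered and non-overlapping in time.
#' @export
#' @examples
#' s <- gaze_stream(data.frame(t = seq(0, 380, by = 20), x = 0.5, y = 0.5))
#' detect_fixations(s)  # one fixation of 380 ms
detect_fixations <- function(stream, velocity_threshold = 2,
                             min_duration = 60,
                             max_sample_gap = 1.5 * 1000 / attr(stream, "rate_hz")) {
  if (!is.numeric(velocity_threshold) || length(velocity_threshold) != 1 ||
      is.na(velocity_threshold) || velocity_threshold <= 0) {
    stop_gazeflow("`velocity_threshold` must be a single positive number.",
                  "gazeflow_param_error")
  }
  empty <- tibble(t_start = numeric(), duration = numeric(),
                  cx = numeric(), cy = numeric(), n_samples = integer())
  v_idx <- which(stream$valid)
  if (length(v_idx) < 2) {
    warn("fewer than 2 valid samples; no fixations detectable.")
    return(empty)
  }
  t <- stream$t[v_idx]; x <- stream$x[v_idx]; y <- stream$y[v_idx]
  dt <- diff(t)                                   # ms
  vel <- sqrt(diff(x)^2 + diff(y)^2) / (dt / 1000) # units per second
  # zero-dt segments (duplicate timestamps) are treated as stationary
  vel[dt == 0] <- 0
  fixlike <- vel < velocity_threshold & dt <= max_sample_gap
  runs <- rle(fixlike)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- purrr::map_dfr(which(runs$values), function(r) {
    i <- starts[r]; j <- ends[r] + 1L  # segments i..ends[r] span samples i..j
    tibble(t_start = t[i], duration = t[j] - t[i],
           cx = mean(x[i:j]), cy = mean(y[i:j]), n_samples = j - i + 1L)
  })
  if (nrow(out) == 0) return(empty)
  out <- out[out$duration >= min_duration & out$duration > 0, , drop = FALSE]
  as_tibble(out)
}

#' Merge glances separated by short gaps
#'
#' Fuses consecutive fixations whose inter-fixation gap is strictly shorter
#' than `max_gap` milliseconds (default 75 ms, the conventional blink
#' interval below which two glances at an AOI are treated as one). The rule
#' is applied iteratively until no mergeable pair remains; a gap of exactly
#' `max_gap` never merges.
#'
#' When `same_aoi_required = TRUE` (the default) and the fixation table
#' carries an `aoi` column, only glances at the same AOI are merged —
#' the merge is then naturally applied *after* AOI coding. Without an `aoi`
#' column the requirement is vacuous and merging is driven by the gap alone,
#' which is the appropriate pre-coding behaviour for healing blink splits.
#'
#' @param fixations a time-ordered fixation tibble, as from
#'   [detect_fixations()] (optionally AOI-coded).
#' @param max_gap maximum gap in ms, exclusive.
#' @param same_aoi_required logical; require identical AOI labels to merge.
#' @return a fixation tibble; merged fixations span from the first start to
#'   the last end, with sample-count-weighted centroids.
#' @export
merge_glances <- function(fixations, max_gap = 75, same_aoi_required = TRUE) {
  fx <- as_tibble(fixations)
  if (nrow(fx) <= 1) return(fx)
  if (is.unsorted(fx$t_start)) {
    stop_gazeflow("fixations must be ordered by `t_start`.", "gazeflow_data_error")
  }
  has_aoi <- "aoi" %in% names(fx)
  repeat {
    gap <- fx$t_start[-1] - (fx$t_start[-nrow(fx)] + fx$duration[-nrow(fx)])
    mergeable <- gap < max_gap
    if (same_aoi_required && has_aoi) {
      same <- fx$aoi[-1] == fx$aoi[-nrow(fx)]
      same[is.na(same)] <- FALSE
      mergeable <- mergeable & same
    }
    k <- which(mergeable)
    if (length(k) == 0) break
    i <- k[1]
    w <- fx$n_samples[c(i, i + 1L)]
    fx$duration[i] <- fx$t_start[i + 1L] + fx$duration[i + 1L] - fx$t_start[i]
    fx$cx[i] <- sum(fx$cx[c(i, i + 1L)] * w) / sum(w)
    fx$cy[i] <- sum(fx$cy[c(i, i + 1L)] * w) / sum(w)
    fx$n_samples[i] <- sum(w)
    fx <- fx[-(i + 1L), , drop = FALSE]
  }
  fx
}
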