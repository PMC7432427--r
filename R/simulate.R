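#' Simulate an AOI fixation sequence from a Markov chain
#'
#' Draws a label sequence from a first-order Markov chain with transition
#' matrix `P` and attaches per-fixation durations from a per-state duration
#' model. The first state is drawn from the chain's stationary distribution
#' unless `start` is given. Durations default to gamma draws — positive and
#' right-skewed, the standard shape for fixation durations — with per-state
#' means on the 80–260 ms scale typical of on-road driving recordings.
#'
#' @param n_fixations sequence length (number of fixations).
#' @param P row-stochastic transition matrix with state dimnames, or
#'   unnamed (then `states` must be given).
#' @param states state labels; defaults to `P`'s rownames.
#' @param duration_means named per-state mean durations in ms; a single
#'   value is recycled. Defaults to the per-area means of the bundled
#'   on-road driver statistics (see [driver_gaze_stats()]) when the states
#'   are the nine AOI labels, otherwise 180 ms.
#' @param duration_model `"gamma"` (default), `"lognormal"` or
#'   `"constant"`.
#' @param duration_cv coefficient of variation of the duration
#'   distribution (ignored for `"constant"`).
#' @param start optional fixed first state.
#' @param seed integer seed; required, so every simulated sequence is
#'   reproducible. The global RNG state is left untouched.
#' @return an [aoi_sequence()] tibble with attribute `P_true`.
#' @export
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE,
#'             dimnames = list(c("D", "E"), c("D", "E")))
#' simulate_aoi_sequence(5, P, seed = 1)
simulate_aoi_sequence <- function(n_fixations, P, states = rownames(P),
                                  duration_means = NULL,
                                  duration_model = c("gamma", "lognormal", "constant"),
                                  duration_cv = 0.4,
                                  start = NULL, seed) {
  duration_model <- match.arg(duration_model)
  if (missing(seed) || is.null(seed)) {
    stop_gazeflow("`seed` is required: simulations must be reproducible.",
                  "gazeflow_config_error")
  }
  if (is.null(states)) {
    stop_gazeflow("`states` must be supplied when `P` has no rownames.",
                  "gazeflow_config_error")
  }
  dimnames(P) <- list(states, states)
  check_stochastic(P)
  if (is.null(duration_means)) {
    duration_means <- if (setequal(states, aoi_labels())) {
      means <- driver_gaze_stats() |>
        dplyr::filter(!.data$abnormal) |>
        dplyr::group_by(.data$area) |>
        dplyr::summarise(m = mean(.data$mean_duration_ms), .groups = "drop")
      stats::setNames(means$m, means$area)[states]
    } else {
      stats::setNames(rep(180, length(states)), states)
    }
  }
  if (length(duration_means) == 1 && is.null(names(duration_means))) {
    duration_means <- stats::setNames(rep(duration_means, length(states)), states)
  }
  if (!all(states %in% names(duration_means)) || any(duration_means[states] <= 0)) {
    stop_gazeflow("`duration_means` must name every state with a positive mean.",
                  "gazeflow_config_error")
  }
  withr::with_seed(as.integer(seed), {
    cum <- t(apply(P, 1, cumsum))
    labels <- character(n_fixations)
    labels[1] <- if (!is.null(start)) {
      if (!start %in% states) {
        stop_gazeflow("`start` is not one of the states.", "gazeflow_config_error")
      }
      start
    } else {
      pi0 <- stationary_distribution(P)
      states[findInterval(runif(1), cumsum(pi0), left.open = TRUE) + 1L]
    }
    if (n_fixations > 1) {
      u <- runif(n_fixations - 1)
      for (i in seq(2, n_fixations)) {
        r <- match(labels[i - 1], states)
        labels[i] <- states[findInterval(u[i - 1], cum[r, ], left.open = TRUE) + 1L]
      }
    }
    mu <- unname(duration_means[labels])
    durations <- switch(duration_model,
      gamma = {
        shape <- 1 / duration_cv^2
        rgamma(n_fixations, shape = shape, scale = mu / shape)
      },
      lognormal = {
        sdlog <- sqrt(log(1 + duration_cv^2))
        rlnorm(n_fixations, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      },
      constant = mu
    )
    # physiological floor: genuine fixations shorter than ~80 ms are not
    # meaningful attention events, so the generator does not produce them
    durations <- pmax(durations, pmin(80, mu))
    out <- aoi_sequence(labels, durations,
                        labels = unique(c(aoi_labels(), states)))
    attr(out, "P_true") <- P
    out
  })
}

#' Simulate a raw gaze-point stream from an AOI sequence
#'
#' Renders an AOI fixation sequence as a timestamped gaze stream: for each
#' fixation, samples at `rate_hz` jittered around the centre of the
#' fixated region; between fixations, a fast linear saccade sweep; and,
#' with probability `blink_prob` per fixation, a blink gap of `blink_ms`
#' (samples marked invalid) injected mid-fixation. The ground-truth
#' fixation table travels along as an attribute, so detection and coding
#' can be scored exactly.
#'
#' @param sequence an [aoi_sequence()] with durations, e.g. from
#'   [simulate_aoi_sequence()].
#' @param scheme an [aoi_scheme()] covering the coordinate space.
#' @param rate_hz sampling rate (50 or 100 Hz).
#' @param jitter_sd within-fixation positional noise (coordinate units);
#'   must be small relative to region size.
#' @param saccade_ms duration of inter-fixation saccade sweeps.
#' @param blink_prob per-fixation probability of an injected blink gap.
#' @param blink_ms blink gap length in ms (keep below 75 to exercise glance
#'   merging; at or above 75 the split must survive merging).
#' @param min_segment_ms blinks are only injected into fixations long
#'   enough that both flanking segments remain at least this long, so a
#'   detector with the default minimum duration can recover them.
#' @param seed integer seed; required.
#' @return a [gaze_stream()] with attribute `ground_truth`: tibble of
#'   `fixation`, `aoi`, `t_start`, `duration`.
#' @export
simulate_gaze_stream <- function(sequence, scheme = aoi_scheme_grid(),
                                 rate_hz = 50, jitter_sd = 0.005,
                                 saccade_ms = 40, blink_prob = 0,
                                 blink_ms = 50, min_segment_ms = 60, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_gazeflow("`seed` is required: simulations must be reproducible.",
                  "gazeflow_config_error")
  }
  seq_tbl <- as_tibble(sequence)
  if (nrow(seq_tbl) == 0) {
    stop_gazeflow("cannot render an empty AOI sequence.", "gazeflow_data_error")
  }
  centers <- scheme |>
    dplyr::mutate(cx = (.data$xmin + .data$xmax) / 2,
                  cy = (.data$ymin + .data$ymax) / 2)
  half_min <- min(c(centers$xmax - centers$xmin, centers$ymax - centers$ymin)) / 2
  if (jitter_sd * 4 > half_min) {
    stop_gazeflow("`jitter_sd` too large for the region size: samples would routinely leave their AOI.",
                  "gazeflow_config_error")
  }
  cx <- stats::setNames(centers$cx, centers$aoi)
  cy <- stats::setNames(centers$cy, centers$aoi)
  dt <- 1000 / rate_hz
  withr::with_seed(as.integer(seed), {
    t <- numeric(0); x <- numeric(0); y <- numeric(0); valid <- logical(0)
    truth <- vector("list", nrow(seq_tbl))
    now <- 0
    for (i in seq_len(nrow(seq_tbl))) {
      aoi <- seq_tbl$aoi[i]
      n_s <- max(2L, round(seq_tbl$duration_ms[i] / dt) + 1L)
      ts <- now + dt * (seq_len(n_s) - 1L)
      xs <- cx[[aoi]] + rnorm(n_s, 0, jitter_sd)
      ys <- cy[[aoi]] + rnorm(n_s, 0, jitter_sd)
      ok <- rep(TRUE, n_s)
      if (blink_prob > 0 && runif(1) < blink_prob) {
        n_blink <- max(1L, round(blink_ms / dt) - 1L)
        # keep both flanks long enough to survive detection at the default
        # minimum fixation duration
        n_keep <- as.integer(ceiling(min_segment_ms / dt)) + 1L
        if (n_s >= 2L * n_keep + n_blink) {
          ok[seq(n_keep + 1L, n_keep + n_blink)] <- FALSE
        }
      }
      truth[[i]] <- tibble(fixation = i, aoi = aoi,
                           t_start = ts[1], duration = ts[n_s] - ts[1])
      t <- c(t, ts); x <- c(x, xs); y <- c(y, ys); valid <- c(valid, ok)
      now <- ts[n_s] + dt
      if (i < nrow(seq_tbl) && seq_tbl$aoi[i + 1] != aoi) {
        n_sac <- max(1L, round(saccade_ms / dt) - 1L)
        frac <- seq_len(n_sac) / (n_sac + 1L)
        nxt <- seq_tbl$aoi[i + 1]
        t <- c(t, now + dt * (seq_len(n_sac) - 1L))
        x <- c(x, cx[[aoi]] + frac * (cx[[nxt]] - cx[[aoi]]))
        y <- c(y, cy[[aoi]] + frac * (cy[[nxt]] - cy[[aoi]]))
        valid <- c(valid, rep(TRUE, n_sac))
        now <- now + dt * n_sac
      }
    }
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
    stream <- gaze_stream(tibble(t = t, x = x, y = y, valid = valid),
                          rate_hz = rate_hz,
                          coordinate_space = attr(scheme, "coordinate_space"))
    attr(stream, "ground_truth") <- dplyr::bind_rows(truth)
    stream
  })
}

#' Workload preset simulation configurations
#'
#' Four illustrative gaze-behaviour presets — `"mild"`, `"moderate"` and
#' `"deep"` cognitive workload plus `"normal"` driving — whose merged
#' six-group stationary structure is front-dominant (front mass above 0.85)
#' with the right side as the secondary area, the structure characteristic
#' of on-road driving. Each preset is a nine-state chain built as
#' \eqn{P = \alpha I + (1-\alpha) \mathbf{1}\pi^\top}, which has stationary
#' distribution exactly \eqn{\pi} for any self-stickiness \eqn{\alpha}.
#' The presets are illustrative fixtures for exercising the pipeline, not
#' estimates of any particular driver population.
#'
#' @param condition one of `"mild"`, `"moderate"`, `"deep"`, `"normal"`.
#' @param alpha self-transition stickiness in \[0, 1).
#' @return list with `condition`, `states`, `P` (9x9), `pi` (stationary),
#'   `duration_means`.
#' @export
workload_preset <- function(condition = c("mild", "moderate", "deep", "normal"),
                            alpha = 0.2) {
  condition <- match.arg(condition)
  # nine-state occupancy targets; merged (A+B, C, D+E, F, G+H, I) masses are
  # front-dominant with a secondary right side, growing front concentration
  # under workload and near-front (E) dominance at deeper levels
  pi9 <- switch(condition,
    mild = c(A = 0, B = 0, C = 0, D = 0.6710, E = 0.2237, F = 0,
             G = 0.0527, H = 0.0526, I = 0),
    moderate = c(A = 0, B = 0, C = 0, D = 0.4483, E = 0.4483, F = 0,
                 G = 0.0517, H = 0.0517, I = 0),
    deep = c(A = 0.0018, B = 0.0017, C = 0, D = 0.4031, E = 0.5000, F = 0,
             G = 0.0467, H = 0.0467, I = 0),
    normal = c(A = 0.006, B = 0.005, C = 0.0004, D = 0.4597, E = 0.4596,
               F = 0.0019, G = 0.030, H = 0.0355, I = 0.0019)
  )
  pi9 <- pi9 / sum(pi9)
  n <- length(pi9)
  P <- alpha * diag(n) + (1 - alpha) * matrix(pi9, n, n, byrow = TRUE)
  dimnames(P) <- list(names(pi9), names(pi9))
  means <- driver_gaze_stats() |>
    dplyr::filter(!.data$abnormal) |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(m = mean(.data$mean_duration_ms), .groups = "drop")
  list(condition = condition, states = names(pi9), P = P, pi = pi9,
       duration_means = stats::setNames(means$m, means$area))
}
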