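# Construct a gaze stream of stationary clusters joined by fast sweeps.
# centers: list of c(x, y); n_per: samples per cluster; sweep_n: samples in
# each inter-cluster sweep. Returns a gaze_stream at rate_hz.
cluster_stream <- function(centers, n_per = 20, sweep_n = 3, rate_hz = 50,
                           jitter = 0) {
  dt <- 1000 / rate_hz
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_along(centers)) {
    cx <- centers[[i]][1]; cy <- centers[[i]][2]
    jx <- if (jitter > 0) stats::rnorm(n_per, 0, jitter) else rep(0, n_per)
    jy <- if (jitter > 0) stats::rnorm(n_per, 0, jitter) else rep(0, n_per)
    xs <- c(xs, cx + jx); ys <- c(ys, cy + jy)
    if (i < length(centers)) {
      nx <- centers[[i + 1]][1]; ny <- centers[[i + 1]][2]
      frac <- seq_len(sweep_n) / (sweep_n + 1)
      xs <- c(xs, cx + frac * (nx - cx)); ys <- c(ys, cy + frac * (ny - cy))
    }
  }
  n <- length(xs)
  gaze_stream(data.frame(t = dt * (seq_len(n) - 1), x = xs, y = ys),
              rate_hz = rate_hz)
}

# simple fixation-table builder
fx_tbl <- function(t_start, duration, cx = 0.5, cy = 0.5, n_samples = 10,
                   aoi = NULL) {
  out <- tibble::tibble(t_start = t_start, duration = duration,
                        cx = rep_len(cx, length(t_start)),
                        cy = rep_len(cy, length(t_start)),
                        n_samples = rep_len(as.integer(n_samples), length(t_start)))
  if (!is.null(aoi)) out$aoi <- aoi
  out
}

# power-iteration oracle for stationary distributions
power_iter_stationary <- function(P, iters = 10000) {
  x <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) x <- as.numeric(x %*% P)
  stats::setNames(x, rownames(P))
}

# collapse consecutive repeats of an AOI sequence (adjacent same-AOI
# fixations are indistinguishable after velocity-based detection)
collapse_runs <- function(labels) labels[c(TRUE, labels[-1] != labels[-length(labels)])]
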