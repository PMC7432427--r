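#' Shannon entropy of an AOI occupancy distribution
#'
#' \eqn{E = -\sum_i P_i \log_2 P_i} in bits, with the usual
#' \eqn{0 \cdot \log 0 = 0} convention.
#'
#' @param p probability vector (non-negative, sums to 1 within `tol`).
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(1 / 9, 9))  # log2(9) = 3.1699...
shannon_entropy <- function(p, tol = 1e-6) {
  assert_prob_vector(p, tol = tol, what = "p")
  pos <- p[p > 0]
  -sum(pos * log2(pos))
}

#' Maximum entropy over D areas
#'
#' \eqn{E_{max} = \log_2 D}, attained by the uniform distribution.
#'
#' @param d number of areas, at least 2.
#' @return bits.
#' @export
max_entropy <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 2 || d != round(d)) {
    stop_gazeflow("`d` must be a single integer >= 2.", "gazeflow_param_error")
  }
  log2(d)
}

#' Fixation entropy rate of a per-area summary
#'
#' The duration-weighted gaze-randomness index
#' \deqn{E_n = \sum_{i=1}^{D} \frac{E}{E_{max} \, D \, T_i},}
#' where \eqn{E} is the Shannon entropy (bits) of the occupancy
#' probabilities over the \eqn{D} included areas, \eqn{E_{max} = \log_2 D},
#' and \eqn{T_i} is the mean fixation duration of area \eqn{i} in seconds.
#' High values mean attention that is both dispersed across areas and
#' composed of short glances; \eqn{E_n = 0} iff all gaze is in one area.
#'
#' Areas can be excluded (instrument artefacts such as implausibly short
#' mean durations, or areas with zero occupancy): an excluded area is
#' dropped entirely, the remaining probabilities are renormalized and
#' \eqn{D} becomes the retained-area count. Empty areas (`p = 0`) are always
#' dropped this way, since their mean duration is undefined.
#'
#' Three alternative readings of the statistic are available for
#' sensitivity analysis via `variant`; the default `"validated"` grouping is
#' the one whose per-driver values and sample statistics are internally
#' consistent on published per-area tables (see the package vignette).
#'
#' @param summary a `fixation_summary` tibble (columns `area`, `p`,
#'   `mean_duration_ms`), or anything coercible with those columns.
#' @param variant formula variant: `"validated"` (default,
#'   \eqn{\sum_i E/(E_{max} D T_i)}), `"summed_product"`
#'   (\eqn{\sum_i (E/E_{max}) D T_i}), `"per_area"`
#'   (\eqn{\sum_i -P_i \log_2 P_i /(E_{max} D T_i)}), or `"mean_duration"`
#'   (\eqn{E/(E_{max} D \bar T)}).
#' @param exclude character vector of area labels to exclude, or `NULL`.
#' @param min_duration_ms additionally exclude areas whose mean duration is
#'   below this threshold (ms); `NULL` keeps all.
#' @param tol tolerance for the probability checks.
#' @return a `gaze_entropy` object: list with `E`, `E_max`, `E_n`, `D`,
#'   `variant` and a per-area `areas` tibble (renormalized `p`, duration in
#'   seconds, per-area term, exclusion flag/reason). Supports [tidy()] and
#'   [glance()].
#' @seealso [fixation_entropy_rate()] for just the number.
#' @export
fixation_entropy <- function(summary,
                             variant = c("validated", "summed_product",
                                         "per_area", "mean_duration"),
                             exclude = NULL, min_duration_ms = NULL,
                             tol = 1e-6) {
  variant <- match.arg(variant)
  s <- as_tibble(summary)
  for (col in c("area", "p", "mean_duration_ms")) {
    if (!col %in% names(s)) {
      stop_gazeflow(sprintf("summary is missing column `%s`.", col),
                    "gazeflow_data_error")
    }
  }
  assert_prob_vector(s$p, tol = tol, what = "summary$p")
  reason <- rep(NA_character_, nrow(s))
  reason[s$p == 0] <- "empty"
  if (!is.null(exclude)) reason[s$area %in% exclude & is.na(reason)] <- "excluded"
  if (!is.null(min_duration_ms)) {
    reason[s$mean_duration_ms < min_duration_ms & is.na(reason)] <- "short_duration"
  }
  keep <- is.na(reason)
  D <- sum(keep)
  if (D < 2) {
    stop_gazeflow("fewer than 2 areas retained; entropy rate is undefined.",
                  "gazeflow_data_error")
  }
  p <- s$p[keep] / sum(s$p[keep])
  T_s <- s$mean_duration_ms[keep] / 1000
  if (any(T_s <= 0)) {
    stop_gazeflow(sprintf("non-positive mean duration in retained area(s): %s",
                          paste(s$area[keep][T_s <= 0], collapse = ", ")),
                  "gazeflow_data_error")
  }
  E <- shannon_entropy(p, tol = tol)
  E_max <- log2(D)
  terms <- switch(variant,
    validated     = E / (E_max * D * T_s),
    summed_product = (E / E_max) * D * T_s,
    per_area      = ifelse(p > 0, -p * log2(p), 0) / (E_max * D * T_s),
    mean_duration = rep(E / (E_max * D * mean(T_s)), D) / D
  )
  areas <- tibble(area = s$area,
                  p_renormalized = replace(rep(NA_real_, nrow(s)), keep, p),
                  duration_s = replace(rep(NA_real_, nrow(s)), keep, T_s),
                  term = replace(rep(NA_real_, nrow(s)), keep, terms),
                  excluded = !keep,
                  reason = reason)
  structure(list(E = E, E_max = E_max, E_n = sum(terms), D = D,
                 variant = variant, areas = areas),
            class = "gaze_entropy")
}

#' Fixation entropy rate (scalar convenience)
#'
#' @inheritParams fixation_entropy
#' @param ... passed to [fixation_entropy()].
#' @return the entropy rate \eqn{E_n} as a single number.
#' @export
fixation_entropy_rate <- function(summary, ...) {
  fixation_entropy(summary, ...)$E_n
}

#' Percent difference between two groups of entropy rates
#'
#' `100 * (mean(a) - mean(b)) / mean(b)`: how much higher (in percent of the
#' reference group's mean) group `a`'s mean entropy rate is than group
#' `b`'s.
#'
#' @param group_a,group_b numeric vectors of entropy rates (non-empty).
#' @return percent difference (positive when `a` exceeds `b`).
#' @export
#' @examples
#' group_percent_difference(3.2, 2.6)  # 23.08
group_percent_difference <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_gazeflow("both groups must be non-empty.", "gazeflow_data_error")
  }
  mb <- mean(group_b)
  if (mb == 0) {
    stop_gazeflow("reference group mean is zero; percent difference undefined.",
                  "gazeflow_data_error")
  }
  100 * (mean(group_a) - mb) / mb
}

#' @export
print.gaze_entropy <- function(x, ...) {
  cat(sprintf("<gaze_entropy> E = %.4f bits, E_max = %.4f bits, E_n = %.4f (D = %d, variant = %s)\n",
              x$E, x$E_max, x$E_n, x$D, x$variant))
  if (any(x$areas$excluded)) {
    cat("  excluded areas:",
        paste(sprintf("%s (%s)", x$areas$area[x$areas$excluded],
                      x$areas$reason[x$areas$excluded]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fixation_entropy
#' @param x a `gaze_entropy` object.
#' @param ... unused.
#' @method tidy gaze_entropy
#' @export
tidy.gaze_entropy <- function(x, ...) x$areas

#' @rdname fixation_entropy
#' @method glance gaze_entropy
#' @export
glance.gaze_entropy <- function(x, ...) {
  tibble(E = x$E, E_max = x$E_max, E_n = x$E_n, D = x$D, variant = x$variant,
         n_excluded = sum(x$areas$excluded))
}
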