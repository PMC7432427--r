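#' Run the full gaze-analysis pipeline
#'
#' Orchestrates the stages read → detect → merge → code → summarize →
#' entropy → transitions on one input, which may be either a raw
#' [gaze_stream()] (detection and coding are run) or an [aoi_sequence()]
#' (detection stages are skipped). Produces the per-area fixation summary,
#' the entropy result, the nine-state and merged six-state transition
#' models with their stationary distributions, and a manifest of the
#' parameters used. With the same input and parameters the output is
#' byte-identical — every stage is deterministic.
#'
#' @param input a `gaze_stream` or an `aoi_sequence` (or path to a file of
#'   either kind — `.csv` AOI sequences via [read_aoi_sequence()]).
#' @param scheme AOI scheme used for coding raw streams.
#' @param velocity_threshold,min_duration,max_gap I-VT and glance-merge
#'   parameters (see [detect_fixations()] and [merge_glances()]).
#' @param grouping state grouping for the merged model.
#' @param entropy_variant formula variant for [fixation_entropy()].
#' @param output_dir optional directory; when given, all tables plus a JSON
#'   manifest are written there.
#' @return a `gaze_pipeline` list: `fixations`, `sequence`, `summary`,
#'   `entropy`, `model9` (or full-state model), `model_merged`,
#'   `stationary`, `stationary_merged`, `manifest`.
#' @export
run_gaze_pipeline <- function(input, scheme = aoi_scheme_grid(),
                              velocity_threshold = 2, min_duration = 60,
                              max_gap = 75,
                              grouping = aoi_grouping_default6(),
                              entropy_variant = "validated",
                              output_dir = NULL) {
  stage <- "input"
  result <- tryCatch({
    if (is.character(input) && length(input) == 1) {
      input <- read_aoi_sequence(input)
    }
    if (inherits(input, "gaze_stream")) {
      stage <- "detect"
      fx <- detect_fixations(input, velocity_threshold = velocity_threshold,
                             min_duration = min_duration)
      stage <- "code"
      fx <- code_fixations(fx, scheme)
      stage <- "merge"
      # merging follows coding: a sub-75 ms gap bridges a blink only when
      # both glances are at the same AOI, never across a short saccade
      fx <- merge_glances(fx, max_gap = max_gap, same_aoi_required = TRUE)
      sequence <- as_aoi_sequence(fx)
    } else {
      fx <- NULL
      sequence <- aoi_sequence(as_tibble(input)$aoi, as_tibble(input)$duration_ms)
    }
    stage <- "summarize"
    summary <- summarize_fixations(sequence)
    stage <- "entropy"
    entropy <- fixation_entropy(summary, variant = entropy_variant)
    stage <- "transitions"
    model9 <- fit_transition_model(sequence, states = aoi_labels())
    model_merged <- merge_states(model9, grouping = grouping)
    list(fixations = fx,
         sequence = sequence,
         summary = summary,
         entropy = entropy,
         model9 = model9,
         model_merged = model_merged,
         stationary = stationary_distribution(model9),
         stationary_merged = stationary_distribution(model_merged))
  }, gazeflow_error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
          class = "gazeflow_pipeline_error", parent = e)
  })
  result$manifest <- list(
    package = "gazeflow",
    version = as.character(utils::packageVersion("gazeflow")),
    parameters = list(velocity_threshold = velocity_threshold,
                      min_duration = min_duration, max_gap = max_gap,
                      entropy_variant = entropy_variant,
                      grouping = as.list(grouping)),
    n_fixations = nrow(result$sequence),
    artifacts = c("fixations", "sequence", "summary", "entropy",
                  "one_step", "two_step", "stationary", "stationary_merged")
  )
  class(result) <- "gaze_pipeline"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(result$fixations)) {
      readr::write_csv(result$fixations, file.path(output_dir, "fixations.csv"))
    }
    readr::write_csv(result$sequence, file.path(output_dir, "aoi_sequence.csv"))
    write_gaze_report(result$summary, result$model9, output_dir)
    write_matrix_csv(result$model_merged$P1,
                     file.path(output_dir, "one_step_matrix_merged.csv"))
    if (!is.null(result$model_merged$P2_emp)) {
      write_matrix_csv(result$model_merged$P2_emp,
                       file.path(output_dir, "two_step_matrix_merged.csv"))
    }
    readr::write_csv(tibble(state = names(result$stationary_merged),
                            probability = as.numeric(result$stationary_merged)),
                     file.path(output_dir, "stationary_merged.csv"))
    jsonlite::write_json(result$manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.gaze_pipeline <- function(x, ...) {
  cat(sprintf("<gaze_pipeline> %d fixations, E_n = %.4f\n",
              nrow(x$sequence), x$entropy$E_n))
  cat("merged stationary distribution:\n")
  print(round(x$stationary_merged, 4))
  invisible(x)
}

# SPSS-convention (type 2) skewness / kurtosis, as commonly printed by
# statistics packages in human-factors reports
describe_sample <- function(x) {
  s <- if (length(x) > 1) sd(x) else 0  # degenerate but defined
  tibble(n = length(x),
         mean = mean(x),
         median = median(x),
         sd = s,
         sem = s / sqrt(length(x)),
         skewness = if (length(x) >= 3) e1071::skewness(x, type = 2) else NA_real_,
         kurtosis = if (length(x) >= 4) e1071::kurtosis(x, type = 2) else NA_real_)
}

#' Per-driver entropy report with group comparison
#'
#' Computes the fixation entropy rate for every driver from per-area
#' summary statistics, then reports descriptive statistics of the entropy
#' sample (mean, median, sample SD, SEM, skewness, kurtosis), group means
#' and their percent difference, and informational normality tests
#' (Shapiro–Wilk, and Lilliefors-style one-sample Kolmogorov–Smirnov
#' against the fitted normal).
#'
#' @param data long tibble with columns `driver`, `area`,
#'   `mean_duration_ms`, `gaze_share_pct` (or `p`), optional `abnormal`
#'   flag and a grouping column. Defaults to the bundled on-road study
#'   statistics.
#' @param group name of the grouping column (default `"sex"`); set `NULL`
#'   for no group comparison.
#' @param exclude_abnormal drop areas flagged `abnormal` (entire area
#'   removed, probabilities renormalized, area count D reduced) before
#'   computing the entropy rate. Default `TRUE`, since artefact cells make
#'   the duration-weighted statistic meaningless.
#' @param variant entropy formula variant, see [fixation_entropy()].
#' @return a `gaze_driver_report`: list with `per_driver` tibble (`driver`,
#'   group, `E`, `E_max`, `E_n`, `D`), `stats` (descriptives), `groups`
#'   (per-group means), `percent_difference`, `normality`.
#' @export
#' @examples
#' rep <- driver_entropy_report()
#' rep$stats$mean   # sample mean entropy rate
driver_entropy_report <- function(data = driver_gaze_stats(), group = "sex",
                                  exclude_abnormal = TRUE,
                                  variant = "validated") {
  data <- as_tibble(data)
  if (!"abnormal" %in% names(data)) data$abnormal <- FALSE
  share_col <- if ("gaze_share_pct" %in% names(data)) "gaze_share_pct" else "p"
  if (!share_col %in% names(data)) {
    stop_gazeflow("data needs a `gaze_share_pct` or `p` column.", "gazeflow_data_error")
  }
  drivers <- unique(data$driver)
  per_driver <- purrr::map_dfr(drivers, function(d) {
    sub <- data[data$driver == d, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop_gazeflow(sprintf("driver %s has no rows.", d), "gazeflow_data_error")
    }
    s <- fixation_summary(sub$area, sub[[share_col]], sub$mean_duration_ms)
    excl <- if (exclude_abnormal) sub$area[sub$abnormal] else NULL
    e <- fixation_entropy(s, variant = variant, exclude = excl)
    row <- tibble(driver = d, E = e$E, E_max = e$E_max, E_n = e$E_n, D = e$D)
    if (!is.null(group) && group %in% names(sub)) row[[group]] <- sub[[group]][1]
    row
  })
  stats_tbl <- describe_sample(per_driver$E_n)
  groups_tbl <- NULL
  pct_diff <- NA_real_
  if (!is.null(group) && group %in% names(per_driver)) {
    groups_tbl <- per_driver |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::summarise(n = dplyr::n(), mean_E_n = mean(.data$E_n),
                       sd_E_n = ifelse(dplyr::n() > 1, sd(.data$E_n), 0),
                       .groups = "drop")
    if (nrow(groups_tbl) == 2) {
      ord <- order(groups_tbl$mean_E_n, decreasing = TRUE)
      pct_diff <- group_percent_difference(
        per_driver$E_n[per_driver[[group]] == groups_tbl[[group]][ord[1]]],
        per_driver$E_n[per_driver[[group]] == groups_tbl[[group]][ord[2]]])
    }
  }
  normality <- if (nrow(per_driver) >= 3) {
    sw <- shapiro.test(per_driver$E_n)
    ks <- suppressWarnings(ks.test(per_driver$E_n, "pnorm",
                                   mean(per_driver$E_n), sd(per_driver$E_n)))
    tibble(test = c("shapiro_wilk", "kolmogorov_smirnov"),
           statistic = c(unname(sw$statistic), unname(ks$statistic)),
           p_value = c(sw$p.value, ks$p.value))
  }
  structure(list(per_driver = per_driver, stats = stats_tbl,
                 groups = groups_tbl, percent_difference = pct_diff,
                 normality = normality, group = group),
            class = "gaze_driver_report")
}

#' @export
print.gaze_driver_report <- function(x, ...) {
  cat(sprintf("<gaze_driver_report> %d drivers; mean E_n = %.5f (median %.5f, SD %.7f)\n",
              x$stats$n, x$stats$mean, x$stats$median, x$stats$sd))
  if (!is.null(x$groups)) {
    print(x$groups)
    if (!is.na(x$percent_difference)) {
      cat(sprintf("higher group exceeds lower by %.2f%%\n", x$percent_difference))
    }
  }
  invisible(x)
}

#' @rdname driver_entropy_report
#' @param x a `gaze_driver_report`.
#' @param ... unused.
#' @method tidy gaze_driver_report
#' @export
tidy.gaze_driver_report <- function(x, ...) x$per_driver

#' @rdname driver_entropy_report
#' @method glance gaze_driver_report
#' @export
glance.gaze_driver_report <- function(x, ...) {
  dplyr::bind_cols(x$stats, tibble(percent_difference = x$percent_difference))
}
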