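#' Construct a gaze stream
#'
#' A gaze stream is a tibble of timestamped gaze samples with one row per
#' eye-tracker record: `t` (milliseconds since stream start), `x`, `y`
#' (gaze coordinates in the declared coordinate space) and `valid`
#' (logical validity flag). Invalid samples carry `NA` coordinates.
#'
#' @param data data frame with columns `t`, `x`, `y` and optionally `valid`.
#' @param rate_hz nominal sampling rate in Hz. Wearable trackers of the kind
#'   this package targets record at 50 or 100 Hz; other rates are accepted
#'   when listed in `allowed_rates`.
#' @param coordinate_space free-text declaration of units and origin, e.g.
#'   `"normalized [0,1] x [0,1]"` or `"pixels 1920x1080"`.
#' @param allowed_rates numeric vector of acceptable sampling rates.
#' @return a `gaze_stream` tibble with attributes `rate_hz` and
#'   `coordinate_space`.
#' @export
gaze_stream <- function(data, rate_hz = 50,
                        coordinate_space = "normalized [0,1] x [0,1]",
                        allowed_rates = c(50, 100)) {
  data <- as_tibble(data)
  for (col in c("t", "x", "y")) {
    if (!col %in% names(data)) {
      stop_gazeflow(sprintf("gaze stream is missing required column `%s`.", col),
                    "gazeflow_config_error")
    }
  }
  if (!"valid" %in% names(data)) data$valid <- TRUE
  data$valid <- data$valid & !is.na(data$x) & !is.na(data$y)
  data$x[!data$valid] <- NA_real_
  data$y[!data$valid] <- NA_real_
  if (nrow(data) > 1) {
    dt <- diff(data$t)
    bad <- which(dt < 0)
    if (length(bad) > 0) {
      stop_gazeflow(sprintf("timestamps must be non-decreasing; first violation at row %d (t = %g after %g).",
                            bad[1] + 1L, data$t[bad[1] + 1L], data$t[bad[1]]),
                    "gazeflow_data_error")
    }
  }
  if (!rate_hz %in% allowed_rates) {
    stop_gazeflow(sprintf("rate_hz = %g is not among the allowed rates (%s).",
                          rate_hz, paste(allowed_rates, collapse = ", ")),
                  "gazeflow_config_error")
  }
  structure(data[c("t", "x", "y", "valid")],
            rate_hz = rate_hz,
            coordinate_space = coordinate_space,
            class = c("gaze_stream", class(tibble())))
}

#' Read a raw gaze stream from a delimited file
#'
#' Parses a TSV/CSV export of a wearable eye tracker into a [gaze_stream()].
#' The column mapping is configuration-driven because vendors disagree on
#' column names. Rows whose coordinates fail to parse are kept and marked
#' invalid, never dropped, so sample counts stay faithful to the recording.
#'
#' @param path path to a delimited text file with a header row.
#' @param col_map named character vector mapping stream fields to file
#'   columns; names must include `t`, `x`, `y` and may include `valid`.
#' @param delim field delimiter; guessed from the first line (tab vs comma)
#'   when `NULL`.
#' @inheritParams gaze_stream
#' @return a `gaze_stream` tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("timestamp\tgaze_x\tgaze_y\tvalidity",
#'              "0\t0.5\t0.5\t1", "20\t0.51\t0.49\t1", "40\t\t0.5\t1"), tf)
#' s <- read_gaze_stream(tf)
#' sum(s$valid)  # third row is invalid, not dropped
read_gaze_stream <- function(path,
                             col_map = c(t = "timestamp", x = "gaze_x",
                                         y = "gaze_y", valid = "validity"),
                             rate_hz = 50,
                             coordinate_space = "normalized [0,1] x [0,1]",
                             delim = NULL,
                             allowed_rates = c(50, 100)) {
  if (!file.exists(path)) {
    stop_gazeflow(sprintf("file not found: %s", path), "gazeflow_io_error")
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- col_map[intersect(c("t", "x", "y"), names(col_map))]
  missing <- setdiff(unname(needed), names(raw))
  if (length(missing) > 0) {
    stop_gazeflow(sprintf("declared column(s) not in file: %s", paste(missing, collapse = ", ")),
                  "gazeflow_config_error")
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  t <- num(raw[[col_map[["t"]]]])
  if (anyNA(t)) {
    stop_gazeflow(sprintf("unparseable timestamp at row %d.", which(is.na(t))[1]),
                  "gazeflow_data_error")
  }
  x <- num(raw[[col_map[["x"]]]])
  y <- num(raw[[col_map[["y"]]]])
  valid <- rep(TRUE, nrow(raw))
  if ("valid" %in% names(col_map) && col_map[["valid"]] %in% names(raw)) {
    v <- raw[[col_map[["valid"]]]]
    valid <- !(tolower(trimws(v)) %in% c("0", "false", "invalid", "no")) & !is.na(v)
  }
  gaze_stream(tibble(t = t, x = x, y = y, valid = valid),
              rate_hz = rate_hz, coordinate_space = coordinate_space,
              allowed_rates = allowed_rates)
}

#' AOI labels of the nine-region scheme
#'
#' The nine areas of interest used throughout: `A`/`B`/`C` left distant /
#' left near / bottom-left (left mirror), `D`/`E` front far / front near,
#' `F` in-vehicle, `G`/`H`/`I` right distant / right near / bottom-right.
#' @return character vector `LETTERS[1:9]`.
#' @export
aoi_labels <- function() LETTERS[1:9]

#' Construct an AOI fixation sequence
#'
#' An AOI sequence is the ordered list of fixated areas with their
#' durations: the observed path of the gaze process over the discrete AOI
#' state space, and the input to all transition and entropy statistics.
#'
#' @param aoi character vector of AOI labels.
#' @param duration_ms numeric vector of fixation durations in milliseconds.
#' @param labels permitted labels (default the nine-region labels).
#' @return an `aoi_sequence` tibble with columns `aoi`, `duration_ms`.
#' @export
aoi_sequence <- function(aoi, duration_ms = NA_real_, labels = aoi_labels()) {
  aoi <- as.character(aoi)
  unknown <- setdiff(unique(aoi), c(labels, "unclassified"))
  if (length(unknown) > 0) {
    stop_gazeflow(sprintf("unknown AOI label(s) %s; permitted labels: %s",
                          paste(unknown, collapse = ", "),
                          paste(labels, collapse = ", ")),
                  "gazeflow_data_error")
  }
  out <- tibble(aoi = aoi,
                duration_ms = rep_len(as.numeric(duration_ms), length(aoi)))
  class(out) <- c("aoi_sequence", class(tibble()))
  out
}

#' Read an AOI fixation sequence from a two-column CSV
#'
#' Expects columns `aoi` (labels among the permitted set) and `duration_ms`.
#' File order is preserved. An empty file yields an empty sequence;
#' downstream operations decide whether that is an error.
#'
#' @param path path to the CSV file.
#' @param labels permitted AOI labels.
#' @return an `aoi_sequence` tibble.
#' @export
read_aoi_sequence <- function(path, labels = aoi_labels()) {
  if (!file.exists(path)) {
    stop_gazeflow(sprintf("file not found: %s", path), "gazeflow_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    return(aoi_sequence(character(), numeric(), labels = labels))
  }
  for (col in c("aoi", "duration_ms")) {
    if (!col %in% names(raw)) {
      stop_gazeflow(sprintf("AOI sequence file is missing column `%s`.", col),
                    "gazeflow_config_error")
    }
  }
  aoi_sequence(raw$aoi, raw$duration_ms, labels = labels)
}

#' Write analysis results to disk
#'
#' Writes a fixation summary and a transition model as round-trippable
#' plain-text files: CSV tables for the summary, the one-/two-step matrices
#' (with an explicit state-order header row and column) and the stationary
#' distribution, plus a JSON bundle of everything.
#'
#' @param summary a fixation summary tibble, as from [summarize_fixations()].
#' @param model a `gaze_markov` transition model, as from
#'   [fit_transition_model()].
#' @param dir output directory, created if needed.
#' @return invisibly, a named character vector of the files written.
#' @seealso [read_gaze_report()] for the inverse.
#' @export
write_gaze_report <- function(summary, model, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop_gazeflow(sprintf("cannot write to directory: %s", dir), "gazeflow_io_error")
  }
  paths <- c(summary = file.path(dir, "fixation_summary.csv"),
             one_step = file.path(dir, "one_step_matrix.csv"),
             two_step = file.path(dir, "two_step_matrix.csv"),
             stationary = file.path(dir, "stationary.csv"),
             bundle = file.path(dir, "report.json"))
  readr::write_csv(summary, paths[["summary"]])
  write_matrix_csv(model$P1, paths[["one_step"]])
  if (!is.null(model$P2_emp)) write_matrix_csv(model$P2_emp, paths[["two_step"]])
  pi_hat <- stationary_distribution(model)
  readr::write_csv(tibble(state = names(pi_hat), probability = as.numeric(pi_hat)),
                   paths[["stationary"]])
  bundle <- list(states = model$states,
                 summary = summary,
                 one_step = matrix_to_list(model$P1),
                 two_step = if (!is.null(model$P2_emp)) matrix_to_list(model$P2_emp),
                 stationary = as.list(stats::setNames(as.numeric(pi_hat), names(pi_hat))))
  jsonlite::write_json(bundle, paths[["bundle"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a written report
#'
#' @param dir directory previously populated by [write_gaze_report()].
#' @return list with elements `summary`, `one_step`, `two_step` (may be
#'   `NULL`), `stationary`.
#' @export
read_gaze_report <- function(dir) {
  list(summary = readr::read_csv(file.path(dir, "fixation_summary.csv"),
                                 show_col_types = FALSE, progress = FALSE),
       one_step = read_matrix_csv(file.path(dir, "one_step_matrix.csv")),
       two_step = if (file.exists(file.path(dir, "two_step_matrix.csv")))
         read_matrix_csv(file.path(dir, "two_step_matrix.csv")),
       stationary = {
         s <- readr::read_csv(file.path(dir, "stationary.csv"),
                              show_col_types = FALSE, progress = FALSE)
         stats::setNames(s$probability, s$state)
       })
}

write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  out <- cbind(tibble(state = rownames(m)), df)
  readr::write_csv(as_tibble(out), path)
}

read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$state
  m
}

matrix_to_list <- function(m) {
  lapply(stats::setNames(seq_len(nrow(m)), rownames(m)),
         function(i) as.list(stats::setNames(m[i, ], colnames(m))))
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> %d samples at %g Hz, %s, %d valid\n",
              nrow(x), attr(x, "rate_hz"), attr(x, "coordinate_space"),
              sum(x$valid)))
  NextMethod()
}
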