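#' Define an AOI scheme of labelled rectangles
#'
#' An AOI scheme partitions the gaze plane into labelled, non-overlapping
#' rectangles that jointly cover the declared coordinate space. The default
#' nine-region semantics follow the driving-scene layout: a left column
#' (A distant, B near, C bottom/left mirror), a centre column (D front far,
#' E front near, F in-vehicle) and a right column (G distant, H near,
#' I bottom/glove box).
#'
#' Region membership uses a half-open convention — a point belongs to a
#' region when `xmin <= x < xmax` and `ymin <= y < ymax` — so every interior
#' boundary point has exactly one label. Points lying on the outer maximum
#' edge of the coordinate space are assigned to the bordering region.
#'
#' @param regions tibble/data frame with columns `aoi`, `xmin`, `xmax`,
#'   `ymin`, `ymax`.
#' @param labels the full label set the scheme must cover exactly once.
#' @param coordinate_space free-text description of units/origin.
#' @return an `aoi_scheme` tibble.
#' @export
aoi_scheme <- function(regions, labels = aoi_labels(),
                       coordinate_space = "normalized [0,1] x [0,1]") {
  regions <- as_tibble(regions)
  needed <- c("aoi", "xmin", "xmax", "ymin", "ymax")
  if (!all(needed %in% names(regions))) {
    stop_gazeflow(sprintf("scheme needs columns: %s", paste(needed, collapse = ", ")),
                  "gazeflow_config_error")
  }
  if (!setequal(regions$aoi, labels) || anyDuplicated(regions$aoi)) {
    stop_gazeflow(sprintf("scheme must contain each of %s exactly once.",
                          paste(labels, collapse = ", ")),
                  "gazeflow_config_error")
  }
  if (any(regions$xmax <= regions$xmin) || any(regions$ymax <= regions$ymin)) {
    stop_gazeflow("every region must have positive width and height.",
                  "gazeflow_config_error")
  }
  # pairwise disjointness of open interiors
  n <- nrow(regions)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ox <- min(regions$xmax[i], regions$xmax[j]) - max(regions$xmin[i], regions$xmin[j])
    oy <- min(regions$ymax[i], regions$ymax[j]) - max(regions$ymin[i], regions$ymin[j])
    if (ox > 1e-12 && oy > 1e-12) {
      stop_gazeflow(sprintf("regions %s and %s overlap.", regions$aoi[i], regions$aoi[j]),
                    "gazeflow_config_error")
    }
  }
  structure(regions[needed],
            coordinate_space = coordinate_space,
            xlim = c(min(regions$xmin), max(regions$xmax)),
            ylim = c(min(regions$ymin), max(regions$ymax)),
            class = c("aoi_scheme", class(tibble())))
}

#' Default 3x3 grid AOI scheme
#'
#' Maps a 3-by-3 grid over the coordinate space to the nine-region layout:
#' columns left/centre/right, rows top (distant), middle (near) and bottom,
#' with y increasing upward. Top-left is A, top-centre D, top-right G;
#' middle row B/E/H; bottom row C/F/I. Real recordings should supply a
#' measured geometry via [aoi_scheme()] or [read_aoi_scheme()]; the grid is
#' a convenience for simulation and testing.
#'
#' @param xlim,ylim extent of the coordinate space.
#' @inheritParams aoi_scheme
#' @return an `aoi_scheme` tibble.
#' @export
aoi_scheme_grid <- function(xlim = c(0, 1), ylim = c(0, 1),
                            coordinate_space = "normalized [0,1] x [0,1]") {
  xs <- seq(xlim[1], xlim[2], length.out = 4)
  ys <- seq(ylim[1], ylim[2], length.out = 4)
  # layout[row, col], row 1 = top (largest y)
  layout <- matrix(c("A", "D", "G",
                     "B", "E", "H",
                     "C", "F", "I"), nrow = 3, byrow = TRUE)
  regions <- purrr::map_dfr(1:3, function(r) purrr::map_dfr(1:3, function(c) {
    tibble(aoi = layout[r, c],
           xmin = xs[c], xmax = xs[c + 1],
           ymin = ys[4 - r], ymax = ys[5 - r])
  }))
  aoi_scheme(regions, coordinate_space = coordinate_space)
}

#' Read an AOI scheme from a YAML or JSON config file
#'
#' The file must contain a `regions` list of objects with fields `aoi`,
#' `xmin`, `xmax`, `ymin`, `ymax`, and may declare `coordinate_space`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `aoi_scheme` tibble.
#' @export
read_aoi_scheme <- function(path) {
  if (!file.exists(path)) {
    stop_gazeflow(sprintf("file not found: %s", path), "gazeflow_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$regions)) {
    stop_gazeflow("scheme file must contain a `regions` entry.", "gazeflow_config_error")
  }
  regions <- purrr::map_dfr(if (is.data.frame(cfg$regions)) list(cfg$regions) else cfg$regions,
                            as_tibble)
  aoi_scheme(regions,
             coordinate_space = cfg$coordinate_space %||% "normalized [0,1] x [0,1]")
}

locate_aoi <- function(x, y, scheme) {
  xlim <- attr(scheme, "xlim"); ylim <- attr(scheme, "ylim")
  out <- rep("unclassified", length(x))
  for (i in seq_len(nrow(scheme))) {
    xmax <- scheme$xmax[i]; ymax <- scheme$ymax[i]
    in_x <- x >= scheme$xmin[i] & (x < xmax | (xmax >= xlim[2] & x == xmax))
    in_y <- y >= scheme$ymin[i] & (y < ymax | (ymax >= ylim[2] & y == ymax))
    hit <- in_x & in_y & out == "unclassified"
    out[hit] <- scheme$aoi[i]
  }
  out
}

#' Assign fixations to AOI regions
#'
#' Labels each fixation with the AOI region containing its centroid.
#' Centroids falling outside every region receive the sentinel label
#' `"unclassified"` and are reported in a warning — never silently assigned
#' or dropped.
#'
#' @param fixations fixation tibble from [detect_fixations()] /
#'   [merge_glances()].
#' @param scheme an [aoi_scheme()].
#' @return the fixation tibble with an `aoi` column appended; row order
#'   unchanged. Use [as_aoi_sequence()] to extract the label/duration pairs.
#' @export
code_fixations <- function(fixations, scheme) {
  fx <- as_tibble(fixations)
  fx$aoi <- locate_aoi(fx$cx, fx$cy, scheme)
  n_out <- sum(fx$aoi == "unclassified")
  if (n_out > 0) {
    warn(sprintf("%d fixation centroid(s) fell outside all AOI regions and were labelled 'unclassified'.",
                 n_out))
  }
  fx
}

#' Extract the AOI sequence from coded fixations
#'
#' @param fixations an AOI-coded fixation tibble (with `aoi` and `duration`
#'   columns).
#' @param drop_unclassified drop `"unclassified"` fixations (default TRUE).
#' @return an [aoi_sequence()] tibble.
#' @export
as_aoi_sequence <- function(fixations, drop_unclassified = TRUE) {
  fx <- as_tibble(fixations)
  if (drop_unclassified) fx <- fx[fx$aoi != "unclassified", , drop = FALSE]
  aoi_sequence(fx$aoi, fx$duration)
}

#' Summarize an AOI sequence into per-area statistics
#'
#' Computes, for each area, the fixation probability `p` and the mean
#' fixation duration `mean_duration_ms`. By default `p` is duration-weighted
#' (the share of total gaze time spent in the area), which pairs naturally
#' with per-area mean durations in the entropy-rate statistic; the
#' count-weighted share of fixations is available via `weight = "count"`.
#' Areas with no fixations get `p = 0`, `mean_duration_ms = 0` and
#' `empty = TRUE`.
#'
#' @param sequence an [aoi_sequence()] (or coded fixation tibble).
#' @param areas area labels to tabulate over; defaults to the scheme's nine
#'   labels.
#' @param weight `"duration"` (default) or `"count"`.
#' @return a `fixation_summary` tibble with columns `area`, `n_fixations`,
#'   `total_duration_ms`, `mean_duration_ms`, `p`, `empty`.
#' @export
#' @examples
#' s <- aoi_sequence(c("D", "D", "E"), c(200, 200, 100))
#' summarize_fixations(s, areas = c("D", "E"))
summarize_fixations <- function(sequence, areas = aoi_labels(),
                                weight = c("duration", "count")) {
  weight <- match.arg(weight)
  seq_tbl <- as_tibble(sequence)
  if ("duration" %in% names(seq_tbl) && !"duration_ms" %in% names(seq_tbl)) {
    seq_tbl$duration_ms <- seq_tbl$duration
  }
  if (nrow(seq_tbl) == 0) {
    stop_gazeflow("cannot summarize an empty AOI sequence.", "gazeflow_data_error")
  }
  stray <- setdiff(unique(seq_tbl$aoi), areas)
  if (length(stray) > 0) {
    stop_gazeflow(sprintf("sequence contains labels outside `areas`: %s",
                          paste(stray, collapse = ", ")),
                  "gazeflow_data_error")
  }
  agg <- seq_tbl |>
    dplyr::mutate(area = factor(.data$aoi, levels = areas)) |>
    dplyr::group_by(.data$area, .drop = FALSE) |>
    dplyr::summarise(n_fixations = dplyr::n(),
                     total_duration_ms = sum(.data$duration_ms),
                     mean_duration_ms = ifelse(dplyr::n() > 0,
                                               mean(.data$duration_ms), 0),
                     .groups = "drop") |>
    dplyr::mutate(total_duration_ms = dplyr::coalesce(.data$total_duration_ms, 0),
                  mean_duration_ms = dplyr::coalesce(.data$mean_duration_ms, 0),
                  p = if (weight == "duration") {
                    .data$total_duration_ms / sum(.data$total_duration_ms)
                  } else {
                    .data$n_fixations / sum(.data$n_fixations)
                  },
                  empty = .data$n_fixations == 0L,
                  area = as.character(.data$area))
  out <- agg[c("area", "n_fixations", "total_duration_ms",
               "mean_duration_ms", "p", "empty")]
  class(out) <- c("fixation_summary", class(tibble()))
  out
}

#' Build a fixation summary directly from per-area statistics
#'
#' Convenience constructor for the common case where per-area mean durations
#' and occupancy shares are already tabulated (e.g. published per-driver
#' statistics). Shares are renormalized to sum to 1.
#'
#' @param area area labels.
#' @param p occupancy probabilities or percentage shares (renormalized).
#' @param mean_duration_ms per-area mean fixation duration in ms.
#' @return a `fixation_summary` tibble.
#' @export
fixation_summary <- function(area, p, mean_duration_ms) {
  if (any(p < 0) || sum(p) <= 0) {
    stop_gazeflow("`p` must be non-negative with a positive sum.", "gazeflow_data_error")
  }
  out <- tibble(area = as.character(area),
                n_fixations = NA_integer_,
                total_duration_ms = NA_real_,
                mean_duration_ms = as.numeric(mean_duration_ms),
                p = p / sum(p),
                empty = p == 0)
  class(out) <- c("fixation_summary", class(tibble()))
  out
}
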