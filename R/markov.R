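default_states <- function(labels) {
  u <- unique(labels)
  if (all(u %in% aoi_labels())) aoi_labels() else sort(u)
}

seq_labels <- function(sequence) {
  if (is.character(sequence)) return(sequence)
  s <- as_tibble(sequence)
  if (!"aoi" %in% names(s)) {
    stop_gazeflow("sequence must be a character vector or a tibble with an `aoi` column.",
                  "gazeflow_data_error")
  }
  s$aoi
}

count_lag_pairs <- function(labels, states, lag) {
  n <- length(labels)
  from <- factor(labels[seq_len(n - lag)], levels = states)
  to <- factor(labels[seq(lag + 1, n)], levels = states)
  if (anyNA(from) || anyNA(to)) {
    stop_gazeflow("sequence contains labels outside the declared state set.",
                  "gazeflow_data_error")
  }
  m <- table(from, to)
  matrix(as.integer(m), nrow = length(states),
         dimnames = list(states, states))
}

row_normalize <- function(counts) {
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  P[rs == 0, ] <- 0
  P
}

#' Fit a Markov transition model to an AOI sequence
#'
#' Estimates the one-step transition matrix (counts of adjacent fixation
#' pairs, row-normalized) and, when the sequence has at least three
#' entries, the *empirical* two-step matrix: lag-2 pair frequencies,
#' deliberately not the matrix square of the one-step matrix. The two are
#' equal in expectation only when the gaze process is genuinely first-order
#' Markov (Chapman–Kolmogorov); comparing them is how "looking back"
#' behaviour — whether gaze returns to an area after two shifts — is read
#' off real scanpaths.
#'
#' States with no observed outgoing transitions keep all-zero rows and are
#' reported in `zero_rows`; such matrices are handled gracefully by
#' [stationary_distribution()].
#'
#' @param sequence an [aoi_sequence()], coded fixation tibble, or character
#'   vector of labels.
#' @param states ordered state labels; defaults to the nine AOI labels when
#'   all observed labels belong to them, otherwise the sorted observed set.
#' @return a `gaze_markov` object: list with `states`, `counts1`, `P1`,
#'   `counts2`, `P2_emp` (both `NULL` for length-2 sequences), `n_obs`,
#'   `zero_rows`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' m <- fit_transition_model(c("D", "E", "D", "D"))
#' m$P1["D", ]
fit_transition_model <- function(sequence, states = NULL) {
  labels <- seq_labels(sequence)
  if (length(labels) < 2) {
    stop_gazeflow("need at least 2 fixations to estimate one-step transitions.",
                  "gazeflow_data_error")
  }
  states <- states %||% default_states(labels)
  counts1 <- count_lag_pairs(labels, states, 1L)
  counts2 <- if (length(labels) >= 3) count_lag_pairs(labels, states, 2L)
  P1 <- row_normalize(counts1)
  structure(list(states = states,
                 counts1 = counts1, P1 = P1,
                 counts2 = counts2,
                 P2_emp = if (!is.null(counts2)) row_normalize(counts2),
                 n_obs = length(labels),
                 zero_rows = states[rowSums(counts1) == 0]),
            class = "gaze_markov")
}

#' One-step transition matrix estimate
#'
#' @inheritParams fit_transition_model
#' @return a `gaze_markov` model (see [fit_transition_model()]).
#' @export
estimate_one_step <- function(sequence, states = NULL) {
  fit_transition_model(sequence, states = states)
}

#' Empirical two-step transition matrix
#'
#' Row-normalized frequencies of lag-2 pairs \eqn{(s_t, s_{t+2})} — the
#' observed two-step matrix, not the square of the one-step matrix.
#'
#' @inheritParams fit_transition_model
#' @return a row-stochastic matrix (zero rows where a state was never seen
#'   at lag-2 origin).
#' @export
estimate_two_step_empirical <- function(sequence, states = NULL) {
  labels <- seq_labels(sequence)
  if (length(labels) < 3) {
    stop_gazeflow("need at least 3 fixations to estimate two-step transitions.",
                  "gazeflow_data_error")
  }
  states <- states %||% default_states(labels)
  row_normalize(count_lag_pairs(labels, states, 2L))
}

check_stochastic <- function(P, tol = 1e-8, allow_zero_rows = FALSE) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || anyNA(P)) {
    stop_gazeflow("transition matrix must be a square numeric matrix without NA/NaN.",
                  "gazeflow_data_error")
  }
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop_gazeflow("transition probabilities must lie in [0, 1].", "gazeflow_data_error")
  }
  rs <- rowSums(P)
  bad <- if (allow_zero_rows) abs(rs - 1) > tol & rs != 0 else abs(rs - 1) > tol
  if (any(bad)) {
    stop_gazeflow(sprintf("row(s) %s do not sum to 1.",
                          paste(which(bad), collapse = ", ")),
                  "gazeflow_data_error")
  }
  invisible(P)
}

#' k-step transition matrix by matrix power
#'
#' For a first-order Markov chain the k-step transition matrix is the k-th
#' power of the one-step matrix.
#'
#' @param P1 row-stochastic one-step matrix.
#' @param k positive integer number of steps.
#' @return the matrix power `P1^k` (row-stochastic).
#' @export
k_step_power <- function(P1, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != round(k)) {
    stop_gazeflow("`k` must be a single positive integer.", "gazeflow_param_error")
  }
  check_stochastic(P1)
  out <- P1
  if (k > 1) for (i in seq_len(k - 1)) out <- out %*% P1
  out
}

#' Stationary distribution of a transition matrix
#'
#' Solves \eqn{X P = X} with \eqn{\sum_i x_i = 1} through the stacked
#' least-squares system \eqn{[P^\top - I;\; \mathbf{1}^\top] x = [0; 1]}
#' using the Moore–Penrose pseudoinverse, so reducible matrices and
#' matrices with unobserved (all-zero, treated as absorbing-in-place) rows
#' still yield a well-defined answer: the minimum-norm solution, which is
#' uniform over the solution set when the stationary distribution is not
#' unique (e.g. the identity matrix). Tiny negative entries from the solve
#' are clipped and the vector renormalized.
#'
#' @param P a row-stochastic matrix or a `gaze_markov` model. For a model
#'   with unobserved states the solve is restricted to the recurrent
#'   observed sub-chain and the unvisited states carry exact zeros — the
#'   form steady-state gaze vectors are conventionally reported in.
#' @param tol numerical tolerance.
#' @return named probability vector with attributes `unique` (is the
#'   eigenvalue 1 simple?) and `reducible_rows` (states with no observed
#'   outgoing transitions).
#' @export
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' stationary_distribution(P)  # (5/6, 1/6)
stationary_distribution <- function(P, tol = 1e-10) {
  zero_rows <- character()
  if (inherits(P, "gaze_markov")) {
    model <- P
    zero_rows <- model$zero_rows
    if (length(zero_rows) > 0) {
      # solve on the observed sub-chain; unvisited states carry exact zeros
      keep <- setdiff(model$states, zero_rows)
      repeat {
        rs <- rowSums(model$counts1[keep, keep, drop = FALSE])
        if (all(rs > 0) || length(keep) == 0) break
        keep <- keep[rs > 0]
      }
      if (length(keep) == 0) {
        stop_gazeflow("no recurrent observed states; stationary distribution undefined.",
                      "gazeflow_data_error")
      }
      sub <- model$counts1[keep, keep, drop = FALSE]
      x_sub <- stationary_distribution(sub / rowSums(sub), tol = tol)
      x <- stats::setNames(numeric(length(model$states)), model$states)
      x[keep] <- as.numeric(x_sub)
      return(structure(x, unique = attr(x_sub, "unique"),
                       reducible_rows = zero_rows))
    }
    P <- model$P1
  }
  check_stochastic(P)
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  x <- as.numeric(MASS::ginv(A) %*% b)
  x[x < 0 & x > -1e-8] <- 0
  if (any(x < 0)) {
    stop_gazeflow("stationary solve produced substantially negative entries.",
                  "gazeflow_data_error")
  }
  x <- x / sum(x)
  ev <- eigen(t(P), only.values = TRUE)$values
  unique_soln <- sum(abs(ev - 1) < 1e-8) == 1
  structure(stats::setNames(x, rownames(P) %||% paste0("s", seq_len(n))),
            unique = unique_soln, reducible_rows = zero_rows)
}

#' Default six-state AOI grouping
#'
#' Merges the nine regions into the six analysis groups: left (`A+B`),
#' left-bottom (`C`), front (`D+E`), in-vehicle (`F`), right (`G+H`),
#' right-bottom (`I`).
#'
#' @return named character vector mapping each nine-region label to its
#'   group, in the canonical group order `A+B, C, D+E, F, G+H, I`.
#' @export
aoi_grouping_default6 <- function() {
  c(A = "A+B", B = "A+B", C = "C", D = "D+E", E = "D+E",
    F = "F", G = "G+H", H = "G+H", I = "I")
}

#' Merge states of a transition model
#'
#' Aggregates the raw transition counts over a grouping of the state space
#' (both axes) and re-normalizes, conserving total transition counts
#' exactly. The default grouping collapses the nine AOI regions to the six
#' left/front/right analysis groups.
#'
#' @param model a `gaze_markov` model.
#' @param grouping named character vector mapping every state of `model` to
#'   a group label; group order follows first appearance in `grouping`.
#' @return a `gaze_markov` model over the merged state space.
#' @export
merge_states <- function(model, grouping = aoi_grouping_default6()) {
  missing <- setdiff(model$states, names(grouping))
  if (length(missing) > 0) {
    stop_gazeflow(sprintf("grouping does not cover state(s): %s",
                          paste(missing, collapse = ", ")),
                  "gazeflow_config_error")
  }
  groups <- unique(unname(grouping[model$states]))
  agg <- function(cnt) {
    if (is.null(cnt)) return(NULL)
    g <- factor(grouping[model$states], levels = groups)
    m <- rowsum(t(rowsum(cnt, g)), g)
    out <- matrix(as.numeric(t(m)), nrow = length(groups),
                  dimnames = list(groups, groups))
    out
  }
  counts1 <- agg(model$counts1)
  counts2 <- agg(model$counts2)
  structure(list(states = groups,
                 counts1 = counts1, P1 = row_normalize(counts1),
                 counts2 = counts2,
                 P2_emp = if (!is.null(counts2)) row_normalize(counts2),
                 n_obs = model$n_obs,
                 zero_rows = groups[rowSums(counts1) == 0]),
            class = "gaze_markov")
}

#' Change proportion between one- and two-step transition probabilities
#'
#' Quantifies how a transition's probability changes from the one-step to
#' the (empirical) two-step matrix:
#' increase `100 * (p_two - p_one) / p_one`, reduce
#' `100 * (p_one - p_two) / p_one`. A rise marks transitions that become
#' *more* likely after an intervening fixation (gaze returning to the
#' area); a drop marks areas not held under continuous gaze.
#'
#' @param p_one one-step probability (> 0).
#' @param p_two two-step probability.
#' @param direction `"increase"` or `"reduce"`.
#' @return percent change (vectorized over the probabilities).
#' @export
#' @examples
#' transition_change_proportion(0.1539, 0.2308, "increase")  # 49.97
transition_change_proportion <- function(p_one, p_two,
                                         direction = c("increase", "reduce")) {
  direction <- match.arg(direction)
  if (any(p_one <= 0)) {
    stop_gazeflow("`p_one` must be positive; change proportion is undefined at 0.",
                  "gazeflow_data_error")
  }
  if (any(c(p_one, p_two) < 0) || any(c(p_one, p_two) > 1)) {
    stop_gazeflow("probabilities must lie in [0, 1].", "gazeflow_data_error")
  }
  if (direction == "increase") 100 * (p_two - p_one) / p_one
  else 100 * (p_one - p_two) / p_one
}

#' @export
print.gaze_markov <- function(x, ...) {
  cat(sprintf("<gaze_markov> %d states (%s), %d fixations\n",
              length(x$states), paste(x$states, collapse = ", "), x$n_obs))
  cat("one-step matrix:\n")
  print(round(x$P1, 4))
  if (length(x$zero_rows) > 0) {
    cat("states with no observed outgoing transitions:",
        paste(x$zero_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a transition model into long form
#'
#' @param x a `gaze_markov` model.
#' @param ... unused.
#' @return tibble with columns `step` (`"one"`/`"two"`), `from`, `to`,
#'   `count`, `probability`.
#' @method tidy gaze_markov
#' @export
tidy.gaze_markov <- function(x, ...) {
  long <- function(cnt, P, step) {
    if (is.null(cnt)) return(NULL)
    tidyr::expand_grid(from = x$states, to = x$states) |>
      dplyr::mutate(step = step,
                    count = as.integer(cnt[cbind(.data$from, .data$to)]),
                    probability = P[cbind(.data$from, .data$to)]) |>
      dplyr::select("step", "from", "to", "count", "probability")
  }
  dplyr::bind_rows(long(x$counts1, x$P1, "one"),
                   long(x$counts2, x$P2_emp, "two"))
}

#' One-row summary of a transition model
#'
#' @param x a `gaze_markov` model.
#' @param ... unused.
#' @return tibble with state/observation counts, zero-row count and
#'   whether the stationary distribution is unique.
#' @method glance gaze_markov
#' @export
glance.gaze_markov <- function(x, ...) {
  pi_hat <- stationary_distribution(x)
  tibble(n_states = length(x$states),
         n_fixations = x$n_obs,
         n_transitions = sum(x$counts1),
         n_zero_rows = length(x$zero_rows),
         stationary_unique = attr(pi_hat, "unique"))
}
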