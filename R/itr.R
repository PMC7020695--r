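#' Wolpaw information transfer rate per trial
#'
#' Computes the channel-capacity-style information transfer rate (ITR) of an
#' N-class selection system with accuracy P, in bits per trial:
#'
#' \deqn{ITR = \log_2 N + P \log_2 P + (1 - P) \log_2\frac{1 - P}{N - 1}}
#'
#' The convention \eqn{x \log_2 x = 0} at \eqn{x = 0} is used, so both
#' `accuracy = 0` and `accuracy = 1` are finite; at chance level
#' (`accuracy = 1/num_classes`) the expression collapses to exactly zero.
#'
#' The formula is evaluated verbatim for below-chance accuracy
#' (`accuracy < 1/num_classes`), where it is positive even though the channel
#' is uninformative in the intended direction; a warning is raised rather
#' than clamping the value.
#'
#' @param num_classes Integer number of selectable classes N, at least 2.
#'   Vectorised.
#' @param accuracy Classification accuracy P in \[0, 1\]. Vectorised.
#' @return Numeric vector of bits per trial.
#' @examples
#' bits_per_trial(2, 0.75)   # 0.1887 -> prints as 0.19 at 2 decimals
#' bits_per_trial(2, 0.5)    # exactly 0 at chance
#' bits_per_trial(10, 1)     # log2(10)
#' @seealso [bits_per_minute()], [archetype_table()]
#' @export
bits_per_trial <- function(num_classes, accuracy) {
  check_num_classes(num_classes)
  check_probability(accuracy, "accuracy")
  n <- vctrs_recycle(num_classes, accuracy)
  num_classes <- n[[1]]
  accuracy <- n[[2]]
  if (any(accuracy < 1 / num_classes - 1e-12)) {
    warn(paste(
      "accuracy below chance level (1/num_classes): the Wolpaw formula is",
      "evaluated verbatim and yields a positive value in this regime"
    ), class = "bbisim_below_chance")
  }
  log2(num_classes) + xlog2x(accuracy) +
    (1 - accuracy) * log2_ratio(1 - accuracy, num_classes - 1)
}

# x * log2(x) with the information-theoretic limit 0 at x = 0
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

# log2(x / d), finite companion for (1-P) * log2((1-P)/(N-1)); the caller
# multiplies by (1-P), so the value at 1-P = 0 is irrelevant but must not be NaN
log2_ratio <- function(x, d) {
  out <- log2(x / d)
  out[x == 0] <- 0
  out
}

vctrs_recycle <- function(a, b) {
  n <- max(length(a), length(b))
  list(rep_len(a, n), rep_len(b, n))
}

check_num_classes <- function(num_classes) {
  if (!is.numeric(num_classes) || any(is.na(num_classes)) ||
      any(num_classes < 2) || any(num_classes != round(num_classes))) {
    abort("`num_classes` must be an integer >= 2", class = "bbisim_domain_error")
  }
}

check_probability <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", what), class = "bbisim_domain_error")
  }
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive", what), class = "bbisim_domain_error")
  }
}

#' Trials per minute of a windowed BCI
#'
#' Converts an analysis window of length `window_length` seconds refreshed at
#' `update_rate` hertz into a trial rate, `window_length * update_rate * 60`.
#' This product is a trial count under the convention that every window
#' update constitutes a trial (the passive-monitoring reading); systems where
#' this does not hold can override `trials_per_min` directly in [bci_spec()].
#'
#' @param window_length Window length L in seconds, positive.
#' @param update_rate Window update rate U in hertz, positive.
#' @return Trials per minute.
#' @examples
#' trials_per_minute(1, 10) # 600, the two-class monitoring archetype
#' @export
trials_per_minute <- function(window_length, update_rate) {
  check_positive(window_length, "window_length")
  check_positive(update_rate, "update_rate")
  window_length * update_rate * 60
}

#' Convert bits per trial to bits per minute
#'
#' @param bits_per_trial Bits per trial, non-negative.
#' @param trials_per_min Trials per minute, non-negative.
#' @param round_first If `TRUE`, `bits_per_trial` is first rounded to two
#'   decimals, reproducing the printed-table convention in which the
#'   per-minute rate is the displayed per-trial value times the trial rate
#'   (e.g. 0.19 x 600 = 114, not 0.1887 x 600 = 113.2). Defaults to `FALSE`
#'   (exact product).
#' @return Bits per minute.
#' @examples
#' bits_per_minute(bits_per_trial(2, 0.75), 600, round_first = TRUE) # 114
#' @export
bits_per_minute <- function(bits_per_trial, trials_per_min, round_first = FALSE) {
  if (any(bits_per_trial < 0) || any(trials_per_min < 0)) {
    abort("`bits_per_trial` and `trials_per_min` must be non-negative",
          class = "bbisim_domain_error")
  }
  if (round_first) bits_per_trial <- round(bits_per_trial, 2)
  bits_per_trial * trials_per_min
}

#' BCI system specification
#'
#' Bundles the read-side (brain-to-computer) parameters of a closed-loop
#' interface: number of classes, classifier accuracy, analysis window length
#' and update rate. `trials_per_min` defaults to the window product
#' [trials_per_minute()] but may be overridden for protocols where a trial is
#' not one window update.
#'
#' @param num_classes Integer N >= 2.
#' @param accuracy Classifier accuracy P in \[0, 1\].
#' @param window_length Window length L in seconds, positive.
#' @param update_rate Update rate U in hertz, positive.
#' @param trials_per_min Trials per minute; defaults to
#'   `window_length * update_rate * 60`.
#' @return An object of class `bci_spec`.
#' @examples
#' bci_spec(2, 0.99999, window_length = 1, update_rate = 10)
#' @export
bci_spec <- function(num_classes, accuracy, window_length = 1,
                     update_rate = 10,
                     trials_per_min = trials_per_minute(window_length, update_rate)) {
  check_num_classes(num_classes)
  check_probability(accuracy, "accuracy")
  check_positive(window_length, "window_length")
  check_positive(update_rate, "update_rate")
  check_positive(trials_per_min, "trials_per_min")
  structure(
    list(
      num_classes = as.integer(num_classes), accuracy = accuracy,
      window_length = window_length, update_rate = update_rate,
      trials_per_min = trials_per_min
    ),
    class = "bci_spec"
  )
}

#' @export
print.bci_spec <- function(x, ...) {
  cat(sprintf(
    "<bci_spec> N = %d classes, P = %g, window %g s @ %g Hz (%g trials/min)\n",
    x$num_classes, x$accuracy, x$window_length, x$update_rate, x$trials_per_min
  ))
  invisible(x)
}

# The four reference EEG BCI archetypes: a passive two-class medical monitor,
# a consumer (gaming) headset, a many-channel research rig and a P300-style
# virtual keyboard.
bci_archetypes <- function() {
  tibble::tibble(
    archetype = c("medical monitor", "consumer", "research", "virtual keyboard"),
    num_classes = c(2L, 5L, 10L, 50L),
    trials_per_min = c(600, 60, 30, 30)
  )
}

#' Reference ITR table for four EEG BCI archetypes
#'
#' Evaluates bits per trial and bits per minute for four archetypal EEG BCI
#' systems (two-class medical monitor at 600 trials/min, five-class consumer
#' at 60, ten-class research at 30, fifty-class virtual keyboard at 30) at
#' low, medium and near-perfect accuracy. The near-perfect level is
#' P = 0.99999, labelled "~1 (0.99999)": at that accuracy bits/trial equals
#' log2(N) to two decimals, which P = 0.99 would not (N = 10 at P = 0.99
#' gives 3.21, not 3.32).
#'
#' Bits/trial is reported rounded to two decimals and bits/min as the rounded
#' bits/trial times trials/min, the convention of the printed reference table
#' (see [bits_per_minute()] argument `round_first`).
#'
#' @param accuracies Accuracy levels to tabulate; default `c(0.5, 0.75, 0.99999)`.
#' @return A tibble with one row per archetype x accuracy: `archetype`,
#'   `num_classes`, `accuracy`, `accuracy_label`, `bits_per_trial`,
#'   `trials_per_min`, `bits_per_min`.
#' @examples
#' archetype_table()
#' @export
archetype_table <- function(accuracies = c(0.5, 0.75, 0.99999)) {
  check_probability(accuracies, "accuracies")
  tidyr::crossing(bci_archetypes(), accuracy = accuracies) |>
    dplyr::mutate(
      accuracy_label = ifelse(.data$accuracy > 0.99 & .data$accuracy < 1,
                              sprintf("~1 (%g)", .data$accuracy),
                              as.character(.data$accuracy)),
      bits_per_trial = round(bits_per_trial(.data$num_classes, .data$accuracy), 2),
      bits_per_min = bits_per_minute(.data$bits_per_trial, .data$trials_per_min)
    ) |>
    dplyr::arrange(factor(.data$archetype, levels = bci_archetypes()$archetype),
                   .data$accuracy) |>
    dplyr::select("archetype", "num_classes", "accuracy", "accuracy_label",
                  "bits_per_trial", "trials_per_min", "bits_per_min")
}

# Printed reference values for the archetype table (three rows per archetype:
# bits/trial, trials/min, bits/min at accuracies 0.5 / 0.75 / ~1).
table1_printed <- function() {
  tibble::tribble(
    ~archetype,         ~accuracy, ~bits_per_trial, ~trials_per_min, ~bits_per_min,
    "medical monitor",  0.5,       0,               600,             0,
    "medical monitor",  0.75,      0.19,            600,             114,
    "medical monitor",  0.99999,   1,               600,             600,
    "consumer",         0.5,       0.32,            60,              19.2,
    "consumer",         0.75,      1.01,            60,              60.6,
    "consumer",         0.99999,   2.32,            60,              139.2,
    "research",         0.5,       0.74,            30,              22.2,
    "research",         0.75,      1.72,            30,              51.6,
    "research",         0.99999,   3.32,            30,              99.6,
    "virtual keyboard", 0.5,       1.84,            30,              55.2,
    "virtual keyboard", 0.75,      3.43,            30,              102.9,
    "virtual keyboard", 0.99999,   5.64,            30,              169.2
  )
}

#' Recompute the reference archetype table and compare with its printed values
#'
#' Recomputes every computed numeric cell of the four-archetype reference
#' table — bits/trial and bits/min for 4 archetypes x 3 accuracy levels, 24
#' cells — and compares each, at the printed precision, with the published
#' value. The trials/min rows are inputs to the table, not computed cells,
#' and are excluded from the comparison.
#'
#' @return A tibble with one row per cell: `archetype`, `accuracy`,
#'   `quantity`, `printed`, `recomputed`, `match`. The attribute `n_match`
#'   holds the number of matching cells out of `n_cells`.
#' @examples
#' cmp <- reproduce_table1()
#' sum(cmp$match) # 24 of 24
#' @export
reproduce_table1 <- function() {
  recomputed <- archetype_table() |>
    dplyr::select("archetype", "accuracy", "bits_per_trial", "bits_per_min") |>
    tidyr::pivot_longer(c("bits_per_trial", "bits_per_min"),
                        names_to = "quantity", values_to = "recomputed")
  printed <- table1_printed() |>
    dplyr::select(-"trials_per_min") |>
    tidyr::pivot_longer(c("bits_per_trial", "bits_per_min"),
                        names_to = "quantity", values_to = "printed")
  out <- dplyr::left_join(printed, recomputed,
                          by = c("archetype", "accuracy", "quantity")) |>
    dplyr::mutate(match = abs(round(.data$recomputed, 2) - .data$printed) < 1e-9)
  structure(out, n_match = sum(out$match), n_cells = nrow(out))
}

#' Write the archetype ITR table to CSV
#'
#' Numeric ITR columns are formatted to two decimals to mirror the printed
#' reference table.
#'
#' @param table Result of [archetype_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_archetype_csv <- function(table, path) {
  out <- table |>
    dplyr::mutate(
      bits_per_trial = sprintf("%.2f", .data$bits_per_trial),
      bits_per_min = sprintf("%.2f", .data$bits_per_min)
    ) |>
    dplyr::select("archetype", "accuracy", "num_classes", "bits_per_trial",
                  "trials_per_min", "bits_per_min")
  readr::write_csv(out, path)
  invisible(path)
}
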