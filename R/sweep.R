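#' Parameter grid for a latency x SFR x timeout sweep
#'
#' Default grids follow the reference study conditions: latencies from 0.1
#' to 1.0 s in 0.1-s steps, stimulation failure rates
#' \{0, 5, 10, 25, 50, 75, 100\}%, timeouts from 0.1 to 1.5 s in 0.1-s
#' steps, all driving the two-class passive-monitoring BCI (N = 2,
#' P = 0.99999, 1-s window at 10 Hz, 600 trials/min). Cells with a timeout
#' shorter than the latency violate the cycle-budget constraint and are
#' excluded from the sweep rather than zero-filled.
#'
#' The default loop composition for sweeps is `"pipelined"` (the next
#' analysis window overlaps the stimulation cycle): that is the composition
#' under which the monitoring loop approaches its 600 bpm ceiling at low
#' latency even under a 25% failure rate, with the most efficient timeout no
#' more than twice the latency. See [effective_itr()] for the sequential
#' alternative.
#'
#' @param latencies Latency grid in seconds.
#' @param sfrs Stimulation-failure-rate grid, probabilities.
#' @param timeouts Timeout grid in seconds.
#' @param bci Base [bci_spec()] held constant across the sweep.
#' @param mode Loop composition for every cell, `"pipelined"` (default) or
#'   `"sequential"`.
#' @param method `"analytic"` (default) or `"monte_carlo"` per cell.
#' @param n_trials Monte-Carlo trials per cell.
#' @param seed Base seed; per-cell seeds are derived from it
#'   deterministically.
#' @param max_attempts Retry cap per cell; default 3.
#' @return An object of class `sweep_grid`.
#' @examples
#' sweep_grid()
#' @export
sweep_grid <- function(latencies = seq(0.1, 1.0, by = 0.1),
                       sfrs = c(0, 0.05, 0.10, 0.25, 0.50, 0.75, 1.0),
                       timeouts = seq(0.1, 1.5, by = 0.1),
                       bci = bci_spec(2, 0.99999, window_length = 1, update_rate = 10),
                       mode = c("pipelined", "sequential"),
                       method = c("analytic", "monte_carlo"),
                       n_trials = 1e4, seed = 1L, max_attempts = 3) {
  mode <- rlang::arg_match(mode)
  method <- rlang::arg_match(method)
  check_positive(latencies, "latencies")
  check_probability(sfrs, "sfrs")
  check_positive(timeouts, "timeouts")
  stopifnot(inherits(bci, "bci_spec"))
  if (length(latencies) == 0 || length(sfrs) == 0 || length(timeouts) == 0) {
    abort("all three grids must be non-empty", class = "bbisim_config_error")
  }
  structure(
    list(latencies = sort(unique(latencies)), sfrs = sort(unique(sfrs)),
         timeouts = sort(unique(timeouts)), bci = bci, mode = mode,
         method = method, n_trials = n_trials, seed = as.integer(seed),
         max_attempts = max_attempts),
    class = "sweep_grid"
  )
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf(
    "<sweep_grid> %d latencies x %d SFRs x %d timeouts, mode %s, method %s\n",
    length(x$latencies), length(x$sfrs), length(x$timeouts), x$mode, x$method
  ))
  invisible(x)
}

#' Run a latency x SFR x timeout sweep
#'
#' Evaluates [effective_itr()] once per feasible grid cell (timeout at least
#' the latency) and returns the long-format table the downstream hypothesis
#' checks, surfaces and ANOVA consume. Rows are sorted lexicographically by
#' (sfr, latency, timeout). Monte-Carlo cells draw from per-cell seeds
#' derived from the grid seed, so a re-run with the same grid is
#' reproducible bit for bit.
#'
#' @param grid A [sweep_grid()].
#' @return A tibble of class `sweep_table` with columns `latency`, `sfr`,
#'   `timeout`, `feasible_attempts`, `delivery_rate`, `mean_cbi_time`,
#'   `mean_trial_period`, `effective_bpm`. Attributes `mode`, `method` and
#'   `base_bpm` (the unrestricted BCI rate `bits_per_trial x trials/min`)
#'   record the sweep conditions.
#' @examples
#' head(run_sweep(sweep_grid()))
#' @export
run_sweep <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- tidyr::crossing(sfr = grid$sfrs, latency = grid$latencies,
                           timeout = grid$timeouts) |>
    dplyr::filter(.data$timeout >= .data$latency - 1e-9) |>
    dplyr::arrange(.data$sfr, .data$latency, .data$timeout)
  if (nrow(cells) == 0) {
    abort("no feasible grid cells: every timeout is shorter than every latency",
          class = "bbisim_config_error")
  }
  res <- purrr::pmap(
    list(cells$latency, cells$sfr, cells$timeout, seq_len(nrow(cells))),
    function(l, f, t, idx) {
      cbi <- cbi_spec(l, f, t, max_attempts = grid$max_attempts)
      s <- effective_itr(
        grid$bci, cbi, mode = grid$mode, method = grid$method,
        n_trials = grid$n_trials, seed = cell_seed(grid$seed, idx)
      )
      tibble::tibble(
        feasible_attempts = feasible_attempts(cbi),
        delivery_rate = s$delivery_rate, mean_cbi_time = s$mean_cbi_time,
        mean_trial_period = s$mean_trial_period,
        effective_bpm = s$effective_bpm
      )
    }
  ) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    cells[, c("latency", "sfr", "timeout")], res
  )
  attr(out, "mode") <- grid$mode
  attr(out, "method") <- grid$method
  attr(out, "base_bpm") <- bits_per_trial(grid$bci$num_classes, grid$bci$accuracy) *
    grid$bci$trials_per_min
  class(out) <- c("sweep_table", class(out))
  out
}

# deterministic per-cell seed kept inside 32-bit integer range
cell_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(idx)) %% 2147483647)
}

# tolerance for comparing effective_bpm values that are analytically equal
# but computed through different attempt-count branches
bpm_tol <- function(table) 1e-8 * max(table$effective_bpm, 1)

#' Best-performing cell at a given failure rate
#'
#' Scans the sweep table at one SFR for the cell with maximal effective
#' bits/min; ties (within numerical tolerance) are broken toward the smaller
#' latency, then the smaller timeout.
#'
#' @param table A `sweep_table` from [run_sweep()].
#' @param sfr Failure rate to condition on; must be present in the table.
#' @return A one-row tibble: `latency`, `timeout`, `effective_bpm`.
#' @examples
#' find_optimum(run_sweep(sweep_grid()), sfr = 0.25)
#' @export
find_optimum <- function(table, sfr) {
  slice <- table[abs(table$sfr - sfr) < 1e-9, ]
  if (nrow(slice) == 0) {
    abort(sprintf("sfr = %g is not present in the sweep table", sfr),
          class = "bbisim_lookup_error")
  }
  tol <- bpm_tol(slice)
  best <- slice |>
    dplyr::filter(.data$effective_bpm >= max(.data$effective_bpm) - tol) |>
    dplyr::arrange(.data$latency, .data$timeout) |>
    dplyr::slice(1)
  best[, c("latency", "timeout", "effective_bpm")]
}

#' Check that shorter latency never hurts throughput
#'
#' Operationalizes the first design hypothesis of the loop model: a shorter
#' latency improves (never worsens) the effective ITR, even at high failure
#' rates. Cells are stratified by (sfr, timeout/latency ratio) so that the
#' compared cells share the same feasible-attempt structure, and within each
#' stratum the effective bits/min must be non-increasing in latency.
#'
#' @param table A `sweep_table` from [run_sweep()].
#' @return An object of class `hypothesis_check`: `holds` (logical),
#'   `violations` (tibble of offending cell pairs), `n_strata`.
#' @examples
#' check_hypothesis1(run_sweep(sweep_grid()))
#' @export
check_hypothesis1 <- function(table) {
  tol <- bpm_tol(table)
  strata <- table |>
    dplyr::mutate(ratio = round(.data$timeout / .data$latency, 6)) |>
    dplyr::group_by(.data$sfr, .data$ratio) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(.data$latency, .by_group = TRUE)
  violations <- strata |>
    dplyr::mutate(
      prev_latency = dplyr::lag(.data$latency),
      prev_bpm = dplyr::lag(.data$effective_bpm),
      increase = .data$effective_bpm - .data$prev_bpm
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$increase), .data$increase > tol) |>
    dplyr::select("sfr", "ratio", "prev_latency", "latency",
                  "prev_bpm", "effective_bpm", "increase")
  new_hypothesis_check(
    name = "shorter latency improves ITR, even at high failure rates",
    holds = nrow(violations) == 0,
    violations = violations,
    n_strata = dplyr::n_groups(strata)
  )
}

#' Check that timeout selection stabilizes the ITR drop under failure
#'
#' Operationalizes the second design hypothesis: a higher failure rate
#' lowers the effective ITR, but a well-chosen timeout threshold limits the
#' decline. Two conditions are verified on the sweep table:
#'
#' * monotonicity: within every (latency, timeout) cell, effective bits/min
#'   is non-increasing in SFR;
#' * stabilization: for every latency, define the *best* timeout as the one
#'   maximizing the mean bits/min across failure rates (ties toward the
#'   shortest timeout) and the *worst* analogously; across every adjacent
#'   SFR step the bits/min drop under the best timeout must not exceed the
#'   drop under the worst one.
#'
#' @param table A `sweep_table` from [run_sweep()] covering at least two
#'   SFRs and two timeouts.
#' @return An object of class `hypothesis_check` with elements `holds`,
#'   `violations` (monotonicity offenders), `stabilization` (per latency and
#'   SFR step: drops under best/worst timeout and the margin between them)
#'   and `best_timeouts` (per-latency best timeout).
#' @examples
#' chk <- check_hypothesis2(run_sweep(sweep_grid()))
#' chk$best_timeouts
#' @export
check_hypothesis2 <- function(table) {
  tol <- bpm_tol(table)

  mono_viol <- table |>
    dplyr::group_by(.data$latency, .data$timeout) |>
    dplyr::arrange(.data$sfr, .by_group = TRUE) |>
    dplyr::mutate(increase = .data$effective_bpm - dplyr::lag(.data$effective_bpm)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$increase), .data$increase > tol) |>
    dplyr::select("latency", "timeout", "sfr", "effective_bpm", "increase")

  # per latency: timeout ranked by mean bpm across the SFR grid
  ranking <- table |>
    dplyr::group_by(.data$latency, .data$timeout) |>
    dplyr::summarise(mean_bpm = mean(.data$effective_bpm), .groups = "drop")
  best <- ranking |>
    dplyr::group_by(.data$latency) |>
    dplyr::filter(.data$mean_bpm >= max(.data$mean_bpm) - tol) |>
    dplyr::summarise(best_timeout = min(.data$timeout), .groups = "drop")
  worst <- ranking |>
    dplyr::group_by(.data$latency) |>
    dplyr::filter(.data$mean_bpm <= min(.data$mean_bpm) + tol) |>
    dplyr::summarise(worst_timeout = max(.data$timeout), .groups = "drop")

  step_drops <- function(chosen, col) {
    table |>
      dplyr::inner_join(chosen, by = "latency") |>
      dplyr::filter(abs(.data$timeout - .data[[col]]) < 1e-9) |>
      dplyr::group_by(.data$latency) |>
      dplyr::arrange(.data$sfr, .by_group = TRUE) |>
      dplyr::mutate(
        sfr_from = dplyr::lag(.data$sfr),
        drop = dplyr::lag(.data$effective_bpm) - .data$effective_bpm
      ) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$drop)) |>
      dplyr::select("latency", "sfr_from", sfr_to = "sfr", "drop")
  }
  drops <- dplyr::inner_join(
    step_drops(best, "best_timeout") |> dplyr::rename(drop_best = "drop"),
    step_drops(worst, "worst_timeout") |> dplyr::rename(drop_worst = "drop"),
    by = c("latency", "sfr_from", "sfr_to")
  ) |>
    dplyr::mutate(margin = .data$drop_worst - .data$drop_best)

  stabil_ok <- all(drops$margin >= -tol)
  new_hypothesis_check(
    name = "timeout selection stabilizes the ITR decline under failure",
    holds = nrow(mono_viol) == 0 && stabil_ok,
    violations = mono_viol,
    stabilization = drops,
    best_timeouts = best
  )
}

new_hypothesis_check <- function(name, holds, violations, ...) {
  structure(list(name = name, holds = holds, violations = violations, ...),
            class = "hypothesis_check")
}

#' @export
print.hypothesis_check <- function(x, ...) {
  cat(sprintf("<hypothesis_check> %s: %s\n", x$name,
              if (x$holds) "holds" else "VIOLATED"))
  if (nrow(x$violations) > 0) {
    cat(sprintf("  %d violating cell(s):\n", nrow(x$violations)))
    print(x$violations, n = 10)
  }
  invisible(x)
}

#' Extract a 2-D ITR surface from a sweep table
#'
#' Fixing either the SFR or the latency reduces the sweep to a matrix of
#' effective bits/min over the remaining two variables (infeasible cells are
#' `NA`).
#'
#' @param table A `sweep_table` from [run_sweep()].
#' @param sfr,latency Exactly one of the two must be given; the value must
#'   be present in the table.
#' @return A tibble whose first column is the row variable (`latency` when
#'   `sfr` is fixed, `sfr` when `latency` is fixed) and whose remaining
#'   columns are the timeout grid.
#' @examples
#' surface_matrix(run_sweep(sweep_grid()), sfr = 0.25)
#' @export
surface_matrix <- function(table, sfr = NULL, latency = NULL) {
  if (is.null(sfr) == is.null(latency)) {
    abort("fix exactly one of `sfr` or `latency`", class = "bbisim_usage_error")
  }
  if (!is.null(sfr)) {
    slice <- table[abs(table$sfr - sfr) < 1e-9, ]
    if (nrow(slice) == 0) {
      abort(sprintf("sfr = %g is not present in the sweep table", sfr),
            class = "bbisim_lookup_error")
    }
    rowvar <- "latency"
  } else {
    slice <- table[abs(table$latency - latency) < 1e-9, ]
    if (nrow(slice) == 0) {
      abort(sprintf("latency = %g is not present in the sweep table", latency),
            class = "bbisim_lookup_error")
    }
    rowvar <- "sfr"
  }
  slice |>
    dplyr::select(dplyr::all_of(rowvar), "timeout", "effective_bpm") |>
    dplyr::arrange(.data[[rowvar]], .data$timeout) |>
    tidyr::pivot_wider(names_from = "timeout", values_from = "effective_bpm")
}

#' Write an ITR surface to CSV
#'
#' @inheritParams surface_matrix
#' @param path Output CSV path.
#' @return The surface tibble, invisibly.
#' @export
export_surface <- function(table, path, sfr = NULL, latency = NULL) {
  surf <- surface_matrix(table, sfr = sfr, latency = latency)
  readr::write_csv(surf, path)
  invisible(surf)
}

#' Write a sweep table to CSV
#'
#' @param table A `sweep_table` from [run_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Heat-map of effective ITR surfaces
#'
#' One latency x timeout panel per failure rate, tile colour giving the
#' effective bits/min of the closed loop.
#'
#' @param object A `sweep_table` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(run_sweep(sweep_grid()))
#' @method autoplot sweep_table
#' @export
autoplot.sweep_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$timeout, .data$latency,
                                       fill = .data$effective_bpm)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~sfr, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "bits/min") +
    ggplot2::labs(x = "timeout threshold (s)", y = "latency (s)",
                  title = "Effective ITR of the closed loop")
}

#' Line plot of one ITR surface at a fixed failure rate
#'
#' @param table A `sweep_table` from [run_sweep()].
#' @param sfr Failure rate to condition on.
#' @return A ggplot object: effective bits/min against timeout, one line per
#'   latency.
#' @export
plot_itr_surface <- function(table, sfr) {
  slice <- table[abs(table$sfr - sfr) < 1e-9, ]
  if (nrow(slice) == 0) {
    abort(sprintf("sfr = %g is not present in the sweep table", sfr),
          class = "bbisim_lookup_error")
  }
  ggplot2::ggplot(slice, ggplot2::aes(.data$timeout, .data$effective_bpm,
                                      colour = factor(.data$latency))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "timeout threshold (s)", y = "effective ITR (bits/min)",
                  colour = "latency (s)",
                  title = sprintf("Effective ITR at SFR = %g", sfr))
}
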