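#' CBI stimulation-cycle specification
#'
#' Bundles the write-side (computer-to-brain) parameters of a closed-loop
#' interface. One delivery attempt occupies `latency` seconds (command
#' transmission, stimulation, and confirmation of delivery by an
#' amplitude-threshold detector, abstracted here into a single Bernoulli
#' success event). A failed attempt is retried back-to-back, up to
#' `max_attempts` times, but an attempt is launched only if it can complete
#' within the wall-clock `timeout` budget.
#'
#' @param latency Full command-stimulate-confirm cycle time in seconds,
#'   positive.
#' @param sfr Stimulation failure rate: probability in \[0, 1\] that a single
#'   delivery attempt fails. Attempts are independent.
#' @param timeout Wall-clock budget in seconds for the whole stimulation
#'   cycle; must be at least as long as the latency period.
#' @param max_attempts Maximum delivery attempts per trial; default 3 (the
#'   initial stimulation plus up to two more attempts).
#' @return An object of class `cbi_spec`.
#' @examples
#' cbi_spec(latency = 0.1, sfr = 0.25, timeout = 0.2)
#' @export
cbi_spec <- function(latency, sfr, timeout, max_attempts = 3) {
  check_positive(latency, "latency")
  check_probability(sfr, "sfr")
  if (!is.numeric(timeout) || length(timeout) != 1 || is.na(timeout)) {
    abort("`timeout` must be a number", class = "bbisim_domain_error")
  }
  if (timeout < latency - 1e-12) {
    abort(
      "the timeout threshold must be at least as long as the latency period",
      class = "bbisim_constraint_error"
    )
  }
  if (length(max_attempts) != 1 || is.na(max_attempts) || max_attempts < 1 ||
      max_attempts != round(max_attempts)) {
    abort("`max_attempts` must be an integer >= 1", class = "bbisim_domain_error")
  }
  structure(
    list(latency = latency, sfr = sfr, timeout = timeout,
         max_attempts = as.integer(max_attempts)),
    class = "cbi_spec"
  )
}

#' @export
print.cbi_spec <- function(x, ...) {
  cat(sprintf(
    "<cbi_spec> latency %g s, SFR %g, timeout %g s, max %d attempts (%d feasible)\n",
    x$latency, x$sfr, x$timeout, x$max_attempts, feasible_attempts(x)
  ))
  invisible(x)
}

#' Number of delivery attempts that fit the timeout budget
#'
#' Attempt i occupies the interval `((i-1) * latency, i * latency]`; an
#' attempt is feasible only if it completes within the timeout, so the count
#' is `min(max_attempts, floor(timeout / latency))`. A timeout equal to the
#' latency leaves a single-shot delivery; a timeout of twice the latency
#' admits exactly two attempts.
#'
#' @param cbi A [cbi_spec()].
#' @return Integer number of feasible attempts, at least 1.
#' @examples
#' feasible_attempts(cbi_spec(0.1, 0.25, 0.2)) # 2
#' @export
feasible_attempts <- function(cbi) {
  stopifnot(inherits(cbi, "cbi_spec"))
  # tolerance so grid values like 0.3 / 0.1 are not floored to 2 by FP error
  max(1L, min(cbi$max_attempts, as.integer(floor(cbi$timeout / cbi$latency + 1e-9))))
}

#' Exact outcome distribution of one stimulation cycle
#'
#' Enumerates the Bernoulli retry tree: attempt i succeeds with probability
#' `1 - sfr`, the first success stops the cycle, and exhausting all feasible
#' attempts leaves the trial undelivered.
#'
#' @param cbi A [cbi_spec()].
#' @return A tibble with one row per outcome: `attempts`, `delivered`,
#'   `prob`, `cbi_time` (seconds spent, `attempts * latency`).
#' @examples
#' attempt_distribution(cbi_spec(0.1, 0.25, 1.5))
#' @export
attempt_distribution <- function(cbi) {
  kp <- feasible_attempts(cbi)
  f <- cbi$sfr
  i <- seq_len(kp)
  tibble::tibble(
    attempts = c(i, kp),
    delivered = c(rep(TRUE, kp), FALSE),
    prob = c(f^(i - 1) * (1 - f), f^kp),
    cbi_time = .data$attempts * cbi$latency
  )
}

#' Probability that a stimulation cycle delivers
#'
#' Closed form of the retry tree: `1 - sfr^k` where k is the number of
#' feasible attempts ([feasible_attempts()]).
#'
#' @param cbi A [cbi_spec()].
#' @return Delivery probability in \[0, 1\].
#' @examples
#' delivery_probability(cbi_spec(0.1, 0.25, 0.2)) # 1 - 0.25^2 = 0.9375
#' @export
delivery_probability <- function(cbi) {
  1 - cbi$sfr^feasible_attempts(cbi)
}

#' Expected number of delivery attempts per cycle
#'
#' Mean of the truncated-geometric attempt count:
#' `(1 - sfr^k) / (1 - sfr)` for `sfr < 1` and k attempts for `sfr = 1`.
#'
#' @param cbi A [cbi_spec()].
#' @return Expected attempts, in \[1, k\].
#' @export
expected_attempts <- function(cbi) {
  kp <- feasible_attempts(cbi)
  if (cbi$sfr >= 1) return(as.numeric(kp))
  (1 - cbi$sfr^kp) / (1 - cbi$sfr)
}

#' Expected time spent in one stimulation cycle
#'
#' Under the default accounting an abandoned cycle is charged only for the
#' attempts actually made (`k * latency`); `failed_charge = "timeout"`
#' instead charges the full timeout budget for undelivered trials.
#'
#' @param cbi A [cbi_spec()].
#' @param failed_charge Time charged to an undelivered trial: `"attempts"`
#'   (default, attempts made) or `"timeout"` (full budget).
#' @return Expected cycle time in seconds.
#' @examples
#' expected_cbi_time(cbi_spec(0.1, 0.25, 0.2)) # 0.1 * (1 - 0.0625) / 0.75
#' @export
expected_cbi_time <- function(cbi, failed_charge = c("attempts", "timeout")) {
  failed_charge <- rlang::arg_match(failed_charge)
  dist <- attempt_distribution(cbi)
  time <- dist$cbi_time
  if (failed_charge == "timeout") time[!dist$delivered] <- cbi$timeout
  sum(dist$prob * time)
}

#' Simulate stimulation cycles
#'
#' Draws `n_trials` independent cycles of the retry model: attempt i
#' succeeds with probability `1 - sfr`, the first success delivers, and the
#' cycle is abandoned once no further attempt fits the timeout budget.
#'
#' @param cbi A [cbi_spec()].
#' @param n_trials Number of trials to draw, at least 1.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param failed_charge See [expected_cbi_time()].
#' @return A tibble with one row per trial: `trial`, `attempts`, `delivered`,
#'   `cbi_time`.
#' @examples
#' simulate_trials(cbi_spec(0.1, 0.25, 1.5), n_trials = 5, seed = 42)
#' @export
simulate_trials <- function(cbi, n_trials, seed = NULL,
                            failed_charge = c("attempts", "timeout")) {
  stopifnot(inherits(cbi, "cbi_spec"))
  failed_charge <- rlang::arg_match(failed_charge)
  if (n_trials < 1) abort("`n_trials` must be >= 1", class = "bbisim_domain_error")
  n_trials <- as.integer(n_trials)
  kp <- feasible_attempts(cbi)
  f <- cbi$sfr
  draw <- function() {
    if (f >= 1) {
      rep.int(kp + 1L, n_trials)        # never succeeds
    } else {
      # attempts needed for first success; rgeom counts failures before it
      1L + rgeom(n_trials, prob = 1 - f)
    }
  }
  needed <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  delivered <- needed <= kp
  attempts <- pmin(needed, kp)
  cbi_time <- attempts * cbi$latency
  if (failed_charge == "timeout") cbi_time[!delivered] <- cbi$timeout
  tibble::tibble(
    trial = seq_len(n_trials),
    attempts = attempts,
    delivered = delivered,
    cbi_time = cbi_time
  )
}

#' Effective ITR of the closed BCI-CBI loop
#'
#' Couples a BCI read side ([bci_spec()]) to a CBI write side ([cbi_spec()])
#' and computes the long-run information rate of the closed loop by
#' renewal-reward analysis: each trial earns `bits_per_trial(N, P)` bits if
#' its stimulation is delivered and zero bits otherwise, while always
#' consuming its trial period, so
#'
#' \deqn{\mathrm{bpm} = b \cdot 60 \cdot \Pr(\mathrm{delivered}) / E[\mathrm{period}]}
#'
#' The trial period is `1/U + cbi_time` when analysis and stimulation are
#' `"sequential"`, or `max(1/U, cbi_time)` when the next analysis window is
#' `"pipelined"` with the stimulation cycle. Delivery failure costs time and
#' lost trials only; it does not degrade the classifier accuracy P.
#'
#' @param bci A [bci_spec()].
#' @param cbi A [cbi_spec()].
#' @param mode Loop composition, `"sequential"` (default) or `"pipelined"`.
#' @param method `"analytic"` (exact, from the attempt distribution) or
#'   `"monte_carlo"` (average over simulated trials).
#' @param n_trials Trials for the Monte-Carlo method; ignored for analytic.
#' @param seed Optional seed for the Monte-Carlo method.
#' @param failed_charge See [expected_cbi_time()].
#' @return A one-row tibble of class `loop_summary`: `mode`, `method`,
#'   `n_trials` (NA for analytic), `delivery_rate`, `mean_cbi_time`,
#'   `mean_trial_period`, `effective_bpm`.
#' @examples
#' bci <- bci_spec(2, 0.99999, 1, 10)
#' effective_itr(bci, cbi_spec(0.1, 0.25, 0.2))                     # ~250 bpm
#' effective_itr(bci, cbi_spec(0.1, 0.25, 0.2), mode = "pipelined") # ~450 bpm
#' @export
effective_itr <- function(bci, cbi, mode = c("sequential", "pipelined"),
                          method = c("analytic", "monte_carlo"),
                          n_trials = 1e5, seed = NULL,
                          failed_charge = c("attempts", "timeout")) {
  stopifnot(inherits(bci, "bci_spec"), inherits(cbi, "cbi_spec"))
  mode <- rlang::arg_match(mode)
  method <- rlang::arg_match(method)
  failed_charge <- rlang::arg_match(failed_charge)
  bits <- bits_per_trial(bci$num_classes, bci$accuracy)
  update_period <- 1 / bci$update_rate

  if (method == "analytic") {
    dist <- attempt_distribution(cbi)
    time <- dist$cbi_time
    if (failed_charge == "timeout") time[!dist$delivered] <- cbi$timeout
    period <- if (mode == "sequential") update_period + time
              else pmax(update_period, time)
    delivery_rate <- sum(dist$prob[dist$delivered])
    mean_cbi_time <- sum(dist$prob * time)
    mean_period <- sum(dist$prob * period)
    n_used <- NA_integer_
  } else {
    trials <- simulate_trials(cbi, n_trials, seed = seed,
                              failed_charge = failed_charge)
    period <- if (mode == "sequential") update_period + trials$cbi_time
              else pmax(update_period, trials$cbi_time)
    delivery_rate <- mean(trials$delivered)
    mean_cbi_time <- mean(trials$cbi_time)
    mean_period <- mean(period)
    n_used <- as.integer(n_trials)
  }

  effective_bpm <- if (delivery_rate == 0) 0 else
    bits * 60 * delivery_rate / mean_period
  out <- tibble::tibble(
    mode = mode, method = method, n_trials = n_used,
    delivery_rate = delivery_rate, mean_cbi_time = mean_cbi_time,
    mean_trial_period = mean_period, effective_bpm = effective_bpm
  )
  class(out) <- c("loop_summary", class(out))
  out
}

#' Serialize a loop summary to JSON
#'
#' @param summary A `loop_summary` from [effective_itr()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
loop_summary_json <- function(summary, path = NULL) {
  json <- jsonlite::toJSON(as.list(summary), auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
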