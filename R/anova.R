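#' Greenhouse-Geisser sphericity epsilon
#'
#' Computed from the covariance matrix S of the k repeated measures via the
#' double-centered matrix \eqn{\tilde S}:
#' \deqn{\epsilon_{GG} = \frac{(\mathrm{tr}\,\tilde S)^2}{(k-1)\,\mathrm{tr}(\tilde S^2)}}
#' clipped to \eqn{[1/(k-1), 1]}. Under compound symmetry (sphericity holds
#' exactly) the value is 1; with k = 2 levels a single contrast cannot
#' violate sphericity, so the value is 1 by construction.
#'
#' @param within_cov Symmetric k x k covariance matrix of the repeated
#'   measures, k >= 2.
#' @return The epsilon estimate in \[1/(k-1), 1\].
#' @examples
#' gg_epsilon(diag(4) + 0.3) # compound symmetric -> 1
#' @export
gg_epsilon <- function(within_cov) {
  if (!is.matrix(within_cov) || nrow(within_cov) != ncol(within_cov)) {
    abort("`within_cov` must be a square matrix", class = "bbisim_domain_error")
  }
  if (max(abs(within_cov - t(within_cov))) > 1e-8 * max(abs(within_cov), 1)) {
    abort("`within_cov` must be symmetric", class = "bbisim_domain_error")
  }
  k <- nrow(within_cov)
  if (k < 2) abort("`within_cov` must be at least 2 x 2",
                   class = "bbisim_domain_error")
  rm <- rowMeans(within_cov)
  ctr <- within_cov - outer(rm, rep(1, k)) - outer(rep(1, k), rm) +
    mean(within_cov)
  denom <- (k - 1) * sum(ctr^2)
  if (denom < .Machine$double.eps) return(1) # degenerate: sphericity trivially holds
  eps <- sum(diag(ctr))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' Huynh-Feldt sphericity epsilon
#'
#' The less conservative companion of [gg_epsilon()]:
#' \deqn{\epsilon_{HF} = \frac{n(k-1)\epsilon_{GG} - 2}{(k-1)\,(n - 1 - (k-1)\epsilon_{GG})}}
#' capped at 1. Always at least as large as the Greenhouse-Geisser value.
#'
#' @param gg Greenhouse-Geisser epsilon.
#' @param n Number of subjects; must exceed `k - 1`.
#' @param k Number of within-factor levels.
#' @return The capped Huynh-Feldt epsilon.
#' @export
hf_epsilon <- function(gg, n, k) {
  if (gg < 1 / (k - 1) - 1e-9 || gg > 1 + 1e-9) {
    abort("`gg` must lie in [1/(k-1), 1]", class = "bbisim_domain_error")
  }
  denom <- (k - 1) * (n - 1 - (k - 1) * gg)
  if (denom <= 0) {
    abort("degenerate Huynh-Feldt denominator: need n - 1 > (k-1) * gg",
          class = "bbisim_domain_error")
  }
  min(1, (n * (k - 1) * gg - 2) / denom)
}

#' Lower-bound sphericity epsilon
#'
#' The maximal possible sphericity violation for k levels: `1 / (k - 1)`.
#'
#' @param k Number of within-factor levels, at least 2.
#' @return `1 / (k - 1)`.
#' @export
lb_epsilon <- function(k) {
  if (k < 2) abort("`k` must be >= 2", class = "bbisim_domain_error")
  1 / (k - 1)
}

#' Repeated-measures ANOVA with sphericity corrections
#'
#' Fits a balanced within-subject ANOVA on long-format data: the response is
#' decomposed into grand mean, subject stratum, one main effect per within
#' factor, and a single pooled error stratum (the residual after subject and
#' main effects, into which all interactions are folded). Every effect is
#' tested against the pooled error mean square, matching the classical
#' single-error-row presentation.
#'
#' For each within factor the sphericity epsilons are estimated from the
#' covariance of the subject-by-level means ([gg_epsilon()], [hf_epsilon()],
#' [lb_epsilon()]), and corrected p-values are obtained by scaling both the
#' numerator and the denominator degrees of freedom by the respective
#' epsilon. The corrections inflate the p-value of any effect whose F
#' statistic is appreciably above 1, the regime in which they are used;
#' no clamping is applied.
#'
#' @param data Long-format data frame: one response per subject x cell,
#'   complete and balanced (every combination exactly once).
#' @param response Name of the response column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of within-factor column names.
#' @return An object of class `rm_anova` with elements `table` (tibble:
#'   `term`, `sumsq`, `df`, `meansq`, `statistic`, `p.value`, `p.gg`,
#'   `p.hf`, `p.lb`), `epsilons` (per within factor), `n_subjects`,
#'   `error_df`, `error_ms`, and per-factor level means for post hoc tests.
#'   Supports [tidy()], [glance()] and [tukey_hsd()].
#' @examples
#' d <- expand.grid(subject = 1:6, a = 1:3, b = 1:2)
#' d$y <- d$a + 0.5 * d$b + stats::rnorm(nrow(d), sd = 0.2)
#' rm_anova(d, "y", "subject", c("a", "b"))
#' @export
rm_anova <- function(data, response, subject, within) {
  cols <- c(response, subject, within)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("columns not found in `data`:",
                paste(missing_cols, collapse = ", ")),
          class = "bbisim_domain_error")
  }
  if (length(within) < 1) {
    abort("at least one within factor is required", class = "bbisim_domain_error")
  }
  y <- data[[response]]
  subj <- factor(data[[subject]])
  facs <- lapply(data[within], factor)
  n_subj <- nlevels(subj)
  k_lev <- vapply(facs, nlevels, integer(1))
  n_cells <- prod(k_lev)

  counts <- table(subj, interaction(facs, drop = FALSE))
  if (any(counts != 1)) {
    abort(paste(
      "unsupported design: `rm_anova` requires a complete balanced layout",
      "with exactly one observation per subject x cell"
    ), class = "bbisim_design_error")
  }
  if (n_subj < 2) {
    abort("at least two subjects are required", class = "bbisim_design_error")
  }

  n_tot <- length(y)
  grand <- mean(y)
  ss_int <- n_tot * grand^2
  ss_total_c <- sum((y - grand)^2)
  ss_subj <- n_cells * sum((tapply(y, subj, mean) - grand)^2)
  ss_fac <- vapply(facs, function(f) {
    (n_tot / nlevels(f)) * sum((tapply(y, f, mean) - grand)^2)
  }, numeric(1))
  df_fac <- k_lev - 1
  ss_err <- ss_total_c - ss_subj - sum(ss_fac)
  df_err <- (n_tot - 1) - (n_subj - 1) - sum(df_fac)
  ms_err <- ss_err / df_err

  # epsilons from the covariance of subject-by-level means, one per factor
  eps <- purrr::map2(facs, k_lev, function(f, k) {
    m <- tapply(y, list(subj, f), mean)
    s <- cov(m)
    gg <- gg_epsilon(s)
    list(gg = gg, hf = hf_epsilon(gg, n_subj, k), lb = lb_epsilon(k))
  })

  corrected <- function(stat, df1, e) {
    pf(stat, e * df1, e * df_err, lower.tail = FALSE)
  }
  fac_rows <- purrr::pmap(
    list(within, ss_fac, df_fac, eps),
    function(nm, ss, df1, e) {
      # a zero effect carries zero evidence even when the error MS is zero
      stat <- if (ss == 0) 0 else (ss / df1) / ms_err
      tibble::tibble(
        term = nm, sumsq = ss, df = df1, meansq = ss / df1, statistic = stat,
        p.value = pf(stat, df1, df_err, lower.tail = FALSE),
        p.gg = corrected(stat, df1, e$gg),
        p.hf = corrected(stat, df1, e$hf),
        p.lb = corrected(stat, df1, e$lb)
      )
    }
  ) |> purrr::list_rbind()

  int_stat <- ss_int / ms_err
  int_p <- pf(int_stat, 1, df_err, lower.tail = FALSE)
  subj_stat <- (ss_subj / (n_subj - 1)) / ms_err
  tab <- dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", sumsq = ss_int, df = 1,
                   meansq = ss_int, statistic = int_stat, p.value = int_p,
                   p.gg = int_p, p.hf = int_p, p.lb = int_p),
    tibble::tibble(term = "Subject", sumsq = ss_subj, df = n_subj - 1,
                   meansq = ss_subj / (n_subj - 1), statistic = subj_stat,
                   p.value = pf(subj_stat, n_subj - 1, df_err, lower.tail = FALSE),
                   p.gg = NA_real_, p.hf = NA_real_, p.lb = NA_real_),
    fac_rows,
    tibble::tibble(term = "Error", sumsq = ss_err, df = df_err,
                   meansq = ms_err, statistic = NA_real_, p.value = NA_real_,
                   p.gg = NA_real_, p.hf = NA_real_, p.lb = NA_real_)
  )

  level_means <- lapply(facs, function(f) {
    tibble::tibble(
      level = levels(f),
      mean = as.numeric(tapply(y, f, mean)),
      n = as.integer(n_tot / nlevels(f))
    )
  })

  structure(
    list(
      table = tab,
      epsilons = tibble::tibble(
        term = within,
        gg = unname(vapply(eps, `[[`, numeric(1), "gg")),
        hf = unname(vapply(eps, `[[`, numeric(1), "hf")),
        lb = unname(vapply(eps, `[[`, numeric(1), "lb"))
      ),
      n_subjects = n_subj, n_cells = n_cells, within = within,
      response = response, error_df = df_err, error_ms = ms_err,
      total_ss = ss_total_c, level_means = level_means
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: %s, %d subjects x %d cells\n",
              x$response, x$n_subjects, x$n_cells))
  print(x$table)
  cat("Sphericity epsilons:\n")
  print(x$epsilons)
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  x$table
}

#' @rdname rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_cells = x$n_cells,
    total_ss = x$total_ss, error_df = x$error_df, error_ms = x$error_ms
  )
}

#' Tukey HSD post hoc comparisons
#'
#' Pairwise studentized-range tests: for groups i and j,
#' \eqn{q_{ij} = |\bar y_i - \bar y_j| / \sqrt{MSE / n}}, with the adjusted
#' p-value from the studentized-range distribution on the error degrees of
#' freedom.
#'
#' The default method takes explicit group means; the `rm_anova` method
#' compares the levels of one within factor using the fit's pooled error
#' mean square and degrees of freedom.
#'
#' @param x Named numeric vector of group means, or an `rm_anova` fit.
#' @param ... Passed to methods.
#' @return A tibble with one row per pair: `contrast`, `estimate` (mean
#'   difference), `q`, `adj.p.value`.
#' @examples
#' tukey_hsd(c(a = 1.0, b = 1.4, c = 2.1), mse = 0.2, n_per_group = 8,
#'           df_error = 21)
#' @export
tukey_hsd <- function(x, ...) UseMethod("tukey_hsd")

#' @rdname tukey_hsd
#' @param mse Pooled error mean square, positive.
#' @param n_per_group Observations per group (balanced).
#' @param df_error Error degrees of freedom.
#' @export
tukey_hsd.default <- function(x, mse, n_per_group, df_error, ...) {
  if (length(x) < 2) {
    abort("at least two group means are required", class = "bbisim_domain_error")
  }
  if (!is.numeric(mse) || mse <= 0) {
    abort("`mse` must be positive", class = "bbisim_domain_error")
  }
  k <- length(x)
  nm <- names(x) %||% as.character(seq_len(k))
  x <- as.vector(x)
  pairs <- utils::combn(k, 2)
  est <- x[pairs[2, ]] - x[pairs[1, ]]
  q <- abs(est) / sqrt(mse / n_per_group)
  tibble::tibble(
    contrast = paste(nm[pairs[2, ]], "-", nm[pairs[1, ]]),
    estimate = unname(est),
    q = unname(q),
    adj.p.value = ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
  )
}

#' @rdname tukey_hsd
#' @param term Which within factor of the fit to compare.
#' @export
tukey_hsd.rm_anova <- function(x, term, ...) {
  if (!term %in% x$within) {
    abort(sprintf("`%s` is not a within factor of this fit", term),
          class = "bbisim_lookup_error")
  }
  lm <- x$level_means[[term]]
  tukey_hsd(setNames(lm$mean, lm$level), mse = x$error_ms,
            n_per_group = lm$n[1], df_error = x$error_df)
}

# Table-2-shaped CSV headers
anova_csv_headers <- c("Effect", "SumSq", "DF", "MeanSq", "F", "p Value",
                       "p Val. GG", "p Val. HF", "p Val. LB")

#' Write an ANOVA table to CSV
#'
#' Columns use the classical repeated-measures presentation headers
#' (SumSq, DF, MeanSq, F, p Value, p Val. GG, p Val. HF, p Val. LB).
#'
#' @param fit An [rm_anova()] fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(fit, path) {
  out <- fit$table |>
    rlang::set_names(anova_csv_headers)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Simulate a repeated-measures dataset from the sweep model
#'
#' Generates the balanced within-subject design used for the statistical
#' analysis of the sweep: each "subject" is an independently seeded
#' Monte-Carlo replicate of the closed-loop simulation, measured on every
#' cell of a (latency x SFR x timeout-ratio) grid binned to a small number
#' of levels per factor. Timeouts are expressed as multiples of the latency
#' so that every cell is feasible and the design stays balanced.
#'
#' @param n_subjects Number of replicate simulation runs; default 8.
#' @param latencies Latency levels in seconds; default 4 levels spanning the
#'   sweep range.
#' @param sfrs Failure-rate levels; default 4 levels.
#' @param timeout_ratios Timeout/latency ratios; default 4 levels >= 1.
#' @param bci Base [bci_spec()]; default the two-class monitoring system.
#' @param mode Loop composition; default `"pipelined"` (the sweep default).
#' @param n_trials Monte-Carlo trials per subject x cell; default 200 (kept
#'   deliberately small so each measurement carries sampling noise, which
#'   plays the role of within-subject error).
#' @param seed Base seed for the replicate runs.
#' @return A long-format tibble: `subject`, `latency`, `sfr`,
#'   `timeout_ratio`, `timeout`, `effective_bpm`.
#' @examples
#' d <- simulate_rm_sweep(n_subjects = 4, n_trials = 100, seed = 7)
#' rm_anova(d, "effective_bpm", "subject", c("latency", "sfr", "timeout_ratio"))
#' @export
simulate_rm_sweep <- function(n_subjects = 8,
                              latencies = c(0.1, 0.4, 0.7, 1.0),
                              sfrs = c(0, 0.10, 0.25, 0.50),
                              timeout_ratios = c(1, 1.5, 2, 3),
                              bci = bci_spec(2, 0.99999, 1, 10),
                              mode = c("pipelined", "sequential"),
                              n_trials = 200, seed = 1L) {
  mode <- rlang::arg_match(mode)
  if (any(timeout_ratios < 1)) {
    abort("`timeout_ratios` must be >= 1 so every cell is feasible",
          class = "bbisim_config_error")
  }
  cells <- tidyr::crossing(subject = seq_len(n_subjects), latency = latencies,
                           sfr = sfrs, timeout_ratio = timeout_ratios) |>
    dplyr::mutate(timeout = .data$latency * .data$timeout_ratio)
  bpm <- purrr::pmap_dbl(
    list(cells$latency, cells$sfr, cells$timeout, seq_len(nrow(cells))),
    function(l, f, t, idx) {
      s <- effective_itr(bci, cbi_spec(l, f, t), mode = mode,
                         method = "monte_carlo", n_trials = n_trials,
                         seed = cell_seed(seed, idx))
      s$effective_bpm
    }
  )
  dplyr::mutate(cells, effective_bpm = bpm)
}
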