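# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Enumerate the retry tree of one stimulation cycle attempt by attempt.
# Returns a data.frame of outcomes with probabilities, attempt counts and
# elapsed times.
oracle_attempt_tree <- function(latency, sfr, timeout, max_attempts = 3) {
  outcomes <- list()
  p_reach <- 1 # probability of reaching the current attempt
  i <- 0
  repeat {
    i <- i + 1
    if (i > max_attempts || i * latency > timeout + 1e-9) {
      # no further attempt can be launched: trial abandoned
      outcomes[[length(outcomes) + 1]] <- data.frame(
        attempts = i - 1, delivered = FALSE, prob = p_reach,
        time = (i - 1) * latency
      )
      break
    }
    outcomes[[length(outcomes) + 1]] <- data.frame(
      attempts = i, delivered = TRUE, prob = p_reach * (1 - sfr),
      time = i * latency
    )
    p_reach <- p_reach * sfr
    if (p_reach == 0) break
  }
  do.call(rbind, outcomes)
}

oracle_delivery_probability <- function(latency, sfr, timeout, max_attempts = 3) {
  tree <- oracle_attempt_tree(latency, sfr, timeout, max_attempts)
  sum(tree$prob[tree$delivered])
}

oracle_expected_time <- function(latency, sfr, timeout, max_attempts = 3) {
  tree <- oracle_attempt_tree(latency, sfr, timeout, max_attempts)
  sum(tree$prob * tree$time)
}

# Renewal-reward effective rate computed directly from the outcome tree.
oracle_effective_bpm <- function(bits, update_rate, latency, sfr, timeout,
                                 mode, max_attempts = 3) {
  tree <- oracle_attempt_tree(latency, sfr, timeout, max_attempts)
  period <- switch(mode,
    sequential = 1 / update_rate + tree$time,
    pipelined = pmax(1 / update_rate, tree$time)
  )
  delivered <- sum(tree$prob[tree$delivered])
  if (delivered == 0) return(0)
  bits * 60 * delivered / sum(tree$prob * period)
}

# Textbook sum-of-squares partition for a balanced fully-crossed layout with
# one observation per subject x cell, computed from scratch with loops.
oracle_ss_partition <- function(data, response, subject, within) {
  y <- data[[response]]
  grand <- mean(y)
  out <- list(intercept = length(y) * grand^2,
              total_corrected = sum((y - grand)^2))
  groups <- c(setNames(list(subject), "subject"), setNames(as.list(within), within))
  for (nm in names(groups)) {
    col <- data[[groups[[nm]]]]
    ss <- 0
    for (lev in unique(col)) {
      idx <- col == lev
      ss <- ss + sum(idx) * (mean(y[idx]) - grand)^2
    }
    out[[nm]] <- ss
  }
  out$error <- out$total_corrected - out$subject -
    sum(unlist(out[within]))
  out
}

# Greenhouse-Geisser epsilon straight from its matrix definition, written
# independently (explicit centering matrix product).
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  C <- diag(k) - matrix(1 / k, k, k)
  St <- C %*% S %*% C
  eps <- sum(diag(St))^2 / ((k - 1) * sum(diag(St %*% St)))
  min(1, max(1 / (k - 1), eps))
}

# The default two-class passive-monitoring loop used throughout the suite.
monitor_bci <- function() bci_spec(2, 0.99999, window_length = 1, update_rate = 10)
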