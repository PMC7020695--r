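# balanced within-subject dataset with real effects and correlated residuals
make_rm_data <- function(seed, n = 10, ka = 4, kb = 3, sd = 0.6) {
  withr::with_seed(seed, {
    d <- expand.grid(subject = factor(seq_len(n)), a = factor(seq_len(ka)),
                     b = factor(seq_len(kb)))
    subj_eff <- rnorm(n, sd = 0.8)
    d$y <- 2.5 * as.numeric(d$a) + 1.5 * as.numeric(d$b) +
      subj_eff[as.integer(d$subject)] +
      rnorm(nrow(d), sd = sd) * as.numeric(d$a) # heteroscedastic -> non-spherical
    d
  })
}

test_that("Greenhouse-Geisser epsilon matches its matrix-arithmetic oracle", {
  withr::with_seed(21, {
    for (k in c(3, 4, 6)) {
      m <- matrix(rnorm(30 * k), 30, k) %*% matrix(rnorm(k * k), k, k)
      s <- cov(m)
      expect_equal(gg_epsilon(s), oracle_gg_epsilon(s), tolerance = 1e-12)
    }
  })
  # a 1-DF contrast cannot violate sphericity
  withr::with_seed(22, {
    s2 <- cov(matrix(rnorm(40), 20, 2) %*% matrix(c(2, 1, 0, 3), 2, 2))
    expect_equal(gg_epsilon(s2), 1)
  })
  # compound symmetry: sphericity holds exactly at any size
  for (k in c(3, 5, 8)) {
    cs <- matrix(0.4, k, k) + diag(k) * 0.6
    expect_equal(gg_epsilon(cs), 1)
  }
  expect_error(gg_epsilon(matrix(1:6, 2, 3)), class = "bbisim_domain_error")
  asym <- matrix(c(1, 0.9, 0.1, 1), 2, 2)
  expect_error(gg_epsilon(asym), class = "bbisim_domain_error")
})

test_that("epsilon estimates stay within their theoretical bounds", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      k <- sample(3:6, 1)
      n <- k + sample(3:10, 1)
      m <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k, k)
      gg <- gg_epsilon(cov(m))
      hf <- hf_epsilon(gg, n, k)
      expect_gte(gg, 1 / (k - 1))
      expect_lte(gg, 1)
      expect_gte(hf, gg - 1e-12) # known ordering
      expect_lte(hf, 1)
    }
  })
  # direct formula evaluation
  expect_equal(hf_epsilon(0.5, 10, 4),
               (10 * 3 * 0.5 - 2) / (3 * (10 - 1 - 3 * 0.5)))
  expect_equal(hf_epsilon(1, 100, 3), 1) # capped
  expect_equal(lb_epsilon(4), 1 / 3)
  expect_error(hf_epsilon(0.5, 2, 4), class = "bbisim_domain_error")
  expect_error(lb_epsilon(1), class = "bbisim_domain_error")
})

test_that("rm_anova reproduces the brute-force sum-of-squares partition", {
  d <- make_rm_data(101)
  fit <- rm_anova(d, "y", "subject", c("a", "b"))
  ss <- oracle_ss_partition(d, "y", "subject", c("a", "b"))
  tab <- fit$table
  expect_equal(tab$sumsq[tab$term == "(Intercept)"], ss$intercept, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "Subject"], ss$subject, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "a"], ss$a, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "b"], ss$b, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "Error"], ss$error, tolerance = 1e-10)
  # conservation of variance over the displayed strata
  expect_equal(sum(tab$sumsq[tab$term != "(Intercept)"]), ss$total_corrected)
  # MeanSq = SumSq / DF and F = MS_effect / MS_error on every testable row
  expect_equal(tab$meansq, tab$sumsq / tab$df)
  ms_err <- tab$meansq[tab$term == "Error"]
  for (trm in c("a", "b")) {
    row <- tab[tab$term == trm, ]
    expect_equal(row$statistic, row$meansq / ms_err)
    expect_gte(row$statistic, 0)
  }
  # degrees of freedom: levels - 1 per main effect
  expect_equal(tab$df[tab$term == "a"], 3)
  expect_equal(tab$df[tab$term == "b"], 2)
})

test_that("rm_anova agrees with stats::aov on the same decomposition", {
  d <- make_rm_data(202, n = 8, ka = 4, kb = 4)
  fit <- rm_anova(d, "y", "subject", c("a", "b"))
  ref <- summary(stats::aov(y ~ subject + a + b, data = d))[[1]]
  tab <- fit$table
  for (pair in list(c("Subject", "subject"), c("a", "a"), c("b", "b"),
                    c("Error", "Residuals"))) {
    ref_row <- ref[trimws(rownames(ref)) == pair[2], ]
    mine <- tab[tab$term == pair[1], ]
    expect_equal(mine$sumsq, ref_row[["Sum Sq"]], tolerance = 1e-8)
    expect_equal(mine$df, ref_row[["Df"]])
  }
  for (trm in c("a", "b")) {
    ref_row <- ref[trimws(rownames(ref)) == trm, ]
    mine <- tab[tab$term == trm, ]
    expect_equal(mine$statistic, ref_row[["F value"]], tolerance = 1e-8)
    expect_equal(mine$p.value, ref_row[["Pr(>F)"]], tolerance = 1e-8)
  }
})

test_that("epsilons and corrected p-values match car's multivariate machinery", {
  skip_if_not_installed("car")
  withr::with_seed(77, {
    n <- 12; k <- 4
    m <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k, k) +
      matrix(rep(c(0, 2, 3, 5), each = n), n, k)
  })
  long <- data.frame(subject = factor(rep(seq_len(n), k)),
                     a = factor(rep(seq_len(k), each = n)), y = c(m))
  fit <- rm_anova(long, "y", "subject", "a")
  ref <- summary(car::Anova(stats::lm(m ~ 1), idata = data.frame(a = factor(1:k)),
                            idesign = ~a, type = 3), multivariate = FALSE)
  adj <- ref$pval.adjustments
  expect_equal(fit$epsilons$gg, unname(adj["a", "GG eps"]), tolerance = 1e-10)
  expect_equal(fit$epsilons$hf, unname(adj["a", "HF eps"]), tolerance = 1e-10)
  tab <- fit$table
  expect_equal(tab$p.gg[tab$term == "a"], unname(adj["a", "Pr(>F[GG])"]),
               tolerance = 1e-6)
  expect_equal(tab$p.hf[tab$term == "a"], unname(adj["a", "Pr(>F[HF])"]),
               tolerance = 1e-6)
  uni <- ref$univariate.tests
  expect_equal(tab$statistic[tab$term == "a"], unname(uni["a", "F value"]),
               tolerance = 1e-8)
  expect_equal(tab$p.value[tab$term == "a"], unname(uni["a", "Pr(>F)"]),
               tolerance = 1e-8)
})

test_that("corrections only inflate the p-value of genuine effects", {
  for (seed in c(41, 42, 43, 44, 45)) {
    d <- make_rm_data(seed)
    tab <- rm_anova(d, "y", "subject", c("a", "b"))$table
    fac <- tab[tab$term %in% c("a", "b"), ]
    expect_true(all(fac$statistic > 2)) # real effects: the corrected regime
    expect_true(all(fac$p.gg >= fac$p.value - 1e-15))
    expect_true(all(fac$p.hf >= fac$p.value - 1e-15))
    expect_true(all(fac$p.lb >= fac$p.gg - 1e-15))
  }
})

test_that("degenerate and malformed designs are handled explicitly", {
  d <- expand.grid(subject = factor(1:6), a = factor(1:3))
  d$y <- 5 # all responses identical
  fit <- rm_anova(d, "y", "subject", "a")
  tab <- fit$table
  expect_equal(tab$sumsq[tab$term == "a"], 0)
  expect_equal(tab$statistic[tab$term == "a"], 0)
  # unbalanced: drop one observation
  d2 <- make_rm_data(55)[-1, ]
  expect_error(rm_anova(d2, "y", "subject", c("a", "b")),
               class = "bbisim_design_error")
  expect_error(rm_anova(make_rm_data(55), "z", "subject", "a"),
               class = "bbisim_domain_error")
})

test_that("tukey_hsd matches TukeyHSD to four decimals", {
  withr::with_seed(66, {
    g <- data.frame(grp = factor(rep(letters[1:4], each = 7)),
                    y = rnorm(28) + rep(c(0, 0.4, 1.1, 1.6), each = 7))
  })
  a1 <- stats::aov(y ~ grp, data = g)
  ref <- stats::TukeyHSD(a1)$grp
  mse <- summary(a1)[[1]]["Residuals", "Mean Sq"]
  mine <- tukey_hsd(tapply(g$y, g$grp, mean), mse = mse, n_per_group = 7,
                    df_error = stats::df.residual(a1))
  expect_equal(mine$estimate, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(mine$adj.p.value, unname(ref[, "p adj"]), tolerance = 1e-4)
})

test_that("tukey_hsd degenerate cases behave as theory dictates", {
  # identical means: zero range statistics, adjusted p of 1
  same <- tukey_hsd(c(a = 2, b = 2, c = 2), mse = 1, n_per_group = 5,
                    df_error = 12)
  expect_true(all(same$q == 0))
  expect_true(all(same$adj.p.value == 1))
  # two groups: the Tukey p equals the two-sided t-test p (q = sqrt(2) |t|)
  m <- c(a = 1, b = 2.2)
  two <- tukey_hsd(m, mse = 0.8, n_per_group = 6, df_error = 10)
  tstat <- (2.2 - 1) / sqrt(0.8 * 2 / 6)
  expect_equal(two$adj.p.value, 2 * stats::pt(-abs(tstat), 10), tolerance = 1e-8)
  expect_error(tukey_hsd(c(a = 1, b = 2), mse = -1, n_per_group = 5,
                         df_error = 10),
               class = "bbisim_domain_error")
})

test_that("post hoc comparisons run off a fitted rm_anova", {
  d <- make_rm_data(88)
  fit <- rm_anova(d, "y", "subject", c("a", "b"))
  tk <- tukey_hsd(fit, "a")
  expect_equal(nrow(tk), choose(4, 2))
  # largest-vs-smallest level difference is the strongest contrast
  expect_lt(tk$adj.p.value[tk$contrast == "4 - 1"], min(tk$adj.p.value) + 1e-12)
  expect_error(tukey_hsd(fit, "c"), class = "bbisim_lookup_error")
})

test_that("the simulated repeated-measures sweep recovers the latency and SFR effects", {
  d <- simulate_rm_sweep(n_subjects = 6, n_trials = 150, seed = 19)
  expect_equal(nrow(d), 6 * 4 * 4 * 4)
  fit <- rm_anova(d, "effective_bpm", "subject", c("latency", "sfr", "timeout_ratio"))
  tab <- fit$table
  expect_lt(tab$p.value[tab$term == "latency"], 0.001)
  expect_lt(tab$p.value[tab$term == "sfr"], 0.001)
  expect_equal(tab$df[tab$term %in% c("latency", "sfr", "timeout_ratio")],
               rep(3, 3))
})

test_that("tidy, glance and the CSV export expose the fitted table", {
  d <- make_rm_data(99, n = 6)
  fit <- rm_anova(d, "y", "subject", c("a", "b"))
  td <- tidy(fit)
  expect_named(td, c("term", "sumsq", "df", "meansq", "statistic", "p.value",
                     "p.gg", "p.hf", "p.lb"))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 6)
  expect_equal(gl$error_df, fit$error_df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_anova_csv(fit, path)
  header <- readLines(path, n = 1)
  expect_equal(header,
               "Effect,SumSq,DF,MeanSq,F,p Value,p Val. GG,p Val. HF,p Val. LB")
})
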