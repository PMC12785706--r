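test_that("observed summaries tally errors and quantile bins exactly", {
  # error-free single participant, 100 distinct RTs per condition:
  # ten bins of ten trials each, empty error bin
  rts <- lapply(1:4, function(i) seq(200, 600, length.out = 100) + i)
  names(rts) <- c("frequent_congruent", "frequent_incongruent",
                  "infrequent_congruent", "infrequent_incongruent")
  obs <- summarize_observed(trials_from_rts(rts))
  for (key in names(obs)) {
    expect_equal(unname(obs[[key]]$bin_counts),
                 c(0, rep(10, 10)))
    expect_equal(obs[[key]]$error_pct, 0)
    expect_equal(obs[[key]]$n, 100)
  }

  # hand-built 20-trial condition with 3 errors: manual tallies
  set.seed(14)
  x <- sort(round(rnorm(20, 400, 40), 1))
  cond <- list(frequent_congruent = c(x, 390, 410, 430),
               frequent_incongruent = x + 5,
               infrequent_congruent = x + 10,
               infrequent_incongruent = x + 15)
  ok <- list(frequent_congruent = c(rep(TRUE, 20), rep(FALSE, 3)),
             frequent_incongruent = rep(TRUE, 20),
             infrequent_congruent = rep(TRUE, 20),
             infrequent_incongruent = rep(TRUE, 20))
  obs <- summarize_observed(trials_from_rts(cond, ok))
  fc <- obs$frequent_congruent
  expect_equal(fc$n_errors, 3)
  expect_equal(fc$error_pct, 100 * 3 / 23)
  expect_equal(sum(fc$bin_counts), 23)
  expect_equal(unname(fc$bin_counts[1]), 3)
  q <- quantile(x, seq(0.1, 0.9, 0.1), type = 7)
  expect_equal(unname(fc$quantiles), unname(q))
  expect_equal(unname(fc$bin_counts[-1]),
               as.vector(table(cut(x, c(-Inf, q, Inf)))))

  # too few correct trials for nine quantiles
  tiny <- lapply(cond, function(v) v[1:8])
  expect_error(summarize_observed(trials_from_rts(tiny)), "fewer than 10")
})

test_that("stage-1 discrepancy is a weighted RMS over quantiles and errors", {
  rts <- lapply(1:4, function(i) seq(200, 600, length.out = 50))
  names(rts) <- c("frequent_congruent", "frequent_incongruent",
                  "infrequent_congruent", "infrequent_incongruent")
  obs <- summarize_observed(trials_from_rts(rts))
  expect_equal(stage1_objective(obs, obs), 0)

  # one quantile off by 5 ms among 4 x (1 + 9) statistics
  sim <- obs
  sim$frequent_congruent$quantiles[3] <-
    sim$frequent_congruent$quantiles[3] + 5
  expect_equal(stage1_objective(obs, sim),
               sqrt((5 / 1000)^2 / 40))

  # worked two-condition example against independent arithmetic
  o2 <- list(a = list(error_pct = 4, quantiles = c(300, 400, 500)),
             b = list(error_pct = 10, quantiles = c(350, 450, 560)))
  s2 <- list(a = list(error_pct = 6, quantiles = c(310, 395, 500)),
             b = list(error_pct = 10, quantiles = c(350, 458, 548)))
  dev <- c((4 - 6) / 100, c(-10, 5, 0) / 1000,
           0, c(0, -8, 12) / 1000)
  expect_equal(stage1_objective(o2, s2), sqrt(mean(dev^2)),
               tolerance = 1e-12)
  expect_error(stage1_objective(o2, s2[1]), "different")
})

test_that("G-squared vanishes at exact agreement and matches direct evaluation", {
  obs <- list(c1 = list(bin_counts = c(error = 10, 45, 45)))
  prd <- list(c1 = list(bin_props = c(error = 0.1, 0.45, 0.45), n = 1e5))
  expect_equal(as.numeric(g2_statistic(obs, prd)), 0)

  # 60/40 split against even predictions: 2*(60 ln 1.2 + 40 ln 0.8)
  obs <- list(c1 = list(bin_counts = c(error = 0, 60, 40)))
  prd <- list(c1 = list(bin_props = c(error = 0, 0.5, 0.5), n = 1e5))
  expect_equal(as.numeric(g2_statistic(obs, prd, eps = 0)),
               2 * (60 * log(1.2) + 40 * log(0.8)), tolerance = 1e-12)

  # nonnegative over random tables
  set.seed(15)
  for (i in 1:20) {
    p <- as.vector(rmultinom(1, 100, runif(5))) / 100
    p <- pmax(p, 1e-3)
    p <- p / sum(p)
    O <- as.vector(rmultinom(1, 200, runif(5)))
    g <- g2_statistic(list(c1 = list(bin_counts = O)),
                      list(c1 = list(bin_props = p, n = 1e4)))
    expect_gte(as.numeric(g), 0)
  }

  # epsilon floor rescues impossible bins and reports doing so
  obs <- list(c1 = list(bin_counts = c(error = 2, 50, 48)))
  prd <- list(c1 = list(bin_props = c(error = 0, 0.5, 0.5), n = 1000))
  g <- g2_statistic(obs, prd)
  expect_true(is.finite(as.numeric(g)))
  expect_equal(attr(g, "floored"), 1L)
})

test_that("predicted summaries put proper proportions in observed bins", {
  set.seed(16)
  sims <- simulate_four_conditions(quick_params(),
                                   variant_spec("preparation"), 2000)
  obs <- simonlca:::condition_sims_to_observed(sims)
  pred <- predicted_summary(quick_params(), variant_spec("preparation"),
                            obs, 2000)
  for (key in names(pred)) {
    expect_equal(sum(pred[[key]]$bin_props), 1, tolerance = 1e-12)
    expect_true(all(pred[[key]]$bin_props >= 0))
  }
})

test_that("the generating parameters beat perturbed preparation probabilities", {
  # identifiability smoke test: G-squared at the truth is smaller than at
  # pi shifted by -0.2 / +0.09 for most seeds
  p <- lca_params()
  v <- variant_spec("preparation", pi_freq = 0.9)
  wins <- 0L
  n_seeds <- 6
  for (s in 1:n_seeds) {
    set.seed(1000 + s)
    obs <- simonlca:::condition_sims_to_observed(
      simulate_four_conditions(p, v, 10000))
    g2_at <- function(pi) {
      set.seed(5000 + s)
      pred <- predicted_summary(p, variant_spec("preparation", pi),
                                obs, 10000)
      as.numeric(g2_statistic(obs, pred))
    }
    g_true <- g2_at(0.9)
    if (g_true < g2_at(0.7) && g_true < g2_at(0.99)) wins <- wins + 1L
  }
  expect_gte(wins, n_seeds - 1)
})

test_that("AIC replication adds the parameter penalty and scales with noise", {
  p <- quick_params()
  v <- variant_spec("preparation", free = c("pi_freq", "irr_amplitude"))
  set.seed(17)
  obs <- simonlca:::condition_sims_to_observed(
    simulate_four_conditions(p, v, 4000))
  set.seed(18)
  a <- aic_distribution(p, v, obs, replicates = 12, trials = 3000)
  expect_equal(a$k, 2L)
  expect_equal(a$samples, a$g2_samples + 4)
  expect_equal(a$mean, mean(a$g2_samples) + 4)
  set.seed(18)
  b <- aic_distribution(p, v, obs, replicates = 12, trials = 3000)
  expect_identical(a$samples, b$samples)
  # fewer simulated trials per replicate: noisier goodness of fit
  set.seed(19)
  small <- aic_distribution(p, v, obs, replicates = 20, trials = 400)
  set.seed(20)
  large <- aic_distribution(p, v, obs, replicates = 20, trials = 4000)
  expect_gt(small$sd, large$sd)
})

test_that("prediction intervals are reproducible, ordered, and tighten with n", {
  p <- quick_params()
  v <- variant_spec("preparation")
  n4 <- c(frequent_congruent = 150, frequent_incongruent = 150,
          infrequent_congruent = 150, infrequent_incongruent = 150)
  set.seed(21)
  pi1 <- prediction_intervals(p, v, n4, replicates = 40)
  set.seed(21)
  pi2 <- prediction_intervals(p, v, n4, replicates = 40)
  expect_identical(pi1, pi2)
  expect_true(all(pi1$mean_rt["lower", ] <= pi1$mean_rt["upper", ]))
  expect_true(all(pi1$error_pct["lower", ] <= pi1$error_pct["upper", ]))
  set.seed(22)
  wide <- prediction_intervals(p, v, n4 / 3, replicates = 40)
  set.seed(23)
  narrow <- prediction_intervals(p, v, n4 * 4, replicates = 40)
  expect_gt(mean(wide$mean_rt["upper", ] - wide$mean_rt["lower", ]),
            mean(narrow$mean_rt["upper", ] - narrow$mean_rt["lower", ]))
})

test_that("fitting is deterministic and flags stage-1-only runs", {
  p <- quick_params()
  v <- variant_spec("preparation", pi_freq = 0.9, free = "pi_freq")
  set.seed(24)
  obs <- simonlca:::condition_sims_to_observed(
    simulate_four_conditions(p, v, 3000))
  ctl <- fit_control(trials_per_eval = 1500, stage1_maxit = 6,
                     stage2_maxit = 4, stage1_cycles = 1,
                     stage2_cycles = 1, n_restarts = 1, eval_seed = 77)
  start <- variant_spec("preparation", pi_freq = 0.7, free = "pi_freq")
  set.seed(25)
  f1 <- fit_model(obs, p, start, ctl)
  set.seed(25)
  f2 <- fit_model(obs, p, start, ctl)
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(f1$k, 1L)
  expect_true(f1$converged)

  ctl0 <- fit_control(trials_per_eval = 1500, stage1_maxit = 6,
                      stage2_maxit = 0, stage1_cycles = 1,
                      n_restarts = 1, eval_seed = 77)
  set.seed(26)
  f0 <- fit_model(obs, p, start, ctl0)
  expect_false(f0$converged)
  expect_true(is.finite(f0$g2_value))

  expect_error(fit_model(obs, p, variant_spec("preparation"), ctl),
               "no free parameters")
})
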