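conditions_grid <- function() {
  expand.grid(frequency_class = c("frequent", "infrequent"),
              congruency = c("congruent", "incongruent"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

condition_key <- function(freq, cong) paste(freq, cong, sep = "_")

#' Summarize a trial table for model fitting
#'
#' Reproduces the observed-data summary used by the fitting machinery:
#' trials are screened for outliers per participant and condition
#' ([screen_outliers()]), correct-response RTs are pooled across
#' participants per condition ([pool_participants()]), and each condition
#' is reduced to its error percentage, nine deciles (.1, .2, ..., .9) of
#' the pooled correct RTs, and the frequency of errors plus correct
#' responses in the ten bins bounded by those deciles.
#'
#' @param trials A data frame with columns `participant`,
#'   `required_response`, `congruency`, `rt`, `correct`, `timed_out`
#'   (timeouts excluded from all counts).
#' @param probs Quantile probabilities (default the nine deciles).
#' @param pool Pool across participants before summarizing (default TRUE;
#'   set FALSE for single-participant or already-pooled input).
#' @return An object of class `"observed_summary"`: a list of per-condition
#'   entries (keyed `frequent_congruent`, ...) each holding `n` (errors +
#'   correct after screening), `n_correct`, `n_errors`, `error_pct`,
#'   `quantiles`, `bin_counts` (length `length(probs) + 2`: the error bin
#'   first, then the RT bins), and `rts` (pooled correct RTs); plus
#'   attribute `probs`.
#' @export
summarize_observed <- function(trials, probs = seq(0.1, 0.9, by = 0.1),
                               pool = TRUE) {
  stopifnot(all(c("participant", "required_response", "congruency", "rt",
                  "correct") %in% names(trials)))
  if ("timed_out" %in% names(trials)) trials <- trials[!trials$timed_out, ]
  grid <- conditions_grid()
  out <- list()
  for (i in seq_len(nrow(grid))) {
    fc <- grid$frequency_class[i]
    cg <- grid$congruency[i]
    sub <- trials[trials$required_response == fc & trials$congruency == cg, ]
    n_err <- 0L
    samples <- list()
    for (p in unique(sub$participant)) {
      psub <- sub[sub$participant == p, ]
      scr <- screen_outliers(psub$rt)
      keep <- psub$rt >= 100 & psub$rt <= scr$ceiling
      psub <- psub[keep, ]
      n_err <- n_err + sum(!psub$correct)
      samples[[as.character(p)]] <- psub$rt[psub$correct]
    }
    rts <- if (pool && length(samples) > 1) {
      pool_participants(samples)$pooled
    } else {
      unlist(samples, use.names = FALSE)
    }
    if (length(rts) < 10)
      stop("condition ", condition_key(fc, cg), " has fewer than 10 ",
           "correct trials; quantile summary undefined")
    qs <- rt_quantiles(rts, probs)
    bins <- tabulate(findInterval(rts, unname(qs)) + 1L,
                     nbins = length(probs) + 1L)
    entry <- list(frequency_class = fc, congruency = cg,
                  n = length(rts) + n_err, n_correct = length(rts),
                  n_errors = n_err,
                  error_pct = 100 * n_err / (length(rts) + n_err),
                  quantiles = qs,
                  bin_counts = c(error = n_err, bins),
                  rts = rts)
    out[[condition_key(fc, cg)]] <- entry
  }
  attr(out, "probs") <- probs
  class(out) <- "observed_summary"
  out
}

#' Summarize simulated conditions as model predictions
#'
#' Simulates every frequency-by-congruency condition at `n_sim` trials and
#' returns the same per-condition structure as [summarize_observed()],
#' with `bin_props`: the predicted proportion of the error bin and of the
#' correct-RT bins bounded by the *observed* condition's quantiles (needed
#' for the G-squared statistic).
#'
#' @inheritParams simulate_condition
#' @param observed An `"observed_summary"` (supplies the bin boundaries).
#' @param n_sim Simulated trials per condition.
#' @return An object of class `"predicted_summary"`.
#' @export
predicted_summary <- function(params, variant, observed, n_sim,
                              cueing = c("none", "always-valid")) {
  cueing <- match.arg(cueing)
  probs <- attr(observed, "probs")
  out <- list()
  for (key in names(observed)) {
    obs <- observed[[key]]
    sim <- simulate_condition(params, variant, obs$frequency_class,
                              obs$congruency, n_sim, cueing, probs)
    n_done <- sim$n_correct + sim$n_errors
    p_err <- sim$n_errors / n_done
    rtbins <- tabulate(findInterval(sim$rts, unname(obs$quantiles)) + 1L,
                       nbins = length(probs) + 1L)
    out[[key]] <- list(frequency_class = obs$frequency_class,
                       congruency = obs$congruency,
                       n = n_done, n_errors = sim$n_errors,
                       error_pct = 100 * p_err,
                       quantiles = sim$quantiles,
                       mean_rt = sim$mean_rt,
                       bin_props = c(error = p_err,
                                     (1 - p_err) * rtbins / sim$n_correct))
  }
  attr(out, "probs") <- probs
  class(out) <- "predicted_summary"
  out
}

#' Stage-1 discrepancy: weighted RMS over quantiles and error rates
#'
#' Square root of the mean weighted squared deviation between observed and
#' predicted error percentages and reaction-time quantiles across all
#' conditions. To put both statistic families on comparable numeric
#' ranges, quantiles enter in seconds and error rates as proportions, each
#' with unit weight by default.
#'
#' @param observed An `"observed_summary"`.
#' @param simulated A `"predicted_summary"` (or observed-like structure
#'   with `error_pct` and `quantiles` per condition).
#' @param weights List with elements `error` and `quantile` (default both
#'   1).
#' @return Nonnegative scalar.
#' @export
stage1_objective <- function(observed, simulated,
                             weights = list(error = 1, quantile = 1)) {
  if (!setequal(names(observed), names(simulated)))
    stop("observed and simulated summaries cover different conditions")
  dev <- c()
  w <- c()
  for (key in names(observed)) {
    o <- observed[[key]]
    s <- simulated[[key]]
    if (length(o$quantiles) != length(s$quantiles))
      stop("quantile vectors of unequal length in condition ", key)
    dev <- c(dev, (o$error_pct - s$error_pct) / 100,
             (unname(o$quantiles) - unname(s$quantiles)) / 1000)
    w <- c(w, weights$error, rep(weights$quantile, length(o$quantiles)))
  }
  sqrt(sum(w * dev^2) / length(dev))
}

#' Likelihood-ratio discrepancy over quantile-bin frequencies
#'
#' `G^2 = 2 * sum O * log(O / (N * p))` summed over the error bin and the
#' correct-RT bins of every condition, with `O` the observed counts, `N`
#' the condition's trial total and `p` the predicted bin proportions.
#' Zero-count bins contribute nothing. Predicted proportions are floored
#' at `eps` (then renormalized) so that bins the simulation never hit do
#' not produce infinite discrepancies; any application of the floor is
#' recorded in attribute `"floored"`.
#'
#' @param observed An `"observed_summary"` (uses `bin_counts`).
#' @param predicted A `"predicted_summary"` (uses `bin_props`).
#' @param eps Floor for predicted proportions (default `0.5 / n_sim` per
#'   condition, with `n_sim` the predicted summary's simulated count).
#' @return Nonnegative scalar with attribute `"floored"` (number of bins
#'   floored).
#' @export
g2_statistic <- function(observed, predicted, eps = NULL) {
  if (!setequal(names(observed), names(predicted)))
    stop("observed and predicted summaries cover different conditions")
  g2 <- 0
  floored <- 0L
  for (key in names(observed)) {
    O <- observed[[key]]$bin_counts
    p <- predicted[[key]]$bin_props
    if (length(O) != length(p))
      stop("bin structures differ in condition ", key)
    if (abs(sum(p) - 1) > 1e-6)
      stop("predicted proportions do not sum to 1 in condition ", key)
    e <- if (is.null(eps)) 0.5 / predicted[[key]]$n else eps
    low <- p < e
    if (any(low & O > 0)) floored <- floored + sum(low & O > 0)
    p <- pmax(p, e)
    p <- p / sum(p)
    N <- sum(O)
    pos <- O > 0
    g2 <- g2 + 2 * sum(O[pos] * log(O[pos] / (N * p[pos])))
  }
  attr(g2, "floored") <- floored
  g2
}

# ---- parameter bounds and free-parameter plumbing -------------------------

default_bounds <- function(threshold) {
  list(pi_freq = c(0.01, 0.999), pi_infr = c(0.01, 0.999),
       rel_input = c(0.40, 0.80),
       irr_amplitude = c(0, 1), irr_tau = c(20, 500),
       lead_mean = c(0, 300), lead_sd = c(0, 100),
       leak = c(0, 0.2), lateral = c(0, 0.2),
       noise_sd = c(0.02, 2),
       prep_bias = c(0, 0.9 * threshold),
       resid_mean = c(50, 500), resid_sd = c(0, 100),
       attention_rel_same = c(0.40, 0.80),
       attention_rel_opposite = c(0.40, 0.80),
       contingency_rel_freqside = c(0.40, 0.80),
       contingency_rel_infrside = c(0.40, 0.80),
       contingency_irr_freqside = c(0, 1),
       contingency_irr_infrside = c(0, 1),
       shield_irr_amplitude = c(0, 1),
       shield_irr_tau = c(20, 800))
}

apply_free_params <- function(params, variant, values) {
  base_names <- intersect(names(values), names(unclass(params)))
  var_names <- setdiff(names(values), base_names)
  if (length(base_names))
    params <- do.call(update_params,
                      c(list(params), as.list(values[base_names])))
  for (nm in var_names) {
    if (!nm %in% names(variant)) stop("unknown free parameter: ", nm)
    variant[[nm]] <- unname(values[nm])
  }
  validate_variant_spec(variant)
  list(params = params, variant = variant)
}

to_unit <- function(x, lo, hi) stats::qlogis(pmin(pmax((x - lo) / (hi - lo),
                                                       1e-6), 1 - 1e-6))
from_unit <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Control settings for model fitting
#'
#' @param trials_per_eval Simulated trials per condition per objective
#'   evaluation (default 20000).
#' @param stage1_maxit,stage2_maxit Nelder-Mead iteration budgets per
#'   cycle for the two stages.
#' @param stage1_cycles,stage2_cycles Maximum number of simplex runs per
#'   stage, each restarted from the incumbent solution with a fresh
#'   simplex. Restarting is essential with a simulation-based objective:
#'   the simplex tends to collapse prematurely on its residual roughness.
#' @param cycle_tol Relative improvement below which cycling stops early.
#' @param n_restarts Independent starts from jittered starting points
#'   (default 3; the best stage-1 solution seeds stage 2).
#' @param restart_jitter Relative jitter of the starting values on the
#'   transformed scale.
#' @param eval_seed Seed fixed before every objective evaluation (common
#'   random numbers, making the simulation-based objective
#'   quasi-deterministic); drawn once from the session RNG if `NULL`.
#' @param cueing Passed to the condition simulator.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(trials_per_eval = 20000,
                        stage1_maxit = 50, stage2_maxit = 40,
                        stage1_cycles = 4, stage2_cycles = 2,
                        cycle_tol = 0.02,
                        n_restarts = 3, restart_jitter = 0.3,
                        eval_seed = NULL,
                        cueing = c("none", "always-valid")) {
  cueing <- match.arg(cueing)
  if (is.null(eval_seed))
    eval_seed <- sample.int(.Machine$integer.max, 1)
  ctl <- list(trials_per_eval = trials_per_eval,
              stage1_maxit = stage1_maxit, stage2_maxit = stage2_maxit,
              stage1_cycles = stage1_cycles, stage2_cycles = stage2_cycles,
              cycle_tol = cycle_tol,
              n_restarts = n_restarts, restart_jitter = restart_jitter,
              eval_seed = eval_seed, cueing = cueing)
  class(ctl) <- "fit_control"
  ctl
}

#' Fit a model variant to an observed summary
#'
#' Two-stage procedure: stage 1 minimizes the weighted RMS deviation of
#' error percentages and RT quantiles ([stage1_objective()]); stage 2,
#' starting from the stage-1 solution, minimizes the G-squared statistic
#' over quantile-bin frequencies ([g2_statistic()]). Both stages use a
#' bounded derivative-free simplex search (Nelder-Mead on a logit-transformed
#' scale). Every objective evaluation simulates `trials_per_eval` trials
#' per condition under common random numbers (the same seed before every
#' evaluation), which makes the noisy simulation objective
#' quasi-deterministic and the whole fit reproducible.
#'
#' The free parameters are the ones named in `variant$free`; all other
#' parameters stay fixed at their values in `params` / `variant`.
#'
#' @param observed An `"observed_summary"` from [summarize_observed()].
#' @param params Starting/fixed base parameters ([lca_params()]).
#' @param variant The model variant with its `free` ledger
#'   ([variant_spec()]).
#' @param control A [fit_control()] list.
#' @param bounds Optional named list of `c(lower, upper)` overriding the
#'   defaults per free parameter.
#' @return An object of class `"lca_fit"`: a list with `estimates` (named
#'   vector of fitted free parameters), `params` and `variant` (with the
#'   estimates substituted), `stage1_value`, `g2_value`, `k`,
#'   `n_evaluations`, `converged`, `control`.
#' @export
fit_model <- function(observed, params, variant, control = fit_control(),
                      bounds = list()) {
  stopifnot(inherits(observed, "observed_summary"),
            inherits(params, "lca_params"),
            inherits(variant, "lca_variant"))
  free <- variant$free
  if (length(free) == 0) stop("variant has no free parameters to fit")
  bd <- default_bounds(params$threshold)
  bd[names(bounds)] <- bounds
  missing_bd <- setdiff(free, names(bd))
  if (length(missing_bd))
    stop("no bounds for parameter(s): ", paste(missing_bd, collapse = ", "))
  lo <- vapply(free, function(nm) bd[[nm]][1], numeric(1))
  hi <- vapply(free, function(nm) bd[[nm]][2], numeric(1))

  start_vals <- vapply(free, function(nm) {
    v <- if (nm %in% names(unclass(params))) params[[nm]] else variant[[nm]]
    if (is.na(v)) mean(c(lo[nm], hi[nm])) else v
  }, numeric(1))
  z0 <- to_unit(start_vals, lo, hi)

  n_eval <- 0L
  objective <- function(z, type) {
    n_eval <<- n_eval + 1L
    vals <- from_unit(z, lo, hi)
    names(vals) <- free
    eff <- apply_free_params(params, variant, vals)
    set.seed(control$eval_seed)  # common random numbers
    pred <- predicted_summary(eff$params, eff$variant, observed,
                              control$trials_per_eval, control$cueing)
    if (type == "stage1") stage1_objective(observed, pred)
    else as.numeric(g2_statistic(observed, pred))
  }

  # starting points for the restarts are drawn before optimization so the
  # evaluation-time reseeding cannot interfere with them
  starts <- list(z0)
  if (control$n_restarts > 1) {
    for (r in 2:control$n_restarts)
      starts[[r]] <- z0 + stats::rnorm(length(z0), 0, control$restart_jitter)
  }

  # one stage = up to `cycles` simplex runs, each restarted (with a fresh
  # simplex) from the incumbent; stops early once a cycle no longer
  # improves the objective by more than cycle_tol (relative)
  run_stage <- function(z0, type, maxit, cycles) {
    best <- list(par = z0, value = Inf)
    for (cyc in seq_len(cycles)) {
      # Nelder-Mead is kept even for one free parameter (optim warns):
      # the restart-cycling contract is the same in every dimension
      o <- suppressWarnings(
        stats::optim(best$par, objective, type = type,
                     method = "Nelder-Mead",
                     control = list(maxit = maxit)))
      improved <- o$value < best$value * (1 - control$cycle_tol)
      if (o$value < best$value) best <- o
      if (!improved && cyc > 1) break
    }
    best
  }

  best1 <- NULL
  for (st in starts) {
    o1 <- run_stage(st, "stage1", control$stage1_maxit,
                    control$stage1_cycles)
    if (is.null(best1) || o1$value < best1$value) best1 <- o1
  }
  converged <- TRUE
  if (control$stage2_maxit > 0) {
    o2 <- run_stage(best1$par, "g2", control$stage2_maxit,
                    control$stage2_cycles)
    zfin <- o2$par
    g2 <- o2$value
  } else {
    converged <- FALSE  # stage-1-only result
    zfin <- best1$par
    g2 <- objective(best1$par, "g2")
  }

  est <- from_unit(zfin, lo, hi)
  names(est) <- free
  eff <- apply_free_params(params, variant, est)
  res <- list(estimates = est, params = eff$params, variant = eff$variant,
              stage1_value = best1$value, g2_value = g2,
              k = n_free_params(variant), n_evaluations = n_eval,
              converged = converged, control = control)
  class(res) <- "lca_fit"
  res
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca_fit> %s model, k = %d, stage-1 RMS = %.4f, G^2 = %.2f (%d evaluations%s)\n",
              x$variant$variant, x$k, x$stage1_value, x$g2_value,
              x$n_evaluations,
              if (x$converged) "" else "; stage-1 only"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Distribution of the AIC under repeated simulation
#'
#' With a simulation-based likelihood the goodness-of-fit statistic is
#' itself noisy. This evaluates G-squared `replicates` times at fixed
#' parameters, each time with a fresh set of `trials` simulated trials per
#' condition, and reports the distribution of `AIC = G^2 + 2k`.
#'
#' @param params,variant Fitted parameter set and variant (its `free`
#'   ledger supplies `k`).
#' @param observed The observed summary the G-squared is computed against.
#' @param replicates Number of replicate evaluations (default 100).
#' @param trials Simulated trials per condition per replicate (default
#'   100000).
#' @param cueing Passed to the condition simulator.
#' @return A list with `mean`, `sd`, `samples` (AIC per replicate),
#'   `g2_samples` and `k`.
#' @export
aic_distribution <- function(params, variant, observed, replicates = 100,
                             trials = 100000,
                             cueing = c("none", "always-valid")) {
  cueing <- match.arg(cueing)
  k <- n_free_params(variant)
  g2s <- vapply(seq_len(replicates), function(r) {
    pred <- predicted_summary(params, variant, observed, trials, cueing)
    as.numeric(g2_statistic(observed, pred))
  }, numeric(1))
  aic <- g2s + 2 * k
  list(mean = mean(aic), sd = stats::sd(aic), samples = aic,
       g2_samples = g2s, k = k)
}

#' Simulation-based 95 percent prediction intervals
#'
#' Simulates `replicates` datasets with the same number of trials per
#' condition as observed, summarizes each (mean RT and error percentage
#' per condition; delta plots per frequency class at the five standard
#' quantiles), and returns the central 95 percent interval of each
#' statistic across replicates.
#'
#' @param params,variant Generating parameter set and variant.
#' @param observed_n Named integer vector of trials per condition (names as
#'   in [summarize_observed()]: `frequent_congruent`, ...).
#' @param replicates Number of simulated datasets (default 1000).
#' @param level Interval coverage (default 0.95).
#' @param probs Delta-plot quantiles.
#' @param cueing Passed to the condition simulator.
#' @return A list with `mean_rt`, `error_pct` (each a matrix with rows
#'   lower/mean/upper, columns conditions) and `delta` (per frequency
#'   class, rows lower/mean/upper, columns quantiles).
#' @export
prediction_intervals <- function(params, variant, observed_n,
                                 replicates = 1000, level = 0.95,
                                 probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 cueing = c("none", "always-valid")) {
  cueing <- match.arg(cueing)
  grid <- conditions_grid()
  keys <- condition_key(grid$frequency_class, grid$congruency)
  stopifnot(all(keys %in% names(observed_n)))
  nq <- length(probs)
  mean_rt <- err <- matrix(NA_real_, replicates, 4,
                           dimnames = list(NULL, keys))
  delta <- list(frequent = matrix(NA_real_, replicates, nq),
                infrequent = matrix(NA_real_, replicates, nq))
  for (r in seq_len(replicates)) {
    sims <- list()
    for (i in seq_len(nrow(grid))) {
      key <- keys[i]
      sims[[key]] <- simulate_condition(params, variant,
                                        grid$frequency_class[i],
                                        grid$congruency[i],
                                        observed_n[[key]], cueing, probs)
      mean_rt[r, key] <- sims[[key]]$mean_rt
      err[r, key] <- sims[[key]]$error_pct
    }
    for (fc in c("frequent", "infrequent")) {
      delta[[fc]][r, ] <-
        unname(rt_quantiles(sims[[paste0(fc, "_incongruent")]]$rts, probs) -
               rt_quantiles(sims[[paste0(fc, "_congruent")]]$rts, probs))
    }
  }
  a <- (1 - level) / 2
  band <- function(m) apply(m, 2, function(col)
    c(lower = unname(stats::quantile(col, a)), mean = mean(col),
      upper = unname(stats::quantile(col, 1 - a))))
  list(mean_rt = band(mean_rt), error_pct = band(err),
       delta = lapply(delta, band), level = level, probs = probs,
       replicates = replicates)
}

#' Parameter-recovery harness
#'
#' Generates an observed summary from known parameters by large-n
#' simulation of all four conditions, then fits the same variant with the
#' requested free parameters and reports truth, estimate and error.
#'
#' @param params,variant Generating (true) parameter set and variant; the
#'   variant's `free` ledger defines what is re-estimated.
#' @param n_obs Simulated trials per condition for the synthetic observed
#'   data.
#' @param control A [fit_control()] for the fit.
#' @param start_params,start_variant Optional starting values for the fit
#'   (default: the true objects, with free parameters started mid-bounds
#'   by perturbation `start_jitter`).
#' @param start_jitter Relative perturbation of the true free-parameter
#'   values used as starting point (default 0.2), so the fit does not
#'   start at the truth.
#' @return A list with `truth`, `estimates`, `error` (estimate - truth),
#'   `fit` (the full `"lca_fit"`) and `observed`.
#' @export
parameter_recovery <- function(params, variant, n_obs = 50000,
                               control = fit_control(),
                               start_jitter = 0.2) {
  grid <- conditions_grid()
  # synthetic observed data: large-n simulation of each condition
  sims <- list()
  for (i in seq_len(nrow(grid))) {
    key <- condition_key(grid$frequency_class[i], grid$congruency[i])
    sims[[key]] <- simulate_condition(params, variant,
                                      grid$frequency_class[i],
                                      grid$congruency[i], n_obs,
                                      control$cueing)
  }
  observed <- condition_sims_to_observed(sims)

  truth <- vapply(variant$free, function(nm)
    if (nm %in% names(unclass(params))) params[[nm]] else variant[[nm]],
    numeric(1))
  bd <- default_bounds(params$threshold)
  lo <- vapply(variant$free, function(nm) bd[[nm]][1], numeric(1))
  hi <- vapply(variant$free, function(nm) bd[[nm]][2], numeric(1))
  # perturb away from the truth, reflecting at the bounds so the start
  # never saturates the optimizer's transformed scale
  start <- truth * (1 + start_jitter * rep_len(c(1, -1), length(truth)))
  flip <- start > hi - 0.05 * (hi - lo) | start < lo + 0.05 * (hi - lo)
  start[flip] <- truth[flip] * (1 - start_jitter *
                                  rep_len(c(1, -1), length(truth))[flip])
  start <- pmin(pmax(start, lo + 0.05 * (hi - lo)), hi - 0.05 * (hi - lo))
  names(start) <- variant$free
  sp <- apply_free_params(params, variant, start)

  fit <- fit_model(observed, sp$params, sp$variant, control)
  list(truth = truth, estimates = fit$estimates,
       error = fit$estimates - truth, fit = fit, observed = observed)
}

# Convert a list of condition_summary objects (keyed by condition) into an
# observed_summary structure usable by the objectives.
condition_sims_to_observed <- function(sims,
                                       probs = seq(0.1, 0.9, by = 0.1)) {
  out <- list()
  for (key in names(sims)) {
    s <- sims[[key]]
    qs <- rt_quantiles(s$rts, probs)
    bins <- tabulate(findInterval(s$rts, unname(qs)) + 1L,
                     nbins = length(probs) + 1L)
    out[[key]] <- list(frequency_class = s$frequency_class,
                       congruency = s$congruency,
                       n = s$n_correct + s$n_errors,
                       n_correct = s$n_correct, n_errors = s$n_errors,
                       error_pct = s$error_pct,
                       quantiles = qs,
                       bin_counts = c(error = s$n_errors, bins),
                       rts = s$rts)
  }
  attr(out, "probs") <- probs
  class(out) <- "observed_summary"
  out
}
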