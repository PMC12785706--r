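#' Time course of the automatic (irrelevant) input
#'
#' Step response of a critically damped second-order high-pass filter,
#' `sign * amplitude * (1 - t/tau) * exp(-t/tau)`. The input equals
#' `sign * amplitude` at stimulus onset (`t = 0`), crosses zero once at
#' `t = tau`, reverses its arithmetic sign — so an initially facilitating
#' stimulus location becomes transiently inhibitory and vice versa — and
#' decays to zero. Its integral over `[0, Inf)` is exactly zero.
#'
#' @param t Time since stimulus onset, ms, >= 0 (vectorized).
#' @param amplitude Initial magnitude, dimensionless, >= 0.
#' @param tau Zero-crossing time, ms, > 0.
#' @param sign `+1` for the stimulus-side response code, `-1` for the
#'   opposite code.
#' @return Numeric vector of input values.
#' @examples
#' irrelevant_timecourse(c(0, 100, 200), amplitude = 0.3, tau = 100)
#' @export
irrelevant_timecourse <- function(t, amplitude, tau, sign = 1) {
  if (any(t < 0)) stop("t must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  sign * amplitude * (1 - t / tau) * exp(-t / tau)
}

#' Resolve the effective parameters of one trial
#'
#' Applies the active model variant's rules to the base parameter set given
#' a trial context: the preparation model leaves the base parameters
#' untouched (only the expectation state matters); the +attention model
#' switches the relevant input by whether the stimulus is on the expected
#' response's side; the +contingency model switches both relevant and
#' irrelevant inputs by the stimulus-location side; the +shielding model
#' substitutes the shielded irrelevant-input parameters on prepared trials.
#'
#' @param base An [lca_params()] object.
#' @param variant An [variant_spec()] object.
#' @param ctx A [trial_context()] object.
#' @return An `"lca_params"` object with the effective per-trial values.
#' @export
resolve_trial_parameters <- function(base, variant, ctx) {
  stopifnot(inherits(base, "lca_params"), inherits(variant, "lca_variant"),
            inherits(ctx, "trial_context"))
  p <- base
  switch(variant$variant,
    preparation = NULL,
    attention = {
      same <- ctx$stimulus_side == ctx$expected_response
      p <- update_params(p, rel_input = if (same) variant$attention_rel_same
                                        else variant$attention_rel_opposite)
    },
    contingency = {
      freqside <- ctx$stimulus_side == "frequent"
      p <- update_params(p,
        rel_input = if (freqside) variant$contingency_rel_freqside
                    else variant$contingency_rel_infrside,
        irr_amplitude = if (freqside) variant$contingency_irr_freqside
                        else variant$contingency_irr_infrside)
    },
    shielding = {
      if (ctx$prepared)
        p <- update_params(p, irr_amplitude = variant$shield_irr_amplitude,
                           irr_tau = variant$shield_irr_tau)
    },
    stop("unknown variant: ", variant$variant)
  )
  p
}

# Vectorized variant resolution for a batch of trials. Returns the
# per-trial input vectors handed to the compiled simulator.
resolve_trial_vectors <- function(params, variant, required, congruency,
                                  expected) {
  n <- length(required)
  other <- ifelse(required == "frequent", "infrequent", "frequent")
  side <- ifelse(congruency == "congruent", required, other)
  prepared <- expected == required
  rel <- rep(params$rel_input, n)
  amp <- rep(params$irr_amplitude, n)
  tau <- rep(params$irr_tau, n)
  if (variant$variant == "attention") {
    same <- side == expected
    rel <- ifelse(same, variant$attention_rel_same,
                  variant$attention_rel_opposite)
  } else if (variant$variant == "contingency") {
    freqside <- side == "frequent"
    rel <- ifelse(freqside, variant$contingency_rel_freqside,
                  variant$contingency_rel_infrside)
    amp <- ifelse(freqside, variant$contingency_irr_freqside,
                  variant$contingency_irr_infrside)
  } else if (variant$variant == "shielding") {
    amp <- ifelse(prepared, variant$shield_irr_amplitude, amp)
    tau <- ifelse(prepared, variant$shield_irr_tau, tau)
  }
  list(rel = rel, irr_amp = amp, irr_tau = tau,
       prep_correct = ifelse(prepared, params$prep_bias, 0),
       prep_error = ifelse(prepared, 0, params$prep_bias),
       congruent = as.integer(congruency == "congruent"))
}

#' Simulate a batch of trials
#'
#' Runs the discrete-time accumulator for each row of a trial table. The
#' expectation state must already be assigned (column `expected_response`);
#' use [simulate_condition()] or [generate_synthetic_dataset()] to draw it
#' from the preparation probabilities.
#'
#' @param params An [lca_params()] object (base parameters).
#' @param variant An [variant_spec()] object.
#' @param trials A data frame with columns `required_response`,
#'   `congruency`, `expected_response`.
#' @return `trials` with columns `rt` (ms), `correct` (logical),
#'   `timed_out` (logical), `decision_time` (ms) appended. Timed-out trials
#'   carry `NA` reaction times.
#' @export
simulate_trials <- function(params, variant, trials) {
  stopifnot(inherits(params, "lca_params"), inherits(variant, "lca_variant"),
            is.data.frame(trials),
            all(c("required_response", "congruency", "expected_response")
                %in% names(trials)))
  n <- nrow(trials)
  v <- resolve_trial_vectors(params, variant, trials$required_response,
                             trials$congruency, trials$expected_response)
  # master seed for the per-trial RNG substreams, drawn from the session
  # RNG so set.seed() governs reproducibility; under a fixed master seed
  # every trial's noise path is a fixed function of its index (common
  # random numbers across parameter values)
  master <- sum(sample.int(2147483647L, 2) * c(2^20, 1))
  m <- lca_simulate_cpp(n, v$rel, v$irr_amp, v$irr_tau, v$prep_correct,
                        v$prep_error, v$congruent,
                        params$lead_mean, params$lead_sd, params$leak,
                        params$lateral, params$noise_sd, params$threshold,
                        params$resid_mean, params$resid_sd,
                        params$dt, params$max_time, master)
  trials$rt <- m[, "rt"]
  trials$correct <- as.logical(m[, "correct"])
  trials$timed_out <- m[, "timed_out"] > 0
  trials$decision_time <- m[, "decision_time"]
  trials
}

#' Simulate a single trial
#'
#' @inheritParams simulate_trials
#' @param ctx A [trial_context()] object.
#' @return A one-row data frame with `rt`, `correct`, `timed_out`,
#'   `decision_time`.
#' @export
simulate_trial <- function(params, variant, ctx) {
  stopifnot(inherits(ctx, "trial_context"))
  df <- data.frame(required_response = ctx$required_response,
                   congruency = ctx$congruency,
                   expected_response = ctx$expected_response,
                   stringsAsFactors = FALSE)
  out <- simulate_trials(params, variant, df)
  out[, c("rt", "correct", "timed_out", "decision_time")]
}

# Draw the expectation state for a batch of trials. Without cues the
# frequent response is expected with probability pi_freq regardless of the
# required response; with always-valid cues the cued (= required) response
# is prepared with probability pi_freq / pi_infr depending on its class,
# otherwise the other response is expected.
draw_expectation <- function(variant, required,
                             cueing = c("none", "always-valid")) {
  cueing <- match.arg(cueing)
  n <- length(required)
  other <- ifelse(required == "frequent", "infrequent", "frequent")
  if (cueing == "none") {
    ifelse(stats::runif(n) < variant$pi_freq, "frequent", "infrequent")
  } else {
    if (is.na(variant$pi_infr))
      stop("always-valid cueing requires pi_infr")
    p_prep <- ifelse(required == "frequent", variant$pi_freq,
                     variant$pi_infr)
    ifelse(stats::runif(n) < p_prep, required, other)
  }
}

#' Simulate one experimental condition
#'
#' Draws each trial's expectation state from the preparation probabilities,
#' simulates `n` trials, and summarizes the outcome: correct-response RT
#' sample, error percentage (among completed trials), RT quantiles, and the
#' timeout count.
#'
#' @inheritParams simulate_trials
#' @param frequency_class `"frequent"` or `"infrequent"`: the required
#'   response's relative-frequency class.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param n Number of trials, >= 1.
#' @param cueing `"none"` (expectation drawn from `pi_freq` toward the
#'   frequent response) or `"always-valid"` (the required response is
#'   prepared with its class-specific probability).
#' @param probs Quantile probabilities for the summary.
#' @return An object of class `"condition_summary"`: a list with
#'   `frequency_class`, `congruency`, `n`, `n_correct`, `n_errors`,
#'   `n_timeouts`, `error_pct`, `quantiles`, `mean_rt` and the raw
#'   correct-response RTs in `rts`.
#' @examples
#' set.seed(1)
#' s <- simulate_condition(lca_params(), variant_spec("preparation"),
#'                         "frequent", "congruent", n = 500)
#' s$error_pct
#' @export
simulate_condition <- function(params, variant, frequency_class, congruency,
                               n, cueing = c("none", "always-valid"),
                               probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(n >= 1)
  cueing <- match.arg(cueing)
  frequency_class <- match.arg(frequency_class, c("frequent", "infrequent"))
  congruency <- match.arg(congruency, c("congruent", "incongruent"))
  required <- rep(frequency_class, n)
  expected <- draw_expectation(variant, required, cueing)
  df <- data.frame(required_response = required,
                   congruency = rep(congruency, n),
                   expected_response = expected,
                   stringsAsFactors = FALSE)
  sim <- simulate_trials(params, variant, df)
  done <- !sim$timed_out
  if (!any(done)) stop("all ", n, " simulated trials timed out")
  correct_rts <- sim$rt[done & sim$correct]
  n_err <- sum(done & !sim$correct)
  qs <- if (length(correct_rts) >= length(probs))
    rt_quantiles(correct_rts, probs) else rep(NA_real_, length(probs))
  out <- list(frequency_class = frequency_class, congruency = congruency,
              n = n, n_correct = length(correct_rts), n_errors = n_err,
              n_timeouts = sum(!done),
              error_pct = 100 * n_err / sum(done),
              quantiles = qs,
              mean_rt = mean(correct_rts),
              rts = correct_rts)
  class(out) <- "condition_summary"
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s-%s: n=%d, mean RT %.1f ms, %.2f%% errors, %d timeouts\n",
              x$frequency_class, x$congruency, x$n, x$mean_rt, x$error_pct,
              x$n_timeouts))
  invisible(x)
}

#' Deterministic crossing time of the noise-free accumulator
#'
#' Reference integrator for the noiseless coupled dynamics (sigma = 0,
#' fixed lead, no residual variability): plain R Euler integration at an
#' arbitrary step size, with within-step linear interpolation of the
#' threshold crossing. Intended for verifying the stochastic simulator
#' against a fine-step solution of the same ordinary differential equation.
#'
#' @param params An [lca_params()] object; `noise_sd`, `lead_sd` and
#'   `resid_sd` are ignored (treated as zero), `lead_mean` is used as the
#'   fixed lead.
#' @param congruent Logical: stimulus on the correct response's side?
#' @param prepared `"correct"`, `"error"` or `"none"`: which code starts at
#'   `prep_bias`.
#' @param dt Integration step in ms (defaults to `params$dt`).
#' @return A list with `time` (interpolated crossing time, ms; `NA` if no
#'   crossing by `max_time`) and `winner` (`"correct"`, `"error"` or `NA`).
#' @export
deterministic_crossing_time <- function(params, congruent = TRUE,
                                        prepared = c("correct", "error",
                                                     "none"),
                                        dt = params$dt) {
  stopifnot(inherits(params, "lca_params"))
  prepared <- match.arg(prepared)
  a1 <- if (prepared == "correct") params$prep_bias else 0
  a2 <- if (prepared == "error") params$prep_bias else 0
  s1 <- if (congruent) 1 else -1
  lead <- params$lead_mean
  theta <- params$threshold
  nstep <- ceiling(params$max_time / dt)
  for (step in seq_len(nstep) - 1L) {
    t <- step * dt
    h <- s1 * irrelevant_timecourse(t, params$irr_amplitude, params$irr_tau)
    on <- as.numeric(t >= lead)
    b1 <- a1 + dt * (on * params$rel_input + h -
                       params$leak * a1 - params$lateral * a2)
    b2 <- a2 + dt * (on * (1 - params$rel_input) - h -
                       params$leak * a2 - params$lateral * a1)
    b1 <- max(0, b1)
    b2 <- max(0, b2)
    if (b1 >= theta || b2 >= theta) {
      f1 <- if (b1 >= theta) (theta - a1) / (b1 - a1) else 2
      f2 <- if (b2 >= theta) (theta - a2) / (b2 - a2) else 2
      winner <- if (f1 <= f2) "correct" else "error"
      return(list(time = t + dt * min(f1, f2), winner = winner))
    }
    a1 <- b1
    a2 <- b2
  }
  list(time = NA_real_, winner = NA_character_)
}
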