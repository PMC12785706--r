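#' Parameters of the extended leaky competing accumulator
#'
#' Bundles all parameters governing a single simulated trial: the controlled
#' (relevant) input, the transient automatic (irrelevant) input and its
#' temporal lead, the accumulator dynamics (leak, lateral inhibition, noise,
#' threshold), the preparation head start, the residual-time distribution,
#' and the integration settings.
#'
#' The two response codes share the scale constraint of the original LCA:
#' the correct code receives `rel_input` and the error code
#' `1 - rel_input`, so the controlled inputs always sum to one. The
#' irrelevant input follows the step response of a critically damped
#' second-order high-pass filter, `A * (1 - t/tau) * exp(-t/tau)`: it starts
#' at `A`, crosses zero once at `t = tau`, reverses sign and decays to zero
#' (see [irrelevant_timecourse()]).
#'
#' @param rel_input Controlled input to the correct response code,
#'   dimensionless in (0, 1). The error code receives `1 - rel_input`.
#' @param irr_amplitude Initial magnitude of the automatic input,
#'   dimensionless, >= 0.
#' @param irr_tau Time constant of the irrelevant-input decline (its
#'   zero-crossing time), ms, > 0.
#' @param lead_mean,lead_sd Mean and trial-to-trial SD of the temporal lead
#'   of the irrelevant over the relevant input, ms, >= 0. The lead is drawn
#'   once per trial from a normal truncated at zero.
#' @param leak Self-inhibition rate k, 1/ms, >= 0.
#' @param lateral Lateral inhibition rate beta, 1/ms, >= 0.
#' @param noise_sd Diffusion scale sigma per sqrt(ms), dimensionless, >= 0.
#' @param threshold Decision threshold theta, dimensionless, > 0. Fixed as
#'   the scale anchor alongside the unit-sum input constraint.
#' @param prep_bias Initial activation of the expected (prepared) response
#'   code; the other code starts at 0. Must be below `threshold`.
#' @param resid_mean,resid_sd Residual (non-decision) time distribution,
#'   normal truncated at zero, ms, >= 0.
#' @param dt Euler integration step, ms, > 0.
#' @param max_time Decision deadline for the simulator, ms. Trials in which
#'   neither code crosses by `max_time` are flagged as timed out.
#'
#' @return An object of class `"lca_params"` (a named list).
#' @examples
#' p <- lca_params()
#' p$irr_tau
#' @export
lca_params <- function(rel_input = 0.53,
                       irr_amplitude = 0.30,
                       irr_tau = 90,
                       lead_mean = 100,
                       lead_sd = 25,
                       leak = 0.01,
                       lateral = 0.02,
                       noise_sd = 0.15,
                       threshold = 25,
                       prep_bias = 6,
                       resid_mean = 150,
                       resid_sd = 20,
                       dt = 1,
                       max_time = 3000) {
  p <- list(rel_input = rel_input, irr_amplitude = irr_amplitude,
            irr_tau = irr_tau, lead_mean = lead_mean, lead_sd = lead_sd,
            leak = leak, lateral = lateral, noise_sd = noise_sd,
            threshold = threshold, prep_bias = prep_bias,
            resid_mean = resid_mean, resid_sd = resid_sd,
            dt = dt, max_time = max_time)
  validate_lca_params(p)
  class(p) <- "lca_params"
  p
}

validate_lca_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  }
  if (p$rel_input <= 0 || p$rel_input >= 1)
    stop("rel_input must lie strictly in (0, 1)")
  if (p$irr_amplitude < 0) stop("irr_amplitude must be >= 0")
  if (p$irr_tau <= 0) stop("irr_tau must be > 0")
  if (p$lead_mean < 0 || p$lead_sd < 0)
    stop("lead_mean and lead_sd must be >= 0")
  if (p$leak < 0 || p$lateral < 0)
    stop("leak and lateral must be >= 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$threshold <= 0) stop("threshold must be > 0")
  if (p$prep_bias < 0) stop("prep_bias must be >= 0")
  if (p$prep_bias >= p$threshold)
    stop("prep_bias must be below threshold (no trial may terminate at t = 0)")
  if (p$resid_mean < 0 || p$resid_sd < 0)
    stop("resid_mean and resid_sd must be >= 0")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$max_time <= p$dt) stop("max_time must exceed dt")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params An [lca_params()] object.
#' @param ... Named fields to replace.
#' @return An `"lca_params"` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "lca_params"))
  repl <- list(...)
  if (length(repl)) {
    bad <- setdiff(names(repl), names(unclass(params)))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(repl)] <- repl
  }
  p <- unclass(params)
  validate_lca_params(p)
  class(p) <- "lca_params"
  p
}

#' @export
print.lca_params <- function(x, ...) {
  cat("<lca_params>\n")
  v <- unlist(unclass(x))
  cat(paste0("  ", format(names(v), width = 14), " ", format(v)), sep = "\n")
  invisible(x)
}

#' Model-variant specification
#'
#' Describes which extension of the preparation model is active and carries
#' the variant-specific parameters plus the ledger of free parameter names
#' used for the AIC penalty (`k = length(free)`).
#'
#' Variants:
#' \describe{
#'   \item{preparation}{Frequent and infrequent responses differ only in the
#'     probability of being expected (and prepared): the frequent response
#'     is expected with probability `pi_freq`, the infrequent one otherwise.
#'     With always-valid cues, `pi_freq` and `pi_infr` give the probability
#'     that the cued (required) response is actually prepared.}
#'   \item{attention}{Adds a dependence of the relevant input on whether the
#'     stimulus appears on the same side as the expected response
#'     (`attention_rel_same`) or the opposite side
#'     (`attention_rel_opposite`).}
#'   \item{contingency}{Adds a dependence of both the relevant and the
#'     irrelevant input on the task-irrelevant stimulus location: values for
#'     stimuli on the frequent-response side vs the infrequent-response
#'     side.}
#'   \item{shielding}{Prepared responses are shielded against distraction:
#'     the irrelevant input starts weaker (`shield_irr_amplitude` <= base
#'     amplitude) and declines more slowly (`shield_irr_tau` >= base tau)
#'     when the trial's required response is the prepared one.}
#' }
#'
#' @param variant One of `"preparation"`, `"attention"`, `"contingency"`,
#'   `"shielding"`.
#' @param pi_freq Probability of preparing the frequent response.
#' @param pi_infr Probability of preparing the infrequent response under
#'   always-valid cueing; ignored (may be `NA`) without cues, where the
#'   infrequent response is prepared with probability `1 - pi_freq`.
#' @param attention_rel_same,attention_rel_opposite Relevant input when the
#'   stimulus is on the same/opposite side as the expected response.
#' @param contingency_rel_freqside,contingency_rel_infrside Relevant input
#'   by stimulus-location side.
#' @param contingency_irr_freqside,contingency_irr_infrside Irrelevant-input
#'   amplitude by stimulus-location side.
#' @param shield_irr_amplitude,shield_irr_tau Irrelevant-input amplitude and
#'   time constant for prepared responses.
#' @param free Character vector naming the free parameters of the fitted
#'   model (the AIC ledger). Only fields meaningful for the active variant
#'   (or base [lca_params()] fields) may appear.
#'
#' @return An object of class `"lca_variant"`.
#' @examples
#' variant_spec("preparation", pi_freq = 0.9,
#'              free = c("pi_freq", "irr_amplitude", "lead_mean"))
#' @export
variant_spec <- function(variant = c("preparation", "attention",
                                     "contingency", "shielding"),
                         pi_freq = 0.9, pi_infr = NA_real_,
                         attention_rel_same = NA_real_,
                         attention_rel_opposite = NA_real_,
                         contingency_rel_freqside = NA_real_,
                         contingency_rel_infrside = NA_real_,
                         contingency_irr_freqside = NA_real_,
                         contingency_irr_infrside = NA_real_,
                         shield_irr_amplitude = NA_real_,
                         shield_irr_tau = NA_real_,
                         free = character()) {
  variant <- match.arg(variant)
  v <- list(variant = variant, pi_freq = pi_freq, pi_infr = pi_infr,
            attention_rel_same = attention_rel_same,
            attention_rel_opposite = attention_rel_opposite,
            contingency_rel_freqside = contingency_rel_freqside,
            contingency_rel_infrside = contingency_rel_infrside,
            contingency_irr_freqside = contingency_irr_freqside,
            contingency_irr_infrside = contingency_irr_infrside,
            shield_irr_amplitude = shield_irr_amplitude,
            shield_irr_tau = shield_irr_tau,
            free = free)
  validate_variant_spec(v)
  class(v) <- "lca_variant"
  v
}

variant_fields <- list(
  preparation = c("pi_freq", "pi_infr"),
  attention   = c("pi_freq", "pi_infr", "attention_rel_same",
                  "attention_rel_opposite"),
  contingency = c("pi_freq", "pi_infr", "contingency_rel_freqside",
                  "contingency_rel_infrside", "contingency_irr_freqside",
                  "contingency_irr_infrside"),
  shielding   = c("pi_freq", "pi_infr", "shield_irr_amplitude",
                  "shield_irr_tau")
)

validate_variant_spec <- function(v) {
  prob_ok <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!prob_ok(v$pi_freq) || !prob_ok(v$pi_infr))
    stop("preparation probabilities must lie in [0, 1]")
  if (is.na(v$pi_freq)) stop("pi_freq is required")
  req <- switch(v$variant,
    attention = c("attention_rel_same", "attention_rel_opposite"),
    contingency = c("contingency_rel_freqside", "contingency_rel_infrside",
                    "contingency_irr_freqside", "contingency_irr_infrside"),
    shielding = c("shield_irr_amplitude", "shield_irr_tau"),
    character())
  for (nm in req) {
    if (is.na(v[[nm]]))
      stop("variant '", v$variant, "' requires field '", nm, "'")
  }
  if (!is.character(v$free)) stop("free must be a character vector")
  allowed <- c(variant_fields[[v$variant]],
               names(formals(lca_params)))
  bad <- setdiff(v$free, allowed)
  if (length(bad))
    stop("free parameter(s) not applicable to the '", v$variant,
         "' variant: ", paste(bad, collapse = ", "))
  invisible(v)
}

#' @export
print.lca_variant <- function(x, ...) {
  cat("<lca_variant> ", x$variant, "\n", sep = "")
  v <- unlist(x[setdiff(names(x), c("variant", "free"))])
  v <- v[!is.na(v)]
  if (length(v))
    cat(paste0("  ", format(names(v), width = 24), " ", format(v)), sep = "\n")
  cat("  free: ", if (length(x$free)) paste(x$free, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Number of free parameters of a variant specification
#'
#' @param variant An [variant_spec()] object.
#' @return Integer count `k` used in the AIC penalty `2k`.
#' @export
n_free_params <- function(variant) {
  stopifnot(inherits(variant, "lca_variant"))
  length(variant$free)
}

#' Trial context
#'
#' One trial's condition: which response is required (frequency class),
#' congruency of the irrelevant stimulus location, and the expectation
#' state. The stimulus side is determined by the required response and
#' congruency: congruent stimuli appear on the required response's side,
#' incongruent stimuli on the other side. A trial is `prepared` when the
#' expected response equals the required one.
#'
#' @param required_response `"frequent"` or `"infrequent"`.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param expected_response `"frequent"` or `"infrequent"`.
#' @return An object of class `"trial_context"` with fields
#'   `required_response`, `congruency`, `stimulus_side` (side labelled by
#'   the response whose side the stimulus occupies), `expected_response`,
#'   `prepared`.
#' @examples
#' trial_context("frequent", "incongruent", "frequent")
#' @export
trial_context <- function(required_response = c("frequent", "infrequent"),
                          congruency = c("congruent", "incongruent"),
                          expected_response = c("frequent", "infrequent")) {
  required_response <- match.arg(required_response)
  congruency <- match.arg(congruency)
  expected_response <- match.arg(expected_response)
  other <- function(r) if (r == "frequent") "infrequent" else "frequent"
  side <- if (congruency == "congruent") required_response
          else other(required_response)
  ctx <- list(required_response = required_response,
              congruency = congruency,
              stimulus_side = side,
              expected_response = expected_response,
              prepared = expected_response == required_response)
  class(ctx) <- "trial_context"
  ctx
}
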