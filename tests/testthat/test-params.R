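test_that("parameter construction enforces domains", {
  expect_s3_class(lca_params(), "lca_params")
  expect_error(lca_params(rel_input = 0), "rel_input")
  expect_error(lca_params(rel_input = 1), "rel_input")
  expect_error(lca_params(irr_tau = 0), "irr_tau")
  expect_error(lca_params(irr_amplitude = -0.1), "irr_amplitude")
  expect_error(lca_params(noise_sd = -1), "noise_sd")
  expect_error(lca_params(threshold = 0), "threshold")
  expect_error(lca_params(prep_bias = 25, threshold = 25), "prep_bias")
  expect_error(lca_params(dt = 0), "dt")
  expect_error(lca_params(lead_mean = -5), "lead_mean")
})

test_that("update_params replaces fields and re-validates", {
  p <- lca_params()
  q <- update_params(p, irr_amplitude = 0.1, lead_mean = 80)
  expect_equal(q$irr_amplitude, 0.1)
  expect_equal(q$lead_mean, 80)
  expect_equal(q$threshold, p$threshold)
  expect_error(update_params(p, nonsense = 1), "unknown parameter")
  expect_error(update_params(p, prep_bias = p$threshold), "prep_bias")
})

test_that("variant specification validates its fields and free ledger", {
  v <- variant_spec("preparation", pi_freq = 0.9)
  expect_equal(n_free_params(v), 0L)
  v2 <- variant_spec("preparation", free = c("pi_freq", "irr_amplitude"))
  expect_equal(n_free_params(v2), 2L)
  expect_error(variant_spec("preparation", pi_freq = 1.2), "probabilities")
  expect_error(variant_spec("attention", pi_freq = 0.9), "attention_rel_same")
  expect_error(variant_spec("shielding", pi_freq = 0.9), "shield_irr")
  # a contingency-only field cannot be free under the preparation variant
  expect_error(variant_spec("preparation",
                            free = "contingency_irr_freqside"),
               "not applicable")
})

test_that("trial context derives stimulus side and preparation state", {
  ctx <- trial_context("frequent", "congruent", "frequent")
  expect_equal(ctx$stimulus_side, "frequent")
  expect_true(ctx$prepared)
  ctx <- trial_context("frequent", "incongruent", "infrequent")
  expect_equal(ctx$stimulus_side, "infrequent")
  expect_false(ctx$prepared)
  ctx <- trial_context("infrequent", "incongruent", "infrequent")
  expect_equal(ctx$stimulus_side, "frequent")
  expect_true(ctx$prepared)
})

test_that("variant rules resolve per-trial parameters", {
  base <- lca_params()

  # preparation: identity mapping
  v <- variant_spec("preparation")
  ctx <- trial_context("frequent", "congruent", "frequent")
  expect_identical(unclass(resolve_trial_parameters(base, v, ctx)),
                   unclass(base))

  # attention: relevant input switches with stimulus-side/expectation match
  v <- variant_spec("attention", attention_rel_same = 0.539,
                    attention_rel_opposite = 0.502)
  same <- trial_context("frequent", "congruent", "frequent")
  opp <- trial_context("frequent", "incongruent", "frequent")
  expect_equal(resolve_trial_parameters(base, v, same)$rel_input, 0.539)
  expect_equal(resolve_trial_parameters(base, v, opp)$rel_input, 0.502)

  # contingency: both inputs switch with the stimulus-location side
  v <- variant_spec("contingency",
                    contingency_rel_freqside = 0.533,
                    contingency_rel_infrside = 0.505,
                    contingency_irr_freqside = 0.298,
                    contingency_irr_infrside = 0.273)
  freqside <- trial_context("frequent", "congruent", "frequent")
  infrside <- trial_context("frequent", "incongruent", "frequent")
  expect_equal(resolve_trial_parameters(base, v, freqside)$irr_amplitude,
               0.298)
  expect_equal(resolve_trial_parameters(base, v, freqside)$rel_input, 0.533)
  expect_equal(resolve_trial_parameters(base, v, infrside)$irr_amplitude,
               0.273)

  # shielding: irrelevant input replaced only on prepared trials
  v <- variant_spec("shielding", shield_irr_amplitude = 0.15,
                    shield_irr_tau = 180)
  prep <- trial_context("frequent", "congruent", "frequent")
  unprep <- trial_context("frequent", "congruent", "infrequent")
  rp <- resolve_trial_parameters(base, v, prep)
  ru <- resolve_trial_parameters(base, v, unprep)
  expect_equal(rp$irr_amplitude, 0.15)
  expect_equal(rp$irr_tau, 180)
  expect_equal(ru$irr_amplitude, base$irr_amplitude)
  expect_equal(ru$irr_tau, base$irr_tau)
})
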