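# Shared fixtures for the test suite. Everything is generated in code.

# fast parameter set for unit tests that only need plumbing, not realism
quick_params <- function(...) {
  lca_params(noise_sd = 0.2, max_time = 2000, ...)
}

# random parameter sets in the model's operating range, used by the
# oracle-equivalence checks
random_param_grid <- function(n, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    lca_params(rel_input = runif(1, 0.5, 0.6),
               irr_amplitude = runif(1, 0, 0.4),
               irr_tau = runif(1, 60, 150),
               lead_mean = runif(1, 50, 150), lead_sd = 0,
               leak = runif(1, 0.005, 0.02),
               lateral = runif(1, 0.01, 0.03),
               noise_sd = 0,
               threshold = runif(1, 15, 30),
               prep_bias = runif(1, 0, 8),
               resid_mean = 100, resid_sd = 0))
}

# simulate all four frequency-by-congruency conditions and return their
# condition summaries keyed as in summarize_observed()
simulate_four_conditions <- function(params, variant, n,
                                     cueing = "none") {
  grid <- expand.grid(fc = c("frequent", "infrequent"),
                      cg = c("congruent", "incongruent"),
                      stringsAsFactors = FALSE)
  sims <- list()
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$fc[i], grid$cg[i], sep = "_")
    sims[[key]] <- simulate_condition(params, variant, grid$fc[i],
                                      grid$cg[i], n, cueing)
  }
  sims
}

# mean Simon effects (incongruent - congruent) per frequency class
simon_effects <- function(sims) {
  c(frequent = sims$frequent_incongruent$mean_rt -
      sims$frequent_congruent$mean_rt,
    infrequent = sims$infrequent_incongruent$mean_rt -
      sims$infrequent_congruent$mean_rt)
}

# build a single-participant trial table from raw per-condition RT vectors
trials_from_rts <- function(cond_rts, correct = NULL) {
  rows <- lapply(names(cond_rts), function(key) {
    parts <- strsplit(key, "_")[[1]]
    rts <- cond_rts[[key]]
    ok <- if (is.null(correct)) rep(TRUE, length(rts)) else correct[[key]]
    data.frame(participant = 1L, required_response = parts[1],
               congruency = parts[2], rt = rts, correct = ok,
               timed_out = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
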