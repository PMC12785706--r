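test_that("preset designs reproduce the published trial counts", {
  e1 <- expected_condition_counts(design_preset("exp1"))
  expect_equal(e1$total, 480)
  expect_equal(unname(e1$per_condition),
               c(180, 180, 60, 60))
  expect_equal(expected_condition_counts(design_preset("exp2"))$total, 640)
  expect_equal(expected_condition_counts(design_preset("exp3"))$total, 384)
  # symmetric control: 50/50 responses over 100 trials -> 25 per condition
  d <- design_spec("even", 10, 10, p_frequent_response = 0.5)
  expect_equal(unname(expected_condition_counts(d)$per_condition),
               rep(25, 4))
})

test_that("location-congruency contingencies follow from the response frequencies", {
  ct <- contingency_table(design_preset("exp1"))
  expect_equal(unname(ct$joint["frequent", "frequent_side"]), 0.375)
  expect_equal(unname(ct$joint["infrequent", "frequent_side"]), 0.125)
  expect_equal(sum(ct$joint), 1)
  expect_equal(unname(ct$p_congruent_given_location["frequent_side"]), 0.75)
  expect_equal(unname(ct$p_congruent_given_location["infrequent_side"]),
               0.25)
  # no contingency under equal response frequencies
  ct50 <- contingency_table(design_spec("even", 1, 8,
                                        p_frequent_response = 0.5))
  expect_equal(unname(ct50$p_congruent_given_location), c(0.5, 0.5))
  expect_true(all(ct50$joint == 0.25))
  # 90/10 responses concentrate congruent trials on the frequent side
  ct90 <- contingency_table(design_spec("steep", 1, 20,
                                        p_frequent_response = 0.9))
  expect_equal(unname(ct90$p_congruent_given_location["frequent_side"]),
               0.45 / (0.45 + 0.05))
})

test_that("trial tables realize the design exactly and reproducibly", {
  d <- design_preset("exp1")
  set.seed(3)
  tab <- build_trial_table(d)
  expect_equal(nrow(tab), 480 * d$n_participants)
  counts <- table(tab$required_response, tab$congruency) / d$n_participants
  expect_equal(unname(counts["frequent", "congruent"]), 180)
  expect_equal(unname(counts["infrequent", "incongruent"]), 60)
  # balanced within every block: 18/18/6/6 of 48
  blk <- tab[tab$participant == 1 & tab$block == 1, ]
  expect_equal(unname(table(blk$required_response, blk$congruency)["frequent", "congruent"]), 18)
  expect_equal(unname(table(blk$required_response, blk$congruency)["infrequent", "congruent"]), 6)
  # congruent stimuli sit on the required response's side
  expect_true(all(tab$stimulus_side[tab$congruency == "congruent"] ==
                    tab$required_response[tab$congruency == "congruent"]))
  set.seed(3)
  expect_identical(tab, build_trial_table(d))

  # always-valid cueing stamps every trial with its required response
  set.seed(4)
  t3 <- build_trial_table(design_preset("exp3"))
  expect_true(all(t3$cue == t3$required_response))
  expect_true(all(is.na(tab$cue)))

  # indivisible per-block counts fall back to multinomial assignment
  odd <- design_spec("odd", 2, 10, n_participants = 2)
  set.seed(5)
  expect_warning(build_trial_table(odd), "multinomial")
})

test_that("synthetic datasets carry their ground truth and variability", {
  d <- design_spec("mini", n_test_blocks = 2, trials_per_block = 48,
                   n_participants = 4)
  p <- quick_params()
  v <- variant_spec("preparation", pi_freq = 1)
  dat <- generate_synthetic_dataset(d, p, v, participant_spec(0, 0),
                                    seed = 9)
  gt <- attr(dat, "ground_truth")
  expect_identical(gt$params, p)
  expect_equal(gt$scale, rep(1, 4))
  expect_equal(gt$shift, rep(0, 4))
  # pi = 1: every frequent-response trial is prepared
  freq <- dat[dat$required_response == "frequent", ]
  expect_true(all(freq$expected_response == "frequent"))
  # reproducible end to end
  dat2 <- generate_synthetic_dataset(d, p, v, participant_spec(0, 0),
                                     seed = 9)
  expect_equal(dat$rt, dat2$rt)
  # participant transforms actually move the reaction times
  dat3 <- generate_synthetic_dataset(d, p, v,
                                     participant_spec(0.2, 50), seed = 9)
  gt3 <- attr(dat3, "ground_truth")
  expect_false(all(gt3$scale == 1))
  m <- tapply(dat3$rt, dat3$participant, mean, na.rm = TRUE)
  expect_gt(max(m) - min(m), 10)
})
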