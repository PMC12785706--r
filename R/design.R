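#' Experimental design specification
#'
#' Encodes one of the response-frequency Simon experiments: block structure,
#' the 75/25 response-frequency manipulation (with all four stimulus colors
#' — and hence stimulus locations — equally frequent), optional always-valid
#' response cueing, and the outlier-screening rules applied downstream.
#'
#' @param name Label for the design.
#' @param n_test_blocks Test blocks per session.
#' @param trials_per_block Trials per test block.
#' @param n_sessions Number of sessions.
#' @param p_frequent_response Probability that a trial requires the
#'   frequent response (default 0.75).
#' @param p_congruent_within_response Probability of a congruent stimulus
#'   location given the required response (default 0.5).
#' @param cueing `"none"` or `"always-valid"`.
#' @param n_participants Number of participants.
#' @param rt_floor_ms Outlier floor in ms.
#' @param rt_ceiling_sd Outlier ceiling multiplier (mean + this many SD).
#' @return An object of class `"design_spec"`.
#' @examples
#' design_preset("exp1")
#' @export
design_spec <- function(name, n_test_blocks, trials_per_block,
                        n_sessions = 1,
                        p_frequent_response = 0.75,
                        p_congruent_within_response = 0.5,
                        cueing = c("none", "always-valid"),
                        n_participants = 16,
                        rt_floor_ms = 100, rt_ceiling_sd = 3) {
  cueing <- match.arg(cueing)
  stopifnot(n_test_blocks >= 1, trials_per_block >= 1, n_sessions >= 1,
            p_frequent_response >= 0, p_frequent_response <= 1,
            p_congruent_within_response >= 0,
            p_congruent_within_response <= 1,
            n_participants >= 1)
  d <- list(name = name, n_test_blocks = n_test_blocks,
            trials_per_block = trials_per_block, n_sessions = n_sessions,
            p_frequent_response = p_frequent_response,
            p_congruent_within_response = p_congruent_within_response,
            cueing = cueing, n_participants = n_participants,
            rt_floor_ms = rt_floor_ms, rt_ceiling_sd = rt_ceiling_sd)
  class(d) <- "design_spec"
  d
}

#' Built-in design presets
#'
#' `"exp1"`: 10 test blocks of 48 trials, 16 participants, no cues (480
#' analyzed trials per participant). `"exp2"`: 2 sessions of 10 blocks of
#' 32 trials, 16 participants (640 trials). `"exp3"`: 8 blocks of 48 trials
#' with always-valid response cues, 24 participants (384 trials). All use
#' 75/25 relative response frequencies with equally frequent stimulus
#' locations.
#'
#' @param name `"exp1"`, `"exp2"` or `"exp3"`.
#' @return A [design_spec()] object.
#' @export
design_preset <- function(name = c("exp1", "exp2", "exp3")) {
  name <- match.arg(name)
  switch(name,
    exp1 = design_spec("exp1", n_test_blocks = 10, trials_per_block = 48,
                       n_sessions = 1, n_participants = 16),
    exp2 = design_spec("exp2", n_test_blocks = 10, trials_per_block = 32,
                       n_sessions = 2, n_participants = 16),
    exp3 = design_spec("exp3", n_test_blocks = 8, trials_per_block = 48,
                       n_sessions = 1, cueing = "always-valid",
                       n_participants = 24))
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %s: %d session(s) x %d blocks x %d trials (%d analyzed/participant), %d participants, cueing %s\n",
              x$name, x$n_sessions, x$n_test_blocks, x$trials_per_block,
              x$n_sessions * x$n_test_blocks * x$trials_per_block,
              x$n_participants, x$cueing))
  invisible(x)
}

#' Expected per-condition trial counts
#'
#' Total analyzed trials per participant and their split over the four
#' frequency-by-congruency conditions: each frequency class contributes
#' `total * p(class)`, divided evenly between congruent and incongruent.
#'
#' @param design A [design_spec()] object.
#' @return A list with `total` and a named numeric vector `per_condition`
#'   (`frequent_congruent`, `frequent_incongruent`, `infrequent_congruent`,
#'   `infrequent_incongruent`).
#' @examples
#' expected_condition_counts(design_preset("exp1"))$per_condition
#' @export
expected_condition_counts <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  total <- design$n_sessions * design$n_test_blocks * design$trials_per_block
  pf <- design$p_frequent_response
  per <- c(frequent_congruent = total * pf / 2,
           frequent_incongruent = total * pf / 2,
           infrequent_congruent = total * (1 - pf) / 2,
           infrequent_incongruent = total * (1 - pf) / 2)
  list(total = total, per_condition = per)
}

#' Location-congruency contingency table
#'
#' With unequal response frequencies but equally likely congruent and
#' incongruent stimuli within each response, the two task-irrelevant
#' stimulus locations carry different proportions of congruent trials: the
#' frequent-response side is mostly congruent, the infrequent-response side
#' mostly incongruent.
#'
#' @param design A [design_spec()] object.
#' @return A list with `joint` (a 2x2 matrix of joint proportions,
#'   rows = response class, columns = stimulus-location side) and
#'   `p_congruent_given_location` (named by location side).
#' @examples
#' contingency_table(design_preset("exp1"))$p_congruent_given_location
#' @export
contingency_table <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  pf <- design$p_frequent_response
  pc <- design$p_congruent_within_response
  # joint cells: frequent-congruent stimuli fall on the frequent side,
  # frequent-incongruent on the infrequent side, and vice versa
  joint <- matrix(c(pf * pc,        pf * (1 - pc),
                    (1 - pf) * (1 - pc), (1 - pf) * pc),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(response = c("frequent", "infrequent"),
                                  location = c("frequent_side",
                                               "infrequent_side")))
  p_loc <- colSums(joint)
  # congruent trials at the frequent side come from frequent responses;
  # at the infrequent side from infrequent responses
  p_cong <- c(frequent_side = joint["frequent", "frequent_side"] /
                p_loc["frequent_side"],
              infrequent_side = joint["infrequent", "infrequent_side"] /
                p_loc["infrequent_side"])
  list(joint = joint, p_congruent_given_location = unname2(p_cong))
}

unname2 <- function(x) {
  names(x) <- sub("\\..*$", "", names(x))
  x
}

#' Build a randomized trial table for a design
#'
#' Realizes the design's condition frequencies per participant. Where the
#' per-block condition counts divide evenly (as in all three presets),
#' conditions are balanced exactly within each block and the order is
#' shuffled; otherwise trials are assigned by sequential multinomial
#' sampling and a warning is issued. With always-valid cueing every trial
#' carries a cue equal to its required response.
#'
#' @param design A [design_spec()] object.
#' @return A data frame with columns `participant`, `session`, `block`,
#'   `trial`, `required_response`, `congruency`, `stimulus_side`, `cue`.
#' @examples
#' set.seed(1)
#' tab <- build_trial_table(design_preset("exp1"))
#' nrow(tab) / 16
#' @export
build_trial_table <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  pf <- design$p_frequent_response
  pc <- design$p_congruent_within_response
  tpb <- design$trials_per_block
  probs <- c(frequent_congruent = pf * pc,
             frequent_incongruent = pf * (1 - pc),
             infrequent_congruent = (1 - pf) * pc,
             infrequent_incongruent = (1 - pf) * (1 - pc))
  counts <- probs * tpb
  balanced <- all(abs(counts - round(counts)) < 1e-9)
  if (!balanced)
    warning("trials_per_block (", tpb,
            ") does not divide the condition proportions evenly; ",
            "using multinomial assignment per block")
  one_block <- function() {
    cond <- if (balanced) {
      sample(rep(names(probs), times = round(counts)))
    } else {
      sample(names(probs), tpb, replace = TRUE, prob = probs)
    }
    req <- ifelse(startsWith(cond, "frequent"), "frequent", "infrequent")
    cong <- ifelse(endsWith(cond, "_congruent"), "congruent", "incongruent")
    data.frame(required_response = req, congruency = cong,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  idx <- 1L
  for (p in seq_len(design$n_participants)) {
    for (s in seq_len(design$n_sessions)) {
      for (b in seq_len(design$n_test_blocks)) {
        blk <- one_block()
        blk$participant <- p
        blk$session <- s
        blk$block <- b
        blk$trial <- seq_len(nrow(blk))
        rows[[idx]] <- blk
        idx <- idx + 1L
      }
    }
  }
  tab <- do.call(rbind, rows)
  other <- ifelse(tab$required_response == "frequent", "infrequent",
                  "frequent")
  tab$stimulus_side <- ifelse(tab$congruency == "congruent",
                              tab$required_response, other)
  tab$cue <- if (design$cueing == "always-valid") tab$required_response
             else NA_character_
  tab[, c("participant", "session", "block", "trial", "required_response",
          "congruency", "stimulus_side", "cue")]
}

#' Inter-participant variability specification
#'
#' Multiplicative reaction-time scale factors and additive shifts giving a
#' synthetic multi-participant dataset the location/scale heterogeneity
#' that the pooling stage is designed to undo. Scale factors are lognormal
#' with log-SD `scale_log_sd` (median 1); shifts are normal with SD
#' `shift_sd_ms`.
#'
#' @param scale_log_sd SD of the log scale factor (default 0.08, about
#'   8 percent between-participant RT-scale variability).
#' @param shift_sd_ms SD of the additive shift in ms (default 20).
#' @return An object of class `"participant_spec"`.
#' @export
participant_spec <- function(scale_log_sd = 0.08, shift_sd_ms = 20) {
  stopifnot(scale_log_sd >= 0, shift_sd_ms >= 0)
  p <- list(scale_log_sd = scale_log_sd, shift_sd_ms = shift_sd_ms)
  class(p) <- "participant_spec"
  p
}

#' Generate a synthetic multi-participant dataset from the model
#'
#' Builds the design's trial table, draws each trial's expectation state
#' from the variant's preparation probabilities, simulates every trial with
#' the accumulator model, and applies per-participant linear RT
#' transformations (`rt * scale + shift`). The generating parameters are
#' attached as attribute `"ground_truth"` for parameter-recovery studies.
#'
#' @param design A [design_spec()] object.
#' @param params An [lca_params()] object (base parameters).
#' @param variant An [variant_spec()] object.
#' @param participants A [participant_spec()] object.
#' @param seed Optional master seed (integer); if supplied, `set.seed` is
#'   called first so the dataset is fully reproducible.
#' @return A data frame: the trial table plus `expected_response`, `rt`
#'   (ms, participant-transformed), `correct`, `timed_out`. Attribute
#'   `"ground_truth"` holds `params`, `variant`, `participants`, `design`,
#'   `seed` and the realized per-participant `scale`/`shift`.
#' @examples
#' dat <- generate_synthetic_dataset(design_preset("exp1"), lca_params(),
#'                                   variant_spec("preparation"),
#'                                   participant_spec(0, 0), seed = 1)
#' table(dat$required_response, dat$congruency) / 16
#' @export
generate_synthetic_dataset <- function(design, params, variant,
                                       participants = participant_spec(),
                                       seed = NULL) {
  stopifnot(inherits(design, "design_spec"),
            inherits(params, "lca_params"),
            inherits(variant, "lca_variant"),
            inherits(participants, "participant_spec"))
  if (!is.null(seed)) set.seed(seed)
  tab <- build_trial_table(design)
  tab$expected_response <- draw_expectation(variant, tab$required_response,
                                            design$cueing)
  tab <- simulate_trials(params, variant, tab)
  np <- design$n_participants
  scale <- exp(stats::rnorm(np, 0, participants$scale_log_sd))
  shift <- stats::rnorm(np, 0, participants$shift_sd_ms)
  tab$rt <- tab$rt * scale[tab$participant] + shift[tab$participant]
  attr(tab, "ground_truth") <- list(params = params, variant = variant,
                                    participants = participants,
                                    design = design, seed = seed,
                                    scale = scale, shift = shift)
  tab
}
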