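#' Read a run configuration file
#'
#' Runs are configured by a YAML file with nested sections (`design`,
#' `params`, `variant`, `participants`, `fit`, and a mandatory top-level
#' `seed`). Unknown top-level keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A list of class `"run_config"` with fully constructed objects:
#'   `seed`, and (where the corresponding section is present) `design`
#'   ([design_spec()] or a preset name), `params` ([lca_params()]),
#'   `variant` ([variant_spec()]), `participants` ([participant_spec()]),
#'   `fit` ([fit_control()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "design", "params", "variant", "participants", "fit",
             "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$seed)) stop("configuration must set a master 'seed'")
  cfg <- list(seed = as.integer(raw$seed), output_dir = raw$output_dir)
  if (!is.null(raw$design)) {
    cfg$design <- if (is.character(raw$design)) design_preset(raw$design)
                  else do.call(design_spec, raw$design)
  }
  if (!is.null(raw$params)) cfg$params <- do.call(lca_params, raw$params)
  if (!is.null(raw$variant)) {
    v <- raw$variant
    if (!is.null(v$free)) v$free <- as.character(unlist(v$free))
    cfg$variant <- do.call(variant_spec, v)
  }
  if (!is.null(raw$participants))
    cfg$participants <- do.call(participant_spec, raw$participants)
  if (!is.null(raw$fit)) cfg$fit <- do.call(fit_control, raw$fit)
  class(cfg) <- "run_config"
  cfg
}

#' Write a provenance record for an output directory
#'
#' Every analysis output directory gets a `provenance.yaml` naming the
#' package version, the master seed, and the resolved parameter ledger, so
#' the directory can be regenerated bit-identically.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed used for the run.
#' @param ... Further named items (parameter sets, variant specs, design
#'   names) to record; objects are flattened to plain lists.
#' @return The path to the written file, invisibly.
#' @export
write_provenance <- function(dir, seed, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  items <- lapply(list(...), function(x) {
    if (is.list(x)) lapply(unclass(x), function(el)
      if (is.null(el)) NULL else unname(el)) else x
  })
  rec <- c(list(package = "simonlca",
                version = as.character(utils::packageVersion("simonlca")),
                r_version = as.character(getRversion()),
                seed = seed),
           items)
  path <- file.path(dir, "provenance.yaml")
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Export a simulated trial table as CSV
#'
#' Writes the standard trial schema: `participant`, `session`, `block`,
#' `trial`, `required_response` (as `frequency_class`), `congruency`,
#' `expected_response`, `rt_ms`, `correct`.
#'
#' @param trials A trial table from [generate_synthetic_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trials_csv <- function(trials, path) {
  out <- data.frame(participant = trials$participant,
                    session = trials$session,
                    block = trials$block,
                    trial = trials$trial,
                    frequency_class = trials$required_response,
                    congruency = trials$congruency,
                    expected_response = trials$expected_response,
                    rt_ms = trials$rt,
                    correct = trials$correct)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table CSV written by [export_trials_csv()]
#'
#' @param path CSV path.
#' @return A trial table data frame with the column names the analysis
#'   functions expect.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "frequency_class"] <- "required_response"
  names(d)[names(d) == "rt_ms"] <- "rt"
  d$timed_out <- is.na(d$rt)
  d
}
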