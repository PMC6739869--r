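#' Default run configuration
#'
#' All defaults reproduce the standard protocol constants: 25 trials, 8-s
#' CS, VT-90 s schedule on 30-150 s, classification thresholds of 0.30
#' (sessions 4-5) or 0.20 (session 3), censored latencies at the CS
#' duration, baseline-mean percent-change normalization with a 6/5/7
#' fraction schedule, and two-sided tests at alpha 0.05.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- default_config(regime = "exp2")
#' cfg$regime
#' @export
default_config <- function(...) {
  cfg <- list(
    trial_config = trial_config(),
    regime = "exp1",
    n_perm = 999,
    alpha = 0.05,
    seed = 1,
    exclude_phenotype_change = FALSE,
    dialysis_min_baseline = 4,
    dialysis_min_session = 5,
    crt_duration_s = 2400,
    crt_presentation_s = 2,
    arms = c("VEH", "CNO"),
    cohort = list(n_per_cell = 6,
                  sessions_acquisition = 1:5,
                  sessions_rescreen = 6:10,
                  sessions_test = 11:16,
                  treat_shift = 0)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Read and validate an event-log table
#'
#' The interchange format is a delimited UTF-8 table with a header row and
#' columns `rat_id`, `phase`, `session`, `trial`, `event_type`, `time_s`
#' (seconds from session start). Validation reports offending row numbers:
#' unknown event types, negative times, and — for PavCA phases — trials
#' lacking exactly one `cs_on`/`cs_off` pair or with `cs_off` at or before
#' `cs_on`.
#'
#' @param path Path to a CSV file.
#' @return A validated event-log tibble.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_event_log(raw)
}

#' @rdname read_event_log
#' @param events An event-log tibble to validate in memory.
#' @export
validate_event_log <- function(events) {
  assert_cols(events, c("rat_id", "phase", "session", "trial", "event_type",
                        "time_s"), "event log")
  bad_type <- which(!events$event_type %in% EVENT_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown event_type at row(s): ",
         paste(head(bad_type, 5), collapse = ", "), call. = FALSE)
  }
  bad_time <- which(events$time_s < 0)
  if (length(bad_time) > 0) {
    stop("negative time_s at row(s): ",
         paste(head(bad_time, 5), collapse = ", "), call. = FALSE)
  }
  pav <- filter(events, .data$phase %in%
                  c("pretrain", "acquisition", "rescreen", "test"))
  if (nrow(pav) > 0) {
    cs_counts <- pav %>%
      filter(.data$event_type %in% c("cs_on", "cs_off")) %>%
      count(.data$rat_id, .data$session, .data$trial, .data$event_type)
    bad <- cs_counts %>% filter(.data$n != 1)
    trials <- distinct(pav, .data$rat_id, .data$session, .data$trial)
    have_both <- cs_counts %>%
      count(.data$rat_id, .data$session, .data$trial) %>%
      filter(.data$n == 2)
    missing <- nrow(trials) - nrow(have_both)
    if (nrow(bad) > 0 || missing > 0) {
      ex <- if (nrow(bad) > 0) bad else
        dplyr::anti_join(trials, have_both,
                         by = c("rat_id", "session", "trial"))
      stop(sprintf(
        "each PavCA trial needs exactly one cs_on and one cs_off (first offender: rat %s session %s trial %s)",
        ex$rat_id[1], ex$session[1], ex$trial[1]), call. = FALSE)
    }
    cs <- pav %>%
      filter(.data$event_type %in% c("cs_on", "cs_off")) %>%
      tidyr::pivot_wider(id_cols = c("rat_id", "session", "trial"),
                         names_from = "event_type", values_from = "time_s")
    rev_cs <- filter(cs, .data$cs_off <= .data$cs_on)
    if (nrow(rev_cs) > 0) {
      stop(sprintf("cs_off at or before cs_on (rat %s session %s trial %s)",
                   rev_cs$rat_id[1], rev_cs$session[1], rev_cs$trial[1]),
           call. = FALSE)
    }
  }
  events
}

#' Write an event-log table
#'
#' @param events Event-log tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read a microdialysis fraction table
#'
#' Delimited table with columns `rat_id`, `analyte`, `fraction`, `phase`
#' (`baseline`/`pre`/`session`), `conc_nM`, plus any metadata columns (e.g.
#' `treatment`). A `col_map` renames externally-named columns onto this
#' schema, which is how deposited per-rat tables with other headers are
#' ingested.
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping `schema_name = "file_name"`.
#' @return A validated fraction tibble.
#' @export
read_fraction_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  assert_cols(raw, c("rat_id", "analyte", "fraction", "phase", "conc_nM"),
              "fraction table")
  bad <- which(!raw$phase %in% c("baseline", "pre", "session"))
  if (length(bad) > 0) {
    stop("unknown phase at row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  raw
}

#' Classify a vector of mean PavCA indices
#'
#' Thresshold-only variant of [classify()] for pre-averaged per-rat index
#' tables (the format of deposited per-rat score tables): inclusive cutoffs,
#' `ST` at or above `threshold`, `GT` at or below `-threshold`, `IN`
#' between.
#'
#' @param mean_index Numeric vector of per-rat mean indices.
#' @param threshold Positive cutoff (0.30 or 0.20 in the standard regimes).
#' @return Character vector of calls.
#' @examples
#' table(classify_mean_index(c(-0.5, -0.2, 0.1, 0.35), 0.30))
#' @export
classify_mean_index <- function(mean_index, threshold) {
  stopifnot(threshold > 0)
  ifelse(mean_index >= threshold, "ST",
         ifelse(mean_index <= -threshold, "GT", "IN"))
}

#' Expected session duration under a variable-time schedule
#'
#' Closed form for the expected duration of a session of `n_trials` trials
#' whose inter-event times average `iti_mean_s` seconds, plus any fixed
#' per-trial CS time. The pre-training schedule (25 pellet deliveries on a
#' VT-30 s schedule, no CS) gives 25 x 30 s = 12.5 min.
#'
#' @param n_trials Trials per session.
#' @param iti_mean_s Mean inter-trial time (seconds).
#' @param cs_duration_s Fixed CS time per trial (seconds); 0 for
#'   pre-training.
#' @return Expected duration in minutes.
#' @examples
#' expected_session_minutes(25, 30)      # 12.5 (pre-training)
#' expected_session_minutes(25, 90, 8)   # about 40.8 (PavCA training)
#' @export
expected_session_minutes <- function(n_trials, iti_mean_s,
                                     cs_duration_s = 0) {
  stopifnot(n_trials >= 1, iti_mean_s >= 0, cs_duration_s >= 0)
  n_trials * (iti_mean_s + cs_duration_s) / 60
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate (optional) -> session scoring -> PavCA index ->
#' classification -> counterbalanced assignment -> CRT scoring -> dialysis
#' normalization -> interaction inference, writing every stage's table plus
#' a JSON manifest (configuration, seed, stage list, exclusion counts) to
#' `output_dir`. With `input_dir = NULL` the cohort is simulated from
#' `config$cohort`; otherwise `events.csv` (and optionally `crt_events.csv`,
#' `fractions.csv`) are read from `input_dir`.
#'
#' @param config A [default_config()].
#' @param input_dir Directory of input tables, or `NULL` to simulate.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, a list with every stage's output and the manifest.
#' @export
run_pipeline <- function(config = default_config(), input_dir = NULL,
                         output_dir = tempfile("pavca_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  exclusions <- list()
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  truth <- NULL
  if (is.null(input_dir)) {
    cohort <- step("simulate", {
      des <- do.call(cohort_design,
                     c(config$cohort,
                       list(seed = config$seed,
                            trial_config = config$trial_config,
                            treatments = config$arms)))
      simulate_cohort(des)
    })
    events <- cohort$events
    truth <- cohort$truth
    write_event_log(events, file.path(output_dir, "events.csv"))
    write.csv(truth, file.path(output_dir, "ground_truth.csv"),
              row.names = FALSE)
  } else {
    events <- step("read", read_event_log(file.path(input_dir,
                                                    "events.csv")))
  }

  summaries <- step("score-sessions", summarize_sessions(
    filter(events, .data$phase != "crt")))
  scores <- step("pavca-index",
                 pavca_index(summaries, config$trial_config$cs_duration_s))

  reg <- classification_regime(config$regime)
  acq_scores <- filter(scores, .data$phase %in% c("acquisition", "rescreen"))
  calls <- step("classify", classify(
    select(acq_scores, "rat_id", "session", "index"), config$regime))
  n_in <- sum(calls$excluded)
  exclusions$intermediate_band <- n_in

  if (isTRUE(config$exclude_phenotype_change) &&
      all(c("acquisition", "rescreen") %in% scores$phase)) {
    resc <- scores %>% filter(.data$phase == "rescreen") %>%
      group_by(.data$rat_id) %>%
      summarise(mean_index = mean(.data$index), .groups = "drop") %>%
      mutate(call = classify_mean_index(.data$mean_index, reg$threshold))
    audit <- phenotype_change_audit(calls, resc)
    changed <- audit$rat_id[audit$changed]
    exclusions$phenotype_change <- length(changed)
    calls <- filter(calls, !.data$rat_id %in% changed)
  }

  assignment <- step("assign",
                     assign_groups(calls, config$arms, seed = config$seed))

  crt_path <- if (!is.null(input_dir))
    file.path(input_dir, "crt_events.csv") else NULL
  crt_summary <- NULL
  if (!is.null(crt_path) && file.exists(crt_path)) {
    crt_events <- read_event_log(crt_path)
    crt_summary <- step("score-crt", {
      bind_rows(lapply(split(crt_events, crt_events$rat_id), summarize_crt,
                       duration_s = config$crt_duration_s,
                       presentation_s = config$crt_presentation_s))
    })
    write.csv(crt_summary, file.path(output_dir, "crt_summary.csv"),
              row.names = FALSE)
  }

  frac_path <- if (!is.null(input_dir))
    file.path(input_dir, "fractions.csv") else NULL
  dialysis <- NULL
  if (!is.null(frac_path) && file.exists(frac_path)) {
    fr <- read_fraction_table(frac_path)
    dialysis <- step("dialysis", normalize_dialysis(
      fr, config$dialysis_min_baseline, config$dialysis_min_session))
    exclusions$dialysis_incomplete <- nrow(dialysis$excluded)
    write.csv(dialysis$summary, file.path(output_dir,
                                          "dialysis_summary.csv"),
              row.names = FALSE)
  }

  inference <- NULL
  if (all(c("rescreen", "test") %in% scores$phase) && !is.null(truth)) {
    inference <- step("analyze", {
      arms_tbl <- distinct(truth, .data$rat_id, .data$treatment)
      long <- scores %>%
        filter(.data$phase %in% c("rescreen", "test")) %>%
        group_by(.data$rat_id, block = .data$phase) %>%
        summarise(value = mean(.data$index), .groups = "drop") %>%
        left_join(arms_tbl, by = "rat_id") %>%
        select("rat_id", "block", "treatment", "value")
      write.csv(long, file.path(output_dir, "long_table.csv"),
                row.names = FALSE)  # export hook for external model fitting
      interaction_permutation_test(long, n_perm = config$n_perm,
                                   seed = config$seed, arms = config$arms,
                                   blocks = c("rescreen", "test"))
    })
  }

  write.csv(summaries, file.path(output_dir, "session_summaries.csv"),
            row.names = FALSE)
  write.csv(scores, file.path(output_dir, "pavca_scores.csv"),
            row.names = FALSE)
  write.csv(calls, file.path(output_dir, "phenotype_calls.csv"),
            row.names = FALSE)
  write.csv(assignment, file.path(output_dir, "assignment.csv"),
            row.names = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pavca")),
    seed = config$seed,
    config_hash = sprintf("%x", stable_hash(as.character(cfg_json))),
    stages = stages,
    exclusions = exclusions,
    n_rats = dplyr::n_distinct(events$rat_id)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(events = events, truth = truth, summaries = summaries,
                 scores = scores, calls = calls, assignment = assignment,
                 crt_summary = crt_summary, dialysis = dialysis,
                 inference = inference, manifest = manifest,
                 output_dir = output_dir))
}
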