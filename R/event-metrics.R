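#' Latency to the first target event within a trial
#'
#' Returns the time from CS onset to the first lever contact (or magazine
#' entry) of the trial. Trials with no target event are censored at the full
#' CS duration, the convention that lets the latency-difference component of
#' the PavCA index reach its \eqn{\pm 1} extremes.
#'
#' @param trial Event-log rows for a single trial, including its `cs_on` and
#'   `cs_off` rows.
#' @param target `"lever"` or `"magazine"`.
#' @return Latency in seconds, in `[0, cs_duration]`.
#' @examples
#' tr <- tibble::tibble(rat_id = "r1", phase = "acquisition", session = 1L,
#'   trial = 1L, event_type = c("cs_on", "lever_contact", "cs_off", "pellet"),
#'   time_s = c(10, 11.2, 18, 19))
#' trial_latency(tr, "lever")    # 1.2
#' trial_latency(tr, "magazine") # 8 (censored)
#' @export
trial_latency <- function(trial, target = c("lever", "magazine")) {
  target <- match.arg(target)
  assert_cols(trial, c("event_type", "time_s"), "trial")
  cs_on <- trial$time_s[trial$event_type == "cs_on"]
  cs_off <- trial$time_s[trial$event_type == "cs_off"]
  if (length(cs_on) != 1 || length(cs_off) != 1) {
    stop("trial must contain exactly one cs_on and one cs_off", call. = FALSE)
  }
  cs_dur <- cs_off - cs_on
  type <- if (target == "lever") "lever_contact" else "mag_entry"
  t_ev <- trial$time_s[trial$event_type == type &
                         trial$time_s >= cs_on & trial$time_s < cs_off]
  if (length(t_ev) == 0) cs_dur else min(t_ev) - cs_on
}

#' Summarize an event log into per-session PavCA measures
#'
#' Computes, for every rat-by-session in the log, the six session measures of
#' Pavlovian conditioned approach — lever contacts, CS-period magazine
#' entries, the probability of contacting the lever (or entering the
#' magazine) on a trial, and mean latencies to each target — plus the count
#' of magazine entries during the intertrial interval, which indexes general
#' locomotor activity. Probabilities are trial fractions (a trial counts once
#' no matter how many contacts it holds); latencies average per-trial first
#' latencies, with responseless trials contributing the full CS duration.
#' The CS window is half-open `[cs_on, cs_off)`: a magazine entry at exactly
#' CS offset belongs to the ITI, and `pellet` events are never counted as
#' magazine entries.
#'
#' @param events Event-log tibble (see [read_event_log()] for the schema),
#'   restricted to PavCA phases.
#' @return A tibble with one row per rat-session: `rat_id`, `phase`,
#'   `session`, `lever_contacts`, `mag_entries_cs`, `prob_lever`, `prob_mag`,
#'   `lat_lever_s`, `lat_mag_s`, `iti_mag_entries`, `n_trials`.
#' @examples
#' set.seed(1)
#' log <- simulate_pavca_session(make_agent("ST", 1), session = 1)
#' summarize_sessions(log)
#' @export
summarize_sessions <- function(events) {
  assert_cols(events, c("rat_id", "phase", "session", "trial", "event_type",
                        "time_s"), "event log")
  if (nrow(events) == 0) stop("empty event log", call. = FALSE)

  cs <- events %>%
    filter(.data$event_type %in% c("cs_on", "cs_off")) %>%
    tidyr::pivot_wider(id_cols = c("rat_id", "phase", "session", "trial"),
                       names_from = "event_type", values_from = "time_s")
  if (anyNA(cs$cs_on) || anyNA(cs$cs_off)) {
    stop("every trial needs exactly one cs_on and one cs_off", call. = FALSE)
  }

  resp <- events %>%
    filter(.data$event_type %in% c("lever_contact", "mag_entry")) %>%
    left_join(cs, by = c("rat_id", "phase", "session", "trial")) %>%
    mutate(in_cs = .data$time_s >= .data$cs_on & .data$time_s < .data$cs_off)

  per_trial <- resp %>%
    group_by(.data$rat_id, .data$phase, .data$session, .data$trial) %>%
    summarise(
      n_lever = sum(.data$event_type == "lever_contact" & .data$in_cs),
      n_mag_cs = sum(.data$event_type == "mag_entry" & .data$in_cs),
      n_mag_iti = sum(.data$event_type == "mag_entry" & !.data$in_cs),
      lat_lever = if (any(.data$event_type == "lever_contact" & .data$in_cs))
        min(.data$time_s[.data$event_type == "lever_contact" &
                           .data$in_cs]) - .data$cs_on[1] else NA_real_,
      lat_mag = if (any(.data$event_type == "mag_entry" & .data$in_cs))
        min(.data$time_s[.data$event_type == "mag_entry" &
                           .data$in_cs]) - .data$cs_on[1] else NA_real_,
      .groups = "drop"
    )

  cs %>%
    left_join(per_trial, by = c("rat_id", "phase", "session", "trial")) %>%
    mutate(
      cs_dur = .data$cs_off - .data$cs_on,
      n_lever = ifelse(is.na(.data$n_lever), 0L, .data$n_lever),
      n_mag_cs = ifelse(is.na(.data$n_mag_cs), 0L, .data$n_mag_cs),
      n_mag_iti = ifelse(is.na(.data$n_mag_iti), 0L, .data$n_mag_iti),
      lat_lever = ifelse(is.na(.data$lat_lever), .data$cs_dur, .data$lat_lever),
      lat_mag = ifelse(is.na(.data$lat_mag), .data$cs_dur, .data$lat_mag)
    ) %>%
    group_by(.data$rat_id, .data$phase, .data$session) %>%
    summarise(
      lever_contacts = sum(.data$n_lever),
      mag_entries_cs = sum(.data$n_mag_cs),
      prob_lever = mean(.data$n_lever > 0),
      prob_mag = mean(.data$n_mag_cs > 0),
      lat_lever_s = mean(.data$lat_lever),
      lat_mag_s = mean(.data$lat_mag),
      iti_mag_entries = sum(.data$n_mag_iti),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Summarize a single rat-session
#'
#' Strict single-session variant of [summarize_sessions()]: rejects logs that
#' mix rats or sessions, and empty logs.
#'
#' @param events Event-log rows for one rat-session.
#' @return A one-row session-summary tibble.
#' @export
summarize_session <- function(events) {
  if (nrow(events) == 0) stop("empty event log", call. = FALSE)
  key <- distinct(events, .data$rat_id, .data$session)
  if (nrow(key) != 1) {
    stop("events mix rats or sessions; use summarize_sessions()",
         call. = FALSE)
  }
  summarize_sessions(events)
}

#' Mean ITI magazine entries over a phase window
#'
#' The per-rat mean of `iti_mag_entries` across the sessions of one phase;
#' used as a locomotor-activity index when comparing rescreen and test
#' blocks.
#'
#' @param summaries Session-summary tibble from [summarize_sessions()].
#' @param window Phase label (e.g. `"rescreen"`).
#' @return Tibble `rat_id`, `phase`, `mean_iti_entries`.
#' @examples
#' s <- tibble::tibble(rat_id = "r1", phase = "test", session = 1:2,
#'                     iti_mag_entries = c(10, 20))
#' iti_activity(s, "test")$mean_iti_entries  # 15
#' @export
iti_activity <- function(summaries, window) {
  assert_cols(summaries, c("rat_id", "phase", "iti_mag_entries"),
              "session summaries")
  sel <- filter(summaries, .data$phase == window)
  if (nrow(sel) == 0) stop("no sessions in window '", window, "'",
                           call. = FALSE)
  sel %>%
    group_by(.data$rat_id, .data$phase) %>%
    summarise(mean_iti_entries = mean(.data$iti_mag_entries),
              .groups = "drop")
}
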