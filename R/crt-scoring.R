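#' Incentive value index
#'
#' `(active_pokes + lever_contacts) - inactive_pokes`: the composite score
#' summarizing a conditioned reinforcement session. Positive values indicate
#' that the lever-CS both reinforces the new nosepoke response and attracts
#' interaction; the index can be negative when the inactive port dominates.
#'
#' @param active_pokes,inactive_pokes,lever_contacts Non-negative counts
#'   (vectorized).
#' @return Signed integer count.
#' @examples
#' incentive_value_index(30, 10, 20)  # 40
#' incentive_value_index(5, 25, 0)    # -20
#' @export
incentive_value_index <- function(active_pokes, inactive_pokes,
                                  lever_contacts) {
  if (any(active_pokes < 0) || any(inactive_pokes < 0) ||
      any(lever_contacts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  (active_pokes + lever_contacts) - inactive_pokes
}

#' Summarize a conditioned reinforcement (FR1) session
#'
#' Tallies active/inactive nosepokes and lever contacts from a CRT event log
#' and reconstructs lever presentations under the FR1 rule: an active poke
#' triggers a presentation of `presentation_s` seconds unless one is already
#' ongoing, in which case the poke is counted but does not retrigger the
#' lever. Consequently `presentations <= active_pokes`.
#'
#' @param events Event log for one rat's CRT session with event types
#'   `active_poke`, `inactive_poke`, `lever_contact`.
#' @param duration_s Session length (default 2400 s, a 40-min test); events
#'   beyond it are rejected.
#' @param presentation_s Lever presentation length in seconds.
#' @return One-row tibble: `rat_id`, `active_pokes`, `inactive_pokes`,
#'   `lever_contacts`, `presentations`, `incentive_value_index`.
#' @examples
#' ev <- tibble::tibble(rat_id = "r1", phase = "crt", session = 17L,
#'   trial = NA_integer_, event_type = c("active_poke", "active_poke"),
#'   time_s = c(10, 11))
#' summarize_crt(ev)  # 2 pokes, 1 presentation
#' @export
summarize_crt <- function(events, duration_s = 2400, presentation_s = 2) {
  assert_cols(events, c("rat_id", "event_type", "time_s"), "CRT event log")
  if (nrow(events) == 0) {
    return(tibble(rat_id = NA_character_, active_pokes = 0L,
                  inactive_pokes = 0L, lever_contacts = 0L,
                  presentations = 0L, incentive_value_index = 0L))
  }
  if (dplyr::n_distinct(events$rat_id) != 1) {
    stop("summarize_crt() expects a single rat's session", call. = FALSE)
  }
  if (any(events$time_s < 0 | events$time_s > duration_s)) {
    stop("events fall outside the session bounds [0, duration_s]",
         call. = FALSE)
  }
  events <- arrange(events, .data$time_s)
  active_t <- events$time_s[events$event_type == "active_poke"]
  pres <- 0L
  last_end <- -Inf
  for (t in active_t) {
    if (t >= last_end) {
      pres <- pres + 1L
      last_end <- t + presentation_s
    }
  }
  a <- length(active_t)
  i <- sum(events$event_type == "inactive_poke")
  l <- sum(events$event_type == "lever_contact")
  tibble(rat_id = events$rat_id[1], active_pokes = a, inactive_pokes = i,
         lever_contacts = l, presentations = pres,
         incentive_value_index = incentive_value_index(a, i, l))
}
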