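# Fixture builders and brute-force oracles, independent of the package's
# summarization path.

# A hand-rolled random event log: trials on a fixed grid, random lever and
# magazine events scattered in and out of the CS window.
random_event_log <- function(n_trials = 10, cs_dur = 8, seed = 1,
                             rat_id = "r1", session = 1L,
                             p_lever = 0.5, p_mag = 0.5, max_ev = 3) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_trials)) {
      cs_on <- 40 * i
      cs_off <- cs_on + cs_dur
      ev_t <- numeric(0); ev_y <- character(0)
      if (runif(1) < p_lever) {
        k <- sample(max_ev, 1)
        ev_t <- c(ev_t, cs_on + sort(runif(k, 0, cs_dur - 1e-3)))
        ev_y <- c(ev_y, rep("lever_contact", k))
      }
      if (runif(1) < p_mag) {
        k <- sample(max_ev, 1)
        ev_t <- c(ev_t, cs_on + sort(runif(k, 0, cs_dur - 1e-3)))
        ev_y <- c(ev_y, rep("mag_entry", k))
      }
      n_iti <- rpois(1, 1.5)
      if (n_iti > 0) {
        ev_t <- c(ev_t, sort(runif(n_iti, cs_on - 30, cs_on)))
        ev_y <- c(ev_y, rep("mag_entry", n_iti))
      }
      rows[[i]] <- tibble::tibble(
        rat_id = rat_id, phase = "acquisition", session = session,
        trial = i,
        event_type = c("cs_on", ev_y, "cs_off", "pellet"),
        time_s = c(cs_on, ev_t, cs_off, cs_off + 1)
      )
    }
    dplyr::bind_rows(rows)
  })
}

# Event-by-event recount of the six session measures using plain loops.
oracle_summary <- function(log) {
  trials <- sort(unique(log$trial))
  n_lever <- n_mag <- n_iti <- 0
  lever_hit <- mag_hit <- 0
  lat_l <- lat_m <- numeric(0)
  for (i in trials) {
    tr <- log[log$trial == i, ]
    on <- tr$time_s[tr$event_type == "cs_on"]
    off <- tr$time_s[tr$event_type == "cs_off"]
    cs_dur <- off - on
    lev <- tr$time_s[tr$event_type == "lever_contact" &
                       tr$time_s >= on & tr$time_s < off]
    mag_cs <- tr$time_s[tr$event_type == "mag_entry" &
                          tr$time_s >= on & tr$time_s < off]
    mag_iti <- tr$time_s[tr$event_type == "mag_entry" &
                           (tr$time_s < on | tr$time_s >= off)]
    n_lever <- n_lever + length(lev)
    n_mag <- n_mag + length(mag_cs)
    n_iti <- n_iti + length(mag_iti)
    lever_hit <- lever_hit + (length(lev) > 0)
    mag_hit <- mag_hit + (length(mag_cs) > 0)
    lat_l <- c(lat_l, if (length(lev) > 0) min(lev) - on else cs_dur)
    lat_m <- c(lat_m, if (length(mag_cs) > 0) min(mag_cs) - on else cs_dur)
  }
  list(lever_contacts = n_lever, mag_entries_cs = n_mag,
       prob_lever = lever_hit / length(trials),
       prob_mag = mag_hit / length(trials),
       lat_lever_s = mean(lat_l), lat_mag_s = mean(lat_m),
       iti_mag_entries = n_iti, n_trials = length(trials))
}

# Degenerate one-sided log: an event on the given target at `lat` seconds
# into every CS window, nothing else.
degenerate_log <- function(target = c("lever", "magazine"), n_trials = 25,
                           lat = 0, cs_dur = 8) {
  target <- match.arg(target)
  type <- if (target == "lever") "lever_contact" else "mag_entry"
  rows <- lapply(seq_len(n_trials), function(i) {
    cs_on <- 100 * i
    tibble::tibble(
      rat_id = "r1", phase = "acquisition", session = 1L, trial = i,
      event_type = c("cs_on", type, "cs_off", "pellet"),
      time_s = c(cs_on, cs_on + lat, cs_on + cs_dur, cs_on + cs_dur + 1)
    )
  })
  dplyr::bind_rows(rows)
}

# Mirror every lever/magazine role in a session summary.
swap_roles <- function(summary_tbl) {
  out <- summary_tbl
  out$lever_contacts <- summary_tbl$mag_entries_cs
  out$mag_entries_cs <- summary_tbl$lever_contacts
  out$prob_lever <- summary_tbl$prob_mag
  out$prob_mag <- summary_tbl$prob_lever
  out$lat_lever_s <- summary_tbl$lat_mag_s
  out$lat_mag_s <- summary_tbl$lat_lever_s
  out
}
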