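#' Simulate one PavCA session for an agent
#'
#' Generates the trial-level event log for a single session. Each trial is an
#' intertrial interval drawn uniformly on the configured range, followed by
#' the CS window. With probability `respond_prob` the agent emits a CS-period
#' response, directed at the lever with probability `(1 + theta) / 2` and at
#' the food magazine otherwise. The first response latency is drawn from an
#' exponential of mean `lat_scale_s` truncated to the CS window; additional
#' contacts within the same trial follow a Poisson count. Magazine entries
#' during the ITI arrive as a Poisson count per trial, and every trial ends
#' with a pellet-retrieval event shortly after CS offset. Timestamps are
#' seconds from session start at millisecond resolution.
#'
#' Uses the current RNG state; seed management is the caller's job (see
#' [simulate_cohort()] for the per-rat substream scheme).
#'
#' @param agent An [make_agent()] object.
#' @param session Session number (>= 1).
#' @param cfg A [trial_config()].
#' @param phase Phase label stored in the log.
#' @param theta Optional latent bias override; defaults to
#'   [theta_at_session()] with no treatment.
#' @return A tibble in the event-log schema (`rat_id`, `phase`, `session`,
#'   `trial`, `event_type`, `time_s`).
#' @examples
#' set.seed(1)
#' log <- simulate_pavca_session(make_agent("ST", 1), session = 1)
#' table(log$event_type)
#' @export
simulate_pavca_session <- function(agent, session, cfg = trial_config(),
                                   phase = "acquisition", theta = NULL) {
  stopifnot(inherits(agent, "agent_params"), session >= 1,
            inherits(cfg, "trial_config"))
  theta <- theta %||% theta_at_session(agent, session)
  n <- cfg$n_trials
  cs_dur <- cfg$cs_duration_s

  iti <- runif(n, cfg$iti_range_s[1], cfg$iti_range_s[2])
  # round CS onsets once so cs_off - cs_on stays exactly cs_dur after the
  # millisecond quantization of the log
  cs_on <- round(cumsum(iti) + cs_dur * (seq_len(n) - 1), 3)
  cs_off <- cs_on + cs_dur

  responds <- runif(n) < agent$respond_prob
  to_lever <- runif(n) < (1 + theta) / 2
  first_lat <- rtrunc_exp(n, agent$lat_scale_s, cs_dur)
  n_extra <- rpois(n, agent$extra_event_rate)
  n_iti_mag <- rpois(n, agent$iti_rate)

  iti_start <- c(0, cs_off[-n])

  # CS-period response events, vectorized over trials
  resp_idx <- which(responds)
  k_resp <- 1L + n_extra[resp_idx]
  resp_trial <- rep(resp_idx, k_resp)
  is_first <- sequence(k_resp) == 1L
  extra_u <- runif(length(resp_trial))
  lat <- first_lat[resp_trial]
  offset <- ifelse(is_first, lat, lat + extra_u * (cs_dur - lat))
  # quantize within-CS offsets and keep them strictly inside [0, cs_dur)
  offset <- pmin(round(offset, 3), cs_dur - 0.001)
  ev_resp_time <- cs_on[resp_trial] + offset
  ev_resp_type <- ifelse(to_lever[resp_trial], "lever_contact", "mag_entry")

  # ITI magazine entries in the interval preceding each trial
  iti_trial <- rep(seq_len(n), n_iti_mag)
  ev_iti_time <- runif(length(iti_trial)) *
    (cs_on[iti_trial] - iti_start[iti_trial]) + iti_start[iti_trial]
  ev_iti_time <- pmin(round(ev_iti_time, 3), cs_on[iti_trial] - 0.001)

  pellet_t <- round(cs_off + runif(n, 0.25, 3), 3)

  out <- tibble(
    rat_id = agent$rat_id, phase = phase, session = as.integer(session),
    trial = as.integer(c(seq_len(n), seq_len(n), seq_len(n),
                         resp_trial, iti_trial)),
    event_type = c(rep("cs_on", n), rep("cs_off", n), rep("pellet", n),
                   ev_resp_type, rep("mag_entry", length(iti_trial))),
    time_s = c(cs_on, cs_off, pellet_t, ev_resp_time, ev_iti_time)
  )
  arrange(out, .data$trial, .data$time_s, .data$event_type)
}

#' Simulate a full cohort
#'
#' Runs every rat of a [cohort_design()] through all acquisition, rescreen
#' and test sessions. Agent parameters and all randomness for a rat come from
#' a substream seeded by a stable hash of the rat id combined with the cohort
#' seed, so outputs are bit-reproducible and adding rats to a design never
#' changes the logs of existing rats. Rats in treatment arms other than the
#' first (control) level have the design's `treat_shift` applied to theta
#' from `treatment_onset_session` onward.
#'
#' @param design A [cohort_design()].
#' @return A list with `events` (event-log tibble over all rats/sessions) and
#'   `truth` (tibble `rat_id`, `phenotype_truth`, `treatment`, `session`,
#'   `theta` recording the generating state).
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_per_cell = 1, seed = 7,
#'   sessions_acquisition = 1:2, sessions_rescreen = 3, sessions_test = 4))
#' dplyr::n_distinct(cohort$events$rat_id)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  blocks <- list(acquisition = design$sessions_acquisition,
                 rescreen = design$sessions_rescreen,
                 test = design$sessions_test)
  cells <- expand.grid(phenotype = design$phenotypes,
                       treatment = design$treatments,
                       idx = seq_len(design$n_per_cell),
                       stringsAsFactors = FALSE)
  control <- design$treatments[1]

  ev <- vector("list", nrow(cells))
  tr <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    rat_id <- sprintf("%s_%s_%02d", cells$phenotype[r], cells$treatment[r],
                      cells$idx[r])
    sub <- substream_seed(design$seed, rat_id)
    treated <- cells$treatment[r] != control
    agent <- make_agent(cells$phenotype[r], seed = sub, rat_id = rat_id,
                        treat_shift = design$treat_shift)
    rat_ev <- list()
    rat_theta <- numeric(0)
    rat_sess <- integer(0)
    withr::with_seed(sub, {
      for (ph in names(blocks)) {
        for (s in blocks[[ph]]) {
          th <- theta_at_session(agent, s, treated = treated,
                                 treatment_onset_session =
                                   design$treatment_onset_session)
          rat_ev[[length(rat_ev) + 1L]] <-
            simulate_pavca_session(agent, s, design$trial_config,
                                   phase = ph, theta = th)
          rat_theta <- c(rat_theta, th)
          rat_sess <- c(rat_sess, s)
        }
      }
    })
    ev[[r]] <- bind_rows(rat_ev)
    tr[[r]] <- tibble(rat_id = rat_id,
                      phenotype_truth = cells$phenotype[r],
                      treatment = cells$treatment[r],
                      session = rat_sess, theta = rat_theta)
  }
  list(events = bind_rows(ev), truth = bind_rows(tr))
}

#' Simulate a conditioned reinforcement (FR1) session
#'
#' Nosepokes into the active port arrive as a Poisson process whose rate
#' increases with `max(theta, 0)`; each active poke triggers a 2-s lever
#' presentation unless one is already ongoing (FR1 with a refractory
#' presentation). The agent contacts the lever within a presentation with a
#' probability increasing in theta; inactive-port pokes arrive at a low
#' phenotype-independent rate. Uses the current RNG state.
#'
#' @param agent An [make_agent()] object.
#' @param duration_s Session length in seconds (default 2400, a 40-min test).
#' @param theta Latent bias; defaults to the agent's asymptote.
#' @param active_rate_per_min,inactive_rate_per_min Optional explicit poke
#'   rates; by default the active rate is `0.3 + 1.7 * max(theta, 0)` per
#'   minute and the inactive rate 0.2 per minute.
#' @param presentation_s Lever presentation length (seconds).
#' @param session Session number stored in the log.
#' @return An event-log tibble with event types `active_poke`,
#'   `inactive_poke`, `lever_contact` (phase `"crt"`, `trial` `NA`).
#' @examples
#' set.seed(1)
#' crt <- simulate_crt_session(make_agent("ST", 1))
#' table(crt$event_type)
#' @export
simulate_crt_session <- function(agent, duration_s = 2400, theta = NULL,
                                 active_rate_per_min = NULL,
                                 inactive_rate_per_min = 0.2,
                                 presentation_s = 2, session = 17L) {
  stopifnot(inherits(agent, "agent_params"), duration_s >= 0)
  theta <- theta %||% agent$theta_asym
  if (duration_s == 0) {
    return(tibble(rat_id = character(0), phase = character(0),
                  session = integer(0), trial = integer(0),
                  event_type = character(0), time_s = numeric(0)))
  }
  active_rate <- (active_rate_per_min %||% (0.3 + 1.7 * max(theta, 0))) / 60
  inactive_rate <- inactive_rate_per_min / 60

  poisson_times <- function(rate) {
    k <- rpois(1, rate * duration_s)
    sort(runif(k, 0, duration_s))
  }
  active <- poisson_times(active_rate)
  inactive <- poisson_times(inactive_rate)

  # FR1 reconstruction: a poke during an ongoing presentation is counted but
  # does not retrigger the lever
  pres_start <- numeric(0)
  last_end <- -Inf
  for (t in active) {
    if (t >= last_end) {
      pres_start <- c(pres_start, t)
      last_end <- t + presentation_s
    }
  }
  p_contact <- max(theta, 0) * 0.8
  contacted <- runif(length(pres_start)) < p_contact
  contact_t <- pres_start[contacted] +
    runif(sum(contacted), 0, presentation_s * 0.99)

  out <- tibble(
    event_type = c(rep("active_poke", length(active)),
                   rep("inactive_poke", length(inactive)),
                   rep("lever_contact", length(contact_t))),
    time_s = round(c(active, inactive, contact_t), 3)
  )
  out <- arrange(out, .data$time_s, .data$event_type)
  tibble(rat_id = agent$rat_id, phase = "crt",
         session = as.integer(session), trial = NA_integer_,
         event_type = out$event_type, time_s = out$time_s)
}

#' Simulate a microdialysis fraction series
#'
#' Emits the standard fraction schedule (6 baseline, 5 pre-session, 7
#' in-session 5-min fractions) for each analyte. The in-session dopamine
#' concentration is coupled to the rat's realized PavCA index:
#' `conc = da_base_nM * (1 + (da_coupling * index + e) / 100)` with a single
#' series-level noise draw `e ~ Normal(0, da_noise_sd)`. The other analytes
#' (ACh, GABA, Glu, 5-HT) get an independent noise draw and zero structural
#' coupling. Baseline and pre-session fractions sit at the analyte's
#' baseline concentration, so percent change recovers the coupling exactly
#' when noise is zero. Uses the current RNG state.
#'
#' @param agent An [make_agent()] object.
#' @param realized_index Realized PavCA index in \[-1, 1\].
#' @param analytes Analyte subset to emit.
#' @return A fraction-table tibble: `rat_id`, `analyte`, `fraction`,
#'   `phase` (baseline/pre/session), `minutes`, `conc_nM`.
#' @examples
#' set.seed(1)
#' d <- simulate_dialysis_series(make_agent("GT", 2), realized_index = -0.5)
#' table(d$phase) / length(unique(d$analyte))
#' @export
simulate_dialysis_series <- function(agent, realized_index,
                                     analytes = ANALYTES) {
  stopifnot(inherits(agent, "agent_params"),
            realized_index >= -1, realized_index <= 1)
  base_conc <- c(DA = agent$da_base_nM, ACh = 4, GABA = 30, Glu = 50,
                 `5-HT` = 0.5)
  phase <- rep(c("baseline", "pre", "session"), c(6L, 5L, 7L))
  frac <- seq_along(phase)
  minutes <- 5 * frac
  out <- vector("list", length(analytes))
  for (j in seq_along(analytes)) {
    a <- analytes[j]
    eps <- rnorm(1, 0, agent$da_noise_sd)
    coupling <- if (a == "DA") agent$da_coupling else 0
    sess_conc <- base_conc[[a]] *
      (1 + (coupling * realized_index + eps) / 100)
    conc <- pmax(ifelse(phase == "session", sess_conc, base_conc[[a]]), 0)
    out[[j]] <- tibble(rat_id = agent$rat_id, analyte = a, fraction = frac,
                       phase = phase, minutes = minutes, conc_nM = conc)
  }
  bind_rows(out)
}
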