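#' Trial configuration for a PavCA session
#'
#' Defaults reproduce the standard autoshaping protocol: 25 lever-CS/food
#' pairings per session, an 8-s illuminated lever presentation, and a
#' variable-time 90-s schedule with intertrial intervals drawn uniformly on
#' 30-150 s.
#'
#' @param n_trials Number of CS trials per session.
#' @param cs_duration_s CS (lever presentation) duration in seconds.
#' @param iti_mean_s Mean intertrial interval in seconds.
#' @param iti_range_s Length-2 numeric, closed ITI range in seconds.
#' @return A list of class `trial_config`.
#' @examples
#' trial_config()
#' @export
trial_config <- function(n_trials = 25, cs_duration_s = 8,
                         iti_mean_s = 90, iti_range_s = c(30, 150)) {
  stopifnot(n_trials >= 1, cs_duration_s > 0, length(iti_range_s) == 2)
  if (iti_mean_s < iti_range_s[1] || iti_mean_s > iti_range_s[2]) {
    stop("iti_mean_s must lie inside iti_range_s", call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials), cs_duration_s = cs_duration_s,
         iti_mean_s = iti_mean_s, iti_range_s = iti_range_s),
    class = "trial_config"
  )
}

#' Construct a behavioral agent
#'
#' Builds the parameter set for one simulated rat. The agent carries a single
#' latent lever-bias `theta` in \[-1, 1\]: the probability that a CS-period
#' response is directed at the lever rather than the food magazine is
#' `(1 + theta) / 2`. Across sessions theta relaxes geometrically from its
#' starting value toward a phenotype-specific asymptote, which produces the
#' usual acquisition curves; a treatment shift can be added to theta from a
#' given session onward (see [theta_at_session()]). A dopamine channel is
#' linearly coupled to the realized PavCA index through `da_coupling`, with
#' Gaussian noise `da_noise_sd`, both on the percent-change scale.
#'
#' Default asymptotes put sign-trackers (`ST`) near +0.6, goal-trackers
#' (`GT`) near -0.6 and intermediates (`IN`) near 0, so the measured
#' session-4/5 PavCA index lands in the conventional classification bands
#' (ST above +0.3, GT below -0.3) in expectation.
#'
#' @param phenotype One of `"ST"`, `"GT"`, `"IN"`.
#' @param seed Integer seed; the same (phenotype, seed) pair always returns
#'   identical parameters, and the caller's RNG state is left untouched.
#' @param rat_id Identifier carried through all outputs.
#' @param theta_asym Optional fixed asymptote overriding the phenotype draw.
#' @param treat_shift Additive shift applied to theta from the first treated
#'   session, in \[-2, 2\].
#' @return A list of class `agent_params` with fields `rat_id`,
#'   `phenotype_truth`, `theta0`, `theta_asym`, `learn_rate`, `treat_shift`,
#'   `respond_prob`, `lat_scale_s`, `extra_event_rate`, `iti_rate`,
#'   `da_base_nM`, `da_coupling`, `da_noise_sd`.
#' @examples
#' a <- make_agent("ST", seed = 1)
#' a$theta_asym > 0
#' @export
make_agent <- function(phenotype = c("ST", "GT", "IN"), seed,
                       rat_id = paste0(phenotype[1], "_", seed),
                       theta_asym = NULL, treat_shift = 0) {
  phenotype <- match.arg(phenotype)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (abs(treat_shift) > 2) stop("treat_shift must be in [-2, 2]", call. = FALSE)
  withr::with_seed(as.integer(seed %% 2147483647), {
    asym <- theta_asym %||% switch(phenotype,
      ST = 0.6 + runif(1, -0.1, 0.1),
      GT = -0.6 + runif(1, -0.1, 0.1),
      IN = runif(1, -0.15, 0.15)
    )
    if (phenotype == "ST" && asym <= 0) stop("ST asymptote must be > 0")
    if (phenotype == "GT" && asym >= 0) stop("GT asymptote must be < 0")
    structure(
      list(
        rat_id = rat_id,
        phenotype_truth = phenotype,
        theta0 = runif(1, -0.15, 0.15),
        theta_asym = clamp(asym),
        learn_rate = 0.6,
        treat_shift = treat_shift,
        respond_prob = runif(1, 0.85, 0.97),
        lat_scale_s = runif(1, 1.5, 3),
        extra_event_rate = 0.7,
        iti_rate = runif(1, 1, 3),
        da_base_nM = runif(1, 1.5, 3),
        da_coupling = 40,
        da_noise_sd = 10
      ),
      class = "agent_params"
    )
  })
}

#' Latent lever bias at a given session
#'
#' theta relaxes geometrically from `theta0` toward `theta_asym` at rate
#' `learn_rate` per session; for treated rats the agent's `treat_shift` is
#' added from `treatment_onset_session` onward. The result is clamped to
#' \[-1, 1\].
#'
#' @param agent An `agent_params` object.
#' @param session Session number (1-based).
#' @param treated Logical; does this rat receive the active treatment?
#' @param treatment_onset_session First session at which the shift applies.
#' @return theta in \[-1, 1\].
#' @export
theta_at_session <- function(agent, session, treated = FALSE,
                             treatment_onset_session = Inf) {
  stopifnot(inherits(agent, "agent_params"), session >= 1)
  th <- agent$theta_asym +
    (agent$theta0 - agent$theta_asym) * (1 - agent$learn_rate)^(session - 1)
  if (treated && session >= treatment_onset_session) {
    th <- th + agent$treat_shift
  }
  clamp(th)
}

#' Cohort design for a simulated experiment
#'
#' Session ranges follow the two-phase screening layout: acquisition,
#' a rescreen block, then a test block during which treated rats receive the
#' manipulation from `treatment_onset_session` (defaulting to the first test
#' session).
#'
#' @param n_per_cell Rats per phenotype-by-treatment cell.
#' @param sessions_acquisition,sessions_rescreen,sessions_test Integer
#'   vectors of session numbers; must be disjoint and increasing.
#' @param treatment_onset_session First treated session.
#' @param seed Cohort seed; per-rat substreams are derived from it by stable
#'   hashing of the rat id.
#' @param trial_config A [trial_config()].
#' @param phenotypes,treatments Factor levels defining the cells. The first
#'   treatment level is the control arm (no shift applied).
#' @param treat_shift Theta shift given to treated rats.
#' @return A list of class `cohort_design`.
#' @examples
#' cohort_design(n_per_cell = 2, seed = 7)
#' @export
cohort_design <- function(n_per_cell,
                          sessions_acquisition = 1:5,
                          sessions_rescreen = 6:10,
                          sessions_test = 11:16,
                          treatment_onset_session = NULL,
                          seed = 1,
                          trial_config = pavca::trial_config(),
                          phenotypes = c("ST", "GT"),
                          treatments = c("VEH", "CNO"),
                          treat_shift = 0) {
  blocks <- list(acquisition = sessions_acquisition,
                 rescreen = sessions_rescreen, test = sessions_test)
  all_sessions <- unlist(blocks)
  if (anyDuplicated(all_sessions) || is.unsorted(all_sessions)) {
    stop("session ranges must be disjoint and ordered", call. = FALSE)
  }
  if (is.null(treatment_onset_session)) {
    treatment_onset_session <-
      if (length(sessions_test) > 0) min(sessions_test) else Inf
  }
  structure(
    list(n_per_cell = as.integer(n_per_cell),
         sessions_acquisition = sessions_acquisition,
         sessions_rescreen = sessions_rescreen,
         sessions_test = sessions_test,
         treatment_onset_session = treatment_onset_session,
         seed = as.integer(seed),
         trial_config = trial_config,
         phenotypes = phenotypes,
         treatments = treatments,
         treat_shift = treat_shift),
    class = "cohort_design"
  )
}
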