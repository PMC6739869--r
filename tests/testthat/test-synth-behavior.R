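test_that("make_agent is deterministic and respects phenotype sign", {
  a1 <- make_agent("ST", 1)
  a2 <- make_agent("ST", 1)
  expect_identical(a1, a2)
  expect_gt(make_agent("ST", 1)$theta_asym, 0)
  expect_lt(make_agent("GT", 1)$theta_asym, 0)
  expect_error(make_agent("XX", 1))
  # caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_agent("GT", 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("theta relaxes toward the asymptote and clamps to [-1, 1]", {
  a <- make_agent("ST", 4, theta_asym = 0.8, treat_shift = 1.5)
  th <- vapply(1:10, function(s) theta_at_session(a, s), numeric(1))
  expect_true(all(th >= -1 & th <= 1))
  expect_lt(abs(th[10] - 0.8), 1e-3)
  # monotone approach from below or above
  expect_true(all(diff(abs(th - 0.8)) <= 1e-12))
  shifted <- theta_at_session(a, 10, treated = TRUE,
                              treatment_onset_session = 5)
  expect_identical(shifted, 1)  # 0.8 + 1.5 clamped
})

test_that("a degenerate lever agent produces only lever CS responses", {
  a <- make_agent("ST", 3, theta_asym = 1)
  a$respond_prob <- 1
  a$iti_rate <- 0
  set.seed(1)
  log <- simulate_pavca_session(a, 10, theta = 1)
  expect_identical(sum(log$event_type == "mag_entry"), 0L)
  expect_identical(length(unique(log$trial[log$event_type ==
                                             "lever_contact"])), 25L)
  set.seed(1)
  log_gt <- simulate_pavca_session(a, 10, theta = -1)
  expect_identical(sum(log_gt$event_type == "lever_contact"), 0L)
})

test_that("CS-period allocation follows Bernoulli((1 + theta) / 2)", {
  a <- make_agent("IN", 5, theta_asym = 0)
  a$respond_prob <- 1
  cfg <- trial_config(n_trials = 25)
  set.seed(7)
  logs <- dplyr::bind_rows(lapply(1:400, function(i) {
    l <- simulate_pavca_session(a, 1, cfg, theta = 0)
    l$session <- i
    l
  }))
  s <- summarize_sessions(logs)
  # 10^4 trials; fraction of lever trials within 3 binomial SEs of 1/2
  frac <- sum(s$prob_lever * s$n_trials) / sum(s$n_trials)
  n_tr <- 400 * 25
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_tr))
})

test_that("simulated ITI durations average the configured mean", {
  a <- make_agent("GT", 6)
  cfg <- trial_config()
  set.seed(2)
  logs <- dplyr::bind_rows(lapply(1:400, function(i) {
    l <- simulate_pavca_session(a, 1, cfg)
    l$session <- i
    l
  }))
  cs <- tidyr::pivot_wider(
    dplyr::filter(logs, event_type %in% c("cs_on", "cs_off")),
    id_cols = c(session, trial), names_from = event_type,
    values_from = time_s)
  cs <- dplyr::arrange(cs, session, trial)
  prev_off <- ifelse(cs$trial == 1, 0, dplyr::lag(cs$cs_off, default = 0))
  iti <- cs$cs_on - prev_off
  expect_gt(length(iti), 1e4 - 1)
  expect_lt(abs(mean(iti) - cfg$iti_mean_s) / cfg$iti_mean_s, 0.01)
  expect_true(all(iti >= cfg$iti_range_s[1] - 1e-9 &
                    iti <= cfg$iti_range_s[2] + 1e-9))
})

test_that("cohorts are bit-reproducible and substream-stable", {
  des <- cohort_design(n_per_cell = 5, seed = 7,
                       sessions_acquisition = 1:2, sessions_rescreen = 3,
                       sessions_test = 4)
  c1 <- simulate_cohort(des)
  c2 <- simulate_cohort(des)
  expect_identical(c1, c2)
  # growing the cohort leaves existing rats' logs untouched
  des_big <- cohort_design(n_per_cell = 6, seed = 7,
                           sessions_acquisition = 1:2,
                           sessions_rescreen = 3, sessions_test = 4)
  c3 <- simulate_cohort(des_big)
  shared <- dplyr::semi_join(c3$events, c1$events, by = "rat_id")
  key <- c("rat_id", "session", "trial", "time_s", "event_type")
  expect_identical(dplyr::arrange(shared, dplyr::across(dplyr::all_of(key))),
                   dplyr::arrange(c1$events,
                                  dplyr::across(dplyr::all_of(key))))
})

test_that("ground truth records the treatment shift from onset only", {
  des <- cohort_design(n_per_cell = 2, seed = 3, sessions_acquisition = 1:2,
                       sessions_rescreen = 3:4, sessions_test = 5:6,
                       treat_shift = -0.5)
  co <- simulate_cohort(des)
  tr <- co$truth
  expect_true(all(tr$theta >= -1 & tr$theta <= 1))
  # CNO arm theta drops at test onset relative to its own rescreen
  drop <- dplyr::summarise(
    dplyr::group_by(tr, rat_id, treatment),
    d = mean(theta[session >= 5]) - mean(theta[session %in% 3:4]))
  expect_true(all(drop$d[drop$treatment == "CNO"] < 0))
})

test_that("a negative treatment shift lowers the ST test-phase index", {
  # Monte-Carlo oracle on the generator itself, 20 replicate mini-cohorts
  deltas <- vapply(1:20, function(i) {
    des <- cohort_design(n_per_cell = 3, seed = 100 + i,
                         sessions_acquisition = integer(0),
                         sessions_rescreen = 1:2, sessions_test = 3:4,
                         phenotypes = "ST", treat_shift = -0.6)
    co <- simulate_cohort(des)
    tab <- cohort_block_means(co, des)
    treated <- tab$treatment == "CNO"
    mean(tab$value[treated & tab$block == "test"]) -
      mean(tab$value[treated & tab$block == "rescreen"])
  }, numeric(1))
  expect_lt(mean(deltas), 0)
  expect_gt(mean(deltas < 0), 0.8)
})

test_that("CRT pokes follow the configured Poisson rates", {
  a <- make_agent("ST", 8)
  set.seed(5)
  tot_active <- 0; tot_inactive <- 0
  for (i in 1:200) {
    log <- simulate_crt_session(a, duration_s = 2400,
                                active_rate_per_min = 1,
                                inactive_rate_per_min = 0.2)
    tot_active <- tot_active + sum(log$event_type == "active_poke")
    tot_inactive <- tot_inactive + sum(log$event_type == "inactive_poke")
  }
  # expected totals 8000 and 1600; ratio 5 with MC sd ~0.14
  expect_lt(abs(tot_active / tot_inactive - 5), 0.5)
})

test_that("CRT limit cases: zero duration and magazine-biased agents", {
  a <- make_agent("GT", 9, theta_asym = -1)
  expect_identical(nrow(simulate_crt_session(a, duration_s = 0)), 0L)
  set.seed(4)
  log <- simulate_crt_session(a, theta = -1)
  expect_identical(sum(log$event_type == "lever_contact"), 0L)
})

test_that("dialysis series has the 6/5/7 schedule and exact coupling", {
  a <- make_agent("ST", 10)
  a$da_noise_sd <- 0
  a$da_coupling <- 50
  set.seed(1)
  d <- simulate_dialysis_series(a, realized_index = 1)
  da <- d[d$analyte == "DA", ]
  expect_identical(as.integer(table(da$phase)[c("baseline", "pre",
                                                "session")]),
                   c(6L, 5L, 7L))
  pc <- percent_change(da)
  expect_equal(unique(pc$pct_change[pc$phase == "session"]), 50)
  set.seed(1)
  d0 <- simulate_dialysis_series(a, realized_index = 0)
  pc0 <- percent_change(d0[d0$analyte == "DA", ])
  expect_equal(unique(pc0$pct_change[pc0$phase == "session"]), 0)
  # non-DA analytes carry no structural coupling
  a$da_noise_sd <- 0
  set.seed(2)
  d1 <- simulate_dialysis_series(a, realized_index = 1)
  ach <- percent_change(d1[d1$analyte == "ACh", ])
  expect_equal(unique(ach$pct_change[ach$phase == "session"]), 0)
})
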