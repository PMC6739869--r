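test_that("index components follow their defining arithmetic", {
  expect_equal(response_bias(25, 0), 1)
  expect_equal(response_bias(10, 10), 0)
  expect_equal(probability_difference(1, 0), 1)
  expect_equal(probability_difference(0.5, 0.5), 0)
  expect_equal(probability_difference(0.2, 0.9), -0.7)
  expect_equal(latency_difference(0, 8), 1)
  expect_equal(latency_difference(8, 0), -1)
  expect_equal(latency_difference(2, 6), 0.5)
  expect_error(response_bias(-1, 0), "non-negative")
  expect_error(probability_difference(1.2, 0), "0, 1")
  expect_error(latency_difference(9, 0), "cs_duration")
})

test_that("a zero-response session maps to 0 and is flagged undefined", {
  expect_equal(response_bias(0, 0), 0)
  expect_false(response_bias_defined(0, 0))
  s <- tibble::tibble(rat_id = "r1", phase = "acquisition", session = 1L,
                      lever_contacts = 0, mag_entries_cs = 0,
                      prob_lever = 0, prob_mag = 0,
                      lat_lever_s = 8, lat_mag_s = 8,
                      iti_mag_entries = 0, n_trials = 25)
  sc <- pavca_index(s)
  expect_false(sc$defined)
  expect_equal(sc$index, 0)
})

test_that("extreme sessions reach index +1 / -1 and symmetry gives 0", {
  st <- tibble::tibble(rat_id = "r1", phase = "acquisition", session = 1L,
                       lever_contacts = 25, mag_entries_cs = 0,
                       prob_lever = 1, prob_mag = 0,
                       lat_lever_s = 0, lat_mag_s = 8,
                       iti_mag_entries = 0, n_trials = 25)
  expect_equal(pavca_index(st)$index, 1)
  expect_equal(pavca_index(swap_roles(st))$index, -1)
  sym <- tibble::tibble(rat_id = "r1", phase = "acquisition", session = 1L,
                        lever_contacts = 10, mag_entries_cs = 10,
                        prob_lever = 0.5, prob_mag = 0.5,
                        lat_lever_s = 4, lat_mag_s = 4,
                        iti_mag_entries = 0, n_trials = 25)
  expect_equal(pavca_index(sym)$index, 0)
})

test_that("the index is bounded and antisymmetric under role swap", {
  for (seed in 1:30) {
    log <- random_event_log(n_trials = 8, seed = seed)
    s <- summarize_session(log)
    sc <- pavca_index(s)
    expect_gte(sc$index, -1)
    expect_lte(sc$index, 1)
    expect_equal(pavca_index(swap_roles(s))$index, -sc$index)
  }
})

test_that("classification thresholds are inclusive and regime-specific", {
  sc <- tibble::tibble(rat_id = "r1", session = 4:5, index = c(0.5, 0.3))
  expect_identical(classify(sc, "exp1")$call, "ST")
  mid <- tibble::tibble(rat_id = "r1", session = 4:5, index = c(-0.1, 0.1))
  out <- classify(mid, "exp1")
  expect_identical(out$call, "IN")
  expect_true(out$excluded)
  # inclusive boundary: mean exactly -0.20 on session 3 is a GT under exp2
  b <- tibble::tibble(rat_id = "r1", session = 3L, index = -0.20)
  bc <- classify(b, "exp2")
  expect_identical(bc$call, "GT")
  expect_true(bc$at_boundary)
  # same value under exp1 (threshold 0.30) is intermediate
  b45 <- tibble::tibble(rat_id = "r1", session = 4:5, index = c(-0.2, -0.2))
  expect_identical(classify(b45, "exp1")$call, "IN")
  expect_error(classify(b, "exp1"), "missing window")
})

test_that("classification is monotone and the bands partition the line", {
  grid <- seq(-1, 1, by = 0.05)
  calls <- classify_mean_index(grid, 0.30)
  expect_identical(calls[grid >= 0.30], rep("ST", sum(grid >= 0.30)))
  expect_identical(calls[grid <= -0.30], rep("GT", sum(grid <= -0.30)))
  expect_identical(calls[abs(grid) < 0.30],
                   rep("IN", sum(abs(grid) < 0.30)))
  # monotone: no GT above an ST
  expect_true(max(grid[calls == "GT"]) < min(grid[calls == "ST"]))
})

test_that("simulated classification calls track the generating phenotype", {
  # a small mixed cohort: ST calls only among ST-truth rats, GT only among
  # GT-truth rats (cohort-level recovery rates live in the acceptance suite)
  des <- cohort_design(n_per_cell = 5, seed = 11)
  co <- simulate_cohort(des)
  sc <- pavca_index(summarize_sessions(co$events))
  calls <- classify(dplyr::select(sc, rat_id, session, index), "exp1")
  joined <- dplyr::inner_join(
    calls, dplyr::distinct(co$truth, rat_id, phenotype_truth),
    by = "rat_id")
  expect_false(any(joined$call == "ST" & joined$phenotype_truth == "GT"))
  expect_false(any(joined$call == "GT" & joined$phenotype_truth == "ST"))
  expect_gt(mean(joined$call == joined$phenotype_truth), 0.7)
})

test_that("counterbalanced assignment matches arm means", {
  calls <- tibble::tibble(rat_id = paste0("r", 1:4), call = "ST",
                          excluded = FALSE,
                          mean_index = c(0.9, 0.8, 0.4, 0.35))
  asg <- assign_groups(calls, c("CNO", "VEH"))
  m <- tapply(asg$mean_index, asg$arm, mean)
  expect_lt(abs(diff(m)), sd(calls$mean_index))
  # single rat, single arm
  one <- tibble::tibble(rat_id = "r1", call = "GT", excluded = FALSE,
                        mean_index = -0.5)
  expect_identical(assign_groups(one, "VEH")$arm, "VEH")
  expect_warning(assign_groups(one, c("A", "B")), "fewer rats")
})

test_that("assignment beats random allocation on arm-mean balance", {
  set.seed(11)
  calls <- tibble::tibble(rat_id = sprintf("r%03d", 1:200),
                          call = rep(c("ST", "GT"), each = 100),
                          excluded = FALSE,
                          mean_index = c(runif(100, 0.3, 1),
                                         runif(100, -1, -0.3)))
  arms <- c("a1", "a2", "a3", "a4")
  asg <- assign_groups(calls, arms)
  max_gap <- function(tbl) {
    m <- tapply(tbl$mean_index, tbl$arm, mean)
    max(dist(m))
  }
  gap_st <- max_gap(asg[asg$call == "ST", ])
  random_gaps <- vapply(1:500, function(i) {
    tbl <- asg[asg$call == "ST", ]
    tbl$arm <- sample(tbl$arm)
    max_gap(tbl)
  }, numeric(1))
  expect_lt(gap_st, median(random_gaps))
  # determinism
  expect_identical(asg, assign_groups(calls, arms))
})

test_that("phenotype change between screens is audited, not dropped", {
  init <- tibble::tibble(rat_id = c("r1", "r2"), mean_index = c(0.5, -0.5),
                         call = c("ST", "GT"))
  resc <- tibble::tibble(rat_id = c("r1", "r2"), mean_index = c(0.1, -0.6),
                         call = c("IN", "GT"))
  audit <- phenotype_change_audit(init, resc)
  expect_identical(audit$changed, c(TRUE, FALSE))
})
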