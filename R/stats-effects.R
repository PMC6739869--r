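#' Tukey 1.5 x IQR outlier report
#'
#' Boxplot-rule outlier screen: values below `Q1 - 1.5 IQR` or above
#' `Q3 + 1.5 IQR` are flagged. Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7), the convention the flagging
#' depends on. With fewer than 4 values no flagging is attempted and the
#' removed set is empty (with a warning). The rule is invariant under adding
#' a constant and equivariant under positive rescaling.
#'
#' @param values Numeric vector.
#' @return List of class `outlier_report`: `kept`, `removed`, `q1`, `q3`,
#'   `iqr`, `bounds`.
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))$removed  # 100
#' @export
iqr_outliers <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    warning("fewer than 4 values; no outlier flagging attempted",
            call. = FALSE)
    return(structure(list(kept = values, removed = numeric(0),
                          q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                          bounds = c(NA_real_, NA_real_)),
                     class = "outlier_report"))
  }
  q <- unname(quantile(values, c(0.25, 0.75), type = 7, names = FALSE))
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out <- values < bounds[1] | values > bounds[2]
  structure(list(kept = values[!out], removed = values[out],
                 q1 = q[1], q3 = q[2], iqr = iqr, bounds = bounds),
            class = "outlier_report")
}

#' Cohen's d for two independent groups
#'
#' `(mean1 - mean2) / s_pooled`, pooling the two group variances with
#' degrees-of-freedom weights. Conventional magnitude bands: below 0.2
#' small, 0.2-0.8 medium, above 0.8 large. Antisymmetric under swapping the
#' groups.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return Cohen's d.
#' @examples
#' cohens_d(c(0, 1, 2), c(-1, 0, 1))  # 1
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("pooled SD is zero", call. = FALSE)
  (mean(group1) - mean(group2)) / sqrt(sp2)
}

#' Two-sample t-test with effect size
#'
#' Student's pooled-variance t-test (two-sided), matching the classical
#' `n1 + n2 - 2` degrees of freedom for the unpaired case; optionally a
#' paired t-test on the differences. The result bundles Cohen's d (pooled-SD
#' d for unpaired, mean difference over SD of differences for paired).
#'
#' @param group1,group2 Numeric vectors (equal length when `paired`).
#' @param paired Logical.
#' @return List of class `comparison_result`: `statistic`, `df`, `p`,
#'   `effect_size_d`, `n1`, `n2`, `method`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))$df  # 4
#' @export
two_sample_t <- function(group1, group2, paired = FALSE) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (paired && n1 != n2) stop("paired test needs equal lengths",
                               call. = FALSE)
  if (var(group1) == 0 && var(group2) == 0 &&
      (!paired || var(group1 - group2) == 0) &&
      mean(group1) == mean(group2)) {
    # degenerate but well-defined: no difference, no evidence
    ht <- list(statistic = 0, parameter = if (paired) n1 - 1 else n1 + n2 - 2,
               p.value = 1)
  } else {
    ht <- t.test(group1, group2, paired = paired, var.equal = TRUE)
  }
  d <- if (paired) {
    dd <- group1 - group2
    if (sd(dd) == 0) 0 else mean(dd) / sd(dd)
  } else {
    if (var(group1) == 0 && var(group2) == 0) 0 else cohens_d(group1, group2)
  }
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 effect_size_d = d, n1 = n1, n2 = n2,
                 method = if (paired) "paired t" else "pooled t"),
            class = "comparison_result")
}

#' Permutation test for a treatment-by-session-block interaction
#'
#' A design-based replacement for repeated-measures mixed models in the
#' two-block, two-arm case (e.g. rescreen vs test means per rat, vehicle vs
#' drug). The observed statistic is the difference-in-differences of arm
#' means across blocks:
#' `(mean treated block2 - mean treated block1) -
#'  (mean control block2 - mean control block1)`.
#' The null distribution permutes treatment labels across rats while keeping
#' each rat's block pairing intact, and the p-value uses the add-one rule
#' `p = (1 + #\{|null| >= |obs|\}) / (n_perm + 1)`, which is valid (never
#' anti-conservative) under exchangeability.
#'
#' @param long_table Tibble with columns `rat_id`, `block`, `treatment`,
#'   `value`; exactly two blocks and two treatment arms, every rat observed
#'   in both blocks.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the permutation draws.
#' @param arms Optional length-2 vector fixing (control, treated) order;
#'   defaults to the unique labels in order of first appearance, the first
#'   taken as control (the sign of `observed` depends on this; the p-value
#'   does not).
#' @param blocks Optional length-2 vector fixing (first, second) block
#'   order; defaults to first appearance.
#' @return List of class `interaction_test`: `observed`, `p`, `n_perm`,
#'   `arms`, `blocks`, `null_stats`.
#' @export
interaction_permutation_test <- function(long_table, n_perm = 999, seed = 1,
                                         arms = NULL, blocks = NULL) {
  assert_cols(long_table, c("rat_id", "block", "treatment", "value"),
              "long table")
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  blocks <- blocks %||% unique(as.character(long_table$block))
  arms <- arms %||% unique(as.character(long_table$treatment))
  if (length(blocks) != 2 || length(arms) != 2) {
    stop("need exactly two blocks and two treatment arms", call. = FALSE)
  }
  wide <- long_table %>%
    mutate(block = as.character(.data$block),
           treatment = as.character(.data$treatment)) %>%
    tidyr::pivot_wider(id_cols = c("rat_id", "treatment"),
                       names_from = "block", values_from = "value")
  if (anyNA(wide[[blocks[1]]]) || anyNA(wide[[blocks[2]]])) {
    stop("every rat must have a value in both blocks", call. = FALSE)
  }
  diffs <- wide[[blocks[2]]] - wide[[blocks[1]]]
  treated <- wide$treatment == arms[2]
  if (sum(treated) < 2 || sum(!treated) < 2) {
    stop("need at least 2 rats per arm", call. = FALSE)
  }
  stat <- function(tr) mean(diffs[tr]) - mean(diffs[!tr])
  obs <- stat(treated)
  n_treat <- sum(treated)
  n_rat <- length(diffs)
  null_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- logical(n_rat)
      perm[sample.int(n_rat, n_treat)] <- TRUE
      stat(perm)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, p = p, n_perm = n_perm, arms = arms,
                 blocks = blocks, null_stats = null_stats),
            class = "interaction_test")
}

#' Balanced two-way ANOVA
#'
#' Classical sums-of-squares decomposition for a balanced two-factor design
#' with replication (e.g. nose port by treatment), via `stats::aov`. The
#' design must be balanced with at least two replicates per cell; unbalanced
#' tables are rejected with a pointer to the permutation test.
#'
#' @param table Tibble with columns `factor_a`, `factor_b`, `value`.
#' @return Tibble with one row per term (`factor_a`, `factor_b`,
#'   `interaction`, `residuals`): `df`, `sum_sq`, `f`, `p`.
#' @examples
#' df <- expand.grid(factor_a = c("x", "y"), factor_b = c("u", "v"),
#'                   rep = 1:3)
#' df$value <- rnorm(nrow(df))
#' balanced_two_way_anova(df)
#' @export
balanced_two_way_anova <- function(table) {
  assert_cols(table, c("factor_a", "factor_b", "value"), "ANOVA table")
  cell_n <- table %>% count(.data$factor_a, .data$factor_b) %>% pull(n)
  n_cells <- length(unique(table$factor_a)) * length(unique(table$factor_b))
  if (length(cell_n) != n_cells || length(unique(cell_n)) != 1) {
    stop("unbalanced design; use interaction_permutation_test() instead",
         call. = FALSE)
  }
  if (cell_n[1] < 2) stop("need >= 2 replicates per cell", call. = FALSE)
  df <- data.frame(A = factor(table$factor_a), B = factor(table$factor_b),
                   value = table$value)
  fit <- aov(value ~ A * B, data = df)
  tab <- summary(fit)[[1]]
  tibble(
    term = c("factor_a", "factor_b", "interaction", "residuals"),
    df = tab[["Df"]],
    sum_sq = tab[["Sum Sq"]],
    f = tab[["F value"]],
    p = tab[["Pr(>F)"]]
  )
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Post-hoc pairwise pooled t-tests across group levels with Bonferroni
#' correction, intended to follow a significant interaction.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @return Tibble `group1`, `group2`, `statistic`, `df`, `p_raw`,
#'   `p_bonferroni`, `effect_size_d`.
#' @export
pairwise_posthoc <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  lev <- unique(as.character(groups))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    r <- two_sample_t(values[groups == pr[1]], values[groups == pr[2]])
    tibble(group1 = pr[1], group2 = pr[2], statistic = r$statistic,
           df = r$df, p_raw = r$p, effect_size_d = r$effect_size_d)
  })
  out <- bind_rows(rows)
  mutate(out, p_bonferroni = pmin(1, .data$p_raw * length(pairs)))
}

#' Simulation-based power for the interaction test
#'
#' Estimates the power of [interaction_permutation_test()] at level `alpha`
#' for a given treatment shift, by simulating cohorts with the package's
#' agent-based generator, scoring them through the full pipeline (events to
#' session summaries to PavCA index to per-rat block means) and counting
#' rejections. Reported with a 95% normal-approximation binomial CI.
#'
#' @param treat_shift Theta shift given to treated rats (0 gives the type-I
#'   rate).
#' @param n_per_arm Rats per treatment arm (single phenotype).
#' @param phenotype Phenotype simulated.
#' @param alpha Test level.
#' @param n_sim Number of simulated cohorts (>= 100 for a stable estimate).
#' @param seed Base seed; each replicate derives its own substream.
#' @param n_perm Permutations per test.
#' @param sessions_rescreen,sessions_test Session blocks used for the
#'   per-rat block means.
#' @param trial_config A [trial_config()].
#' @return List: `power`, `ci`, `alpha`, `n_sim`, `rejections`.
#' @export
power_by_simulation <- function(treat_shift, n_per_arm, phenotype = "ST",
                                alpha = 0.05, n_sim = 100, seed = 1,
                                n_perm = 199,
                                sessions_rescreen = 1:2,
                                sessions_test = 3:4,
                                trial_config = pavca::trial_config()) {
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  rej <- vapply(seq_len(n_sim), function(i) {
    des <- cohort_design(
      n_per_cell = n_per_arm,
      sessions_acquisition = integer(0),
      sessions_rescreen = sessions_rescreen,
      sessions_test = sessions_test,
      seed = substream_seed(seed, paste0("powersim", i)),
      trial_config = trial_config,
      phenotypes = phenotype,
      treat_shift = treat_shift
    )
    tab <- cohort_block_means(simulate_cohort(des), des)
    res <- interaction_permutation_test(tab, n_perm = n_perm,
                                        seed = substream_seed(seed,
                                          paste0("powerperm", i)))
    res$p <= alpha
  }, logical(1))
  k <- sum(rej)
  p_hat <- k / n_sim
  se <- sqrt(p_hat * (1 - p_hat) / n_sim)
  list(power = p_hat, ci = c(max(0, p_hat - 1.96 * se),
                             min(1, p_hat + 1.96 * se)),
       alpha = alpha, n_sim = n_sim, rejections = k)
}

#' Per-rat block means of the PavCA index for a simulated cohort
#'
#' Convenience bridge from a [simulate_cohort()] result to the long table
#' consumed by [interaction_permutation_test()]: summarizes the events,
#' computes the PavCA index, and averages it per rat over the rescreen and
#' test blocks.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param design The [cohort_design()] that produced it.
#' @return Tibble `rat_id`, `block` (`rescreen`/`test`), `treatment`,
#'   `value`.
#' @export
cohort_block_means <- function(cohort, design) {
  scores <- pavca_index(summarize_sessions(cohort$events),
                        design$trial_config$cs_duration_s)
  arms <- distinct(cohort$truth, .data$rat_id, .data$treatment)
  scores %>%
    filter(.data$phase %in% c("rescreen", "test")) %>%
    group_by(.data$rat_id, block = .data$phase) %>%
    summarise(value = mean(.data$index), .groups = "drop") %>%
    left_join(arms, by = "rat_id") %>%
    select("rat_id", "block", "treatment", "value")
}
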