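#' Baseline mean of a dialysis series
#'
#' Arithmetic mean of the baseline-phase concentrations (by convention the
#' mean of all baseline fractions, normally six 5-min fractions collected
#' over 30 min). Rejects series without baseline fractions, with negative
#' concentrations, or whose baseline mean is zero (percent change would be
#' undefined).
#'
#' @param series Fraction tibble for one rat-analyte with columns `phase`
#'   and `conc_nM`.
#' @return Baseline mean concentration (nM).
#' @examples
#' s <- tibble::tibble(phase = rep("baseline", 6), conc_nM = rep(2, 6))
#' baseline_mean(s)  # 2
#' @export
baseline_mean <- function(series) {
  assert_cols(series, c("phase", "conc_nM"), "dialysis series")
  if (any(series$conc_nM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  b <- series$conc_nM[series$phase == "baseline"]
  if (length(b) == 0) stop("series has no baseline fractions", call. = FALSE)
  m <- mean(b)
  if (m <= 0) stop("baseline mean is zero; percent change undefined",
                   call. = FALSE)
  m
}

#' Percent change from baseline
#'
#' Adds `pct_change = 100 * (conc - baseline_mean) / baseline_mean` to every
#' fraction of a single rat-analyte series, baseline fractions included
#' (their mean percent change is 0 by construction). Percent change is
#' invariant under rescaling all concentrations by a positive constant.
#'
#' @param series Fraction tibble for one rat-analyte.
#' @return The series with `baseline_mean` and `pct_change` columns.
#' @examples
#' s <- tibble::tibble(phase = c(rep("baseline", 6), "session"),
#'                     conc_nM = c(rep(2, 6), 3))
#' tail(percent_change(s)$pct_change, 1)  # +50
#' @export
percent_change <- function(series) {
  m <- baseline_mean(series)
  mutate(series, baseline_mean = m,
         pct_change = 100 * (.data$conc_nM - m) / m)
}

#' Session-average percent change
#'
#' Mean percent change over the in-session fractions (normally seven 5-min
#' fractions spanning the 35-min session).
#'
#' @param series Fraction tibble for one rat-analyte.
#' @return Mean percent change (a scalar).
#' @export
session_average_change <- function(series) {
  pc <- percent_change(series)
  s <- pc$pct_change[pc$phase == "session"]
  if (length(s) == 0) stop("series has no session fractions", call. = FALSE)
  mean(s)
}

#' Normalize a dialysis fraction table
#'
#' Applies the percent-change normalization per rat-analyte series, with a
#' completeness rule: series with fewer than `min_baseline` baseline or
#' `min_session` session fractions are excluded and reported (mirroring the
#' practice of dropping samples lost to technical difficulties).
#'
#' @param fractions Fraction table: `rat_id`, `analyte`, `fraction`, `phase`,
#'   `conc_nM` (and optionally `minutes`).
#' @param min_baseline,min_session Minimum fraction counts for inclusion.
#' @return List with `fractions` (normalized rows), `summary` (per
#'   rat-analyte `session_avg_pct`), and `excluded` (tibble of dropped
#'   series with reason codes).
#' @export
normalize_dialysis <- function(fractions, min_baseline = 4, min_session = 5) {
  assert_cols(fractions, c("rat_id", "analyte", "phase", "conc_nM"),
              "fraction table")
  keys <- distinct(fractions, .data$rat_id, .data$analyte)
  norm <- vector("list", nrow(keys))
  excl <- vector("list", nrow(keys))
  for (r in seq_len(nrow(keys))) {
    ser <- filter(fractions, .data$rat_id == keys$rat_id[r],
                  .data$analyte == keys$analyte[r])
    nb <- sum(ser$phase == "baseline")
    ns <- sum(ser$phase == "session")
    if (nb < min_baseline || ns < min_session) {
      excl[[r]] <- tibble(rat_id = keys$rat_id[r],
                          analyte = keys$analyte[r],
                          n_baseline = nb, n_session = ns,
                          reason = "incomplete_series")
      next
    }
    norm[[r]] <- percent_change(ser)
  }
  norm <- bind_rows(norm)
  summary <- if (nrow(norm) > 0) {
    norm %>%
      filter(.data$phase == "session") %>%
      group_by(.data$rat_id, .data$analyte) %>%
      summarise(session_avg_pct = mean(.data$pct_change), .groups = "drop")
  } else {
    tibble(rat_id = character(0), analyte = character(0),
           session_avg_pct = numeric(0))
  }
  list(fractions = norm, summary = summary, excluded = bind_rows(excl))
}

#' Regress the PavCA index on dopamine percent change
#'
#' Ordinary least squares with the per-rat session-average dopamine percent
#' change as the predictor and the PavCA index as the dependent variable.
#' `r_squared` equals the squared Pearson correlation, and
#' `F = r2 (n - 2) / (1 - r2)` on (1, n - 2) degrees of freedom.
#'
#' @param pct_da Numeric vector of per-rat dopamine percent changes.
#' @param index Numeric vector of per-rat PavCA indices (same length).
#' @return List: `slope`, `intercept`, `r_squared`, `f_statistic`, `df1`,
#'   `df2`, `p_value`, `n`.
#' @examples
#' fit <- regress_behavior_on_da(c(0, 10, 20, 30), c(-0.4, -0.2, 0, 0.2))
#' fit$r_squared  # 1 (collinear)
#' @export
regress_behavior_on_da <- function(pct_da, index) {
  if (length(pct_da) != length(index)) {
    stop("pct_da and index must have equal length", call. = FALSE)
  }
  n <- length(pct_da)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (var(pct_da) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- lm(index ~ pct_da)
  r2 <- summary(fit)$r.squared
  f <- r2 * (n - 2) / (1 - r2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, f_statistic = f, df1 = 1, df2 = n - 2,
       p_value = pf(f, 1, n - 2, lower.tail = FALSE), n = n)
}

#' Baseline group comparison
#'
#' Unpaired pooled-variance t-test on per-rat baseline means between two
#' treatment groups, reported as part of the dialysis QC (treated and
#' control rats should not differ before the manipulation).
#'
#' @param fractions Fraction table with a `treatment` column.
#' @param analyte Analyte to test.
#' @return A [two_sample_t()] result.
#' @export
compare_baselines <- function(fractions, analyte = "DA") {
  assert_cols(fractions, c("rat_id", "analyte", "phase", "conc_nM",
                           "treatment"), "fraction table")
  sel <- filter(fractions, .data$analyte == !!analyte,
                .data$phase == "baseline")
  per_rat <- sel %>%
    group_by(.data$rat_id, .data$treatment) %>%
    summarise(base = mean(.data$conc_nM), .groups = "drop")
  arms <- sort(unique(per_rat$treatment))
  if (length(arms) != 2) stop("need exactly two treatment groups",
                              call. = FALSE)
  two_sample_t(per_rat$base[per_rat$treatment == arms[1]],
               per_rat$base[per_rat$treatment == arms[2]])
}
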