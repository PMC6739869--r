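#' Response bias
#'
#' `(lever - magazine) / (lever + magazine)` over CS-period session totals.
#' A session with no responses at all (0/0) is mapped to 0 and flagged
#' undefined rather than dropped, so downstream tables keep the rat-session
#' auditable; check the flag with [response_bias_defined()].
#'
#' @param lever_contacts,mag_entries_cs Non-negative session counts
#'   (vectorized).
#' @return Numeric in \[-1, 1\].
#' @examples
#' response_bias(25, 0)   # +1
#' response_bias(10, 10)  # 0
#' response_bias(0, 0)    # 0, undefined
#' @export
response_bias <- function(lever_contacts, mag_entries_cs) {
  if (any(lever_contacts < 0) || any(mag_entries_cs < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- lever_contacts + mag_entries_cs
  ifelse(tot == 0, 0, (lever_contacts - mag_entries_cs) / tot)
}

#' @rdname response_bias
#' @return `response_bias_defined()`: logical, `FALSE` where both counts are
#'   zero.
#' @export
response_bias_defined <- function(lever_contacts, mag_entries_cs) {
  (lever_contacts + mag_entries_cs) > 0
}

#' Probability difference
#'
#' `prob_lever - prob_mag`, the difference between the per-trial
#' probabilities of contacting the lever and entering the magazine during
#' the CS.
#'
#' @param prob_lever,prob_mag Probabilities in \[0, 1\] (vectorized).
#' @return Numeric in \[-1, 1\].
#' @examples
#' probability_difference(1, 0)     # +1
#' probability_difference(0.2, 0.9) # -0.7
#' @export
probability_difference <- function(prob_lever, prob_mag) {
  if (any(prob_lever < 0 | prob_lever > 1) ||
      any(prob_mag < 0 | prob_mag > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  prob_lever - prob_mag
}

#' Latency difference
#'
#' `-(lat_lever - lat_mag) / cs_duration`, so faster approach to the lever
#' than to the magazine scores positive. With censored latencies equal to
#' the CS duration, the component spans exactly \[-1, 1\].
#'
#' @param lat_lever_s,lat_mag_s Mean session latencies in
#'   `[0, cs_duration_s]` (vectorized). Values within one part in 10^9 of
#'   the bounds are clamped rather than rejected, absorbing the rounding of
#'   timestamp differences.
#' @param cs_duration_s CS duration (the divisor), default 8 s.
#' @return Numeric in \[-1, 1\].
#' @examples
#' latency_difference(0, 8) # +1
#' latency_difference(2, 6) # +0.5
#' @export
latency_difference <- function(lat_lever_s, lat_mag_s, cs_duration_s = 8) {
  tol <- cs_duration_s * 1e-9
  if (any(lat_lever_s < -tol | lat_lever_s > cs_duration_s + tol) ||
      any(lat_mag_s < -tol | lat_mag_s > cs_duration_s + tol)) {
    stop("latencies must be in [0, cs_duration_s]", call. = FALSE)
  }
  lat_lever_s <- clamp(lat_lever_s, 0, cs_duration_s)
  lat_mag_s <- clamp(lat_mag_s, 0, cs_duration_s)
  -(lat_lever_s - lat_mag_s) / cs_duration_s
}

#' PavCA composite index
#'
#' The unweighted mean of response bias, probability difference and latency
#' difference for each rat-session summary. The index ranges from -1 (an
#' extreme goal-tracker whose conditioned responses all target the food
#' magazine) to +1 (an extreme sign-tracker whose responses all target the
#' lever-CS).
#'
#' @param summaries Session-summary tibble from [summarize_sessions()].
#' @param cs_duration_s CS duration used by the latency component.
#' @return The input with columns `response_bias`, `prob_diff`,
#'   `latency_diff`, `index` and `defined` appended.
#' @examples
#' s <- tibble::tibble(rat_id = "r1", phase = "acquisition", session = 1L,
#'   lever_contacts = 25, mag_entries_cs = 0, prob_lever = 1, prob_mag = 0,
#'   lat_lever_s = 0, lat_mag_s = 8, iti_mag_entries = 0, n_trials = 25)
#' pavca_index(s)$index  # +1
#' @export
pavca_index <- function(summaries, cs_duration_s = 8) {
  assert_cols(summaries,
              c("lever_contacts", "mag_entries_cs", "prob_lever", "prob_mag",
                "lat_lever_s", "lat_mag_s"), "session summaries")
  mutate(
    summaries,
    response_bias = response_bias(.data$lever_contacts, .data$mag_entries_cs),
    prob_diff = probability_difference(.data$prob_lever, .data$prob_mag),
    latency_diff = latency_difference(.data$lat_lever_s, .data$lat_mag_s,
                                      cs_duration_s),
    index = (.data$response_bias + .data$prob_diff + .data$latency_diff) / 3,
    defined = response_bias_defined(.data$lever_contacts,
                                    .data$mag_entries_cs)
  )
}

#' Classification regimes
#'
#' Threshold regimes for phenotype calls: `exp1` averages the index over
#' sessions 4 and 5 with cutoffs at \eqn{\pm 0.30}; `exp2` uses session 3
#' alone with cutoffs at \eqn{\pm 0.20} (a looser criterion because the
#' conditioned response is not fully developed that early). Thresholds are
#' applied inclusively (>= / <=).
#'
#' @param regime `"exp1"` or `"exp2"`.
#' @return List with `window_sessions` and `threshold`.
#' @export
classification_regime <- function(regime = c("exp1", "exp2")) {
  regime <- match.arg(regime)
  switch(regime,
         exp1 = list(window_sessions = c(4L, 5L), threshold = 0.30),
         exp2 = list(window_sessions = 3L, threshold = 0.20))
}

#' Classify rats as sign-, goal- or intermediate trackers
#'
#' Averages each rat's PavCA index over the regime's window sessions and
#' thresholds it inclusively: mean index at or above the cutoff is a
#' sign-tracker (`ST`), at or below the negative cutoff a goal-tracker
#' (`GT`), and anything strictly inside the band an intermediate (`IN`).
#' Intermediates carry an exclusion flag, mirroring the usual screening
#' practice of dropping them from phenotype-contrast designs.
#'
#' @param scores Tibble with `rat_id`, `session`, `index` (e.g. from
#'   [pavca_index()]).
#' @param regime `"exp1"` or `"exp2"`, or a list like
#'   [classification_regime()] for custom windows/thresholds.
#' @return Tibble `rat_id`, `mean_index`, `call`, `excluded`, `regime`,
#'   plus boundary flags (`at_boundary` marks rats whose mean index sits
#'   exactly on a cutoff).
#' @examples
#' sc <- tibble::tibble(rat_id = "r1", session = 4:5, index = c(0.5, 0.3))
#' classify(sc, "exp1")$call  # "ST"
#' @export
classify <- function(scores, regime = "exp1") {
  assert_cols(scores, c("rat_id", "session", "index"), "scores")
  reg <- if (is.character(regime)) classification_regime(regime) else regime
  reg_label <- if (is.character(regime)) regime else "custom"
  win <- reg$window_sessions
  thr <- reg$threshold

  have <- scores %>%
    filter(.data$session %in% win) %>%
    group_by(.data$rat_id) %>%
    summarise(n_win = dplyr::n_distinct(.data$session),
              mean_index = mean(.data$index), .groups = "drop")
  incomplete <- union(
    have$rat_id[have$n_win < length(win)],
    setdiff(unique(scores$rat_id), have$rat_id)
  )
  if (length(incomplete) > 0) {
    stop("missing window session(s) for rat(s): ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  have %>%
    mutate(
      call = ifelse(.data$mean_index >= thr, "ST",
                    ifelse(.data$mean_index <= -thr, "GT", "IN")),
      excluded = .data$call == "IN",
      at_boundary = abs(abs(.data$mean_index) - thr) < .Machine$double.eps^0.5,
      regime = reg_label
    ) %>%
    select("rat_id", "mean_index", "call", "excluded", "at_boundary",
           "regime")
}

#' Audit phenotype stability across screening windows
#'
#' Flags rats whose call differs between two classifications (e.g. initial
#' acquisition vs a post-incubation rescreen). Reported, not auto-excluded;
#' exclusion is a pipeline configuration switch.
#'
#' @param calls_initial,calls_rescreen Outputs of [classify()].
#' @return Tibble `rat_id`, `call_initial`, `call_rescreen`, `changed`.
#' @export
phenotype_change_audit <- function(calls_initial, calls_rescreen) {
  dplyr::inner_join(
    select(calls_initial, "rat_id", call_initial = "call"),
    select(calls_rescreen, "rat_id", call_rescreen = "call"),
    by = "rat_id"
  ) %>%
    mutate(changed = .data$call_initial != .data$call_rescreen)
}

#' Counterbalanced group assignment
#'
#' Deals rats into treatment arms so that arm-wise mean PavCA indices are
#' matched within each phenotype: rats are sorted by `mean_index`
#' (descending, ties broken by rat id) and assigned round-robin across arms,
#' with the arm order rotating every round so no arm systematically receives
#' the higher-scoring rat. Deterministic given the input and seed.
#'
#' @param calls Tibble with `rat_id`, `call`, `mean_index` (from
#'   [classify()]); `IN` rats flagged `excluded` are not assigned.
#' @param arms Character vector of arm labels.
#' @param seed Seed for tie-breaking jitter in the sort (ties are first
#'   broken by rat id; the seed only matters for exact index ties among
#'   identical ids, kept for reproducibility of the contract).
#' @return Tibble `rat_id`, `call`, `mean_index`, `arm`.
#' @examples
#' calls <- tibble::tibble(rat_id = paste0("r", 1:4), call = "ST",
#'   excluded = FALSE, mean_index = c(0.9, 0.8, 0.4, 0.35))
#' assign_groups(calls, c("CNO", "VEH"))
#' @export
assign_groups <- function(calls, arms, seed = 1) {
  assert_cols(calls, c("rat_id", "call", "mean_index"), "calls")
  if (length(arms) == 0) stop("arms must be nonempty", call. = FALSE)
  if ("excluded" %in% names(calls)) calls <- filter(calls, !.data$excluded)
  if (nrow(calls) == 0) stop("no assignable rats", call. = FALSE)

  k <- length(arms)
  out <- calls %>%
    group_by(.data$call) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < k) {
        warning(sprintf("phenotype %s has fewer rats (%d) than arms (%d)",
                        key$call, nrow(df), k), call. = FALSE)
      }
      df <- arrange(df, dplyr::desc(.data$mean_index), .data$rat_id)
      # serpentine deal: reverse arm order on alternate rounds so arm means
      # stay matched even when the index declines steeply down the list
      rounds <- ceiling(nrow(df) / k)
      order_fwd <- seq_len(k)
      arm_idx <- unlist(lapply(seq_len(rounds), function(r) {
        if (r %% 2 == 1) order_fwd else rev(order_fwd)
      }))[seq_len(nrow(df))]
      df$arm <- arms[arm_idx]
      df
    }) %>%
    ungroup()
  select(out, "rat_id", "call", "mean_index", "arm")
}
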