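---
title: "Scoring and simulating Pavlovian conditioned approach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and simulating Pavlovian conditioned approach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavca)
library(dplyr)
```

## The behavioral model

When a localizable cue (an illuminated, retractable lever) reliably predicts
response-independent food delivery, rats develop one of two conditioned
responses: *sign-trackers* (STs) approach and engage the lever itself,
*goal-trackers* (GTs) approach the food magazine where the pellet will
arrive. The distinction matters because it indexes individual variation in
incentive-salience attribution — for STs the cue acquires motivational value
of its own, beyond its predictive value.

The standard protocol runs daily sessions of 25 lever-CS/food pairings. The
lever extends for 8 s; retraction coincides with pellet delivery. Trials
are separated by a variable-time 90-s schedule with intertrial intervals
(ITIs) spanning 30–150 s. Six measures summarize each rat-session: lever
contacts, CS-period magazine entries, the per-trial probability of each
response, and the latency to each response. These combine into the **PavCA
index**, the mean of three components:

* response bias: $(L - M) / (L + M)$ over session totals,
* probability difference: $P_\text{lever} - P_\text{mag}$,
* latency difference: $-(\bar\ell_\text{lever} - \bar\ell_\text{mag}) / 8$.

Each component lies in $[-1, 1]$, so the index does too: $+1$ is an extreme
sign-tracker responding on every trial at the lever instantly, $-1$ the
mirror-image goal-tracker.

## Conventions the index forces

The protocol literature states the component formulas but not every edge
convention; the package fixes them as follows.

**Censored latencies.** A trial with no response to a target contributes the
full CS duration (8 s) to that target's latency. This is the only convention
under which the latency component — and hence the index — attains $\pm 1$
for all-or-none sessions, which the index's stated range requires.

**Per-trial probabilities.** The probability measures are fractions of
trials with at least one response, not event counts; again the only reading
for which the component is a probability and the extremes are $\pm 1$.
Multiple contacts within a trial all count toward the session totals, which
is why lever-contact totals above 25 occur.

**Zero-response sessions.** The response bias is 0/0 for a session with no
CS-period responses at all. The package maps it to 0 and flags the
rat-session (`defined = FALSE`) rather than dropping it, so the exclusion
decision stays with the analyst.

**Half-open CS window.** Events at exactly CS offset belong to the ITI;
lever timestamps are only valid inside the window (the lever is retracted
otherwise). Pellet-retrieval events are typed separately and never counted
as magazine entries.

**Latency aggregation.** The per-session latency is the mean of per-trial
first-event latencies, censored trials included. A median would also be
defensible; the mean is the one consistent with the extreme-score logic and
is used throughout.

## Classification and counterbalancing

Phenotype calls threshold the mean index over a screening window. Two
regimes are built in: `exp1` (sessions 4–5, cutoffs $\pm 0.30$) for fully
acquired responses, and `exp2` (session 3 alone, cutoffs $\pm 0.20$) for
early-training designs where the response is not yet developed. Cutoffs are
applied inclusively; written criteria use $\ge$/$\le$ while some figure
legends use strict inequalities, and the package follows the written
criteria, flagging rats that sit exactly on a boundary (`at_boundary`) so
the handful of affected cases are auditable. Intermediate rats carry an
exclusion flag; a phenotype that changes between screening windows is
audited (`phenotype_change_audit()`), with actual exclusion left to a
configuration switch.

Group assignment (`assign_groups()`) deals rats into treatment arms in a
serpentine order down the index-sorted list within each phenotype, so arms
are matched on mean index by construction — the behavioral analog of
stratified counterbalancing. It is deterministic given the input table.

## Conditioned reinforcement scoring

The conditioned reinforcement test (CRT) asks whether the cue alone can
reinforce a new instrumental response: nosepokes into an active port earn a
2-s lever presentation on an FR1 schedule; the inactive port does nothing.
The **incentive value index** is
$(\text{active pokes} + \text{lever contacts}) - \text{inactive pokes}$.
`summarize_crt()` reconstructs presentations under the FR1 rule with the
presentation itself refractory: a poke landing during an ongoing 2-s
presentation is counted but does not retrigger the lever. The protocol
sources do not state this explicitly; it is the conventional FR1 reading
and gives `presentations <= active_pokes` as an invariant. Lever contacts
are constrained to presentation windows in the simulator, since the lever
is physically retracted otherwise.

## Microdialysis normalization

Dialysate fractions are collected on a 5-min schedule: six baseline
fractions (30 min), five post-injection/pre-session fractions, seven
in-session fractions. Concentrations are expressed as percent change from
baseline,
$100 \times (c_i - \bar c_\text{base}) / \bar c_\text{base}$,
with the denominator the mean of **all** baseline fractions (the block is
stated in protocols, the formula rarely; the all-fraction mean is the
stable choice and is applied uniformly). Series missing fractions are
excluded by a completeness rule — at least 4 baseline and 5 session
fractions — and reported with reason codes rather than silently dropped.
Behavior–dopamine coupling is quantified by OLS of the PavCA index on the
per-rat session-average percent change in dopamine; $r^2$ equals the
squared Pearson correlation and $F = r^2(n-2)/(1-r^2)$ on $(1, n-2)$
degrees of freedom.

## Inference layer

Repeated-measures questions of the form *did the treated arm change from
the rescreen block to the test block more than the control arm?* are
answered by a permutation test (`interaction_permutation_test()`): the
statistic is the difference-in-differences of arm means across blocks, the
null permutes treatment labels across rats (preserving each rat's block
pairing), and the p-value uses the add-one rule, which is valid at any
permutation count. This replaces mixed-effects modelling with REML and
covariance-structure selection: for the balanced two-block design the
difference-in-differences is exactly the interaction contrast, the
permutation null is assumption-light, and the procedure is fully
specifiable and testable. A long-format table is exported by the pipeline
for analysts who want to fit mixed models externally.

Supporting tools follow the conventions of the field: Tukey's 1.5 × IQR
boxplot rule with type-7 (linear-interpolation) quartiles — the flagged set
depends on the quartile convention, so it is pinned and documented;
pooled-variance t-tests with classical degrees of freedom; Cohen's d with
df-weighted pooling; balanced two-way ANOVA by classical sums of squares
(unbalanced tables are rejected with a pointer to the permutation test);
Bonferroni correction for post-hoc pairwise contrasts; and power by
simulation (`power_by_simulation()`), which runs the full
generate–score–test loop rather than an analytic approximation.

## The synthetic cohort generator

No generative model exists in the protocol literature, so the package
invents a deliberately minimal one: each rat carries a single latent lever
bias $\theta \in [-1, 1]$, and a CS-period response is directed at the
lever with probability $(1 + \theta)/2$. Across sessions $\theta$ relaxes
geometrically toward a phenotype asymptote (learning); treatment adds a
shift to $\theta$ from its onset session. One parameter per rat is enough
to produce the ST/GT continuum, acquisition curves, treatment effects, and
— through the allocation, response-probability and latency machinery — all
six session measures with realistic coupling among them.

Default parameters, chosen once as plausible for the paradigm:

| parameter | default | meaning |
|---|---|---|
| asymptote | $+0.6 \pm 0.1$ (ST), $-0.6 \pm 0.1$ (GT), $0 \pm 0.15$ (IN) | phenotype band targets |
| `learn_rate` | 0.6 | per-session fractional approach to the asymptote |
| `respond_prob` | 0.85–0.97 | per-trial probability of any CS response |
| `lat_scale_s` | 1.5–3 s | mean of the truncated-exponential first latency |
| `iti_rate` | 1–3 | Poisson ITI magazine entries per trial |
| `da_coupling` | 40 | % dopamine change per unit of realized index |
| `da_noise_sd` | 10 | SD of the series-level dopamine noise (% scale) |

ITIs are uniform on 30–150 s — the simplest law consistent with the stated
mean and range. Latencies are truncated-exponential inside the 8-s window,
giving the right-skew seen in operant latencies. Timestamps are seconds
from session start at millisecond resolution; CS onsets are quantized
before offsets are derived so every logged trial has an exactly 8-s
window. Dialysis series couple the in-session dopamine concentration
linearly to the realized index with one noise draw per series; the other
analytes (ACh, GABA, Glu, 5-HT) have zero structural coupling.

Reproducibility is structural: a cohort seed plus a stable hash of each
rat id defines a per-rat substream, so the same design is bit-identical on
re-simulation and *adding rats never perturbs existing ones*. CRT pokes
are Poisson processes whose active-port rate rises with
$\max(\theta, 0)$; latency and rate parameters can be overridden
explicitly for calibration work.

What the generator does **not** emulate: within-session learning, CNO
pharmacokinetics, satiety or circadian drift, chamber artifacts, and any
mechanistic dopamine dynamics. Passing tests therefore certify the
*analysis pipeline* — that the measures, index, classification, and
inference recover what the generative model planted — not distributional
fidelity to any particular animal dataset.

## Calibration checks and their problem sizes

The test suite ties the generator and the analysis together with
property-style checks, at sizes chosen to balance Monte-Carlo error
against runtime:

* degenerate agents reproduce index $\pm 1$ exactly through the full
  event-log path;
* session summaries equal brute-force event recounts on randomized logs;
* empirical ITI means match the schedule within 1% over $10^4$ trials;
* the permutation test's type-I rate over several hundred null cohorts
  (8 rats, two 2-session blocks each) stays inside the central 99%
  binomial band around $\alpha = 0.05$;
* classification on an 80-rat cohort with asymptotes $\pm 0.6$ recovers
  the generating phenotype for at least 95% of decisive (non-intermediate)
  calls. Rats whose measured index lands in the intermediate band are
  counted as screening exclusions — the treatment they receive in actual
  phenotype-contrast designs — and their fraction is itself bounded and
  reported;
* with coupling and noise set for a 0.9 signal fraction at $n = 10$, the
  mean regression $r^2$ over 100 replicate dialysis cohorts recovers 0.9
  within $\pm 0.08$.

## A worked example

```{r example}
des <- cohort_design(n_per_cell = 3, seed = 42,
                     sessions_acquisition = 1:5,
                     sessions_rescreen = 6:7, sessions_test = 8:9,
                     treat_shift = -0.5)
cohort <- simulate_cohort(des)
scores <- pavca_index(summarize_sessions(cohort$events))
calls <- classify(select(scores, rat_id, session, index), "exp1")
table(calls$call)

tab <- cohort_block_means(cohort, des)
interaction_permutation_test(tab, n_perm = 499, seed = 1,
                             arms = c("VEH", "CNO"))[c("observed", "p")]
```

A negative observed statistic here reflects the simulated treatment
pushing the treated arm's index down from rescreen to test relative to
vehicle.

## Known limitations

* The agent model is phenomenological; its parameters are not estimates of
  any published cohort, and latency/ITI-rate defaults are placeholders in
  the absence of published per-phenotype distributions.
* The permutation interaction test covers the two-block, two-arm design
  only; multi-session repeated measures require the exported long table
  and an external mixed-model fit.
* Real deposited per-rat tables can be ingested via the documented column
  mappings, but no such data ship with the package; bundled examples are
  synthetic.
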