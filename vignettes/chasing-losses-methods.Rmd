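---
title: "Operationalizing loss-chasing from account-based transaction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operationalizing loss-chasing from account-based transaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasemetrics)
library(dplyr)
```

## The problem

Chasing losses — gambling more, or again, to recover money already lost —
is one of the nine DSM-5 criteria for gambling disorder and is widely
regarded as a pivotal step in its development. Survey instruments ask about
it retrospectively; an online operator's account ledger, in contrast,
records every wager, win, deposit and withdrawal with timestamps and
balance snapshots, and so permits *behavioral* operationalizations.
`chasemetrics` implements five such operationalizations at three time
scales (within a session, between nearby sessions, between consecutive
days) plus two deposit/balance-based markers, and the cohort-level
statistics used to ask which of them actually tracks an externally
assigned gambling-risk classification.

The package takes three things as given: a transaction log, player
demographics, and a per-player risk label (low/medium/high) produced by an
external behavioral tracking system. How that label is computed is
explicitly out of scope — it is an input, never an output.

## Sessionization

A session is a maximal run of one player's wagers in which consecutive
wagers are separated by at most the gap parameter `gap_minutes`
(default 15; "within 15 minutes" is read inclusively, so a gap of exactly
15:00 does not split a session). Only wagers define sessions: a deposit or
win never bridges a longer silence. Non-wager events are attached
afterwards by directional windows:

* deposits: `[first wager − gap, last wager]` — money is loaded just
  before or during play;
* wins and withdrawals: `[first wager, last wager + gap]` — settlements
  trail play.

The gap rule makes windows of adjacent sessions disjoint; if they could
ever compete, the earlier session wins. Events landing in no window are
returned with `session = NA` — reported, never silently dropped. The
end-of-session balance is the `balance_after` of the chronologically last
*attached* transaction, not the last wager: a final win or withdrawal
settles after the last wager and is the balance the player actually walks
away with. Day aggregation uses calendar dates in a configurable timezone
(default UTC; with players from several countries any single choice is a
convention, and UTC keeps runs reproducible).

## The five metrics and their definedness rules

Spearman correlations are computed as rank transforms (average ranks on
ties) followed by the product-moment correlation. A correlation over a
constant vector is *undefined*, not zero — a session where every stake is
identical carries no evidence of escalation either way, and treating it as
zero would bias player averages toward zero. Undefined per-session values
are skipped from the player mean; a player with no eligible session is
undefined on that metric.

* **Within-session**: sessions need at least three wagers (two points
  always correlate perfectly, which is uninformative). The player value is
  the unweighted mean over eligible sessions — each session is one
  realization of session-level behavior, so a 100-wager session should not
  dominate ten 5-wager sessions.
* **Across-session**: pairs (loss of session *t−1*, wagered in session
  *t*) for consecutive sessions whose end-to-start gap is at most
  `pair_window_hours` (default 24). At least `min_pairs` (default 3) pairs
  are required; the published rule states the ≥3 floor only for the
  within-session metric, and we extend it here because one or two pairs
  give rank correlations of exactly ±1 regardless of behavior.
* **Across-days**: identical, over consecutive calendar dates only.
* **Depletion / frequent depositing**: strict inequalities, as written:
  end balance strictly below 5 units; strictly more than one deposit.

All thresholds (gap, 5-unit balance, 24-hour window, `min_pairs`) are
arguments with these defaults.

## Cohort statistics

Group comparisons use tie-corrected Kruskal–Wallis tests; the gender split
uses Pearson's chi-squared without continuity correction (the comparisons
span three groups). Normality screening uses the D'Agostino–Pearson K²
omnibus statistic — implemented from the standard skewness and kurtosis
normalizing transformations and checked against an independent reference
implementation — which requires n ≥ 20 and a non-degenerate sample.

The joint model is a maximum-likelihood multinomial logit
(`nnet::multinom`, up to 500 iterations) of the risk label on the five
metrics, with the high-risk group as the default reference so coefficients
read as log-odds of being low- or medium-risk rather than high-risk.
Fit quality is McFadden's pseudo-R², `1 − ll/ll₀`, with an intercept-only
null model, plus the likelihood-ratio test on 2×5 degrees of freedom. The
significance convention throughout is 1%.

Clustering z-scores the chosen metrics (sample sd, divisor n−1) so each
carries equal weight, then runs `stats::kmeans` with 10 restarts under a
fixed seed — published analyses rarely state their initialization, and
seeded restarts make the solution reproducible while guarding against bad
local minima. The number of clusters is chosen by a deterministic elbow
rule: both axes of the (k, WSS) curve are rescaled to the unit interval
and the k farthest from the chord joining the endpoints is selected. This
automates the visual "where the slope changes most" reading. Two caveats
are deliberate: (i) on data with no cluster structure the WSS curve decays
smoothly like 1/k and the chord rule still returns an interior k (about 4
on a spherical Gaussian) — it detects curvature, not the *absence* of
structure; (ii) an exactly flat curve (attainable only in degenerate data)
returns the smallest k with a warning. Cluster profiles report sizes,
shares, centroid means in original units, and the risk-label composition —
the label is never among the clustering variables.

## The synthetic cohort generator

Real operator ledgers are proprietary, so the generator is a first-class
module: it emulates the structure the pipeline consumes, with every knob a
documented `group_profile()` parameter. `preset_paper()` pins the three
group profiles to published group-level summaries: cohort shares
(77.13/16.44/6.43%), session counts (negative-binomial with mean/sd
20.97/15.02, 32.00/25.78, 39.01/30.54, floored at 1), active days
(10.93/13.76/15.02 on average), multi-deposit session probabilities
(5/13/18%), depletion probabilities (69/65/64%), across-session rank
couplings (0.08/0.06/0.05), zero within-session drift (the published
within-session correlations are −0.01 to 0.01), and the published age and
gender marginals.

Where the publication is silent the defaults were chosen once as realistic
online-casino conditions and are not tuned: session wagered totals are
log-normal (median 60 units, log-sd 0.8); the return-to-player ratio 0.9
locates the session-loss magnitude marginal (log-normal, log-sd 0.6) so
the expected net loss is 10% of expected wagering; wagers per session are
`1 + Poisson(6)`, putting ~98% of sessions over the three-wager floor;
intra-session wager gaps are uniform 20–120 s and inter-session gaps
exceed the 15-minute threshold by 5–60 minutes, so the sessionizer
recovers intended sessions *exactly* by construction; sessions sit on a
consecutive run of active days starting at 17:00–18:00.

Two mechanisms deserve detail:

* **The loss→wager chain.** A latent Gaussian chain gives session *t*'s
  wagered total Gaussian-copula rank correlation ρ with session *t−1*'s
  loss (latent Pearson `2 sin(πρ/6)`), preserving both marginals. Losses
  are truncated at −wagered so implied wins are nonnegative; with the
  default marginals truncation affects ~2% of sessions and perturbs the
  rank coupling negligibly (recovered within ±0.02 at 10⁵ pairs). The
  chain acts at session level only; day-level coupling then *emerges* from
  aggregation rather than being separately enforced — a session-level and
  an independent day-level chain cannot both hold exactly, since day
  totals are sums of session totals. Per-metric recovery is unaffected;
  reproducing the published regression coefficient magnitudes would
  require the unknown joint law and is not attempted.
* **Exact ledger accounting.** All money is integer cents. Each session
  draws an end-balance target (uniform on [0, 5) when depleted, [5, 200]
  otherwise), then the opening deposit is solved from
  `deposit = end − start − loss − extras`, floored at the larger of 1 unit
  and whatever keeps the running balance nonnegative through the wagers;
  any overshoot is returned by a closing withdrawal. Wins settle as one
  aggregate `WIN` 30 s after the last wager — only session and day totals
  enter any metric, and a single settlement keeps the accounting solvable
  in one pass. Multi-deposit sessions get `1 + Poisson(0.5)` extra
  deposits placed inside the session span. Every emitted log passes
  `validate_log()` with zero violations, by construction.

What the generator does *not* emulate: game-level structure (per-game RTP,
bonus mechanics), currency heterogeneity, within-month trends, and any
joint dependence between the five behaviors beyond the loss→wager chain.
Passing calibration tests therefore shows the pipeline measures what the
generator encodes — it does not show that real cohorts share the
generator's independence assumptions.

## Numerical and testing choices

Balance validation uses a 0.005-unit tolerance, matching two-decimal money
storage; timestamps serialize as whole-second ISO-8601 UTC, and ties within
a second preserve input order (wager/win pairs often share a second).
Simulation-based checks run at sizes chosen to keep the full suite
comfortably fast while leaving Monte-Carlo error well inside the asserted
tolerances: calibration recovery uses 2,000 players per group (binomial
standard errors ≤ 0.2 pp for the rate metrics), the chain recovery 10⁵
pairs, the sessionizer oracle 1,000 random timestamp sets, and the type-I
error checks 1,000 null replicates against the exact binomial 95% band.
Calibration means are taken over all players for whom the metric is
defined; the eligibility filter is applied only where the analysis needs
all five metrics at once (regression, clustering).

## Known limitations

* The five metrics are computed on one observation window; players active
  at its edges lose pairs (first/last sessions have no predecessor or
  successor), which slightly reduces pair counts near boundaries.
* The elbow rule's no-structure behavior (above) means a k ≈ 4 answer on
  unstructured data is possible; inspect `autoplot()` of the curve rather
  than trusting k* blindly.
* Undefined metrics make ineligibility more likely for low-activity
  players, so the eligible subset over-represents active players — the
  same selection the published cohort applies, but worth remembering when
  generalizing.
* Day aggregation assigns wins to the calendar day of their settlement; a
  win settling just after midnight counts toward the next day's total.
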