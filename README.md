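# chasemetrics

Loss-chasing — continuing or escalating gambling to win back prior losses —
is a core diagnostic criterion for gambling disorder, yet it is rarely
operationalized from the account-level transaction data that online
operators actually hold. `chasemetrics` implements a complete, tested
pipeline that turns raw account ledgers (one row per wager, win, deposit or
withdrawal, with balance snapshots) into five per-player behavioral markers
of chasing, and compares them across externally assigned gambling-risk
groups. It is aimed at responsible-gambling researchers, analysts at
operators or regulators, and anyone evaluating behavioral markers of harm
on player-tracking data.

## The method

**Sessionization.** A gambling session is a maximal run of a player's
wagers in which consecutive wagers are separated by at most a gap *G*
(default 15 minutes, inclusive). Deposits attach to the session window
`[first wager − G, last wager]`; wins and withdrawals to
`[first wager, last wager + G]`.

**Five chasing metrics per player *i*.**

1. *Within-session chasing* — for each session *s* with at least three
   wagers, the Spearman correlation between wager amounts and their order,
   `corr(w_is, t_is)`, averaged over eligible sessions:
   `corr_i = avg_s corr(w_is, t_is)`. Positive values mean stakes escalate
   through a session. Undefined for constant stakes (zero variance).
2. *Across-session chasing* — Spearman correlation between a session's
   loss `l_{t−1}` (won − wagered, so net losses are negative) and the next
   session's total wagered `w_t`, over consecutive-session pairs occurring
   within 24 hours. Negative values are the chasing signature.
3. *Across-days chasing* — the same correlation at calendar-day
   granularity, over pairs of consecutive gambling days.
4. *Regular account depletion* — fraction of sessions ending with strictly
   less than 5 currency units in the account.
5. *Frequent session depositing* — fraction of sessions with strictly more
   than one deposit.

A player is *eligible* when all five are defined. Cohort analysis then
runs D'Agostino K² normality tests, Kruskal–Wallis group comparisons, a
multinomial logit of the risk label on the five metrics (McFadden pseudo-R²
`1 − ll/ll₀`), and k-means on z-scored metrics with an automated
(max-chord-distance) elbow rule.

Because operator data are proprietary, the package ships a seeded,
balance-exact synthetic cohort generator (`generate_cohort()` +
`preset_paper()`) whose group shares, session-count marginals, depletion and
multi-deposit probabilities, demographics and loss→wager rank coupling are
calibrated to published group-level summaries of a December 2021 European
online-casino cohort.

## Worked example

```r
library(chasemetrics)
library(dplyr)

cohort  <- generate_cohort(preset_paper(), n_players = 400, seed = 2021)
metrics <- chasing_metrics(cohort$transactions)

s <- risk_group_summary(filter_eligible(metrics), cohort$players)
s$groups[, c("risk_label", "n", "frequent_deposit_rate_mean",
             "depletion_rate_mean")]
#>   risk_label   n frequent_deposit_rate_mean depletion_rate_mean
#> 1        low 265                      0.049               0.694
#> 2     medium  54                      0.130               0.643
#> 3       high  20                      0.172               0.636
```

Frequent session depositing rises steeply with risk (4.9% → 13.0% → 17.2%
of sessions) while account depletion falls slightly — the same pattern the
metrics were designed to expose. The attached Kruskal–Wallis tests agree:

```r
s$tests[s$tests$variable %in% c("frequent_deposit_rate", "across_days"), ]
#>                variable           test statistic df  p.value
#>           across_days  kruskal-wallis      3.48   2 1.8e-01
#>  frequent_deposit_rate kruskal-wallis     95.23   2 2.1e-21
```

Day-aggregated chasing does not separate the groups; frequent session
depositing does, overwhelmingly. The multinomial model (high-risk as
reference) makes the direction explicit — a higher frequent-deposit rate
sharply lowers the odds of being low-risk rather than high-risk:

```r
eligible <- filter_eligible(metrics) |>
  inner_join(cohort$players, by = "player_id")
fit <- fit_multinomial(eligible, risk_label,
  c("within_session", "across_session", "across_days",
    "depletion_rate", "frequent_deposit_rate"), reference = "high")
tidy(fit) |> filter(term == "frequent_deposit_rate")
#>  y.level                  term estimate std.error statistic p.value
#>      low frequent_deposit_rate   -34.6      4.98     -6.95  3.5e-12
#>   medium frequent_deposit_rate    -9.28     4.18     -2.22  2.6e-02
glance(fit)$mcfadden_pseudo_r2
#> [1] 0.318
```

Clustering on the two depositing/depletion metrics (`select_k_elbow()`,
`kmeans_fit()`, `cluster_profiles()`) isolates a cluster with a high
frequent-deposit rate that concentrates the high-risk players
(18.9% high-risk vs ≤1.7% elsewhere in this run); `autoplot()` draws the
elbow curve and the cluster map.

A full end-to-end run — simulate (or load files), validate the ledger,
sessionize, compute metrics, analyze, and write every table plus a hashed
`manifest.json` — is one call:

```r
run_pipeline(run_config(preset = "paper", n_players = 500, seed = 1,
                        out_dir = "report"))
```

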