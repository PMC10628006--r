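#' Spearman rank correlation with average ranks, undefined on constants
#'
#' Rank-transforms both vectors (average ranks on ties) and returns the
#' product-moment correlation of the ranks. When either vector is constant
#' its rank standard deviation is zero and the correlation is undefined:
#' `NA_real_` is returned, not an error — undefinedness is a meaningful
#' outcome for the chasing metrics (e.g. a session with a constant amount
#' wagered).
#'
#' @param x,y Numeric vectors of equal length, at least 2.
#' @return A number in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' spearman_rho(c(3, 1, 2), c(1, 2, 3)) # -0.5
#' spearman_rho(c(5, 5, 5), c(1, 2, 3)) # NA: constant vector
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  if (length(x) < 2) {
    abort("Need at least 2 observations for a rank correlation.")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(NA_real_)
  }
  as.numeric(cor(rx, ry))
}

# fast per-session Spearman of amounts against wager order 1..n;
# order ranks are already 1..n so only the amounts need ranking
.rho_vs_order <- function(amounts) {
  n <- length(amounts)
  r <- rank(amounts)
  if (sd(r) == 0) {
    return(NA_real_)
  }
  as.numeric(cor(r, seq_len(n)))
}

#' Within-session chasing: does the amount wagered escalate through sessions?
#'
#' For each session with at least three wagers and a non-constant amount
#' wagered, the Spearman correlation between the wager amounts and their
#' within-session order (1..n) is computed; a player's metric is the
#' unweighted mean over those eligible sessions. Positive values mean the
#' player tends to increase stakes as a session progresses. Sessions with
#' fewer than three wagers, or a constant amount, contribute nothing (they
#' are skipped, not counted as zero); a player with no eligible session gets
#' `NA`.
#'
#' @param session_wagers Output of [build_sessions()].
#' @return A tibble with one row per player: `player_id`, `within_session`,
#'   `n_sessions_within` (number of eligible sessions averaged).
#' @export
within_session_chasing <- function(session_wagers) {
  per_session <- session_wagers %>%
    group_by(.data$player_id, .data$session) %>%
    summarise(
      rho = if (dplyr::n() >= 3) .rho_vs_order(.data$amount) else NA_real_,
      .groups = "drop"
    )
  per_session %>%
    group_by(.data$player_id) %>%
    summarise(
      within_session = if (any(!is.na(.data$rho))) {
        mean(.data$rho, na.rm = TRUE)
      } else {
        NA_real_
      },
      n_sessions_within = sum(!is.na(.data$rho)),
      .groups = "drop"
    )
}

# generic lagged-pair rank correlation used by the across-session and
# across-days metrics: pairs (loss of period t-1, wagered of period t),
# keeping only pairs flagged valid; NA unless >= min_pairs and both
# coordinates non-constant
.lagged_pair_rho <- function(loss, wagered, valid_pair, min_pairs) {
  prev_loss <- loss[-length(loss)]
  next_wager <- wagered[-1]
  keep <- valid_pair
  x <- prev_loss[keep]
  y <- next_wager[keep]
  n_pairs <- length(x)
  rho <- if (n_pairs >= max(min_pairs, 2)) spearman_rho(x, y) else NA_real_
  list(rho = rho, n_pairs = n_pairs)
}

#' Across-session chasing: wagering more after a bigger session loss
#'
#' Pairs each session's loss (won minus wagered; net losses are negative)
#' with the next session's total amount wagered, keeping only pairs of
#' consecutive sessions that happened within `pair_window_hours` of each
#' other (measured from the end of the earlier session to the start of the
#' later one), and returns the Spearman correlation over a player's pairs.
#' A negative value means larger losses are followed by larger wagering —
#' the loss-chasing signature. Undefined (`NA`) with fewer than `min_pairs`
#' pairs or a constant coordinate.
#'
#' @param session_summaries Output of [summarize_sessions()].
#' @param pair_window_hours Maximum end-to-start gap between paired
#'   sessions, in hours. Default 24.
#' @param min_pairs Minimum number of pairs for the correlation to be
#'   defined. Default 3.
#' @return A tibble with `player_id`, `across_session`, `n_session_pairs`.
#' @export
across_session_chasing <- function(session_summaries, pair_window_hours = 24,
                                   min_pairs = 3) {
  win_s <- pair_window_hours * 3600
  session_summaries %>%
    arrange(.data$player_id, .data$session) %>%
    group_by(.data$player_id) %>%
    summarise(
      .res = {
        if (dplyr::n() < 2) {
          list(list(rho = NA_real_, n_pairs = 0L))
        } else {
          gap <- as.numeric(.data$start[-1]) -
            as.numeric(.data$end[-dplyr::n()])
          list(.lagged_pair_rho(
            .data$loss, .data$total_wagered, gap <= win_s, min_pairs
          ))
        }
      },
      .groups = "drop"
    ) %>%
    mutate(
      across_session = purrr::map_dbl(.data$.res, "rho"),
      n_session_pairs = purrr::map_int(.data$.res, ~ as.integer(.x$n_pairs))
    ) %>%
    select("player_id", "across_session", "n_session_pairs")
}

#' Across-days chasing: wagering more the day after a bigger daily loss
#'
#' The day-level analogue of [across_session_chasing()]: pairs each gambling
#' day's loss with the next day's total wagered, keeping only pairs of
#' consecutive calendar dates.
#'
#' @param day_summaries Output of [aggregate_days()].
#' @param min_pairs Minimum number of pairs for the correlation to be
#'   defined. Default 3.
#' @return A tibble with `player_id`, `across_days`, `n_day_pairs`.
#' @export
across_days_chasing <- function(day_summaries, min_pairs = 3) {
  day_summaries %>%
    arrange(.data$player_id, .data$date) %>%
    group_by(.data$player_id) %>%
    summarise(
      .res = {
        if (dplyr::n() < 2) {
          list(list(rho = NA_real_, n_pairs = 0L))
        } else {
          consec <- diff(as.integer(.data$date)) == 1L
          list(.lagged_pair_rho(
            .data$loss, .data$total_wagered, consec, min_pairs
          ))
        }
      },
      .groups = "drop"
    ) %>%
    mutate(
      across_days = purrr::map_dbl(.data$.res, "rho"),
      n_day_pairs = purrr::map_int(.data$.res, ~ as.integer(.x$n_pairs))
    ) %>%
    select("player_id", "across_days", "n_day_pairs")
}

#' Regular account depletion: sessions ending with a near-empty account
#'
#' Fraction of a player's sessions whose end-of-session balance is strictly
#' below `threshold` currency units (default 5, the published cut-off).
#'
#' @inheritParams across_session_chasing
#' @param threshold Balance threshold in currency units; strictly-below
#'   counts. Default 5.
#' @return A tibble with `player_id`, `depletion_rate`, `n_sessions`.
#' @export
account_depletion_rate <- function(session_summaries, threshold = 5) {
  session_summaries %>%
    group_by(.data$player_id) %>%
    summarise(
      depletion_rate = mean(.data$end_balance < threshold),
      n_sessions = dplyr::n(),
      .groups = "drop"
    )
}

#' Frequent session depositing: sessions with more than one deposit
#'
#' Fraction of a player's sessions containing strictly more than one
#' monetary deposit.
#'
#' @inheritParams across_session_chasing
#' @return A tibble with `player_id`, `frequent_deposit_rate`, `n_sessions`.
#' @export
frequent_session_depositing <- function(session_summaries) {
  session_summaries %>%
    group_by(.data$player_id) %>%
    summarise(
      frequent_deposit_rate = mean(.data$deposit_count > 1),
      n_sessions = dplyr::n(),
      .groups = "drop"
    )
}

#' Compute all five chasing metrics for every player in a log
#'
#' Runs sessionization and day aggregation, then the five per-player
#' loss-chasing metrics. A player is `eligible` when all five metrics are
#' defined; undefined metrics are `NA`, never an error.
#'
#' @param transactions A transaction tibble (one or many players).
#' @param gap_minutes Inter-wager session gap in minutes. Default 15.
#' @param depletion_threshold End-balance threshold in currency units for
#'   the depletion metric. Default 5.
#' @param pair_window_hours Session-pairing window in hours for the
#'   across-session metric. Default 24.
#' @param min_pairs Minimum pairs for the across-session and across-days
#'   correlations. Default 3.
#' @param tz Timezone for the day boundary. Default `"UTC"`.
#'
#' @return A tibble with one row per player appearing in the log:
#'   `player_id`, the five metrics (`within_session`, `across_session`,
#'   `across_days`, `depletion_rate`, `frequent_deposit_rate`), `eligible`,
#'   and diagnostics (`n_sessions`, `n_days`, `n_sessions_within`,
#'   `n_session_pairs`, `n_day_pairs`). Players with zero wagers get all
#'   metrics `NA`.
#' @examples
#' cohort <- generate_cohort(n_players = 5, seed = 1)
#' chasing_metrics(cohort$transactions)
#' @export
chasing_metrics <- function(transactions, gap_minutes = 15,
                            depletion_threshold = 5, pair_window_hours = 24,
                            min_pairs = 3, tz = "UTC") {
  tx <- as_tibble(transactions)
  all_players <- tibble(player_id = unique(tx$player_id))

  sw <- build_sessions(tx, gap_minutes)
  ss <- summarize_sessions(tx, gap_minutes)
  dd <- aggregate_days(tx, tz)

  if (nrow(ss) == 0) {
    out <- all_players %>%
      mutate(
        within_session = NA_real_, across_session = NA_real_,
        across_days = NA_real_, depletion_rate = NA_real_,
        frequent_deposit_rate = NA_real_, eligible = FALSE,
        n_sessions = 0L, n_days = 0L, n_sessions_within = 0L,
        n_session_pairs = 0L, n_day_pairs = 0L
      )
    return(out)
  }

  m_within <- within_session_chasing(sw)
  m_across_s <- across_session_chasing(ss, pair_window_hours, min_pairs)
  m_across_d <- across_days_chasing(dd, min_pairs)
  m_depl <- account_depletion_rate(ss, depletion_threshold)
  m_freq <- frequent_session_depositing(ss) %>%
    select("player_id", "frequent_deposit_rate")
  n_days <- dd %>% count(.data$player_id, name = "n_days")

  out <- all_players %>%
    left_join(m_within, by = "player_id") %>%
    left_join(m_across_s, by = "player_id") %>%
    left_join(m_across_d, by = "player_id") %>%
    left_join(m_depl, by = "player_id") %>%
    left_join(m_freq, by = "player_id") %>%
    left_join(n_days, by = "player_id") %>%
    mutate(
      across(
        c("n_sessions", "n_days", "n_sessions_within", "n_session_pairs",
          "n_day_pairs"),
        ~ as.integer(dplyr::coalesce(.x, 0L))
      ),
      eligible = !is.na(.data$within_session) &
        !is.na(.data$across_session) & !is.na(.data$across_days) &
        !is.na(.data$depletion_rate) & !is.na(.data$frequent_deposit_rate)
    ) %>%
    select(
      "player_id", "within_session", "across_session", "across_days",
      "depletion_rate", "frequent_deposit_rate", "eligible",
      "n_sessions", "n_days", "n_sessions_within", "n_session_pairs",
      "n_day_pairs"
    )
  out
}

#' Keep only players with all five chasing metrics defined
#'
#' @param metrics Output of [chasing_metrics()].
#' @return The eligible subset of `metrics`.
#' @seealso [exclusion_report()] for who was dropped and why.
#' @export
filter_eligible <- function(metrics) {
  filter(metrics, .data$eligible)
}

#' Count exclusions by which metric was undefined
#'
#' A player can be counted under several metrics when more than one is
#' undefined.
#'
#' @param metrics Output of [chasing_metrics()].
#' @return A tibble with `metric`, `n_undefined`, plus one `total_excluded`
#'   attribute-free summary row is not added; combine with
#'   [filter_eligible()] for the retained set.
#' @export
exclusion_report <- function(metrics) {
  ineligible <- filter(metrics, !.data$eligible)
  metric_cols <- c(
    "within_session", "across_session", "across_days",
    "depletion_rate", "frequent_deposit_rate"
  )
  tibble(
    metric = metric_cols,
    n_undefined = vapply(
      metric_cols, function(col) sum(is.na(ineligible[[col]])), integer(1)
    ),
    n_excluded_total = nrow(ineligible)
  )
}
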