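#' Partition wagers into gambling sessions by the inter-wager gap rule
#'
#' A session is a maximal run of a player's wagers in which consecutive
#' wagers are separated by at most `gap_minutes` ("within 15 min" is read
#' inclusively: a gap of exactly 15:00 keeps the two wagers in one session).
#' Non-wager events play no role in session membership and never bridge a
#' longer gap.
#'
#' @param transactions A transaction tibble covering one or many players.
#' @param gap_minutes Maximum inter-wager gap inside a session, in minutes.
#'   Default 15.
#'
#' @return A tibble of the wager rows with columns `player_id`, `session`
#'   (1-based ordinal within player), `wager_index` (1..n within session),
#'   `timestamp`, `amount`, `balance_after`. Players with no wagers
#'   contribute no rows.
#' @examples
#' tx <- generate_cohort(n_players = 1, seed = 1)$transactions
#' build_sessions(tx)
#' @export
build_sessions <- function(transactions, gap_minutes = 15) {
  stopifnot(gap_minutes > 0)
  w <- as_tibble(transactions) %>%
    filter(.data$event_type == "WAGER") %>%
    arrange(.data$player_id, .data$timestamp)
  if (nrow(w) == 0) {
    return(tibble(
      player_id = character(), session = integer(), wager_index = integer(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      amount = numeric(), balance_after = numeric()
    ))
  }
  gap_s <- gap_minutes * 60
  w %>%
    group_by(.data$player_id) %>%
    mutate(
      .gap = as.numeric(.data$timestamp) - lag(as.numeric(.data$timestamp)),
      session = cumsum(is.na(.data$.gap) | .data$.gap > gap_s),
      session = as.integer(.data$session)
    ) %>%
    group_by(.data$player_id, .data$session) %>%
    mutate(wager_index = row_number()) %>%
    ungroup() %>%
    select(
      "player_id", "session", "wager_index", "timestamp", "amount",
      "balance_after"
    )
}

# Session window table used for event attachment: one row per session with
# first/last wager instants (numeric seconds).
session_windows <- function(session_wagers) {
  if (nrow(session_wagers) == 0) {
    return(tibble(
      player_id = character(), session = integer(),
      first_wager = numeric(), last_wager = numeric()
    ))
  }
  session_wagers %>%
    group_by(.data$player_id, .data$session) %>%
    summarise(
      first_wager = min(as.numeric(.data$timestamp)),
      last_wager = max(as.numeric(.data$timestamp)),
      .groups = "drop"
    )
}

#' Attach non-wager events to reconstructed sessions
#'
#' Deposits are assigned to a session when they fall in
#' `[first_wager - gap, last_wager]`: money is typically loaded just before
#' or during play. Wins and withdrawals settle after play, so they are
#' assigned on `[first_wager, last_wager + gap]`. Whenever windows of
#' adjacent sessions could compete, the earlier session wins; events falling
#' in no window are returned with `session = NA` rather than dropped.
#'
#' @inheritParams build_sessions
#' @return A tibble of the non-wager rows with an added integer `session`
#'   column (`NA` for unassigned events).
#' @export
attach_events <- function(transactions, gap_minutes = 15) {
  tx <- as_tibble(transactions)
  ev <- tx %>%
    filter(.data$event_type != "WAGER") %>%
    arrange(.data$player_id, .data$timestamp)
  win <- session_windows(build_sessions(tx, gap_minutes))
  gap_s <- gap_minutes * 60
  if (nrow(ev) == 0 || nrow(win) == 0) {
    ev$session <- rep(NA_integer_, nrow(ev))
    return(ev)
  }
  assign_group <- function(e, w) {
    t <- as.numeric(e$timestamp)
    is_dep <- e$event_type == "DEPOSIT"
    # deposit windows: [first - gap, last]; win/withdrawal: [first, last + gap]
    dep_idx <- findInterval(t, w$first_wager - gap_s)
    dep_ok <- dep_idx >= 1 & t <= w$last_wager[pmax(dep_idx, 1)]
    set_idx <- findInterval(t, w$first_wager)
    set_ok <- set_idx >= 1 & t <= (w$last_wager + gap_s)[pmax(set_idx, 1)]
    sess <- ifelse(is_dep,
      ifelse(dep_ok, w$session[pmax(dep_idx, 1)], NA_integer_),
      ifelse(set_ok, w$session[pmax(set_idx, 1)], NA_integer_)
    )
    e$session <- as.integer(sess)
    e
  }
  ev %>%
    group_by(.data$player_id) %>%
    dplyr::group_modify(function(e, key) {
      w <- win[win$player_id == key$player_id, ]
      if (nrow(w) == 0) {
        e$session <- NA_integer_
        return(e)
      }
      assign_group(e, w[order(w$first_wager), ])
    }) %>%
    ungroup()
}

#' Summarise reconstructed sessions
#'
#' Computes, per session: total amount wagered, total amount won, the session
#' loss (won minus wagered, so net losses are negative), the end-of-session
#' account balance (the `balance_after` of the chronologically last attached
#' transaction — a final win or withdrawal settles after the last wager and
#' is the balance the player actually ends with), and the number of attached
#' deposits.
#'
#' @inheritParams build_sessions
#' @return A tibble with one row per (player, session): `player_id`,
#'   `session`, `first_wager_time`, `last_wager_time`, `session_time_min`,
#'   `n_wagers`, `total_wagered`, `total_won`, `loss`, `end_balance`,
#'   `deposit_count`, `start`, `end` (first/last attached event instants).
#' @export
summarize_sessions <- function(transactions, gap_minutes = 15) {
  sw <- build_sessions(transactions, gap_minutes)
  if (nrow(sw) == 0) {
    return(tibble(
      player_id = character(), session = integer(),
      first_wager_time = as.POSIXct(character(), tz = "UTC"),
      last_wager_time = as.POSIXct(character(), tz = "UTC"),
      session_time_min = numeric(), n_wagers = integer(),
      total_wagered = numeric(), total_won = numeric(), loss = numeric(),
      end_balance = numeric(), deposit_count = integer(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC")
    ))
  }
  ev <- attach_events(transactions, gap_minutes)

  wsum <- sw %>%
    group_by(.data$player_id, .data$session) %>%
    summarise(
      first_wager_time = min(.data$timestamp),
      last_wager_time = max(.data$timestamp),
      n_wagers = dplyr::n(),
      total_wagered = sum(.data$amount),
      .last_wager_balance = .data$balance_after[which.max(as.numeric(.data$timestamp))],
      .groups = "drop"
    )

  attached <- filter(ev, !is.na(.data$session))
  if (nrow(attached) == 0) {
    esum <- tibble(
      player_id = character(), session = integer(), total_won = numeric(),
      deposit_count = integer(), .ev_last_time = numeric(),
      .ev_last_balance = numeric(), .ev_first_time = numeric()
    )
  } else {
    esum <- attached %>%
      group_by(.data$player_id, .data$session) %>%
      summarise(
        total_won = sum(.data$amount[.data$event_type == "WIN"]),
        deposit_count = sum(.data$event_type == "DEPOSIT"),
        .ev_last_time = max(as.numeric(.data$timestamp)),
        .ev_last_balance = .data$balance_after[which.max(as.numeric(.data$timestamp))],
        .ev_first_time = min(as.numeric(.data$timestamp)),
        .groups = "drop"
      )
  }

  out <- wsum %>%
    left_join(esum, by = c("player_id", "session")) %>%
    mutate(
      total_won = dplyr::coalesce(.data$total_won, 0),
      deposit_count = as.integer(dplyr::coalesce(.data$deposit_count, 0L)),
      loss = .data$total_won - .data$total_wagered,
      session_time_min =
        as.numeric(.data$last_wager_time) - as.numeric(.data$first_wager_time),
      session_time_min = .data$session_time_min / 60,
      end_balance = ifelse(
        !is.na(.data$.ev_last_time) &
          .data$.ev_last_time > as.numeric(.data$last_wager_time),
        .data$.ev_last_balance, .data$.last_wager_balance
      ),
      start = as.POSIXct(
        pmin(as.numeric(.data$first_wager_time), .data$.ev_first_time,
          na.rm = TRUE
        ),
        origin = "1970-01-01", tz = "UTC"
      ),
      end = as.POSIXct(
        pmax(as.numeric(.data$last_wager_time), .data$.ev_last_time,
          na.rm = TRUE
        ),
        origin = "1970-01-01", tz = "UTC"
      )
    ) %>%
    select(
      "player_id", "session", "first_wager_time", "last_wager_time",
      "session_time_min", "n_wagers", "total_wagered", "total_won", "loss",
      "end_balance", "deposit_count", "start", "end"
    ) %>%
    arrange(.data$player_id, .data$session)
  out
}

#' Aggregate wagers and wins to calendar days
#'
#' One record per (player, calendar date) with at least one wager, in the
#' configured timezone. The day loss is total won minus total wagered over
#' that date; wins falling on a date with no wager are not part of any day
#' record.
#'
#' @inheritParams build_sessions
#' @param tz Timezone defining the day boundary. Default `"UTC"`.
#' @return A tibble with `player_id`, `date`, `n_wagers`, `total_wagered`,
#'   `total_won`, `loss`, sorted by player and date.
#' @export
aggregate_days <- function(transactions, tz = "UTC") {
  tx <- as_tibble(transactions) %>%
    filter(.data$event_type %in% c("WAGER", "WIN")) %>%
    mutate(date = as.Date(.data$timestamp, tz = tz))
  day <- tx %>%
    group_by(.data$player_id, .data$date) %>%
    summarise(
      n_wagers = sum(.data$event_type == "WAGER"),
      total_wagered = sum(.data$amount[.data$event_type == "WAGER"]),
      total_won = sum(.data$amount[.data$event_type == "WIN"]),
      .groups = "drop"
    ) %>%
    filter(.data$n_wagers >= 1) %>%
    mutate(loss = .data$total_won - .data$total_wagered) %>%
    arrange(.data$player_id, .data$date)
  day
}
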