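# helper: fabricate a build_sessions()-shaped wager table
session_wager_tbl <- function(amount_lists, player_id = "P1") {
  purrr::imap_dfr(amount_lists, function(a, s) {
    tibble::tibble(
      player_id = player_id, session = as.integer(s),
      wager_index = seq_along(a),
      timestamp = BASE_TIME + (s * 100 + seq_along(a)) * 60,
      amount = a, balance_after = 0
    )
  })
}

# helper: fabricate a summarize_sessions()-shaped summary table with
# hour-spaced sessions
session_summary_tbl <- function(loss, wagered = rep(10, length(loss)),
                                end_balance = rep(10, length(loss)),
                                deposit_count = rep(1L, length(loss)),
                                gap_hours = rep(1, length(loss) - 1),
                                player_id = "P1") {
  n <- length(loss)
  starts <- BASE_TIME + c(0, cumsum(gap_hours + 0.5)) * 3600
  tibble::tibble(
    player_id = player_id, session = seq_len(n),
    first_wager_time = starts, last_wager_time = starts + 1800,
    session_time_min = 30, n_wagers = 5L,
    total_wagered = wagered, total_won = wagered + loss, loss = loss,
    end_balance = end_balance, deposit_count = as.integer(deposit_count),
    start = starts, end = starts + 1800
  )
}

test_that("spearman_rho matches the d-squared and average-rank oracles", {
  expect_equal(spearman_rho(1:3, 1:3), 1.0)
  # distinct ranks: 1 - 6 * sum(d^2) / (n (n^2 - 1)), sum(d^2) = 6
  expect_equal(spearman_rho(c(3, 1, 2), c(1, 2, 3)), 1 - 6 * 6 / (3 * 8))
  expect_true(is.na(spearman_rho(c(5, 5, 5), 1:3)))
  # tied pair: average ranks by hand give 4.5 / sqrt(22.5)
  expect_equal(spearman_rho(c(1, 2, 2, 3), 1:4), 4.5 / sqrt(22.5))
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(1, 1), "at least 2")

  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- rnorm(n)
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y))
    expect_equal(
      spearman_rho(x, y),
      suppressWarnings(cor(x, y, method = "spearman"))
    )
  }
})

test_that("within-session chasing averages eligible sessions only", {
  sw <- session_wager_tbl(list(c(1, 2, 3), c(3, 2, 1), c(2, 2)))
  r <- within_session_chasing(sw)
  expect_equal(r$within_session, 0) # (+1 - 1) / 2, third session skipped
  expect_equal(r$n_sessions_within, 2L)

  expect_true(is.na(within_session_chasing(
    session_wager_tbl(list(c(5, 5, 5)))
  )$within_session))

  # ranks (1.5, 1.5, 3) against (1, 2, 3)
  r3 <- within_session_chasing(session_wager_tbl(list(c(1, 1, 2))))
  expect_equal(r3$within_session, spearman_oracle(c(1, 1, 2), 1:3))
  expect_equal(round(r3$within_session, 3), 0.866)
})

test_that("across-session chasing pairs consecutive sessions within the window", {
  # all gaps < 24 h: losses (-10, -2, -30) vs next wagers (5, 50)
  # full example: 4 sessions so 3 pairs exist
  ss <- session_summary_tbl(
    loss = c(-10, -2, -30, -1), wagered = c(20, 5, 50, 8)
  )
  r <- across_session_chasing(ss)
  expect_equal(r$n_session_pairs, 3L)
  expect_equal(
    r$across_session,
    spearman_oracle(c(-10, -2, -30), c(5, 50, 8))
  )

  # losses (-10, -2, -30) followed by wagers (20, 5, 50): the bigger the
  # loss, the bigger the next wager -> perfect chasing signature, rho = -1
  ss2 <- session_summary_tbl(loss = c(-10, -2, -30, -5), wagered = c(9, 20, 5, 50))
  expect_equal(across_session_chasing(ss2)$across_session, -1)

  # a 30-hour gap drops that pair below min_pairs -> undefined
  ss3 <- session_summary_tbl(
    loss = c(-10, -2, -30, -1), wagered = c(20, 5, 50, 8),
    gap_hours = c(1, 1, 30)
  )
  r3 <- across_session_chasing(ss3)
  expect_equal(r3$n_session_pairs, 2L)
  expect_true(is.na(r3$across_session))

  # constant next-session wagers -> zero variance -> undefined
  ss4 <- session_summary_tbl(loss = c(-1, -2, -3, -4), wagered = rep(10, 4))
  expect_true(is.na(across_session_chasing(ss4)$across_session))
})

test_that("across-days chasing uses consecutive calendar dates only", {
  day_tbl <- function(dates, loss, wagered) {
    tibble::tibble(
      player_id = "P1", date = as.Date(dates), n_wagers = 5L,
      total_wagered = wagered, total_won = wagered + loss, loss = loss
    )
  }
  d <- day_tbl(
    c("2021-12-01", "2021-12-02", "2021-12-03", "2021-12-04"),
    loss = c(-5, -50, -1, -3), wagered = c(7, 10, 100, 2)
  )
  r <- across_days_chasing(d)
  expect_equal(r$n_day_pairs, 3L)
  expect_equal(r$across_days, spearman_oracle(c(-5, -50, -1), c(10, 100, 2)))

  # no consecutive days -> no pairs
  d2 <- day_tbl(c("2021-12-01", "2021-12-03"), c(-5, -2), c(10, 10))
  r2 <- across_days_chasing(d2)
  expect_equal(r2$n_day_pairs, 0L)
  expect_true(is.na(r2$across_days))

  # identical loss every day -> constant vector -> undefined
  d3 <- day_tbl(
    c("2021-12-01", "2021-12-02", "2021-12-03", "2021-12-04"),
    loss = rep(-5, 4), wagered = c(1, 2, 3, 4)
  )
  expect_true(is.na(across_days_chasing(d3)$across_days))
})

test_that("depletion and frequent-deposit rates use strict thresholds", {
  ss <- session_summary_tbl(
    loss = rep(-1, 4), end_balance = c(4.99, 5.00, 0.00, 10.00),
    deposit_count = c(0L, 1L, 2L, 3L)
  )
  expect_equal(account_depletion_rate(ss, threshold = 5)$depletion_rate, 0.5)
  expect_equal(frequent_session_depositing(ss)$frequent_deposit_rate, 0.5)

  ss_all_high <- session_summary_tbl(
    loss = rep(-1, 3), end_balance = c(6, 7, 8), deposit_count = rep(0L, 3)
  )
  expect_equal(account_depletion_rate(ss_all_high)$depletion_rate, 0)
  expect_equal(frequent_session_depositing(ss_all_high)$frequent_deposit_rate, 0)

  ss_one <- session_summary_tbl(
    loss = -1, end_balance = 0, deposit_count = 2L, gap_hours = numeric(0)
  )
  expect_equal(account_depletion_rate(ss_one)$depletion_rate, 1)
  expect_equal(frequent_session_depositing(ss_one)$frequent_deposit_rate, 1)
})

test_that("player metrics compose the five metrics with eligibility", {
  # one 3-wager increasing session, two deposits, end balance 1
  tx <- make_tx(
    c(-2, -1, 0, 1, 2),
    c("DEPOSIT", "DEPOSIT", "WAGER", "WAGER", "WAGER"),
    c(4, 3, 1, 2, 3)
  )
  m <- chasing_metrics(tx)
  expect_equal(m$within_session, 1)
  expect_equal(m$depletion_rate, 1)
  expect_equal(m$frequent_deposit_rate, 1)
  expect_true(is.na(m$across_session))
  expect_true(is.na(m$across_days))
  expect_false(m$eligible)

  # a rich generated player has everything defined
  coh <- generate_cohort(preset_paper(), 1, seed = 5, groups = "high")
  m2 <- chasing_metrics(coh$transactions)
  expect_true(m2$eligible)

  # no wagers at all: every metric undefined
  tx3 <- make_tx(0, "DEPOSIT", 10)
  m3 <- chasing_metrics(tx3)
  expect_true(all(is.na(m3[, c(
    "within_session", "across_session", "across_days",
    "depletion_rate", "frequent_deposit_rate"
  )])))
  expect_false(m3$eligible)
})

test_that("eligibility filter retains eligible players and explains exclusions", {
  coh <- small_cohort(n = 25, seed = 8)
  m <- chasing_metrics(coh$transactions)
  kept <- filter_eligible(m)
  expect_true(all(kept$eligible))
  rep <- exclusion_report(m)
  expect_equal(rep$n_excluded_total[1], nrow(m) - nrow(kept))
  expect_setequal(rep$metric, c(
    "within_session", "across_session", "across_days",
    "depletion_rate", "frequent_deposit_rate"
  ))
  # every excluded player has at least one undefined metric counted
  if (nrow(m) > nrow(kept)) expect_gt(sum(rep$n_undefined), 0)
})

test_that("correlation metrics are scale invariant; depletion is not", {
  coh <- small_cohort(n = 10, seed = 31)
  tx <- coh$transactions
  # a power-of-two factor scales exactly in floating point, so money ties
  # (which decide average ranks) are preserved bit for bit
  scaled <- dplyr::mutate(tx, dplyr::across(
    c(amount, balance_before, balance_after), ~ .x * 4
  ))
  m1 <- chasing_metrics(tx)
  m2 <- chasing_metrics(scaled)
  expect_equal(m2$within_session, m1$within_session, tolerance = 1e-12)
  expect_equal(m2$across_session, m1$across_session, tolerance = 1e-12)
  expect_equal(m2$across_days, m1$across_days, tolerance = 1e-12)
  expect_equal(m2$frequent_deposit_rate, m1$frequent_deposit_rate)
  # scaling threshold with the money restores the depletion rate
  m3 <- chasing_metrics(scaled, depletion_threshold = 20)
  expect_equal(m3$depletion_rate, m1$depletion_rate)
})

test_that("reversing a session's wager order negates its correlation", {
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1))
    fwd <- within_session_chasing(session_wager_tbl(list(a)))$within_session
    rev_ <- within_session_chasing(session_wager_tbl(list(rev(a))))$within_session
    if (is.na(fwd)) {
      expect_true(is.na(rev_))
    } else {
      expect_equal(rev_, -fwd, tolerance = 1e-12)
    }
  }
})
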