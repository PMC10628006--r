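# shared fixture builders and independent oracles

BASE_TIME <- as.POSIXct("2021-12-01 10:00:00", tz = "UTC")

# build a chain-consistent one-player log from event specs; balances are
# walked forward from start_balance so the ledger is valid by construction
make_tx <- function(minutes, types, amounts, player_id = "P1",
                    start_balance = 0, base = BASE_TIME) {
  stopifnot(length(minutes) == length(types), length(types) == length(amounts))
  signed <- ifelse(types %in% c("DEPOSIT", "WIN"), amounts, -amounts)
  after <- start_balance + cumsum(signed)
  tibble::tibble(
    player_id = player_id,
    timestamp = base + minutes * 60,
    event_type = types,
    amount = amounts,
    balance_before = after - signed,
    balance_after = after
  )
}

# wager-only log at given minute marks, unit stakes
make_wagers <- function(minutes, amounts = rep(1, length(minutes)),
                        player_id = "P1", base = BASE_TIME) {
  make_tx(minutes, rep("WAGER", length(minutes)), amounts,
    player_id = player_id, start_balance = sum(amounts), base = base
  )
}

# independent brute-force sessionizer: walks sorted times and opens a new
# group whenever the gap to the previous wager exceeds gap_s
brute_split <- function(times_s, gap_s) {
  times_s <- sort(times_s)
  g <- integer(length(times_s))
  cur <- 1L
  g[1] <- 1L
  for (i in seq_along(times_s)[-1]) {
    if (times_s[i] - times_s[i - 1] > gap_s) cur <- cur + 1L
    g[i] <- cur
  }
  g
}

# independent Spearman oracle: explicit average ranks + the Pearson
# product-moment formula written out by hand
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    s <- sort(v)
    vapply(v, function(vi) mean(which(s == vi)), numeric(1))
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) NA_real_ else num / den
}

# small preset cohort reused across tests
small_cohort <- function(n = 30, seed = 42, groups = NULL) {
  generate_cohort(preset_paper(), n_players = n, seed = seed, groups = groups)
}
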