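#' Behavioral profile of one risk group for the cohort generator
#'
#' Bundles the per-group parameters the generator draws from: how many
#' sessions and active days a player has, the session-level wagered-amount
#' and loss marginals, the probability a session is a multi-deposit session
#' or ends depleted, the within-session stake drift, and the rank
#' correlation coupling one session's loss to the next session's wagering.
#'
#' @param label Group label, e.g. `"low"`, `"medium"`, `"high"`.
#' @param share Cohort share in `[0, 1]`.
#' @param sessions_mean,sessions_sd Mean and sd of the per-player session
#'   count (negative-binomial marginal, floored at 1).
#' @param days_mean,days_sd Mean and sd of the number of active days the
#'   sessions are spread over (normal draw, clamped).
#' @param wagers_lambda Per-session wager count is `1 + Poisson(lambda)`;
#'   the default 6 gives `P(n >= 3) = 1 - ppois(1, 6)`, about 0.983, so
#'   nearly all sessions qualify for the within-session correlation.
#' @param wager_meanlog,wager_sdlog Log-normal location/scale of the total
#'   amount wagered per session, in currency units.
#' @param rtp Return-to-player ratio in `(0, 1)`; sets the location of the
#'   session-loss marginal so that the expected net loss is
#'   `(1 - rtp)` times the expected session wagering.
#' @param loss_sdlog Log-scale spread of the session net-loss magnitude.
#' @param extra_deposit_prob Probability a session carries more than one
#'   deposit (the frequent-session-depositing event).
#' @param depletion_prob Probability a session ends with balance below the
#'   depletion threshold.
#' @param within_trend Monotone within-session stake drift `delta`; 0 makes
#'   wager amounts exchangeable within a session (zero expected
#'   within-session correlation), positive values scale the j-th wager by
#'   `exp(delta * (j-1)/(n-1))` before renormalization.
#' @param across_session_rho Target Spearman correlation between a
#'   session's loss and the next session's total wagered, induced via a
#'   Gaussian copula.
#' @param across_days_rho Recorded day-level analogue. The generator's
#'   chain acts at session level; day-level rank dependence emerges from it
#'   and is not separately calibrated.
#' @param age_mean,age_sd Age marginal (normal, clamped to 18-90).
#' @param female_share Probability a player is recorded as female.
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(label, share, sessions_mean, sessions_sd,
                          days_mean, days_sd, wagers_lambda = 6,
                          wager_meanlog = log(60), wager_sdlog = 0.8,
                          rtp = 0.9, loss_sdlog = 0.6,
                          extra_deposit_prob = 0.1, depletion_prob = 0.6,
                          within_trend = 0, across_session_rho = 0,
                          across_days_rho = 0, age_mean = 41, age_sd = 11,
                          female_share = 0.5) {
  probs <- c(share, extra_deposit_prob, depletion_prob, female_share)
  if (any(probs < 0 | probs > 1)) {
    abort("share, extra_deposit_prob, depletion_prob and female_share must lie in [0, 1].")
  }
  if (abs(across_session_rho) >= 1) abort("across_session_rho must lie in (-1, 1).")
  if (rtp <= 0 || rtp >= 1) abort("rtp must lie in (0, 1).")
  if (sessions_mean <= 0 || sessions_sd <= 0) {
    abort("sessions_mean and sessions_sd must be positive.")
  }
  # loss-magnitude location chosen so E[loss magnitude] = (1 - rtp) E[wagered]
  expected_wagered <- exp(wager_meanlog + wager_sdlog^2 / 2)
  loss_meanlog <- log((1 - rtp) * expected_wagered) - loss_sdlog^2 / 2
  structure(
    list(
      label = label, share = share,
      sessions_mean = sessions_mean, sessions_sd = sessions_sd,
      days_mean = days_mean, days_sd = days_sd,
      wagers_lambda = wagers_lambda,
      wager_meanlog = wager_meanlog, wager_sdlog = wager_sdlog,
      rtp = rtp, loss_meanlog = loss_meanlog, loss_sdlog = loss_sdlog,
      extra_deposit_prob = extra_deposit_prob,
      depletion_prob = depletion_prob,
      within_trend = within_trend,
      across_session_rho = across_session_rho,
      across_days_rho = across_days_rho,
      age_mean = age_mean, age_sd = age_sd, female_share = female_share
    ),
    class = "group_profile"
  )
}

#' Generator configuration: group profiles plus cohort-level mechanics
#'
#' The intra-session inter-wager gap law has support strictly below the
#' session gap and the inter-session gap law strictly above it, so the
#' generator's intended sessions are recovered exactly by the sessionizer.
#'
#' @param profiles List of [group_profile()] objects; shares must sum to 1.
#' @param window_start First calendar day of the observation window.
#' @param n_window_days Number of days in the window. Default 31 (a
#'   December-style month).
#' @param gap_minutes Session gap the generated gaps must respect.
#'   Default 15.
#' @param depletion_threshold End-balance threshold in currency units.
#'   Default 5.
#' @param intra_gap_range_s Range (seconds) of inter-wager gaps inside a
#'   session; must stay below `gap_minutes`. Default `c(20, 120)`.
#' @param inter_gap_extra_min Range (minutes) added beyond the session gap
#'   between consecutive sessions. Default `c(5, 60)`.
#' @param day_start_hour Hour of day the first session of a day starts
#'   (plus up to one uniform hour). Default 17.
#' @param deposit_lead_s Range (seconds) a session's opening deposit
#'   precedes its first wager; must stay below the session gap.
#'   Default `c(60, 600)`.
#' @param extra_deposit_meanlog,extra_deposit_sdlog Log-normal size of
#'   additional (non-opening) deposits, currency units.
#' @param extra_count_lambda Number of additional deposits in a
#'   multi-deposit session is `1 + Poisson(lambda)`. Default 0.5.
#' @param end_balance_max Upper bound (currency units) for non-depleted
#'   end-of-session balances, drawn uniformly above the threshold.
#'   Default 200.
#' @param min_first_deposit Minimum opening-deposit size, currency units.
#'   Default 1.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(profiles,
                             window_start = as.Date("2021-12-01"),
                             n_window_days = 31,
                             gap_minutes = 15,
                             depletion_threshold = 5,
                             intra_gap_range_s = c(20, 120),
                             inter_gap_extra_min = c(5, 60),
                             day_start_hour = 17,
                             deposit_lead_s = c(60, 600),
                             extra_deposit_meanlog = log(20),
                             extra_deposit_sdlog = 0.5,
                             extra_count_lambda = 0.5,
                             end_balance_max = 200,
                             min_first_deposit = 1) {
  if (!is.list(profiles) || !all(vapply(profiles, inherits, logical(1), "group_profile"))) {
    abort("`profiles` must be a list of group_profile objects.")
  }
  shares <- vapply(profiles, `[[`, numeric(1), "share")
  if (abs(sum(shares) - 1) > 1e-8) abort("Group shares must sum to 1.")
  if (max(intra_gap_range_s) >= gap_minutes * 60) {
    abort("Intra-session gaps must stay strictly below the session gap.")
  }
  if (min(inter_gap_extra_min) <= 0) {
    abort("Inter-session gaps must exceed the session gap strictly.")
  }
  if (max(deposit_lead_s) >= gap_minutes * 60) {
    abort("Opening-deposit lead must stay below the session gap so it attaches.")
  }
  names(profiles) <- vapply(profiles, `[[`, character(1), "label")
  structure(
    list(
      profiles = profiles, window_start = window_start,
      n_window_days = n_window_days, gap_minutes = gap_minutes,
      depletion_threshold = depletion_threshold,
      intra_gap_range_s = intra_gap_range_s,
      inter_gap_extra_min = inter_gap_extra_min,
      day_start_hour = day_start_hour,
      deposit_lead_s = deposit_lead_s,
      extra_deposit_meanlog = extra_deposit_meanlog,
      extra_deposit_sdlog = extra_deposit_sdlog,
      extra_count_lambda = extra_count_lambda,
      end_balance_max = end_balance_max,
      min_first_deposit = min_first_deposit
    ),
    class = "generator_config"
  )
}

#' Generator preset calibrated to the published three-group cohort
#'
#' Group shares, session-count marginals, active-day counts, depletion and
#' multi-deposit probabilities, demographic marginals and across-session
#' rank-correlation targets are set to the published group-level summaries
#' of the December 2021 operator cohort; the remaining laws (wager
#' marginals, gap laws, deposit sizes) are unconstrained by the publication
#' and carry documented defaults.
#'
#' @return A `generator_config` with `"low"`, `"medium"` and `"high"`
#'   profiles.
#' @examples
#' cfg <- preset_paper()
#' sum(sapply(cfg$profiles, `[[`, "share")) # 1
#' @export
preset_paper <- function() {
  generator_config(list(
    group_profile(
      label = "low", share = 0.7713,
      sessions_mean = 20.97, sessions_sd = 15.02,
      days_mean = 10.93, days_sd = 5.4,
      extra_deposit_prob = 0.05, depletion_prob = 0.69,
      within_trend = 0, across_session_rho = 0.08, across_days_rho = 0.07,
      age_mean = 40.61, age_sd = 11.96, female_share = 0.52
    ),
    group_profile(
      label = "medium", share = 0.1644,
      sessions_mean = 32.00, sessions_sd = 25.78,
      days_mean = 13.76, days_sd = 6.86,
      extra_deposit_prob = 0.13, depletion_prob = 0.65,
      within_trend = 0, across_session_rho = 0.06, across_days_rho = 0.09,
      age_mean = 41.57, age_sd = 11.72, female_share = 0.46
    ),
    group_profile(
      label = "high", share = 0.0643,
      sessions_mean = 39.01, sessions_sd = 30.54,
      days_mean = 15.02, days_sd = 7.02,
      extra_deposit_prob = 0.18, depletion_prob = 0.64,
      within_trend = 0, across_session_rho = 0.05, across_days_rho = 0.08,
      age_mean = 41.41, age_sd = 10.64, female_share = 0.43
    )
  ))
}

#' Coupled session totals: a latent-Gaussian loss-to-wager chain
#'
#' Draws a sequence of (total wagered, loss) session pairs in which the
#' amount wagered in session t has Gaussian-copula rank correlation `rho`
#' with the loss of session t-1 (latent Pearson correlation
#' `2 sin(pi rho / 6)`), while both marginals are preserved: wagered totals
#' are log-normal and losses are negative log-normal magnitudes, truncated
#' at `-total_wagered` so the implied session win is never negative.
#'
#' @param n Number of sessions.
#' @param rho Target Spearman correlation in `(-1, 1)` between a session's
#'   loss and the next session's wagered total.
#' @param wager_meanlog,wager_sdlog Log-normal parameters of the wagered
#'   total.
#' @param loss_meanlog,loss_sdlog Log-normal parameters of the loss
#'   magnitude (losses are emitted negative).
#' @return A tibble with `total_wagered` and `loss`, one row per session,
#'   drawn from the current RNG state.
#' @export
session_total_chain <- function(n, rho, wager_meanlog = log(60),
                                wager_sdlog = 0.8, loss_meanlog = log(8),
                                loss_sdlog = 0.6) {
  if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
  if (wager_sdlog <= 0 || loss_sdlog <= 0) {
    abort("Log-normal scale parameters must be positive.")
  }
  r <- 2 * sin(pi * rho / 6)
  z <- rnorm(n + 1) # z[t] is the loss latent of session t-1; z[t+1] of t
  eps <- rnorm(n)
  wlat <- r * z[seq_len(n)] + sqrt(1 - r^2) * eps
  total_wagered <- qlnorm(pnorm(wlat), wager_meanlog, wager_sdlog)
  loss <- -qlnorm(pnorm(-z[seq_len(n) + 1]), loss_meanlog, loss_sdlog)
  loss <- pmax(loss, -total_wagered)
  tibble(total_wagered = total_wagered, loss = loss)
}

# split an integer-cent total over weights, each part >= 1 cent,
# largest-remainder rounding so the parts sum exactly
split_cents <- function(total, weights) {
  k <- length(weights)
  if (k == 1) {
    return(total)
  }
  total <- max(total, k)
  p <- weights / sum(weights) * total
  base <- floor(p)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(p - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  # enforce the 1-cent floor, taking from the largest parts
  zero <- base < 1
  while (any(zero)) {
    need <- sum(1 - base[zero])
    base[zero] <- 1
    top <- which.max(base)
    base[top] <- base[top] - need
    zero <- base < 1
  }
  base
}

#' Generate one player's balance-consistent transaction history
#'
#' Draws the player's session count, spreads sessions over a consecutive
#' run of active days, draws per-session wager counts and coupled
#' (wagered, loss) totals from the latent chain, decomposes each total into
#' individual wagers (with the configured within-session drift), decides
#' which sessions are multi-deposit and which end depleted, and then solves
#' the deposit sizes (plus a closing withdrawal when the account would
#' otherwise overshoot its end-balance target) so that the forward balance
#' walk is exactly consistent in integer cents. Wins are settled as one
#' aggregate `WIN` just after the last wager of a session.
#'
#' @param profile A [group_profile()].
#' @param config A [generator_config()].
#' @param player_id Identifier for the emitted rows.
#' @return A list with `player` (one-row tibble: demographics, risk label
#'   and intended session/day counts) and `transactions` (tidy transaction
#'   tibble). Uses the current RNG state.
#' @export
generate_player <- function(profile, config, player_id = "P00001") {
  p <- profile
  cfg <- config

  # --- session skeleton ------------------------------------------------
  mu <- p$sessions_mean
  v <- p$sessions_sd^2
  n_sess <- if (v > mu) {
    max(1L, rnbinom(1, size = mu^2 / (v - mu), mu = mu))
  } else {
    max(1L, rpois(1, mu))
  }
  n_days <- round(rnorm(1, p$days_mean, p$days_sd))
  n_days <- max(1L, min(n_sess, cfg$n_window_days, n_days))
  start_day <- sample.int(cfg$n_window_days - n_days + 1L, 1)
  per_day <- rep(n_sess %/% n_days, n_days)
  rem <- n_sess %% n_days
  if (rem > 0) {
    bump <- sample.int(n_days, rem)
    per_day[bump] <- per_day[bump] + 1L
  }
  day_of_session <- rep(seq_len(n_days), times = per_day)

  n_wagers <- 1L + rpois(n_sess, p$wagers_lambda)

  # --- coupled totals, targets, flags (integer cents) -------------------
  chain <- session_total_chain(
    n_sess, p$across_session_rho,
    p$wager_meanlog, p$wager_sdlog, p$loss_meanlog, p$loss_sdlog
  )
  W <- pmax(round(100 * chain$total_wagered), n_wagers)
  L <- pmax(round(100 * chain$loss), -W)
  V <- W + L # aggregate win, >= 0

  thr_c <- round(100 * cfg$depletion_threshold)
  depleted <- rbinom(n_sess, 1, p$depletion_prob) == 1
  E <- ifelse(depleted,
    floor(runif(n_sess, 0, thr_c)), # 0 .. thr - 1 cents
    floor(runif(n_sess, thr_c, 100 * cfg$end_balance_max + 1))
  )

  multi <- rbinom(n_sess, 1, p$extra_deposit_prob) == 1
  n_extra <- ifelse(multi, 1L + rpois(n_sess, cfg$extra_count_lambda), 0L)
  extra_amounts <- pmax(
    round(100 * rlnorm(sum(n_extra), cfg$extra_deposit_meanlog,
      cfg$extra_deposit_sdlog
    )), 1
  )
  extra_session <- rep(seq_len(n_sess), times = n_extra)
  extras_sum <- vapply(
    seq_len(n_sess),
    function(s) sum(extra_amounts[extra_session == s]), numeric(1)
  )

  B_start <- c(0, E[-n_sess])[seq_len(n_sess)]
  needed <- E - B_start - L
  cover <- pmax(0, W - B_start)
  d1 <- needed - extras_sum
  floor_d1 <- pmax(cover, round(100 * cfg$min_first_deposit))
  fix <- d1 < floor_d1
  d1[fix] <- floor_d1[fix]
  wd <- ifelse(fix, d1 + extras_sum - needed, 0)

  # --- timestamps -------------------------------------------------------
  day_start <- as.numeric(as.POSIXct(cfg$window_start, tz = "UTC")) +
    (start_day + seq_len(n_days) - 2) * 86400 +
    cfg$day_start_hour * 3600 + runif(n_days, 0, 3600)
  gap_s <- cfg$gap_minutes * 60
  wager_rel <- lapply(n_wagers, function(k) {
    if (k == 1) 0 else c(0, cumsum(runif(k - 1, cfg$intra_gap_range_s[1],
      cfg$intra_gap_range_s[2]
    )))
  })
  duration <- vapply(wager_rel, max, numeric(1))
  fw <- numeric(n_sess)
  lw_prev <- -Inf
  prev_day <- 0L
  for (s in seq_len(n_sess)) {
    d <- day_of_session[s]
    inter <- gap_s + 60 * runif(1, cfg$inter_gap_extra_min[1],
      cfg$inter_gap_extra_min[2]
    )
    fw[s] <- if (d != prev_day) {
      max(day_start[d], lw_prev + inter)
    } else {
      lw_prev + inter
    }
    lw_prev <- fw[s] + duration[s]
    prev_day <- d
  }
  lw <- fw + duration

  # --- wager decomposition ---------------------------------------------
  sess_of_wager <- rep(seq_len(n_sess), times = n_wagers)
  j_norm <- unlist(lapply(n_wagers, function(k) {
    if (k == 1) 0 else (seq_len(k) - 1) / (k - 1)
  }), use.names = FALSE)
  raw_w <- rlnorm(sum(n_wagers), 0, 1) * exp(p$within_trend * j_norm)
  wager_amt <- unlist(lapply(seq_len(n_sess), function(s) {
    split_cents(W[s], raw_w[sess_of_wager == s])
  }), use.names = FALSE)
  wager_time <- fw[sess_of_wager] + unlist(wager_rel, use.names = FALSE)

  # --- assemble events --------------------------------------------------
  d1_time <- fw - runif(n_sess, cfg$deposit_lead_s[1], cfg$deposit_lead_s[2])
  extra_time <- if (sum(n_extra) > 0) {
    vapply(seq_along(extra_session), function(i) {
      s <- extra_session[i]
      if (n_wagers[s] >= 2) {
        runif(1, fw[s] + 1, lw[s] - 1)
      } else {
        fw[s] - runif(1, 5, 50) # single-wager span: just before the wager
      }
    }, numeric(1))
  } else {
    numeric(0)
  }
  win_keep <- V > 0
  wd_keep <- wd > 0

  ev_time <- c(
    d1_time, extra_time, wager_time,
    lw[win_keep] + 30, lw[wd_keep] + 90
  )
  ev_type <- c(
    rep("DEPOSIT", n_sess), rep("DEPOSIT", length(extra_time)),
    rep("WAGER", length(wager_time)),
    rep("WIN", sum(win_keep)), rep("WITHDRAWAL", sum(wd_keep))
  )
  ev_amt <- c(d1, extra_amounts, wager_amt, V[win_keep], wd[wd_keep])

  ord <- order(floor(ev_time), ev_time)
  ev_time <- floor(ev_time[ord])
  ev_type <- ev_type[ord]
  ev_amt <- ev_amt[ord]
  signed <- ifelse(ev_type %in% c("DEPOSIT", "WIN"), ev_amt, -ev_amt)
  bal_after <- cumsum(signed)
  bal_before <- bal_after - signed

  transactions <- tibble(
    player_id = player_id,
    timestamp = as.POSIXct(ev_time, origin = "1970-01-01", tz = "UTC"),
    event_type = ev_type,
    amount = ev_amt / 100,
    balance_before = bal_before / 100,
    balance_after = bal_after / 100
  )
  player <- tibble(
    player_id = player_id,
    age = max(18, min(90, round(rnorm(1, p$age_mean, p$age_sd)))),
    gender = if (runif(1) < p$female_share) "F" else "M",
    country = sample(c("UK", "SE", "ES"), 1),
    risk_label = p$label,
    n_sessions_intended = n_sess,
    n_days_intended = n_days
  )
  list(player = player, transactions = transactions)
}

#' Generate a seeded multi-group synthetic cohort
#'
#' Assigns each player to a risk group (multinomially by the profile
#' shares, or restricted to `groups`), generates every player's
#' transaction history with [generate_player()], and returns the cohort as
#' a transaction log plus player records. Fixed `seed` gives byte-identical
#' output.
#'
#' @param config A [generator_config()]; default [preset_paper()].
#' @param n_players Cohort size.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param groups Optional character vector restricting generation to a
#'   subset of group labels (shares renormalized).
#' @return A list with `transactions` (tidy transaction tibble across the
#'   cohort) and `players` (one row per player with demographics,
#'   `risk_label` equal to the generating group, and the intended session
#'   and day counts).
#' @examples
#' cohort <- generate_cohort(n_players = 3, seed = 42)
#' cohort$players
#' @export
generate_cohort <- function(config = preset_paper(), n_players, seed = NULL,
                            groups = NULL) {
  stopifnot(n_players >= 1)
  if (!is.null(seed)) set.seed(seed)
  profiles <- config$profiles
  if (!is.null(groups)) {
    groups <- tolower(groups)
    missing <- setdiff(groups, names(profiles))
    if (length(missing) > 0) {
      abort(paste0("Unknown group(s): ", paste(missing, collapse = ", ")))
    }
    profiles <- profiles[groups]
  }
  shares <- vapply(profiles, `[[`, numeric(1), "share")
  labels <- names(profiles)
  assignment <- if (length(labels) == 1) {
    rep(labels, n_players)
  } else {
    sample(labels, n_players, replace = TRUE, prob = shares / sum(shares))
  }
  ids <- sprintf("P%05d", seq_len(n_players))
  out <- purrr::map(seq_len(n_players), function(i) {
    generate_player(profiles[[assignment[i]]], config, ids[i])
  })
  list(
    transactions = bind_rows(purrr::map(out, "transactions")),
    players = bind_rows(purrr::map(out, "player"))
  )
}
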