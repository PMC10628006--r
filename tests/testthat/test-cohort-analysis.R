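test_that("D'Agostino K2 matches an independently computed reference", {
  # reference statistic computed with an independent implementation of the
  # same skewness/kurtosis transformations (frozen)
  x <- c(
    0.1, 1.4, -0.7, 2.2, 0.3, -1.1, 0.8, 1.9, -0.2, 0.5,
    3.1, -0.4, 0.9, 1.2, -1.6, 0.6, 2.5, 0.0, 1.1, -0.9,
    4.2, 0.7, 1.3, -0.3, 0.2
  )
  r <- dagostino_k2(x)
  expect_equal(r$statistic, 3.217432804012252, tolerance = 1e-10)
  expect_equal(r$z_skewness, 1.5425043623301176, tolerance = 1e-10)
  expect_equal(r$z_kurtosis, 0.9154851698442794, tolerance = 1e-10)
  expect_equal(r$p.value, 0.200144354155847, tolerance = 1e-10)
})

test_that("D'Agostino K2 holds its level under normality and flags skew", {
  set.seed(11)
  p_null <- replicate(100, dagostino_k2(rnorm(5000))$p.value)
  expect_gte(mean(p_null > 0.01), 0.95)

  set.seed(12)
  expect_lt(dagostino_k2(rexp(500))$p.value, 1e-3)

  expect_error(dagostino_k2(rep(1, 30)), "constant")
  expect_error(dagostino_k2(rnorm(10)), "n >= 20")
})

test_that("Kruskal-Wallis reproduces the hand rank-sum computation", {
  d <- data.frame(y = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
  r <- kruskal_wallis(d, y, g)
  # H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(r$df, 1)

  same <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(same, y, g)$statistic, 0)

  expect_error(
    kruskal_wallis(data.frame(y = 1:3, g = "a"), y, g), "two"
  )
})

test_that("proportion chi-squared matches the hand Pearson formula", {
  m <- matrix(c(20, 10, 10, 20), 2)
  r <- proportion_chisq(m)
  # 2x2 Pearson without correction: n (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(r$statistic, 60 * (20 * 20 - 10 * 10)^2 / 30^4, tolerance = 1e-12)
  expect_equal(proportion_chisq(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(proportion_chisq(matrix(c(5, 5, 0, 0), 2)), "positive")
})

test_that("multinomial fit handles the null case and keeps its identities", {
  set.seed(21)
  n <- 300
  d0 <- data.frame(
    risk = rep(c("low", "medium", "high"), each = n / 3),
    f1 = rep(1.5, n), f2 = rep(-2, n)
  )
  fit0 <- fit_multinomial(d0, risk, c("f1", "f2"), reference = "high")
  slopes <- dplyr::filter(tidy(fit0), term != "(Intercept)")$estimate
  expect_true(all(abs(slopes) < 1e-6))
  expect_lt(abs(fit0$mcfadden_pseudo_r2), 1e-10)

  # identities on an informative fit
  d1 <- data.frame(
    risk = rep(c("low", "medium", "high"), each = n / 3),
    f1 = rnorm(n) + rep(c(0, 0.5, 1.5), each = n / 3)
  )
  fit1 <- fit_multinomial(d1, risk, "f1", reference = "high")
  expect_equal(
    fit1$mcfadden_pseudo_r2,
    1 - fit1$log_likelihood / fit1$null_log_likelihood,
    tolerance = 1e-10
  )
  expect_gte(fit1$lr_statistic, 0)
  expect_equal(
    fit1$lr_statistic,
    2 * (fit1$log_likelihood - fit1$null_log_likelihood),
    tolerance = 1e-8
  )
  g <- glance(fit1)
  expect_true(g$converged)
  expect_equal(g$nobs, n)

  expect_error(fit_multinomial(d1, risk, "f1", reference = "absent"), "Reference")
})

test_that("monotone label dependence is recovered with the right sign", {
  set.seed(31)
  hits <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    n <- 300
    x <- rnorm(n)
    # larger x pushes players away from the high-risk reference
    lp_low <- 1.5 * x
    lp_med <- 0.5 * x
    pr <- cbind(exp(lp_low), exp(lp_med), 1)
    pr <- pr / rowSums(pr)
    lab <- apply(pr, 1, function(p) sample(c("low", "medium", "high"), 1, prob = p))
    d <- data.frame(risk = lab, x = x)
    if (length(unique(lab)) < 3) next
    fit <- fit_multinomial(d, risk, "x", reference = "high")
    est <- dplyr::filter(tidy(fit), term == "x", y.level == "low")$estimate
    if (est > 0) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("z-scoring centres and scales with the n-1 divisor, idempotently", {
  z <- zscore(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(z$scaled), c(-1, 0, 1))
  expect_equal(as.numeric(z$scale), 1)

  z2 <- zscore(z$scaled)
  expect_equal(z2$scaled, z$scaled, tolerance = 1e-12)

  expect_error(zscore(cbind(a = c(1, 1, 1), b = c(1, 2, 3))), "a")
})

test_that("k-means recovers separated blobs and is seed-deterministic", {
  set.seed(41)
  centers <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  blob <- do.call(rbind, lapply(1:4, function(i) {
    cbind(
      rnorm(50, centers[i, 1], 0.05),
      rnorm(50, centers[i, 2], 0.05)
    )
  }))
  d <- data.frame(x = blob[, 1], y = blob[, 2], truth = rep(1:4, each = 50))

  fit <- kmeans_fit(d, c("x", "y"), k = 4, seed = 13)
  # assignments recover the blobs exactly (up to label permutation)
  tab <- table(fit$cluster, d$truth)
  expect_true(all(apply(tab, 2, function(col) sum(col > 0)) == 1))

  fit2 <- kmeans_fit(d, c("x", "y"), k = 4, seed = 13)
  expect_identical(fit$cluster, fit2$cluster)

  one <- kmeans_fit(d, c("x", "y"), k = 1, seed = 13)
  z <- zscore(d[, c("x", "y")])$scaled
  expect_equal(one$tot_withinss, sum(scale(z, scale = FALSE)^2), tolerance = 1e-8)

  expect_error(kmeans_fit(d, c("x", "y"), k = 0), "k")
  expect_error(kmeans_fit(d, c("x", "y"), k = nrow(d) + 1), "k")

  td <- tidy(fit)
  expect_equal(sum(td$size), 200)
  expect_equal(sum(td$share), 1)
})

test_that("the elbow rule finds the true cluster count on blob fixtures", {
  set.seed(42)
  centers <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  blob4 <- do.call(rbind, lapply(1:4, function(i) {
    cbind(rnorm(50, centers[i, 1], 0.05), rnorm(50, centers[i, 2], 0.05))
  }))
  d4 <- data.frame(x = blob4[, 1], y = blob4[, 2])
  e4 <- select_k_elbow(d4, c("x", "y"), 1:10, seed = 7)
  expect_equal(e4$k_star, 4L)
  # WSS is non-increasing across the scanned range
  expect_true(all(diff(e4$curve$tot_withinss) <= 1e-8))

  blob2 <- rbind(
    cbind(rnorm(60, 0, 0.05), rnorm(60, 0, 0.05)),
    cbind(rnorm(60, 1, 0.05), rnorm(60, 1, 0.05))
  )
  d2 <- data.frame(x = blob2[, 1], y = blob2[, 2])
  expect_equal(select_k_elbow(d2, c("x", "y"), 1:8, seed = 7)$k_star, 2L)

  # flat curve (two distinct point locations, k >= 2 everywhere exact):
  # smallest k wins with a warning
  dflat <- data.frame(
    x = rep(c(0, 1), each = 20), y = rep(c(0, 1), each = 20)
  )
  expect_warning(
    eflat <- select_k_elbow(dflat, c("x", "y"), 2:5, seed = 7),
    "flat"
  )
  expect_equal(eflat$k_star, 2L)
})

test_that("cluster profiles report sizes, shares and risk composition", {
  d <- data.frame(
    a = c(0, 0.1, -0.1, 10), b = c(0, 0.1, -0.1, 10),
    risk_label = c("low", "low", "medium", "high")
  )
  fit <- kmeans_fit(d, c("a", "b"), k = 2, seed = 3)
  prof <- cluster_profiles(fit, d, risk_label)
  expect_equal(sort(prof$n), c(1, 3))
  expect_equal(sort(prof$share), c(0.25, 0.75))
  pct_cols <- grep("^pct_", names(prof), value = TRUE)
  expect_equal(unname(rowSums(prof[, pct_cols])), rep(100, 2))
  # the singleton cluster is the lone high-risk player
  expect_equal(prof$pct_high[prof$n == 1], 100)
})

test_that("risk-group summary equals hand computation on a toy cohort", {
  metrics <- tibble::tibble(
    player_id = paste0("P", 1:6),
    within_session = c(0.1, 0.2, 0.3, 0.4, -0.1, 0),
    across_session = c(0, 0, 0.5, 0.5, 0.2, 0.2),
    across_days = c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3),
    depletion_rate = c(0.5, 0.7, 0.6, 0.8, 0.2, 0.4),
    frequent_deposit_rate = c(0, 0.1, 0.2, 0.3, 0.05, 0.15),
    eligible = TRUE,
    n_sessions = c(10L, 20L, 15L, 25L, 8L, 12L),
    n_days = c(5L, 8L, 6L, 9L, 4L, 6L),
    n_sessions_within = 5L, n_session_pairs = 5L, n_day_pairs = 4L
  )
  players <- tibble::tibble(
    player_id = paste0("P", 1:6),
    age = c(30, 40, 50, 60, 35, 45),
    gender = c("F", "M", "F", "M", "F", "F"),
    country = "UK",
    risk_label = c("low", "low", "medium", "medium", "high", "high")
  )
  s <- risk_group_summary(metrics, players)
  g <- s$groups
  expect_equal(g$n, c(2L, 2L, 2L))
  expect_equal(g$pct_players, rep(100 / 3, 3), tolerance = 1e-10)
  expect_equal(g$age_mean, c(35, 55, 40))
  expect_equal(g$depletion_rate_mean, c(0.6, 0.7, 0.3))
  expect_equal(g$pct_female[g$risk_label == "high"], 100)
  expect_true("kruskal-wallis" %in% s$tests$test)

  # single-group cohort: summaries produced, tests skipped with warning
  one <- players[players$risk_label == "low", ]
  expect_warning(
    s1 <- risk_group_summary(metrics[1:2, ], one),
    "skipped"
  )
  expect_equal(nrow(s1$tests), 0)
})
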