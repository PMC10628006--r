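#' D'Agostino-Pearson K-squared omnibus normality test
#'
#' Combines the D'Agostino skewness test and the Anscombe-Glynn kurtosis
#' test: each sample moment is transformed to an approximately standard
#' normal deviate (Z1 for skewness, Z2 for kurtosis) and
#' K2 = Z1^2 + Z2^2 is referred to a chi-squared distribution with 2
#' degrees of freedom. Skewed or heavy-tailed samples yield large K2.
#'
#' @param x Numeric vector, n >= 20 (the normal approximations underlying
#'   the test degrade below that).
#' @return A one-row tibble with `statistic` (K2), `z_skewness`,
#'   `z_kurtosis`, `p.value`, `n`.
#' @examples
#' set.seed(1)
#' dagostino_k2(rnorm(200))
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20) {
    abort("dagostino_k2() needs n >= 20; the approximation is unreliable below that.")
  }
  if (sd(x) == 0) {
    abort("Sample is constant; normality test undefined (zero variance).")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) transformation
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2_g1 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2_g1 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
    ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble(
    statistic = k2, z_skewness = z1, z_kurtosis = z2,
    p.value = pchisq(k2, df = 2, lower.tail = FALSE), n = n
  )
}

#' Kruskal-Wallis rank test for group differences
#'
#' Tidy wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-squared reference with groups - 1 degrees of freedom).
#'
#' @param data A data frame.
#' @param value Column (unquoted) holding the response.
#' @param group Column (unquoted) holding the group labels.
#' @return A one-row tibble with `statistic` (H), `df`, `p.value`, `n`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
#' kruskal_wallis(d, y, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  if (nlevels(g) < 2) {
    abort("kruskal_wallis() needs at least two non-empty groups.")
  }
  if (any(table(g) == 0)) {
    abort("Every group must be non-empty.")
  }
  ht <- stats::kruskal.test(v, g)
  tibble(
    statistic = as.numeric(ht$statistic),
    df = as.numeric(ht$parameter),
    p.value = ht$p.value,
    n = length(v)
  )
}

#' Pearson chi-squared test on a 2 x g proportion table
#'
#' No continuity correction (the published comparisons span three groups).
#'
#' @param contingency A 2 x g matrix of nonnegative counts with positive
#'   row and column sums.
#' @return A one-row tibble with `statistic`, `df`, `p.value`, `n`.
#' @export
proportion_chisq <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) abort("Counts must be nonnegative.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Every row and column of the contingency table must have a positive sum.")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(
    statistic = as.numeric(ht$statistic),
    df = as.numeric(ht$parameter),
    p.value = ht$p.value,
    n = sum(m)
  )
}

#' McFadden pseudo R-squared from fitted and null log-likelihoods
#'
#' `1 - logLik(model) / logLik(null)`, the share of null log-likelihood
#' explained by the model.
#'
#' @param log_likelihood Fitted-model log-likelihood (negative).
#' @param null_log_likelihood Intercept-only log-likelihood (negative).
#' @return A number in `[0, 1)`.
#' @export
mcfadden_r2 <- function(log_likelihood, null_log_likelihood) {
  1 - log_likelihood / null_log_likelihood
}

#' Multinomial logistic regression of risk group on chasing metrics
#'
#' Fits a maximum-likelihood multinomial logit (via [nnet::multinom()]) of a
#' categorical label on a set of numeric features, with coefficients
#' expressed relative to a configurable reference category, plus an
#' intercept-only null fit for McFadden's pseudo R-squared and the
#' likelihood-ratio test.
#'
#' @param data A data frame holding features and labels.
#' @param response Column (unquoted) with the categorical outcome.
#' @param features Character vector of feature column names.
#' @param reference Reference category the log-odds are measured against.
#'   Default `"high"`.
#' @param maxit Maximum optimizer iterations. Default 500.
#' @return An object of class `chase_multinom`; see [tidy.chase_multinom()]
#'   and [glance.chase_multinom()].
#' @export
fit_multinomial <- function(data, response, features, reference = "high",
                            maxit = 500) {
  y <- factor(dplyr::pull(data, {{ response }}))
  if (!reference %in% levels(y)) {
    abort(paste0("Reference category '", reference, "' not present in the response."))
  }
  if (nlevels(y) < 2) abort("Response must have at least two categories.")
  X <- data[, features, drop = FALSE]
  if (any(!vapply(X, is.numeric, logical(1)))) {
    abort("All features must be numeric.")
  }
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  y <- stats::relevel(y, ref = reference)
  d <- cbind(data.frame(.y = y), X)

  fml <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  fit <- nnet::multinom(fml, data = d, trace = FALSE, maxit = maxit, Hess = TRUE)
  fit0 <- nnet::multinom(.y ~ 1, data = d, trace = FALSE, maxit = maxit)

  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  lr <- 2 * (ll - ll0)
  df_lr <- (nlevels(y) - 1) * length(features)

  sm <- summary(fit)
  co <- coef(fit)
  se <- sm$standard.errors
  if (is.null(dim(co))) { # two-category fit collapses to a vector
    co <- matrix(co, nrow = 1, dimnames = list(levels(y)[2], names(co)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  coef_tbl <- purrr::map_dfr(rownames(co), function(lvl) {
    tibble(
      y.level = lvl,
      term = colnames(co),
      estimate = as.numeric(co[lvl, ]),
      std.error = as.numeric(se[lvl, ])
    )
  }) %>%
    mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pnorm(-abs(.data$statistic))
    )

  structure(
    list(
      fit = fit,
      reference = reference,
      coefficients = coef_tbl,
      log_likelihood = ll,
      null_log_likelihood = ll0,
      mcfadden_pseudo_r2 = mcfadden_r2(ll, ll0),
      lr_statistic = max(lr, 0),
      lr_df = df_lr,
      lr_p = pchisq(max(lr, 0), df = df_lr, lower.tail = FALSE),
      converged = fit$convergence == 0,
      nobs = nrow(d)
    ),
    class = "chase_multinom"
  )
}

#' @export
print.chase_multinom <- function(x, ...) {
  cat("Multinomial logit (reference: ", x$reference, ")\n", sep = "")
  cat(sprintf(
    "logLik %.1f  null %.1f  McFadden R2 %.4f  LR %.1f (df %d, p %.3g)\n",
    x$log_likelihood, x$null_log_likelihood, x$mcfadden_pseudo_r2,
    x$lr_statistic, x$lr_df, x$lr_p
  ))
  print(x$coefficients, ...)
  invisible(x)
}

#' Tidy a multinomial risk-model fit
#'
#' @param x A `chase_multinom` object.
#' @param ... Unused.
#' @return A tibble with one row per (non-reference category, term):
#'   `y.level`, `term`, `estimate` (log-odds), `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.chase_multinom <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a multinomial risk-model fit
#'
#' @param x A `chase_multinom` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `null_logLik`, `mcfadden_pseudo_r2`,
#'   `lr_statistic`, `lr_df`, `lr_p`, `nobs`, `converged`.
#' @export
glance.chase_multinom <- function(x, ...) {
  tibble(
    logLik = x$log_likelihood,
    null_logLik = x$null_log_likelihood,
    mcfadden_pseudo_r2 = x$mcfadden_pseudo_r2,
    lr_statistic = x$lr_statistic,
    lr_df = x$lr_df,
    lr_p = x$lr_p,
    nobs = x$nobs,
    converged = x$converged
  )
}

#' Z-score standardization by column
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (divisor n - 1).
#'
#' @param x A numeric matrix or all-numeric data frame.
#' @return A list with `scaled` (matrix), `center` (means), `scale` (sds).
#' @export
zscore <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("zscore() needs numeric columns.")
  sds <- apply(m, 2, sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    abort(paste0(
      "Constant column(s) cannot be z-scored: ",
      paste(colnames(m)[const], collapse = ", ")
    ))
  }
  means <- colMeans(m)
  list(
    scaled = sweep(sweep(m, 2, means, "-"), 2, sds, "/"),
    center = means,
    scale = sds
  )
}

#' Seeded best-of-restarts k-means on z-scored variables
#'
#' Standardizes the chosen columns (so each carries the same weight), runs
#' [stats::kmeans()] with `restarts` random starts under a fixed seed, and
#' reports centroids both in standardized and original units.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric column names to cluster on.
#' @param k Number of clusters, `1 <= k <= nrow(data)`.
#' @param seed Integer seed making the restarts reproducible. Default 1.
#' @param restarts Number of random starts. Default 10.
#' @param standardize Z-score the variables first. Default `TRUE`.
#' @return An object of class `chase_kmeans` with elements `k`, `cluster`
#'   (assignments), `centers` (original units), `centers_scaled`, `size`,
#'   `tot_withinss`, `center`/`scale` (standardization parameters), `vars`.
#' @export
kmeans_fit <- function(data, vars, k, seed = 1, restarts = 10,
                       standardize = TRUE) {
  m <- as.matrix(data[, vars, drop = FALSE])
  n <- nrow(m)
  if (k < 1 || k > n) abort("`k` must satisfy 1 <= k <= nrow(data).")
  if (standardize) {
    z <- zscore(m)
  } else {
    z <- list(scaled = m, center = rep(0, ncol(m)), scale = rep(1, ncol(m)))
  }
  set.seed(seed)
  km <- kmeans(z$scaled, centers = k, nstart = restarts, iter.max = 100)
  centers_orig <- sweep(sweep(km$centers, 2, z$scale, "*"), 2, z$center, "+")
  structure(
    list(
      k = k,
      cluster = km$cluster,
      centers = centers_orig,
      centers_scaled = km$centers,
      size = km$size,
      tot_withinss = km$tot.withinss,
      center = z$center,
      scale = z$scale,
      vars = vars,
      seed = seed,
      restarts = restarts
    ),
    class = "chase_kmeans"
  )
}

#' @export
print.chase_kmeans <- function(x, ...) {
  cat("k-means solution: k =", x$k, " total WSS =",
    format(x$tot_withinss, digits = 5), "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a k-means solution
#'
#' @param x A `chase_kmeans` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: `cluster`, `size`, `share`,
#'   and the centroid in original units, one column per clustering variable.
#' @export
tidy.chase_kmeans <- function(x, ...) {
  out <- tibble(
    cluster = seq_len(x$k),
    size = x$size,
    share = x$size / sum(x$size)
  )
  dplyr::bind_cols(out, as_tibble(x$centers))
}

#' One-row summary of a k-means solution
#'
#' @param x A `chase_kmeans` object.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `tot_withinss`, `n`.
#' @export
glance.chase_kmeans <- function(x, ...) {
  tibble(k = x$k, tot_withinss = x$tot_withinss, n = sum(x$size))
}

#' Choose the number of clusters by an automated elbow rule
#'
#' Computes the within-cluster sum of squares over `k_range` and selects the
#' k whose point on the (k, WSS) curve — with both axes rescaled to the
#' unit interval —
#' lies farthest from the chord joining the curve's endpoints. This is a
#' deterministic stand-in for reading the elbow off the plot. A flat curve
#' (no structure to elbow on) returns the smallest k with a warning.
#'
#' @inheritParams kmeans_fit
#' @param k_range Ascending integer vector of cluster counts to scan.
#'   Default `1:10`.
#' @return An object of class `chase_elbow`: list with `k_star` and `curve`
#'   (tibble of `k`, `tot_withinss`). Supports [autoplot()].
#' @export
select_k_elbow <- function(data, vars, k_range = 1:10, seed = 1,
                           restarts = 10, standardize = TRUE) {
  k_range <- as.integer(k_range)
  if (is.unsorted(k_range) || length(k_range) < 2) {
    abort("`k_range` must be an ascending vector of at least two values.")
  }
  if (max(k_range) > nrow(data)) abort("max(k_range) exceeds the number of rows.")
  n_distinct_rows <- nrow(unique(as.matrix(data[, vars, drop = FALSE])))
  wss <- vapply(
    k_range,
    function(k) {
      # beyond the number of distinct points a zero-WSS fit already exists
      if (k > n_distinct_rows) {
        return(0)
      }
      kmeans_fit(data, vars, k,
        seed = seed, restarts = restarts,
        standardize = standardize
      )$tot_withinss
    },
    numeric(1)
  )
  curve <- tibble(k = k_range, tot_withinss = wss)
  span <- max(wss) - min(wss)
  if (span <= 1e-12 * max(abs(wss), 1)) {
    warn("WSS curve is flat; returning the smallest k.")
    k_star <- k_range[1]
  } else {
    kn <- (k_range - min(k_range)) / (max(k_range) - min(k_range))
    wn <- (wss - min(wss)) / span
    # perpendicular distance from each point to the chord between endpoints
    x1 <- kn[1]; y1 <- wn[1]
    x2 <- kn[length(kn)]; y2 <- wn[length(wn)]
    d <- abs((x2 - x1) * (y1 - wn) - (x1 - kn) * (y2 - y1)) /
      sqrt((x2 - x1)^2 + (y2 - y1)^2)
    k_star <- k_range[which.max(d)]
  }
  structure(list(k_star = k_star, curve = curve), class = "chase_elbow")
}

#' @export
print.chase_elbow <- function(x, ...) {
  cat("Elbow selection: k* =", x$k_star, "\n")
  print(x$curve, ...)
  invisible(x)
}

#' Per-cluster behavioral and risk-composition profiles
#'
#' Summarises a clustering by cluster size, cohort share, the mean of each
#' clustering variable in original units, and the risk-label composition.
#' The risk label is never used to form the clusters; its composition per
#' cluster is purely descriptive.
#'
#' @param solution A `chase_kmeans` object.
#' @param data The data frame the solution was fitted on.
#' @param risk_label Column (unquoted) in `data` with the risk labels.
#' @return A tibble with one row per cluster, ordered by descending size:
#'   `cluster`, `n`, `share`, the mean of each clustering variable, and one
#'   `pct_<label>` column per risk label (each row's percentages sum to 100).
#' @export
cluster_profiles <- function(solution, data, risk_label) {
  stopifnot(inherits(solution, "chase_kmeans"))
  d <- as_tibble(data)
  d$.cluster <- solution$cluster
  labs <- dplyr::pull(d, {{ risk_label }})
  d$.risk <- factor(labs)

  base <- d %>%
    group_by(.data$.cluster) %>%
    summarise(
      n = dplyr::n(),
      across(dplyr::all_of(solution$vars), mean),
      .groups = "drop"
    ) %>%
    mutate(share = .data$n / sum(.data$n))

  comp <- d %>%
    count(.data$.cluster, .data$.risk) %>%
    group_by(.data$.cluster) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    tidyr::pivot_wider(
      names_from = ".risk", values_from = "pct",
      names_prefix = "pct_", values_fill = 0
    )

  base %>%
    left_join(comp, by = ".cluster") %>%
    rename(cluster = ".cluster") %>%
    arrange(desc(.data$n)) %>%
    select("cluster", "n", "share", dplyr::everything())
}

#' Group-level summary of a risk-labelled cohort
#'
#' Builds the standard cohort description: per risk group the player count
#' and share, demographic summaries, gambling-intensity summaries (sessions,
#' days, deposits) and the mean/sd of each chasing metric, together with the
#' attached hypothesis tests (Kruskal-Wallis per numeric variable; Pearson
#' chi-squared for the gender split). With fewer than two risk groups the
#' summaries are still produced and the tests are skipped with a warning.
#'
#' @param metrics Output of [chasing_metrics()] (eligible players).
#' @param players A player-record tibble with `player_id`, `age`, `gender`,
#'   `risk_label`.
#' @return A list of class `risk_group_summary` with `groups` (one row per
#'   risk group of per-variable means/sds) and `tests` (one row per tested
#'   variable: `variable`, `test`, `statistic`, `df`, `p.value`).
#' @export
risk_group_summary <- function(metrics, players) {
  d <- dplyr::inner_join(as_tibble(metrics), as_tibble(players),
    by = "player_id"
  )
  if (nrow(d) == 0) abort("No overlap between metrics and player records.")
  d$risk_label <- factor(d$risk_label, levels = c("low", "medium", "high"))
  d <- filter(d, !is.na(.data$risk_label))

  num_vars <- c(
    "age", "n_sessions", "n_days", "within_session", "across_session",
    "across_days", "depletion_rate", "frequent_deposit_rate"
  )
  num_vars <- num_vars[num_vars %in% names(d)]

  groups <- d %>%
    group_by(.data$risk_label) %>%
    summarise(
      n = dplyr::n(),
      pct_players = NA_real_,
      pct_female = 100 * mean(tolower(.data$gender) %in% c("f", "female")),
      across(dplyr::all_of(num_vars),
        list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))
      ),
      .groups = "drop"
    ) %>%
    mutate(pct_players = 100 * .data$n / sum(.data$n))

  n_groups <- nlevels(droplevels(d$risk_label))
  if (n_groups < 2) {
    warn("Fewer than two risk groups present; group tests skipped.")
    tests <- tibble(
      variable = character(), test = character(),
      statistic = numeric(), df = numeric(), p.value = numeric()
    )
  } else {
    tests <- purrr::map_dfr(num_vars, function(v) {
      ok <- !is.na(d[[v]])
      if (length(unique(d$risk_label[ok])) < 2 || sum(ok) < 3) {
        return(tibble(
          variable = v, test = "kruskal-wallis",
          statistic = NA_real_, df = NA_real_, p.value = NA_real_
        ))
      }
      kw <- kruskal_wallis(
        data.frame(y = d[[v]][ok], g = d$risk_label[ok]), y, g
      )
      tibble(
        variable = v, test = "kruskal-wallis",
        statistic = kw$statistic, df = kw$df, p.value = kw$p.value
      )
    })
    tab <- table(
      tolower(d$gender) %in% c("f", "female"),
      droplevels(d$risk_label)
    )
    if (nrow(tab) == 2 && all(colSums(tab) > 0) && all(rowSums(tab) > 0)) {
      cs <- proportion_chisq(tab)
      tests <- bind_rows(tests, tibble(
        variable = "pct_female", test = "chi-squared",
        statistic = cs$statistic, df = cs$df, p.value = cs$p.value
      ))
    }
  }
  structure(list(groups = groups, tests = tests), class = "risk_group_summary")
}

#' @export
print.risk_group_summary <- function(x, ...) {
  cat("Risk-group summary\n")
  print(x$groups, ...)
  if (nrow(x$tests) > 0) {
    cat("\nGroup tests\n")
    print(x$tests, ...)
  }
  invisible(x)
}
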