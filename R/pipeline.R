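#' Configuration for a full pipeline run
#'
#' Exactly one input source must be set: either paths to existing
#' transaction and player files, or a simulation preset. All parameters are
#' echoed into the run manifest.
#'
#' @param transactions_file,players_file Paths to delimited input files
#'   (mutually exclusive with `preset`).
#' @param preset A [generator_config()] to simulate from (mutually
#'   exclusive with input paths), or `"paper"` for [preset_paper()].
#' @param n_players Cohort size when simulating. Default 500.
#' @param groups Optional group restriction when simulating.
#' @param gap_minutes,depletion_threshold,pair_window_hours,min_pairs,tz
#'   Metric parameters; see [chasing_metrics()].
#' @param reference Reference risk category for the multinomial model.
#'   Default `"high"`.
#' @param cluster_vars Metric columns used for clustering. Default
#'   `c("depletion_rate", "frequent_deposit_rate")`.
#' @param k_range Cluster counts scanned by the elbow rule. Default `1:10`.
#' @param restarts k-means restarts. Default 10.
#' @param seed Master seed; stage-specific substream seeds are derived from
#'   it so adding a stage never perturbs earlier stages. Default 1.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(transactions_file = NULL, players_file = NULL,
                       preset = NULL, n_players = 500, groups = NULL,
                       gap_minutes = 15, depletion_threshold = 5,
                       pair_window_hours = 24, min_pairs = 3, tz = "UTC",
                       reference = "high",
                       cluster_vars = c("depletion_rate", "frequent_deposit_rate"),
                       k_range = 1:10, restarts = 10, seed = 1,
                       out_dir = tempfile("chasemetrics-run-")) {
  has_files <- !is.null(transactions_file) || !is.null(players_file)
  if (has_files && !is.null(preset)) {
    abort("Set either input files or a simulation preset, not both.")
  }
  if (!has_files && is.null(preset)) {
    abort("Set input files or a simulation preset.")
  }
  if (has_files && (is.null(transactions_file) || is.null(players_file))) {
    abort("Both transactions_file and players_file are required for file input.")
  }
  if (identical(preset, "paper")) preset <- preset_paper()
  structure(
    list(
      transactions_file = transactions_file, players_file = players_file,
      preset = preset, n_players = n_players, groups = groups,
      gap_minutes = gap_minutes, depletion_threshold = depletion_threshold,
      pair_window_hours = pair_window_hours, min_pairs = min_pairs, tz = tz,
      reference = reference, cluster_vars = cluster_vars,
      k_range = k_range, restarts = restarts, seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

# derive independent substream seeds from the master seed; stage order is
# fixed so adding stages at the end never changes earlier substreams
substream_seeds <- function(seed, stages) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1, length(stages)), stages)
}

#' Run the full chasing-losses pipeline
#'
#' Simulates (or loads) a cohort, validates the ledger, reconstructs
#' sessions, computes the five chasing metrics with the eligibility filter,
#' and — when at least two risk groups are present — runs the group
#' comparison, the multinomial risk regression and the k-means/elbow
#' clustering. Every artifact is written as delimited text under
#' `config$out_dir` and listed, with content hashes and all parameters, in
#' `manifest.json`. Reruns with an identical config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`metrics`,
#'   `validation`, `summary`, `model`, `elbow`, `clusters`, `profiles`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- substream_seeds(cfg$seed, c("simulate", "cluster"))
  log_line <- function(...) message(sprintf(...))

  # stage 1: input
  if (!is.null(cfg$preset)) {
    cohort <- generate_cohort(cfg$preset, cfg$n_players,
      seed = seeds[["simulate"]], groups = cfg$groups
    )
    tx <- cohort$transactions
    players <- cohort$players
  } else {
    tx <- read_transaction_log(cfg$transactions_file)
    players <- read_player_records(cfg$players_file)
  }
  log_line("input: %d transactions, %d players", nrow(tx), nrow(players))

  # stage 2: validation
  validation <- validate_log(tx)
  readr::write_csv(as_tibble(unclass(validation)),
    file.path(cfg$out_dir, "validation.csv")
  )
  log_line("validate: %d violations", nrow(validation))

  # stage 3: sessions
  sessions <- summarize_sessions(tx, cfg$gap_minutes)
  readr::write_csv(sessions, file.path(cfg$out_dir, "sessions.csv"))
  log_line("sessions: %d sessions", nrow(sessions))

  # stage 4: metrics + eligibility
  metrics <- chasing_metrics(tx,
    gap_minutes = cfg$gap_minutes,
    depletion_threshold = cfg$depletion_threshold,
    pair_window_hours = cfg$pair_window_hours,
    min_pairs = cfg$min_pairs, tz = cfg$tz
  )
  readr::write_csv(metrics, file.path(cfg$out_dir, "metrics.csv"))
  readr::write_csv(exclusion_report(metrics),
    file.path(cfg$out_dir, "exclusions.csv")
  )
  eligible <- filter_eligible(metrics)
  log_line("metrics: %d players, %d eligible", nrow(metrics), nrow(eligible))

  # stage 5: cohort analysis (needs labels and >= 2 groups)
  model <- NULL
  elbow <- NULL
  clusters <- NULL
  profiles <- NULL
  summary_tbl <- NULL
  analysed <- dplyr::inner_join(eligible, players, by = "player_id")
  n_groups <- length(unique(analysed$risk_label))
  metric_cols <- c(
    "within_session", "across_session", "across_days",
    "depletion_rate", "frequent_deposit_rate"
  )
  if (nrow(analysed) > 0) {
    summary_tbl <- risk_group_summary(eligible, players)
    readr::write_csv(summary_tbl$groups, file.path(cfg$out_dir, "group_summary.csv"))
    readr::write_csv(summary_tbl$tests, file.path(cfg$out_dir, "group_tests.csv"))
  }
  if (n_groups >= 2 && nrow(analysed) >= 50) {
    model <- fit_multinomial(analysed, risk_label, metric_cols,
      reference = cfg$reference
    )
    readr::write_csv(tidy(model), file.path(cfg$out_dir, "regression.csv"))
    readr::write_csv(glance(model), file.path(cfg$out_dir, "regression_fit.csv"))
    log_line(
      "regression: pseudo-R2 %.4f, converged %s",
      model$mcfadden_pseudo_r2, model$converged
    )
  } else {
    log_line("regression: skipped (%d groups, %d eligible)", n_groups, nrow(analysed))
  }
  if (nrow(analysed) >= max(cfg$k_range) && nrow(analysed) >= 2) {
    elbow <- select_k_elbow(analysed, cfg$cluster_vars,
      k_range = cfg$k_range,
      seed = seeds[["cluster"]], restarts = cfg$restarts
    )
    clusters <- kmeans_fit(analysed, cfg$cluster_vars, elbow$k_star,
      seed = seeds[["cluster"]], restarts = cfg$restarts
    )
    profiles <- cluster_profiles(clusters, analysed, risk_label)
    readr::write_csv(elbow$curve, file.path(cfg$out_dir, "elbow_curve.csv"))
    readr::write_csv(profiles, file.path(cfg$out_dir, "cluster_profiles.csv"))
    log_line("clustering: k* = %d", elbow$k_star)
  }

  artifacts <- list.files(cfg$out_dir, pattern = "\\.csv$")
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "preset")],
    preset = if (!is.null(cfg$preset)) "generator_config" else NULL,
    substream_seeds = as.list(seeds),
    n_transactions = nrow(tx),
    n_players = nrow(players),
    n_eligible = nrow(eligible),
    artifacts = lapply(setNames(artifacts, artifacts), function(f) {
      unname(tools::md5sum(file.path(cfg$out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(list(
    metrics = metrics, validation = validation, summary = summary_tbl,
    model = model, elbow = elbow, clusters = clusters, profiles = profiles,
    manifest = manifest
  ))
}
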