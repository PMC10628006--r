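#' Event types recognised in a transaction log
#'
#' @format Character vector of the four money-event types.
#' @keywords internal
EVENT_TYPES <- c("WAGER", "WIN", "DEPOSIT", "WITHDRAWAL")

# required columns of the canonical transaction schema, in write order
TX_COLUMNS <- c(
  "player_id", "timestamp", "event_type",
  "amount", "balance_before", "balance_after"
)

#' Read an account-based transaction log
#'
#' Reads a delimiter-separated text file with one row per money event (wager,
#' win, deposit or withdrawal) and returns a tidy transaction table, grouped
#' by player and chronologically sorted within each player. Ties on the
#' timestamp preserve the file order, which matters for wager/win pairs that
#' settle within the same second.
#'
#' @param file Path to a delimited text file with a header row.
#' @param delim Field delimiter. Default `","`.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`player_id`, `timestamp`, `event_type`, `amount`,
#'   `balance_before`, `balance_after`) to the column names used in the file,
#'   e.g. `c(player_id = "account")`. Columns not mentioned are assumed to
#'   carry their canonical names.
#' @param tz Timezone used to interpret timestamps without an explicit
#'   offset. Default `"UTC"`.
#'
#' @return A tibble with columns `player_id` (character), `timestamp`
#'   (POSIXct), `event_type` (one of `WAGER`, `WIN`, `DEPOSIT`,
#'   `WITHDRAWAL`), `amount`, `balance_before`, `balance_after` (numeric,
#'   currency units), sorted by player then time (stable).
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "player_id,timestamp,event_type,amount,balance_before,balance_after",
#'   "P1,2021-12-01T10:00:00,DEPOSIT,50,0,50",
#'   "P1,2021-12-01T10:01:00,WAGER,10,50,40"
#' ), f)
#' read_transaction_log(f)
#' @export
read_transaction_log <- function(file, delim = ",", schema = NULL, tz = "UTC") {
  raw <- readr::read_delim(
    file,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  cols <- setNames(TX_COLUMNS, TX_COLUMNS)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), TX_COLUMNS)
    if (length(bad) > 0) {
      abort(paste0("Unknown schema entries: ", paste(bad, collapse = ", ")))
    }
    cols[names(schema)] <- unname(schema)
  }
  missing <- cols[!cols %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0(
      "Missing required column(s) in ", file, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  tx <- tibble(
    player_id = raw[[cols["player_id"]]],
    timestamp_raw = raw[[cols["timestamp"]]],
    event_type = raw[[cols["event_type"]]],
    amount_raw = raw[[cols["amount"]]],
    balance_before_raw = raw[[cols["balance_before"]]],
    balance_after_raw = raw[[cols["balance_after"]]]
  )

  ts <- suppressWarnings(
    readr::parse_datetime(tx$timestamp_raw, locale = readr::locale(tz = tz))
  )
  bad_rows <- which(is.na(ts) & !is.na(tx$timestamp_raw))
  if (length(bad_rows) > 0) {
    abort(paste0(
      "Unparseable timestamp(s) at row(s): ",
      paste(utils::head(bad_rows, 10), collapse = ", "),
      " (value '", tx$timestamp_raw[bad_rows[1]], "')"
    ))
  }

  nums <- lapply(c("amount_raw", "balance_before_raw", "balance_after_raw"),
    function(col) {
      v <- suppressWarnings(as.numeric(tx[[col]]))
      bad <- which(is.na(v) & !is.na(tx[[col]]))
      if (length(bad) > 0) {
        abort(paste0(
          "Unparseable numeric value in '", sub("_raw$", "", col),
          "' at row(s): ", paste(utils::head(bad, 10), collapse = ", ")
        ))
      }
      v
    }
  )

  unknown <- setdiff(unique(tx$event_type), EVENT_TYPES)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown event type(s): ", paste(unknown, collapse = ", "),
      ". Expected one of ", paste(EVENT_TYPES, collapse = ", "), "."
    ))
  }

  out <- tibble(
    player_id = tx$player_id,
    timestamp = ts,
    event_type = tx$event_type,
    amount = nums[[1]],
    balance_before = nums[[2]],
    balance_after = nums[[3]]
  )
  # stable per-player chronological order; ties keep file order
  out[order(out$player_id, out$timestamp, method = "radix"), ]
}

#' Read player demographic and risk-label records
#'
#' @param file Path to a delimited text file with columns `player_id`, `age`,
#'   `gender`, `country`, `risk_label`.
#' @param delim Field delimiter. Default `","`.
#' @return A tibble with `risk_label` lower-cased to one of
#'   `"low"`, `"medium"`, `"high"`.
#' @export
read_player_records <- function(file, delim = ",") {
  req <- c("player_id", "age", "gender", "country", "risk_label")
  raw <- readr::read_delim(
    file, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble(
    player_id = raw$player_id,
    age = as.numeric(raw$age),
    gender = raw$gender,
    country = raw$country,
    risk_label = tolower(raw$risk_label)
  )
  bad <- setdiff(unique(out$risk_label), c("low", "medium", "high"))
  if (length(bad) > 0) {
    abort(paste0("Unknown risk label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.na(out$age) & out$age <= 0)) {
    abort("Player ages must be positive.")
  }
  out
}

#' Validate the balance arithmetic of a transaction log
#'
#' Checks every row of a transaction table against the account-ledger
#' semantics: a `WAGER` or `WITHDRAWAL` decreases the balance by `amount`, a
#' `WIN` or `DEPOSIT` increases it, and within a player consecutive rows must
#' chain (`balance_before` equals the previous row's `balance_after`).
#' Negative amounts are also reported. Validation never fails on content —
#' it returns a report of violations and leaves the log untouched.
#'
#' @param transactions A transaction tibble as returned by
#'   [read_transaction_log()].
#' @param tolerance Money tolerance for balance comparisons, in currency
#'   units. Default `0.005`, matching two-decimal money storage.
#'
#' @return A tibble of violations (possibly empty) with columns `player_id`,
#'   `row` (row index within the input), `kind` (`"arithmetic"`, `"chain"` or
#'   `"negative_amount"`) and `detail`, carrying class `"validation_report"`.
#' @examples
#' tx <- tibble::tibble(
#'   player_id = "P1",
#'   timestamp = as.POSIXct("2021-12-01 10:00", tz = "UTC"),
#'   event_type = "WAGER", amount = 10,
#'   balance_before = 100, balance_after = 95
#' )
#' validate_log(tx)  # one arithmetic violation
#' @export
validate_log <- function(transactions, tolerance = 0.005) {
  stopifnot(is.data.frame(transactions))
  tx <- as_tibble(transactions)
  tx$.row <- seq_len(nrow(tx))

  sign <- ifelse(tx$event_type %in% c("WIN", "DEPOSIT"), 1, -1)
  expected_after <- tx$balance_before + sign * tx$amount
  arith_bad <- abs(tx$balance_after - expected_after) > tolerance

  neg_bad <- tx$amount < 0

  tx_ord <- tx[order(tx$player_id, tx$timestamp, method = "radix"), ]
  prev_after <- ave(tx_ord$balance_after, tx_ord$player_id,
    FUN = function(x) c(NA_real_, x[-length(x)])
  )
  chain_bad_ord <- !is.na(prev_after) &
    abs(tx_ord$balance_before - prev_after) > tolerance

  report <- bind_rows(
    tibble(
      player_id = tx$player_id[arith_bad],
      row = tx$.row[arith_bad],
      kind = "arithmetic",
      detail = sprintf(
        "%s of %.2f: balance %.2f -> %.2f (expected %.2f)",
        tx$event_type[arith_bad], tx$amount[arith_bad],
        tx$balance_before[arith_bad], tx$balance_after[arith_bad],
        expected_after[arith_bad]
      )
    ),
    tibble(
      player_id = tx$player_id[neg_bad],
      row = tx$.row[neg_bad],
      kind = "negative_amount",
      detail = sprintf("amount %.2f < 0", tx$amount[neg_bad])
    ),
    tibble(
      player_id = tx_ord$player_id[chain_bad_ord],
      row = tx_ord$.row[chain_bad_ord],
      kind = "chain",
      detail = sprintf(
        "balance_before %.2f != previous balance_after %.2f",
        tx_ord$balance_before[chain_bad_ord], prev_after[chain_bad_ord]
      )
    )
  )
  report <- report[order(report$row), ]
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Transaction log valid: 0 violations.\n")
  } else {
    cat("Transaction log: ", nrow(x), " violation(s)\n", sep = "")
    print(as_tibble(unclass(x)) %>% count(.data$kind), ...)
  }
  invisible(x)
}

#' Write a transaction log to delimited text
#'
#' Money columns are serialized with two decimals and timestamps as ISO-8601
#' in UTC, so that `read_transaction_log(write_transaction_log(x))`
#' reproduces the table field for field.
#'
#' @param transactions A transaction tibble.
#' @param file Output path.
#' @param delim Field delimiter. Default `","`.
#' @return The input, invisibly.
#' @export
write_transaction_log <- function(transactions, file, delim = ",") {
  tx <- as_tibble(transactions)[, TX_COLUMNS[TX_COLUMNS %in% names(transactions)]]
  out <- tibble(
    player_id = tx$player_id,
    timestamp = format(tx$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    event_type = tx$event_type,
    amount = sprintf("%.2f", round(tx$amount, 2)),
    balance_before = sprintf("%.2f", round(tx$balance_before, 2)),
    balance_after = sprintf("%.2f", round(tx$balance_after, 2))
  )
  readr::write_delim(out, file, delim = delim, progress = FALSE)
  invisible(transactions)
}

#' Write player records to delimited text
#'
#' @inheritParams write_transaction_log
#' @param players A player-record tibble.
#' @return The input, invisibly.
#' @export
write_player_records <- function(players, file, delim = ",") {
  readr::write_delim(
    as_tibble(players)[, c("player_id", "age", "gender", "country", "risk_label")],
    file, delim = delim, progress = FALSE
  )
  invisible(players)
}
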