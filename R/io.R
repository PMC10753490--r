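budget_csv_columns <- function() {
  c("date", "flight_h", "forage_h", "on_water_h", "on_land_h", "sst_c", "air_c")
}

#' Read a multi-day activity budget CSV
#'
#' Fixed dialect: UTF-8, comma-separated, `.` decimal, ISO 8601 dates, header
#' `date,flight_h,forage_h,on_water_h,on_land_h,sst_c,air_c`. Every row is
#' validated (finite non-negative hours summing to 24 h within 1e-6, finite
#' temperatures); errors name the offending row. With `renormalise = TRUE`,
#' rows whose hours sum elsewhere are rescaled proportionally and a message is
#' logged per adjusted row.
#'
#' @param path Path to the CSV file.
#' @param renormalise Rescale row budgets to 24 h instead of erroring.
#' @return Data frame in the budget schema, rows ordered by date.
#' @export
read_budget_csv <- function(path, renormalise = FALSE) {
  if (!file.exists(path)) stop("budget file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(budget_csv_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("budget CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[budget_csv_columns()]
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    bad <- which(is.na(dates))[1L]
    stop("row ", bad, ": unparseable ISO 8601 date '", df$date[bad], "'",
         call. = FALSE)
  }
  df$date <- dates
  hour_cols <- c("flight_h", "forage_h", "on_water_h", "on_land_h")
  for (i in seq_len(nrow(df))) {
    h <- as.numeric(df[i, hour_cols])
    if (any(!is.finite(h)) || any(h < 0)) {
      stop("row ", i, ": activity hours must be finite and >= 0", call. = FALSE)
    }
    total <- sum(h)
    if (abs(total - 24) > 1e-6) {
      if (renormalise && total > 0) {
        message(sprintf("renormalising row %d (%s): hours summed to %.4f h",
                        i, format(df$date[i]), total))
        df[i, hour_cols] <- h * (24 / total)
      } else {
        stop(sprintf("row %d (%s): hours sum to %.6f h, not 24 h",
                     i, format(df$date[i]), total), call. = FALSE)
      }
    }
    if (!all(is.finite(as.numeric(df[i, c("sst_c", "air_c")])))) {
      stop("row ", i, ": temperatures must be finite", call. = FALSE)
    }
  }
  df[order(df$date), , drop = FALSE]
}

#' Write a results table to CSV
#'
#' Same fixed dialect as the budget reader; dates are written as ISO 8601.
#'
#' @param results Data frame (e.g. from [dee_series()] or a simulation's
#'   `daily` table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  df <- results
  if ("date" %in% names(df)) df$date <- format(as.Date(df$date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate random, valid fixture budgets
#'
#' Emits `n_days` of synthetic daily budgets for testing and examples: hours
#' are drawn uniformly from the simplex over the activities the guild performs
#' (via normalised Exponential(1) draws) and scaled to 24 h, so every row is a
#' valid budget and activities the guild never performs (e.g. flight for a
#' flightless guild) get exactly zero hours. Temperatures follow a mild
#' seasonal sinusoid with Gaussian noise inside the plausibility band.
#'
#' @param n_days Number of days (>= 1).
#' @param guild One-row guild data frame, see [guild_of()].
#' @param seed Optional integer seed; the output is deterministic given it.
#' @param start_date First date (default `"2023-01-01"`).
#' @return Data frame in the budget CSV schema.
#' @export
#' @examples
#' generate_fixture_budgets(3, guild_of("Alcidae"), seed = 1)
generate_fixture_budgets <- function(n_days, guild, seed = NULL,
                                     start_date = "2023-01-01") {
  if (!is.numeric(n_days) || n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  n_days <- as.integer(n_days)
  if (!is.null(seed)) set.seed(seed)
  acts <- performable_activities(guild)
  all_acts <- activity_kinds()
  hours <- matrix(0, nrow = n_days, ncol = length(all_acts),
                  dimnames = list(NULL, all_acts))
  for (i in seq_len(n_days)) {
    w <- stats::rexp(length(acts))
    hours[i, acts] <- 24 * w / sum(w)
  }
  doy <- (seq_len(n_days) - 1L) %% 365L + 1L
  sst <- 8 + 5 * cos(2 * pi * (doy - 233) / 365) + stats::rnorm(n_days, 0, 0.5)
  air <- 8 + 7 * cos(2 * pi * (doy - 212) / 365) + stats::rnorm(n_days, 0, 1)
  data.frame(
    date = seq(as.Date(start_date), by = "day", length.out = n_days),
    flight_h = hours[, "flight"], forage_h = hours[, "forage"],
    on_water_h = hours[, "on_water"], on_land_h = hours[, "on_land"],
    sst_c = round(sst, 2), air_c = round(air, 2)
  )
}
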