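#' Daily series of event counts, exposure and weather
#'
#' Constructs and validates the basic analysis table: one row per calendar
#' day with the daily event count, the pollutant concentration (e.g. ozone
#' 8-h daily maximum, ppb), mean temperature (degrees C) and relative
#' humidity (%). Dates must be strictly increasing; non-consecutive dates
#' are allowed but flagged with a warning because the lag structure assumes
#' a gap-free daily grid. Missing values are permitted in any measured
#' column and are dropped per lag at design-construction time.
#'
#' @param date vector coercible to `Date` (ISO-8601 strings accepted).
#' @param count non-negative integer daily event counts (NA allowed).
#' @param exposure non-negative daily concentrations, ppb (NA allowed).
#' @param temperature daily mean temperature, degrees C (NA allowed).
#' @param humidity daily relative humidity in \[0, 100\] (NA allowed).
#' @return A `data.frame` of class `daily_series` with the five columns
#'   above, ordered by date.
#' @examples
#' d <- daily_series(date = as.Date("2000-01-01") + 0:2,
#'                   count = c(70, 85, 90), exposure = c(20, 25, 18),
#'                   temperature = c(-5, -3, -6), humidity = c(70, 65, 72))
#' @export
daily_series <- function(date, count, exposure, temperature, humidity) {
  date <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(date)) stop("invalid dates: all dates must parse as ISO-8601 calendar days")
  n <- length(date)
  stopifnot(length(count) == n, length(exposure) == n,
            length(temperature) == n, length(humidity) == n)
  if (n > 1 && any(diff(as.integer(date)) <= 0))
    stop("dates must be strictly increasing")
  if (n > 1 && any(diff(as.integer(date)) != 1))
    warning("dates are not consecutive: ", sum(diff(as.integer(date)) != 1),
            " gap(s) in the daily grid")
  count <- as.numeric(count)
  if (any(count < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (any(abs(count - round(count)) > 1e-8, na.rm = TRUE))
    stop("counts must be integers")
  exposure <- as.numeric(exposure)
  if (any(exposure < 0, na.rm = TRUE)) stop("exposure must be non-negative")
  humidity <- as.numeric(humidity)
  if (any(humidity < 0 | humidity > 100, na.rm = TRUE))
    stop("humidity must lie in [0, 100]")
  out <- data.frame(date = date, count = count, exposure = exposure,
                    temperature = as.numeric(temperature), humidity = humidity)
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Read a daily series from CSV
#'
#' Expects a header with columns `date,count,exposure,temperature,humidity`;
#' dates ISO-8601; missing values blank or `NA`.
#'
#' @param path path to the CSV file.
#' @return a [daily_series()].
#' @export
read_daily_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  need <- c("date", "count", "exposure", "temperature", "humidity")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("input CSV is missing column(s): ", paste(miss, collapse = ", "))
  daily_series(x$date, x$count, x$exposure, x$temperature, x$humidity)
}

#' Write a daily series to CSV
#'
#' Writes the standard five-column input CSV. If the series carries a
#' simulation truth record (see [simulate_daily_series()]) it can be saved
#' alongside as JSON for later assertions.
#'
#' @param x a [daily_series()].
#' @param path output CSV path.
#' @param truth_path optional path for the JSON sidecar with the true
#'   concentration-response parameters (only written when `x` has a
#'   `truth` attribute).
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(x, path, truth_path = NULL) {
  stopifnot(inherits(x, "daily_series"))
  out <- as.data.frame(x)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  truth <- attr(x, "truth")
  if (!is.null(truth_path) && !is.null(truth))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Number of days in a closed study interval
#'
#' @param start,end calendar days (coercible to `Date`), `start <= end`.
#' @return integer count of days, both endpoints included.
#' @examples
#' study_day_count("1992-04-01", "2002-03-31")  # 3652
#' @export
study_day_count <- function(start, end) {
  start <- tryCatch(as.Date(start), error = function(e) NA)
  end <- tryCatch(as.Date(end), error = function(e) NA)
  if (anyNA(c(start, end))) stop("invalid dates")
  if (end < start) stop("reversed interval: end precedes start")
  as.integer(end - start) + 1L
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("daily_series: %d days, %s to %s\n", nrow(x),
              format(min(x$date)), format(max(x$date))))
  cat(sprintf("  total events: %s; exposure range: [%.1f, %.1f]\n",
              format(sum(x$count, na.rm = TRUE), big.mark = ","),
              min(x$exposure, na.rm = TRUE), max(x$exposure, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
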