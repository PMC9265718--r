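#' Time-stratified case-crossover strata
#'
#' Assigns each day to its case-crossover stratum, defined by the
#' hierarchical calendar structure year : calendar month : day-of-week.
#' All days sharing a weekday within one calendar month form a stratum, so
#' every stratum in a complete month has 4 or 5 days. The conditional
#' Poisson model compares the event count on each day with the counts on
#' the other days of its stratum, which removes confounding by factors that
#' vary slowly (season, long-term trend) or not at all (population
#' characteristics).
#'
#' Weekdays follow the ISO convention (Monday = 1 ... Sunday = 7); only
#' label equality matters downstream, so any fixed convention is
#' equivalent.
#'
#' @param dates vector coercible to `Date`.
#' @return factor of stratum labels of the form `"YYYY:MM:W"`, one per day.
#' @examples
#' build_strata(c("1992-04-06", "1992-04-13"))  # same stratum (April Mondays)
#' @export
build_strata <- function(dates) {
  dates <- tryCatch(as.Date(dates), error = function(e) NA)
  if (anyNA(dates)) stop("invalid dates")
  lt <- as.POSIXlt(dates)
  wday <- ifelse(lt$wday == 0L, 7L, lt$wday)  # ISO: Mon=1..Sun=7
  factor(sprintf("%04d:%02d:%d", lt$year + 1900L, lt$mon + 1L, wday))
}

#' Align counts with lagged exposure and weather
#'
#' Pairs the event count on day t with the exposure, temperature and
#' humidity measured L days earlier (lag L), the alignment under which the
#' per-lag model is fitted. The first L days have no lagged covariates and
#' are dropped, so with complete data the result has `nrow(series) - L`
#' rows. Stratum labels always come from the event day t.
#'
#' @param series a [daily_series()].
#' @param L non-negative integer lag in days, `L < nrow(series)`.
#' @return a `data.frame` with columns `date`, `count`, `stratum` (of day
#'   t) and `exposure`, `temperature`, `humidity` (of day t - L). Rows may
#'   still contain NA; see [build_lagged_design()] for the fit-ready,
#'   complete-case design.
#' @export
lag_series <- function(series, L) {
  stopifnot(inherits(series, "daily_series"))
  L <- as.integer(L)
  if (L < 0) stop("lag must be non-negative")
  n <- nrow(series)
  if (L >= n) stop("lag must be smaller than the number of days")
  idx <- (L + 1L):n
  data.frame(date = series$date[idx],
             count = series$count[idx],
             stratum = build_strata(series$date)[idx],
             exposure = series$exposure[idx - L],
             temperature = series$temperature[idx - L],
             humidity = series$humidity[idx - L])
}

#' Natural cubic spline basis
#'
#' Basis used for the weather confounders: `df` columns with interior knots
#' at equally spaced quantiles of `x` (for df = 3: the 33.3% and 66.7%
#' quantiles) and boundary knots at the observed min/max, beyond which the
#' fitted function is constrained to be linear.
#'
#' @param x numeric vector (NA allowed, propagated).
#' @param df degrees of freedom (number of basis columns), default 3.
#' @return an `nrow(x) x df` basis matrix (a [splines::ns()] object).
#' @export
natural_spline_basis <- function(x, df = 3) {
  if (df < 1) stop("df must be >= 1")
  ux <- unique(x[is.finite(x)])
  if (length(ux) < df + 2)
    stop("x is degenerate: need at least df + 2 distinct finite values")
  splines::ns(x, df = df)
}

#' Fit-ready lagged case-crossover design
#'
#' Assembles, for one lag, the response, covariate matrix and stratum
#' labels on which the conditional Poisson model is fitted: the transformed
#' exposure column is left to the caller (the raw lagged exposure is
#' returned), while the temperature and humidity spline bases are built
#' here from the analysis sample. Rows with any missing value are dropped
#' (listwise, per lag); strata reduced to fewer than 2 rows or with zero
#' total events carry no information under the conditional likelihood and
#' are dropped too.
#'
#' @param series a [daily_series()].
#' @param L lag in days.
#' @param df spline degrees of freedom for each weather term (default 3).
#' @return list of class `lagged_design`: `lag`, `y` (counts), `z` (lagged
#'   exposure), `W` (6-column spline matrix: temperature then humidity),
#'   `strata` (factor, droplevels applied), `date`, `r` (observed exposure
#'   range max - min on the retained rows), `n_dropped_na`,
#'   `n_dropped_strata`.
#' @export
build_lagged_design <- function(series, L, df = 3) {
  d <- lag_series(series, L)
  ok <- stats::complete.cases(d[c("count", "exposure", "temperature", "humidity")])
  n_na <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no complete rows at lag ", L)
  # strata must retain within-stratum contrast: >=2 rows and >=1 event
  tab <- table(d$stratum)
  ev <- tapply(d$count, d$stratum, sum)
  keep_lab <- names(tab)[tab >= 2 & ev[names(tab)] > 0]
  drop_rows <- !(as.character(d$stratum) %in% keep_lab)
  n_str <- sum(drop_rows)
  d <- d[!drop_rows, , drop = FALSE]
  if (nrow(d) == 0) stop("no informative strata at lag ", L)
  d$stratum <- droplevels(d$stratum)
  W <- cbind(natural_spline_basis(d$temperature, df),
             natural_spline_basis(d$humidity, df))
  colnames(W) <- c(paste0("temp_ns", seq_len(df)), paste0("rhum_ns", seq_len(df)))
  si <- as.integer(d$stratum)
  structure(list(lag = L, y = d$count, z = d$exposure, W = W,
                 strata = d$stratum, date = d$date,
                 r = max(d$exposure) - min(d$exposure),
                 n_dropped_na = n_na, n_dropped_strata = n_str,
                 # cached stratum indexing for repeated refits
                 si = si, Ys = drop(rowsum(d$count, si)),
                 grp = split(seq_len(nrow(d)), si)),
            class = "lagged_design")
}
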