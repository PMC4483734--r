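#' Construct a validated daily mortality time series
#'
#' Bundles daily mean temperature, relative humidity and one or more
#' non-negative integer death-count series on a strictly contiguous daily
#' calendar. All downstream modelling assumes contiguity because lagged
#' exposures are read off the series itself.
#'
#' @param dates vector coercible to `Date`; must be strictly increasing with
#'   a step of exactly one day.
#' @param tmean daily mean temperature (degrees C), finite.
#' @param rh daily mean relative humidity (%), in (0, 100].
#' @param deaths data frame (or named list) of daily death counts, one column
#'   per mortality category; non-negative integers.
#' @return An object of class `mortality_ts`: a data frame with columns
#'   `date`, `tmean`, `rh` and one column per category, plus a `categories`
#'   attribute giving the category order.
#' @export
mortality_ts <- function(dates, tmean, rh, deaths) {
  dates <- as.Date(dates)
  deaths <- as.data.frame(deaths)
  if (length(dates) == 0L) stop("empty series")
  if (anyNA(dates)) stop("unparseable or missing dates")
  n <- length(dates)
  if (anyDuplicated(dates)) {
    stop("duplicate dates: ", paste(dates[duplicated(dates)], collapse = ", "))
  }
  if (n > 1L) {
    step <- diff(as.integer(dates))
    if (any(step <= 0L)) stop("dates are not strictly increasing")
    if (any(step != 1L)) {
      i <- which(step != 1L)[1L]
      stop(sprintf("date gap between %s and %s (missing %d day(s))",
                   dates[i], dates[i + 1L], step[i] - 1L))
    }
  }
  if (length(tmean) != n || length(rh) != n || nrow(deaths) != n) {
    stop("tmean, rh and death counts must all have one value per date")
  }
  if (!all(is.finite(tmean))) stop("tmean contains non-finite values")
  if (!all(is.finite(rh)) || any(rh <= 0 | rh > 100)) {
    stop("rh must lie in (0, 100]")
  }
  if (ncol(deaths) == 0L) stop("at least one death-count category is required")
  for (nm in names(deaths)) {
    y <- deaths[[nm]]
    bad <- which(!is.finite(y) | y < 0 | y != round(y))
    if (length(bad)) {
      stop(sprintf("category '%s': non-integer or negative count at row %d (value %s)",
                   nm, bad[1L], format(y[bad[1L]])))
    }
    deaths[[nm]] <- as.integer(round(y))
  }
  out <- data.frame(date = dates, tmean = as.numeric(tmean),
                    rh = as.numeric(rh), deaths, check.names = FALSE)
  structure(out, categories = names(deaths),
            class = c("mortality_ts", "data.frame"))
}

#' Mortality categories of a series
#' @param series a `mortality_ts`.
#' @return character vector of category column names.
#' @export
categories <- function(series) attr(series, "categories")

#' Read a daily mortality time series from CSV
#'
#' Expects a header row with columns `date` (ISO 8601), `tmean`, `rh`, and
#' one column per mortality category. Validation is strict: duplicate dates,
#' calendar gaps, and negative or non-integer counts are errors (contiguity
#' is required by the lag structure). With `allow_gaps = TRUE` nothing is
#' imputed; the series is split at each gap and a list of contiguous
#' `mortality_ts` segments is returned.
#'
#' @param path CSV file path.
#' @param category_columns optional character vector naming the count columns
#'   to keep (default: every column other than date/tmean/rh).
#' @param allow_gaps split at gaps instead of erroring.
#' @return a `mortality_ts`, or a list of them when `allow_gaps = TRUE` and
#'   gaps are present.
#' @export
read_timeseries <- function(path, category_columns = NULL, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("date", "tmean", "rh")) {
    if (!col %in% names(raw)) stop("missing required column: ", col)
  }
  if (is.null(category_columns)) {
    category_columns <- setdiff(names(raw), c("date", "tmean", "rh"))
  }
  missing_cat <- setdiff(category_columns, names(raw))
  if (length(missing_cat)) {
    stop("missing category column: ", paste(missing_cat, collapse = ", "))
  }
  if (length(category_columns) == 0L) stop("no category columns found")
  build <- function(rows) {
    mortality_ts(raw$date[rows], raw$tmean[rows], raw$rh[rows],
                 raw[rows, category_columns, drop = FALSE])
  }
  if (!allow_gaps) return(build(seq_len(nrow(raw))))
  d <- as.Date(raw$date)
  if (anyNA(d)) stop("unparseable dates")
  seg <- cumsum(c(1L, diff(as.integer(d)) != 1L))
  pieces <- lapply(split(seq_len(nrow(raw)), seg), build)
  if (length(pieces) == 1L) pieces[[1L]] else unname(pieces)
}

#' Write a mortality time series to CSV
#'
#' Inverse of [read_timeseries()]: `read_timeseries(write_timeseries(s, f))`
#' reproduces `s`.
#'
#' @param series a `mortality_ts`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify dates into PAGASA climatological seasons
#'
#' The Philippine seasonal quarters: DJF (northeast monsoon; December to
#' February), MAM (summer; March to May), JJA (southwest monsoon; June to
#' August) and SON (transition; September to November). A pure function of
#' the calendar month.
#'
#' @param date vector coercible to `Date`.
#' @return factor with levels `DJF`, `MAM`, `JJA`, `SON`.
#' @export
classify_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  lab <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
           "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  factor(lab, levels = c("DJF", "MAM", "JJA", "SON"))
}

#' Derive calendar covariates for a mortality series
#'
#' Computes the regression controls used by the mortality models: day of week
#' (factor, Monday = 0), a 0/1 public-holiday indicator, day of year,
#' a 0-based time index for the long-term trend spline, and the PAGASA
#' season label.
#'
#' @param series a `mortality_ts`.
#' @param holidays vector of holiday dates (default none; the holiday
#'   calendar is study-specific and supplied externally).
#' @return data frame with columns `dow`, `hod`, `doy`, `time_index`,
#'   `season`, one row per series day.
#' @export
derive_calendar_covariates <- function(series, holidays = as.Date(character())) {
  holidays <- as.Date(holidays)
  d <- series$date
  outside <- holidays[holidays < min(d) | holidays > max(d)]
  if (length(outside)) {
    warning("holiday outside series range: ",
            paste(format(outside), collapse = ", "))
  }
  dow <- factor(as.integer(format(d, "%u")) - 1L, levels = 0:6)
  data.frame(
    dow = dow,
    hod = as.integer(d %in% holidays),
    doy = as.POSIXlt(d)$yday + 1L,
    time_index = seq_along(d) - 1L,
    season = classify_season(d)
  )
}

#' Summary statistics table for a mortality series
#'
#' Per variable (temperature, humidity, each mortality category; optionally
#' repeated within each PAGASA season): mean, SD, minimum, 10th/50th/90th
#' percentiles and maximum. Percentiles use linear interpolation between
#' order statistics (quantile type 7) throughout the package, so reported
#' percentile temperatures are reproducible.
#'
#' @param series a `mortality_ts`.
#' @param by_season also compute the statistics within each season.
#' @return data frame with columns `variable`, `season` (`"all"` for the
#'   pooled rows), `mean`, `sd`, `min`, `p10`, `p50`, `p90`, `max`.
#' @export
summary_statistics <- function(series, by_season = FALSE) {
  if (nrow(series) == 0L) stop("empty series")
  vars <- c("tmean", "rh", categories(series))
  one <- function(x, variable, season) {
    q <- stats::quantile(x, c(.1, .5, .9), type = 7, names = FALSE)
    data.frame(variable = variable, season = season, mean = mean(x),
               sd = stats::sd(x), min = min(x), p10 = q[1L], p50 = q[2L],
               p90 = q[3L], max = max(x))
  }
  out <- do.call(rbind, lapply(vars, function(v) one(series[[v]], v, "all")))
  if (by_season) {
    sn <- classify_season(series$date)
    for (s in levels(sn)) {
      rows <- sn == s
      if (!any(rows)) next
      out <- rbind(out, do.call(rbind, lapply(vars, function(v) {
        one(series[[v]][rows], v, s)
      })))
    }
  }
  rownames(out) <- NULL
  out
}
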