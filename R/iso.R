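# ISO 8601 value codec for TIMEX3 Value strings.
#
# An iso_value is one of four variants:
#   date     - calendar date with precision year / month / day
#   time     - clock time, optionally carrying its calendar date
#   duration - PnYnMnWnDTnHnMnS with non-negative integer components
#   set      - bracketed, comma-joined list of calendar dates
# Precision is part of the value: "2014" and "2014-01" are different values.

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  ifelse(month == 2L & leap, 29L, dm[month])
}

#' Construct a calendar-date value
#'
#' @param year integer year.
#' @param month optional month 1-12; `NA` for year precision.
#' @param day optional day of month; `NA` for month precision.
#' @return an `iso_value` of variant `"date"`.
#' @export
iso_date <- function(year, month = NA, day = NA) {
  year <- as.integer(year); month <- as.integer(month); day <- as.integer(day)
  if (is.na(year)) stop("iso_date: year is required")
  if (is.na(month) && !is.na(day)) stop("iso_date: day without month")
  if (!is.na(month) && (month < 1 || month > 12)) {
    stop(sprintf("iso_date: month %d out of range", month))
  }
  if (!is.na(day) && (day < 1 || day > days_in_month(year, month))) {
    stop(sprintf("iso_date: day %d invalid for %04d-%02d", day, year, month))
  }
  structure(list(kind = "date", year = year, month = month, day = day),
            class = "iso_value")
}

#' Construct a clock-time value
#'
#' @param date optional `iso_value` date (day precision) the time belongs to.
#' @param hour,minute,second integer clock fields.
#' @return an `iso_value` of variant `"time"`.
#' @export
iso_time <- function(date = NULL, hour, minute = 0, second = 0) {
  hour <- as.integer(hour); minute <- as.integer(minute); second <- as.integer(second)
  if (hour < 0 || hour > 23 || minute < 0 || minute > 59 || second < 0 || second > 60) {
    stop("iso_time: clock field out of range")
  }
  if (!is.null(date)) {
    stopifnot(inherits(date, "iso_value"), date$kind == "date")
    if (is.na(date$day)) stop("iso_time: date part must have day precision")
  }
  structure(list(kind = "time", date = date, hour = hour, minute = minute,
                 second = second), class = "iso_value")
}

#' Construct a duration value
#'
#' Pure-week durations serialize as PnW; weeks mixed with any other unit are
#' converted to days (ISO 8601 forbids mixing the W designator).
#'
#' @param years,months,weeks,days,hours,minutes,seconds non-negative integers.
#' @return an `iso_value` of variant `"duration"`.
#' @export
iso_duration <- function(years = 0, months = 0, weeks = 0, days = 0,
                         hours = 0, minutes = 0, seconds = 0) {
  v <- vapply(list(years, months, weeks, days, hours, minutes, seconds),
              as.integer, integer(1))
  if (any(is.na(v)) || any(v < 0)) stop("iso_duration: components must be non-negative integers")
  if (sum(v) == 0) stop("iso_duration: at least one component must be nonzero")
  names(v) <- c("years", "months", "weeks", "days", "hours", "minutes", "seconds")
  if (v[["weeks"]] > 0 && sum(v[-3]) > 0) {
    v[["days"]] <- v[["days"]] + 7L * v[["weeks"]]
    v[["weeks"]] <- 0L
  }
  structure(c(list(kind = "duration"), as.list(v)), class = "iso_value")
}

#' Construct a date-set value
#'
#' @param dates non-empty list of date `iso_value`s.
#' @return an `iso_value` of variant `"set"`.
#' @export
iso_dateset <- function(dates) {
  if (length(dates) == 0) stop("iso_dateset: set must be non-empty")
  ok <- vapply(dates, function(d) inherits(d, "iso_value") && d$kind == "date",
               logical(1))
  if (!all(ok)) stop("iso_dateset: all members must be calendar dates")
  structure(list(kind = "set", dates = dates), class = "iso_value")
}

iso_precision <- function(v) {
  stopifnot(inherits(v, "iso_value"))
  switch(v$kind,
    date = if (!is.na(v$day)) "day" else if (!is.na(v$month)) "month" else "year",
    time = if (!is.null(v$date)) "second" else "clock",
    stop("iso_precision: defined for date/time values only"))
}

# Date part of a value (day-precise date), or NULL.
iso_date_part <- function(v) {
  if (v$kind == "date" && !is.na(v$day)) return(v)
  if (v$kind == "time" && !is.null(v$date)) return(v$date)
  NULL
}

iso_to_Date <- function(v) {
  d <- iso_date_part(v)
  if (is.null(d)) stop("value has no day-precise date part")
  as.Date(sprintf("%04d-%02d-%02d", d$year, d$month, d$day))
}

Date_to_iso <- function(d) {
  lt <- as.POSIXlt(d)
  iso_date(lt$year + 1900L, lt$mon + 1L, lt$mday)
}

#' Serialize an ISO 8601 value to its canonical string
#'
#' Months, days and clock fields are always zero-padded; durations omit zero
#' components; date sets serialize as a bracketed comma-joined list.
#' `parse_iso(format_iso(v))` reproduces `v`.
#'
#' @param v an `iso_value`.
#' @return character scalar.
#' @export
format_iso <- function(v) {
  stopifnot(inherits(v, "iso_value"))
  switch(v$kind,
    date = {
      if (is.na(v$month)) sprintf("%04d", v$year)
      else if (is.na(v$day)) sprintf("%04d-%02d", v$year, v$month)
      else sprintf("%04d-%02d-%02d", v$year, v$month, v$day)
    },
    time = {
      clock <- sprintf("%02d:%02d:%02d", v$hour, v$minute, v$second)
      if (is.null(v$date)) clock else paste0(format_iso(v$date), "T", clock)
    },
    duration = {
      units <- c(years = "Y", months = "M", weeks = "W", days = "D")
      tunits <- c(hours = "H", minutes = "M", seconds = "S")
      dpart <- paste0(unlist(lapply(names(units), function(u) {
        if (v[[u]] > 0) paste0(v[[u]], units[[u]]) else NULL
      })), collapse = "")
      tpart <- paste0(unlist(lapply(names(tunits), function(u) {
        if (v[[u]] > 0) paste0(v[[u]], tunits[[u]]) else NULL
      })), collapse = "")
      paste0("P", dpart, if (nzchar(tpart)) paste0("T", tpart) else "")
    },
    set = paste0("[", paste(vapply(v$dates, format_iso, character(1)),
                            collapse = ","), "]")
  )
}

#' Parse an ISO 8601 value string
#'
#' Accepts calendar dates at year/month/day precision (zero-padded or,
#' leniently, unpadded), clock times with optional date part, durations
#' (PnYnMnWnDTnHnMnS), and bracketed date sets.
#'
#' @param s a non-empty value string.
#' @return an `iso_value`; malformed input raises an error naming the
#'   offending token.
#' @export
parse_iso <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) {
    stop("parse_iso: input must be a non-empty string")
  }
  if (startsWith(s, "[")) {
    if (!endsWith(s, "]")) stop(sprintf("parse_iso: unterminated set '%s'", s))
    inner <- substr(s, 2, nchar(s) - 1)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    if (length(parts) == 0 || any(!nzchar(parts))) {
      stop(sprintf("parse_iso: empty member in set '%s'", s))
    }
    return(iso_dateset(lapply(parts, parse_iso_date)))
  }
  if (startsWith(s, "P")) return(parse_iso_duration(s))
  if (grepl("T", s, fixed = TRUE)) {
    halves <- strsplit(s, "T", fixed = TRUE)[[1]]
    if (length(halves) != 2) stop(sprintf("parse_iso: malformed time '%s'", s))
    d <- parse_iso_date(halves[1])
    if (is.na(d$day)) stop(sprintf("parse_iso: time requires a full date in '%s'", s))
    return(parse_iso_clock(halves[2], d))
  }
  if (grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?$", s)) return(parse_iso_clock(s, NULL))
  parse_iso_date(s)
}

parse_iso_date <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{4})(?:-([0-9]{1,2})(?:-([0-9]{1,2}))?)?$", s))[[1]]
  if (length(m) == 0) stop(sprintf("parse_iso: malformed date token '%s'", s))
  iso_date(as.integer(m[2]),
           if (nzchar(m[3])) as.integer(m[3]) else NA,
           if (nzchar(m[4])) as.integer(m[4]) else NA)
}

parse_iso_clock <- function(s, date) {
  m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{1,2})(?::([0-9]{1,2}))?$", s))[[1]]
  if (length(m) == 0) stop(sprintf("parse_iso: malformed clock token '%s'", s))
  iso_time(date, as.integer(m[2]), as.integer(m[3]),
           if (nzchar(m[4])) as.integer(m[4]) else 0L)
}

parse_iso_duration <- function(s) {
  m <- regmatches(s, regexec(
    "^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)W)?(?:([0-9]+)D)?(?:T(?:([0-9]+)H)?(?:([0-9]+)M)?(?:([0-9]+)S)?)?$",
    s))[[1]]
  if (length(m) == 0 || s == "P" || endsWith(s, "T")) {
    stop(sprintf("parse_iso: malformed duration token '%s'", s))
  }
  num <- function(x) if (nzchar(x)) as.integer(x) else 0L
  comps <- vapply(m[2:8], num, integer(1))
  if (sum(comps) == 0) stop(sprintf("parse_iso: empty duration '%s'", s))
  iso_duration(comps[1], comps[2], comps[3], comps[4], comps[5], comps[6], comps[7])
}

#' @export
print.iso_value <- function(x, ...) {
  cat("<iso_value ", x$kind, "> ", format_iso(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.iso_value <- function(x, ...) format_iso(x)

iso_equal <- function(a, b) identical(format_iso(a), format_iso(b))
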