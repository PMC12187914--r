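# FAERS dates are 4-, 6- or 8-digit numerics (year / year-month /
# year-month-day).  They are carried around as raw digit strings and parsed
# into a small partial-date table on demand.

#' Parse FAERS partial-precision dates
#'
#' FAERS date fields hold 4, 6 or 8 digits giving year, year+month or a full
#' calendar date. `parse_partial_date()` splits such strings into components
#' and records the attained precision (`"Y"`, `"YM"` or `"YMD"`). Full dates
#' must be calendar-valid (so `"20180230"` is rejected).
#'
#' @param x character vector of digit strings; `NA` or empty strings are
#'   treated as missing and yield an all-`NA` row.
#' @param strict if `TRUE` (default) any non-missing value that is not a valid
#'   4/6/8-digit date is an error; if `FALSE` such values yield an all-`NA`
#'   row so callers can collect record-level rejects.
#' @return a data frame with one row per input and columns `year`, `month`,
#'   `day` (integer, `NA` beyond the attained precision) and `precision`
#'   (character, `NA` for missing/invalid input).
#' @export
#' @examples
#' parse_partial_date(c("2018", "202406", "20040101"))
parse_partial_date <- function(x, strict = TRUE) {
  x <- as.character(x)
  x[!is.na(x)] <- trimws(x[!is.na(x)])
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  blank <- is.na(x) | x == ""
  form_ok <- !blank & grepl("^[0-9]+$", x) & nchar(x) %in% c(4L, 6L, 8L)
  valid <- form_ok

  idx <- which(form_ok)
  if (length(idx)) {
    y <- as.integer(substr(x[idx], 1, 4))
    m <- ifelse(nchar(x[idx]) >= 6, as.integer(substr(x[idx], 5, 6)), NA_integer_)
    d <- ifelse(nchar(x[idx]) == 8, as.integer(substr(x[idx], 7, 8)), NA_integer_)

    bad_m <- !is.na(m) & (m < 1L | m > 12L)
    valid[idx[bad_m]] <- FALSE
    i8 <- which(!is.na(d) & !bad_m)
    if (length(i8)) {
      cal <- as.Date(x[idx][i8], format = "%Y%m%d")
      valid[idx[i8][is.na(cal)]] <- FALSE
    }

    keep <- valid[idx]
    year[idx][keep] <- y[keep]
    month[idx][keep] <- m[keep]
    day[idx][keep] <- d[keep]
    precision[idx][keep] <- c("Y", "YM", "YMD")[nchar(x[idx][keep]) / 2 - 1]
  }

  if (strict && any(!blank & !valid)) {
    bad <- x[!blank & !valid]
    stop("invalid partial date(s): ", paste(utils::head(unique(bad), 5), collapse = ", "),
         call. = FALSE)
  }
  data.frame(year = year, month = month, day = day, precision = precision,
             stringsAsFactors = FALSE)
}

# Numeric sort key on the yyyymmdd scale; missing month/day pad with 00 so a
# lower-precision date sorts before any full date in the same month/year.
# Missing/invalid input -> NA.
#' @noRd
partial_date_key <- function(x) {
  pd <- parse_partial_date(x, strict = FALSE)
  ifelse(is.na(pd$precision), NA_real_,
         pd$year * 10000 + ifelse(is.na(pd$month), 0, pd$month) * 100 +
           ifelse(is.na(pd$day), 0, pd$day))
}

# Date conversion for full-precision values only; else NA.
#' @noRd
partial_date_as_date <- function(x) {
  pd <- parse_partial_date(x, strict = FALSE)
  out <- as.Date(rep(NA, length(x)))
  full <- !is.na(pd$precision) & pd$precision == "YMD"
  if (any(full)) {
    out[full] <- as.Date(sprintf("%04d%02d%02d", pd$year[full], pd$month[full],
                                 pd$day[full]), format = "%Y%m%d")
  }
  out
}
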