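# Device wear-day counting, overnight charging compliance and missing-data
# attribution for the 14-day inclinometer period.

#' Overnight charging compliance
#'
#' The 14-day period contains 13 overnight windows (night of day d to day
#' d+1, d = 1..13). One charging occurrence per window is 100% compliance.
#' A window counts when it contains at least one `charging` epoch. The
#' window runs from `night_start` on day d to `night_end` on day d+1;
#' "overnight" has no printed clock bounds, so both are configurable.
#'
#' @param series A [posture_series()] spanning days 1-14 post discharge.
#' @param night_start,night_end Window bounds as `"HH:MM"` strings
#'   (defaults 18:00 and 12:00).
#' @return A list: `charging_days` (windows with a charge), `n_windows`
#'   (denominator; pro-rated with a warning if the series stops early) and
#'   `compliance_pct`.
#' @export
charging_compliance <- function(series, night_start = "18:00", night_end = "12:00") {
  stopifnot(inherits(series, "posture_series"))
  d0 <- attr(series, "discharge_date")
  eplen <- attr(series, "epoch_length")
  if (!nrow(series)) stop("empty series")
  span_end <- series$timestamp[nrow(series)] + eplen
  hm <- function(day, s) as.POSIXct(paste(format(d0 + day), s), tz = "UTC")
  windows <- lapply(1:13, function(d) c(hm(d, night_start), hm(d + 1, night_end)))
  covered <- vapply(windows, function(w) w[2] <= span_end, logical(1))
  if (!all(covered))
    warning("series shorter than 14 days: pro-rating compliance over ",
            sum(covered), " of 13 overnight windows")
  n_win <- sum(covered)
  charging_ts <- series$timestamp[series$device_status == "charging"]
  charged <- vapply(windows[covered], function(w)
    any(charging_ts >= w[1] & charging_ts < w[2]), logical(1))
  list(charging_days = sum(charged),
       n_windows = n_win,
       compliance_pct = if (n_win > 0) round_half_up(100 * sum(charged) / n_win, 2) else NA_real_)
}

#' Attribute each monitoring day to a wear/missing-data cause
#'
#' A day with at least one worn epoch is `worn`. A day with none is
#' `switched_off` when manually-off epochs strictly dominate the other
#' non-wear states, `battery_dead` when depleted-battery epochs dominate
#' (ties between off and dead resolve to `battery_dead`, conservative
#' toward device fault), and `not_worn` otherwise.
#'
#' @param series A [posture_series()].
#' @return A data frame per calendar day: `date`, `day_index`,
#'   `attribution`.
#' @export
attribute_missing <- function(series) {
  stopifnot(inherits(series, "posture_series"))
  d0 <- attr(series, "discharge_date")
  dates <- epoch_date(series$timestamp)
  rows <- lapply(split(series$device_status, dates), function(st) {
    if (any(st == "worn")) return("worn")
    off <- sum(st == "off")
    dead <- sum(st == "battery_dead")
    other <- sum(st %in% c("not_worn", "charging"))
    if (dead >= off && dead > other) "battery_dead"
    else if (off > dead && off > other) "switched_off"
    else "not_worn"
  })
  out <- data.frame(date = as.Date(names(rows)),
                    attribution = unlist(rows, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out$day_index <- as.integer(out$date - d0)
  rownames(out) <- NULL
  out[order(out$date), c("date", "day_index", "attribution")]
}

#' Device adherence report
#'
#' Combines wear-day counting, per-day missing-data attribution and
#' overnight charging compliance for one patient's 14-day series. Any worn
#' epoch counts the day as worn.
#'
#' @inheritParams charging_compliance
#' @return A list of class `adherence_report`: `days_worn`, `days_observed`,
#'   `attribution` (data frame), `charging_days`, `compliance_pct`.
#' @export
adherence_report <- function(series, night_start = "18:00", night_end = "12:00") {
  attr_days <- attribute_missing(series)
  charge <- charging_compliance(series, night_start, night_end)
  out <- list(days_worn = sum(attr_days$attribution == "worn"),
              days_observed = nrow(attr_days),
              attribution = attr_days,
              charging_days = charge$charging_days,
              n_windows = charge$n_windows,
              compliance_pct = charge$compliance_pct)
  class(out) <- "adherence_report"
  out
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf("Worn on %d of %d days; charged in %d of %d overnight windows (%.2f%%)\n",
              x$days_worn, x$days_observed, x$charging_days, x$n_windows,
              x$compliance_pct))
  invisible(x)
}
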