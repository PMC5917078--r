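# Count-based wear-time validation, intensity classification and daily
# physical-activity summaries.

#' Intensity cut-points for count-per-minute classification
#'
#' Stationary time is `< stationary_below` counts/min; moderate-to-vigorous
#' activity (MVPA) is `>= mvpa_at_or_above`; everything between is light.
#' The stationary cut defaults to 100 cpm; the MVPA cut defaults to the
#' widely used 1952 cpm vertical-axis ambulation threshold and is
#' configurable.
#'
#' @param stationary_below Stationary cut in counts/min (default 100).
#' @param mvpa_at_or_above MVPA cut in counts/min (default 1952).
#' @return A list of class `intensity_cutpoints`.
#' @export
intensity_cutpoints <- function(stationary_below = 100, mvpa_at_or_above = 1952) {
  if (!(stationary_below > 0 && stationary_below < mvpa_at_or_above))
    stop("cut-points must satisfy 0 < stationary_below < mvpa_at_or_above")
  structure(list(stationary_below = stationary_below,
                 mvpa_at_or_above = mvpa_at_or_above),
            class = "intensity_cutpoints")
}

#' Classify epoch counts into intensity bands
#'
#' @param counts_value Numeric vector of counts/min (>= 0).
#' @param cuts An [intensity_cutpoints()] object.
#' @return Factor with levels `stationary`, `light`, `mvpa`.
#' @export
#' @examples
#' classify_intensity(c(0, 99, 100, 1952), intensity_cutpoints())
classify_intensity <- function(counts_value, cuts = intensity_cutpoints()) {
  stopifnot(inherits(cuts, "intensity_cutpoints"))
  if (any(counts_value < 0, na.rm = TRUE)) stop("counts must be non-negative")
  out <- ifelse(counts_value < cuts$stationary_below, "stationary",
                ifelse(counts_value >= cuts$mvpa_at_or_above, "mvpa", "light"))
  factor(out, levels = c("stationary", "light", "mvpa"))
}

#' Flag non-wear in a counts series
#'
#' Any run of at least `window` consecutive zero-count minutes is flagged
#' as not worn; all other epochs are worn. The rule is idempotent and
#' widening the window can only reduce the epochs flagged.
#'
#' @param counts A [counts_series()].
#' @param window Minimum zero run to call non-wear, in minutes (default 60).
#' @return The input series with a logical `worn` column added.
#' @export
detect_nonwear <- function(counts, window = 60) {
  stopifnot(inherits(counts, "counts_series"))
  eplen <- attr(counts, "epoch_length")
  if (window * 60 < eplen) stop("non-wear window is shorter than the epoch length")
  worn <- rep(TRUE, nrow(counts))
  if (nrow(counts)) {
    r <- rle(counts$counts == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long0 <- r$values & (r$lengths * eplen / 60) >= window
    for (i in which(long0)) worn[starts[i]:ends[i]] <- FALSE
  }
  counts$worn <- worn
  counts
}

#' Day-level wear validity and activity summaries
#'
#' Splits a wear-flagged counts series into calendar days and reports, for
#' each: wear minutes, validity (>= 480 worn minutes, i.e. 8 hours), step
#' total over worn epochs and the percentage of worn time spent stationary,
#' in light activity and in MVPA. Percentages are `NA` on zero-wear days.
#'
#' @param flagged A counts series with a `worn` column ([detect_nonwear()]).
#' @param cuts An [intensity_cutpoints()] object.
#' @param valid_min Minimum worn minutes for a valid day (default 480).
#' @return A data frame with one row per day: `date`, `day_index`,
#'   `wear_min`, `valid`, `steps`, `pct_stationary`, `pct_light`,
#'   `pct_mvpa`.
#' @export
validate_days <- function(flagged, cuts = intensity_cutpoints(), valid_min = 480) {
  stopifnot(inherits(flagged, "counts_series"), "worn" %in% names(flagged))
  eplen <- attr(flagged, "epoch_length")
  mpe <- eplen / 60
  d0 <- attr(flagged, "discharge_date")
  dates <- epoch_date(flagged$timestamp)
  rows <- lapply(split(seq_len(nrow(flagged)), dates), function(idx) {
    w <- idx[flagged$worn[idx]]
    wear_min <- length(w) * mpe
    if (length(w)) {
      band <- classify_intensity(flagged$counts[w] / mpe, cuts)
      shares <- as.numeric(table(band)) / length(w)
    } else {
      shares <- rep(NA_real_, 3)
    }
    data.frame(date = dates[idx[1]],
               day_index = as.integer(dates[idx[1]] - d0),
               wear_min = wear_min,
               valid = wear_min >= valid_min,
               steps = as.integer(sum(flagged$steps[w])),
               pct_stationary = round_half_up(100 * shares[1], 2),
               pct_light = round_half_up(100 * shares[2], 2),
               pct_mvpa = round_half_up(100 * shares[3], 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Two-week inclusion rule
#'
#' A patient enters the activity analyses when both post-discharge weeks
#' (days 1-7 and days 8-14) contain at least `min_valid` valid days.
#'
#' @param valid_days Data frame from [validate_days()] with `day_index` in
#'   1..14.
#' @param min_valid Minimum valid days per week (default 4).
#' @return A list: `week1_valid_days`, `week2_valid_days`, `included`.
#' @export
patient_inclusion <- function(valid_days, min_valid = 4) {
  stopifnot(is.data.frame(valid_days), "day_index" %in% names(valid_days))
  if (any(valid_days$day_index < 1 | valid_days$day_index > 14))
    stop("day index outside 1-14: ",
         valid_days$day_index[which(valid_days$day_index < 1 | valid_days$day_index > 14)[1]])
  w1 <- sum(valid_days$valid[valid_days$day_index <= 7])
  w2 <- sum(valid_days$valid[valid_days$day_index >= 8])
  list(week1_valid_days = w1, week2_valid_days = w2,
       included = w1 >= min_valid && w2 >= min_valid)
}

#' Cohort daily activity profile
#'
#' Day-index-wise means of steps and intensity percentages over patients
#' with a valid day at that index (the trial's daily step-trajectory view).
#' Pass only included patients.
#'
#' @param valid_days Data frame combining per-patient [validate_days()]
#'   output with a `patient_id` column.
#' @return A data frame per day index: `day_index`, `n`, `mean_steps`,
#'   `mean_pct_stationary`, `mean_pct_light`, `mean_pct_mvpa`. Empty input
#'   gives an empty profile.
#' @export
cohort_daily_profile <- function(valid_days) {
  stopifnot(is.data.frame(valid_days))
  empty <- data.frame(day_index = integer(), n = integer(),
                      mean_steps = numeric(), mean_pct_stationary = numeric(),
                      mean_pct_light = numeric(), mean_pct_mvpa = numeric())
  if (!nrow(valid_days)) return(empty)
  v <- valid_days[valid_days$valid, , drop = FALSE]
  if (!nrow(v)) return(empty)
  rows <- lapply(split(v, v$day_index), function(d) {
    data.frame(day_index = d$day_index[1], n = nrow(d),
               mean_steps = mean(d$steps),
               mean_pct_stationary = mean(d$pct_stationary),
               mean_pct_light = mean(d$pct_light),
               mean_pct_mvpa = mean(d$pct_mvpa))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$day_index), , drop = FALSE]
}
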