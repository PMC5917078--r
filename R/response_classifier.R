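# Post-prompt behavioural-response adjudication and summary statistics.
#
# For each prompt the subsequent 15 minutes are examined (truncated at the
# next prompt and at the first non-worn epoch). A response is any worn
# standing or stepping epoch inside that window. Latency is measured to the
# completion of the first such epoch, so it lives in (0, 15] minutes at
# 60-s epochs; a response is "within 5 min" when latency <= 5. Response
# magnitudes (minutes standing, minutes walking, steps) are accumulated
# over the 5-minute post-prompt frame only.

#' Classify the behavioural response to a single prompt
#'
#' @param series A [posture_series()].
#' @param prompt A prompt timestamp (POSIXct) or a one-row data frame from
#'   [detect_prompts()].
#' @param next_prompt Timestamp of the following prompt, or `NULL`; the
#'   analysis window is truncated there.
#' @param response_window Analysis window length in minutes (default 15).
#' @param magnitude_window Frame over which magnitudes are accumulated, in
#'   minutes (default 5).
#' @return A one-row data frame: `timestamp`, `responded`, `latency_min`
#'   (`NA` for non-responses), `within_5min`, `stand_min`, `walk_min`,
#'   `steps`, `window_truncated`, `window_worn_min` (worn minutes actually
#'   observed in the window, 0 when the whole window was non-wear).
#' @export
classify_response <- function(series, prompt, next_prompt = NULL,
                              response_window = 15, magnitude_window = 5) {
  stopifnot(inherits(series, "posture_series"))
  t0 <- if (is.data.frame(prompt)) prompt$timestamp[1] else as.POSIXct(prompt, tz = "UTC")
  if (!is.null(next_prompt) && is.data.frame(next_prompt))
    next_prompt <- next_prompt$timestamp[1]
  eplen <- attr(series, "epoch_length")
  mpe <- eplen / 60
  n <- nrow(series)
  if (n == 0 || t0 < series$timestamp[1] || t0 > series$timestamp[n] + eplen)
    stop("prompt timestamp ", format_ts(t0), " lies outside the series span")

  win_end <- t0 + response_window * 60
  truncated <- FALSE
  if (!is.null(next_prompt) && next_prompt < win_end) {
    win_end <- next_prompt
    truncated <- TRUE
  }
  idx <- which(series$timestamp >= t0 & series$timestamp < win_end)
  # truncate at the first non-worn epoch
  nw <- which(series$device_status[idx] != "worn")
  if (length(nw)) {
    idx <- idx[seq_len(nw[1] - 1L)]
    truncated <- TRUE
  }
  # window running off the end of the series also counts as truncation
  if (win_end > series$timestamp[n] + eplen) truncated <- TRUE

  active <- series$posture[idx] %in% ACTIVE_POSTURES
  responded <- any(active)
  latency <- NA_real_
  if (responded) {
    first <- idx[which(active)[1]]
    latency <- as.numeric(difftime(series$timestamp[first], t0, units = "mins")) + mpe
  }
  mag_idx <- idx[series$timestamp[idx] < t0 + magnitude_window * 60]
  data.frame(timestamp = t0,
             responded = responded,
             latency_min = latency,
             within_5min = responded && latency <= 5,
             stand_min = sum(series$posture[mag_idx] == "standing") * mpe,
             walk_min = sum(series$posture[mag_idx] == "stepping") * mpe,
             steps = as.integer(sum(series$steps[mag_idx])),
             window_truncated = truncated,
             window_worn_min = length(idx) * mpe,
             stringsAsFactors = FALSE)
}

#' Classify responses to every prompt in a series
#'
#' Vectorised wrapper around [classify_response()]: each prompt's window is
#' truncated at the next prompt automatically.
#'
#' @param series A [posture_series()].
#' @param prompts Data frame from [detect_prompts()] in temporal order.
#' @inheritParams classify_response
#' @return The `prompts` data frame with the classification columns bound
#'   on, one row per prompt.
#' @export
classify_responses <- function(series, prompts, response_window = 15,
                               magnitude_window = 5) {
  stopifnot(is.data.frame(prompts))
  n <- nrow(prompts)
  if (n == 0) {
    cls <- classify_response(series, series$timestamp[1], NULL,
                             response_window, magnitude_window)[0, ]
    return(cbind(prompts, cls[, setdiff(names(cls), "timestamp"), drop = FALSE]))
  }
  rows <- lapply(seq_len(n), function(i) {
    nxt <- if (i < n) prompts$timestamp[i + 1] else NULL
    classify_response(series, prompts$timestamp[i], nxt,
                      response_window, magnitude_window)
  })
  cls <- do.call(rbind, rows)
  cbind(prompts, cls[, setdiff(names(cls), "timestamp"), drop = FALSE])
}

#' Summarise prompt outcomes
#'
#' Pools classified prompts into the study-level outcome summary: response
#' rate, share of non-responses, share of responses occurring within 5
#' minutes, magnitude means/SDs over within-5-min responses, prompts per
#' day and the share of observed days with at least one prompt.
#'
#' Percentages are reported to two decimals, rounding half away from zero;
#' an empty input yields zero prompts and `NA` rates.
#'
#' @param classifications Data frame from [classify_responses()] (may pool
#'   several patients; needs `responded`, `within_5min`, magnitude and
#'   `day_index` columns).
#' @param n_days_observed Number of monitoring days the prompts were
#'   collected over (> 0).
#' @param nonwear_windows How to treat prompts whose whole analysis window
#'   was non-wear: `"include"` (default; they count as non-responses, the
#'   study's convention) or `"exclude"` (drop them from all denominators).
#' @return A list of class `prompt_summary`.
#' @export
summarize_prompts <- function(classifications, n_days_observed,
                              nonwear_windows = c("include", "exclude")) {
  nonwear_windows <- match.arg(nonwear_windows)
  stopifnot(is.data.frame(classifications))
  if (length(n_days_observed) != 1 || is.na(n_days_observed) || n_days_observed <= 0)
    stop("n_days_observed must be a positive number of days")
  cls <- classifications
  if (nonwear_windows == "exclude" && nrow(cls))
    cls <- cls[cls$window_worn_min > 0, , drop = FALSE]

  n <- nrow(cls)
  n_resp <- sum(cls$responded)
  n_within5 <- sum(cls$within_5min)
  w5 <- cls[cls$within_5min, , drop = FALSE]
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 2) else NA_real_
  days_prompted <- if (n > 0 && "day_index" %in% names(cls))
    length(unique(cls$day_index)) else if (n == 0) 0L else NA_integer_
  out <- list(
    n_prompts = n,
    n_responded = n_resp,
    n_within5 = n_within5,
    response_rate_pct = pct(n_resp, n),
    pct_nonresponse = pct(n - n_resp, n),
    pct_within5_of_responses = pct(n_within5, n_resp),
    mean_stand_min = if (nrow(w5)) mean(w5$stand_min) else NA_real_,
    sd_stand_min = if (nrow(w5) > 1) stats::sd(w5$stand_min) else NA_real_,
    mean_walk_min = if (nrow(w5)) mean(w5$walk_min) else NA_real_,
    sd_walk_min = if (nrow(w5) > 1) stats::sd(w5$walk_min) else NA_real_,
    mean_steps = if (nrow(w5)) mean(w5$steps) else NA_real_,
    sd_steps = if (nrow(w5) > 1) stats::sd(w5$steps) else NA_real_,
    prompts_per_day = n / n_days_observed,
    pct_days_with_any_prompt = pct(days_prompted, n_days_observed),
    n_days_observed = n_days_observed)
  class(out) <- "prompt_summary"
  out
}

#' @export
print.prompt_summary <- function(x, ...) {
  cat(sprintf("Prompts: %d over %g days (%.2f/day)\n",
              x$n_prompts, x$n_days_observed, x$prompts_per_day))
  if (x$n_prompts > 0) {
    cat(sprintf("  responded: %d (%.2f%%); within 5 min: %d (%.2f%% of responses)\n",
                x$n_responded, x$response_rate_pct, x$n_within5,
                ifelse(is.na(x$pct_within5_of_responses), NA,
                       x$pct_within5_of_responses)))
    if (!is.na(x$mean_stand_min))
      cat(sprintf("  per within-5-min response: %.1f min standing, %.1f min walking, %.1f steps\n",
                  x$mean_stand_min, x$mean_walk_min, x$mean_steps))
  }
  invisible(x)
}

#' Stratify prompt outcomes by vibration setting
#'
#' Pools classified prompts across the patients sharing each prompt-interval
#' setting and reports, per setting: prompts per day, percent of days with
#' at least one prompt, percent non-response and percent of responses within
#' 5 minutes.
#'
#' @param classifications Data frame of classified prompts carrying a
#'   `patient_id` column.
#' @param manifest Manifest data frame ([read_manifest()] shape); every
#'   patient in `classifications` and `n_days_by_patient` must appear.
#' @param n_days_by_patient Named numeric vector of observed days per
#'   patient (names are patient ids); patients with zero prompts still
#'   contribute days to the denominators.
#' @return A data frame keyed by `interval`, one row per setting present.
#' @export
stratify_by_setting <- function(classifications, manifest, n_days_by_patient) {
  stopifnot(is.data.frame(classifications), is.data.frame(manifest))
  ids <- names(n_days_by_patient)
  unknown <- setdiff(unique(c(classifications$patient_id, ids)), manifest$patient_id)
  if (length(unknown)) stop("patient not in manifest: ", unknown[1])
  setting_of <- stats::setNames(manifest$prompt_interval, manifest$patient_id)
  settings <- sort(unique(stats::na.omit(setting_of[ids])))
  if (!length(settings)) {
    return(data.frame(interval = numeric(), n_patients = integer(),
                      n_prompts = integer(), prompts_per_day = numeric(),
                      pct_days_prompted = numeric(), pct_nonresponse = numeric(),
                      pct_within5_of_responses = numeric()))
  }
  rows <- lapply(settings, function(s) {
    pats <- ids[!is.na(setting_of[ids]) & setting_of[ids] == s]
    cls <- classifications[classifications$patient_id %in% pats, , drop = FALSE]
    days <- sum(n_days_by_patient[pats])
    n <- nrow(cls)
    n_resp <- sum(cls$responded)
    days_prompted <- if (n) nrow(unique(cls[, c("patient_id", "day_index")])) else 0L
    data.frame(interval = s,
               n_patients = length(pats),
               n_prompts = n,
               prompts_per_day = if (days > 0) n / days else NA_real_,
               pct_days_prompted = if (days > 0) round_half_up(100 * days_prompted / days, 2) else NA_real_,
               pct_nonresponse = if (n > 0) round_half_up(100 * (n - n_resp) / n, 2) else NA_real_,
               pct_within5_of_responses = if (n_resp > 0)
                 round_half_up(100 * sum(cls$within_5min) / n_resp, 2) else NA_real_)
  })
  do.call(rbind, rows)
}
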