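# Vibration-prompt detection from consecutive sedentary time.
#
# The device vibrates the instant a wearer has been continuously sedentary
# (sitting or lying, device worn) for the patient-chosen interval. The
# internal counter resets on any non-sedentary posture, any non-worn epoch,
# at midnight, and on prompt emission itself — so unbroken sitting yields
# consecutive prompts exactly one interval apart. Prompts are stamped at the
# end of the epoch that completes the interval (a minute boundary at the
# default 60-s epochs).

#' Validate a vibration-prompt interval setting
#'
#' @param interval Prompt interval in minutes (>= 1). The device presets are
#'   30, 45 and 60 minutes; other positive values are accepted for analysis.
#' @return The interval as a numeric scalar.
#' @export
prompt_setting <- function(interval) {
  interval <- as.numeric(interval)
  if (length(interval) != 1 || is.na(interval) || interval < 1)
    stop("prompt interval must be a single duration of at least 1 minute")
  interval
}

prompt_columns <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
             bout_start = as.POSIXct(character(), tz = "UTC"),
             interval = numeric(),
             day_index = integer(),
             stringsAsFactors = FALSE)
}

epochs_per_interval <- function(interval, epoch_length) {
  k <- interval * 60 / epoch_length
  if (interval * 60 < epoch_length)
    stop("prompt interval (", interval, " min) is shorter than the epoch length")
  if (k != round(k))
    stop("prompt interval must be a whole number of epochs")
  as.integer(k)
}

#' Detect vibration prompts in a posture series
#'
#' Emits one prompt event whenever the consecutive sedentary-worn counter
#' reaches the interval. Equivalent to a streaming counter that increments
#' on each worn sitting/lying epoch and resets to zero on any other posture
#' or status, at each midnight, and on every emission.
#'
#' @param series A [posture_series()].
#' @param setting Prompt interval in minutes (see [prompt_setting()]).
#' @return A data frame with one row per prompt: `timestamp` (end of the
#'   epoch completing the interval), `bout_start` (start of the maximal
#'   sedentary run containing the prompt), `interval` and `day_index`
#'   (days since discharge of the completing epoch).
#' @seealso [detect_prompts_oracle()] for the exhaustive re-scan used as an
#'   independent cross-check in the test-suite.
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2016-03-01 09:00", tz = "UTC"), by = 60, length.out = 90)
#' s <- posture_series(ts, rep("sitting", 90), 0L, rep("worn", 90))
#' detect_prompts(s, 30)$timestamp # 09:30, 10:00, 10:30
detect_prompts <- function(series, setting) {
  stopifnot(inherits(series, "posture_series"))
  setting <- prompt_setting(setting)
  eplen <- attr(series, "epoch_length")
  k <- epochs_per_interval(setting, eplen)
  n <- nrow(series)
  if (n == 0) return(prompt_columns())

  sed <- is_sedentary_worn(series$posture, series$device_status)
  day <- epoch_date(series$timestamp)
  newrun <- c(TRUE, sed[-1] != sed[-n] | day[-1] != day[-n])
  run_id <- cumsum(newrun)
  pos <- stats::ave(rep(1L, n), run_id, FUN = cumsum)
  hit <- which(sed & pos %% k == 0L)
  data.frame(timestamp = series$timestamp[hit] + eplen,
             bout_start = series$timestamp[hit - pos[hit] + 1L],
             interval = rep(setting, length(hit)),
             day_index = as.integer(day[hit] - attr(series, "discharge_date")),
             stringsAsFactors = FALSE)
}

#' Exhaustive trailing-window prompt detector
#'
#' Independent re-implementation of [detect_prompts()] that checks, for
#' every epoch, whether the trailing window of one interval is entirely
#' sedentary-worn, lies within a single calendar day, and contains no
#' already-emitted prompt. Quadratic-time; intended for validation on small
#' series, where it must agree with [detect_prompts()] exactly.
#'
#' @inheritParams detect_prompts
#' @return Same shape as [detect_prompts()].
#' @export
detect_prompts_oracle <- function(series, setting) {
  stopifnot(inherits(series, "posture_series"))
  setting <- prompt_setting(setting)
  eplen <- attr(series, "epoch_length")
  k <- epochs_per_interval(setting, eplen)
  n <- nrow(series)
  out <- prompt_columns()
  if (n == 0) return(out)
  sed <- is_sedentary_worn(series$posture, series$device_status)
  day <- epoch_date(series$timestamp)
  emitted <- integer()
  for (i in seq_len(n)) {
    if (i < k || !sed[i]) next
    win <- (i - k + 1L):i
    if (any(!sed[win])) next
    if (any(day[win] != day[i])) next
    if (length(emitted) && emitted[length(emitted)] > i - k) next
    emitted <- c(emitted, i)
  }
  if (!length(emitted)) return(out)
  # bout start: walk back to the start of the maximal sedentary same-day run
  starts <- vapply(emitted, function(i) {
    j <- i
    while (j > 1L && sed[j - 1L] && day[j - 1L] == day[i]) j <- j - 1L
    j
  }, integer(1))
  data.frame(timestamp = series$timestamp[emitted] + eplen,
             bout_start = series$timestamp[starts],
             interval = rep(setting, length(emitted)),
             day_index = as.integer(day[emitted] - attr(series, "discharge_date")),
             stringsAsFactors = FALSE)
}

#' Maximal runs of consecutive unanswered prompts
#'
#' Collapses the prompt/response sequence into maximal temporal runs of
#' prompts classified as non-responses.
#'
#' @param prompts Data frame of prompt events (as from [detect_prompts()]),
#'   in temporal order.
#' @param responded Logical vector aligned 1:1 with `prompts`, `TRUE` where
#'   the prompt was answered under the chosen response criterion.
#' @return A data frame with one row per run: `length`, `start` and `end`
#'   (timestamps of the first and last prompt in the run).
#' @export
#' @examples
#' # pattern no/no/yes/no -> runs of length 2 and 1
unanswered_runs <- function(prompts, responded) {
  stopifnot(is.data.frame(prompts))
  responded <- as.logical(responded)
  if (nrow(prompts) != length(responded))
    stop("classifications are not aligned with prompts (", nrow(prompts),
         " prompts vs ", length(responded), " classifications)")
  empty <- data.frame(length = integer(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"))
  if (!nrow(prompts)) return(empty)
  if (anyNA(responded)) stop("responded flags contain NA")
  r <- rle(!responded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  data.frame(length = r$lengths[keep],
             start = prompts$timestamp[starts[keep]],
             end = prompts$timestamp[ends[keep]])
}
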