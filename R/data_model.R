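# Epoch-series containers and delimited-text readers/writers.
#
# Two containers back the whole pipeline:
#   * posture_series — per-epoch posture/step/device-status stream from the
#     waist-worn inclinometer, one series per patient monitoring period;
#   * counts_series  — per-epoch activity counts (+ steps) from the hip-worn
#     accelerometer on the same fixed grid.
# Both are plain data frames with attributes (patient_id, epoch_length in
# seconds, discharge_date) and an S3 class for printing and validation.
# Timestamps are timezone-naive local clock time stored as POSIXct in UTC;
# day index = calendar date - discharge date (discharge = day 0).

#' Construct a posture epoch series
#'
#' Builds and validates the per-epoch posture stream for one patient.
#' Epochs must form a contiguous grid (consecutive timestamps differ by
#' exactly `epoch_length` seconds). Posture may be `NA` only when the device
#' is not worn; steps may be positive only on stepping epochs.
#'
#' @param timestamp POSIXct vector, strictly increasing on a fixed grid.
#' @param posture Character vector of tokens in [POSTURES], `NA` allowed on
#'   non-worn epochs.
#' @param steps Non-negative integer step counts accrued per epoch.
#' @param device_status Character vector of tokens in [DEVICE_STATUSES].
#' @param patient_id Opaque patient identifier.
#' @param discharge_date Calendar `Date` of hospital discharge (day 0).
#'   Defaults to the day before the first epoch.
#' @param epoch_length Epoch length in seconds (default 60).
#' @return A `data.frame` of class `posture_series` with columns
#'   `timestamp`, `posture`, `steps`, `device_status`.
#' @seealso [read_posture_series()], [detect_prompts()]
#' @export
posture_series <- function(timestamp, posture, steps, device_status,
                           patient_id = "P1", discharge_date = NULL,
                           epoch_length = 60) {
  df <- data.frame(timestamp = as.POSIXct(timestamp, tz = "UTC"),
                   posture = as.character(posture),
                   steps = as.integer(steps),
                   device_status = as.character(device_status),
                   stringsAsFactors = FALSE)
  if (is.null(discharge_date)) {
    discharge_date <- if (nrow(df)) epoch_date(df$timestamp[1]) - 1L else Sys.Date()
  }
  attr(df, "patient_id") <- as.character(patient_id)
  attr(df, "epoch_length") <- as.numeric(epoch_length)
  attr(df, "discharge_date") <- as.Date(discharge_date)
  class(df) <- c("posture_series", "data.frame")
  validate_posture_series(df)
  df
}

validate_posture_series <- function(x) {
  stopifnot(inherits(x, "posture_series"))
  ep <- attr(x, "epoch_length")
  if (!is.numeric(ep) || ep <= 0) stop("epoch_length must be a positive number of seconds")
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!x$device_status %in% DEVICE_STATUSES)
  if (length(bad)) stop("epoch ", bad[1], ": unknown device_status '", x$device_status[bad[1]], "'")
  bad <- which(!is.na(x$posture) & !x$posture %in% POSTURES)
  if (length(bad)) stop("epoch ", bad[1], ": unknown posture '", x$posture[bad[1]], "'")
  bad <- which(is.na(x$posture) & x$device_status == "worn")
  if (length(bad)) stop("epoch ", bad[1], ": worn epoch with missing posture")
  if (any(is.na(x$steps) | x$steps < 0)) stop("steps must be non-negative integers")
  bad <- which(x$steps > 0 & (is.na(x$posture) | x$posture != "stepping"))
  if (length(bad)) stop("epoch ", bad[1], ": steps > 0 on a non-stepping epoch")
  if (nrow(x) > 1) {
    d <- diff(as.numeric(x$timestamp))
    if (any(d != ep)) {
      i <- which(d != ep)[1]
      stop("epoch ", i + 1, ": timestamps not on a contiguous ", ep, "-second grid")
    }
  }
  invisible(x)
}

#' @export
print.posture_series <- function(x, ...) {
  cat(sprintf("<posture_series> patient %s: %d epochs of %gs, %s to %s (discharge %s)\n",
              attr(x, "patient_id"), nrow(x), attr(x, "epoch_length"),
              if (nrow(x)) format_ts(x$timestamp[1]) else "-",
              if (nrow(x)) format_ts(x$timestamp[nrow(x)]) else "-",
              attr(x, "discharge_date")))
  invisible(x)
}

#' Construct an activity-count epoch series
#'
#' @param timestamp POSIXct vector on a fixed grid.
#' @param counts Non-negative integer vertical-axis counts per epoch.
#' @param steps Non-negative integer steps per epoch.
#' @inheritParams posture_series
#' @return A `data.frame` of class `counts_series`.
#' @export
counts_series <- function(timestamp, counts, steps = 0L,
                          patient_id = "P1", discharge_date = NULL,
                          epoch_length = 60) {
  df <- data.frame(timestamp = as.POSIXct(timestamp, tz = "UTC"),
                   counts = as.integer(counts),
                   steps = as.integer(rep_len(steps, length(timestamp))),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$counts) | df$counts < 0)) stop("counts must be non-negative integers")
  if (any(is.na(df$steps) | df$steps < 0)) stop("steps must be non-negative integers")
  if (nrow(df) > 1 && any(diff(as.numeric(df$timestamp)) != epoch_length))
    stop("count timestamps not on a contiguous ", epoch_length, "-second grid")
  if (is.null(discharge_date)) {
    discharge_date <- if (nrow(df)) epoch_date(df$timestamp[1]) - 1L else Sys.Date()
  }
  attr(df, "patient_id") <- as.character(patient_id)
  attr(df, "epoch_length") <- as.numeric(epoch_length)
  attr(df, "discharge_date") <- as.Date(discharge_date)
  class(df) <- c("counts_series", "data.frame")
  df
}

#' @export
print.counts_series <- function(x, ...) {
  cat(sprintf("<counts_series> patient %s: %d epochs of %gs\n",
              attr(x, "patient_id"), nrow(x), attr(x, "epoch_length")))
  invisible(x)
}

# Insert not-worn epochs wherever the timestamp grid has holes. Epochs that
# are present are never altered.
fill_series_gaps <- function(df, epoch_length) {
  if (nrow(df) < 2) return(df)
  full <- seq(df$timestamp[1], df$timestamp[nrow(df)], by = epoch_length)
  if (length(full) == nrow(df)) return(df)
  miss <- full[!full %in% df$timestamp]
  filler <- data.frame(timestamp = miss,
                       posture = NA_character_,
                       steps = 0L,
                       device_status = "not_worn",
                       stringsAsFactors = FALSE)
  out <- rbind(df, filler)
  out[order(out$timestamp), , drop = FALSE]
}

#' Read a posture epoch series from delimited text
#'
#' Parses a comma-separated file with header columns `timestamp`, `posture`,
#' `steps`, `device_status` (ISO-8601 timestamps, minute resolution). Gaps
#' in the timestamp grid are filled with `not_worn` epochs. Malformed rows
#' produce an error naming the offending file line.
#'
#' @param path Path to the CSV file.
#' @param epoch_length Epoch length in seconds (default 60).
#' @param patient_id Patient identifier; defaults to the file name stem.
#' @param discharge_date Discharge date; defaults to the day before the
#'   first epoch.
#' @return A [posture_series()].
#' @export
read_posture_series <- function(path, epoch_length = 60,
                                patient_id = NULL, discharge_date = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("timestamp", "posture", "steps", "device_status")
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)), collapse = ", "))
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  ts <- parse_ts(raw$timestamp)
  if (anyNA(ts)) {
    i <- which(is.na(ts))[1]
    stop("line ", line[i], ": malformed timestamp '", raw$timestamp[i], "'")
  }
  posture <- tolower(trimws(raw$posture))
  posture[posture == ""] <- NA_character_
  bad <- which(!is.na(posture) & !posture %in% POSTURES)
  if (length(bad)) stop("line ", line[bad[1]], ": unknown posture token '", raw$posture[bad[1]], "'")
  status <- tolower(trimws(raw$device_status))
  bad <- which(!status %in% DEVICE_STATUSES)
  if (length(bad)) stop("line ", line[bad[1]], ": unknown device_status token '", raw$device_status[bad[1]], "'")
  steps <- suppressWarnings(as.integer(raw$steps))
  bad <- which(is.na(steps) | steps < 0)
  if (length(bad)) stop("line ", line[bad[1]], ": invalid step count '", raw$steps[bad[1]], "'")
  if (nrow(raw) > 1) {
    d <- diff(as.numeric(ts))
    if (any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop("line ", line[i + 1], ": non-monotone timestamp")
    }
    if (any(d %% epoch_length != 0)) {
      i <- which(d %% epoch_length != 0)[1]
      stop("line ", line[i + 1], ": timestamp off the ", epoch_length, "-second epoch grid")
    }
  }
  bad <- which(steps > 0 & (is.na(posture) | posture != "stepping"))
  if (length(bad)) stop("line ", line[bad[1]], ": steps > 0 on a non-stepping epoch")
  bad <- which(is.na(posture) & status == "worn")
  if (length(bad)) stop("line ", line[bad[1]], ": worn epoch with missing posture")

  df <- data.frame(timestamp = ts, posture = posture, steps = steps,
                   device_status = status, stringsAsFactors = FALSE)
  df <- fill_series_gaps(df, epoch_length)
  posture_series(df$timestamp, df$posture, df$steps, df$device_status,
                 patient_id = patient_id %||% sub("\\.[^.]*$", "", basename(path)),
                 discharge_date = discharge_date,
                 epoch_length = epoch_length)
}

#' Write a posture epoch series to delimited text
#'
#' Inverse of [read_posture_series()]: writes the four-column CSV with
#' ISO-8601 timestamps. Missing postures are written as empty fields.
#'
#' @param series A [posture_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posture_series <- function(series, path) {
  stopifnot(inherits(series, "posture_series"))
  out <- data.frame(timestamp = format_ts(series$timestamp),
                    posture = ifelse(is.na(series$posture), "", series$posture),
                    steps = series$steps,
                    device_status = series$device_status,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a counts series to delimited text
#' @param series A [counts_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_series <- function(series, path) {
  stopifnot(inherits(series, "counts_series"))
  out <- data.frame(timestamp = format_ts(series$timestamp),
                    counts = series$counts, steps = series$steps,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a counts series written by [write_counts_series()]
#' @inheritParams read_posture_series
#' @return A [counts_series()].
#' @export
read_counts_series <- function(path, epoch_length = 60,
                               patient_id = NULL, discharge_date = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "counts", "steps")
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)), collapse = ", "))
  ts <- parse_ts(raw$timestamp)
  if (anyNA(ts)) stop("line ", which(is.na(ts))[1] + 1L, ": malformed timestamp")
  counts_series(ts, raw$counts, raw$steps,
                patient_id = patient_id %||% sub("\\.[^.]*$", "", basename(path)),
                discharge_date = discharge_date, epoch_length = epoch_length)
}

#' Write timestamped event records to delimited text
#'
#' Generic writer for flat event tables (detected prompts, response
#' classifications, ground-truth logs...). POSIXct columns are serialized as
#' ISO-8601 and recovered by [read_events()], so `read_events(write_events(x))`
#' round-trips losslessly.
#'
#' @param events A data frame of scalar columns (no list columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  bad <- vapply(events, function(col) is.list(col) || !is.null(dim(col)), logical(1))
  if (any(bad))
    stop("non-scalar (mixed-type) field cannot be serialized: ",
         paste(names(events)[bad], collapse = ", "))
  out <- events
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- format_ts(out[[nm]])
    if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write events to '", path, "'")
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' Columns whose values look like ISO-8601 datetimes are parsed back to
#' POSIXct; everything else keeps the type `read.csv` infers.
#'
#' @param path Path to the CSV file.
#' @return A data frame (zero rows for a header-only file).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.character(col)) {
      probe <- col[!is.na(col) & nzchar(col)]
      if (length(probe) && all(grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", probe))) {
        df[[nm]] <- parse_ts(col)
      }
    }
  }
  df
}

#' Read a patient manifest
#'
#' A manifest row holds patient id, randomization group (`control`,
#' `education`, `education_feedback`), the chosen vibration-prompt interval
#' in minutes (required for the feedback group, empty otherwise) and the
#' discharge date.
#'
#' @param path Path to a CSV with columns `patient_id`, `group`,
#'   `prompt_interval`, `discharge_date`.
#' @return A validated data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "prompt_interval", "discharge_date")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  df$group <- tolower(df$group)
  bad <- which(!df$group %in% c("control", "education", "education_feedback"))
  if (length(bad)) stop("line ", bad[1] + 1L, ": unknown group '", df$group[bad[1]], "'")
  df$prompt_interval <- suppressWarnings(as.numeric(df$prompt_interval))
  fb <- df$group == "education_feedback"
  if (any(fb & is.na(df$prompt_interval)))
    stop("feedback patient without a prompt interval: ",
         df$patient_id[which(fb & is.na(df$prompt_interval))[1]])
  if (any(!fb & !is.na(df$prompt_interval)))
    stop("prompt interval set for a non-feedback patient: ",
         df$patient_id[which(!fb & !is.na(df$prompt_interval))[1]])
  df$discharge_date <- as.Date(df$discharge_date)
  df
}

#' Read a screening/flow log
#'
#' One record per screened patient with logical funnel flags. The funnel
#' must be monotone: consented implies approached implies eligible implies
#' screened, and completed implies enrolled.
#'
#' @param path Path to a CSV with columns `patient_id`, `screened`,
#'   `eligible`, `ineligibility_reason`, `approached`, `consented`,
#'   `enrolled`, `completed_followup`, `group`.
#' @return A validated data frame.
#' @seealso [flow_metrics()]
#' @export
read_flow_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_flow_log(df)
}

validate_flow_log <- function(df) {
  need <- c("patient_id", "screened", "eligible", "approached",
            "consented", "enrolled", "completed_followup")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  for (nm in setdiff(need, "patient_id")) df[[nm]] <- as.logical(df[[nm]])
  viol <- with(df, (consented & !approached) | (approached & !eligible) |
                 (eligible & !screened) | (completed_followup & !enrolled))
  if (any(viol))
    stop("flow funnel violated for record '", df$patient_id[which(viol)[1]], "'")
  df
}

#' Count sit-to-stand transitions in a posture series
#'
#' A transition is a worn epoch whose posture moves from sitting/lying to
#' standing/stepping with the preceding epoch also worn.
#'
#' @param series A [posture_series()].
#' @return Integer transition count.
#' @export
count_transitions <- function(series) {
  stopifnot(inherits(series, "posture_series"))
  n <- nrow(series)
  if (n < 2) return(0L)
  prev_sed <- is_sedentary_worn(series$posture, series$device_status)[-n]
  cur_act <- (series$device_status == "worn" & !is.na(series$posture) &
                series$posture %in% ACTIVE_POSTURES)[-1]
  sum(prev_sed & cur_act)
}
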