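# Builders for small posture/count series used across the tests.

ts_at <- function(hhmm, date = as.Date("2016-03-10")) {
  as.POSIXct(paste(format(date), paste0(hhmm, ":00")), tz = "UTC")
}

# Series from a run-length block list: c(posture_or_status, n_minutes, [steps]).
# "gap"-style statuses are given as the status token with posture NA.
make_series <- function(..., start = "09:00", date = as.Date("2016-03-10"),
                        patient_id = "T1") {
  blocks <- list(...)
  posture <- character(); status <- character(); steps <- integer()
  for (blk in blocks) {
    what <- blk[[1]]
    n <- as.integer(blk[[2]])
    stp <- if (length(blk) >= 3) as.integer(blk[[3]]) else 0L
    if (what %in% DEVICE_STATUSES && what != "worn") {
      posture <- c(posture, rep(NA_character_, n))
      status <- c(status, rep(what, n))
      steps <- c(steps, rep(0L, n))
    } else {
      posture <- c(posture, rep(what, n))
      status <- c(status, rep("worn", n))
      steps <- c(steps, rep(stp, n))
    }
  }
  n <- length(posture)
  posture_series(ts_at(start, date) + (seq_len(n) - 1L) * 60,
                 posture, steps, status,
                 patient_id = patient_id, discharge_date = date - 1)
}

# Randomized series for property tests: blocks of sedentary / active /
# non-worn epochs with occasional midnight spans.
random_series <- function(max_blocks = 12, max_len = 40) {
  n_blocks <- sample.int(max_blocks, 1)
  kinds <- sample(c("sitting", "lying", "standing", "stepping",
                    "not_worn", "off", "charging"),
                  n_blocks, replace = TRUE,
                  prob = c(0.35, 0.15, 0.15, 0.1, 0.1, 0.075, 0.075))
  lens <- sample.int(max_len, n_blocks, replace = TRUE)
  start_h <- sample(c("09:00", "22:30", "23:30"), 1)  # sometimes cross midnight
  args <- Map(function(k, l) list(k, l, if (k == "stepping") 10L else 0L),
              kinds, lens)
  do.call(make_series, c(unname(args), list(start = start_h)))
}

make_counts <- function(counts, start = "08:00", date = as.Date("2016-03-10"),
                        steps = 0L) {
  n <- length(counts)
  counts_series(ts_at(start, date) + (seq_len(n) - 1L) * 60,
                counts, steps, patient_id = "T1", discharge_date = date - 1)
}

# A flow log with the requested funnel counts, built record by record.
make_flow_log <- function(screened, eligible, approached, consented,
                          enrolled = consented, completed,
                          groups = NULL) {
  stopifnot(screened >= eligible, eligible >= approached,
            approached >= consented, consented >= enrolled,
            enrolled >= completed)
  df <- data.frame(patient_id = sprintf("S%03d", seq_len(screened)),
                   screened = TRUE,
                   eligible = seq_len(screened) <= eligible,
                   ineligibility_reason = "",
                   approached = seq_len(screened) <= approached,
                   consented = seq_len(screened) <= consented,
                   enrolled = seq_len(screened) <= enrolled,
                   completed_followup = seq_len(screened) <= completed,
                   stringsAsFactors = FALSE)
  df$ineligibility_reason[!df$eligible] <- "criteria"
  if (!is.null(groups)) {
    df$group <- NA_character_
    df$group[df$enrolled] <- rep_len(groups, enrolled)
  }
  df
}
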