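# Deterministic single-day worked example: a reconstructed concept day for
# a patient on the 30-minute vibration setting.
#
# The day is laid out so that the streaming sedentary counter fires prompts
# at exactly 09:30, 14:45, 16:30, 18:45, 19:15, 19:45, 21:00, 21:45 and
# 22:15. Activity breaks are placed so the prompts at 09:30, 14:45, 16:30,
# 21:00 and 22:15 are followed by movement within 5 minutes, while the
# 18:45/19:15/19:45 trio (one unanswered run of three) and 21:45 are not.
# Morning and afternoon sitting is interrupted at sub-30-minute spacing so
# no further prompts arise, and the device comes off at 22:45.

#' Build the single-day worked-example fixture
#'
#' A deterministically constructed one-day posture series (device worn
#' 07:00-22:45, 60-s epochs) for the 30-minute prompt setting, on which
#' [detect_prompts()] yields nine prompts at the clock times listed above,
#' five of them answered within 5 minutes.
#'
#' @param date Calendar date of the fixture day (day 1 post discharge).
#' @return A list: `series` (a [posture_series()]) and `setting` (30).
#' @export
#' @examples
#' fx <- build_figure1_fixture()
#' format(detect_prompts(fx$series, fx$setting)$timestamp, "%H:%M")
build_figure1_fixture <- function(date = as.Date("2016-03-15")) {
  t0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  ts <- t0 + (0:1439) * 60
  posture <- rep(NA_character_, 1440)
  steps <- integer(1440)
  status <- rep("not_worn", 1440)

  wear <- 421:1365                     # minutes 420..1364 -> 07:00-22:45
  status[wear] <- "worn"
  posture[wear] <- "sitting"

  set_block <- function(from, to, what, n_steps = 0L) {
    idx <- (from + 1L):to               # [from, to) in minutes-of-day
    posture[idx] <<- what
    if (n_steps > 0) steps[idx] <<- as.integer(round(n_steps / length(idx)))
  }

  stand <- function(from, to) set_block(from, to, "standing")
  walk <- function(from, to, n) set_block(from, to, "stepping", n)

  # morning: breaks at sub-30-min spacing, the last ending at 09:00
  stand(440, 442); stand(465, 467); stand(490, 492); stand(515, 517)
  stand(537, 540)
  # 09:00-09:30 sitting -> prompt 09:30, answered at +2 min
  stand(572, 574); walk(574, 575, 20)
  # late morning / early afternoon breaks, the last ending at 14:15
  stand(600, 602); stand(627, 629); stand(654, 656); stand(681, 683)
  stand(708, 710); stand(735, 737); stand(762, 764); stand(789, 791)
  stand(816, 818); stand(843, 845); stand(853, 855)
  # 14:15-14:45 sitting -> prompt 14:45, answered
  stand(887, 889); walk(889, 890, 18)
  # breaks until 16:00
  stand(915, 917); stand(942, 944); stand(958, 960)
  # 16:00-16:30 sitting -> prompt 16:30, answered
  stand(992, 994); walk(994, 995, 22)
  # breaks until 18:15
  stand(1020, 1022); stand(1047, 1049); stand(1074, 1076)
  stand(1093, 1095)
  # 18:15-19:45 unbroken sitting -> prompts 18:45, 19:15, 19:45, unanswered;
  # the first movement comes at 20:05, outside every 15-min window
  stand(1205, 1207); stand(1225, 1230)
  # 20:30-21:00 sitting -> prompt 21:00, answered
  stand(1262, 1264); walk(1264, 1265, 25)
  stand(1273, 1275)
  # 21:15-21:45 sitting -> prompt 21:45, unanswered; sitting continues and
  # the counter refires at 22:15, answered
  stand(1337, 1339); walk(1339, 1340, 21)

  series <- posture_series(ts, posture, steps, status,
                           patient_id = "FIG1", discharge_date = date - 1,
                           epoch_length = 60)
  list(series = series, setting = 30)
}
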