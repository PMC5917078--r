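# Seeded synthetic-cohort generator with ground-truth event log.
#
# Emulates a 14-day post-discharge monitoring period per patient: a fixed
# waking wear window, long sedentary bouts broken by short spontaneous
# stand/walk breaks, vibration prompts fired by the same consecutive-
# sedentary counter contract the detector implements, probabilistic prompt
# responses with latency and stand/walk/step magnitudes, nightly charging
# behaviour, battery depletion and manual power-off days. The seed fully
# determines the output, so every downstream stage can be validated against
# the ground-truth log.
#
# Durations are configured as truncated normals in minutes but the grid is
# 60-s epochs, so draws are discretized by unbiased stochastic rounding.
# Stand and walk epoch counts are coupled so that every response produces
# at least one observable movement epoch while both marginal distributions
# (hence their means) are preserved exactly.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort of COPD patients monitored for 14 days after
#' hospital discharge: prompt-interval choices split 6:1:5 over 30/45/60
#' minutes, a 32.6% response probability with 40.6% of response latencies
#' within 5 minutes, responses of mean 1.4 (SD 0.8) min standing then 0.4
#' (SD 0.3) min walking at a cadence giving ~21.2 steps per response, a
#' 08:00-22:30 waking wear window, 90% of waking wear spent sedentary,
#' nightly charging with probability 0.7 and a 2.5-day battery.
#'
#' @param n_patients Number of patients (default 12).
#' @param seed Integer seed; fully determines the cohort.
#' @param prompt_interval_mix Named proportions over the 30/45/60-minute
#'   presets; patients are allocated deterministically by largest
#'   remainder, so `c("30"=6, "45"=1, "60"=5)/12` reproduces a 6/1/5 split.
#' @param p_respond Probability a prompt elicits a response.
#' @param p_within5 Share of response latencies falling within 5 minutes.
#' @param latency_probs Optional length-15 probability vector over latency
#'   minutes 1..15; defaults to geometric-decay weights within the
#'   (0,5] and (5,15] segments with `p_within5` mass on the first.
#' @param stand_mean,stand_sd Standing-duration truncated normal (min, > 0).
#' @param walk_mean,walk_sd Walking-duration truncated normal (min, > 0).
#' @param step_rate Steps per walking minute; defaults so the mean steps
#'   per response is 21.2.
#' @param wake_start,wake_end Daily waking wear window, `"HH:MM"`.
#' @param sedentary_fraction Target fraction of waking wear spent sedentary.
#' @param p_lying Probability a sedentary bout is spent lying rather than
#'   sitting.
#' @param p_charge_nightly Probability of an overnight charge (per night).
#' @param battery_life_days Days of operation without charging.
#' @param p_manual_off_day Probability a day is manually switched off.
#' @param ambulation_cut Minimum counts/min emitted on stepping epochs.
#' @param n_days Monitoring days (default 14; day 0 is discharge).
#' @param start_date Discharge date of the first patient.
#' @param epoch_length Epoch length in seconds (default 60).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 12, seed = 1,
                             prompt_interval_mix = c("30" = 6, "45" = 1, "60" = 5) / 12,
                             p_respond = 0.326, p_within5 = 0.406,
                             latency_probs = NULL,
                             stand_mean = 1.4, stand_sd = 0.8,
                             walk_mean = 0.4, walk_sd = 0.3,
                             step_rate = NULL,
                             wake_start = "08:00", wake_end = "22:30",
                             sedentary_fraction = 0.9, p_lying = 0.15,
                             p_charge_nightly = 0.7, battery_life_days = 2.5,
                             p_manual_off_day = 0.05,
                             ambulation_cut = 100,
                             n_days = 14, start_date = as.Date("2016-03-01"),
                             epoch_length = 60) {
  probs <- c(p_respond, p_within5, sedentary_fraction, p_lying,
             p_charge_nightly, p_manual_off_day)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!setequal(names(prompt_interval_mix), c("30", "45", "60")))
    stop("prompt_interval_mix must be named over the 30/45/60-minute presets")
  if (any(prompt_interval_mix < 0) || abs(sum(prompt_interval_mix) - 1) > 1e-8)
    stop("prompt_interval_mix must be non-negative proportions that sum to 1")
  if (stand_sd <= 0 || walk_sd <= 0 || stand_mean <= 0 || walk_mean <= 0)
    stop("duration distributions need positive means and SDs")
  if (battery_life_days <= 0) stop("battery_life_days must be positive")
  if (sedentary_fraction == 0)
    stop("infeasible config: sedentary_fraction 0 cannot generate prompts")
  if (sedentary_fraction >= 1)
    stop("sedentary_fraction must be below 1 so breaks can occur")
  if (is.null(latency_probs)) {
    w5 <- 0.5^(0:4); w15 <- 0.85^(0:9)
    latency_probs <- c(p_within5 * w5 / sum(w5), (1 - p_within5) * w15 / sum(w15))
  }
  if (length(latency_probs) != 15 || any(latency_probs < 0))
    stop("latency_probs must be 15 non-negative probabilities (minutes 1..15)")
  latency_probs <- latency_probs / sum(latency_probs)
  mean_stand <- tnorm_mean(stand_mean, stand_sd)
  mean_walk <- tnorm_mean(walk_mean, walk_sd)
  if (is.null(step_rate)) step_rate <- 21.2 / mean_walk
  mean_break <- mean_stand + mean_walk
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    prompt_interval_mix = prompt_interval_mix[c("30", "45", "60")],
    p_respond = p_respond, p_within5 = p_within5,
    latency_probs = latency_probs,
    stand_mean = stand_mean, stand_sd = stand_sd,
    walk_mean = walk_mean, walk_sd = walk_sd,
    step_rate = step_rate,
    wake_start = wake_start, wake_end = wake_end,
    sedentary_fraction = sedentary_fraction, p_lying = p_lying,
    p_charge_nightly = p_charge_nightly,
    battery_life_days = battery_life_days,
    p_manual_off_day = p_manual_off_day,
    ambulation_cut = ambulation_cut,
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    epoch_length = epoch_length,
    # derived quantities (documented in the methods vignette)
    p_break = (1 - sedentary_fraction) / (sedentary_fraction * mean_break),
    p_zero_stand = p_sr_zero(stand_mean, stand_sd),
    p_zero_walk = p_sr_zero(walk_mean, walk_sd)),
    class = "synthetic_config")
}

# P(stochastic round of a >0-truncated normal equals 0) = E[(1-X) 1{X<1}],
# in closed form via partial expectations of the parent normal.
p_sr_zero <- function(mu, sd) {
  z <- stats::pnorm(mu / sd)                      # P(X > 0) of the parent
  a <- -mu / sd; b <- (1 - mu) / sd
  p01 <- (stats::pnorm(b) - stats::pnorm(a)) / z  # P(0 < X < 1 | X > 0)
  ex01 <- (mu * (stats::pnorm(b) - stats::pnorm(a)) +
             sd * (stats::dnorm(a) - stats::dnorm(b))) / z
  p01 - ex01
}

# one draw from a >0-truncated normal
draw_tnorm <- function(mu, sd) {
  repeat {
    x <- stats::rnorm(1, mu, sd)
    if (x > 0) return(x)
  }
}

# unbiased stochastic rounding to an integer epoch count
sr_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(1) < x - f))
}

draw_walk_ge1 <- function(cfg) {
  repeat {
    w <- sr_round(draw_tnorm(cfg$walk_mean, cfg$walk_sd))
    if (w >= 1L) return(w)
  }
}

# Draw one activity block: S standing epochs then W stepping epochs with
# per-epoch steps. Coupled so S + W >= 1 always while both marginals are
# those of the stochastically rounded truncated normals.
draw_block <- function(cfg) {
  s <- sr_round(draw_tnorm(cfg$stand_mean, cfg$stand_sd))
  if (s == 0L) {
    w <- draw_walk_ge1(cfg)
  } else {
    q <- min(1, cfg$p_zero_walk / (1 - cfg$p_zero_stand))
    w <- if (stats::runif(1) < q) 0L else draw_walk_ge1(cfg)
  }
  steps <- if (w > 0) stats::rpois(w, cfg$step_rate) else integer()
  list(stand = s, walk = w, steps = steps)
}

hhmm_to_min <- function(s) {
  p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

# Simulate postures/steps over one contiguous worn stretch, running the
# same consecutive-sedentary counter contract as detect_prompts().
sim_worn_stretch <- function(ts, k, cfg) {
  n <- length(ts)
  posture <- character(n)
  steps <- integer(n)
  prompts <- list()
  eplen <- cfg$epoch_length

  write_block <- function(i, blk) {
    if (blk$stand > 0) {
      idx <- i:min(i + blk$stand - 1L, n)
      if (idx[1] <= n) posture[idx] <<- "standing"
    }
    j <- i + blk$stand
    if (blk$walk > 0 && j <= n) {
      idx <- j:min(j + blk$walk - 1L, n)
      posture[idx] <<- "stepping"
      steps[idx] <<- blk$steps[seq_along(idx)]
    }
    i + blk$stand + blk$walk
  }

  bout_posture <- if (stats::runif(1) < cfg$p_lying) "lying" else "sitting"
  counter <- 0L
  i <- 1L
  suppress_until <- 0L   # an ignored prompt means sitting through its window
  while (i <= n) {
    if (i >= suppress_until && stats::runif(1) < cfg$p_break) {  # spontaneous break
      i <- write_block(i, draw_block(cfg))
      counter <- 0L
      bout_posture <- if (stats::runif(1) < cfg$p_lying) "lying" else "sitting"
      next
    }
    posture[i] <- bout_posture
    counter <- counter + 1L
    if (counter == k) {                        # prompt fires at epoch end
      t_prompt <- ts[i] + eplen
      responded <- stats::runif(1) < cfg$p_respond
      # the prompt's 15-min window holds only the modelled response (if any):
      # no further spontaneous breaks until the window has elapsed
      suppress_until <- i + 16L
      if (responded) {
        lat <- sample.int(15, 1, prob = cfg$latency_probs)
        blk <- draw_block(cfg)
        lat_end <- min(i + lat - 1L, n)        # lat-1 further sedentary epochs
        if (lat_end > i) posture[(i + 1L):lat_end] <- bout_posture
        i <- write_block(lat_end + 1L, blk)
        prompts[[length(prompts) + 1L]] <- data.frame(
          prompt_time = t_prompt, responded = TRUE, latency_min = lat,
          stand_min = blk$stand, walk_min = blk$walk,
          steps = as.integer(sum(blk$steps)))
        counter <- 0L
        bout_posture <- if (stats::runif(1) < cfg$p_lying) "lying" else "sitting"
        next
      } else {
        prompts[[length(prompts) + 1L]] <- data.frame(
          prompt_time = t_prompt, responded = FALSE, latency_min = NA_real_,
          stand_min = NA_real_, walk_min = NA_real_, steps = NA_integer_)
        counter <- 0L
      }
    }
    i <- i + 1L
  }
  list(posture = posture, steps = steps,
       prompts = if (length(prompts)) do.call(rbind, prompts) else NULL)
}

simulate_patient <- function(pid, interval, discharge_date, cfg) {
  eplen <- cfg$epoch_length
  epd <- as.integer(86400 / eplen)             # epochs per day
  n <- cfg$n_days * epd
  t0 <- as.POSIXct(paste(format(discharge_date + 1), "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1L) * eplen
  status <- rep("not_worn", n)
  posture <- rep(NA_character_, n)
  steps <- integer(n)

  wake_lo <- hhmm_to_min(cfg$wake_start)
  wake_hi <- hhmm_to_min(cfg$wake_end)
  min_of_day <- (as.numeric(ts - t0) / 60) %% 1440
  day_of <- rep(seq_len(cfg$n_days), each = epd)

  manual_off <- stats::runif(cfg$n_days) < cfg$p_manual_off_day
  night_charge <- c(stats::runif(cfg$n_days - 1) < cfg$p_charge_nightly)

  status[manual_off[day_of]] <- "off"
  wake <- min_of_day >= wake_lo & min_of_day < wake_hi & !manual_off[day_of]
  status[wake] <- "worn"
  # overnight charge block: 23:00 of night d to 06:00 of day d+1
  for (d in which(night_charge)) {
    blk <- (day_of == d & min_of_day >= 1380) | (day_of == d + 1 & min_of_day < 360)
    status[blk] <- "charging"
  }
  # battery: drains one minute of capacity per epoch whenever the device is
  # on and not charging; a completed charge block restores full capacity
  capacity <- cfg$battery_life_days * 1440
  remaining <- capacity
  draining <- status %in% c("worn", "not_worn")
  chg <- status == "charging"
  i <- 1L
  while (i <= n) {
    if (chg[i]) {
      while (i <= n && chg[i]) i <- i + 1L
      remaining <- capacity
    } else {
      if (draining[i]) {
        remaining <- remaining - eplen / 60
        if (remaining <= 0) {
          j <- i
          while (j <= n && !chg[j]) j <- j + 1L
          dead <- i:(j - 1L)
          status[dead[draining[dead]]] <- "battery_dead"
          i <- j
          next
        }
      }
      i <- i + 1L
    }
  }
  worn <- status == "worn"

  k <- epochs_per_interval(interval, eplen)
  prompt_rows <- list()
  if (any(worn)) {
    widx <- which(worn)
    brk <- c(TRUE, diff(widx) != 1L)
    stretch <- cumsum(brk)
    for (s in split(widx, stretch)) {
      sim <- sim_worn_stretch(ts[s], k, cfg)
      posture[s] <- sim$posture
      steps[s] <- sim$steps
      if (!is.null(sim$prompts)) prompt_rows[[length(prompt_rows) + 1L]] <- sim$prompts
    }
  }
  prompts <- if (length(prompt_rows)) do.call(rbind, prompt_rows) else
    data.frame(prompt_time = as.POSIXct(character(), tz = "UTC"),
               responded = logical(), latency_min = numeric(),
               stand_min = numeric(), walk_min = numeric(), steps = integer())
  prompts <- cbind(patient_id = rep(pid, nrow(prompts)), prompts)

  series <- posture_series(ts, posture, steps, status, patient_id = pid,
                           discharge_date = discharge_date,
                           epoch_length = eplen)
  dead_day <- tapply(status == "battery_dead", day_of, any)
  worn_day <- tapply(worn, day_of, any)
  days <- data.frame(patient_id = pid, day_index = seq_len(cfg$n_days),
                     worn = as.logical(worn_day),
                     charged = c(night_charge, NA),
                     battery_dead = as.logical(dead_day),
                     manual_off = manual_off,
                     stringsAsFactors = FALSE)
  list(series = series, prompts = prompts, days = days)
}

# deterministic largest-remainder allocation of patients to settings
allocate_settings <- function(n, mix) {
  exact <- n * mix
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  rep(as.numeric(names(mix)), times = base)
}

#' Generate a synthetic patient cohort with ground truth
#'
#' Produces, per patient, a 14-day posture series and matched counts
#' series, plus a manifest and a ground-truth log of every simulated
#' prompt (with response, latency and magnitudes) and day-level adherence
#' flags. The simulator fires prompts from the same consecutive-sedentary
#' counter contract as [detect_prompts()], so on clean data the detector
#' reproduces the ground-truth prompt list exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list: `series` (named list of [posture_series()]), `counts`
#'   (named list of [counts_series()]), `manifest` (data frame),
#'   `ground_truth` (list with `prompts` and `days` data frames).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  settings <- allocate_settings(config$n_patients, config$prompt_interval_mix)
  series <- list(); counts <- list()
  prompts <- list(); days <- list()
  for (i in seq_along(ids)) {
    sim <- simulate_patient(ids[i], settings[i], config$start_date, config)
    series[[ids[i]]] <- sim$series
    counts[[ids[i]]] <- generate_counts(sim$series, config)
    prompts[[i]] <- sim$prompts
    days[[i]] <- sim$days
  }
  manifest <- data.frame(patient_id = ids,
                         group = "education_feedback",
                         prompt_interval = settings,
                         discharge_date = config$start_date,
                         stringsAsFactors = FALSE)
  list(series = series, counts = counts, manifest = manifest,
       ground_truth = list(prompts = do.call(rbind, prompts),
                           days = do.call(rbind, days)))
}

#' Map a posture series onto the activity-count scale
#'
#' Sedentary and standing worn epochs draw counts uniformly below the
#' 100-cpm stationary cut (standing still on a hip-worn accelerometer
#' registers as stationary); stepping epochs draw counts at or above the
#' ambulation cut-point; non-worn, off, charging and dead epochs emit zero
#' counts. Steps are carried over from the posture series.
#'
#' @param series A [posture_series()].
#' @param config A [synthetic_config()] (for the ambulation cut-point).
#' @return A [counts_series()] on the same grid. Uses the current RNG
#'   state; seed via [generate_cohort()] or `set.seed()` for
#'   reproducibility.
#' @export
generate_counts <- function(series, config = synthetic_config()) {
  stopifnot(inherits(series, "posture_series"))
  n <- nrow(series)
  counts <- integer(n)
  worn <- series$device_status == "worn"
  still <- worn & series$posture %in% c(SEDENTARY_POSTURES, "standing")
  moving <- worn & series$posture == "stepping"
  counts[still] <- sample.int(100, sum(still), replace = TRUE) - 1L
  counts[moving] <- config$ambulation_cut +
    sample.int(1900, sum(moving), replace = TRUE) - 1L
  counts_series(series$timestamp, counts, series$steps,
                patient_id = attr(series, "patient_id"),
                discharge_date = attr(series, "discharge_date"),
                epoch_length = attr(series, "epoch_length"))
}
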