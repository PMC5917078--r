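# Shared vocabulary and small numeric helpers.

#' Posture and device-status vocabularies
#'
#' Token sets used throughout the package. Postures follow a four-state
#' inclinometer abstraction (sitting, lying, standing, stepping); sedentary
#' behaviour is defined by posture as sitting or lying. Device status
#' distinguishes on-body wear from the states that make posture meaningless.
#'
#' @format Character vectors of lower-case tokens.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
POSTURES <- c("sitting", "lying", "standing", "stepping")

#' @rdname vocabulary
#' @export
SEDENTARY_POSTURES <- c("sitting", "lying")

#' @rdname vocabulary
#' @export
ACTIVE_POSTURES <- c("standing", "stepping")

#' @rdname vocabulary
#' @export
DEVICE_STATUSES <- c("worn", "not_worn", "off", "charging", "battery_dead")

#' @rdname vocabulary
#' @export
PROMPT_PRESETS <- c(30, 45, 60)

# Round half away from zero, the convention used for reported percentages.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) as.POSIXct(x, format = TS_FORMAT, tz = "UTC")

format_ts <- function(x) format(x, TS_FORMAT, tz = "UTC")

epoch_date <- function(ts) as.Date(ts, tz = "UTC")

# Logical mask: epoch is on-body and in a sedentary posture.
is_sedentary_worn <- function(posture, device_status) {
  device_status == "worn" & !is.na(posture) & posture %in% SEDENTARY_POSTURES
}

#' Mean of a normal distribution truncated below
#'
#' Closed-form mean of a normal(mu, sd) left-truncated at `lower`. Used for
#' the generator's duration distributions and as the analytic target in
#' parameter-recovery checks.
#'
#' @param mu,sd Location and scale of the parent normal (sd > 0).
#' @param lower Truncation point (default 0).
#' @return The truncated mean, a single numeric.
#' @export
#' @examples
#' tnorm_mean(1.4, 0.8) # mean standing duration implied by the defaults
tnorm_mean <- function(mu, sd, lower = 0) {
  stopifnot(sd > 0)
  a <- (lower - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
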