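#' @title Inceptor control workload metrics
#' @description Duty cycle, aggressiveness, and their product, the pilot
#'   inceptor workload (PIW) -- the study's control-behaviour baseline for
#'   task difficulty.
#' @name inceptor-metrics
NULL

# per-increment activity indicator shared by both duty-cycle variants:
# an increment i (= 2..n) is inactive only when the deflection rate is
# below the noise threshold AND the stick is off its stop.
.stick_activity <- function(t, delta, delta_max, noise_threshold) {
  n <- length(t)
  if (n < 2) stop("need at least 2 stick samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
  if (delta_max <= 0) stop("delta_max must be positive")
  rate <- abs(diff(delta)) / dt
  # threshold: a fraction of the total (two-sided) displacement range per
  # time increment, converted to a rate with the local dt
  thr_rate <- noise_threshold * (2 * delta_max) / dt
  x <- as.numeric(!(rate < thr_rate & abs(delta[-1]) < delta_max))
  list(x = x, dt = dt)
}

#' Duty cycle of inceptor use
#'
#' The percentage of time the participant actively uses the control. An
#' increment counts as active when its deflection rate reaches the noise
#' threshold (0.5 % of the total displacement range per time increment) or
#' the stick is held at its displacement limit.
#'
#' The default `"time"` mode weights each active increment by its time step
#' and divides by the total increment time, giving a true percentage in
#' \[0, 100\]. The `"count"` mode is the literal printed form: the unitless
#' indicator count divided by `t_n - t_2`.
#'
#' @param t Timestamps, seconds (strictly increasing, n >= 2).
#' @param delta Stick deflections, degrees.
#' @param delta_max Displacement limit, degrees (one-sided).
#' @param noise_threshold Fraction of the total displacement range per time
#'   increment (default 0.005).
#' @param mode `"time"` (default) or `"count"`.
#' @return Duty cycle in percent.
#' @export
duty_cycle <- function(t, delta, delta_max, noise_threshold = 0.005,
                       mode = c("time", "count")) {
  mode <- match.arg(mode)
  a <- .stick_activity(t, delta, delta_max, noise_threshold)
  if (mode == "time") {
    min(100, max(0, 100 * (sum(a$x * a$dt) / sum(a$dt))))
  } else {
    n <- length(t)
    span <- t[n] - t[2]
    if (span <= 0) stop("t_n equals t_2; duty cycle undefined")
    100 * sum(a$x) / span
  }
}

#' Aggressiveness of inceptor inputs
#'
#' Root-mean-square rate of change of the stick deflection over the n - 1
#' increments: `sqrt( 1/(n-1) * sum_i ((delta_i - delta_{i-1}) / (t_i -
#' t_{i-1}))^2 )`, in deg/s. Higher values correspond to more abrupt
#' control activity.
#'
#' @param t Timestamps, seconds.
#' @param delta Stick deflections, degrees.
#' @return Aggressiveness in deg/s.
#' @export
aggressiveness <- function(t, delta) {
  n <- length(t)
  if (n < 2) stop("need at least 2 stick samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
  rate <- diff(delta) / dt
  sqrt(sum(rate^2) / (n - 1))
}

#' Pilot inceptor workload
#'
#' The product of duty cycle and aggressiveness; rises directly with task
#' difficulty.
#'
#' @param dc Duty cycle, percent (>= 0).
#' @param agg Aggressiveness, deg/s (>= 0).
#' @return Scalar PIW.
#' @export
piw <- function(dc, agg) {
  if (!is.finite(dc) || !is.finite(agg) || dc < 0 || agg < 0)
    stop("duty cycle and aggressiveness must be finite and non-negative")
  dc * agg
}

#' Inceptor metrics for one session
#'
#' @param session A `session_data` list (or any list with a `stick` data
#'   frame and `delta_max`).
#' @return Named list `duty_cycle`, `aggressiveness`, `piw`.
#' @export
inceptor_metrics <- function(session) {
  s <- session$stick
  dc <- duty_cycle(s$t, s$delta_deg, session$delta_max)
  ag <- aggressiveness(s$t, s$delta_deg)
  list(duty_cycle = dc, aggressiveness = ag, piw = piw(dc, ag))
}
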