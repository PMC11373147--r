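#' @title Pursuit-evasion engagement simulator
#' @description Point-mass pursuer-evader engagement with augmented
#'   proportional navigation (APN) guidance on radar-delayed observations,
#'   a constant-velocity evader with an oscillating altitude profile or a
#'   LOS-rate-proportional evader, and the reward evaluator used to score
#'   evasive advantage positions. Axes: X lateral, Y altitude, Z forward
#'   range; headings are degrees in the X-Z plane measured from +Z.
#' @name agent-sim
NULL

wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Engagement state of the pursuer-evader pair
#'
#' @param pursuer,evader Numeric `c(x, y, z)` positions in metres.
#' @param v_p,v_e Speeds in m/s (non-negative).
#' @param psi_p,psi_e Headings in degrees (X-Z plane, 0 = +Z).
#' @param time Simulation time, seconds.
#' @return Object of class `engagement_state`.
#' @export
engagement_state <- function(pursuer, evader, v_p, v_e,
                             psi_p = 0, psi_e = 0, time = 0) {
  stopifnot(length(pursuer) == 3, length(evader) == 3,
            all(is.finite(c(pursuer, evader, v_p, v_e, psi_p, psi_e))),
            v_p >= 0, v_e >= 0)
  structure(list(pursuer = as.numeric(pursuer), evader = as.numeric(evader),
                 v_p = v_p, v_e = v_e, psi_p = psi_p, psi_e = psi_e,
                 time = time),
            class = "engagement_state")
}

#' Guidance and scenario configuration
#'
#' @param N Navigation constant (default 3).
#' @param a_nt Target (evader) acceleration fed to the augmented term,
#'   m/s^2.
#' @param radar_latency Radar acquisition/processing latency, s (0.4
#'   nominal, 0.8 degraded).
#' @param radar_range Radar coverage, m (default 1200).
#' @param step Integration step, s.
#' @param evader_los_gain Speed gain (m/s per rad/s of LOS rate) for the
#'   LOS-proportional evader.
#' @param evader_margin Speed margin ensuring the LOS-proportional evader
#'   outruns the pursuer, m/s.
#' @param agent1_alt_amp,agent1_alt_period Altitude oscillation of the
#'   unguided evader: amplitude (m) and period (s).
#' @param climb_gain,climb_max Pursuer vertical channel: proportional gain
#'   on observed altitude error (1/s) and climb-rate limit (m/s).
#' @param a_max Structural limit on the commanded normal acceleration,
#'   m/s^2 (default 88, about 9 g); the raw proportional-navigation command
#'   diverges as the range collapses, so the airframe limit caps it.
#' @return Object of class `guidance_config`.
#' @export
guidance_config <- function(N = 3, a_nt = 0, radar_latency = 0.4,
                            radar_range = 1200, step = 0.01,
                            evader_los_gain = 400, evader_margin = 10,
                            agent1_alt_amp = 50, agent1_alt_period = 20,
                            climb_gain = 0.5, climb_max = 30, a_max = 88) {
  stopifnot(radar_latency >= 0, step > 0, radar_range > 0,
            agent1_alt_period > 0, a_max > 0)
  structure(as.list(environment()), class = "guidance_config")
}

#' Reward thresholds for the evasive-advantage evaluator
#'
#' @param d_min,d_max Distance band, m (`0 <= d_min < d_max`).
#' @param mu_max,eta_max Deviation- and aspect-angle limits, degrees
#'   (positive).
#' @return Object of class `reward_thresholds`.
#' @export
reward_thresholds <- function(d_min, d_max, mu_max, eta_max) {
  stopifnot(d_min >= 0, d_min < d_max, mu_max > 0, eta_max > 0)
  structure(list(d_min = d_min, d_max = d_max,
                 mu_max = mu_max, eta_max = eta_max),
            class = "reward_thresholds")
}

#' Line-of-sight geometry between pursuer and evader
#'
#' Computes the LOS distance `lambda` (Euclidean), its rate, the closing
#' velocity `v_c = v_p - v_e`, and the deviation angle `mu` and aspect
#' angle `eta`:
#' `mu = 180 + psi_p - atan2(x_p - x_e, z_p - z_e)` and
#' `eta = psi_e - atan2(x_e - x_p, z_e - z_p)` (degrees, wrapped to
#' (-180, 180\]); the two-argument arctangent resolves the quadrant
#' ambiguity of the single-argument form, which is undefined for equal
#' forward ranges.
#'
#' `lambda_dot` needs a previous state: with `lambda_dot_mode = "angle"`
#' (default) it is the rotation rate of the LOS unit vector (angle between
#' the two LOS directions over the time step, rad/s, non-negative) -- the
#' quantity the proportional-navigation law consumes; `"range"` gives the
#' range rate `(lambda - lambda_prev) / dt` in m/s.
#'
#' @param s Current [engagement_state()].
#' @param prev Previous [engagement_state()] or `NULL`.
#' @param lambda_dot_mode `"angle"` or `"range"`.
#' @return Object of class `los_geometry`: `lambda`, `lambda_dot`, `v_c`,
#'   `d_t`, `mu`, `eta`, `defined` (FALSE for coincident aircraft).
#' @export
los_geometry <- function(s, prev = NULL,
                         lambda_dot_mode = c("angle", "range")) {
  lambda_dot_mode <- match.arg(lambda_dot_mode)
  r <- s$evader - s$pursuer
  lambda <- sqrt(sum(r^2))
  defined <- lambda > 0
  mu <- eta <- NA_real_
  if (defined) {
    mu <- wrap180(180 + s$psi_p -
                    atan2(s$pursuer[1] - s$evader[1],
                          s$pursuer[3] - s$evader[3]) * 180 / pi)
    eta <- wrap180(s$psi_e -
                     atan2(s$evader[1] - s$pursuer[1],
                           s$evader[3] - s$pursuer[3]) * 180 / pi)
  }
  lambda_dot <- NA_real_
  if (!is.null(prev)) {
    dt <- s$time - prev$time
    if (dt <= 0) stop("previous state must precede the current state")
    if (lambda_dot_mode == "range") {
      rp <- prev$evader - prev$pursuer
      lambda_dot <- (lambda - sqrt(sum(rp^2))) / dt
    } else {
      rp <- prev$evader - prev$pursuer
      np <- sqrt(sum(rp^2))
      if (defined && np > 0) {
        cosang <- sum(r * rp) / (lambda * np)
        lambda_dot <- acos(pmin(1, pmax(-1, cosang))) / dt
      }
    }
  }
  structure(list(lambda = lambda, lambda_dot = lambda_dot,
                 v_c = s$v_p - s$v_e, d_t = lambda, mu = mu, eta = eta,
                 defined = defined),
            class = "los_geometry")
}

#' Augmented proportional navigation acceleration command
#'
#' `a_N = N * v_c * lambda_dot + a_nt * N / 2`, applied normal to the
#' pursuer velocity vector. A negative closing velocity (opening geometry)
#' flows through unchanged.
#'
#' @param g A [los_geometry()] with `lambda_dot` available.
#' @param cfg A [guidance_config()].
#' @return Commanded normal acceleration, m/s^2.
#' @export
apn_accel <- function(g, cfg) {
  if (!is.finite(g$lambda_dot)) stop("lambda_dot unavailable; supply a previous state")
  cfg$N * g$v_c * g$lambda_dot + cfg$a_nt * cfg$N / 2
}

#' Radar observation of the evader with latency and coverage limits
#'
#' Returns the stored state at `t - latency`, provided the history reaches
#' back that far and the pursuer-evader range at that instant was within
#' radar coverage; otherwise `NULL`.
#'
#' @param history Data frame with columns `time`, `xe`, `ye`, `ze`, `ve`,
#'   `psi_e`, `xp`, `yp`, `zp` (one row per recorded instant, increasing
#'   time).
#' @param t Query time, s.
#' @param cfg A [guidance_config()] (uses `radar_latency`, `radar_range`).
#' @return One-row data frame (the delayed evader state and the pursuer
#'   position at that instant), or `NULL`.
#' @export
radar_observe <- function(history, t, cfg) {
  h <- as.matrix(history)
  tq <- t - cfg$radar_latency
  i <- findInterval(tq + 1e-9, h[, "time"])
  if (i < 1) return(NULL)
  row <- h[i, ]
  rng <- sqrt((row[["xe"]] - row[["xp"]])^2 + (row[["ye"]] - row[["yp"]])^2 +
                (row[["ze"]] - row[["zp"]])^2)
  if (rng > cfg$radar_range) return(NULL)
  as.data.frame(as.list(row))
}

#' Evasive-advantage reward evaluator
#'
#' Scores a LOS geometry against the three advantage conditions used to
#' reward an evading agent during reinforcement-learning training: the
#' distance lies strictly inside `(d_min, d_max)`, the deviation angle is
#' strictly below `mu_max`, and the aspect angle strictly below `eta_max`.
#' All comparisons are strict, so a geometry exactly on a bound earns no
#' reward for that condition.
#'
#' @param g A [los_geometry()].
#' @param thr A [reward_thresholds()].
#' @param weights Numeric length-3 reward weights (default 1 each).
#' @return List `reward` (weighted sum of satisfied conditions) and
#'   `components` (named logical vector `distance`, `deviation`, `aspect`).
#' @export
rl_reward <- function(g, thr, weights = c(1, 1, 1)) {
  stopifnot(inherits(thr, "reward_thresholds"), length(weights) == 3)
  comp <- c(distance = isTRUE(g$d_t > thr$d_min && g$d_t < thr$d_max),
            deviation = isTRUE(is.finite(g$mu) && g$mu < thr$mu_max),
            aspect = isTRUE(is.finite(g$eta) && g$eta < thr$eta_max))
  list(reward = sum(weights[comp]), components = comp)
}

#' Simulate a pursuit-evasion engagement
#'
#' Fixed-step forward-Euler point-mass integration. The pursuer holds
#' constant speed and is steered in the horizontal plane by an APN command
#' computed from radar-delayed observations (signed planar LOS-angle rate);
#' its vertical channel is a rate-limited proportional climb toward the
#' observed evader altitude. When the radar returns no observation the
#' pursuer flies straight. Evader modes: `"agent1"` -- constant forward
#' speed on a fixed heading with a sinusoidal altitude profile, unaware of
#' the pursuer; `"los_proportional"` -- flees along the pursuer-to-evader
#' bearing at a speed proportional to the LOS rate, never slower than the
#' pursuer plus a margin.
#'
#' @param initial An [engagement_state()] at t = 0.
#' @param cfg A [guidance_config()].
#' @param evader_mode `"agent1"` or `"los_proportional"`.
#' @param duration Engagement length, s (must be a multiple of `cfg$step`).
#' @param guidance `"apn"` or `"none"` (pursuer keeps its initial heading).
#' @param thresholds Optional [reward_thresholds()]; when given, the evader
#'   reward is evaluated and recorded per step.
#' @return Object of class `engagement_run`: `trajectory` data frame (`t`,
#'   pursuer/evader coordinates, `lambda`, `lambda_dot` (signed planar LOS
#'   angle rate, rad/s), `a_n`, optional `reward`) and `summary` (list
#'   `min_lambda`, `t_min_lambda`, `final_lambda`).
#' @export
simulate_engagement <- function(initial, cfg, evader_mode = c("agent1", "los_proportional"),
                                duration, guidance = c("apn", "none"),
                                thresholds = NULL) {
  evader_mode <- match.arg(evader_mode)
  guidance <- match.arg(guidance)
  stopifnot(inherits(initial, "engagement_state"),
            inherits(cfg, "guidance_config"))
  if (duration <= 0 || cfg$step <= 0) stop("duration and step must be positive")
  steps <- round(duration / cfg$step)
  if (abs(steps * cfg$step - duration) > 1e-9)
    stop("step must divide duration")
  dt <- cfg$step
  nrec <- steps + 1L

  p <- initial$pursuer; e <- initial$evader
  psi_p <- initial$psi_p; psi_e <- initial$psi_e
  v_p <- initial$v_p; v_e0 <- initial$v_e
  ye0 <- e[2]

  hist <- matrix(NA_real_, nrec, 9,
                 dimnames = list(NULL, c("time", "xe", "ye", "ze", "ve",
                                         "psi_e", "xp", "yp", "zp")))
  traj <- matrix(NA_real_, nrec, 10,
                 dimnames = list(NULL, c("t", "xp", "yp", "zp", "xe", "ye",
                                         "ze", "lambda", "lambda_dot", "a_n")))
  reward <- if (!is.null(thresholds)) rep(NA_real_, nrec) else NULL

  # delayed-observation lookup on the in-progress history matrix; same
  # contract as radar_observe() but without per-step data-frame overhead
  lag_steps <- round(cfg$radar_latency / dt)
  observe <- function(i) {
    j <- i - lag_steps
    if (j < 1) return(NULL)
    row <- hist[j, ]
    rng <- sqrt((row[["xe"]] - row[["xp"]])^2 + (row[["ye"]] - row[["yp"]])^2 +
                  (row[["ze"]] - row[["zp"]])^2)
    if (rng > cfg$radar_range) return(NULL)
    row
  }

  sigma_prev_obs <- NA_real_
  sigma_prev_true <- NA_real_

  for (i in seq_len(nrec)) {
    tnow <- (i - 1L) * dt
    hist[i, ] <- c(tnow, e[1], e[2], e[3], v_e0, psi_e, p[1], p[2], p[3])

    r <- e - p
    lambda <- sqrt(sum(r^2))
    sigma_true <- atan2(r[1], r[3])
    lam_dot_true <- if (i == 1) NA_real_ else {
      da <- sigma_true - sigma_prev_true
      da <- atan2(sin(da), cos(da))
      da / dt
    }
    sigma_prev_true <- sigma_true

    ## pursuer command from delayed radar observation
    a_n <- 0
    obs <- if (guidance == "apn") observe(i) else NULL
    if (!is.null(obs)) {
      sigma_obs <- atan2(obs[["xe"]] - p[1], obs[["ze"]] - p[3])
      if (is.finite(sigma_prev_obs)) {
        da <- atan2(sin(sigma_obs - sigma_prev_obs),
                    cos(sigma_obs - sigma_prev_obs))
        lam_dot_obs <- da / dt
        v_c <- v_p - obs[["ve"]]
        a_n <- cfg$N * v_c * lam_dot_obs + cfg$a_nt * cfg$N / 2
        a_n <- max(-cfg$a_max, min(cfg$a_max, a_n))
      }
      sigma_prev_obs <- sigma_obs
    } else {
      sigma_prev_obs <- NA_real_
    }

    traj[i, ] <- c(tnow, p, e, lambda, lam_dot_true, a_n)
    if (!is.null(thresholds)) {
      st <- engagement_state(p, e, v_p, v_e0, psi_p, psi_e, tnow)
      reward[i] <- rl_reward(los_geometry(st), thresholds)$reward
    }
    if (i == nrec) break

    ## pursuer update
    if (guidance == "apn" && v_p > 0)
      psi_p <- psi_p + (a_n / v_p) * dt * 180 / pi
    vy <- 0
    if (guidance == "apn" && !is.null(obs))
      vy <- max(-cfg$climb_max,
                min(cfg$climb_max, cfg$climb_gain * (obs[["ye"]] - p[2])))
    p <- p + dt * c(v_p * sin(psi_p * pi / 180), vy, v_p * cos(psi_p * pi / 180))

    ## evader update
    if (evader_mode == "agent1") {
      e[1] <- e[1] + dt * v_e0 * sin(psi_e * pi / 180)
      e[3] <- e[3] + dt * v_e0 * cos(psi_e * pi / 180)
      e[2] <- ye0 + cfg$agent1_alt_amp *
        sin(2 * pi * (tnow + dt) / cfg$agent1_alt_period)
    } else {
      flee <- atan2(e[1] - p[1], e[3] - p[3])
      v_e <- max(v_p + cfg$evader_margin,
                 cfg$evader_los_gain * abs(if (is.finite(lam_dot_true)) lam_dot_true else 0))
      psi_e <- flee * 180 / pi
      e[1] <- e[1] + dt * v_e * sin(flee)
      e[3] <- e[3] + dt * v_e * cos(flee)
    }
  }

  traj <- as.data.frame(traj)
  if (!is.null(reward)) traj$reward <- reward
  imin <- which.min(traj$lambda)
  structure(list(trajectory = traj,
                 summary = list(min_lambda = traj$lambda[imin],
                                t_min_lambda = traj$t[imin],
                                final_lambda = traj$lambda[nrec])),
            class = "engagement_run")
}

#' Write an engagement trajectory as CSV
#'
#' @param run An `engagement_run`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_engagement_csv <- function(run, path) {
  stopifnot(inherits(run, "engagement_run"))
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}
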