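# Synthetic gait fixtures: cyclic hip/knee/ankle trajectories at three
# speeds, double-bump vertical ground reaction with a heel-to-toe center
# of pressure, assistance-as-needed style support torques per weakening
# level, and the healthy reference plantarflexor activation.
#
# These are honest stand-ins for motion-lab recordings: truncated-Fourier
# templates fitted to normative gait key points, with seeded smooth
# (low-order) jitter for inter-trial variability. All angles follow the
# package convention (dorsiflexion/flexion positive about +z).

# normative key points (phase %, degrees); templates are the least-squares
# truncated Fourier fit (4 harmonics) through their periodic interpolation
.gait_keypoints <- list(
  hip = cbind(c(0, 10, 30, 50, 60, 70, 85, 100),
              c(30, 27, 5, -10, -8, 10, 30, 30)),
  knee = cbind(c(0, 15, 40, 55, 72, 85, 100),
               c(5, 18, 5, 15, 60, 30, 5)),
  ankle = cbind(c(0, 7, 30, 45, 60, 70, 80, 90, 100),
                c(0, -5, 8, 10, -15, -8, 3, 3, 0)))

# Fourier coefficients (a0, a_k, b_k) for one template
#' @noRd
fit_fourier_template <- function(kp, n_harm = 4L) {
  ph <- seq(0, 1, length.out = 201L)[-201L]
  y <- stats::approx(kp[, 1L] / 100, kp[, 2L], xout = ph, rule = 2)$y
  X <- matrix(1, length(ph), 1L + 2L * n_harm)
  for (k in seq_len(n_harm)) {
    X[, 2L * k] <- cos(2 * pi * k * ph)
    X[, 2L * k + 1L] <- sin(2 * pi * k * ph)
  }
  qr.solve(X, y)
}

#' @noRd
eval_fourier <- function(coef, ph, deriv = 0L, period = 1) {
  n_harm <- (length(coef) - 1L) %/% 2L
  out <- if (deriv == 0L) rep(coef[1L], length(ph)) else numeric(length(ph))
  for (k in seq_len(n_harm)) {
    w <- 2 * pi * k / period
    a <- coef[2L * k]; b <- coef[2L * k + 1L]
    out <- out + switch(deriv + 1L,
      a * cos(w * ph * period) + b * sin(w * ph * period),
      w * (-a * sin(w * ph * period) + b * cos(w * ph * period)),
      w^2 * (-a * cos(w * ph * period) - b * sin(w * ph * period)))
  }
  out
}

#' Generate a synthetic gait trial
#'
#' Builds one gait cycle at the requested speed: joint-angle trajectories
#' from truncated-Fourier templates with speed-scaled cycle duration and
#' amplitude, a double-bump vertical ground-reaction profile that is zero
#' during swing, an anteroposterior braking/propulsion component, a
#' heel-to-toe center-of-pressure trace, and seeded low-order jitter for
#' inter-trial variability. Deterministic per `(speed, seed)`.
#'
#' @param speed `"slow"`, `"medium"` or `"fast"`.
#' @param seed integer seed for the jitter stream.
#' @param config an `afo_config` (defaults used when `NULL`).
#' @return An object of class `afo_gait_trial` with time base (s), hip,
#'   knee, ankle angles (rad), vertical and anteroposterior ground
#'   reaction (N), center-of-pressure trace (m, foot frame) and metadata.
#' @export
synth_gait <- function(speed = c("slow", "medium", "fast"), seed = 1,
                       config = NULL) {
  speed <- match.arg(speed)
  if (is.null(config)) config <- default_config()
  gc <- config$gait
  T_ <- gc$cycle_duration[[speed]]
  sf <- gc$stance_fraction[[speed]]
  amp <- gc$amplitude_scale[[speed]]
  bw <- config$model$body_mass * config$controller$gravity

  n <- round(T_ / 0.002)
  time <- seq(0, T_, length.out = n + 1L)
  ph <- time / T_

  jit <- with_seed(as.integer(seed), {
    list(ang = matrix(stats::runif(12L, -1, 1), 3L, 4L),
         grf = stats::runif(2L, -1, 1))
  })
  ja <- gc$jitter_angle_deg * pi / 180
  jitter_curve <- function(row)
    ja * (row[1L] * sin(2 * pi * ph + pi * row[2L]) +
          0.5 * row[3L] * sin(4 * pi * ph + pi * row[4L]))

  ang <- list()
  for (i in seq_along(.gait_keypoints)) {
    nm <- names(.gait_keypoints)[i]
    coef <- fit_fourier_template(.gait_keypoints[[nm]])
    ang[[nm]] <- amp * eval_fourier(coef, ph) * pi / 180 +
      jitter_curve(jit$ang[i, ])
  }
  # enforce exact periodicity of the jittered curves (sin terms already are)
  for (nm in names(ang)) ang[[nm]][n + 1L] <- ang[[nm]][1L]

  # double-bump vertical ground reaction over the stance window
  s <- pmin(ph / sf, 1)
  shape <- sin(pi * s) + 0.25 * sin(3 * pi * s)
  shape[ph > sf] <- 0
  shape <- pmax(shape, 0)
  gmag <- (1 + gc$jitter_grf_frac * jit$grf[1L]) * gc$grf_peak_bw[[speed]]
  grf_v <- bw * gmag * shape / max(shape)
  grf_ap <- -0.16 * bw * sin(2 * pi * s) * (1 + gc$jitter_grf_frac * jit$grf[2L])
  grf_ap[ph > sf] <- 0
  # center of pressure rolls from heel to toe in the foot frame
  cop_x <- -0.04 + 0.19 * (3 * s^2 - 2 * s^3)
  cop_x[ph > sf] <- 0
  cop_y <- rep(-config$model$ankle_height, n + 1L)

  structure(list(
    speed = speed, seed = as.integer(seed), T = T_,
    stance_fraction = sf, body_weight = bw,
    stride_speed = gc$stride_speed[[speed]],
    time = time, hip = ang$hip, knee = ang$knee, ankle = ang$ankle,
    grf_v = grf_v, grf_ap = grf_ap, cop_x = cop_x, cop_y = cop_y),
    class = "afo_gait_trial")
}

#' @export
print.afo_gait_trial <- function(x, ...) {
  cat(sprintf("<afo_gait_trial> %s (T = %.2f s, stance %.0f%%, seed %d)\n",
              x$speed, x$T, 100 * x$stance_fraction, x$seed))
  invisible(x)
}

# periodic numerical derivative on the uniform trial grid (endpoints share
# a sample)
#' @noRd
cyc_deriv <- function(y, dt) {
  n <- length(y)
  yc <- y[-n]
  d <- (yc[c(2:(n - 1L), 1L)] - yc[c(n - 1L, 1:(n - 2L))]) / (2 * dt)
  c(d, d[1L])
}

# base kinematics arrays (ankle center, shank orientation, ankle reference,
# gait forces) at arbitrary times within the cycle
#' @noRd
base_motion_arrays <- function(model, trial, times) {
  dt <- trial$time[2L] - trial$time[1L]
  iget <- function(y) interp_cyclic(times, trial$T, trial$time, y)
  h <- iget(trial$hip); hd <- iget(cyc_deriv(trial$hip, dt))
  hdd <- iget(cyc_deriv(cyc_deriv(trial$hip, dt), dt))
  k <- iget(trial$knee); kd <- iget(cyc_deriv(trial$knee, dt))
  kdd <- iget(cyc_deriv(cyc_deriv(trial$knee, dt), dt))
  th <- iget(trial$ankle); thd <- iget(cyc_deriv(trial$ankle, dt))
  thdd <- iget(cyc_deriv(cyc_deriv(trial$ankle, dt), dt))

  v <- trial$stride_speed
  ph <- (times %% trial$T) / trial$T
  yhip0 <- model$ankle_height + model$shank_length + model$thigh_length - 0.02
  w4 <- 4 * pi / trial$T
  yo <- 0.012 * sin(4 * pi * ph - pi / 2)
  yod <- 0.012 * w4 * cos(4 * pi * ph - pi / 2)
  yodd <- -0.012 * w4^2 * sin(4 * pi * ph - pi / 2)

  Lt <- model$thigh_length; Ls <- model$shank_length
  phis <- h - k; phisd <- hd - kd; phisdd <- hdd - kdd
  pax <- v * times + Lt * sin(h) + Ls * sin(phis)
  pay <- yhip0 + yo - Lt * cos(h) - Ls * cos(phis)
  vax <- v + Lt * hd * cos(h) + Ls * phisd * cos(phis)
  vay <- yod + Lt * hd * sin(h) + Ls * phisd * sin(phis)
  aax <- Lt * (hdd * cos(h) - hd^2 * sin(h)) +
    Ls * (phisdd * cos(phis) - phisd^2 * sin(phis))
  aay <- yodd + Lt * (hdd * sin(h) + hd^2 * cos(h)) +
    Ls * (phisdd * sin(phis) + phisd^2 * cos(phis))

  list(times = times, pax = pax, pay = pay, vax = vax, vay = vay,
       aax = aax, aay = aay, phis = phis, phisd = phisd, phisdd = phisdd,
       theta = th, thetad = thd, thetadd = thdd,
       grf_v = iget(trial$grf_v), grf_ap = iget(trial$grf_ap),
       cop_x = iget(trial$cop_x), cop_y = iget(trial$cop_y))
}

#' Inverse-dynamics ankle moment demand of a gait trial
#'
#' Net ankle moment (Nm, plantarflexion negative) the muscles must produce
#' over the cycle for the foot to follow the reference kinematics under
#' the prescribed ground reaction, computed from the foot segment's
#' Newton-Euler balance about the moving ankle center. This is the
#' screening quantity behind the reference activation and the support
#' profiles.
#'
#' @param model an `afo_model`.
#' @param trial an `afo_gait_trial`.
#' @return Numeric vector over `trial$time`.
#' @export
ankle_moment_demand <- function(model, trial) {
  ba <- base_motion_arrays(model, trial, trial$time)
  pm <- prep_model(model)
  g <- model$gravity
  phif <- ba$phis + ba$theta
  wf <- ba$phisd + ba$thetad
  alf <- ba$phisdd + ba$thetadd
  cf <- cos(phif); sf_ <- sin(phif)
  rx <- pm$r_f[1L] * cf - pm$r_f[2L] * sf_
  ry <- pm$r_f[1L] * sf_ + pm$r_f[2L] * cf
  acx <- ba$aax + alf * (-ry) - wf^2 * rx
  acy <- ba$aay + alf * rx - wf^2 * ry
  copx <- ba$cop_x * cf - ba$cop_y * sf_
  copy <- ba$cop_x * sf_ + ba$cop_y * cf
  pm$If * alf +
    pm$mf * (rx * (acy + g) - ry * acx) -
    (copx * ba$grf_v - copy * ba$grf_ap)
}

#' Healthy reference plantarflexor activation
#'
#' The target activation curve against which simulated plantarflexor
#' activation is compared: the quasi-static activation a healthy
#' (unweakened) plantarflexor group needs to meet the plantarflexion part
#' of the inverse-dynamics ankle moment demand.
#'
#' @param model an `afo_model`.
#' @param trial an `afo_gait_trial`.
#' @return Object of class `afo_reference_activation`: list with `time`,
#'   `phase` (0-100) and `a` in `[0, 1]`.
#' @export
reference_activation <- function(model, trial) {
  tau <- ankle_moment_demand(model, trial)
  cap <- model$muscles$plantarflexors$f_max_iso *
    model$muscles$plantarflexors$moment_arm
  a <- pmin(pmax(-tau, 0) / cap, 1)
  structure(list(time = trial$time, phase = 100 * trial$time / trial$T,
                 a = a),
            class = "afo_reference_activation")
}

# periodic raised-cosine smoothing
#' @noRd
smooth_cyclic <- function(y, frac) {
  n <- length(y) - 1L
  yc <- y[seq_len(n)]
  half <- max(1L, round(frac * n))
  w <- 0.5 * (1 + cos(pi * seq(-half, half) / (half + 1L)))
  w <- w / sum(w)
  idx <- outer(seq_len(n), seq(-half, half), function(i, j) ((i + j - 1L) %% n) + 1L)
  sm <- as.vector(matrix(yc[idx], n) %*% w)
  c(sm, sm[1L])
}

#' Assistance-as-needed style support profile
#'
#' Two-lobe support torque about the device axis (applied to the foot
#' shell, reaction on the calf shell; plantarflexion negative): a
#' late-stance plantarflexion-support lobe equal to the fraction
#' `(1 - w)` of the inverse-dynamics plantarflexion demand that the
#' weakened plantarflexors can no longer produce, and a swing
#' dorsiflexion-assist lobe covering the full dorsiflexion demand of the
#' paralyzed dorsiflexors (holding the foot against gravity sag). The
#' profile is smoothed with a periodic raised-cosine kernel. With `w = 1`
#' and no dorsiflexor paralysis the profile is identically zero.
#'
#' @param model an `afo_model`.
#' @param trial an `afo_gait_trial`.
#' @param level `"PF25"`, `"PF50"`, `"PF75"` or `"PF100"`.
#' @param paralyzed logical; `FALSE` models an intact-dorsiflexor
#'   hypothetical (no swing lobe).
#' @return Object of class `afo_support_profile`: `time`, `phase`,
#'   `torque` (Nm), `level`, `speed`.
#' @export
synth_support <- function(model, trial, level, paralyzed = TRUE) {
  w <- c(PF25 = 0.25, PF50 = 0.50, PF75 = 0.75, PF100 = 1.00)[[level]]
  tau <- ankle_moment_demand(model, trial)
  frac <- model$config$gait$support_smooth_frac
  pf_demand <- smooth_cyclic(pmax(-tau, 0), frac)
  df_demand <- smooth_cyclic(pmax(tau, 0), frac)
  torque <- -(1 - w) * pf_demand + (if (paralyzed) df_demand else 0)
  structure(list(time = trial$time, phase = 100 * trial$time / trial$T,
                 torque = torque, level = level, speed = trial$speed,
                 w = w),
            class = "afo_support_profile")
}

#' @export
print.afo_support_profile <- function(x, ...) {
  cat(sprintf("<afo_support_profile> %s/%s: peak %.1f Nm (stance), %.1f Nm (swing)\n",
              x$level, x$speed, min(x$torque), max(x$torque)))
  invisible(x)
}
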