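# Study-design driver: 4 weakening levels x 3 speeds x 7 misalignment
# directions per synthetic subject, and the outcome measures of the
# protocol: marker-pair relative movement, mean stance-phase plantarflexor
# activation deviation, and residual-actuator plausibility.

# resample a trace (vs phase 0..100) to the standard 101-point grid
#' @noRd
resample_phase <- function(phase, y, n_out = 101L) {
  stats::approx(phase, y, xout = seq(0, 100, length.out = n_out), rule = 2)$y
}

#' Marker-pair relative movement of a trial
#'
#' Per-axis displacement of each shell marker relative to its segment twin
#' (shell minus segment, expressed in the segment frame), resampled to the
#' 101-point gait-phase grid and reported in millimeters.
#'
#' @param result an `afo_trial_result`.
#' @return A data.frame with columns `pair` (`"foot"`, `"shank"`), `axis`
#'   (`"x"`, `"y"`, `"z"`), `phase` (0-100) and `disp_mm`.
#' @export
relative_motion <- function(result) {
  stopifnot(inherits(result, "afo_trial_result"))
  if (is.null(result$markers)) stopf("missing marker traces in result")
  ph <- seq(0, 100, length.out = 101L)
  out <- list()
  for (pair in names(result$markers)) {
    m <- result$markers[[pair]]
    for (ax in 1:3)
      out[[length(out) + 1L]] <- data.frame(
        pair = pair, axis = c("x", "y", "z")[ax], phase = ph,
        disp_mm = 1000 * resample_phase(result$phase, m[, ax]))
  }
  do.call(rbind, out)
}

#' Mean stance-phase activation deviation
#'
#' Mean absolute deviation of the simulated plantarflexor activation from
#' the reference activation curve over the phase window, in percent
#' activation. The stance window is defined as the phase where the
#' vertical ground reaction exceeds 2% of its peak.
#'
#' @param result an `afo_trial_result`.
#' @param ref an `afo_reference_activation`, or `NULL` to use the
#'   reference stored with the result.
#' @param phase_window `"stance"`, `"swing"` or `"cycle"`.
#' @return Scalar deviation, % activation.
#' @export
activation_deviation <- function(result, ref = NULL,
                                 phase_window = c("stance", "swing", "cycle")) {
  stopifnot(inherits(result, "afo_trial_result"))
  phase_window <- match.arg(phase_window)
  a_ref <- if (is.null(ref)) result$a_ref else
    stats::approx(ref$time, ref$a, xout = result$time, rule = 2)$y
  stance <- result$grf_v > 0.02 * max(result$grf_v)
  win <- switch(phase_window, stance = stance, swing = !stance,
                cycle = rep(TRUE, length(stance)))
  if (!any(win)) stopf("empty %s window", phase_window)
  100 * mean(abs(result$act[win, 1L] - a_ref[win]))
}

#' Residual-actuator plausibility check
#'
#' Compares the peak residual usage per base coordinate against the
#' thresholds: residual forces (the net interface load that the virtual
#' base supports must absorb, since the recorded motion came from
#' unassisted walking) against a fraction of the peak ground-reaction
#' magnitude, and the ankle reserve moment against the moment threshold.
#' A residual exactly at the threshold passes (`<=` convention).
#'
#' @param result an `afo_trial_result`.
#' @param thresholds list with `residual_force_frac` (fraction of peak
#'   ground reaction) and `residual_moment` (Nm); defaults from the
#'   model configuration used in the run.
#' @return A data.frame with one row per coordinate: `coordinate`,
#'   `peak`, `threshold`, `margin`, `pass`.
#' @export
residual_check <- function(result, thresholds = NULL) {
  stopifnot(inherits(result, "afo_trial_result"))
  if (is.null(thresholds))
    thresholds <- list(residual_force_frac = 0.05, residual_moment = 25)
  f_thr <- thresholds$residual_force_frac * result$meta$grf_peak
  peaks <- c(apply(abs(result$res_force), 2L, max), max(abs(result$reserve)))
  thr <- c(rep(f_thr, 3L), thresholds$residual_moment)
  data.frame(
    coordinate = c("base_fx", "base_fy", "base_fz", "ankle_reserve"),
    peak = unname(peaks), threshold = thr,
    margin = thr - unname(peaks), pass = unname(peaks) <= thr)
}

#' Run the full weakening x speed x misalignment grid
#'
#' Simulates every condition of the protocol (4 weakening levels x 3
#' speeds x 7 misalignment directions = 84 conditions per synthetic
#' subject). For each subject and speed, one bootstrap per misalignment
#' direction is computed on the unweakened model and shared by all four
#' weakening levels, so every level starts the cycle from the same pose.
#' Per-condition failures are isolated, reported in the condition table,
#' and do not stop the grid.
#'
#' @param config an `afo_config` (defaults when `NULL`); the experiment
#'   section defines levels, speeds, directions and the number of
#'   synthetic subjects.
#' @param seed integer master seed; subject trial seeds derive from it.
#' @param keep_traces logical; keep per-condition phase-resampled marker
#'   traces (needed for trace-level summaries).
#' @return An object of class `afo_deviation_report`: `conditions`
#'   data.frame (one row per condition and subject, with mean stance
#'   activation deviation, peak displacements per pair/axis, residual
#'   verdicts and metadata), `aggregate` (mean of per-subject means per
#'   level x speed x direction), `traces`, and `meta`.
#' @export
run_grid <- function(config = NULL, seed = 1, keep_traces = TRUE) {
  if (is.null(config)) config <- default_config()
  ex <- config$experiment
  chash <- config_hash(config)
  base_model <- build_model(config)

  rows <- list()
  traces <- list()
  for (subject in seq_len(ex$n_subjects)) {
    for (speed in ex$speeds) {
      trial_seed <- as.integer(seed * 1000 + subject * 10 +
                                 match(speed, c("slow", "medium", "fast")))
      trial <- synth_gait(speed, seed = trial_seed, config = config)
      supports <- lapply(stats::setNames(ex$levels, ex$levels), function(lv)
        synth_support(base_model, trial, lv))
      for (direction in ex$directions) {
        m_dir <- apply_misalignment(base_model, direction,
                                    ex$misalignment_magnitude)
        p0 <- list(hip = trial$hip[1L], knee = trial$knee[1L],
                   ankle = trial$ankle[1L])
        st0 <- initial_cmc(m_dir, gait_initial_pose = p0,
                           n_steps = config$controller$n_bootstrap_steps)
        for (level in ex$levels) {
          m_cond <- apply_weakening(m_dir, level)
          res <- tryCatch(
            run_gait_cycle(m_cond, trial, support = supports[[level]],
                           state0 = st0),
            error = function(e) e)
          cond_id <- paste(level, speed, direction, subject, sep = "_")
          if (inherits(res, "error") || !is.null(res$failure)) {
            rows[[length(rows) + 1L]] <- data.frame(
              subject = subject, level = level, speed = speed,
              direction = direction, seed = trial_seed,
              ok = FALSE,
              mean_dev_pct = NA_real_, peak_foot_x = NA_real_,
              peak_foot_y = NA_real_, peak_foot_z = NA_real_,
              peak_shank_x = NA_real_, peak_shank_y = NA_real_,
              peak_shank_z = NA_real_, residual_pass = NA,
              saturated_steps = NA_integer_,
              message = if (inherits(res, "error"))
                conditionMessage(res) else res$failure$msg)
            next
          }
          rc <- residual_check(res, config$thresholds)
          mk <- res$markers
          peak_mm <- function(m, ax) 1000 * max(abs(m[, ax]))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subject, level = level, speed = speed,
            direction = direction, seed = trial_seed, ok = TRUE,
            mean_dev_pct = activation_deviation(res),
            peak_foot_x = peak_mm(mk$foot, 1L),
            peak_foot_y = peak_mm(mk$foot, 2L),
            peak_foot_z = peak_mm(mk$foot, 3L),
            peak_shank_x = peak_mm(mk$shank, 1L),
            peak_shank_y = peak_mm(mk$shank, 2L),
            peak_shank_z = peak_mm(mk$shank, 3L),
            residual_pass = all(rc$pass),
            saturated_steps = sum(res$saturated),
            message = "")
          if (keep_traces) traces[[cond_id]] <- relative_motion(res)
        }
      }
    }
  }
  conditions <- do.call(rbind, rows)
  agg <- stats::aggregate(
    conditions[conditions$ok, c("mean_dev_pct", "peak_foot_y")],
    by = conditions[conditions$ok, c("level", "speed", "direction")],
    FUN = mean)
  structure(list(conditions = conditions, aggregate = agg, traces = traces,
                 meta = list(seed = seed, config_hash = chash,
                             n_subjects = ex$n_subjects,
                             n_conditions = nrow(conditions))),
            class = "afo_deviation_report")
}

#' @export
print.afo_deviation_report <- function(x, ...) {
  cat(sprintf("<afo_deviation_report> %d conditions (%d subjects), %d failed\n",
              nrow(x$conditions), x$meta$n_subjects, sum(!x$conditions$ok)))
  ag <- stats::aggregate(mean_dev_pct ~ level + speed,
                         data = x$conditions[x$conditions$ok, ], FUN = mean)
  ag <- ag[order(ag$speed, ag$level), ]
  cat("mean stance activation deviation [%]:\n")
  print(ag, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize a deviation report per level and speed
#'
#' @param object an `afo_deviation_report`.
#' @param ... ignored.
#' @return A data.frame with mean stance activation deviation (%) and
#'   peak foot-pair |y| displacement (mm) per level x speed, averaged
#'   over directions and subjects.
#' @export
summary.afo_deviation_report <- function(object, ...) {
  ok <- object$conditions[object$conditions$ok, ]
  out <- stats::aggregate(ok[, c("mean_dev_pct", "peak_foot_y")],
                          by = ok[, c("level", "speed")], FUN = mean)
  out[order(match(out$speed, c("slow", "medium", "fast")),
            match(out$level, c("PF25", "PF50", "PF75", "PF100"))), ]
}

#' Base-graphics panel of relative-movement traces
#'
#' Plots the per-axis relative movement of one marker pair against gait
#' phase for a set of grid conditions (synthetic data).
#'
#' @param report an `afo_deviation_report` built with `keep_traces = TRUE`.
#' @param pair `"foot"` or `"shank"`.
#' @param conditions character vector of trace names (default: all).
#' @return Invisibly, the trace names plotted.
#' @export
plot_relative_motion <- function(report, pair = "foot", conditions = NULL) {
  stopifnot(inherits(report, "afo_deviation_report"))
  if (length(report$traces) == 0L) stopf("report has no stored traces")
  if (is.null(conditions)) conditions <- names(report$traces)
  oldpar <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(oldpar))
  for (ax in c("x", "y", "z")) {
    rng <- range(unlist(lapply(conditions, function(cn) {
      tr <- report$traces[[cn]]
      tr$disp_mm[tr$pair == pair & tr$axis == ax]
    })))
    plot(NULL, xlim = c(0, 100), ylim = rng, xlab = "gait phase [%]",
         ylab = sprintf("%s %s [mm]", pair, ax))
    for (cn in conditions) {
      tr <- report$traces[[cn]]
      sel <- tr$pair == pair & tr$axis == ax
      graphics::lines(tr$phase[sel], tr$disp_mm[sel],
                      col = grDevices::grey(0.2 + 0.6 * match(cn, conditions) /
                                              length(conditions)))
    }
  }
  invisible(conditions)
}
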