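# Full gait-cycle simulation: tracking controller at the control period
# (default 10 ms) over the linearly implicit 1 ms integrator, with the
# support torque and recorded ground reaction applied as external forces.

#' Simulate one gait cycle of the coupled model
#'
#' Runs the tracking controller over one cycle of a gait trial: the ankle
#' follows its reference with PD feedback (task weight 10, like the knee;
#' the knee and hip are prescribed base coordinates realized exactly),
#' activations are allocated by the effort optimum, reserve usage is
#' recorded every step, and the interface wrenches and marker-pair
#' displacements are logged at the control rate.
#'
#' @param model an `afo_model` (weakened and misaligned as desired).
#' @param trial an `afo_gait_trial`.
#' @param support an `afo_support_profile`, or `NULL` for no support.
#' @param state0 initial [afo_state()]; when `NULL`, [initial_cmc()] is run
#'   from the neutral pose to the gait initial pose.
#' @param record_elements logical; keep per-element wrench traces.
#' @return An object of class `afo_trial_result`.
#' @export
run_gait_cycle <- function(model, trial, support = NULL, state0 = NULL,
                           record_elements = TRUE) {
  stopifnot(inherits(model, "afo_model"), inherits(trial, "afo_gait_trial"))
  ctrl <- model$config$controller
  pm <- prep_model(model)
  dtc <- ctrl$record_dt
  n_sub <- max(1L, round(dtc / ctrl$dt))
  h <- dtc / n_sub
  n_ctrl <- round(trial$T / dtc)

  if (is.null(state0)) {
    p0 <- list(hip = trial$hip[1L], knee = trial$knee[1L],
               ankle = trial$ankle[1L])
    state0 <- initial_cmc(model, gait_initial_pose = p0,
                          n_steps = ctrl$n_bootstrap_steps)
  }

  # dense base kinematics and externals over the substep grid
  tsub <- seq(0, trial$T, by = h)
  ba <- base_motion_arrays(model, trial, tsub)
  sup <- if (is.null(support)) numeric(length(tsub)) else
    interp_cyclic(tsub, trial$T, support$time, support$torque)
  bs_at <- function(i) list(
    pa = c(ba$pax[i], ba$pay[i]), va = c(ba$vax[i], ba$vay[i]),
    aa = c(ba$aax[i], ba$aay[i]),
    phis = ba$phis[i], phisd = ba$phisd[i], phisdd = ba$phisdd[i])
  ext_at <- function(i) list(
    support = sup[i], grf = c(ba$grf_ap[i], ba$grf_v[i]),
    cop = c(ba$cop_x[i], ba$cop_y[i]), tau_m = 0, gravity = TRUE)

  aref <- reference_activation(model, trial)

  nrec <- n_ctrl + 1L
  rec <- list(
    time = numeric(nrec), q = matrix(0, nrec, 6L), qdot = matrix(0, nrec, 6L),
    act = matrix(0, nrec, 2L, dimnames = list(NULL, c("pf", "df"))),
    a_cmd = matrix(0, nrec, 2L), tau_req = numeric(nrec),
    tau_muscle = numeric(nrec), reserve = numeric(nrec),
    support = numeric(nrec), saturated = logical(nrec),
    grf_v = numeric(nrec),
    res_force = matrix(0, nrec, 3L, dimnames = list(NULL, c("x", "y", "z"))),
    markers = list(foot = matrix(0, nrec, 3L, dimnames = list(NULL, c("x", "y", "z"))),
                   shank = matrix(0, nrec, 3L, dimnames = list(NULL, c("x", "y", "z")))),
    elements = if (record_elements)
      lapply(seq_along(pm$els), function(i)
        matrix(0, nrec, 4L, dimnames = list(NULL, c("fx", "fy", "fz", "tz"))))
      else NULL)

  q <- state0$q; qdot <- state0$qdot; act <- state0$act
  failure <- NULL

  record <- function(j, i_sub, dtm, controls) {
    rec$time[j] <<- tsub[i_sub]
    rec$q[j, ] <<- q; rec$qdot[j, ] <<- qdot; rec$act[j, ] <<- act
    rec$support[j] <<- sup[i_sub]; rec$grf_v[j] <<- ba$grf_v[i_sub]
    rec$res_force[j, ] <<- dtm$res_force
    md <- marker_disp(pm, q, bs_at(i_sub))
    rec$markers$foot[j, ] <<- md["foot", ]
    rec$markers$shank[j, ] <<- md["shank", ]
    if (!is.null(rec$elements))
      for (ei in seq_along(pm$els))
        rec$elements[[ei]][j, ] <<- dtm$elems[[ei]][1:4]
    if (!is.null(controls)) {
      rec$a_cmd[j, ] <<- controls$a_cmd
      rec$tau_req[j] <<- controls$tau_req
      rec$tau_muscle[j] <<- controls$tau_muscle
      rec$reserve[j] <<- controls$reserve
      rec$saturated[j] <<- controls$saturated
    }
  }

  for (j in seq_len(n_ctrl)) {
    i0 <- (j - 1L) * n_sub + 1L
    bs <- bs_at(i0); ext <- ext_at(i0)
    # matrices refreshed once per record window; forces every step
    dtm <- tryCatch(
      dyn_terms(pm, q, qdot, bs, ext, need_mats = TRUE),
      error = function(e) e)
    if (inherits(dtm, "error")) { failure <- list(t = tsub[i0], msg = conditionMessage(dtm)); break }
    A_chol <- factor_implicit(dtm$M, dtm$Kg, dtm$Cg, h)
    M11 <- dtm$M[1L, 1L]

    ok <- TRUE
    controls <- NULL
    for (k in seq_len(n_sub)) {
      i <- i0 + k - 1L
      bsk <- bs_at(i)
      extk <- ext_at(i)
      Q <- if (k == 1L) dtm$Q else
        tryCatch(dyn_terms(pm, q, qdot, bsk, extk, need_mats = FALSE)$Q,
                 error = function(e) e)
      if (inherits(Q, "error")) {
        failure <- list(t = tsub[i], msg = conditionMessage(Q)); ok <- FALSE; break
      }
      qdd_des <- ba$thetadd[i] +
        ctrl$k_v * (ba$thetad[i] - qdot[1L]) +
        ctrl$k_p * (ba$theta[i] - q[1L])
      tau_req <- M11 * qdd_des - Q[1L]
      ast <- activation_step(pm, ctrl, act, tau_req, h)
      act <- ast$act
      if (k == 1L) {
        controls <- list(a_cmd = ast$a_cmd, tau_req = tau_req,
                         tau_muscle = ast$tau_muscle, reserve = ast$reserve,
                         saturated = ast$saturated)
        record(j, i0, dtm, controls)
      }
      Q[1L] <- Q[1L] + ast$tau_muscle + ast$reserve
      qdot <- implicit_step(Q, qdot, h, dtm$M, A_chol)
      q <- q + h * qdot
      if (!all(is.finite(q))) {
        failure <- list(t = tsub[i], msg = "non-finite state")
        ok <- FALSE
        break
      }
    }
    if (!ok) break
  }
  if (is.null(failure)) {
    i_end <- n_ctrl * n_sub + 1L
    dtm <- dyn_terms(pm, q, qdot, bs_at(i_end), ext_at(i_end), need_mats = FALSE)
    record(nrec, i_end, dtm, NULL)
    n_valid <- nrec
  } else {
    n_valid <- max(1L, sum(rec$time > 0) + 1L)
    warning(sprintf("integration failure at t = %.3f s: %s",
                    failure$t, failure$msg), call. = FALSE)
  }

  structure(list(
    time = rec$time[seq_len(n_valid)],
    phase = 100 * rec$time[seq_len(n_valid)] / trial$T,
    q = rec$q[seq_len(n_valid), , drop = FALSE],
    qdot = rec$qdot[seq_len(n_valid), , drop = FALSE],
    act = rec$act[seq_len(n_valid), , drop = FALSE],
    a_cmd = rec$a_cmd[seq_len(n_valid), , drop = FALSE],
    a_ref = stats::approx(aref$time, aref$a, xout = rec$time[seq_len(n_valid)],
                          rule = 2)$y,
    tau_req = rec$tau_req[seq_len(n_valid)],
    tau_muscle = rec$tau_muscle[seq_len(n_valid)],
    reserve = rec$reserve[seq_len(n_valid)],
    support = rec$support[seq_len(n_valid)],
    saturated = rec$saturated[seq_len(n_valid)],
    grf_v = rec$grf_v[seq_len(n_valid)],
    res_force = rec$res_force[seq_len(n_valid), , drop = FALSE],
    markers = lapply(rec$markers, function(m) m[seq_len(n_valid), , drop = FALSE]),
    elements = if (!is.null(rec$elements))
      lapply(rec$elements, function(m) m[seq_len(n_valid), , drop = FALSE]),
    failure = failure,
    meta = list(level = model$weakening_level,
                speed = trial$speed, T = trial$T,
                stance_fraction = trial$stance_fraction,
                direction = if (is.null(model$misalignment_direction)) "zero"
                  else model$misalignment_direction,
                misalignment = model$misalignment,
                seed = trial$seed,
                config_hash = config_hash(model$config),
                grf_peak = max(trial$grf_v))),
    class = "afo_trial_result")
}

#' @export
print.afo_trial_result <- function(x, ...) {
  cat(sprintf(
    "<afo_trial_result> %s/%s/%s seed %d: %d samples%s\n",
    x$meta$level, x$meta$speed, x$meta$direction, x$meta$seed,
    length(x$time),
    if (is.null(x$failure)) "" else sprintf(" (FAILED at t=%.3f)", x$failure$t)))
  invisible(x)
}

#' Export a trial result as tidy CSV plus JSON metadata sidecar
#'
#' @param result an `afo_trial_result`.
#' @param path CSV output path; metadata is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_trial_result <- function(result, path) {
  stopifnot(inherits(result, "afo_trial_result"))
  d <- data.frame(
    time = result$time, phase = result$phase,
    ankle = result$q[, 1L],
    aux_tx = result$q[, 2L], aux_ty = result$q[, 3L], aux_tz = result$q[, 4L],
    foot_shell_rz = result$q[, 5L], calf_shell_rz = result$q[, 6L],
    a_pf = result$act[, 1L], a_df = result$act[, 2L],
    a_ref = result$a_ref,
    tau_muscle = result$tau_muscle, reserve = result$reserve,
    support = result$support, grf_v = result$grf_v,
    foot_dx = result$markers$foot[, 1L], foot_dy = result$markers$foot[, 2L],
    foot_dz = result$markers$foot[, 3L],
    shank_dx = result$markers$shank[, 1L], shank_dy = result$markers$shank[, 2L],
    shank_dz = result$markers$shank[, 3L],
    res_fx = result$res_force[, 1L], res_fy = result$res_force[, 2L],
    res_fz = result$res_force[, 3L])
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(result$meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
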