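# Multibody dynamics of the coupled leg + AFO system, and the tracking
# controller in the style of computed muscle control.
#
# Free generalized coordinates, in order:
#   q = (ankle rz, aux tx, aux ty, aux tz, foot-shell rz, calf-shell rz)
# Aux translations are expressed in the shank frame; shell angles are
# relative to the auxiliary body (which cannot rotate, so they equal the
# shell angle relative to the shank). Hip and knee are prescribed base
# coordinates; their motion enters through the base kinematics (ankle
# center position and shank orientation with rates).
#
# Integrator: fixed-step linearly implicit Euler at dt = 1 ms. The interface
# stiffness (up to 10,000 N/m) acting on the light device/auxiliary
# assembly makes the system stiff; the spring-damper contribution to the
# force Jacobian is treated implicitly (assembled from the element
# Jacobians as J' K J and J' C J), which keeps the step stable without
# iteration.

# ---------------------------------------------------------------------------
# Precomputed model constants

#' @noRd
prep_model <- function(model) {
  sg <- model$segments
  els <- lapply(model$elements, function(e) {
    rs <- as.numeric(e$r_seg)
    list(site = e$site, name = e$name,
         r_seg = rs[1:2], r_seg_z = rs[3],
         r_shell = rs[1:2] - model$misalignment[1:2],
         k2 = e$params$k_trans[1:2], kz = e$params$k_trans[3],
         c2 = e$params$c_trans[1:2], cz = e$params$c_trans[3],
         kr = e$params$k_rot[3], cr = e$params$c_rot[3])
  })
  mus <- model$muscles
  list(
    mf = sg$foot$mass, If = sg$foot$inertia, r_f = sg$foot$com[1:2],
    md = sg$aux_body$mass,
    mfs = sg$foot_shell$mass, Ifs = sg$foot_shell$inertia,
    r_fs = sg$foot_shell$com[1:2] - model$misalignment[1:2],
    mcs = sg$calf_shell$mass, Ics = sg$calf_shell$inertia,
    r_cs = sg$calf_shell$com[1:2] - model$misalignment[1:2],
    mis = model$misalignment[1:2],
    els = els,
    mz = sg$aux_body$mass + sg$foot_shell$mass + sg$calf_shell$mass,
    kz_tot = sum(vapply(els, `[[`, 0, "kz")),
    cz_tot = sum(vapply(els, `[[`, 0, "cz")),
    cap_pf = mus$plantarflexors$w * mus$plantarflexors$f_max_iso *
      mus$plantarflexors$moment_arm,
    cap_df = mus$dorsiflexors$w * mus$dorsiflexors$f_max_iso *
      mus$dorsiflexors$moment_arm,
    tau_act = c(mus$plantarflexors$tau_act, mus$dorsiflexors$tau_act),
    tau_deact = c(mus$plantarflexors$tau_deact, mus$dorsiflexors$tau_deact),
    markers = marker_pairs(model),
    g = model$gravity)
}

# ---------------------------------------------------------------------------
# Dynamics terms at one instant
#
# bs: base scalars at time t: pa (2), va, aa, phis, phisd, phisdd
# ext: support (Nm, on foot shell, reaction on calf shell), grf (2, N),
#      cop (2, foot frame, m), tau_m (ankle muscle+reserve torque, Nm),
#      gravity (logical)

#' @noRd
dyn_terms <- function(pm, q, qdot, bs, ext, need_mats = TRUE) {
  th <- q[1L]; axy <- q[2:3]; az <- q[4L]; psf <- q[5L]; psc <- q[6L]
  thd <- qdot[1L]; adxy <- qdot[2:3]; azd <- qdot[4L]
  psfd <- qdot[5L]; pscd <- qdot[6L]

  Rs <- rot2(bs$phis); Rf <- rot2(bs$phis + th)
  Rfs <- rot2(bs$phis + psf); Rcs <- rot2(bs$phis + psc)
  g <- if (isTRUE(ext$gravity)) pm$g else 0

  # auxiliary body kinematics
  ma <- pm$mis + axy
  Rma <- as.vector(Rs %*% ma)
  pd <- bs$pa + Rma
  Rad <- as.vector(Rs %*% adxy)
  vd <- bs$va + bs$phisd * perp2(Rma) + Rad
  bd <- bs$aa + bs$phisdd * perp2(Rma) - bs$phisd^2 * Rma +
    2 * bs$phisd * perp2(Rad)

  Q <- numeric(6L)
  elem_out <- vector("list", length(pm$els))
  Kg <- if (need_mats) matrix(0, 6L, 6L) else NULL
  Cg <- if (need_mats) matrix(0, 6L, 6L) else NULL
  res_force <- c(0, 0, 0)   # net interface load on the human segments

  for (i in seq_along(pm$els)) {
    e <- pm$els[[i]]
    foot_side <- e$site == "foot"
    if (foot_side) {
      Rseg <- Rf; wseg <- bs$phisd + thd
      pseg <- bs$pa + as.vector(Rf %*% e$r_seg)
      vseg <- bs$va + wseg * perp2(as.vector(Rf %*% e$r_seg))
      Rsh <- Rfs; wsh <- bs$phisd + psfd
      dth <- psf - th; dthd <- psfd - thd
      icoord <- 5L
    } else {
      Rseg <- Rs; wseg <- bs$phisd
      pseg <- bs$pa + as.vector(Rs %*% e$r_seg)
      vseg <- bs$va + wseg * perp2(as.vector(Rs %*% e$r_seg))
      Rsh <- Rcs; wsh <- bs$phisd + pscd
      dth <- psc; dthd <- pscd
      icoord <- 6L
    }
    ush <- as.vector(Rsh %*% e$r_shell)
    psh <- pd + ush
    vsh <- vd + wsh * perp2(ush)
    d <- psh - pseg
    drel <- crossprod(Rseg, d)[, 1L]                       # seg frame
    dvel <- crossprod(Rseg, (vsh - vseg) - wseg * perp2(d))[, 1L]
    f2 <- -(e$k2 * drel + e$c2 * dvel)                     # on shell, seg frame
    fz <- -(e$kz * az + e$cz * azd)
    tz <- -(e$kr * dth + e$cr * dthd)
    Fw <- as.vector(Rseg %*% f2)                           # world

    # shell side
    Q[2:3] <- Q[2:3] + crossprod(Rs, Fw)[, 1L]
    Q[4L] <- Q[4L] + fz
    jsh <- perp2(ush)
    Q[icoord] <- Q[icoord] + sum(jsh * Fw) + tz
    # segment side (reaction)
    if (foot_side) {
      jseg <- perp2(as.vector(Rf %*% e$r_seg))
      Q[1L] <- Q[1L] - sum(jseg * Fw) - tz
    }
    res_force <- res_force - c(Fw, fz)

    if (need_mats) {
      # element Jacobian rows: d(drel)/dqdot (x, y), d(dz)/dqdot, d(dth)/dqdot
      J <- matrix(0, 4L, 6L)
      RtRs <- crossprod(Rseg, Rs)
      J[1:2, 2:3] <- RtRs
      J[1:2, icoord] <- crossprod(Rseg, jsh)[, 1L]
      if (foot_side) J[1:2, 1L] <- -crossprod(Rseg, jseg)[, 1L]
      J[3L, 4L] <- 1
      J[4L, icoord] <- 1
      if (foot_side) J[4L, 1L] <- -1
      kvec <- c(e$k2, e$kz, e$kr)
      cvec <- c(e$c2, e$cz, e$cr)
      Kg <- Kg + crossprod(J, kvec * J)
      Cg <- Cg + crossprod(J, cvec * J)
    }
    # layout: force (seg frame) x,y,z, moment z, deflections x,y,z,rz,
    # deflection rates x,y,z,rz
    elem_out[[i]] <- c(f2, fz, tz, drel, az, dth, dvel, azd, dthd)
  }

  # gravity
  uf <- as.vector(Rf %*% pm$r_f)
  if (g != 0) {
    Q[1L] <- Q[1L] - pm$mf * g * uf[1L]        # perp(uf) . (0,-mg) = -mg*ux
    Q[2:3] <- Q[2:3] + crossprod(Rs, c(0, -g * pm$mz))[, 1L]
    ufs <- as.vector(Rfs %*% pm$r_fs)
    ucs <- as.vector(Rcs %*% pm$r_cs)
    Q[5L] <- Q[5L] - pm$mfs * g * ufs[1L]
    Q[6L] <- Q[6L] - pm$mcs * g * ucs[1L]
  } else {
    ufs <- as.vector(Rfs %*% pm$r_fs)
    ucs <- as.vector(Rcs %*% pm$r_cs)
  }

  # support torque between the two shells about the device axis
  if (ext$support != 0) {
    Q[5L] <- Q[5L] + ext$support
    Q[6L] <- Q[6L] - ext$support
  }

  # ground reaction at the center of pressure on the foot
  if (any(ext$grf != 0)) {
    ucop <- as.vector(Rf %*% ext$cop)
    Q[1L] <- Q[1L] + ucop[1L] * ext$grf[2L] - ucop[2L] * ext$grf[1L]
  }

  # ankle muscle + reserve torque
  Q[1L] <- Q[1L] + ext$tau_m

  # inertial bias from the prescribed base motion and velocity products
  wf <- bs$phisd + thd
  bf <- bs$aa + bs$phisdd * perp2(uf) - wf^2 * uf
  Q[1L] <- Q[1L] - pm$mf * sum(perp2(uf) * bf) - pm$If * bs$phisdd
  wfs <- bs$phisd + psfd
  bfs <- bd + bs$phisdd * perp2(ufs) - wfs^2 * ufs
  wcs <- bs$phisd + pscd
  bcs <- bd + bs$phisdd * perp2(ucs) - wcs^2 * ucs
  Q[2:3] <- Q[2:3] -
    crossprod(Rs, pm$md * bd + pm$mfs * bfs + pm$mcs * bcs)[, 1L]
  Q[5L] <- Q[5L] - pm$mfs * sum(perp2(ufs) * bfs) - pm$Ifs * bs$phisdd
  Q[6L] <- Q[6L] - pm$mcs * sum(perp2(ucs) * bcs) - pm$Ics * bs$phisdd

  M <- NULL
  if (need_mats) {
    M <- matrix(0, 6L, 6L)
    M[1L, 1L] <- pm$If + pm$mf * sum(pm$r_f^2)
    mtot <- pm$md + pm$mfs + pm$mcs
    M[2L, 2L] <- mtot; M[3L, 3L] <- mtot
    M[4L, 4L] <- pm$mz
    c5 <- pm$mfs * crossprod(Rs, perp2(ufs))[, 1L]
    M[2:3, 5L] <- c5; M[5L, 2:3] <- c5
    M[5L, 5L] <- pm$Ifs + pm$mfs * sum(pm$r_fs^2)
    c6 <- pm$mcs * crossprod(Rs, perp2(ucs))[, 1L]
    M[2:3, 6L] <- c6; M[6L, 2:3] <- c6
    M[6L, 6L] <- pm$Ics + pm$mcs * sum(pm$r_cs^2)
  }

  list(Q = Q, M = M, Kg = Kg, Cg = Cg, elems = elem_out,
       res_force = res_force, pd = pd)
}

# marker displacement (shell marker minus segment marker, segment frame, m)
#' @noRd
marker_disp <- function(pm, q, bs) {
  th <- q[1L]
  Rs <- rot2(bs$phis); Rf <- rot2(bs$phis + th)
  Rfs <- rot2(bs$phis + q[5L]); Rcs <- rot2(bs$phis + q[6L])
  pd <- bs$pa + as.vector(Rs %*% (pm$mis + q[2:3]))
  out <- matrix(0, 2L, 3L, dimnames = list(c("foot", "shank"), c("x", "y", "z")))
  mk <- pm$markers
  rf <- mk$foot$r_seg[1:2]
  psh <- pd + as.vector(Rfs %*% (rf - pm$mis))
  psg <- bs$pa + as.vector(Rf %*% rf)
  out["foot", 1:2] <- crossprod(Rf, psh - psg)[, 1L]
  out["foot", 3L] <- q[4L]
  rs <- mk$shank$r_seg[1:2]
  psh <- pd + as.vector(Rcs %*% (rs - pm$mis))
  psg <- bs$pa + as.vector(Rs %*% rs)
  out["shank", 1:2] <- crossprod(Rs, psh - psg)[, 1L]
  out["shank", 3L] <- q[4L]
  out
}

# ---------------------------------------------------------------------------
# Public state and EOM surface

#' Simulation state
#'
#' @param q free generalized coordinates (ankle rz rad, aux tx/ty/tz m,
#'   foot-shell rz rad, calf-shell rz rad).
#' @param qdot generalized rates.
#' @param act muscle activations `c(plantarflexors, dorsiflexors)`, each in
#'   `[0, 1]`.
#' @param t time, s.
#' @return An object of class `afo_state`.
#' @export
afo_state <- function(q = numeric(6), qdot = numeric(6),
                      act = c(0, 0), t = 0) {
  stopifnot(length(q) == 6L, length(qdot) == 6L, length(act) == 2L)
  if (any(act < 0 | act > 1)) stopf("activations must lie in [0, 1]")
  if (!all(is.finite(c(q, qdot, act, t)))) stopf("non-finite state")
  structure(list(q = as.numeric(q), qdot = as.numeric(qdot),
                 act = as.numeric(act), t = as.numeric(t)),
            class = "afo_state")
}

#' Static base kinematics
#'
#' Base descriptor for a model held in a fixed pose (hip point fixed, hip
#' and knee angles constant): the ankle center rests at a constant world
#' position and the shank orientation is constant, with zero rates. Useful
#' for isolated dynamic tests and for the bootstrap phase.
#'
#' @param model an `afo_model`.
#' @param hip,knee hip and knee flexion angles, rad.
#' @return A list of base scalars (`pa`, `va`, `aa`, `phis`, `phisd`,
#'   `phisdd`).
#' @export
static_base <- function(model, hip = 0, knee = 0) {
  yhip <- model$ankle_height + model$shank_length + model$thigh_length
  ph <- c(0, yhip)
  pk <- ph + model$thigh_length * c(sin(hip), -cos(hip))
  pa <- pk + model$shank_length * c(sin(hip - knee), -cos(hip - knee))
  list(pa = pa, va = c(0, 0), aa = c(0, 0),
       phis = hip - knee, phisd = 0, phisdd = 0)
}

#' @noRd
default_externals <- function() {
  list(support = 0, grf = c(0, 0), cop = c(0, 0), tau_m = 0, gravity = TRUE)
}

#' Equations of motion of the free coordinates
#'
#' Computes the accelerations of the six free coordinates from the mass
#' matrix and the generalized forces: gravity, interface-element wrenches,
#' support torque between the shells, ground reaction at the center of
#' pressure, ankle muscle/reserve torque, and the inertial bias from the
#' prescribed base motion.
#'
#' @param model an `afo_model`.
#' @param state an [afo_state()].
#' @param externals list with any of `support` (Nm), `grf` (length-2 N),
#'   `cop` (length-2 m, foot frame), `tau_m` (Nm), `gravity` (logical),
#'   `base` (base scalars as from [static_base()]; default static neutral).
#' @return Numeric length-6 acceleration vector.
#' @export
equations_of_motion <- function(model, state, externals = list()) {
  stopifnot(inherits(model, "afo_model"), inherits(state, "afo_state"))
  ext <- utils::modifyList(default_externals(),
                           externals[setdiff(names(externals), "base")])
  bs <- if (!is.null(externals$base)) externals$base else static_base(model)
  pm <- prep_model(model)
  dt_ <- dyn_terms(pm, state$q, state$qdot, bs, ext, need_mats = TRUE)
  rc <- rcond(dt_$M)
  if (!is.finite(rc) || rc < 1e-14)
    stopf("singular mass matrix (reciprocal condition %.3g)", rc)
  as.vector(solve(dt_$M, dt_$Q))
}

# one linearly implicit step: solves
#   (M + dt*Cg + dt^2*Kg) v_new = M v + dt*Q + dt*Cg v
# with Q evaluated at the current state (A_chol caches the factorization;
# its "Cg" and "LT" attributes carry the damping matrix and the transposed
# factor).
#' @noRd
implicit_step <- function(Q, qdot, dt, M, A_chol) {
  rhs <- M %*% qdot + dt * Q + dt * attr(A_chol, "Cg") %*% qdot
  as.vector(backsolve(A_chol, forwardsolve(attr(A_chol, "LT"), rhs)))
}

#' @noRd
factor_implicit <- function(M, Kg, Cg, dt) {
  A_chol <- chol(M + dt * Cg + dt * dt * Kg)
  attr(A_chol, "Cg") <- Cg
  attr(A_chol, "LT") <- t(A_chol)
  A_chol
}

# ---------------------------------------------------------------------------
# Effort allocation (activation-squared optimum with penalized reserves)

#' Allocate an ankle torque between muscle groups and the reserve actuator
#'
#' Minimizes `a_pf^2 + a_df^2 + lambda * (reserve / scale)^2` subject to
#' producing the required ankle torque, with activations bounded to
#' `[0, 1]`. Only the muscle group whose moment sign matches the demand is
#' activated (activating the antagonist would raise both terms). The
#' reserve picks up the (tiny) interior-optimal share and the full deficit
#' whenever the muscles saturate or are paralyzed, in which case the step
#' is flagged.
#'
#' @param tau_req required ankle torque, Nm (plantarflexion negative).
#' @param cap_pf,cap_df maximum torque of each group
#'   (`w * f_max_iso * moment_arm`), Nm.
#' @param scale reserve optimal torque, Nm.
#' @param lambda reserve penalty weight.
#' @return list with `a_pf`, `a_df`, `reserve` (Nm) and `saturated`.
#' @export
allocate_ankle_effort <- function(tau_req, cap_pf, cap_df,
                                  scale = 2, lambda = 1) {
  a_pf <- 0; a_df <- 0; reserve <- 0; saturated <- FALSE
  if (tau_req < 0 && cap_pf > 0) {          # plantarflexion demand
    a <- -tau_req / (cap_pf * (1 + scale^2 / (lambda * cap_pf^2)))
    if (a > 1) { a <- 1; saturated <- TRUE }
    a_pf <- a
    reserve <- tau_req + a * cap_pf
  } else if (tau_req > 0 && cap_df > 0) {   # dorsiflexion demand
    a <- tau_req / (cap_df * (1 + scale^2 / (lambda * cap_df^2)))
    if (a > 1) { a <- 1; saturated <- TRUE }
    a_df <- a
    reserve <- tau_req - a * cap_df
  } else {
    reserve <- tau_req
    if (tau_req != 0) saturated <- TRUE     # no muscle available
  }
  list(a_pf = a_pf, a_df = a_df, reserve = reserve, saturated = saturated)
}

# advance activations one step toward the effort-optimal torque split:
# the commanded excitation inverts the first-order activation filter
# (within its [0, 1] bounds) so the realized activation reaches the
# optimizer's target within the step; the reserve covers the remaining
# deficit (activation slew limits, saturation, paralyzed groups) exactly,
# so the desired acceleration is always realized and reserve usage is a
# faithful record of what the muscles could not do.
#' @noRd
activation_step <- function(pm, ctrl, act, tau_req, h) {
  al <- allocate_ankle_effort(tau_req, pm$cap_pf, pm$cap_df,
                              scale = ctrl$reserve_scale,
                              lambda = ctrl$reserve_penalty)
  a_t <- c(al$a_pf, al$a_df)
  a_cmd <- numeric(2L); act_new <- numeric(2L)
  for (m in 1:2) {
    e_up <- exp(-h / pm$tau_act[m]); e_dn <- exp(-h / pm$tau_deact[m])
    cmd <- (a_t[m] - act[m] * e_up) / (1 - e_up)
    if (cmd < act[m]) cmd <- (a_t[m] - act[m] * e_dn) / (1 - e_dn)
    cmd_c <- min(max(cmd, 0), 1)
    e <- if (cmd_c >= act[m]) e_up else e_dn
    act_new[m] <- cmd_c + (act[m] - cmd_c) * e
    a_cmd[m] <- cmd_c
  }
  tau_muscle <- -act_new[1L] * pm$cap_pf + act_new[2L] * pm$cap_df
  list(act = act_new, a_cmd = a_cmd, tau_muscle = tau_muscle,
       reserve = tau_req - tau_muscle,
       saturated = al$saturated)
}

#' Weighted task-space solve
#'
#' General weighted tracking solve used when several tracking tasks compete
#' for the same actuators: minimizes
#' `sum_j w_j (A[j, ] u + b_j - des_j)^2 + u' R u` over box-bounded `u`.
#' Raising the weight of a task can only reduce (or keep equal) that
#' task's achieved acceleration error.
#'
#' @param A task-by-actuator matrix mapping controls to task accelerations.
#' @param b task acceleration offsets (passive dynamics).
#' @param des desired task accelerations.
#' @param weights positive task weights.
#' @param R positive-definite effort penalty matrix.
#' @param lower,upper control bounds.
#' @return list with `u` and per-task `error`.
#' @export
weighted_task_solve <- function(A, b, des, weights, R,
                                lower = rep(-Inf, ncol(A)),
                                upper = rep(Inf, ncol(A))) {
  A <- as.matrix(A)
  W <- diag(weights, length(weights))
  H <- crossprod(A, W %*% A) + R
  f <- crossprod(A, W %*% (b - des))
  u <- as.vector(solve(H, -f))
  # active-set clipping for the box bounds
  for (iter in 1:10) {
    lo <- u < lower; hi <- u > upper
    if (!any(lo | hi)) break
    u[lo] <- lower[lo]; u[hi] <- upper[hi]
    free <- !(lo | hi)
    if (!any(free)) break
    rhs <- -f[free] - H[free, !free, drop = FALSE] %*% u[!free]
    u[free] <- as.vector(solve(H[free, free, drop = FALSE], rhs))
  }
  u <- pmin(pmax(u, lower), upper)
  list(u = u, error = as.vector(A %*% u + b - des))
}

# ---------------------------------------------------------------------------
# Tracking tasks

#' Tracking task
#'
#' @param coordinate coordinate name (e.g. `"ankle"`, `"knee"`).
#' @param ref function of time returning `list(q, qdot, qddot)` for the
#'   reference trajectory.
#' @param weight positive task weight (knee and ankle default to 10 in the
#'   gait protocol, all other coordinates to 1).
#' @param k_p,k_v PD feedback gains, 1/s^2 and 1/s.
#' @return An object of class `afo_task`.
#' @export
tracking_task <- function(coordinate, ref, weight = 1, k_p = 100, k_v = 20) {
  if (!is.function(ref)) stopf("ref must be a function of time")
  if (!is.finite(weight) || weight <= 0) stopf("task weight must be > 0")
  structure(list(coordinate = coordinate, ref = ref, weight = weight,
                 k_p = k_p, k_v = k_v), class = "afo_task")
}

#' One controller step
#'
#' Advances the state over one window: at every integration step the PD
#' desired acceleration of the tasked ankle coordinate is turned into the
#' required ankle torque through the equations of motion, allocated to
#' muscle activations and the reserve actuator
#' ([allocate_ankle_effort()]), the activation dynamics are advanced, and
#' the mechanical state is integrated with the linearly implicit stepper
#' (un-tasked shell and auxiliary coordinates evolve freely). The mass and
#' stabilization matrices are refreshed on a coarser grid (every 10
#' integration steps); the generalized forces every step. Saturation is
#' flagged, never silently dropped.
#'
#' @param model an `afo_model`.
#' @param state an [afo_state()].
#' @param tasks list of [tracking_task()]s; the task named `"ankle"` drives
#'   the dynamic ankle coordinate.
#' @param dt window length, s (a multiple of the integration step).
#' @param externals as in [equations_of_motion()]; `base` may be a function
#'   of time returning base scalars.
#' @return list with `controls` (activation commands, reserve, required
#'   torque, saturation flag at the end of the window) and `state` (the
#'   advanced [afo_state()]).
#' @export
cmc_step <- function(model, state, tasks, dt, externals = list()) {
  pm <- prep_model(model)
  ctrl <- model$config$controller
  ext <- utils::modifyList(default_externals(),
                           externals[setdiff(names(externals), "base")])
  base_fn <- externals$base
  if (is.null(base_fn)) base_fn <- function(t) static_base(model)
  if (!is.function(base_fn)) { bval <- base_fn; base_fn <- function(t) bval }
  cmc_step_core(pm, ctrl, state, tasks, dt, base_fn, function(t) ext)
}

# internal path shared by cmc_step and initial_cmc; ext_fn(t) returns the
# externals (support, grf, cop) at time t
#' @noRd
cmc_step_core <- function(pm, ctrl, state, tasks, dt, base_fn, ext_fn,
                          mats_every = 10L) {
  t0 <- state$t
  ankle_task <- NULL
  for (tk in tasks) if (tk$coordinate == "ankle") ankle_task <- tk
  h <- ctrl$dt
  n_sub <- max(1L, round(dt / h))
  q <- state$q; qdot <- state$qdot; act <- state$act
  M <- NULL; A_chol <- NULL
  controls <- list(a_cmd = c(0, 0), reserve = 0, tau_req = 0,
                   tau_muscle = 0, saturated = FALSE, qdd_des = 0)
  dtm_full <- NULL
  for (k in seq_len(n_sub)) {
    tk_ <- t0 + (k - 1L) * h
    bs <- base_fn(tk_)
    ext <- ext_fn(tk_)
    ext$tau_m <- 0
    if ((k - 1L) %% mats_every == 0L) {
      dtm_full <- dyn_terms(pm, q, qdot, bs, ext, need_mats = TRUE)
      M <- dtm_full$M
      A_chol <- factor_implicit(M, dtm_full$Kg, dtm_full$Cg, h)
      Q <- dtm_full$Q
    } else {
      Q <- dyn_terms(pm, q, qdot, bs, ext, need_mats = FALSE)$Q
    }
    tau_req <- 0; qdd_des <- 0
    if (!is.null(ankle_task)) {
      r <- ankle_task$ref(tk_)
      qdd_des <- r$qddot + ankle_task$k_v * (r$qdot - qdot[1L]) +
        ankle_task$k_p * (r$q - q[1L])
      # the ankle row decouples from the device coordinates in M
      tau_req <- M[1L, 1L] * qdd_des - Q[1L]
    }
    ast <- activation_step(pm, ctrl, act, tau_req, h)
    act <- ast$act
    Q[1L] <- Q[1L] + ast$tau_muscle + ast$reserve
    qdot <- implicit_step(Q, qdot, h, M, A_chol)
    q <- q + h * qdot
    controls <- list(a_cmd = ast$a_cmd, reserve = ast$reserve,
                     tau_req = tau_req, tau_muscle = ast$tau_muscle,
                     saturated = ast$saturated, qdd_des = qdd_des)
  }
  list(controls = controls,
       state = afo_state(q, qdot, pmin(pmax(act, 0), 1), t0 + n_sub * h),
       dyn = dtm_full)
}

# ---------------------------------------------------------------------------
# Bootstrap ("initial CMC")

#' Bootstrap the device state before a gait simulation
#'
#' The pose of the gait start differs from the model's standard pose, so
#' the device coordinates have no obvious initial condition. The bootstrap
#' ramps the tasked joint angles linearly from the standard (anatomical
#' neutral) pose to the gait initial pose within `n_steps` controller
#' steps, with external gait forces excluded and the pelvis held by virtual
#' supports, then lets the interface settle at the final pose. It always
#' runs on the unweakened model, so every weakening level and misalignment
#' starts the gait from the same body pose.
#'
#' @param model an `afo_model`.
#' @param default_pose,gait_initial_pose named lists with `hip`, `knee`,
#'   `ankle` angles (rad).
#' @param n_steps number of linear interpolation steps (default 10).
#' @return An [afo_state()] at `t = 0`, carrying attributes
#'   `"settled"` (logical) and `"ramp"` (the tasked-coordinate ramp, one row
#'   per step, for inspection).
#' @export
initial_cmc <- function(model, default_pose = list(hip = 0, knee = 0, ankle = 0),
                        gait_initial_pose = list(hip = 0, knee = 0, ankle = 0),
                        n_steps = 10) {
  stopifnot(inherits(model, "afo_model"))
  ctrl <- model$config$controller
  # bootstrap uses the basic (unweakened) model
  mb <- model
  mb$muscles$plantarflexors$w <- 1
  mb$muscles$dorsiflexors$w <- 1
  pm <- prep_model(mb)
  dtc <- ctrl$record_dt

  lam <- function(k) min(1, max(0, k / n_steps))
  pose_at <- function(t) {
    s <- lam(t / dtc)
    list(hip = default_pose$hip + s * (gait_initial_pose$hip - default_pose$hip),
         knee = default_pose$knee + s * (gait_initial_pose$knee - default_pose$knee),
         ankle = default_pose$ankle + s * (gait_initial_pose$ankle - default_pose$ankle))
  }
  base_fn <- function(t) {
    p <- pose_at(t)
    static_base(mb, hip = p$hip, knee = p$knee)
  }
  ankle_ref <- function(t) {
    p0 <- pose_at(t); p1 <- pose_at(t + dtc)
    list(q = p0$ankle, qdot = (p1$ankle - p0$ankle) / dtc, qddot = 0)
  }
  tasks <- list(tracking_task("ankle", ankle_ref,
                              weight = ctrl$task_weights$ankle,
                              k_p = ctrl$k_p, k_v = ctrl$k_v))
  ext_fn <- function(t) default_externals()   # no gait forces

  st <- afo_state(q = numeric(6), qdot = numeric(6), act = c(0, 0), t = 0)
  ramp <- matrix(NA_real_, n_steps, 3L,
                 dimnames = list(NULL, c("hip", "knee", "ankle")))
  n_settle <- ceiling(ctrl$settle_time / dtc)
  settled <- FALSE
  for (k in seq_len(n_steps + n_settle)) {
    out <- cmc_step_core(pm, ctrl, st, tasks, dtc, base_fn, ext_fn)
    st <- out$state
    if (k <= n_steps) {
      p <- pose_at(st$t)
      ramp[k, ] <- c(p$hip, p$knee, p$ankle)
    } else if (max(abs(st$qdot[2:6])) < ctrl$settle_tol) {
      settled <- TRUE
      break
    }
  }
  if (!settled && max(abs(st$qdot[2:6])) < ctrl$settle_tol) settled <- TRUE
  if (!settled)
    warning("initial CMC: interface not settled below tolerance ",
            "at the end of the bootstrap", call. = FALSE)
  st$t <- 0
  out <- afo_state(st$q, st$qdot, st$act, 0)
  attr(out, "settled") <- settled
  attr(out, "ramp") <- ramp
  out
}
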