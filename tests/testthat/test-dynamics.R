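# Equations of motion, controller, bootstrap, and the numerical oracles.

test_that("equations of motion satisfy the closed-form base cases", {
  m <- build_model()
  # all forces zero, zero velocity: zero acceleration
  qdd <- equations_of_motion(m, afo_state(), list(gravity = FALSE))
  expect_equal(max(abs(qdd)), 0)
  # device assembly as a point mass along z: acceleration = F / m
  pm <- afosim:::prep_model(m)
  az <- 0.013
  qdd2 <- equations_of_motion(m, afo_state(q = c(0, 0, 0, az, 0, 0)),
                              list(gravity = FALSE))
  expect_equal(qdd2[4], -pm$kz_tot * az / pm$mz)
  expect_equal(max(abs(qdd2[-4])), 0)
  # singular mass matrix rejected with a condition diagnostic
  m_bad <- m
  m_bad$segments$foot$inertia <- 0
  m_bad$segments$foot$com <- c(0, 0, 0)
  expect_error(equations_of_motion(m_bad, afo_state()), "condition")
})

test_that("effort allocation matches the single-actuator closed form", {
  # a = |M| / (w f r) when feasible (up to the tiny optimal reserve share)
  al <- allocate_ankle_effort(-30, cap_pf = 100, cap_df = 40)
  expect_equal(al$a_pf, 30 / 100, tolerance = 1e-3)
  expect_equal(al$a_df, 0)
  expect_false(al$saturated)
  expect_lt(abs(al$reserve), 0.05)
  # torque + muscle torque + reserve is consistent
  expect_equal(-al$a_pf * 100 + al$reserve, -30)
  # beyond capacity: a = 1 and the deficit is flagged reserve
  al2 <- allocate_ankle_effort(-150, cap_pf = 100, cap_df = 40)
  expect_equal(al2$a_pf, 1)
  expect_true(al2$saturated)
  expect_equal(al2$reserve, -50)
  # paralyzed agonist: reserve absorbs everything, flagged
  al3 <- allocate_ankle_effort(25, cap_pf = 100, cap_df = 0)
  expect_equal(al3$a_df, 0)
  expect_equal(al3$reserve, 25)
  expect_true(al3$saturated)
  # antagonist never recruited
  expect_equal(allocate_ankle_effort(40, cap_pf = 100, cap_df = 50)$a_pf, 0)
})

test_that("raising a task weight reduces that task's acceleration error", {
  # two tasks compete for one actuator
  A <- matrix(c(1, 0.5), 2, 1)
  b <- c(0, 0)
  des <- c(2, -1)
  R <- diag(0.1, 1)
  err1 <- abs(weighted_task_solve(A, b, des, weights = c(1, 1), R)$error)
  err2 <- abs(weighted_task_solve(A, b, des, weights = c(2, 1), R)$error)
  expect_lte(err2[1], err1[1])
  expect_lt(err2[1], err1[1] + 1e-12)
  # bounds respected
  sol <- weighted_task_solve(A, b, des, weights = c(1, 1), R,
                             lower = 0, upper = 0.5)
  expect_lte(sol$u, 0.5)
  expect_gte(sol$u, 0)
})

test_that("controller is quiescent at a perfect static match", {
  m <- build_model()
  tasks <- list(tracking_task("ankle",
                              function(t) list(q = 0, qdot = 0, qddot = 0)))
  out <- cmc_step(m, afo_state(), tasks, 0.01,
                  externals = list(gravity = FALSE))
  # no demand: activations at the lower bound, no reserve
  expect_equal(out$controls$a_cmd, c(0, 0))
  expect_equal(out$controls$reserve, 0, tolerance = 1e-9)
  expect_equal(max(abs(out$state$q)), 0, tolerance = 1e-12)
})

test_that("bootstrap ramps linearly over 10 steps and settles", {
  m <- build_model()
  expect_equal(formals(initial_cmc)$n_steps, 10)
  pose1 <- list(hip = 0.3, knee = 0.15, ankle = -0.05)
  st <- initial_cmc(m, gait_initial_pose = pose1)
  expect_true(attr(st, "settled"))
  expect_equal(st$t, 0)
  ramp <- attr(st, "ramp")
  expect_equal(nrow(ramp), 10L)
  # independent linear interpolation oracle
  for (coord in c("hip", "knee", "ankle")) {
    expected <- (seq_len(10) / 10) * pose1[[coord]]
    expect_equal(unname(ramp[, coord]), expected, tolerance = 1e-12)
  }
  # equal poses: tasked coordinate stays put, shells settle to equilibrium
  st0 <- initial_cmc(m)
  expect_true(attr(st0, "settled"))
  expect_lt(abs(st0$q[1]), 0.01)
  expect_lt(max(abs(st0$qdot)), 2e-3)
  # gravity sag of the device is small but nonzero
  expect_gt(max(abs(st0$q[2:6])), 0)
})

test_that("quasi-static deflection matches an independent static solve", {
  m <- build_model()
  cfg <- m$config
  # independent oracle: Newton iteration on the static force balance with
  # finite-difference Jacobian (no integrator involved)
  static_solve <- function(model, support) {
    pmx <- afosim:::prep_model(model)
    bs <- static_base(model)
    ext <- list(support = support, grf = c(0, 0), cop = c(0, 0),
                tau_m = 0, gravity = TRUE)
    f <- function(qq) afosim:::dyn_terms(pmx, qq, numeric(6), bs, ext,
                                         need_mats = FALSE)$Q[-1]
    q <- numeric(6)
    for (it in 1:50) {
      Fv <- f(q)
      if (max(abs(Fv)) < 1e-10) break
      J <- matrix(0, 5, 5)
      for (j in 1:5) {
        dq <- numeric(6); dq[j + 1] <- 1e-7
        J[, j] <- (f(q + dq) - Fv) / 1e-7
      }
      q[2:6] <- q[2:6] - solve(J, Fv)
    }
    q
  }
  q_static <- static_solve(m, 12)
  # slow ramp through the dynamic engine, ankle tasked to zero
  tasks <- list(tracking_task("ankle",
                              function(t) list(q = 0, qdot = 0, qddot = 0),
                              k_p = cfg$controller$k_p,
                              k_v = cfg$controller$k_v))
  st <- afo_state()
  for (i in 1:250) {
    s <- min(1, i / 150) * 12
    st <- cmc_step(m, st, tasks, 0.01, externals = list(support = s))$state
  }
  # per-axis agreement within 5% (absolute floor for near-zero axes)
  for (j in 2:6) {
    tol <- max(0.05 * abs(q_static[j]), 1e-6)
    expect_lt(abs(st$q[j] - q_static[j]), tol)
  }
})

test_that("work-energy balance closes to integrator tolerance", {
  m <- build_model()
  pm <- afosim:::prep_model(m)
  bs <- static_base(m)
  ctrl <- m$config$controller
  audit <- function(h, n, support = 8) {
    ext <- list(support = support, grf = c(0, 0), cop = c(0, 0),
                tau_m = 0, gravity = FALSE)
    q <- numeric(6); qd <- numeric(6)
    Wsup <- 0; Wmus <- 0; D <- 0
    for (i in seq_len(n)) {
      if ((i - 1) %% 10 == 0) {
        dtm <- afosim:::dyn_terms(pm, q, qd, bs, ext, need_mats = TRUE)
        A <- afosim:::factor_implicit(dtm$M, dtm$Kg, dtm$Cg, h)
      }
      out <- afosim:::dyn_terms(pm, q, qd, bs, ext, need_mats = FALSE)
      Q <- out$Q
      tau <- dtm$M[1, 1] * (-ctrl$k_p * q[1] - ctrl$k_v * qd[1]) - Q[1]
      Q[1] <- Q[1] + tau
      qd_new <- afosim:::implicit_step(Q, qd, h, dtm$M, A)
      mid <- 0.5 * (qd + qd_new)
      Wsup <- Wsup + support * (mid[5] - mid[6]) * h
      Wmus <- Wmus + tau * mid[1] * h
      qd <- qd_new; q <- q + h * qd
      el <- afosim:::dyn_terms(pm, q, qd, bs, ext, need_mats = FALSE)$elems
      for (j in seq_along(pm$els)) {
        e <- pm$els[[j]]; rates <- el[[j]][9:12]
        D <- D + (sum(e$c2 * rates[1:2]^2) + e$cz * rates[3]^2 +
                    e$cr * rates[4]^2) * h
      }
    }
    dtmE <- afosim:::dyn_terms(pm, q, qd, bs, ext, need_mats = TRUE)
    KE <- 0.5 * sum(qd * (dtmE$M %*% qd))
    PE <- 0
    for (j in seq_along(pm$els)) {
      e <- pm$els[[j]]; v <- dtmE$elems[[j]]
      PE <- PE + 0.5 * sum(e$k2 * v[5:6]^2) + 0.5 * e$kz * v[7]^2 +
        0.5 * e$kr * v[8]^2
    }
    list(input = Wsup + Wmus, stored = KE + PE, dissipated = D,
         imbalance = (Wsup + Wmus) - (KE + PE + D))
  }
  # first-order integrator: balance within 3% of the injected work at the
  # default step, and the defect shrinks when the step is halved
  a1 <- audit(1e-3, 600)
  expect_lt(abs(a1$imbalance) / abs(a1$input), 0.03)
  expect_gte(a1$dissipated, 0)
  a2 <- audit(5e-4, 1200)
  expect_lt(abs(a2$imbalance), abs(a1$imbalance))
})

test_that("support torque step deflects the shank pair consistently", {
  # quasi-static force balance: the sign of the shank-pair x displacement
  # follows the sign of the support torque (shell pressing the shank)
  m <- build_model()
  tasks <- list(tracking_task("ankle",
                              function(t) list(q = 0, qdot = 0, qddot = 0)))
  settle <- function(support) {
    st <- afo_state()
    for (i in 1:120)
      st <- cmc_step(m, st, tasks, 0.01,
                     externals = list(support = support, gravity = FALSE))$state
    afosim:::marker_disp(afosim:::prep_model(m), st$q, static_base(m))
  }
  up <- settle(+10)   # dorsiflexion assist
  dn <- settle(-10)   # plantarflexion assist
  expect_gt(up["shank", "x"], 0)
  expect_lt(dn["shank", "x"], 0)
  # near-linear interface: doubling the torque about doubles the deflection
  dn2 <- settle(-20)
  expect_equal(unname(dn2["shank", "x"] / dn["shank", "x"]), 2,
               tolerance = 0.05)
})
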