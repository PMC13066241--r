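# Interface element: per-axis spring-damper law and its invariants.

test_that("bushing wrench follows the per-axis spring-damper law", {
  # identity case
  p <- default_interface_params("tibia")
  w0 <- bushing_wrench(p, frame_pose(), frame_pose())
  expect_equal(w0$force, c(0, 0, 0))
  expect_equal(w0$moment, c(0, 0, 0))

  # hand-computed K*delta oracle: 10,000 N/m * 0.002 m on the tibia y axis
  w <- bushing_wrench(p, frame_pose(position = c(0, 0.002, 0)))
  expect_equal(w$force[2], -20)
  expect_equal(w$force[c(1, 3)], c(0, 0))  # no deflection on the 100 N/m axes

  # full K*d + C*ddot oracle on random deflections, both sites
  set.seed(42)
  for (site in c("tibia", "foot")) {
    pp <- default_interface_params(site)
    for (rep in 1:5) {
      dx <- runif(3, -0.05, 0.05); dth <- runif(3, -0.2, 0.2)
      vx <- runif(3, -0.5, 0.5); vth <- runif(3, -1, 1)
      w <- bushing_wrench(pp, frame_pose(dx, dth), frame_pose(vx, vth))
      expect_equal(w$force, -(pp$k_trans * dx + pp$c_trans * vx))
      expect_equal(w$moment, -(pp$k_rot * dth + pp$c_rot * vth))
    }
  }

  # spring and damper moments oppose when deflection and rate have
  # opposite signs
  w2 <- bushing_wrench(p, frame_pose(rotation = c(0, 0, 0.1)),
                       frame_pose(rotation = c(0, 0, -0.1)))
  spring <- -p$k_rot[3] * 0.1
  damper <- -p$c_rot[3] * -0.1
  expect_true(sign(spring) != sign(damper))
  expect_equal(w2$moment[3], spring + damper)

  # non-finite input rejected with the axis named
  expect_error(bushing_wrench(p, frame_pose(position = c(0, NaN, 0))),
               "axis y")
})

test_that("spring part is linear and axes are decoupled", {
  p <- default_interface_params("foot")
  set.seed(7)
  d <- runif(3, -0.02, 0.02); r <- runif(3, -0.1, 0.1)
  for (alpha in c(-2, 0.5, 3)) {
    w1 <- bushing_wrench(p, frame_pose(d, r))
    wa <- bushing_wrench(p, frame_pose(alpha * d, alpha * r))
    expect_equal(wa$force, alpha * w1$force)
    expect_equal(wa$moment, alpha * w1$moment)
  }
  # perturbing axis i changes only component i
  base <- bushing_wrench(p, frame_pose())
  for (i in 1:3) {
    d <- c(0, 0, 0); d[i] <- 0.01
    w <- bushing_wrench(p, frame_pose(position = d))
    expect_equal(which(w$force != base$force), i)
    expect_equal(w$moment, base$moment)
  }
})

test_that("default parameters match the published table and damping", {
  tib <- default_interface_params("tibia")
  expect_equal(tib$k_trans, c(100, 10000, 100))
  expect_equal(tib$k_rot, c(200, 500, 200))
  foot <- default_interface_params("foot")
  expect_equal(foot$k_trans, c(10000, 500, 500))
  expect_equal(foot$k_rot, c(500, 200, 200))
  expect_equal(foot$k_trans[1], 10000)
  expect_equal(foot$k_rot[1], 500)
  for (p in list(tib, foot)) {
    expect_equal(p$c_trans, c(5, 5, 5))
    expect_equal(p$c_rot, c(5, 5, 5))
  }
  expect_error(default_interface_params("thigh"), "tibia, foot")
  # round-trip through the configuration file is bit-exact
  cfg <- default_config()
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(model = list(interface = cfg$model$interface)), tf)
  cfg2 <- load_config(tf)
  expect_identical(cfg2$model$interface, cfg$model$interface)
})

test_that("interface power splits into recoverable and dissipated parts", {
  p <- bushing_params(k_trans = c(0, 0, 0), k_rot = c(0, 0, 0),
                      c_trans = c(5, 5, 5), c_rot = c(5, 5, 5))
  # pure damper: dissipated power = sum c v^2 >= 0 for any motion
  set.seed(11)
  for (rep in 1:10) {
    v <- frame_pose(runif(3, -1, 1), runif(3, -2, 2))
    w <- bushing_wrench(p, frame_pose(), v)
    pw <- interface_power(w, v, p)
    expect_equal(pw$dissipated,
                 sum(5 * v$position^2) + sum(5 * v$rotation^2))
    expect_gte(pw$dissipated, 0)
    expect_equal(pw$total, -pw$dissipated)  # k = 0: all power dissipated
  }
  # zero rate: zero power
  w <- bushing_wrench(default_interface_params("foot"),
                      frame_pose(position = c(0.01, 0, 0)))
  expect_equal(interface_power(w, frame_pose(),
                               default_interface_params("foot"))$total, 0)
  # one full harmonic cycle, spring only: net work ~ 0 (quadrature oracle)
  ps <- bushing_params(k_trans = c(1000, 0, 0), k_rot = rep(0, 3),
                       c_trans = rep(0, 3), c_rot = rep(0, 3))
  tt <- seq(0, 2 * pi, length.out = 2001)
  W <- 0
  for (i in seq_along(tt)[-1]) {
    tm <- (tt[i] + tt[i - 1]) / 2
    x <- 0.02 * sin(tm); v <- 0.02 * cos(tm)
    w <- bushing_wrench(ps, frame_pose(position = c(x, 0, 0)),
                        frame_pose(position = c(v, 0, 0)))
    W <- W + interface_power(w, frame_pose(position = c(v, 0, 0)))$total *
      (tt[i] - tt[i - 1])
  }
  expect_lt(abs(W), 1e-8)
  # frame mismatch rejected
  expect_error(interface_power(wrench(frame = "a"), frame_pose(frame = "b")),
               "frame")
})

test_that("damper work is non-negative over arbitrary trajectories", {
  p <- default_interface_params("tibia")
  set.seed(99)
  for (rep in 1:20) {
    tt <- seq(0, 1, length.out = 501)
    coefs <- matrix(runif(12, -1, 1), 6)
    D <- 0
    for (i in seq_along(tt)) {
      v <- c(coefs[, 1] * cos(2 * pi * tt[i]) +
               coefs[, 2] * sin(4 * pi * tt[i]))
      pw <- interface_power(
        bushing_wrench(p, frame_pose(), frame_pose(v[1:3], v[4:6])),
        frame_pose(v[1:3], v[4:6]), p)
      D <- D + pw$dissipated * (tt[2] - tt[1])
    }
    expect_gte(D, 0)
  }
})
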