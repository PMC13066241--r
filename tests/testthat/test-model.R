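# Coupled leg + AFO model assembly, weakening, misalignment, markers.

test_that("default model topology matches the modeling concept", {
  m <- build_model()
  expect_s3_class(m, "afo_model")
  expect_length(m$elements, 4L)
  sites <- vapply(m$elements, `[[`, "", "site")
  expect_equal(sum(sites == "foot"), 2L)
  expect_equal(sum(sites == "tibia"), 2L)
  expect_equal(m$segments$aux_body$mass, 1e-05)
  # zero offset: device axis coincides with the ankle axis
  expect_equal(m$misalignment, c(0, 0, 0))
  # free coordinates: ankle rz, aux translations, two shell rz
  expect_equal(m$joints$ankle$free, "rz")
  expect_equal(m$joints$aux_joint$free, c("tx", "ty", "tz"))
  expect_equal(m$joints$aux_joint$locked, c("rx", "ry", "rz"))
  expect_equal(m$joints$foot_shell_pin$free, "rz")
  expect_equal(m$joints$calf_shell_pin$free, "rz")
  # missing segment parameters rejected by name
  cfg <- default_config()
  cfg$model$segments$calf_shell <- NULL
  expect_error(build_model(cfg), "calf_shell")
})

test_that("weakening sets the published strength factors and nothing else", {
  m <- build_model()
  w_map <- c(PF25 = 0.25, PF50 = 0.50, PF75 = 0.75, PF100 = 1.00)
  for (lv in names(w_map)) {
    mw <- apply_weakening(m, lv)
    expect_equal(mw$muscles$plantarflexors$w, unname(w_map[lv]))
    expect_equal(mw$muscles$dorsiflexors$w, 0)
    # idempotent
    expect_identical(apply_weakening(mw, lv), mw)
    # mass properties and interface untouched
    expect_identical(mw$segments, m$segments)
    expect_identical(mw$elements, m$elements)
  }
  expect_error(apply_weakening(m, "PF10"), "PF25")
})

test_that("misalignment grid shifts only the auxiliary-body attachment", {
  m <- build_model()
  expect_equal(apply_misalignment(m, "zero")$misalignment, c(0, 0, 0))
  expect_equal(apply_misalignment(m, "up", 0.02)$misalignment, c(0, 0.02, 0))
  expect_equal(apply_misalignment(m, "down", 0.02)$misalignment, c(0, -0.02, 0))
  expect_equal(apply_misalignment(m, "front", 0.02)$misalignment, c(0.02, 0, 0))
  expect_equal(apply_misalignment(m, "back", 0.02)$misalignment, c(-0.02, 0, 0))
  expect_equal(apply_misalignment(m, "inside", 0.02)$misalignment, c(0, 0, -0.02))
  expect_equal(apply_misalignment(m, "outside", 0.02)$misalignment, c(0, 0, 0.02))
  dirs <- c("zero", "front", "back", "up", "down", "inside", "outside")
  offs <- t(vapply(dirs, function(d)
    apply_misalignment(m, d)$misalignment, numeric(3)))
  expect_equal(nrow(unique(offs)), 7L)
  expect_equal(sum(abs(sqrt(rowSums(offs^2)) - 0.02) < 1e-12), 6L)
  # only the offset changes
  mm <- apply_misalignment(m, "front")
  expect_identical(mm$elements, m$elements)
  expect_identical(mm$muscles, m$muscles)
  expect_error(apply_misalignment(m, "up", -0.01), ">= 0")
  expect_error(apply_misalignment(m, "sideways"), "valid")
})

test_that("marker pairs coincide initially and read out shell displacement", {
  m <- build_model()
  pairs <- marker_pairs(m)
  expect_named(pairs, c("foot", "shank"))
  pm <- afosim:::prep_model(m)
  bs <- static_base(m)
  # initial state: both pair distances zero
  d0 <- afosim:::marker_disp(pm, numeric(6), bs)
  expect_equal(max(abs(d0)), 0)
  # rigid translation of the whole model leaves pair distances zero
  bs2 <- bs; bs2$pa <- bs$pa + c(0.3, -0.1)
  expect_equal(max(abs(afosim:::marker_disp(pm, numeric(6), bs2))), 0)
  # misaligned model still coincides at the neutral pose
  pm_mis <- afosim:::prep_model(apply_misalignment(m, "front"))
  expect_equal(max(abs(afosim:::marker_disp(pm_mis, numeric(6), bs))), 0)
  # displacing the device by d along y with the segments fixed reads d
  d <- 0.02
  q <- c(0, 0, d, 0, 0, 0)
  md <- afosim:::marker_disp(pm, q, bs)
  expect_equal(md["foot", "y"], d, tolerance = 1e-12)
  expect_equal(md["shank", "y"], d, tolerance = 1e-12)
  # shell rotation moves the off-axis marker by about r * psi
  q2 <- c(0, 0, 0, 0, 0.1, 0)
  md2 <- afosim:::marker_disp(pm, q2, bs)
  r <- m$markers$foot[1:2]
  expect_equal(unname(md2["foot", c("x", "y")]),
               as.vector((afosim:::rot2(0.1) - diag(2)) %*% r))
  expect_equal(unname(md2["shank", c("x", "y")]), c(0, 0))
})

test_that("patient variants cover the four severities with paralyzed dorsiflexors", {
  base <- build_model()
  vars <- patient_variants(base)
  expect_length(vars, 4L)
  expect_named(vars, c("PF25", "PF50", "PF75", "PF100"))
  for (v in vars) expect_equal(v$muscles$dorsiflexors$w, 0)
  expect_equal(vapply(vars, function(v) v$muscles$plantarflexors$w, 0),
               c(PF25 = 0.25, PF50 = 0.5, PF75 = 0.75, PF100 = 1))
  # pure function: base untouched
  expect_equal(base$muscles$plantarflexors$w, 1)
  expect_equal(base$muscles$dorsiflexors$w, 1)
})
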