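test_that("first gradient moment follows the whole-module convention", {
  vs <- vs_module_params(gradient_mT_m = 13, duration_ms = 1.2, module_ms = 50)
  expect_equal(first_gradient_moment(vs), 7.8e-7, tolerance = 1e-12)
  expect_equal(first_gradient_moment(vs_module_params(gradient_mT_m = 0)), 0)
  expect_equal(first_gradient_moment(vs_module_params(gradient_mT_m = 26)),
               2 * first_gradient_moment(vs))
  expect_error(vs_module_params(duration_ms = -1), "duration")
  expect_error(vs_module_params(duration_ms = 60, module_ms = 50), "duration")
})

test_that("reference settings give the nominal cutoff velocity within rounding", {
  vc <- cutoff_velocity(vs_module_params())
  expect_lt(abs(vc - 1.6), 0.15)
})

test_that("cutoff velocity is inversely proportional to the first moment", {
  vs <- vs_module_params()
  vs_half <- vs_module_params(gradient_mT_m = vs$gradient_mT_m / 2)
  expect_equal(cutoff_velocity(vs_half), 2 * cutoff_velocity(vs))
  expect_identical(cutoff_velocity(vs_module_params(gradient_mT_m = 0)), Inf)
})

test_that("cutoff velocity is the first zero of the laminar response (bisection oracle)", {
  set.seed(42)
  for (i in 1:10) {
    vs <- vs_module_params(gradient_mT_m = runif(1, 2, 25),
                           duration_ms = runif(1, 0.5, 3),
                           module_ms = runif(1, 20, 80))
    vc <- cutoff_velocity(vs)
    # Vc is the zero giving full saturation on laminar average ...
    root <- uniroot(function(v) laminar_mean_response(v, vs),
                    lower = vc * 0.75, upper = vc * 1.25,
                    tol = vc * 1e-9)$root
    expect_equal(root, vc, tolerance = 1e-6)
    # ... and sits at exactly twice the first null of the response
    first_null <- uniroot(function(v) laminar_mean_response(v, vs),
                          lower = vc / 4, upper = vc * 0.74,
                          tol = vc * 1e-9)$root
    expect_equal(2 * first_null, vc, tolerance = 1e-6)
  }
})

test_that("plug-flow response hits the landmark velocities", {
  vs <- vs_module_params()
  vc <- cutoff_velocity(vs)
  expect_equal(plug_flow_response(0, vs), 1)
  expect_equal(plug_flow_response(vc / 2, vs), 0, tolerance = 1e-12)
  expect_equal(plug_flow_response(vc, vs), -1)
  # control condition is flat unless the module is enabled in control
  expect_equal(plug_flow_response(vc, vs, condition = "control"), 1)
  vs2 <- vs_module_params(enabled_in_control = TRUE)
  expect_equal(plug_flow_response(vc, vs2, condition = "control"), -1)
})

test_that("laminar-averaged response matches its closed form and quadrature", {
  vs <- vs_module_params()
  vc <- cutoff_velocity(vs)
  expect_equal(laminar_mean_response(0, vs), 1)
  expect_equal(laminar_mean_response(vc, vs), 0, tolerance = 1e-12)
  expect_equal(laminar_mean_response(vc / 4, vs), 2 / pi, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:100) {
    vs_i <- vs_module_params(gradient_mT_m = runif(1, 1, 25),
                             duration_ms = runif(1, 0.5, 3),
                             module_ms = runif(1, 20, 80))
    v <- runif(1, 0, 4 * cutoff_velocity(vs_i))
    expect_equal(laminar_mean_response(v, vs_i), quad_laminar(v, vs_i),
                 tolerance = 1e-6)
  }
})

test_that("laminar response is bounded and vanishes at high velocity", {
  vs <- vs_module_params()
  v <- seq(0, 50 * cutoff_velocity(vs), length.out = 5000)
  r <- laminar_mean_response(v, vs)
  expect_true(all(r <= 1 + 1e-12))
  expect_true(all(r >= -0.2173))
  expect_lt(max(abs(r[v > 40 * cutoff_velocity(vs)])), 0.005)
})

test_that("diffusion subtraction error follows the attenuation model", {
  vs <- vs_module_params()
  co <- physical_constants()
  # independent arithmetic for the bipolar-pair b-value
  b_hand <- 2 * (co$gamma * 0.013 * 0.0012)^2 * (0.025 - 0.0012 / 3) * 1e-6
  expect_equal(b_value(vs), b_hand, tolerance = 1e-12)
  expect_equal(diffusion_subtraction_error(vs, D = 0), 0)
  expect_equal(diffusion_subtraction_error(vs_module_params(gradient_mT_m = 0)), 0)
  expect_equal(diffusion_subtraction_error(vs, D = 3e-3),
               1 - exp(-b_hand * 3e-3))
  expect_error(diffusion_subtraction_error(vs, D = -1), "diffusivity")
  # stronger gradients leak more diffusion signal
  errs <- vapply(c(3, 6, 13, 19), function(g)
    diffusion_subtraction_error(vs_module_params(gradient_mT_m = g)), 1)
  expect_true(all(diff(errs) > 0))
})

test_that("background-suppression recovery matches the closed form and time stepping", {
  expect_equal(bgs_longitudinal_mz(1681, numeric(0), 1200), 1)
  t_null <- 1500 * log(2)
  expect_equal(bgs_longitudinal_mz(1500, 0, t_null, mz0 = 1), 0,
               tolerance = 1e-9)
  expect_equal(bgs_longitudinal_mz(1820, c(50, 1160), 1600), 0.283,
               tolerance = 1e-3)
  set.seed(11)
  for (i in 1:5) {
    t1 <- runif(1, 800, 2500)
    t_end <- runif(1, 1200, 2400)
    inv <- sort(runif(2, 10, t_end - 50))
    expect_equal(bgs_longitudinal_mz(t1, inv, t_end),
                 euler_bgs(t1, inv, t_end), tolerance = 1e-4)
  }
  expect_error(bgs_longitudinal_mz(-1, numeric(0), 100), "T1")
  expect_error(bgs_longitudinal_mz(1000, c(200), 100), "precede")
})

test_that("effective PLD accumulates the per-slice readout time", {
  p <- protocol_params(pld_ms = 1000)
  expect_equal(effective_pld(p, 0), 1000)
  expect_equal(effective_pld(p, 12), 1828)
  expect_equal(effective_pld(protocol_params(pld_ms = 400), 1), 469)
  expect_error(effective_pld(p, 13), "out of range")
})

test_that("label signal combines saturation, arrival and decay", {
  p <- reference_protocol()
  vc <- cutoff_velocity(p$vs)
  expect_equal(label_signal(vc, 1000, 1500, p), 0)   # not yet arrived
  expect_equal(label_signal(0, 1681, 0, p), 0)       # static spins unlabeled
  expect_equal(label_signal(vc, 1681, 0, p), exp(-1), tolerance = 1e-9)
  # non-increasing in effective PLD beyond arrival
  plds <- seq(500, 3000, by = 100)
  dm <- label_signal(vc, plds, 400, p)
  expect_true(all(diff(dm) <= 0))
  # dual never exceeds single for any readout velocity
  pd <- dual_protocol()
  v_read <- seq(0, 5 * vc, length.out = 100)
  dm_single <- label_signal(vc, 1600, 0, p)
  dm_dual <- label_signal(rep(vc, 100), 1600, 0, pd, v_readout_cm_s = v_read)
  expect_true(all(dm_dual <= dm_single + 1e-12))
  # smooth arrival ramp is intermediate
  expect_equal(label_signal(vc, 500, 400, p, ramp_ms = 200),
               0.5 * label_signal(vc, 500, 0, p), tolerance = 1e-9)
})

test_that("scan duration reproduces the nominal protocol timings", {
  expect_equal(scan_duration(reference_protocol()), 196)
  expect_equal(scan_duration(dual_protocol()), 358.4)
  expect_equal(scan_duration(protocol_params(n_pairs = 1, n_prep = 0,
                                             tr_ms = 1000)), 3)
})

test_that("T1 reference curve anchors at 400 ms and decays with blood T1", {
  expect_equal(t1_decay_reference(3.2, 400), 3.2)
  expect_equal(t1_decay_reference(1, 2200), exp(-1800 / 1681),
               tolerance = 1e-9)
  expect_equal(t1_decay_reference(0, 1600), 0)
  expect_error(t1_decay_reference(3, 300), "400")
})

test_that("constants are validated and overridable from YAML", {
  co <- physical_constants()
  expect_equal(co$T1_blood, 1681)
  expect_error(physical_constants(T1_blood = -5), "positive")
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(list(T1_blood = 1650), path)
  expect_equal(load_constants(path)$T1_blood, 1650)
  expect_equal(load_constants(path)$gamma, co$gamma)
})

test_that("label/control response bundle is consistent by construction", {
  vs <- vs_module_params()
  vc <- cutoff_velocity(vs)
  r <- label_response(c(0, vc / 2, vc), vs)
  expect_equal(r$dm_static, r$mz_control - r$mz_label)
  expect_equal(r$mz_control, rep(1, 3))
  expect_true(all(abs(r$mz_label) <= 1))
  expect_equal(r$dm_static[3], 2)   # fully inverted plug flow at Vc
  # second module of a dual protocol: both conditions see the cosine
  vs2 <- vs_module_params(enabled_in_control = TRUE)
  r2 <- label_response(vc, vs2)
  expect_equal(r2$dm_static, 0)
})
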