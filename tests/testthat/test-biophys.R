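test_that("the default model is bistable with the published fixed points", {
  m <- membrane_model()
  fp <- find_fixed_points(m)
  expect_equal(nrow(fp), 3)
  expect_equal(sum(fp$stable), 2)
  expect_true(all(abs(fp$current) < 1e-6))
  expect_lt(abs(fp$v[1] - (-80)), 2.5)       # rest near -80 mV
  expect_false(fp$stable[2])                 # separatrix in between
  expect_equal(fp$v[3], -20, tolerance = 1e-6)
  # large input leaves a single depolarized fixed point
  fp_hi <- find_fixed_points(m, i_inj = 30)
  expect_equal(sum(fp_hi$stable), 1)
  expect_gt(fp_hi$v[fp_hi$stable], -30)
  # fully open chloride shunt makes the cell monostable near rest
  fp_cl <- find_fixed_points(m, s_cl = 1)
  expect_equal(nrow(fp_cl), 1)
  expect_true(fp_cl$stable)
  expect_lt(fp_cl$v, -70)
})

test_that("root finding agrees with a dense grid scan of the I-V curve", {
  m <- membrane_model()
  f <- function(v) intrinsic_current(m, v)
  grid <- seq(-120, 20, by = 0.01)
  fv <- f(grid)
  flips <- which(fv[-1] * fv[-length(fv)] < 0 | fv[-length(fv)] == 0)
  fp <- find_fixed_points(m)
  expect_equal(length(flips), nrow(fp))
  expect_true(all(abs(fp$v - grid[flips]) <= 0.011))
})

test_that("the membrane rests at its fixed point without input", {
  m <- membrane_model()
  sim <- simulate_membrane(m, protocol_ramp(0, 0, 2))
  rest <- find_fixed_points(m)$v[1]
  expect_true(all(abs(sim$v_mv - rest) < 0.5))
})

test_that("step series switches first at 3 pA and the shunt blocks switching", {
  m <- membrane_model()
  expect_equal(step_threshold(m), 3)
  # with the chloride gate open no step in the tested grid switches
  expect_true(is.na(step_threshold(m, s_cl = 1)))
  # added chloride leak can only raise the threshold
  m2 <- membrane_model(g_cl = 2 * m$g_cl)
  th1 <- step_threshold(m, s_cl = 0.1)
  th2 <- step_threshold(m2, s_cl = 0.1)
  expect_true(is.na(th1) || is.na(th2) || th2 >= th1)
})

test_that("ramp transitions occur near 2 pA independent of slope", {
  m <- membrane_model()
  r5 <- ramp_threshold(m, 5, 15)
  r10 <- ramp_threshold(m, 10, 15)
  expect_equal(round(r5), 2)
  expect_equal(round(r10), 2)
  expect_lt(abs(r5 - r10), 0.3)
  # as the ramp slows the crossing current approaches the static knee
  grid <- seq(-80, -40, by = 0.001)
  knee <- max(intrinsic_current(m, grid))
  r_slow <- ramp_threshold(m, 5, 60)
  expect_lt(abs(r_slow - knee), 0.2)
  expect_true(is.na(ramp_threshold(m, 1, 15)))  # subthreshold ramp
})

test_that("only coincident drive and disinhibition reach the plateau", {
  m <- membrane_model()
  tt <- and_gate_truth_table(m)
  expect_equal(tt$plateau, tt$awa_drive & tt$glut_release_off)
  on_on <- tt[tt$awa_drive & tt$glut_release_off, ]
  # plateau voltage equals the depolarized fixed point under the same
  # conductances
  fp <- find_fixed_points(m, s_cl = 0, v_awa = m$v_awa_on)
  expect_equal(on_on$final_v_mv, max(fp$v[fp$stable]), tolerance = 1e-3)
  # without a gap junction the (on, on) input has no current path
  m0 <- membrane_model(g_gap = 0)
  tt0 <- and_gate_truth_table(m0)
  expect_false(any(tt0$plateau))
})

test_that("transition times are integration-step invariant and match a stiff solver", {
  skip_if_not_installed("deSolve")
  m <- membrane_model()
  vu <- find_fixed_points(m)$v[2]
  pr <- protocol_steps(3, step_s = 5)
  cross_time <- function(dt) {
    sim <- simulate_membrane(m, pr, dt_ms = dt, record_every = 1L)
    sim$t_s[which(sim$v_mv > vu)[1]]
  }
  t1 <- cross_time(0.1)
  t2 <- cross_time(0.05)
  expect_lt(abs(t1 - t2), 0.1 / 1000 + 1e-9)
  # reference integration segment by segment, so the stiff solver never
  # steps across the current discontinuity
  # pA/pF = mV/ms; lsoda integrates in seconds, hence the factor 1000
  rhs <- function(i_inj) function(t, y, parms)
    list(1000 * (-intrinsic_current(m, y[1]) + i_inj) / m$capacitance_pf)
  v0 <- find_fixed_points(m)$v[1]
  pre <- deSolve::lsoda(c(v = v0), seq(0, 1, by = 1e-3), rhs(-10), NULL,
                        rtol = 1e-10, atol = 1e-10)
  v1 <- unname(pre[nrow(pre), "v"])
  sol <- deSolve::lsoda(c(v = v1), seq(1, 6, by = 1e-4), rhs(3), NULL,
                        rtol = 1e-10, atol = 1e-10)
  t_ref <- sol[which(sol[, "v"] > vu)[1], "time"]
  expect_lt(abs(t1 - t_ref), 0.010)
})

test_that("hysteresis regime is reported consistently with the fixed points", {
  m <- membrane_model()
  h <- hysteresis_report(m)
  expect_true(h$bistable_at_zero)            # -20 mV branch exists at 0 pA
  expect_equal(h$bistable_at_zero, h$persists_after_step)
  expect_equal(h$final_v_mv, -20, tolerance = 0.05)
})
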