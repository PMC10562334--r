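test_that("patient-specific flow rates follow the allometric model", {
  expect_equal(patient_flow_rate("male", 1), 1.36)
  expect_equal(patient_flow_rate("female", 1), 1.89)
  # high-precision evaluation of 1.36 * 70^0.44
  expect_equal(patient_flow_rate("male", 70), 1.36 * exp(0.44 * log(70)),
               tolerance = 1e-12)
  expect_equal(round(patient_flow_rate("male", 70), 1), 8.8)
  expect_error(patient_flow_rate("male", 0), "positive")
})

test_that("simulation flow rate doubles the mean and converts to SI", {
  expect_equal(simulation_flow_rate(1), 2 / 6e4)
  expect_equal(simulation_flow_rate(8.8), 2.933e-4, tolerance = 1e-3)
  # a subject's pre and post runs share the same Q by construction
  co <- generate_cohort(4, seed = 2)
  s <- co$subjects
  Q <- simulation_flow_rate(patient_flow_rate(s$sex, s$weight))
  expect_equal(Q[s$timepoint == "pre"], Q[s$timepoint == "post"])
})

test_that("domain construction tags faces and rejects broken masks", {
  m <- rhinoflow:::airway_mask(array(TRUE, c(3, 10, 4)), 1)
  dom <- build_domain(m)
  expect_equal(dom$n_fluid, 120)
  # wall faces of a straight duct: perimeter * length (slip disabled)
  wfcount <- 2 * (3 + 4) * 10
  fs <- list(converged = TRUE,
             u = array(0, c(6, 10, 6)), v = array(0, c(5, 11, 6)),
             w = array(0, c(5, 10, 7)), p = array(0, c(5, 10, 6)))
  wf <- wall_field(dom, fs)
  expect_equal(nrow(wf), wfcount)
  expect_equal(sum(wf$area), wfcount * 1e-6)
  # disconnected fluid is rejected
  bad <- array(TRUE, c(3, 10, 4))
  bad[, 5, ] <- FALSE
  expect_error(build_domain(rhinoflow:::airway_mask(bad, 1)), "not connected")
  # no fluid on the first slice -> no inlet
  bad2 <- array(TRUE, c(3, 10, 4)); bad2[, 1, ] <- FALSE
  expect_error(build_domain(rhinoflow:::airway_mask(bad2, 1)), "inlet")
})

test_that("channel flow reproduces plane Poiseuille analytics", {
  cs <- channel_solution()
  props <- cs$props
  # developed-region streamwise pressure gradient: 12 mu Q / (W h^3)
  G <- channel_gradient(cs)
  expect_equal(G, 12 * props$mu * cs$Q / (cs$W * cs$h^3), tolerance = 0.05)
  # centreline velocity 1.5 U within 2 % (cell centres straddle the axis)
  jmid <- round(0.6 * cs$ny)
  vmax <- max(cs$flow$v[, jmid, ])
  expect_equal(vmax, 1.5 * cs$U, tolerance = 0.02)
  # wall shear 6 mu U / h within 10 % in the developed region
  wf <- cs$wall
  sel <- wf$y_mm > 0.4 * cs$ny * cs$d & wf$y_mm < 0.75 * cs$ny * cs$d
  expect_equal(mean(wf$taumag[sel]), 6 * props$mu * cs$U / cs$h,
               tolerance = 0.10)
})

test_that("mass is conserved and the target flow rate is met", {
  cs <- channel_solution()
  expect_lt(abs(cs$flow$Q_achieved - cs$Q) / cs$Q, 1e-6)
  d <- dim(cs$dom$flag)
  fl <- cs$dom$flag == 1L
  A <- (cs$d * 1e-3)^2
  Qin <- sum(cs$flow$v[, 1, ][fl[, 1, ]]) * A
  Qout <- sum(cs$flow$v[, d[2] + 1, ][fl[, d[2], ]]) * A
  expect_lt(abs(Qin - Qout) / cs$Q, 1e-6)
})

test_that("wall shear doubles with the flow rate in the Stokes regime", {
  cs1 <- channel_solution(nx = 10, U = 0.001)
  cs2 <- channel_solution(nx = 10, U = 0.002)
  sel <- cs1$wall$y_mm > 0.4 * cs1$ny * cs1$d &
    cs1$wall$y_mm < 0.75 * cs1$ny * cs1$d
  ratio <- cs2$wall$taumag[sel] / cs1$wall$taumag[sel]
  expect_equal(mean(ratio), 2, tolerance = 0.01)
})

test_that("grid refinement converges at first order or better", {
  err <- sapply(c(6, 12, 24), function(nx) {
    cs <- channel_solution(nx = nx)
    G <- channel_gradient(cs)
    Gx <- 12 * cs$props$mu * cs$Q / (cs$W * cs$h^3)
    sel <- cs$wall$y_mm > 0.4 * cs$ny * cs$d &
      cs$wall$y_mm < 0.75 * cs$ny * cs$d
    tx <- 6 * cs$props$mu * cs$U / cs$h
    c(dp = abs(G - Gx) / Gx,
      tau = abs(mean(cs$wall$taumag[sel]) - tx) / tx)
  })
  order_dp <- log2(err["dp", 1] / err["dp", 2])
  order_tau <- mean(log2(err["tau", -3] / err["tau", -1]))
  expect_gte(order_dp, 1)
  expect_gte(order_tau, 1)
})

test_that("temperature respects its physical bounds and limits", {
  cs <- channel_solution()
  Tv <- cs$temp$T[cs$dom$flag == 1L]
  expect_true(all(Tv >= cs$bc$T_amb - 1e-9))
  expect_true(all(Tv <= cs$bc$T_body + 1e-9))
  # adiabatic walls: outlet bulk temperature stays ambient
  bc0 <- boundary_conditions(Q = cs$Q, h_m = 0)
  t0 <- solve_temperature(cs$dom, cs$flow, cs$props, bc0)
  w0 <- wall_field(cs$dom, cs$flow, t0, cs$props, bc0)
  expect_equal(max(abs(w0$q)), 0)
  eb0 <- energy_balance(cs$dom, cs$flow, t0, w0, cs$props)
  expect_equal(eb0$T_bulk_out_K, cs$bc$T_amb, tolerance = 1e-9)
  # temperature requires a converged flow
  broken <- cs$flow; broken$converged <- FALSE
  expect_error(solve_temperature(cs$dom, broken, cs$props, cs$bc),
               "converged")
})

test_that("the Robin wall law holds pointwise and in its limits", {
  # zero local heat flux puts the mucosa at body temperature, 37.00 C
  expect_equal(robin_wall_temperature(0), 310.15)
  # worked example: h_m = 50, T_w = 305.15 K -> q = 250 W/m2
  expect_equal(50 * (310.15 - 305.15), 250)
  cs <- channel_solution()
  wf <- cs$wall
  # per-face consistency of q and T_w with Eq-of-wall law to 1e-9 relative
  expect_lt(max(abs(wf$q - cs$bc$h_m * (cs$bc$T_body - wf$Tw)) /
                  pmax(abs(wf$q), 1e-12)), 1e-9)
  # a stagnant pocket equilibrates to body temperature: invert at q = 0
  expect_equal(robin_wall_temperature(0, h_m = 50) - 273.15, 37)
})

test_that("energy bookkeeping closes to the enthalpy rise", {
  cs <- channel_solution()
  eb <- energy_balance(cs$dom, cs$flow, cs$temp, cs$wall, cs$props)
  expect_lt(eb$relative_error, 0.02)
})

test_that("solution is invariant under 90-degree axis permutation", {
  # small asymmetric cavity: duct with a lateral notch
  m <- array(TRUE, c(8, 24, 6))
  m[1:3, 8:14, 1:3] <- FALSE
  ms <- rhinoflow:::airway_mask(m, 1)
  dom1 <- build_domain(ms)
  mp <- aperm(m, c(3, 2, 1))
  dom2 <- build_domain(rhinoflow:::airway_mask(mp, 1))
  Q <- 2e-5
  bc <- boundary_conditions(Q = Q, h_m = 50)
  f1 <- solve_flow(dom1, fluid_properties(), bc)
  f2 <- solve_flow(dom2, fluid_properties(), bc)
  # pressure fields agree after permuting axes back
  p1 <- f1$p; p2 <- aperm(f2$p, c(3, 2, 1))
  fl <- dom1$flag == 1L
  expect_lt(max(abs(p1[fl] - p2[fl])) / max(abs(p1[fl])), 1e-3)
  # streamwise velocities agree
  v1 <- f1$v; v2 <- aperm(f2$v, c(3, 2, 1))
  expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 1e-3)
})

test_that("h_m calibration brackets, converges and is monotone", {
  cs <- channel_solution()
  ms <- sapply(c(10, 50, 200), function(h) {
    bch <- boundary_conditions(Q = cs$Q, h_m = h)
    tm <- solve_temperature(cs$dom, cs$flow, cs$props, bch)
    mean_wall_temperature(wall_field(cs$dom, cs$flow, tm, cs$props, bch))
  })
  expect_true(all(diff(ms) > 0))
  # a reachable target converges to within 0.1 K
  target <- mean(ms[2:3])
  cal <- calibrate_h_m(cs$dom, cs$flow, cs$props, cs$bc, target = target)
  expect_lt(abs(cal$mean_wall_K - target), 0.1)
  expect_gt(cal$h_m, 10); expect_lt(cal$h_m, 500)
  # body temperature is unreachable for finite h_m
  expect_error(calibrate_h_m(cs$dom, cs$flow, cs$props, cs$bc,
                             target = 310.15), "unreachable")
  expect_error(calibrate_h_m(cs$dom, cs$flow, cs$props, cs$bc,
                             target = 294, range = c(40, 60)), "achievable")
})
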