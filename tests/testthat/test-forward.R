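test_that("rate constants match hand arithmetic and scale as expected", {
  pr <- default_probe()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  expect_equal(kwr, 8.11e-8 * 1.57e-4 * 1.09e10, tolerance = 1e-12)
  expect_equal(kwr, 0.1388, tolerance = 1e-3)
  expect_equal(log(2) / kwr, 5.0, tolerance = 2e-3)
  # proportionality in beta and Lpr
  pr2 <- probe_system(2 * pr$beta, pr$Ar)
  expect_equal(hydrostatic_rate_constant(tp, pr2), 2 * kwr)
  tp_small <- transport_params(Lpr = 8.11e-12)
  expect_equal(hydrostatic_rate_constant(tp_small, pr), kwr * 1e-4,
               tolerance = 1e-12)

  ge <- default_geometry()
  ksr <- solute_rate_constant(tp, pr, ge)
  expect_equal(xylem_volume(ge), 2.945e-10, tolerance = 1e-3)
  expect_equal(ksr, 1.194e-3, tolerance = 1e-3)
  expect_equal(log(2) / ksr, 580, tolerance = 1e-2)
  expect_equal(solute_rate_constant(transport_params(1e-8, Psr = 0), pr, ge), 0)
  ge_half <- root_geometry(conductive_length = ge$conductive_length / 2)
  expect_equal(solute_rate_constant(tp, pr, ge_half), 2 * ksr)
})

test_that("xylem volume is the cylinder volume scaled by the xylem fraction", {
  ge <- root_geometry(conductive_length = 0.1, root_diameter = 5e-4,
                      xylem_fraction = 0.015)
  expect_equal(xylem_volume(ge), 0.015 * pi * (2.5e-4)^2 * 0.1)
  full <- root_geometry(conductive_length = 0.1, root_diameter = 5e-4,
                        xylem_fraction = 1)
  expect_equal(xylem_volume(full), pi * (2.5e-4)^2 * 0.1)
})

test_that("hydrostatic relaxation follows the single exponential", {
  pr <- default_probe()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  tr <- simulate_hydrostatic_relaxation(tp, pr, P_ss = 0.2, deltaP0 = 0.05,
                                        duration = 60, dt = 0.01)
  expect_s3_class(tr, "pressure_trace")
  expect_equal(tr$pressure_mpa[1], 0.25)
  # at the half-time the offset is half the step
  t_half <- log(2) / kwr
  p_at_half <- approx(tr$time_s, tr$pressure_mpa, t_half)$y
  expect_equal(p_at_half - 0.2, 0.025, tolerance = 1e-6)
  # hand value at t = 10 s
  p10 <- tr$pressure_mpa[which.min(abs(tr$time_s - 10))]
  expect_equal(p10 - 0.2, 0.05 * exp(-kwr * 10), tolerance = 1e-12)
  expect_equal(p10 - 0.2, 0.01248, tolerance = 1e-3)
  # zero step: constant trace
  flat <- simulate_hydrostatic_relaxation(tp, pr, deltaP0 = 0)
  expect_true(all(flat$pressure_mpa == flat$pressure_mpa[1]))
})

test_that("osmotic response is biphasic with the analytic minimum", {
  pr <- default_probe()
  ge <- default_geometry()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  ksr <- solute_rate_constant(tp, pr, ge)
  dpi <- control_delta_pi()
  tr <- simulate_osmotic_response(tp, pr, ge, P0 = 0.2, delta_pi = dpi,
                                  duration = 3000, dt = 0.1)
  expect_equal(tr$pressure_mpa[1], 0.2)
  imin <- which.min(tr$pressure_mpa)
  expect_equal(tr$time_s[imin], analytic_tmin(kwr, ksr), tolerance = 0.1)
  expect_equal(tr$time_s[imin], 34.6, tolerance = 1e-2)
  expect_equal(0.2 - min(tr$pressure_mpa), 0.0539, tolerance = 2e-3)
  # recovery toward P0
  expect_gt(tail(tr$pressure_mpa, 1), 0.2 - 0.01)

  # sigma = 0: flat trace
  flat <- simulate_osmotic_response(transport_params(8.11e-8, 2.24e-9, 0),
                                    pr, ge, P0 = 0.2, delta_pi = dpi,
                                    duration = 100, dt = 0.1)
  expect_true(all(flat$pressure_mpa == 0.2))

  # ksr = 0: monotone drop to P0 - sigma * delta_pi
  imp <- simulate_osmotic_response(transport_params(8.11e-8, 0, 0.38),
                                   pr, ge, P0 = 0.2, delta_pi = dpi,
                                   duration = 100, dt = 0.1)
  expect_true(all(diff(imp$pressure_mpa) <= 0))
  expect_equal(tail(imp$pressure_mpa, 1), 0.2 - 0.38 * dpi, tolerance = 1e-6)
})

test_that("analytic tmin matches hand arithmetic, grid argmin and the ln-e case", {
  expect_equal(analytic_tmin(0.1386, 1.194e-3), 34.6, tolerance = 1e-3)
  # ratio e: tmin = 1/(kwr - ksr)
  ksr <- 0.01
  expect_equal(analytic_tmin(exp(1) * ksr, ksr), 1 / (exp(1) * ksr - ksr),
               tolerance = 1e-12)
  expect_error(analytic_tmin(0.1, 0), "no finite minimum")
  # grid-search oracle
  for (kk in list(c(0.1, 0.001), c(0.05, 0.01), c(2, 0.5))) {
    t <- seq(0, 10 / kk[2], by = 0.01 / kk[1])
    dev <- osmotic_deviation(t, kk[1], kk[2])
    expect_equal(t[which.max(dev)], analytic_tmin(kk[1], kk[2]),
                 tolerance = 0.011 / kk[1])
  }
})

test_that("permeation-corrected depth ratio recovers sigma exactly (analytic identity)", {
  # (deltaPr / delta_pi) * exp(ksr * tmin) == sigma under the forward model
  for (kwr in c(0.02, 0.1386, 1)) {
    for (ratio in c(5, 116, 1000)) {
      for (sigma in c(0.1, 0.38, 1)) {
        ksr <- kwr / ratio
        tm <- analytic_tmin(kwr, ksr)
        depth <- sigma * 1 * osmotic_deviation(tm, kwr, ksr)  # delta_pi = 1
        expect_equal(depth * exp(ksr * tm), sigma, tolerance = 1e-10)
      }
    }
  }
})

test_that("closed form agrees with independent ODE integration", {
  skip_if_not_installed("deSolve")
  pr <- default_probe()
  ge <- default_geometry()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  ksr <- solute_rate_constant(tp, pr, ge)
  dpi <- control_delta_pi()
  # two-compartment formulation: the osmotic driving force s decays as the
  # solute permeates; pressure relaxes toward the moving target P0 - s
  rhs <- function(t, y, parms) {
    list(c(dP = -kwr * (y[1] - 0.2 + y[2]),
           ds = -ksr * y[2]))
  }
  times <- seq(0, 3000, by = 1)
  ode <- deSolve::lsoda(c(P = 0.2, s = tp$sigma * dpi), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  closed <- 0.2 - tp$sigma * dpi * osmotic_deviation(times, kwr, ksr)
  amp <- tp$sigma * dpi
  expect_lt(max(abs(ode[, "P"] - closed)) / amp, 1e-3)
})

test_that("the degenerate equal-rates case uses the analytic limit", {
  k <- 0.1
  t <- seq(0, 100, by = 0.5)
  lim <- osmotic_deviation(t, k, k)
  near <- osmotic_deviation(t, k, k * (1 + 1e-9))
  expect_equal(lim, k * t * exp(-k * t), tolerance = 1e-12)
  expect_equal(near, lim, tolerance = 1e-6)
})
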