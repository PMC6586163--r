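test_that("beta calibration recovers the slope through the origin", {
  cal <- calibrate_beta(c(1e-11, 2e-11), c(0.109, 0.218))
  expect_equal(cal$beta, 1.09e10, tolerance = 1e-10)
  expect_equal(cal$residuals, c(0, 0), tolerance = 1e-12)
  # single pair: plain ratio
  expect_equal(calibrate_beta(2e-11, 0.218)$beta, 0.218 / 2e-11)
  expect_error(calibrate_beta(c(1e-11, 2e-11), c(0, 0)), "no elastic response")
  expect_error(calibrate_beta(c(1e-11, -2e-11), c(0.1, 0.2)),
               "inconsistent signs")
})

test_that("exponential phase fit recovers the rate constant", {
  pr <- default_probe()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  tr <- simulate_hydrostatic_relaxation(tp, pr, duration = 60, dt = 0.05)
  fit <- fit_exponential_phase(tr)
  expect_s3_class(fit, "relaxation_fit")
  expect_equal(fit$rate_constant, kwr, tolerance = 1e-6)
  expect_equal(fit$half_time, log(2) / kwr, tolerance = 1e-6)
  expect_equal(fit$asymptote, 0.2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.05, tolerance = 1e-5)

  # rising relaxation (negative step) works too
  tr2 <- simulate_hydrostatic_relaxation(tp, pr, deltaP0 = -0.05)
  expect_equal(fit_exponential_phase(tr2)$rate_constant, kwr,
               tolerance = 1e-6)

  flat <- simulate_hydrostatic_relaxation(tp, pr, deltaP0 = 0)
  expect_error(fit_exponential_phase(flat), "constant trace")
  # growing oscillation: envelope moves away from the asymptote
  grow <- flat
  grow$pressure_mpa <- 0.2 + 0.001 * grow$time_s *
    rep_len(c(1, -1), nrow(grow))
  expect_error(fit_exponential_phase(grow), "no exponential decay")
})

test_that("noisy rate-constant estimates have small median error", {
  pr <- default_probe()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  set.seed(42)
  errs <- replicate(200, {
    tr <- simulate_hydrostatic_relaxation(tp, pr, deltaP0 = 0.05,
                                          duration = 60, dt = 0.1,
                                          noise_sd = 0.002)
    abs(fit_exponential_phase(tr)$rate_constant - kwr) / kwr
  })
  expect_lt(median(errs), 0.02)
})

test_that("biphasic decomposition finds the minimum and the impermeant limit errors", {
  pr <- default_probe()
  ge <- default_geometry()
  tp <- control_params()
  kwr <- hydrostatic_rate_constant(tp, pr)
  ksr <- solute_rate_constant(tp, pr, ge)
  dpi <- control_delta_pi()
  tr <- simulate_osmotic_response(tp, pr, ge, delta_pi = dpi,
                                  duration = 3000, dt = 0.1)
  b <- split_biphasic(tr)
  expect_equal(b$tmin, analytic_tmin(kwr, ksr), tolerance = 0.11)
  expect_equal(b$deltaPr, 0.38 * dpi * osmotic_deviation(
    analytic_tmin(kwr, ksr), kwr, ksr), tolerance = 1e-3)

  flat <- simulate_osmotic_response(transport_params(8.11e-8, 2.24e-9, 0),
                                    pr, ge, delta_pi = dpi, duration = 100,
                                    dt = 0.1)
  expect_error(split_biphasic(flat), class = "rootprobe_no_minimum")
  mono <- simulate_osmotic_response(transport_params(8.11e-8, 0, 0.38),
                                    pr, ge, delta_pi = dpi, duration = 100,
                                    dt = 0.1)
  err <- tryCatch(split_biphasic(mono), error = function(e) e)
  expect_s3_class(err, "rootprobe_no_minimum")
  expect_match(conditionMessage(err), "plateau depth")
})

test_that("transport estimators match hand arithmetic and are inverse in half-time", {
  expect_equal(hydraulic_conductivity(5.0, 1.57e-4, 1.09e10), 8.10e-8,
               tolerance = 1e-3)
  expect_equal(solute_permeability(580, 1.57e-4, 2.945e-10), 2.24e-9,
               tolerance = 1e-3)
  # exact inverse proportionality to half-time
  for (th in c(1, 5, 50)) {
    expect_equal(hydraulic_conductivity(2 * th, 1.57e-4, 1.09e10),
                 hydraulic_conductivity(th, 1.57e-4, 1.09e10) / 2,
                 tolerance = 1e-12)
    expect_equal(solute_permeability(2 * th, 1.57e-4, 2.945e-10),
                 solute_permeability(th, 1.57e-4, 2.945e-10) / 2,
                 tolerance = 1e-12)
  }
  # t1/2s -> infinity gives vanishing permeability
  expect_lt(solute_permeability(1e12, 1.57e-4, 2.945e-10), 1e-17)
})

test_that("reflection coefficient formula behaves and is scale-invariant", {
  expect_equal(reflection_coefficient(0.05, 0.148, 0, 0), 0.05 / 0.148)
  expect_equal(reflection_coefficient(0.0539, 0.148, 1.194e-3, 34.6), 0.380,
               tolerance = 2e-3)
  # homogeneity degree 0 in (deltaPr, delta_pi)
  for (s in c(0.1, 3, 100)) {
    expect_equal(reflection_coefficient(s * 0.0539, s * 0.148, 1.194e-3, 34.6),
                 reflection_coefficient(0.0539, 0.148, 1.194e-3, 34.6),
                 tolerance = 1e-12)
  }
  expect_warning(reflection_coefficient(0.2, 0.148, 1e-3, 100), "exceeds 1")
  expect_error(reflection_coefficient(0.05, 0, 0, 0), "positive")
})

test_that("cut-test QC passes fast full releases and fails blocked roots", {
  pr <- default_probe()
  tp <- control_params()
  pre_tr <- simulate_hydrostatic_relaxation(tp, pr, P_ss = 0.2)
  pre <- fit_exponential_phase(pre_tr)

  # proper cut: pressure to zero, 20x faster relaxation
  fast <- transport_params(Lpr = 20 * 8.11e-8)
  good_cut <- simulate_hydrostatic_relaxation(fast, pr, P_ss = 0,
                                              deltaP0 = 0.2, duration = 10,
                                              dt = 0.01)
  expect_equal(qc_cut_test(pre, good_cut)$verdict, "pass")

  # blocked xylem: pressure stays high
  blocked <- simulate_hydrostatic_relaxation(fast, pr, P_ss = 0.16,
                                             deltaP0 = 0.04, duration = 10,
                                             dt = 0.01)
  qc <- qc_cut_test(pre, blocked)
  expect_equal(qc$verdict, "fail")
  expect_match(paste(qc$reasons, collapse = " "), "blocked")

  # only 2x faster: fail the half-time criterion
  twox <- simulate_hydrostatic_relaxation(transport_params(2 * 8.11e-8), pr,
                                          P_ss = 0, deltaP0 = 0.2,
                                          duration = 30, dt = 0.01)
  expect_equal(qc_cut_test(pre, twox)$verdict, "fail")

  expect_equal(qc_cut_test(pre, NULL)$verdict, "indeterminate")
})

test_that("forward-inverse roundtrip recovers the generating parameters", {
  pr <- default_probe()
  ge <- default_geometry()
  Vx <- xylem_volume(ge)
  dpi <- control_delta_pi()
  for (Lpr in c(1e-8, 3e-8, 8e-8)) {
    for (Psr in c(0.5e-9, 2.2e-9)) {
      for (sigma in c(0.2, 0.38, 0.8)) {
        tp <- transport_params(Lpr, Psr, sigma)
        kwr <- hydrostatic_rate_constant(tp, pr)
        ksr <- solute_rate_constant(tp, pr, ge)
        dt <- log(2) / kwr / 50
        hy <- simulate_hydrostatic_relaxation(tp, pr, duration = 8 * log(2) / kwr,
                                              dt = dt)
        dur <- 3.5 / ksr
        os <- simulate_osmotic_response(tp, pr, ge, delta_pi = dpi,
                                        duration = dur,
                                        dt = max(dt, dur / 20000))
        fit <- probe_fit(hy, os, pr, ge)
        cf <- coef(fit)
        expect_equal(unname(cf["Lpr_hydrostatic"]), Lpr, tolerance = 0.01)
        expect_equal(unname(cf["Psr"]), Psr, tolerance = 0.01)
        expect_equal(unname(cf["sigma"]), sigma, tolerance = 0.01)
      }
    }
  }
})
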