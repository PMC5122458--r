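test_that("analytic heading densities normalize and have the right shape", {
  gl <- gauss_legendre(128, -pi, pi)
  # normalization at the reported parameter sets
  expect_equal(sum(gl$weights * steady_pdf_deterministic(gl$nodes, 0.28, 0.52)),
               1, tolerance = 1e-6)
  expect_equal(sum(gl$weights * steady_pdf_stochastic(gl$nodes, 0.55)),
               1, tolerance = 1e-6)
  # zero bias: uniform on the circle
  expect_equal(steady_pdf_deterministic(c(-1, 0, 2), 0, 0.52),
               rep(1 / (2 * pi), 3))
  expect_equal(steady_pdf_stochastic(c(-1, 0, 2), 0), rep(1 / (2 * pi), 3))
  # mode at the attractant direction pi/2
  th <- seq(-pi, pi, length.out = 721)
  expect_equal(th[which.max(steady_pdf_deterministic(th, 0.28, 0.52))],
               pi / 2, tolerance = 0.01)
  expect_equal(th[which.max(steady_pdf_stochastic(th, 0.55))],
               pi / 2, tolerance = 0.01)
})

test_that("mean of sin(theta) under the stochastic density equals the closed form", {
  gl <- gauss_legendre(256, -pi, pi)
  for (eps in c(0.1, 0.3, 0.55, 0.8, 0.95)) {
    quad <- sum(gl$weights * sin(gl$nodes) * steady_pdf_stochastic(gl$nodes, eps))
    expect_equal(quad, drift_velocity(eps, v = 1), tolerance = 1e-8)
  }
})

test_that("drift velocity closed form has the reported value and limits", {
  expect_equal(round(drift_velocity(0.55, 1), 2), 0.3)
  expect_equal(drift_velocity(0.55, 16.5), 0.3 * 16.5, tolerance = 0.02 * 16.5)
  expect_equal(drift_velocity(0, 10), 0)
  expect_equal(drift_velocity(1, 10), 10)
  expect_lt(drift_velocity(1e-6, 1), 1e-5)
})

test_that("velocity modulation parameter: gamma = 2f (2D) and 3f (3D)", {
  expect_equal(velocity_modulation_gamma(1 / 3, 2), 2 / 3)
  expect_equal(velocity_modulation_gamma(1 / 3, 3), 1)
  expect_equal(velocity_modulation_gamma(0, 2), 0)
  set.seed(7)
  expect_equal(velocity_modulation_gamma(1 / 3, 3, n_mc = 2e5), 1,
               tolerance = 0.02)
})

test_that("free rotational diffusion decorrelates as exp(-dr t)", {
  sp <- strategy_params(eps_d = 0, dr = 0.4)
  e <- simulate_deterministic(sp, n = 20000, t_end = 4, dt = 2e-3, seed = 21,
                              save_every = 250)
  th0 <- e$theta[, 1]
  for (k in c(3, 5, 9)) {
    lag_t <- (k - 1) * e$dt
    expect_equal(mean(cos(e$theta[, k] - th0)), exp(-0.4 * lag_t),
                 tolerance = 0.025)
  }
})

test_that("noiseless steering converges to the attractant direction", {
  sp <- strategy_params(eps_d = 0.5, dr = 1e-9)
  e <- simulate_deterministic(sp, n = 5, t_end = 60, dt = 0.05, seed = 1,
                              save_every = 1200, theta0 = rep(0, 5))
  expect_equal(unname(e$theta[, ncol(e$theta)]), rep(pi / 2, 5),
               tolerance = 1e-3)
})

test_that("simulators match their Fokker-Planck steady states (scaled down)", {
  # full-scale equivalence (n = 1e5 pooled samples, KS < 0.01) runs in the
  # acceptance suite; this is a faster guard at looser tolerance
  sp <- strategy_params(eps_d = 0.28, eps_s = 0.55, dr = 0.52)
  e <- simulate_deterministic(sp, n = 2000, t_end = 25, dt = 2e-3, seed = 4,
                              save_every = 500)
  samp <- as.numeric(e$theta[, 16:26])
  expect_lt(ks_distance_circular(samp, function(t)
    steady_pdf_deterministic(t, 0.28, 0.52)), 0.025)
  sp2 <- strategy_params(eps_s = 0.55, dr = 0.33)
  e2 <- simulate_stochastic(sp2, n = 2000, t_end = 25, dt = 2e-3, seed = 5,
                            save_every = 500)
  samp2 <- as.numeric(e2$theta[, 16:26])
  expect_lt(ks_distance_circular(samp2, function(t)
    steady_pdf_stochastic(t, 0.55)), 0.025)
  # zero-bias stochastic dynamics stay uniform
  sp0 <- strategy_params(eps_s = 0, dr = 0.33)
  e0 <- simulate_stochastic(sp0, n = 2000, t_end = 10, dt = 2e-3, seed = 6,
                            save_every = 500)
  expect_lt(ks_distance_circular(as.numeric(e0$theta),
                                 function(t) rep(1 / (2 * pi), length(t))),
            0.025)
})

test_that("simulator guards: seed and step-size requirements", {
  sp <- strategy_params()
  expect_error(simulate_stochastic(sp, n = 10, t_end = 1), "seed")
  expect_error(simulate_deterministic(strategy_params(eps_d = 5, dr = 0.5),
                                      n = 10, t_end = 1, dt = 0.1, seed = 1),
               "dt too large")
  expect_error(simulate_stochastic(strategy_params(eps_s = 1), n = 10,
                                   t_end = 1, dt = 1e-3, seed = 1),
               "nondegenerate")
})

test_that("turn-angle densities: limits, symmetry, normalization", {
  dphi <- seq(-4.5, 4.5, length.out = 601)
  # zero steering/bias: Gaussian with variance 2 dr dt
  pd0 <- delta_phi_pdf_deterministic(dphi, 0, 0.52, 0.65)
  expect_equal(pd0, dnorm(dphi, sd = sqrt(2 * 0.52 * 0.65)), tolerance = 1e-6)
  ps0 <- delta_phi_pdf_stochastic(dphi, 0, 0.33, 0.65)
  expect_equal(ps0, dnorm(dphi, sd = sqrt(2 * 0.33 * 0.65)), tolerance = 1e-6)
  # reported parameter sets: normalization and first moment
  pd <- delta_phi_pdf_deterministic(dphi, 0.28, 0.52, 0.65)
  ps <- delta_phi_pdf_stochastic(dphi, 0.55, 0.33, 0.65)
  expect_equal(trapz(dphi, pd), 1, tolerance = 1e-3)
  expect_equal(trapz(dphi, ps), 1, tolerance = 1e-3)
  expect_gt(trapz(dphi, dphi * pd), 0.05)    # steering shifts the mean up
  expect_equal(trapz(dphi, dphi * ps), 0, tolerance = 1e-10)  # symmetric
  expect_true(all(pd >= 0) && all(ps >= 0))
})

test_that("turn-angle densities agree with the Monte-Carlo oracle", {
  set.seed(31)
  w <- 0.05
  br <- seq(-3, 3, by = w)
  mids <- br[-1] - w / 2
  for (m in c("deterministic", "stochastic")) {
    eps <- if (m == "deterministic") 0.28 else 0.55
    dr <- if (m == "deterministic") 0.52 else 0.33
    x <- sample_delta_phi(1e6, m, eps, dr, 0.65)
    h <- hist(x[x > -3 & x < 3], breaks = br, plot = FALSE)
    emp <- h$counts / (length(x) * w)
    ana <- if (m == "deterministic") {
      delta_phi_pdf_deterministic(mids, eps, dr, 0.65)
    } else {
      delta_phi_pdf_stochastic(mids, eps, dr, 0.65)
    }
    expect_lt(max(abs(emp - ana)) / max(ana), 0.05)
  }
})

test_that("single-parameter heading fits recover and discriminate", {
  set.seed(17)
  sp <- strategy_params(eps_s = 0.55, dr = 0.33)
  e <- simulate_stochastic(sp, n = 3000, t_end = 25, dt = 2e-3, seed = 8,
                           save_every = 1000)
  samp <- as.numeric(e$theta[, 7:13])
  fs <- fit_angle_model(samp, "stochastic")
  expect_equal(unname(fs$parameter), 0.55, tolerance = 0.055)
  # uniform samples: fitted bias near zero for both families
  u <- runif(20000, -pi, pi)
  expect_lt(abs(fit_angle_model(u, "stochastic")$parameter), 0.02)
  expect_lt(fit_angle_model(u, "deterministic")$parameter, 0.02)
  # samples from the steering model prefer the steering family
  ed <- simulate_deterministic(strategy_params(eps_d = 0.6, dr = 0.3),
                               n = 3000, t_end = 25, dt = 2e-3, seed = 9,
                               save_every = 1000)
  sampd <- as.numeric(ed$theta[, 7:13])
  fd <- fit_angle_model(sampd, "deterministic")
  fs2 <- fit_angle_model(sampd, "stochastic")
  expect_gt(fd$logLik, fs2$logLik)
  expect_equal(unname(fd$parameter), 0.6 / (2 * 0.3), tolerance = 0.08)
})

test_that("turn-angle fit recovers dr and rejects degenerate input", {
  set.seed(23)
  x <- sample_delta_phi(5e4, "stochastic", 0.55, 0.33, 0.65)
  f <- fit_delta_phi(x, "stochastic", fixed = 0.55, dt_lag = 0.65)
  expect_equal(f$dr, 0.33, tolerance = 0.033)
  # the constrained steering family fits stochastic data worse
  fdet <- fit_delta_phi(x, "deterministic", fixed = 0.27, dt_lag = 0.65)
  expect_gt(f$logLik, fdet$logLik)
  expect_error(fit_delta_phi(rep(0.1, 100), "stochastic", fixed = 0.55,
                             dt_lag = 0.65), "degenerate")
})

test_that("angles wrap to (-pi, pi] and quadrature is exact for polynomials", {
  expect_equal(wrap_angle(c(pi, -pi, 3 * pi, -2.5 * pi)),
               c(pi, pi, pi, -0.5 * pi))
  th <- runif(100, -20, 20)
  expect_equal(sin(wrap_angle(th)), sin(th), tolerance = 1e-12)
  gl <- gauss_legendre(8, 0, 2)
  expect_equal(sum(gl$weights * gl$nodes^7), 2^8 / 8, tolerance = 1e-10)
})
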