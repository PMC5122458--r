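test_that("boundary-corrected density integrates to one everywhere", {
  dom <- c(0, 500)
  # single interior point far from walls: a Gaussian bump
  d <- density_profile(250, sigma = 25, domain = dom)
  expect_equal(trapz(d$y, d$rho), 1, tolerance = 1e-9)
  expect_equal(d$rho, dnorm(d$y, 250, 25) /
                 diff(pnorm(c(0, 500), 250, 25)), tolerance = 1e-6)
  # single point exactly at the wall: the correction rescales the half
  # kernel. Closed form (far wall negligible): eta(y) = N(y; 0, s)/Phi(y/s),
  # whose integral is log 2, so rho(y) = N(y; 0, s) / (Phi(y/s) log 2).
  db <- density_profile(0, sigma = 25, domain = dom)
  expect_equal(trapz(db$y, db$rho), 1, tolerance = 1e-9)
  expect_equal(db$rho, dnorm(db$y, 0, 25) / (pnorm(db$y / 25) * log(2)),
               tolerance = 2e-3)
  # all points at the boundary still normalize
  dbb <- density_profile(rep(0, 50), sigma = 10, domain = dom)
  expect_equal(trapz(dbb$y, dbb$rho), 1, tolerance = 1e-9)
  expect_error(density_profile(numeric(0), 25, dom), "no positions")
  expect_error(density_profile(600, 25, dom), "outside")
})

test_that("dense uniform positions give a flat profile", {
  d <- density_profile(seq(0, 500, by = 1), sigma = 25, domain = c(0, 500))
  expect_lt(diff(range(d$rho)) / mean(d$rho), 0.05)
  expect_equal(mean(d$rho), 1 / 500, tolerance = 1e-3)
})

test_that("density profile is shift-equivariant in the interior", {
  pts <- c(200, 230, 260)
  g <- seq(100, 400, length.out = 301)
  d1 <- density_profile(pts, 20, c(0, 500), grid = g)
  d2 <- density_profile(pts + 40, 20, c(0, 500), grid = g + 40)
  expect_equal(d1$rho, d2$rho, tolerance = 1e-6)
})

test_that("velocity series recovers uniform motion and alignment", {
  tr <- rbind(straight_track(1, 30, vy = 12),
              straight_track(2, 30, x0 = 50, vy = 12))
  ts <- track_set(tr, frame_interval = 0.1,
                  gradient_dir = data.frame(t = 0, dir = 1))
  vs <- velocity_series(ts, smooth_window = 0,
                        swap_windows = data.frame(t0 = 0, t1 = 10))
  expect_equal(unique(round(vs$series$v, 9)), 12)
  expect_equal(unique(round(vs$series$vy, 9)), 12)
  expect_equal(unique(round(vs$series$vx, 9)), 0)
  expect_equal(unique(round(vs$alignment$align, 9)), 1)
  # too-short tracks are skipped
  short <- track_set(straight_track(1, 2, vy = 5), min_length = 2)
  expect_error(velocity_series(short), "long enough")
})

test_that("component velocities of an unbiased ensemble average to zero", {
  prof <- uniform_profile()
  cfg <- scenario_config(prof, strategy = strategy_params(dr = 0.33, v = 16.5),
                         n_colonies = 80, duration = 40, seed = 13,
                         dropout = 0, jitter_um = 0)
  g <- generate_tracks(cfg)
  vs <- velocity_series(g$tracks, smooth_window = 0)
  expect_lt(abs(mean(vs$series$vx)), 0.8)
  expect_lt(abs(mean(vs$series$vy)), 0.8)
  expect_equal(mean(vs$series$v), 16.5, tolerance = 0.05)
})

test_that("speed is not modulated by alignment in the stochastic generator", {
  prof <- expgrad_profile()
  cfg <- scenario_config(prof, strategy = strategy_params(dr = 0.33, v = 16.5),
                         response = response_model("tanh_log", vdrift = 5.2,
                                                   alpha = 1850),
                         n_colonies = 100, duration = 40, seed = 19,
                         dropout = 0, jitter_um = 0)
  g <- generate_tracks(cfg)
  vs <- velocity_series(g$tracks, smooth_window = 0,
                        swap_windows = data.frame(t0 = 5, t1 = 40))
  al <- vs$alignment
  slope <- stats::coef(stats::lm(speed ~ align, data = al))[2]
  # relative speed change across the full alignment range stays small
  expect_lt(abs(2 * slope) / mean(al$speed), 0.05)
})

test_that("angle samples follow the sign conventions", {
  # straight up-gradient track: theta = pi/2, no turning
  ts <- track_set(straight_track(1, 30, vy = 10), frame_interval = 0.1)
  a <- angle_samples(ts, dt_lag = 0.5)
  expect_equal(unique(round(a$theta, 12)), pi / 2)
  expect_equal(unique(round(a$dphi, 12)), 0)
  # steady turn toward pi/2 gives positive turn angles
  n <- 25
  th <- seq(-pi / 3, pi / 2, length.out = n)
  pos <- cbind(cumsum(cos(th)), cumsum(sin(th)))
  tr <- data.frame(track_id = 1, frame = seq_len(n),
                   x_um = c(0, pos[-n, 1]), y_um = c(0, pos[-n, 2]))
  ts2 <- track_set(tr, frame_interval = 0.1)
  a2 <- angle_samples(ts2, dt_lag = 0.5)
  expect_true(all(a2$dphi > 0))
  # folding: gradient down flips theta so pi/2 is always up-gradient
  ts3 <- track_set(straight_track(1, 30, vy = -10), frame_interval = 0.1,
                   gradient_dir = data.frame(t = 0, dir = -1))
  a3 <- angle_samples(ts3, dt_lag = 0.5)
  expect_equal(unique(round(a3$theta, 12)), pi / 2)
  expect_error(angle_samples(ts, dt_lag = 0.13), "multiple")
})

test_that("track containers validate and round-trip", {
  tr <- straight_track(1, 10, vy = 5)
  tr2 <- tr; tr2$frame[3] <- tr2$frame[2]
  expect_error(track_set(tr2), "strictly increasing")
  ts <- track_set(rbind(tr, straight_track(2, 2, x0 = 5)), min_length = 3)
  expect_equal(unique(ts$tracks$track_id), 1)  # 2-frame track removed
  path <- tempfile(fileext = ".csv")
  write_tracks(ts, path)
  ts2 <- read_tracks(path, frame_interval = ts$frame_interval)
  expect_equal(ts2$tracks, ts$tracks, ignore_attr = TRUE)
  expect_error(track_set(tr, chamber_y = c(0, 1)), "outside")
})

test_that("angle pipeline reproduces the generator's heading distribution", {
  # uniform-bias world (constant relative gradient); pool early transit
  # times away from walls, before wall reflections symmetrize headings
  prof <- expgrad_profile()
  cfg <- scenario_config(prof, strategy = strategy_params(dr = 0.33, v = 16.5),
                         response = response_model("tanh_log", vdrift = 5.2,
                                                   alpha = 1850),
                         n_colonies = 250, duration = 60, seed = 29,
                         dropout = 0, jitter_um = 0, dt_sim = 2e-3)
  g <- generate_tracks(cfg)
  vt <- 5.2 * tanh(1850 * 0.002)
  eps_loc <- 2 * 16.5 * vt / (16.5^2 + vt^2)
  a <- angle_samples(g$tracks, dt_lag = 0.6,
                     windows = data.frame(t0 = 10, t1 = 45),
                     y_band = c(-350, 350))
  # finite-frame displacement angles blur the distribution slightly, so the
  # threshold is looser than the simulator-level check
  expect_lt(ks_distance_circular(a$theta, function(t)
    steady_pdf_stochastic(t, eps_loc)), 0.08)
  expect_equal(mean(a$dphi), 0, tolerance = 0.02)
})
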