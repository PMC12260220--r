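test_that("step kinematics match closed forms on constructed paths", {
  # uniform 0.01 cm vertical steps every 180 s
  tt <- seq(0, 3600, by = 180)
  tr <- trajectory(tt, x = 0 * tt, y = -0.01 * seq_along(tt), z = 0 * tt)
  sk <- step_kinematics(tr)
  expect_equal(sk$distance$values, rep(0.01, 20))
  expect_equal(sk$velocity$values, rep(0.01 / 180, 20), tolerance = 1e-12)
  expect_equal(sk$acceleration$values, rep(0, 19))
  # stationary tip
  tr0 <- trajectory(tt, x = 0 * tt, y = 0 * tt + 1, z = 0 * tt)
  sk0 <- step_kinematics(tr0)
  expect_true(all(sk0$distance$values == 0))
  expect_true(all(sk0$acceleration$values == 0))
  # uniformly accelerating 1-D path x = c t^2 / 2: finite-difference oracle
  cc <- 1e-7
  tt2 <- seq(0, 7200, by = 180)
  tr2 <- trajectory(tt2, x = cc * tt2^2 / 2, y = 0 * tt2, z = 0 * tt2)
  sk2 <- step_kinematics(tr2)
  v_expect <- cc * (head(tt2, -1) + tail(tt2, -1)) / 2  # step-mean speed
  expect_equal(sk2$velocity$values, v_expect, tolerance = 1e-10)
  expect_equal(sk2$acceleration$values, rep(cc, length(tt2) - 2),
               tolerance = 1e-10)
})

test_that("segmentation angles hit the canonical triplets", {
  tt <- c(0, 180, 360, 540)
  collinear <- trajectory(tt, x = c(0, 1, 2, 3), y = 0 * tt, z = 0 * tt)
  expect_equal(segmentation_angles(collinear)$values, c(0, 0))
  right <- trajectory(tt[1:3], x = c(0, 1, 1), y = c(0, 0, 1), z = c(0, 0, 0))
  expect_equal(segmentation_angles(right)$values, 90)
  reversal <- trajectory(tt[1:3], x = c(0, 1, 0), y = c(0, 0, 0),
                         z = c(0, 0, 0))
  expect_equal(segmentation_angles(reversal)$values, 180)
  # zero-length segment: NA at that index, message logged
  stalled <- trajectory(tt, x = c(0, 1, 1, 2), y = 0 * tt, z = 0 * tt)
  expect_message(ang <- segmentation_angles(stalled), "zero-length")
  expect_true(all(is.na(ang$values)))
})

test_that("growth rates follow the day-wise root length model", {
  tt <- seq(0, 2 * 86400, by = 180)
  tr <- trajectory(tt, x = 0 * tt, y = -tt / 86400, z = 0 * tt)  # 1 cm/day
  gr <- growth_rates(tr)  # default initial length 4 cm
  expect_equal(gr$absolute, 1.0, tolerance = 1e-9)
  expect_equal(gr$relative, mean(c(1 / 4, 1 / 5)), tolerance = 1e-9)
  expect_error(growth_rates(trajectory(c(0, 180, 360), 1:3, 1:3, 1:3)),
               "2 days")
  # helix: absolute rate equals the analytic arc length per day
  a <- 0.1; period <- 5400; vz <- 1 / 86400
  hx <- make_helix(a, period, vz, 2 * 86400, 60)
  gr_h <- growth_rates(hx, initial_length = 4)
  speed <- sqrt((2 * pi * a / period)^2 + vz^2)   # cm/s, constant
  expect_equal(gr_h$absolute, speed * 86400, tolerance = 1e-3)
})

test_that("average hourly tip velocity is total path over span", {
  tt <- seq(0, 7200, by = 180)
  tr <- trajectory(tt, x = 0.01 * seq_along(tt), y = 0 * tt, z = 0 * tt)
  expect_equal(average_hourly_tip_velocity(tr), 0.2, tolerance = 1e-12)
  sk <- step_kinematics(tr)
  expect_equal(average_hourly_tip_velocity(tr),
               mean(sk$distance$values) * 3600 / 180, tolerance = 1e-12)
})

test_that("the main growth component recovers smooth structure", {
  tt <- seq(0, 86400, by = 180)
  straight <- trajectory(tt, x = tt / 86400, y = -2 * tt / 86400, z = 0 * tt)
  mc <- main_growth_component(straight, window = 5400)
  expect_equal(mc$path, coords(straight), tolerance = 1e-12)  # fixed point
  expect_equal(nrow(mc$path), n_samples(straight))
  # helix smoothed over one period collapses to the axis (interior points)
  hx <- make_helix(0.2, 5400, 1 / 86400, 86400, 180)
  mch <- main_growth_component(hx, window = 5400)
  interior <- 31:(nrow(mch$path) - 30)
  axis_dev <- sqrt(mch$path[interior, 1]^2 + mch$path[interior, 3]^2)
  expect_lt(max(axis_dev), 0.05 * 0.2)
  expect_error(main_growth_component(straight, window = 200), "3 samples")
})

test_that("nutation amplitude measures displacement from the main component", {
  tt <- seq(0, 86400, by = 180)
  straight <- trajectory(tt, x = 0 * tt, y = -tt / 86400, z = 0 * tt)
  mc <- main_growth_component(straight, window = 5400)
  amp <- nutation_amplitude(straight, mc)
  expect_lt(max(amp$values), 1e-10)
  hx <- make_helix(0.15, 5400, 1 / 86400, 86400, 180)
  amp_h <- nutation_amplitude(hx, main_growth_component(hx, window = 5400))
  interior <- 31:(length(amp_h$values) - 30)
  expect_equal(mean(amp_h$values[interior]), 0.15, tolerance = 0.1)
  expect_true(all(amp_h$values >= 0))
})

test_that("main nutation period finds the dominant spectral line", {
  tt <- seq(0, 7 * 86400, by = 180)
  n <- length(tt)
  amp <- step_series("nutation_amplitude",
                     1 + 0.5 * sin(2 * pi * tt / 5400), tt)
  est <- main_nutation_period(amp, dt = 180)
  expect_lte(abs(1 / (est$period_min * 60) - 1 / 5400), 1 / (n * 180))
  # dominant peak wins over a smaller fast component
  amp2 <- step_series("nutation_amplitude",
                      1 + 0.5 * sin(2 * pi * tt / 5400) +
                        0.1 * sin(2 * pi * tt / 1800), tt)
  est2 <- main_nutation_period(amp2, dt = 180)
  expect_equal(est2$period_min, est$period_min)
  # doubling the oscillation amplitude quadruples the peak power
  amp4 <- step_series("nutation_amplitude",
                      1 + 1.0 * sin(2 * pi * tt / 5400), tt)
  est4 <- main_nutation_period(amp4, dt = 180)
  expect_equal(est4$peak_power / est$peak_power, 4, tolerance = 1e-6)
  expect_error(main_nutation_period(
    step_series("nutation_amplitude", rep(1, 100),
                seq(0, by = 180, length.out = 100))), "constant")
})

test_that("Welch spectral entropy agrees with the brute-force oracle", {
  set.seed(77)
  fs <- 1 / 180
  tt <- seq(0, 7 * 86400, by = 180)
  sine <- sin(2 * pi * tt / 5400)
  noise <- rnorm(length(tt))
  for (sig in list(sine, noise, sine + 0.2 * noise)) {
    h <- signal_spectral_entropy(sig, fs)
    h_oracle <- entropy_oracle(welch_psd_oracle(sig, fs))
    expect_equal(as.numeric(h), h_oracle, tolerance = 1e-8)
  }
  h_sine <- signal_spectral_entropy(sine, fs)
  h_noise <- signal_spectral_entropy(noise, fs)
  nbins <- attr(h_noise, "nbins")
  expect_lt(h_sine, 0.5 * h_noise)         # concentrated vs spread power
  expect_equal(as.numeric(h_noise), log2(nbins), tolerance = 0.1 * log2(nbins))
  expect_lte(h_noise, log2(nbins))          # entropy bound
  # scale invariance of the normalised spectrum
  expect_equal(as.numeric(signal_spectral_entropy(10 * sine, fs)),
               as.numeric(h_sine), tolerance = 1e-9)
  expect_warning(h0 <- signal_spectral_entropy(rep(1, 100), fs), "all-zero")
  expect_equal(as.numeric(h0), 0)
})

test_that("curvature matches analytic circles and helices", {
  th <- seq(0, 2 * pi, length.out = 2000)
  R <- 3
  circ <- trajectory(th * 100, x = R * cos(th), y = R * sin(th), z = 0 * th)
  k <- curvature_series(circ)
  expect_equal(mean(k$values), 1 / R, tolerance = 0.02)
  # straight line at varying speed still has zero curvature
  tt <- seq(0, 1000, by = 10)
  line <- trajectory(tt, x = (tt / 1000)^2, y = 2 * (tt / 1000)^2, z = 0 * tt)
  expect_lt(max(curvature_series(line)$values, na.rm = TRUE), 1e-8)
  # helix curvature a / (a^2 + b^2) with b the axial rise per radian
  a <- 0.2; period <- 5400; vz <- 2 / 86400
  hx <- make_helix(a, period, vz, 86400, 60)
  b <- vz / (2 * pi / period)
  expect_equal(mean(curvature_series(hx)$values), a / (a^2 + b^2),
               tolerance = 0.02)
})

test_that("total variation of curvature sums absolute changes", {
  th <- seq(0, 2 * pi, length.out = 500)
  circ <- trajectory(th * 100, x = cos(th), y = sin(th), z = 0 * th)
  expect_lt(total_variation_curvature(curvature_series(circ)), 1e-6)
  cvals <- rep(c(0, 2), 10)
  ks <- step_series("curvature", cvals, seq_along(cvals) * 180)
  expect_equal(total_variation_curvature(ks), 2 * (length(cvals) - 1))
})

test_that("tortuosity behaves like a path-straightness ratio", {
  tt <- seq(0, 1000, by = 10)
  line <- trajectory(tt, x = tt, y = 0 * tt, z = 0 * tt)
  expect_equal(tortuosity(line), 1.0, tolerance = 1e-12)
  th <- seq(0, pi, length.out = 2000)
  semi <- trajectory(th * 100, x = cos(th), y = sin(th), z = 0 * th)
  expect_equal(tortuosity(semi), pi / 2, tolerance = 1e-4)
  # statistically monotone in lateral noise amplitude (20 seeds)
  tort_at <- function(noise_sd) {
    vapply(1:20, function(i) {
      p <- growth_params(duration = 86400, noise_sd = noise_sd,
                         seed = 600 + i)
      tortuosity(generate_trajectory(p))
    }, numeric(1))
  }
  expect_gt(mean(tort_at(0.05)), mean(tort_at(0.005)))
  still <- trajectory(c(0, 180, 360), x = c(0, 1, 0), y = c(0, 1, 0),
                      z = c(0, 0, 0))
  expect_error(tortuosity(still), "coincide")
})

test_that("3D shape features are invariant to rigid motions", {
  p <- growth_params(duration = 86400, seed = 13)
  tr <- generate_trajectory(p)
  rot <- random_rotation(99)
  tr2 <- rotate_trajectory(tr, rot, shift = c(3, -2, 5))
  sk1 <- step_kinematics(tr); sk2 <- step_kinematics(tr2)
  expect_equal(sk2$distance$values, sk1$distance$values, tolerance = 1e-9)
  expect_equal(sk2$velocity$values, sk1$velocity$values, tolerance = 1e-9)
  expect_equal(segmentation_angles(tr2)$values,
               segmentation_angles(tr)$values, tolerance = 1e-9)
  k1 <- curvature_series(tr); k2 <- curvature_series(tr2)
  expect_equal(k2$values, k1$values, tolerance = 1e-9)
  expect_equal(total_variation_curvature(k2), total_variation_curvature(k1),
               tolerance = 1e-9)
  expect_equal(tortuosity(tr2), tortuosity(tr), tolerance = 1e-12)
  mc1 <- main_growth_component(tr, 5400)
  mc2 <- main_growth_component(tr2, 5400)
  expect_equal(nutation_amplitude(tr2, mc2)$values,
               nutation_amplitude(tr, mc1)$values, tolerance = 1e-9)
})

test_that("extract_features recovers planted parameters and exposes the canonical names", {
  p <- growth_params(nutation_period = 75, nutation_amplitude = 0.12,
                     noise_sd = 0, amplitude_jitter = 0, period_jitter = 0,
                     seed = 8)
  tr <- generate_trajectory(p)
  fv <- extract_features(tr)
  n <- n_samples(tr)
  expect_lte(abs(1 / (fv$main_nutation_period * 60) - 1 / (75 * 60)),
             1 / (n * 180))
  expect_equal(fv$mean_nutation_amplitude, 0.12, tolerance = 0.1 * 0.12)
  expect_true(all(core_feature_names() %in% names(fv)))
  expect_equal(fv$mean_speed, fv$speed_mean)
  expect_gte(fv$tortuosity, 1)
})
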