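# Independent oracles and fixture builders, kept deliberately separate from
# the package's own code paths.

# Brute-force Welch PSD: explicit DFT sums (no stats::fft), Hann window,
# mean-removed segments, 50% overlap, one-sided density scaling.
welch_psd_oracle <- function(x, fs, nperseg = min(256L, floor(length(x) / 2))) {
  n <- length(x)
  step <- nperseg %/% 2
  starts <- seq(1L, n - nperseg + 1L, by = step)
  k <- 0:(nperseg - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (nperseg - 1)))
  nfreq <- floor(nperseg / 2) + 1L
  dft <- exp(-2i * pi * outer(0:(nfreq - 1), k) / nperseg)
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(dft %*% seg)^2 / (fs * sum(w^2))
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nperseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + as.numeric(sp) * dbl
  }
  acc / length(starts)
}

entropy_oracle <- function(psd) {
  p <- psd / sum(psd)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# analytic helix r(t) = (a cos wt, -b t, a sin wt), vertical axis y
make_helix <- function(a, period_s, pitch_rate, duration, dt,
                       phase = 0) {
  tt <- seq(0, duration, by = dt)
  w <- 2 * pi / period_s
  trajectory(time_s = tt,
             x = a * cos(w * tt + phase),
             y = -pitch_rate * tt,
             z = a * sin(w * tt + phase),
             plant_id = "helix")
}

# random 3D rotation matrix from a fixed seed (QR of a Gaussian matrix)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_trajectory <- function(traj, rot, shift = c(0, 0, 0)) {
  m <- coords(traj) %*% t(rot)
  m <- sweep(m, 2, shift, `+`)
  trajectory(time_s = times(traj), x = m[, 1], y = m[, 2], z = m[, 3],
             plant_id = traj$plant_id, species = traj$species,
             dt_nominal = traj$dt_nominal, metadata = traj$metadata)
}

# hand-built hourly_motion object with a prescribed signed displacement
# series; the stub trajectory supplies valid rp_end lookups
make_hourly_motion <- function(signed) {
  n <- length(signed)
  tt <- seq(0, n * 3600, by = 3600)
  traj <- suppressWarnings(  # hourly stub spacing would trip the gap warning
    trajectory(time_s = tt, x = cumsum(c(0, signed)),
               y = -seq(0, n) * 0.1, z = numeric(n + 1),
               plant_id = "hand"))
  df <- data.frame(hour = seq_len(n),
                   theta_gh = ifelse(signed > 0, 0,
                                     ifelse(signed < 0, 180, 90)),
                   displacement = abs(signed), signed = signed,
                   cumulative = cumsum(signed),
                   sample_end = 2:(n + 1))
  structure(df, pn = c(5, 0), trajectory = traj,
            convention = plane_convention(),
            class = c("hourly_motion", "data.frame"))
}

# minimal plant pair whose focal plant's behaviour call puts rp_end at a
# prescribed signed angle (degrees) from the neighbour direction
stub_pair_at_angle <- function(theta_deg, r = 2, separation = 5) {
  th <- theta_deg * pi / 180
  # neighbour direction is +x; horizontal plane is (x, z)
  disp <- r * c(cos(th), sin(th))
  tt <- c(0, 900, 1800)
  plant <- trajectory(tt, x = c(0, disp[1] / 2, disp[1]),
                      y = c(0, -0.1, -0.2),
                      z = c(0, disp[2] / 2, disp[2]), plant_id = "focal")
  neigh <- trajectory(tt, x = rep(separation, 3), y = c(0, -0.1, -0.2),
                      z = rep(0, 3), plant_id = "neigh")
  pair <- plant_pair(plant, neigh, separation = separation)
  call <- structure(list(label = "aggregative", onset_hour = 2L,
                         rp_end = coords(plant)[3, ],
                         rule_fired = "threshold_positive",
                         f_toward = 1, f_away = 0),
                    class = "behaviour_call")
  list(pair = pair, call = call)
}

# literal four-cell Yates sum (correction capped at the deviation), written
# independently of the package
yates_oracle <- function(m) {
  n <- sum(m)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(m[i, ]) * sum(m[, j]) / n
    d <- abs(m[i, j] - e)
    s <- s + (d - min(0.5, d))^2 / e
  }
  s
}

# default-conditions cohort feature table, built once per test run
cohort_feature_table <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), paste0("rootkin_cohort_", seed))
    man <- generate_cohort(cohort_spec(), dir, seed = seed)
    co <- read_cohort(file.path(dir, "manifest.json"))
    ft <- feature_table(co[co$species == "maize", ])
    cache <<- ft
    ft
  }
})
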