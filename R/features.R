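#' Step series of a trajectory quantity
#'
#' Lightweight container for per-step or per-sample series derived from a
#' trajectory (step distance, velocity, acceleration, segmentation angle,
#' nutation amplitude, curvature).
#'
#' @param kind one of `"distance"`, `"velocity"`, `"acceleration"`,
#'   `"segmentation_angle"`, `"nutation_amplitude"`, `"curvature"`.
#' @param values numeric values (NA where undefined, e.g. a zero-length
#'   segment).
#' @param times timestamps in seconds aligned with `values`.
#' @return a `step_series` object.
#' @export
step_series <- function(kind, values, times) {
  kind <- match.arg(kind, c("distance", "velocity", "acceleration",
                            "segmentation_angle", "nutation_amplitude",
                            "curvature"))
  if (length(values) != length(times))
    stop("values and times must align")
  ok <- values[!is.na(values)]
  if (kind %in% c("distance", "nutation_amplitude", "curvature") &&
      any(ok < 0))
    stop(kind, " values must be non-negative")
  if (kind == "segmentation_angle" && any(ok < 0 | ok > 180))
    stop("segmentation angles must lie in [0, 180] degrees")
  structure(list(kind = kind, values = values, times = times),
            class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("<step_series> %s: %d values (%d NA), mean %.4g\n",
              x$kind, length(x$values), sum(is.na(x$values)),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Step kinematics: distance, velocity, acceleration
#'
#' Computes the kinematic quantities between all consecutive trajectory
#' points: Euclidean step length, step velocity (length over the step's
#' duration) and acceleration (forward difference of velocity over the step
#' interval). No smoothing is applied.
#'
#' @param traj a `root_trajectory` with at least 3 samples.
#' @return a list of `step_series`: `distance` and `velocity` (one value per
#'   step, stamped at the step's end time) and `acceleration` (one per
#'   consecutive velocity pair).
#' @examples
#' tr <- generate_trajectory(growth_params(duration = 86400))
#' sk <- step_kinematics(tr)
#' mean(sk$velocity$values) * 3600  # cm/h
#' @export
step_kinematics <- function(traj) {
  m <- coords(traj)
  t <- times(traj)
  dt <- diff(t)
  if (any(dt == 0)) stop("zero time step")
  d <- sqrt(rowSums(diff(m)^2))
  v <- d / dt
  a <- diff(v) / dt[-length(dt)]
  list(distance = step_series("distance", d, t[-1]),
       velocity = step_series("velocity", v, t[-1]),
       acceleration = step_series("acceleration", a, t[c(-1, -length(t))]))
}

#' Segmentation angles between consecutive trajectory segments
#'
#' For each interior point, the angle between the incoming segment
#' `v_prev = p_i - p_(i-1)` and the outgoing segment `v_next = p_(i+1) - p_i`,
#' via `acos` of their normalised dot product (clamped to `[-1, 1]`), in
#' degrees. 0 deg is a straight continuation, 180 deg an exact reversal; under
#' this formula larger angles are sharper turns. Zero-length segments make the
#' angle undefined at that point: an NA is emitted and a message logged.
#'
#' @param traj a `root_trajectory` with at least 3 samples.
#' @return a `step_series` of kind `segmentation_angle`, one value per
#'   interior sample.
#' @export
segmentation_angles <- function(traj) {
  m <- coords(traj)
  t <- times(traj)
  seg <- diff(m)
  n <- nrow(seg)
  vprev <- seg[-n, , drop = FALSE]
  vnext <- seg[-1, , drop = FALSE]
  np <- sqrt(rowSums(vprev^2))
  nn <- sqrt(rowSums(vnext^2))
  dot <- rowSums(vprev * vnext)
  bad <- np == 0 | nn == 0
  cosang <- rep(NA_real_, n - 1)
  cosang[!bad] <- pmin(1, pmax(-1, dot[!bad] / (np[!bad] * nn[!bad])))
  if (any(bad))
    message(sum(bad), " zero-length segment(s): angle undefined there")
  step_series("segmentation_angle", acos(cosang) * 180 / pi,
              t[2:(length(t) - 1)])
}

#' Absolute and relative daily growth rate
#'
#' Root elongation is approximated by the cumulative path length of the tip
#' trajectory, offset by the root length at the start of tracking (metadata
#' `initial_length`, default 4 cm — seedlings selected at 4 +/- 1 cm). With
#' `L(d)` the so-defined root length at whole day `d`, the absolute rate is
#' the mean of `L(d+1) - L(d)` and the relative rate the mean of
#' `(L(d+1) - L(d)) / L(d)`, over the days covered.
#'
#' @param traj a `root_trajectory` spanning at least 2 days.
#' @param initial_length starting root length in cm; defaults to the
#'   trajectory's metadata, then 4.
#' @return list with `absolute` (cm/day) and `relative` (1/day).
#' @export
growth_rates <- function(traj, initial_length = NULL) {
  if (is.null(initial_length))
    initial_length <- traj$metadata$initial_length %||% 4
  t <- times(traj)
  span <- t[length(t)] - t[1]
  if (span < 2 * 86400) stop("trajectory must span at least 2 days")
  s <- c(0, cumsum(sqrt(rowSums(diff(coords(traj))^2))))
  days <- seq(0, floor(span / 86400)) * 86400
  idx <- vapply(days, function(d) which.min(abs(t - d)), integer(1))
  L <- initial_length + s[idx]
  dL <- diff(L)
  list(absolute = mean(dL), relative = mean(dL / L[-length(L)]))
}

#' Average hourly tip velocity
#'
#' Total path length travelled by the tip divided by the observation span in
#' hours.
#'
#' @param traj a `root_trajectory` spanning at least 1 h.
#' @return cm/h.
#' @export
average_hourly_tip_velocity <- function(traj) {
  t <- times(traj)
  span_h <- (t[length(t)] - t[1]) / 3600
  if (span_h < 1) stop("trajectory must span at least 1 h")
  sum(sqrt(rowSums(diff(coords(traj))^2))) / span_h
}

#' Main growth component of a trajectory
#'
#' The smoothed tip path with nutation oscillations removed: a centered moving
#' average of the 3D coordinates over a time window. Near the edges the
#' window shrinks symmetrically, so the endpoints equal the raw endpoints and
#' the output always has the same length as the input. The window should
#' match one nutation period (a full revolution averages out); 2 h is a
#' serviceable first-pass default at typical periods.
#'
#' @param traj a `root_trajectory`.
#' @param window window width in seconds; must cover at least 3 samples.
#' @return a `main_component` object: list with `path` (n x 3 matrix),
#'   `times`, `window`.
#' @export
main_growth_component <- function(traj, window = 7200) {
  t <- times(traj)
  m <- coords(traj)
  n <- nrow(m)
  dt <- diff(t)
  if (window < 3 * stats::median(dt))
    stop("window must cover at least 3 samples")
  uniform <- diff(range(dt)) < 1e-9 * stats::median(dt)
  if (uniform) {
    h <- floor((window / dt[1]) / 2)
    half <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- seq_len(n) - half
    hi <- seq_len(n) + half
    path <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  } else {
    path <- m
    for (i in seq_len(n)) {
      hw <- min(window / 2, t[i] - t[1], t[n] - t[i])
      j <- which(t >= t[i] - hw - 1e-9 & t <= t[i] + hw + 1e-9)
      path[i, ] <- colMeans(m[j, , drop = FALSE])
    }
  }
  structure(list(path = path, times = t, window = window),
            class = "main_component")
}

#' @export
print.main_component <- function(x, ...) {
  cat(sprintf("<main_component> %d points, window %.0f s\n",
              nrow(x$path), x$window))
  invisible(x)
}

#' Nutation amplitude series
#'
#' Per-sample Euclidean (3D) distance between the raw tip position and the
#' main growth component: the instantaneous displacement of the tip from its
#' smoothed path.
#'
#' @param traj a `root_trajectory`.
#' @param mc a [main_growth_component()] of the same trajectory.
#' @return a `step_series` of kind `nutation_amplitude`.
#' @export
nutation_amplitude <- function(traj, mc) {
  m <- coords(traj)
  if (nrow(m) != nrow(mc$path))
    stop("trajectory and main component lengths differ")
  step_series("nutation_amplitude", sqrt(rowSums((m - mc$path)^2)),
              times(traj))
}

#' Main nutation period from the amplitude spectrum
#'
#' Discrete Fourier transform of the mean-removed nutation-amplitude series
#' (no zero padding, no further detrending); the main period is the inverse
#' of the non-zero frequency carrying maximal power, so the resolution is one
#' Fourier bin.
#'
#' @param amp a nutation-amplitude `step_series` with at least 32 uniformly
#'   spaced samples.
#' @param dt sampling interval in seconds; defaults to the series' median
#'   spacing.
#' @return list with `period_min` (minutes), `peak_power` (power at the peak,
#'   `|X_k|^2 / N`), and `frequency_hz`.
#' @export
main_nutation_period <- function(amp, dt = NULL) {
  stopifnot(inherits(amp, "step_series"))
  x <- amp$values
  if (anyNA(x)) {
    t_ok <- amp$times[!is.na(x)]
    x <- x[!is.na(x)]
  } else t_ok <- amp$times
  n <- length(x)
  if (n < 32) stop("need at least 32 samples for a period estimate")
  dts <- diff(t_ok)
  if (is.null(dt)) dt <- stats::median(dts)
  if (diff(range(dts)) > 1e-6 * dt)
    stop("period estimation requires uniform sampling")
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12)
    stop("amplitude series is constant: period undefined")
  P <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2))    # positive frequencies, zero excluded
  kmax <- k[which.max(P[k + 1L])]
  f <- kmax / (n * dt)
  list(period_min = 1 / f / 60, peak_power = P[kmax + 1L], frequency_hz = f)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is split into
#' `nperseg`-sample segments with the given overlap, each segment is
#' mean-removed, tapered with a Hann window and transformed; the one-sided
#' scaled periodograms are averaged.
#'
#' @param x numeric signal.
#' @param fs sampling frequency in Hz.
#' @param nperseg segment length; default `min(256, floor(length(x)/2))`.
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power/Hz), one-sided.
#' @export
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(256L, floor(n / 2))
  nperseg <- as.integer(nperseg)
  if (nperseg < 8) stop("signal too short for Welch estimation")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)))
  scale <- 1 / (fs * sum(w^2))
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2 * scale
    half <- sp[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist for even nperseg)
    dbl <- rep(2, nfreq)
    dbl[1L] <- 1
    if (nperseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + half * dbl
  }
  list(freq = seq(0, nfreq - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Spectral entropy of a signal
#'
#' Shannon entropy (bits) of the Welch PSD normalised to a probability
#' distribution over frequency bins; zero-power bins contribute 0. Low
#' entropy means power concentrated at few frequencies (regular oscillation);
#' the maximum, `log2(nbins)`, means power spread uniformly (noise-like).
#'
#' @param x numeric signal with at least 64 samples.
#' @param fs sampling frequency in Hz.
#' @param nperseg,overlap passed to [welch_psd()].
#' @return entropy in bits, with attribute `nbins` (number of PSD bins).
#' @export
signal_spectral_entropy <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  if (length(x) < 64) stop("need at least 64 samples for spectral entropy")
  if (max(abs(x - mean(x))) < 1e-15) {
    warning("all-zero signal: spectral entropy defined as 0")
    return(structure(0, nbins = NA_integer_))
  }
  ps <- welch_psd(x, fs, nperseg = nperseg, overlap = overlap)
  p <- ps$psd / sum(ps$psd)
  p <- p[p > 0]
  structure(-sum(p * log2(p)), nbins = length(ps$psd))
}

#' Spectral entropy of a trajectory's nutation signal
#'
#' The analysed signal is the per-sample distance, in the horizontal
#' (interaction) plane, between the raw tip position and the main growth
#' component — the horizontal nutation displacement.
#'
#' @param traj a `root_trajectory` with at least 64 samples.
#' @param mc a [main_growth_component()] of the same trajectory.
#' @param convention a [plane_convention()].
#' @param nperseg,overlap passed to [welch_psd()].
#' @return entropy in bits, with attribute `nbins`.
#' @export
spectral_entropy <- function(traj, mc, convention = plane_convention(),
                             nperseg = NULL, overlap = 0.5) {
  raw <- horizontal_coords(traj, convention)
  smo <- mc$path[, convention$horizontal_idx, drop = FALSE]
  if (nrow(raw) != nrow(smo))
    stop("trajectory and main component lengths differ")
  sig <- sqrt(rowSums((raw - smo)^2))
  fs <- 1 / stats::median(diff(times(traj)))
  signal_spectral_entropy(sig, fs, nperseg = nperseg, overlap = overlap)
}

#' Curvature along a trajectory
#'
#' Curvature of the time-parameterised path, `|r' x r''| / |r'|^3`, with the
#' derivatives taken by central finite differences on the (possibly
#' non-uniform) time grid. Defined at interior samples; points with zero
#' speed get NA (logged).
#'
#' @param traj a `root_trajectory` with at least 5 samples.
#' @return a `step_series` of kind `curvature` (1/cm), one value per interior
#'   sample.
#' @export
curvature_series <- function(traj) {
  m <- coords(traj)
  t <- times(traj)
  n <- nrow(m)
  if (n < 5) stop("need at least 5 samples for curvature")
  i <- 2:(n - 1)
  h1 <- t[i] - t[i - 1]
  h2 <- t[i + 1] - t[i]
  # non-uniform central differences
  d1 <- (m[i + 1, , drop = FALSE] - m[i - 1, , drop = FALSE]) / (h1 + h2)
  d2 <- 2 * (h1 * m[i + 1, , drop = FALSE] -
               (h1 + h2) * m[i, , drop = FALSE] +
               h2 * m[i - 1, , drop = FALSE]) / (h1 * h2 * (h1 + h2))
  cx <- d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]
  cy <- d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]
  cz <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  speed <- sqrt(rowSums(d1^2))
  k <- rep(NA_real_, length(i))
  ok <- speed > 0
  if (any(!ok)) message(sum(!ok), " zero-speed point(s): curvature undefined")
  k[ok] <- sqrt(cx^2 + cy^2 + cz^2)[ok] / speed[ok]^3
  step_series("curvature", k, t[i])
}

#' Total variation of curvature
#'
#' Sum of absolute successive differences of the curvature series over valid
#' (non-NA) consecutive pairs. Zero for straight lines and circles; large
#' when bending keeps changing.
#'
#' @param k a curvature `step_series` with at least 2 values.
#' @return total variation, 1/cm.
#' @export
total_variation_curvature <- function(k) {
  stopifnot(inherits(k, "step_series"))
  v <- k$values
  if (length(v) < 2) stop("need at least 2 curvature values")
  d <- abs(diff(v))
  sum(d[!is.na(d)])
}

#' Tortuosity of a trajectory
#'
#' Total path length divided by the straight-line (3D chord) distance between
#' the first and last samples; 1 for straight monotone growth, larger for
#' convoluted paths.
#'
#' @param traj a `root_trajectory` whose endpoints differ.
#' @return dimensionless value >= 1.
#' @export
tortuosity <- function(traj) {
  m <- coords(traj)
  chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  if (chord == 0) stop("start and end coincide: tortuosity undefined")
  sum(sqrt(rowSums(diff(m)^2))) / chord
}

#' Canonical feature set used by the condition classifier
#'
#' The ten features retained for individual-vs-social classification after
#' correlation pruning of the full battery: mean and minimum speed,
#' tortuosity, mean nutation amplitude, period of main nutation, total
#' variation of curvature, average relative daily growth rate, amplitude of
#' the main frequency in the power spectrum, spectral entropy, and mean
#' segmentation angle.
#'
#' @return character vector of ten feature names.
#' @export
core_feature_names <- function() {
  c("mean_speed", "min_speed", "tortuosity", "mean_nutation_amplitude",
    "main_nutation_period", "total_variation_curvature",
    "relative_growth_rate", "main_frequency_amplitude", "spectral_entropy",
    "mean_segmentation_angle")
}

series_stats <- function(s, prefix) {
  v <- s$values[!is.na(s$values)]
  out <- c(mean(v), stats::median(v), max(v), min(v))
  names(out) <- paste0(prefix, c("_mean", "_median", "_max", "_min"))
  out
}

#' Extract the full per-plant feature vector
#'
#' Runs the whole feature battery on one trajectory: descriptive statistics
#' (mean, median, max, min) of the step distance, velocity, acceleration,
#' segmentation-angle and nutation-amplitude series, plus growth rates,
#' average hourly tip velocity, main nutation period and its spectral power,
#' spectral entropy, total variation of curvature and tortuosity.
#'
#' The main growth component is estimated in two passes: a first pass with
#' `window` (default 2 h) yields a period estimate, and the component is then
#' re-estimated with the window set to that period (one full revolution
#' averages the oscillation out), from which the final amplitude, period,
#' power and entropy are computed.
#'
#' @param traj a validated `root_trajectory` spanning at least 2 days.
#' @param convention a [plane_convention()].
#' @param window first-pass smoothing window in seconds (default 7200).
#' @param refine_window if `TRUE` (default), re-estimate the main component
#'   with the estimated period as window.
#' @return named list of scalar features (see [core_feature_names()] for the
#'   canonical subset), with `plant_id` attached as an attribute.
#' @examples
#' tr <- generate_trajectory(growth_params(duration = 3 * 86400, seed = 2))
#' fv <- extract_features(tr)
#' fv[c("tortuosity", "main_nutation_period")]
#' @export
extract_features <- function(traj, convention = plane_convention(),
                             window = 7200, refine_window = TRUE) {
  sk <- step_kinematics(traj)
  ang <- segmentation_angles(traj)
  gr <- growth_rates(traj)
  dt <- stats::median(diff(times(traj)))
  mc <- main_growth_component(traj, window = window)
  amp <- nutation_amplitude(traj, mc)
  per <- main_nutation_period(amp, dt = dt)
  if (refine_window) {
    w <- max(per$period_min * 60, 3 * dt)
    w <- min(w, span_s(traj) / 4)
    mc <- main_growth_component(traj, window = w)
    amp <- nutation_amplitude(traj, mc)
    per <- main_nutation_period(amp, dt = dt)
  }
  H <- spectral_entropy(traj, mc, convention)
  kser <- curvature_series(traj)
  out <- c(
    as.list(series_stats(sk$distance, "distance")),
    as.list(series_stats(sk$velocity, "speed")),
    as.list(series_stats(sk$acceleration, "acceleration")),
    as.list(series_stats(ang, "segmentation_angle")),
    as.list(series_stats(amp, "nutation_amplitude")),
    list(mean_speed = mean(sk$velocity$values, na.rm = TRUE),
         min_speed = min(sk$velocity$values, na.rm = TRUE),
         mean_segmentation_angle = mean(ang$values, na.rm = TRUE),
         mean_nutation_amplitude = mean(amp$values, na.rm = TRUE),
         absolute_growth_rate = gr$absolute,
         relative_growth_rate = gr$relative,
         average_hourly_tip_velocity = average_hourly_tip_velocity(traj),
         main_nutation_period = per$period_min,
         main_frequency_amplitude = per$peak_power,
         spectral_entropy = as.numeric(H),
         total_variation_curvature = total_variation_curvature(kser),
         tortuosity = tortuosity(traj)))
  attr(out, "plant_id") <- traj$plant_id
  out
}

#' Assemble a per-plant feature table from a cohort
#'
#' @param cohort manifest data.frame with a `trajectory` list-column (from
#'   [read_cohort()] or [generate_cohort()] output read back).
#' @param features character vector of feature names to keep (default the
#'   canonical ten, [core_feature_names()]).
#' @param convention a [plane_convention()].
#' @return data.frame: `plant_id`, `species`, `condition`, `label` (factor
#'   `individual`/`social`) plus one numeric column per feature.
#' @export
feature_table <- function(cohort, features = core_feature_names(),
                          convention = plane_convention()) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    fv <- extract_features(cohort$trajectory[[i]], convention = convention)
    miss <- setdiff(features, names(fv))
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
    cbind(data.frame(plant_id = cohort$plant_id[i],
                     species = cohort$species[i],
                     condition = cohort$condition[i],
                     stringsAsFactors = FALSE),
          as.data.frame(fv[features]))
  })
  out <- do.call(rbind, rows)
  out$label <- factor(ifelse(out$condition == "individual",
                             "individual", "social"),
                      levels = c("individual", "social"))
  out[, c("plant_id", "species", "condition", "label", features)]
}
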