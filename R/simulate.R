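#' Parameters of the synthetic root-growth model
#'
#' The generator emulates the phenomenology of hydroponically grown primary
#' roots imaged every 3 min for a week: monotone axial growth along the
#' vertical axis, helical circumnutation about the growth axis, an optional
#' lateral drift (used to plant aggregative/avoidant behaviour towards a
#' neighbour), and additive measurement noise.
#'
#' Nutation is modelled as rotation at constant phase velocity with
#' once-per-cycle radial modulation: the tip's distance from the axis is
#' `a * (1 + radial_modulation * cos(phase + psi))`, so the tip swings closer
#' to and farther from the axis once per revolution, as real circumnutating
#' roots do. A perfectly circular orbit would keep the tip at constant
#' distance from any smoothed centreline, leaving the amplitude series flat
#' and its oscillation period undefined; the modulation is what makes the
#' rotation period measurable from the amplitude spectrum.
#'
#' @param duration total duration in seconds (default 7 days).
#' @param dt sampling interval in seconds (default 180 = 3 min).
#' @param axial_rate vertical elongation rate, cm/day.
#' @param nutation_amplitude mean orbit radius, cm.
#' @param nutation_period rotation period, minutes; must exceed `2 * dt`.
#' @param amplitude_jitter log-normal sd (per revolution) of the amplitude
#'   multiplier; 0 disables.
#' @param period_jitter log-normal sd (per revolution) of the period
#'   multiplier; 0 disables.
#' @param radial_modulation once-per-cycle radial modulation depth in `[0, 1)`.
#' @param lateral_bias horizontal drift rate, cm/day, applied along
#'   `bias_direction`; sign/direction is set by [generate_pair()] when planting
#'   behaviours.
#' @param bias_direction unit 2-vector in the horizontal plane (fixed axis
#'   order) along which `lateral_bias` acts.
#' @param noise_sd sd of i.i.d. Gaussian measurement noise per axis, cm.
#' @param initial_length initial root length at the start of tracking, cm
#'   (default 4, matching 4-day-old seedlings selected at 4 +/- 1 cm).
#' @param seed integer seed; the trajectory is a deterministic function of the
#'   parameters and this seed.
#' @return a `growth_params` object (validated list).
#' @export
growth_params <- function(duration = 7 * 86400, dt = 180,
                          axial_rate = 1.5, nutation_amplitude = 0.1,
                          nutation_period = 90,
                          amplitude_jitter = 0.1, period_jitter = 0.1,
                          radial_modulation = 0.5,
                          lateral_bias = 0, bias_direction = c(1, 0),
                          noise_sd = 0.01, initial_length = 4, seed = 1L) {
  p <- list(duration = duration, dt = dt, axial_rate = axial_rate,
            nutation_amplitude = nutation_amplitude,
            nutation_period = nutation_period,
            amplitude_jitter = amplitude_jitter,
            period_jitter = period_jitter,
            radial_modulation = radial_modulation,
            lateral_bias = lateral_bias,
            bias_direction = bias_direction,
            noise_sd = noise_sd, initial_length = initial_length,
            seed = as.integer(seed))
  mags <- c(duration, dt, axial_rate, nutation_amplitude, nutation_period,
            amplitude_jitter, period_jitter, noise_sd, initial_length)
  if (any(!is.finite(mags)) || any(mags < 0))
    stop("all growth-parameter magnitudes must be finite and >= 0")
  if (radial_modulation < 0 || radial_modulation >= 1)
    stop("radial_modulation must be in [0, 1)")
  if (nutation_period * 60 <= 2 * dt)
    stop("nutation_period must exceed 2*dt: the oscillation would alias")
  if (abs(sqrt(sum(bias_direction^2)) - 1) > 1e-6 && lateral_bias != 0)
    stop("bias_direction must be a unit 2-vector")
  structure(p, class = "growth_params")
}

# all generator randomness funnels through one RNG scope per plant
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable per-plant seed derived from a master seed; stays below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + as.numeric(index) * 9973) %%
               2147483629)
}

#' Generate one synthetic root-tip trajectory
#'
#' Deterministic given `params$seed`. The tip path is the sum of vertical
#' growth at `axial_rate`, radially modulated circumnutation in the horizontal
#' plane (amplitude and period multiplied by per-revolution log-normal jitter),
#' a lateral drift at `lateral_bias` along `bias_direction`, and i.i.d.
#' Gaussian noise per axis.
#'
#' @param params a [growth_params()] object.
#' @param origin 3-vector, cm: position of the growth axis at t = 0.
#' @param convention a [plane_convention()]; vertical growth is along its
#'   vertical axis (negative direction: roots grow down).
#' @param plant_id,species passed to [trajectory()].
#' @return a `root_trajectory`; the planted parameters are recorded in
#'   `$metadata$planted`.
#' @examples
#' tr <- generate_trajectory(growth_params(duration = 86400, seed = 7))
#' tr
#' @export
generate_trajectory <- function(params, origin = c(0, 0, 0),
                                convention = plane_convention(),
                                plant_id = "synthetic", species = "synthetic") {
  stopifnot(inherits(params, "growth_params"))
  p <- params
  tt <- seq(0, p$duration, by = p$dt)
  n <- length(tt)
  with_seed(p$seed, {
    phi0 <- stats::runif(1, 0, 2 * pi)
    psi <- stats::runif(1, 0, 2 * pi)
    # phase advances at constant velocity within a revolution; amplitude and
    # period factors are resampled each time the phase completes a turn
    phase <- numeric(n)
    amp <- numeric(n)
    cur_period <- p$nutation_period * 60 *
      jitter_factor(p$period_jitter)
    cur_amp <- p$nutation_amplitude * jitter_factor(p$amplitude_jitter)
    ph <- phi0
    next_rev <- phi0 + 2 * pi
    for (i in seq_len(n)) {
      phase[i] <- ph
      amp[i] <- cur_amp
      ph <- ph + 2 * pi * p$dt / cur_period
      if (ph >= next_rev) {
        next_rev <- next_rev + 2 * pi
        cur_period <- p$nutation_period * 60 * jitter_factor(p$period_jitter)
        cur_amp <- p$nutation_amplitude * jitter_factor(p$amplitude_jitter)
      }
    }
    radius <- amp * (1 + p$radial_modulation * cos(phase + psi))
    h1 <- radius * cos(phase) + p$bias_direction[1] * p$lateral_bias * tt / 86400
    h2 <- radius * sin(phase) + p$bias_direction[2] * p$lateral_bias * tt / 86400
    v <- -p$axial_rate * tt / 86400
    m <- matrix(0, n, 3)
    m[, convention$horizontal_idx[1]] <- h1
    m[, convention$horizontal_idx[2]] <- h2
    m[, convention$vertical_idx] <- v
    if (p$noise_sd > 0)
      m <- m + matrix(stats::rnorm(3 * n, sd = p$noise_sd), n, 3)
    m <- sweep(m, 2, origin, `+`)
    trajectory(time_s = tt, x = m[, 1], y = m[, 2], z = m[, 3],
               plant_id = plant_id, species = species, dt_nominal = p$dt,
               metadata = list(planted = unclass(p),
                               initial_length = p$initial_length))
  })
}

jitter_factor <- function(sdlog) {
  if (sdlog <= 0) return(1)
  stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic pair of plants with a planted behaviour
#'
#' Places the focal plant's growth axis at the origin and the neighbour's at
#' `separation` cm along the first horizontal axis, then orients the focal
#' plant's lateral bias toward the neighbour (`aggregative`), away from it
#' (`avoidant`) or sets it to zero (`neutral`). The neighbour keeps the bias
#' given in `params_b`.
#'
#' @param params_a,params_b [growth_params()] for focal plant and neighbour.
#' @param behaviour planted behaviour of the focal plant.
#' @param separation horizontal distance between axes, cm (default 5).
#' @param seed master seed; per-plant seeds are derived from it.
#' @param convention a [plane_convention()].
#' @return a `plant_pair`; the planted behaviour is stored in
#'   `$plant$metadata$planted_behaviour`.
#' @export
generate_pair <- function(params_a, params_b = params_a,
                          behaviour = c("neutral", "aggregative", "avoidant"),
                          separation = 5, seed = 1L,
                          convention = plane_convention()) {
  behaviour <- match.arg(behaviour)
  if (!is.numeric(separation) || separation <= 0)
    stop("separation must be > 0")
  pa <- params_a
  pa$seed <- derive_seed(seed, 1L)
  pb <- params_b
  pb$seed <- derive_seed(seed, 2L)
  # neighbour sits along the first horizontal axis
  if (behaviour == "neutral") {
    pa$lateral_bias <- 0
  } else {
    sgn <- if (behaviour == "aggregative") 1 else -1
    pa$bias_direction <- c(sgn, 0)
    pa$lateral_bias <- abs(pa$lateral_bias)
    if (pa$lateral_bias == 0)
      stop("planting ", behaviour, " behaviour requires lateral_bias > 0")
  }
  n_origin <- c(0, 0, 0)
  n_origin[convention$horizontal_idx[1]] <- separation
  plant <- generate_trajectory(pa, origin = c(0, 0, 0),
                               convention = convention, plant_id = "plant_a")
  plant$metadata$planted_behaviour <- behaviour
  neigh <- generate_trajectory(pb, origin = n_origin,
                               convention = convention, plant_id = "plant_b")
  plant_pair(plant, neigh, separation = separation, convention = convention)
}

#' Specification of a synthetic cohort
#'
#' Default counts mirror the study cohort: 19 individually grown maize, 10
#' maize grown with a conspecific (5 pairs), 12 pea with a conspecific (6
#' pairs), and 8 maize-pea heterospecific pairs (8 maize + 8 pea), with plants
#' 5 cm apart. Social plants receive growth parameters with a shorter nutation
#' period, larger amplitude, stronger jitter and faster axial growth than
#' individual plants, matching the direction of the condition differences the
#' downstream classifier is meant to detect; identical parameters across
#' conditions give a chance-level cohort.
#'
#' @param n_individual individually grown maize plants.
#' @param n_conspecific_maize maize plants paired with maize (must be even).
#' @param n_conspecific_pea pea plants paired with pea (must be even).
#' @param n_heterospecific_pairs maize-pea pairs (each yields one maize and
#'   one pea plant).
#' @param individual_params,social_params [growth_params()] for each
#'   condition.
#' @param behaviour_mix named proportions over
#'   `c(aggregative, avoidant, neutral)` used to plant behaviours for social
#'   plants; must sum to 1.
#' @param separation cm between paired plants (default 5).
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_individual = 19,
                        n_conspecific_maize = 10,
                        n_conspecific_pea = 12,
                        n_heterospecific_pairs = 8,
                        individual_params = growth_params(),
                        social_params = growth_params(
                          axial_rate = 2.5, nutation_amplitude = 0.2,
                          nutation_period = 60, amplitude_jitter = 0.2,
                          period_jitter = 0.05, lateral_bias = 0.6),
                        behaviour_mix = c(aggregative = 0.5, avoidant = 0.25,
                                          neutral = 0.25),
                        separation = 5) {
  counts <- c(n_individual, n_conspecific_maize, n_conspecific_pea,
              n_heterospecific_pairs)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("cohort must contain at least one plant")
  if (n_conspecific_maize %% 2 || n_conspecific_pea %% 2)
    stop("conspecific plant counts must be even (plants come in pairs)")
  if (abs(sum(behaviour_mix) - 1) > 1e-9 ||
      !setequal(names(behaviour_mix), c("aggregative", "avoidant", "neutral")))
    stop("behaviour_mix must be named proportions over aggregative/avoidant/neutral summing to 1")
  structure(list(n_individual = n_individual,
                 n_conspecific_maize = n_conspecific_maize,
                 n_conspecific_pea = n_conspecific_pea,
                 n_heterospecific_pairs = n_heterospecific_pairs,
                 individual_params = individual_params,
                 social_params = social_params,
                 behaviour_mix = behaviour_mix,
                 separation = separation),
            class = "cohort_spec")
}

#' Generate a cohort of synthetic trajectories on disk
#'
#' Writes one canonical CSV + JSON sidecar per plant and a `manifest.json`
#' listing `trajectory_path`, `condition`, `pair_id`, `species`, `plant_id`
#' and (for social plants) `neighbour_id`, `neighbour_species` and the planted
#' behaviour. Per-plant seeds are derived reproducibly from `seed`, so the
#' same spec and seed regenerate byte-identical files.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param convention a [plane_convention()].
#' @return the manifest as a data.frame (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
generate_cohort <- function(spec, out_dir, seed = 1L,
                            convention = plane_convention()) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  k <- 0L
  add_plant <- function(traj, condition, pair_id, neighbour_id = NA,
                        neighbour_species = NA, behaviour = NA) {
    fn <- paste0(traj$plant_id, ".csv")
    write_trajectory(traj, file.path(out_dir, fn))
    data.frame(trajectory_path = fn, condition = condition,
               pair_id = pair_id, plant_id = traj$plant_id,
               species = traj$species, neighbour_id = neighbour_id,
               neighbour_species = neighbour_species,
               planted_behaviour = behaviour, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_individual)) {
    k <- k + 1L
    p <- spec$individual_params
    p$seed <- derive_seed(seed, k)
    p$lateral_bias <- 0
    tr <- generate_trajectory(p, convention = convention,
                              plant_id = sprintf("ind_maize_%02d", i),
                              species = "maize")
    rows[[length(rows) + 1L]] <- add_plant(tr, "individual", NA)
  }
  draw_behaviour <- function(u) {
    cum <- cumsum(spec$behaviour_mix)
    names(cum)[which(u <= cum + 1e-12)[1L]]
  }
  make_social_pair <- function(pair_id, species_a, species_b, tag) {
    k <<- k + 2L
    seeds <- c(derive_seed(seed, k - 1L), derive_seed(seed, k))
    us <- vapply(seeds, function(s) with_seed(s, stats::runif(1)), numeric(1))
    behs <- vapply(us, draw_behaviour, character(1))
    origins <- list(c(0, 0, 0), c(0, 0, 0))
    origins[[2]][convention$horizontal_idx[1]] <- spec$separation
    ids <- sprintf("%s_%s", tag, c("a", "b"))
    species <- c(species_a, species_b)
    trajs <- vector("list", 2)
    for (j in 1:2) {
      p <- spec$social_params
      p$seed <- seeds[j]
      # bias direction points along +/- the inter-plant axis, per behaviour
      toward <- if (j == 1) 1 else -1
      if (behs[j] == "neutral") {
        p$lateral_bias <- 0
      } else {
        p$bias_direction <- c(if (behs[j] == "aggregative") toward else -toward, 0)
        p$lateral_bias <- abs(p$lateral_bias)
      }
      trajs[[j]] <- generate_trajectory(p, origin = origins[[j]],
                                        convention = convention,
                                        plant_id = ids[j],
                                        species = species[j])
      trajs[[j]]$metadata$planted_behaviour <- behs[j]
    }
    cond <- if (species_a == species_b) "social_conspecific" else "social_heterospecific"
    for (j in 1:2)
      rows[[length(rows) + 1L]] <<- add_plant(
        trajs[[j]], cond, pair_id, neighbour_id = ids[3 - j],
        neighbour_species = species[3 - j], behaviour = behs[j])
  }
  np <- 0L
  for (i in seq_len(spec$n_conspecific_maize %/% 2)) {
    np <- np + 1L
    make_social_pair(np, "maize", "maize", sprintf("mm_%02d", i))
  }
  for (i in seq_len(spec$n_conspecific_pea %/% 2)) {
    np <- np + 1L
    make_social_pair(np, "pea", "pea", sprintf("pp_%02d", i))
  }
  for (i in seq_len(spec$n_heterospecific_pairs)) {
    np <- np + 1L
    make_social_pair(np, "maize", "pea", sprintf("mp_%02d", i))
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Reconstruct the plant pairs of a generated cohort
#'
#' @param cohort a manifest data.frame as returned by [read_cohort()] (with
#'   trajectories attached) or by [generate_cohort()] read back in.
#' @param separation pair separation in cm (default 5).
#' @param convention a [plane_convention()].
#' @return named list of `plant_pair` objects, one per social plant (each
#'   plant is focal once), named by plant id.
#' @export
cohort_pairs <- function(cohort, separation = 5,
                         convention = plane_convention()) {
  soc <- cohort[!is.na(cohort$pair_id), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(soc))) {
    j <- which(cohort$plant_id == soc$neighbour_id[i])
    if (!length(j)) stop("neighbour not found for ", soc$plant_id[i])
    out[[soc$plant_id[i]]] <- plant_pair(soc$trajectory[[i]],
                                         cohort$trajectory[[j]],
                                         separation = separation,
                                         convention = convention)
  }
  out
}
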