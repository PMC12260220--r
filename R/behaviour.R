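#' Horizontal vector from a plant's initial tip to its neighbour's
#'
#' The reference direction for all growth angles: the horizontal-plane vector
#' from the focal plant's initial tip position to the neighbour's initial tip
#' position, so an angle of 0 deg means growth exactly towards the
#' neighbour's root.
#'
#' @param pair a `plant_pair`.
#' @param convention a [plane_convention()].
#' @return length-2 numeric vector in the horizontal plane (fixed axis
#'   order).
#' @export
neighbour_vector <- function(pair, convention = plane_convention()) {
  v <- (pair$rn0 - pair$rp0)[convention$horizontal_idx]
  if (sqrt(sum(v^2)) == 0)
    stop("initial tips coincide: neighbour direction undefined")
  unname(v)
}

#' Hourly motion of the root growth main component
#'
#' Smooths the focal plant's trajectory to its main growth component,
#' subsamples it to whole hours, and for every hourly step computes the
#' horizontal displacement vector, its angle `theta_gh` to the neighbour
#' direction, and the signed displacement: `+|step|` when `theta_gh < 90` deg
#' (movement towards the neighbour), `-|step|` when `theta_gh > 90` deg, and
#' 0 at exactly 90 deg or for a zero step. The cumulative signed displacement
#' drives the behaviour rules.
#'
#' @param pair a `plant_pair` whose focal trajectory spans at least 2 h.
#' @param mc optional precomputed [main_growth_component()] of the focal
#'   plant; computed with `window` if omitted.
#' @param convention a [plane_convention()].
#' @param window smoothing window in seconds for the default main component.
#' @return an `hourly_motion` object: data.frame with one row per hourly step
#'   (`hour`, `theta_gh`, `displacement`, `signed`, `cumulative`,
#'   `sample_end` = trajectory sample index at the step's end), plus
#'   attributes `pn` (neighbour vector) and `trajectory`.
#' @export
hourly_motion <- function(pair, mc = NULL, convention = plane_convention(),
                          window = 7200) {
  pn <- neighbour_vector(pair, convention)
  traj <- pair$plant
  if (is.null(mc)) mc <- main_growth_component(traj, window = window)
  # hourly grid on the main component, kept aligned to trajectory samples
  mct <- traj
  mct$samples <- data.frame(time_s = mc$times, x_cm = mc$path[, 1],
                            y_cm = mc$path[, 2], z_cm = mc$path[, 3])
  hr <- resample_hourly(mct)
  t <- times(traj)
  idx <- match(round(times(hr), 6), round(t, 6))
  h2 <- horizontal_coords(hr, convention)
  step <- diff(h2)
  mag <- sqrt(rowSums(step^2))
  npn <- sqrt(sum(pn^2))
  cosang <- rep(NA_real_, length(mag))
  ok <- mag > 0
  cosang[ok] <- pmin(1, pmax(-1, (step[ok, , drop = FALSE] %*% pn) /
                               (mag[ok] * npn)))
  theta <- acos(cosang) * 180 / pi
  signed <- numeric(length(mag))
  signed[ok & theta < 90] <- mag[ok & theta < 90]
  signed[ok & theta > 90] <- -mag[ok & theta > 90]
  # theta == 90 or zero-length steps contribute no signed displacement
  df <- data.frame(hour = seq_along(mag), theta_gh = theta,
                   displacement = mag, signed = signed,
                   cumulative = cumsum(signed),
                   sample_end = idx[-1])
  structure(df, pn = pn, trajectory = traj, convention = convention,
            class = c("hourly_motion", "data.frame"))
}

#' Classify primary-root behaviour from hourly motion
#'
#' Scans the cumulative signed displacement in time order. The first crossing
#' of `+threshold` calls the plant aggregative, of `-threshold` avoidant,
#' with the onset at that hour (later crossings are ignored: only the first
#' behaviour counts). If neither threshold is ever crossed, the fractions of
#' hours moving towards and away from the neighbour decide: when one exceeds
#' the other by more than `dominance` of the total hours, its direction is
#' called; otherwise the plant is neutral.
#'
#' @param hm an [hourly_motion()] with at least 2 hourly steps.
#' @param threshold cumulative-displacement threshold in cm (default 1.2,
#'   about a quarter of the 5 cm separation between plants).
#' @param dominance required margin between the toward- and away-fractions
#'   (default 0.35).
#' @return a `behaviour_call`: list with `label`, `onset_hour` (NA unless a
#'   threshold rule fired), `rp_end` (tip position when the behaviour was
#'   identified: at onset, or the final sample), `rule_fired`, and the
#'   direction fractions.
#' @export
classify_behaviour <- function(hm, threshold = 1.2, dominance = 0.35) {
  stopifnot(inherits(hm, "hourly_motion"))
  if (nrow(hm) < 2) stop("need at least 2 hourly steps")
  traj <- attr(hm, "trajectory")
  m <- coords(traj)
  cross_pos <- which(hm$cumulative > threshold)
  cross_neg <- which(hm$cumulative < -threshold)
  first_pos <- if (length(cross_pos)) cross_pos[1] else Inf
  first_neg <- if (length(cross_neg)) cross_neg[1] else Inf
  f_toward <- mean(hm$signed > 0)
  f_away <- mean(hm$signed < 0)
  if (is.finite(first_pos) || is.finite(first_neg)) {
    if (first_pos <= first_neg) {
      label <- "aggregative"; rule <- "threshold_positive"; onset <- first_pos
    } else {
      label <- "avoidant"; rule <- "threshold_negative"; onset <- first_neg
    }
    rp_end <- m[hm$sample_end[onset], ]
  } else {
    onset <- NA_integer_
    rp_end <- m[nrow(m), ]
    if (f_toward - f_away > dominance) {
      label <- "aggregative"; rule <- "dominance"
    } else if (f_away - f_toward > dominance) {
      label <- "avoidant"; rule <- "dominance"
    } else {
      label <- "neutral"; rule <- "neutral_default"
    }
  }
  structure(list(label = label, onset_hour = onset, rp_end = rp_end,
                 rule_fired = rule, f_toward = f_toward, f_away = f_away),
            class = "behaviour_call")
}

#' @export
print.behaviour_call <- function(x, ...) {
  cat(sprintf("<behaviour_call> %s (%s%s)\n", x$label, x$rule_fired,
              if (!is.na(x$onset_hour))
                sprintf(", onset hour %d", x$onset_hour) else ""))
  invisible(x)
}

#' Run the full behaviour pipeline on a plant pair
#'
#' Convenience wrapper: [hourly_motion()] then [classify_behaviour()].
#'
#' @inheritParams hourly_motion
#' @inheritParams classify_behaviour
#' @return a `behaviour_call`.
#' @export
call_behaviour <- function(pair, convention = plane_convention(),
                           window = 7200, threshold = 1.2,
                           dominance = 0.35) {
  classify_behaviour(hourly_motion(pair, convention = convention,
                                   window = window),
                     threshold = threshold, dominance = dominance)
}

#' Contingency table of aggregative behaviour by neighbour identity
#'
#' Cross-tabulates behaviour calls, collapsed to aggregative vs
#' non-aggregative (avoidant + neutral), against whether the neighbour was a
#' conspecific or a heterospecific.
#'
#' @param labels character vector of behaviour labels
#'   (`aggregative`/`avoidant`/`neutral`).
#' @param neighbour_identity character vector (`conspecific`/
#'   `heterospecific`), same length.
#' @return 2 x 2 integer matrix, rows `conspecific`/`heterospecific`, columns
#'   `aggregative`/`non_aggregative`.
#' @examples
#' behaviour_contingency(c("aggregative", "neutral", "avoidant"),
#'                       c("conspecific", "conspecific", "heterospecific"))
#' @export
behaviour_contingency <- function(labels, neighbour_identity) {
  if (length(labels) != length(neighbour_identity))
    stop("labels and neighbour_identity must align")
  if (anyNA(labels) || anyNA(neighbour_identity))
    stop("missing behaviour label or neighbour identity tag")
  if (!all(labels %in% c("aggregative", "avoidant", "neutral")))
    stop("unknown behaviour label")
  if (!all(neighbour_identity %in% c("conspecific", "heterospecific")))
    stop("neighbour_identity must be conspecific/heterospecific")
  agg <- factor(ifelse(labels == "aggregative", "aggregative",
                       "non_aggregative"),
                levels = c("aggregative", "non_aggregative"))
  who <- factor(neighbour_identity,
                levels = c("conspecific", "heterospecific"))
  as.matrix(table(who, agg))
}
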