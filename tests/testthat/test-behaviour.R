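straight_pair <- function(step_x, step_z = 0, n_hours = 24, separation = 5) {
  tt <- seq(0, n_hours * 3600, by = 180)
  k <- tt / 3600
  plant <- trajectory(tt, x = step_x * k, y = -0.05 * k, z = step_z * k,
                      plant_id = "focal")
  neigh <- trajectory(tt, x = separation + 0 * tt, y = -0.05 * k, z = 0 * tt,
                      plant_id = "neigh")
  plant_pair(plant, neigh, separation = separation)
}

test_that("the neighbour vector follows the forward convention", {
  pr <- straight_pair(0.1)
  expect_equal(neighbour_vector(pr), c(5, 0))
  expect_equal(sqrt(sum(neighbour_vector(pr)^2)), pr$separation)
  same <- plant_pair(pr$plant, pr$plant)
  expect_error(neighbour_vector(same), "coincide")
})

test_that("hourly motion angles and signs match the three canonical directions", {
  # straight toward the neighbour at 0.2 cm/h
  hm_to <- hourly_motion(straight_pair(0.2))
  expect_equal(unique(round(hm_to$theta_gh, 9)), 0)
  expect_equal(hm_to$signed, rep(0.2, nrow(hm_to)), tolerance = 1e-9)
  # perpendicular: 90 degrees, zero signed displacement
  hm_perp <- hourly_motion(straight_pair(0, step_z = 0.2))
  expect_equal(unique(round(hm_perp$theta_gh, 9)), 90)
  expect_true(all(hm_perp$signed == 0))
  # straight away: 180 degrees, negative
  hm_away <- hourly_motion(straight_pair(-0.2))
  expect_equal(unique(round(hm_away$theta_gh, 9)), 180)
  expect_equal(hm_away$signed, rep(-0.2, nrow(hm_away)), tolerance = 1e-9)
  expect_equal(hm_away$cumulative[nrow(hm_away)], -0.2 * nrow(hm_away),
               tolerance = 1e-9)
})

test_that("threshold crossings call aggregative/avoidant with first-behaviour precedence", {
  # steady approach at 0.0325 cm/h: cumulative first exceeds 1.2 at hour 37
  s <- c(rep(0.0325, 40), rep(0, 20))
  call <- classify_behaviour(make_hourly_motion(s))
  expect_equal(call$label, "aggregative")
  expect_equal(call$rule_fired, "threshold_positive")
  expect_equal(call$onset_hour, 37)  # 37 * 0.0325 = 1.2025
  # crosses -1.3 first, +1.3 later: the first behaviour is kept
  s2 <- c(rep(-0.13, 10), rep(+0.13, 25))
  call2 <- classify_behaviour(make_hourly_motion(s2))
  expect_equal(call2$label, "avoidant")
  expect_equal(call2$rule_fired, "threshold_negative")
  expect_equal(call2$onset_hour, 10)
  # rp_end is the tip position at the onset hour
  traj <- attr(make_hourly_motion(s2), "trajectory")
  expect_equal(call2$rp_end, coords(traj)[11, ])
})

test_that("sub-threshold series fall back to the dominance margin", {
  # 52% toward vs 48% away, small steps: neutral (margin 0.04 <= 0.35)
  s <- c(rep(0.01, 52), rep(-0.01, 48))
  call <- classify_behaviour(make_hourly_motion(s))
  expect_equal(call$label, "neutral")
  expect_equal(call$rule_fired, "neutral_default")
  expect_true(is.na(call$onset_hour))
  # 70% toward vs 30% away: aggregative by dominance
  s2 <- c(rep(0.01, 70), rep(-0.01, 30))
  call2 <- classify_behaviour(make_hourly_motion(s2))
  expect_equal(call2$label, "aggregative")
  expect_equal(call2$rule_fired, "dominance")
  # mirrored: avoidant by dominance
  call3 <- classify_behaviour(make_hourly_motion(-s2))
  expect_equal(call3$label, "avoidant")
  expect_equal(call3$rule_fired, "dominance")
  # exactly at the threshold boundary: reaching it is not an exceedance
  # (0.25 is exactly representable, so the boundary comparison is exact)
  s4 <- c(rep(0.25, 5), rep(c(-0.01, 0.01), 48))
  hm4 <- make_hourly_motion(s4)
  expect_equal(max(hm4$cumulative), 1.25)
  call4 <- classify_behaviour(hm4, threshold = 1.25)
  expect_false(call4$rule_fired == "threshold_positive")
  expect_equal(call4$label, "neutral")
})

test_that("the full pipeline recovers strongly planted behaviours", {
  p <- growth_params(lateral_bias = 0.8, noise_sd = 0.02)
  for (b in c("aggregative", "avoidant", "neutral")) {
    for (s in 1:2) {
      pr <- generate_pair(p, behaviour = b, seed = 100 * s + match(b, c(
        "aggregative", "avoidant", "neutral")))
      expect_equal(call_behaviour(pr)$label, b)
    }
  }
})

test_that("hourly angles are invariant to rotating the horizontal frame", {
  pr <- generate_pair(growth_params(lateral_bias = 0.6, seed = 3,
                                    duration = 2 * 86400),
                      behaviour = "aggregative", seed = 3)
  th <- 0.7  # rotate both plants about the vertical (y) axis
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  pa <- rotate_trajectory(pr$plant, rot)
  pb <- rotate_trajectory(pr$neighbour, rot)
  pr2 <- plant_pair(pa, pb, separation = pr$separation)
  hm1 <- hourly_motion(pr); hm2 <- hourly_motion(pr2)
  expect_equal(hm2$theta_gh, hm1$theta_gh, tolerance = 1e-8)
  expect_equal(hm2$signed, hm1$signed, tolerance = 1e-8)
})

test_that("swapping the roles of plant and neighbour flips approach to retreat", {
  # both plants translate in +x: A approaches B, B retreats from A
  tt <- seq(0, 12 * 3600, by = 180)
  k <- tt / 3600
  a <- trajectory(tt, x = 0.1 * k, y = -0.05 * k, z = 0 * tt, plant_id = "a")
  b <- trajectory(tt, x = 5 + 0.1 * k, y = -0.05 * k, z = 0 * tt,
                  plant_id = "b")
  hm_ab <- hourly_motion(plant_pair(a, b))
  hm_ba <- hourly_motion(plant_pair(b, a))
  expect_equal(unique(round(hm_ab$theta_gh, 6)), 0)
  expect_equal(unique(round(hm_ba$theta_gh, 6)), 180)
})

test_that("reversed printed vectors give identical angles (double negation)", {
  set.seed(55)
  for (i in 1:20) {
    pn <- rnorm(2); step <- rnorm(2)
    fwd <- acos(min(1, max(-1, sum(pn * step) /
                             (sqrt(sum(pn^2)) * sqrt(sum(step^2))))))
    rev <- acos(min(1, max(-1, sum((-pn) * (-step)) /
                             (sqrt(sum(pn^2)) * sqrt(sum(step^2))))))
    expect_equal(fwd, rev, tolerance = 1e-12)
  }
})

test_that("the behaviour contingency table cross-tabulates correctly", {
  labels <- c(rep("aggregative", 15), rep("neutral", 4), rep("avoidant", 3),
              rep("aggregative", 3), rep("neutral", 6), rep("avoidant", 7))
  identity <- c(rep("conspecific", 22), rep("heterospecific", 16))
  tab <- behaviour_contingency(labels, identity)
  expect_equal(unname(tab), matrix(c(15, 3, 7, 13), 2))
  expect_equal(sum(tab), 38)
  expect_equal(unname(rowSums(tab)), c(22, 16))
  all_agg <- behaviour_contingency(rep("aggregative", 4),
                                   rep(c("conspecific", "heterospecific"), 2))
  expect_equal(unname(all_agg[, "non_aggregative"]), c(0, 0))
  expect_error(behaviour_contingency("aggregative", "stranger"),
               "conspecific")
  expect_error(behaviour_contingency(c("aggregative", NA),
                                     c("conspecific", "conspecific")),
               "missing")
})
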