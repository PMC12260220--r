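#' Signed global growth angle of an aggregative plant
#'
#' The angle between the neighbour direction and the overall horizontal
#' displacement of the root tip from its initial position to the position at
#' which the behaviour was identified. Unlike the hourly angle it is signed:
#' the 2D cross product in the horizontal plane (counter-clockwise positive
#' in the fixed axis order) orients it, so values span (-180, 180] degrees
#' with 0 meaning growth exactly along the inter-plant axis and the boundary
#' case mapped to +180.
#'
#' @param pair a `plant_pair`.
#' @param call a `behaviour_call` for the focal plant (supplies `rp_end`).
#' @param convention a [plane_convention()].
#' @return signed angle in degrees.
#' @export
global_growth_angle <- function(pair, call, convention = plane_convention()) {
  stopifnot(inherits(call, "behaviour_call"))
  pn <- neighbour_vector(pair, convention)
  disp <- (call$rp_end - pair$rp0)[convention$horizontal_idx]
  if (sqrt(sum(disp^2)) == 0)
    stop("zero horizontal displacement: growth angle undefined")
  cross <- unname(pn[1] * disp[2] - pn[2] * disp[1])
  dot <- unname(sum(pn * disp))
  ang <- atan2(cross, dot) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (isTRUE(all.equal(ang, -180))) ang <- 180
  ang
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk test with the input checks
#' the directional analysis needs (3 to 5000 non-constant values).
#'
#' @param values numeric sample.
#' @return list with `W` (statistic) and `p` (p-value).
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk needs 3 to 5000 values")
  if (max(values) == min(values)) stop("constant sample: W undefined")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = unname(st$p.value))
}

#' Chi-squared test of association with Yates' continuity correction
#'
#' For a 2 x 2 contingency table, computes
#' `sum((|O - E| - 0.5)^2 / E)` over the four cells, with expected counts
#' from the marginals and the continuity correction capped at `|O - E|` (a
#' cell already at its expectation contributes nothing), and refers the
#' statistic to the chi-squared distribution with one degree of freedom.
#'
#' @param table 2 x 2 matrix of non-negative counts with positive marginals.
#' @return a `contingency_stat`: list with `table`, `expected`, `statistic`,
#'   `p_value`, `df`.
#' @examples
#' chi_square_yates(matrix(c(15, 3, 7, 13), 2))$statistic  # 7.204
#' @export
chi_square_yates <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal: test undefined")
  e <- outer(rs, cs) / sum(m)
  dev <- abs(m - e)
  stat <- sum((dev - pmin(0.5, dev))^2 / e)
  structure(list(table = m, expected = e, statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L),
            class = "contingency_stat")
}

#' @export
print.contingency_stat <- function(x, ...) {
  cat(sprintf("<contingency_stat> X-squared (Yates) = %.4f, df = 1, p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Directional-growth report for a cohort of social plants
#'
#' Computes the signed global growth angle for every aggregative plant, tests
#' the pooled angles (and each species' angles) for normality with the
#' Shapiro-Wilk test, and tests the association between neighbour identity
#' and aggregative behaviour with the Yates-corrected chi-squared test on all
#' social plants. Histogram counts (default 10 bins over [-180, 180]) and
#' normal QQ points (Blom plotting positions) are included for plotting.
#'
#' @param pairs named list of `plant_pair` objects (names = plant ids).
#' @param calls named list of `behaviour_call` objects, same names.
#' @param info data.frame with `plant_id`, `species`,
#'   `neighbour_species` for every plant in `pairs`.
#' @param convention a [plane_convention()].
#' @param alpha significance level reported alongside the tests.
#' @param bins histogram bin count over [-180, 180].
#' @return a `directional_result`: per-plant angles, pooled and per-species
#'   Shapiro-Wilk results, histogram counts, QQ points, contingency table and
#'   `contingency_stat`.
#' @export
directional_report <- function(pairs, calls, info,
                               convention = plane_convention(),
                               alpha = 0.05, bins = 10) {
  ids <- names(pairs)
  if (!setequal(ids, names(calls)))
    stop("pairs and calls must cover the same plants")
  miss <- setdiff(ids, info$plant_id)
  if (length(miss)) stop("info missing for: ", paste(miss, collapse = ", "))
  info <- info[match(ids, info$plant_id), ]
  labels <- vapply(calls[ids], function(cl) cl$label, character(1))
  identity <- ifelse(info$species == info$neighbour_species,
                     "conspecific", "heterospecific")
  contingency <- behaviour_contingency(labels, identity)
  ctest <- tryCatch(chi_square_yates(contingency), error = function(e) {
    warning("association test skipped: ", conditionMessage(e))
    NULL
  })
  agg <- ids[labels == "aggregative"]
  theta <- vapply(agg, function(id)
    global_growth_angle(pairs[[id]], calls[[id]], convention), numeric(1))
  angles <- data.frame(plant_id = agg,
                       species = info$species[match(agg, info$plant_id)],
                       theta_g = unname(theta), row.names = NULL)
  run_sw <- function(v, what) {
    if (length(v) < 3) {
      warning("fewer than 3 aggregative plants (", what,
              "): normality test skipped")
      return(NULL)
    }
    if (max(v) == min(v)) {
      warning("constant growth angles (", what,
              "): normality test skipped")
      return(NULL)
    }
    shapiro_wilk(v)
  }
  sw_pooled <- run_sw(angles$theta_g, "pooled")
  sw_species <- lapply(split(angles$theta_g, angles$species), function(v)
    if (length(v) >= 3 && max(v) > min(v)) shapiro_wilk(v) else NULL)
  brk <- seq(-180, 180, length.out = bins + 1)
  hist_counts <- if (nrow(angles))
    graphics::hist(angles$theta_g, breaks = brk, plot = FALSE)$counts
  else integer(bins)
  qq <- NULL
  if (nrow(angles) >= 3) {
    v <- sort(angles$theta_g)
    n <- length(v)
    qq <- data.frame(theoretical = stats::qnorm(((1:n) - 3 / 8) / (n + 1 / 4)),
                     sample = v)
  }
  structure(list(angles = angles, shapiro_pooled = sw_pooled,
                 shapiro_by_species = sw_species, alpha = alpha,
                 histogram = list(breaks = brk, counts = hist_counts),
                 qq_points = qq, contingency = contingency,
                 contingency_test = ctest),
            class = "directional_result")
}

#' @export
print.directional_result <- function(x, ...) {
  cat(sprintf("<directional_result> %d aggregative plants\n",
              nrow(x$angles)))
  if (!is.null(x$shapiro_pooled))
    cat(sprintf("  Shapiro-Wilk (pooled): W = %.4f, p = %.4f\n",
                x$shapiro_pooled$W, x$shapiro_pooled$p))
  if (!is.null(x$contingency_test)) print(x$contingency_test)
  invisible(x)
}
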