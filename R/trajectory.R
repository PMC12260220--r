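#' Construct a root-tip trajectory
#'
#' A `root_trajectory` holds the time-stamped 3D path of one primary-root tip:
#' an ordered set of `(t, x, y, z)` samples, in seconds from the first sample
#' and centimetres. The nominal acquisition interval is 180 s (one frame every
#' 3 min), but irregular spacing and gaps are tolerated; gaps longer than
#' 30 min trigger a warning so tracking dropouts are visible.
#'
#' @param time_s numeric vector of timestamps in seconds, strictly increasing.
#'   The first sample defines the time origin; it need not be 0 on input and is
#'   shifted so that `time_s[1] == 0`.
#' @param x,y,z numeric coordinate vectors in cm, same length as `time_s`.
#' @param plant_id character scalar identifying the plant.
#' @param species one of `"maize"`, `"pea"`, `"synthetic"`.
#' @param dt_nominal nominal sampling interval in seconds (default 180).
#' @param metadata optional named list of extra fields (condition, pair id,
#'   initial root length in cm, ...), carried through I/O.
#'
#' @return An object of class `root_trajectory`: a list with elements
#'   `samples` (data.frame `time_s`, `x_cm`, `y_cm`, `z_cm`), `plant_id`,
#'   `species`, `dt_nominal`, `metadata`.
#' @examples
#' tr <- trajectory(time_s = c(0, 180, 360), x = c(0, 0, 0),
#'                  y = c(0, 0.01, 0.02), z = c(0, 0, 0))
#' n_samples(tr)
#' @export
trajectory <- function(time_s, x, y, z, plant_id = "plant",
                       species = c("synthetic", "maize", "pea"),
                       dt_nominal = 180, metadata = list()) {
  species <- match.arg(species)
  time_s <- as.numeric(time_s)
  n <- length(time_s)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("time_s, x, y, z must have equal length")
  if (n < 3L)
    stop("a trajectory needs at least 3 samples (minimum for a turning angle)")
  if (!all(is.finite(time_s)) || !all(is.finite(x)) ||
      !all(is.finite(y)) || !all(is.finite(z)))
    stop("trajectory coordinates and timestamps must be finite")
  if (any(diff(time_s) <= 0))
    stop("timestamps must be strictly increasing")
  time_s <- time_s - time_s[1L]
  gaps <- diff(time_s)
  if (any(gaps > 1800))
    warning(sprintf("trajectory '%s' has %d gap(s) longer than 30 min",
                    plant_id, sum(gaps > 1800)))
  obj <- structure(
    list(samples = data.frame(time_s = time_s, x_cm = as.numeric(x),
                              y_cm = as.numeric(y), z_cm = as.numeric(z)),
         plant_id = as.character(plant_id), species = species,
         dt_nominal = dt_nominal, metadata = metadata),
    class = "root_trajectory")
  obj
}

#' @export
print.root_trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<root_trajectory> %s (%s): %d samples over %.2f h\n",
              x$plant_id, x$species, nrow(s),
              (s$time_s[nrow(s)] - s$time_s[1]) / 3600))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `root_trajectory`.
#' @export
n_samples <- function(traj) nrow(traj$samples)

#' Coordinate matrix of a trajectory
#'
#' @param traj a `root_trajectory`.
#' @return n x 3 numeric matrix with columns `x_cm`, `y_cm`, `z_cm`.
#' @export
coords <- function(traj) {
  as.matrix(traj$samples[, c("x_cm", "y_cm", "z_cm")])
}

#' Sample times of a trajectory
#'
#' @param traj a `root_trajectory`.
#' @return numeric vector of seconds from the first sample.
#' @export
times <- function(traj) traj$samples$time_s

#' Time span of a trajectory in seconds
#' @param traj a `root_trajectory`.
#' @export
span_s <- function(traj) {
  t <- times(traj)
  t[length(t)] - t[1L]
}

#' Axis convention for the vertical and horizontal (interaction) plane
#'
#' Acquisition frames differ in which axis points along gravity. All
#' horizontal-plane quantities (hourly displacements, growth angles, the
#' spectral-entropy signal) are computed in the plane orthogonal to
#' `vertical_axis`, in a fixed axis order so signed angles are reproducible.
#'
#' @param vertical_axis one of `"x"`, `"y"`, `"z"`; default `"y"` (growth
#'   downwards along y, interaction plane spanned by x and z).
#' @return A `plane_convention` object with the vertical axis name, the two
#'   horizontal axis names (in x, y, z order), and their column indices into a
#'   `coords()` matrix.
#' @examples
#' plane_convention("y")$horizontal  # "x" "z"
#' @export
plane_convention <- function(vertical_axis = c("y", "x", "z")) {
  vertical_axis <- match.arg(vertical_axis)
  axes <- c("x", "y", "z")
  horiz <- setdiff(axes, vertical_axis)
  structure(list(vertical = vertical_axis, horizontal = horiz,
                 vertical_idx = match(vertical_axis, axes),
                 horizontal_idx = match(horiz, axes)),
            class = "plane_convention")
}

#' @export
print.plane_convention <- function(x, ...) {
  cat(sprintf("<plane_convention> vertical: %s, horizontal plane: %s-%s\n",
              x$vertical, x$horizontal[1], x$horizontal[2]))
  invisible(x)
}

#' Project trajectory coordinates onto the horizontal plane
#'
#' @param traj a `root_trajectory` or an n x 3 coordinate matrix.
#' @param convention a [plane_convention()].
#' @return n x 2 matrix of horizontal coordinates, columns in fixed axis order.
#' @export
horizontal_coords <- function(traj, convention = plane_convention()) {
  m <- if (inherits(traj, "root_trajectory")) coords(traj) else as.matrix(traj)
  m[, convention$horizontal_idx, drop = FALSE]
}

#' Pair of trajectories grown in the same container
#'
#' Bundles a focal plant and its neighbour with their initial tip positions
#' and the horizontal separation between them. The initial positions are taken
#' from (and checked against) the first samples of the trajectories.
#'
#' @param plant,neighbour `root_trajectory` objects.
#' @param separation centre-to-centre distance between the plants in cm
#'   (default 5). If `NULL`, computed as the horizontal distance between the
#'   initial tips.
#' @param convention a [plane_convention()], used when deriving separation.
#' @return A `plant_pair` object with elements `plant`, `neighbour`, `rp0`,
#'   `rn0` (initial tip 3-vectors, cm) and `separation`.
#' @export
plant_pair <- function(plant, neighbour, separation = 5,
                       convention = plane_convention()) {
  stopifnot(inherits(plant, "root_trajectory"),
            inherits(neighbour, "root_trajectory"))
  rp0 <- coords(plant)[1L, ]
  rn0 <- coords(neighbour)[1L, ]
  if (is.null(separation)) {
    d <- rn0[convention$horizontal_idx] - rp0[convention$horizontal_idx]
    separation <- sqrt(sum(d^2))
  }
  if (!is.numeric(separation) || separation <= 0)
    stop("separation must be a positive distance in cm")
  structure(list(plant = plant, neighbour = neighbour,
                 rp0 = rp0, rn0 = rn0, separation = separation),
            class = "plant_pair")
}

#' @export
print.plant_pair <- function(x, ...) {
  cat(sprintf("<plant_pair> %s vs %s, separation %.2f cm\n",
              x$plant$plant_id, x$neighbour$plant_id, x$separation))
  invisible(x)
}

#' Read a trajectory from a canonical CSV file
#'
#' The canonical on-disk format is a UTF-8 CSV with header
#' `time_s,x_cm,y_cm,z_cm` and one row per sample, optionally accompanied by a
#' JSON sidecar `<name>.meta.json` holding `plant_id`, `species`, `condition`,
#' `neighbour_id`, `separation_cm` and `vertical_axis`. Other column names can
#' be mapped via `col_map` for imported data.
#'
#' @param path path to the CSV file.
#' @param col_map named character vector mapping canonical names
#'   (`time_s`, `x_cm`, `y_cm`, `z_cm`) to the file's column names.
#' @param scale multiplicative factor applied to coordinates (e.g. 0.1 for a
#'   file in mm); sidecar metadata field `scale_to_cm` overrides it.
#' @return a validated `root_trajectory`; sidecar fields land in `$metadata`.
#' @export
read_trajectory <- function(path, col_map = NULL, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  wanted <- c("time_s", "x_cm", "y_cm", "z_cm")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      j <- match(col_map[[nm]], names(df))
      if (is.na(j)) stop("mapped column not found: ", col_map[[nm]])
      names(df)[j] <- nm
    }
  }
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (nm in wanted) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad))
      stop(sprintf("cannot parse column '%s' at data row %d of %s",
                   nm, bad[1L], path))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' of %s", nm, path))
    df[[nm]] <- v
  }
  meta_path <- sidecar_path(path)
  meta <- list()
  if (file.exists(meta_path))
    meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  if (!is.null(meta$scale_to_cm)) scale <- meta$scale_to_cm
  trajectory(time_s = df$time_s,
             x = df$x_cm * scale, y = df$y_cm * scale, z = df$z_cm * scale,
             plant_id = meta$plant_id %||% sub("\\.csv$", "", basename(path)),
             species = meta$species %||% "synthetic",
             dt_nominal = meta$dt_nominal %||% 180,
             metadata = meta[setdiff(names(meta),
                                     c("plant_id", "species", "dt_nominal"))])
}

sidecar_path <- function(path) sub("\\.csv$", ".meta.json", path)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to the canonical CSV plus JSON sidecar
#'
#' @param traj a valid `root_trajectory`.
#' @param path destination CSV path; the metadata sidecar is written next to
#'   it as `<name>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "root_trajectory"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  df <- traj$samples
  # 17 significant digits make the double -> text -> double round trip exact
  lines <- c("time_s,x_cm,y_cm,z_cm",
             sprintf("%.10g,%.17g,%.17g,%.17g",
                     df$time_s, df$x_cm, df$y_cm, df$z_cm))
  writeLines(lines, path, useBytes = TRUE)
  meta <- c(list(plant_id = traj$plant_id, species = traj$species,
                 dt_nominal = traj$dt_nominal), traj$metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Subsample a trajectory to hourly resolution
#'
#' Selects, for each whole hour from 0 to `floor(span/3600)`, the original
#' sample nearest in time to that hour; the result is always a subsequence of
#' the input. Hourly displacement rules operate on this grid.
#'
#' @param traj a `root_trajectory` spanning at least 2 h.
#' @return a `root_trajectory` with `floor(span/3600) + 1` samples.
#' @examples
#' tr <- generate_trajectory(growth_params(duration = 2 * 86400))
#' n_samples(resample_hourly(tr))  # 49
#' @export
resample_hourly <- function(traj) {
  t <- times(traj)
  span <- t[length(t)] - t[1L]
  if (span < 7200) stop("trajectory must span at least 2 h to resample hourly")
  hours <- seq(0, floor(span / 3600)) * 3600
  idx <- vapply(hours, function(h) which.min(abs(t - h)), integer(1))
  idx <- unique(idx)
  m <- coords(traj)
  out <- traj
  out$samples <- data.frame(time_s = t[idx], x_cm = m[idx, 1],
                            y_cm = m[idx, 2], z_cm = m[idx, 3])
  out$metadata$resampled <- "hourly"
  out
}

#' Read a cohort manifest
#'
#' A manifest is a JSON array of records with fields `trajectory_path`,
#' `condition` (one of `individual`, `social_conspecific`,
#' `social_heterospecific`) and `pair_id` (empty for individual plants).
#' Paths are resolved relative to the manifest's directory.
#'
#' @param path manifest JSON path.
#' @return data.frame with one row per plant and a `trajectory` list-column of
#'   `root_trajectory` objects.
#' @export
read_cohort <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!nrow(man)) stop("empty manifest")
  base <- dirname(path)
  man$trajectory <- lapply(man$trajectory_path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_trajectory(full)
  })
  man
}
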