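#' Annotate points with space-time interpolated environmental values
#'
#' Inverse-distance-weighted spatial interpolation (k nearest valid cells,
#' weights d^-p, exact cell-center hits take the cell value) on the layer
#' matching each point's Julian day, with linear temporal interpolation
#' between bracketing layers when no same-date layer exists.
#'
#' @param points data.frame with `x`, `y`, and `date` (Julian day).
#' @param stacks named list of [env_stack()]s (e.g. from [generate_env()]).
#' @param k neighbors per interpolation (default 4).
#' @param p distance-decay power (default 2).
#' @return `points` with one new column per stack variable; points where
#'   every neighbor is missing are dropped with a message.
#' @export
idw_annotate <- function(points, stacks, k = 4, p = 2) {
  out <- points
  for (v in names(stacks))
    out[[v]] <- stack_extract(stacks[[v]], points$x, points$y, points$date,
                              k = k, p = p)
  bad <- !stats::complete.cases(out[names(stacks)])
  if (any(bad)) {
    message(sprintf("idw_annotate: dropping %d point(s) with no valid neighbors", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Simulate null foraging locations by marginal resampling
#'
#' Builds `n` pseudo-foraging points by independently resampling, with
#' replacement, (i) a timestamp, (ii) a colony-bearing angle, and (iii) a
#' colony distance from the observed foraging points' marginal
#' distributions; the position is colony + distance * (cos a, sin a).
#' Independent resampling breaks the joint structure of the observed
#' points, giving a "random chance" landscape null with the same marginal
#' use of times, directions, and ranges. Points falling on land
#' (bathymetry >= 0) are redrawn up to `max_retries` rounds (logged); a
#' `joint = TRUE` switch resamples whole observed rows instead. Points are
#' grouped into pseudo-trips by simulated calendar date.
#'
#' @param foraging_points observed foraging points ([extract_ars()] output):
#'   needs `timestamp`, `x`, `y` (and `date`, `year`; reconstructed from
#'   `timestamp` if absent).
#' @param colony_xy colony coordinates.
#' @param n number of simulated points (default 10000).
#' @param seed integer seed.
#' @param bathy optional bathymetry `env_grid` for the land screen (no
#'   screen when NULL).
#' @param max_retries redraw rounds before giving up on the land screen.
#' @param joint resample observed rows jointly instead of marginally.
#' @return data.frame: `source` = "simulated", `bird_id` = "sim",
#'   `trip_id` (pseudo-trip per date), `timestamp`, `date`, `year`, `x`,
#'   `y`, `dist_m`, `angle_rad`.
#' @export
simulate_null_points <- function(foraging_points, colony_xy, n = 10000,
                                 seed = 1, bathy = NULL, max_retries = 100,
                                 joint = FALSE) {
  fp <- foraging_points
  if (nrow(fp) == 0) stop("at least one observed foraging point required")
  dx <- fp$x - colony_xy[1]; dy <- fp$y - colony_xy[2]
  obs_dist <- sqrt(dx^2 + dy^2)
  obs_ang <- atan2(dy, dx)
  obs_ts <- fp$timestamp
  with_seed(seed, {
    draw <- function(m) {
      if (joint) {
        i <- sample.int(nrow(fp), m, replace = TRUE)
        list(ts = obs_ts[i], d = obs_dist[i], a = obs_ang[i])
      } else {
        list(ts = obs_ts[sample.int(nrow(fp), m, replace = TRUE)],
             d = obs_dist[sample.int(nrow(fp), m, replace = TRUE)],
             a = obs_ang[sample.int(nrow(fp), m, replace = TRUE)])
      }
    }
    g <- draw(n)
    x <- colony_xy[1] + g$d * cos(g$a)
    y <- colony_xy[2] + g$d * sin(g$a)
    ts <- g$ts; d <- g$d; a <- g$a
    if (!is.null(bathy)) {
      for (r in seq_len(max_retries)) {
        b <- grid_value_at(bathy, x, y)
        land <- !is.na(b) & b >= 0
        if (!any(land)) break
        m <- sum(land)
        gg <- draw(m)
        x[land] <- colony_xy[1] + gg$d * cos(gg$a)
        y[land] <- colony_xy[2] + gg$d * sin(gg$a)
        ts[land] <- gg$ts; d[land] <- gg$d; a[land] <- gg$a
      }
      b <- grid_value_at(bathy, x, y)
      left <- sum(!is.na(b) & b >= 0)
      if (left > 0)
        message(sprintf("simulate_null_points: %d point(s) still on land after %d redraw rounds", left, max_retries))
    }
    data.frame(
      source = "simulated", bird_id = "sim",
      trip_id = paste0("sim_", format(ts, "%Y-%m-%d", tz = "UTC")),
      timestamp = ts, date = julian_day(ts),
      year = as.integer(format(ts, "%Y", tz = "UTC")),
      x = x, y = y, dist_m = d, angle_rad = a
    )
  })
}

#' Project cross-validated suitability onto annotated points
#'
#' @param points annotated points carrying the model's covariate columns.
#' @param cv a [maxent_cv()] fit (its averaged cloglog projection is used).
#' @return `points` with a `suitability` column in (0, 1).
#' @export
project_suitability <- function(points, cv) {
  vars <- cv$models[[1]]$features$vars
  miss <- setdiff(vars, names(points))
  if (length(miss) > 0)
    stop(sprintf("points lack annotated variable(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(!stats::complete.cases(points[vars])))
    stop("unannotated (NA) covariate values: annotate points first")
  points$suitability <- predict(cv, points[vars])
  points
}

#' Trip-mean foraging habitat quality
#'
#' Averages projected suitability within each trip (or pseudo-trip), the
#' analysis response variable; trip-level averaging absorbs the strong
#' within-trip autocorrelation of point suitabilities. Means of exactly 0
#' or 1 are nudged into the open interval with the standard
#' (S (n-1) + 0.5) / n compression (n = number of trips) and flagged.
#'
#' @param points points with `suitability`, `trip_id`, `bird_id`, `date`,
#'   `year`, and optionally `source` ("observed" assumed if absent).
#' @return data.frame, one row per trip: `group`, `year`, `julian_day`,
#'   `bird_id`, `trip_id`, `n_points`, `S`, `boundary_nudged`.
#' @export
trip_mean_quality <- function(points) {
  if (!"source" %in% names(points)) points$source <- "observed"
  sp <- split(points, points$trip_id)
  sp <- sp[vapply(sp, nrow, integer(1)) > 0]
  rows <- lapply(sp, function(tr) data.frame(
    group = tr$source[1], year = tr$year[1], julian_day = tr$date[1],
    bird_id = tr$bird_id[1], trip_id = tr$trip_id[1],
    n_points = nrow(tr), S = mean(tr$suitability)
  ))
  out <- do.call(rbind, rows)
  n <- nrow(out)
  out$boundary_nudged <- out$S <= 0 | out$S >= 1
  out$S[out$boundary_nudged] <- (out$S[out$boundary_nudged] * (n - 1) + 0.5) / n
  rownames(out) <- NULL
  out
}
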