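#' Synthetic study scenario
#'
#' Describes the planar domain, grid resolution, season, and colony location
#' used by all synthetic generators. Coordinates are projected meters. The
#' default domain is a 60 x 40 km coastal shelf with land along the northern
#' edge and the breeding colony on a small island just off the coast,
#' mimicking a barrier-island seabird colony fronting open water.
#'
#' @param width,height domain size (m).
#' @param cellsize grid cell edge (m).
#' @param days inclusive Julian-day span of the season (integer vector).
#' @param colony_xy colony coordinates c(x, y), must lie inside the domain.
#' @param coast_y y coordinate of the land-sea boundary (m); cells north of
#'   it are land.
#' @return object of class `env_scenario`.
#' @export
env_scenario <- function(width = 60000, height = 40000, cellsize = 1000,
                         days = 120:200, colony_xy = c(30000, 35500),
                         coast_y = 36000) {
  if (width <= cellsize || height <= cellsize)
    stop("degenerate extent: domain must span more than one cell per axis")
  if (colony_xy[1] < 0 || colony_xy[1] > width ||
      colony_xy[2] < 0 || colony_xy[2] > height)
    stop("colony_xy must lie inside the domain extent")
  structure(list(width = width, height = height, cellsize = cellsize,
                 days = as.integer(days), colony_xy = colony_xy,
                 coast_y = coast_y),
            class = "env_scenario")
}

#' Ground-truth parameters of the synthetic world
#'
#' Controls the shape of the true prey-suitability surface and the two-mode
#' (transit / area-restricted search) movement model. Defaults encode a
#' menhaden-like prey response: a sharp thermal rise of suitability between
#' 30 and 32 degC, a chlorophyll-a plateau at 10 mg/m^3 and above, and weak
#' unimodal salinity and depth optima. `improvement_rate` is the per-day
#' relative growth of chlorophyll patch amplitude, which drives a
#' season-long increase in the area of high-suitability habitat.
#'
#' @param sst_rise_range degC interval of the steep suitability increase.
#' @param chla_plateau mg/m^3 value at and above which the chlorophyll
#'   response is flat.
#' @param sal_opt,sal_sd optimum and width (PSU) of the weak salinity response.
#' @param bathy_opt,bathy_sd optimum and width (m, negative = depth) of the
#'   weak bathymetry response.
#' @param patch_count number of chlorophyll patches.
#' @param patch_scale patch Gaussian radius (m).
#' @param patch_amp peak log-amplitude of a patch at season start.
#' @param chla_base background chlorophyll (mg/m^3).
#' @param improvement_rate per-day relative amplitude growth (1/day).
#' @param drift_speed patch centroid drift speed (m/day).
#' @param sst_start degC spatial-mean sea surface temperature on the first
#'   season day.
#' @param sst_rate degC/day seasonal warming rate.
#' @param transit_speed,ars_speed movement speeds (m/s).
#' @param ars_turn_sd turning-angle SD (radians) inside an ARS bout; transit
#'   headings are nearly straight.
#' @param ars_radius ARS patch confinement radius (m).
#' @param fix_interval GPS fix interval (s).
#' @param daylight clock interval c(start_hour, end_hour) of tag activity.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(sst_rise_range = c(30, 32), chla_plateau = 10,
                         sal_opt = 32, sal_sd = 4,
                         bathy_opt = -20, bathy_sd = 30,
                         patch_count = 6, patch_scale = 4000,
                         patch_amp = 2.2, chla_base = 1.5,
                         improvement_rate = 0.012, drift_speed = 150,
                         sst_start = 27, sst_rate = 0.09,
                         transit_speed = 10, ars_speed = 0.8,
                         ars_turn_sd = 2.0, ars_radius = 1000,
                         fix_interval = 900, daylight = c(6, 20)) {
  p <- list(sst_rise_range = sst_rise_range, chla_plateau = chla_plateau,
            sal_opt = sal_opt, sal_sd = sal_sd,
            bathy_opt = bathy_opt, bathy_sd = bathy_sd,
            patch_count = patch_count, patch_scale = patch_scale,
            patch_amp = patch_amp, chla_base = chla_base,
            improvement_rate = improvement_rate, drift_speed = drift_speed,
            sst_start = sst_start, sst_rate = sst_rate,
            transit_speed = transit_speed, ars_speed = ars_speed,
            ars_turn_sd = ars_turn_sd, ars_radius = ars_radius,
            fix_interval = fix_interval, daylight = daylight)
  pos <- c("chla_plateau", "sal_sd", "bathy_sd", "patch_count", "patch_scale",
           "improvement_rate", "transit_speed", "ars_speed", "ars_turn_sd",
           "ars_radius", "fix_interval")
  for (nm in pos) if (p[[nm]] <= 0) stop(sprintf("%s must be positive", nm))
  structure(p, class = "truth_params")
}

#' True prey suitability (closed form)
#'
#' Product of per-variable responses: a logistic ramp in sea surface
#' temperature centered on `sst_rise_range`, a linear chlorophyll-a response
#' saturating (flat) at `chla_plateau`, and weak Gaussian-bump responses in
#' salinity and bathymetry scaled to \[0.8, 1\]. Land (bathy >= 0) has
#' suitability 0. Vectorized; output clamped to \[0, 1\].
#'
#' @param sst,chla,sal,bathy environmental values (vectorized).
#' @param truth a [truth_params()] object.
#' @return suitability in \[0, 1\].
#' @export
true_suitability <- function(sst, chla, sal, bathy, truth) {
  mid <- mean(truth$sst_rise_range)
  scl <- diff(truth$sst_rise_range) / 8  # +-4 logistic scales span the rise
  f_sst <- stats::plogis((sst - mid) / scl)
  f_chla <- pmin(chla, truth$chla_plateau) / truth$chla_plateau
  f_sal <- 0.8 + 0.2 * exp(-0.5 * ((sal - truth$sal_opt) / truth$sal_sd)^2)
  f_bat <- 0.8 + 0.2 * exp(-0.5 * ((bathy - truth$bathy_opt) / truth$bathy_sd)^2)
  s <- f_sst * f_chla * f_sal * f_bat
  s[bathy >= 0] <- 0
  pmin(pmax(s, 0), 1)
}

# bathymetry surface: shelf sloping from the northern coast (~2 m per km
# offshore), a small island bump at the colony, a gentle alongshore ripple
synth_bathy <- function(scenario, x, y) {
  depth <- (y - scenario$coast_y) * 0.002
  ripple <- 0.6 * sin(x / 9000)
  d2 <- (x - scenario$colony_xy[1])^2 + (y - scenario$colony_xy[2])^2
  island <- 4 * exp(-d2 / (2 * 500^2))
  depth + island + ripple
}

#' Generate the synthetic environmental stacks
#'
#' Builds one date-indexed [env_stack()] per variable (sst, chla, sal,
#' bathy) over the scenario's season. Sea surface temperature warms smoothly
#' at `sst_rate` degC/day on a mild north-south spatial gradient, crossing
#' the suitability rise interval mid-season. Chlorophyll-a is a patchy
#' lognormal field: Gaussian patches in log space whose centroids drift at
#' `drift_speed` m/day and whose amplitude grows at `improvement_rate`, so
#' the fraction of high-suitability cells is nondecreasing over the season.
#' Salinity is a smooth static coastal gradient; bathymetry is static.
#'
#' @param scenario an [env_scenario()].
#' @param truth a [truth_params()].
#' @param seed integer seed; identical inputs give bit-identical stacks.
#' @return named list of `env_stack`s: `sst`, `chla`, `sal`, `bathy`.
#' @export
generate_env <- function(scenario, truth, seed) {
  nx <- as.integer(scenario$width / scenario$cellsize)
  ny <- as.integer(scenario$height / scenario$cellsize)
  if (nx <= 1L || ny <= 1L)
    stop("degenerate extent: need more than one cell per axis")
  cs <- scenario$cellsize
  cx <- (seq_len(nx) - 0.5) * cs
  cy <- (seq_len(ny) - 0.5) * cs
  X <- matrix(cx, ny, nx, byrow = TRUE)
  Y <- matrix(cy, ny, nx)
  days <- scenario$days
  t0 <- days[1L]

  bathy_m <- synth_bathy(scenario, X, Y)
  water <- bathy_m < 0

  with_seed(seed, {
    # patch centroids start in water, drift with a random per-patch bearing
    idx <- which(water)
    ctr <- idx[sample.int(length(idx), truth$patch_count)]
    px0 <- X[ctr]; py0 <- Y[ctr]
    ang <- stats::runif(truth$patch_count, 0, 2 * pi)
    vx <- truth$drift_speed * cos(ang)
    vy <- truth$drift_speed * sin(ang)
    # static smooth log-scale noise so chla is not exactly closed-form
    noise <- 0.15 * sin(X / 7000 + stats::runif(1, 0, 2 * pi)) *
      cos(Y / 5000 + stats::runif(1, 0, 2 * pi))
    sst_phase <- stats::runif(1, 0, 2 * pi)

    sst_g <- list(); chla_g <- list(); sal_g <- list(); bathy_g <- list()
    # fresher near the coast (estuarine outflow), saltier offshore
    sal_m <- 36 - 8 * exp(-(scenario$coast_y - Y) / 20000) +
      0.3 * sin(X / 11000)
    for (i in seq_along(days)) {
      d <- days[i]
      dt <- d - t0
      sst_m <- truth$sst_start + truth$sst_rate * dt +
        0.8 * (Y - mean(cy)) / scenario$height +
        0.4 * sin(X / 12000 + sst_phase)
      amp <- truth$patch_amp * exp(truth$improvement_rate * dt)
      lg <- log(truth$chla_base) + noise
      for (k in seq_len(truth$patch_count)) {
        pxk <- px0[k] + vx[k] * dt
        pyk <- py0[k] + vy[k] * dt
        # reflect drifting centroids at the domain walls
        pxk <- abs(pxk); pxk <- scenario$width - abs(scenario$width - pxk)
        pyk <- abs(pyk); pyk <- scenario$height - abs(scenario$height - pyk)
        d2 <- (X - pxk)^2 + (Y - pyk)^2
        lg <- lg + amp * exp(-d2 / (2 * truth$patch_scale^2))
      }
      chla_m <- exp(lg)
      sst_g[[i]] <- env_grid(sst_m, 0, 0, cs)
      chla_g[[i]] <- env_grid(chla_m, 0, 0, cs)
      sal_g[[i]] <- env_grid(sal_m, 0, 0, cs)
      bathy_g[[i]] <- env_grid(bathy_m, 0, 0, cs)
    }
    list(sst = env_stack(sst_g, days, "sst"),
         chla = env_stack(chla_g, days, "chla"),
         sal = env_stack(sal_g, days, "sal"),
         bathy = env_stack(bathy_g, days, "bathy"))
  })
}

# nearest-cell environmental values at points for one date
env_at <- function(stacks, x, y, date) {
  i <- match(as.integer(date), stacks$sst$dates)
  if (anyNA(i)) stop("date outside generated stack range")
  list(
    sst = grid_value_at(stacks$sst$grids[[i[1L]]], x, y),
    chla = grid_value_at(stacks$chla$grids[[i[1L]]], x, y),
    sal = grid_value_at(stacks$sal$grids[[i[1L]]], x, y),
    bathy = grid_value_at(stacks$bathy$grids[[i[1L]]], x, y)
  )
}

# suitability grid (matrix) for one date; land = 0
suitability_grid <- function(stacks, truth, date) {
  i <- match(as.integer(date), stacks$sst$dates)
  true_suitability(stacks$sst$grids[[i]]$values,
                   stacks$chla$grids[[i]]$values,
                   stacks$sal$grids[[i]]$values,
                   stacks$bathy$grids[[i]]$values, truth)
}

#' Sample prey presence points by thinning
#'
#' Draws candidate (date, x, y) points uniformly over the season and domain
#' and accepts each with probability equal to the true suitability at that
#' point and date, so presence density is proportional to suitability.
#'
#' @param stacks output of [generate_env()].
#' @param truth a [truth_params()].
#' @param n number of presences (>= 0).
#' @param seed integer seed.
#' @param max_tries candidate draws allowed per accepted point before the
#'   sampler aborts (guards a suitability surface that is zero everywhere).
#' @return data.frame with columns `date` (Julian day), `x`, `y`.
#' @export
sample_prey_presences <- function(stacks, truth, n, seed, max_tries = 2000) {
  if (n == 0)
    return(data.frame(date = integer(), x = numeric(), y = numeric()))
  if (n < 0) stop("n must be >= 0")
  g1 <- stacks$sst$grids[[1L]]
  xmax <- grid_xmax(g1); ymax <- grid_ymax(g1)
  days <- stacks$sst$dates
  with_seed(seed, {
    out_d <- integer(0); out_x <- numeric(0); out_y <- numeric(0)
    tries <- 0L
    while (length(out_x) < n) {
      m <- max(2L * (n - length(out_x)), 100L)
      tries <- tries + 1L
      if (tries > max_tries)
        stop("suitability appears to be zero everywhere: sampling failed")
      d <- days[sample.int(length(days), m, replace = TRUE)]
      x <- stats::runif(m, 0, xmax)
      y <- stats::runif(m, 0, ymax)
      s <- numeric(m)
      for (dd in unique(d)) {
        sel <- d == dd
        e <- env_at(stacks, x[sel], y[sel], dd)
        s[sel] <- true_suitability(e$sst, e$chla, e$sal, e$bathy, truth)
      }
      keep <- stats::runif(m) < s
      out_d <- c(out_d, d[keep]); out_x <- c(out_x, x[keep])
      out_y <- c(out_y, y[keep])
    }
    data.frame(date = out_d[seq_len(n)], x = out_x[seq_len(n)],
               y = out_y[seq_len(n)])
  })
}

#' Simulate central-place forager tracks
#'
#' Per bird and tracking day, one round trip from the colony: outbound
#' transit (fast, nearly straight) to a destination cell drawn with
#' probability proportional to suitability^preference(day) over water cells,
#' an area-restricted search bout (slow, tortuous, confined within
#' `ars_radius` of the destination), and return transit. Fixes are emitted
#' every `fix_interval` seconds inside the daylight window, including
#' stationary colony fixes before departure and after return, so trips can
#' be re-segmented from the fix table alone. An increasing `preference`
#' produces a season-long improvement of occupied patch quality relative to
#' the landscape.
#'
#' @param scenario an [env_scenario()].
#' @param truth a [truth_params()].
#' @param n_birds number of birds (>= 1).
#' @param days Julian days to simulate (defaults to the scenario season).
#' @param preference function(day) -> nonnegative exponent on suitability
#'   when drawing destinations; `function(day) 0` gives uniform use of water.
#' @param seed integer seed.
#' @param stacks environmental stacks (generated from `seed` if missing).
#' @param year calendar year used to build timestamps.
#' @param ars_minutes mean ARS bout duration (minutes).
#' @return data.frame of fixes: `bird_id`, `timestamp` (POSIXct UTC), `x`,
#'   `y`, plus ground-truth columns `state` ("colony", "transit", "ars") and
#'   `dest_x`, `dest_y` (the trip's true patch center; NA at the colony).
#' @export
simulate_tracks <- function(scenario, truth, n_birds, days = scenario$days,
                            preference = function(day) 0, seed = 1,
                            stacks = NULL, year = 2014, ars_minutes = 150) {
  if (n_birds < 1) stop("n_birds must be >= 1")
  cxy <- scenario$colony_xy
  if (cxy[1] < 0 || cxy[1] > scenario$width ||
      cxy[2] < 0 || cxy[2] > scenario$height)
    stop("colony outside extent")
  if (is.null(stacks)) stacks <- generate_env(scenario, truth, seed)
  g1 <- stacks$bathy$grids[[1L]]
  water <- g1$values < 0
  ctr <- grid_centers(g1)
  wx <- matrix(ctr$x, nrow(water), ncol(water), byrow = TRUE)[water]
  wy <- matrix(ctr$y, nrow(water), ncol(water))[water]
  fi <- truth$fix_interval
  day0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")

  with_seed(seed, {
    rows <- vector("list", n_birds * length(days))
    ri <- 0L
    for (b in seq_len(n_birds)) {
      bid <- sprintf("b%02d", b)
      for (d in days) {
        s_grid <- suitability_grid(stacks, truth, d)
        sv <- s_grid[water]
        pref <- preference(d)
        w <- if (pref <= 0) rep(1, length(sv)) else pmax(sv, 1e-12)^pref
        cell <- sample.int(length(sv), 1L, prob = w)
        dest <- c(wx[cell], wy[cell]) +
          stats::runif(2, -scenario$cellsize / 2, scenario$cellsize / 2)

        # continuous timed waypoint path for the day, then sampled exactly
        # on the fix-interval lattice inside the daylight window
        dawn <- truth$daylight[1] * 3600
        dusk <- truth$daylight[2] * 3600
        t_start <- dawn + fi * sample(1:4, 1)    # depart within ~1 h of dawn
        n_ars <- max(3L, stats::rpois(1, ars_minutes * 60 / fi))
        dist_out <- sqrt(sum((dest - cxy)^2))
        t_arr <- t_start + dist_out / truth$transit_speed
        ars_xy <- ars_path(dest, n_ars, truth$ars_speed * fi,
                           truth$ars_turn_sd, truth$ars_radius)
        t_dep <- t_arr + n_ars * fi
        dist_back <- sqrt(sum((ars_xy[n_ars, ] - cxy)^2))
        t_home <- t_dep + dist_back / truth$transit_speed
        if (t_home > dusk - 2 * fi) next         # trip would overrun dusk

        out_w <- transit_waypoints(cxy, dest, fi, t_start, t_arr)
        ret_w <- transit_waypoints(ars_xy[n_ars, ], cxy, fi, t_dep, t_home)
        wpt <- c(dawn, t_start, out_w$t, t_arr + fi * seq_len(n_ars),
                 ret_w$t, dusk)
        wpx <- c(cxy[1], cxy[1], out_w$x, ars_xy[, 1], ret_w$x, cxy[1])
        wpy <- c(cxy[2], cxy[2], out_w$y, ars_xy[, 2], ret_w$y, cxy[2])

        tt <- seq(dawn, dusk, by = fi)
        px <- stats::approx(wpt, wpx, xout = tt)$y
        py <- stats::approx(wpt, wpy, xout = tt)$y
        # clamp to the domain (patches may abut the boundary)
        px <- pmin(pmax(px, 1), scenario$width - 1)
        py <- pmin(pmax(py, 1), scenario$height - 1)
        st <- ifelse(tt <= t_start | tt >= t_home, "colony",
              ifelse(tt >= t_arr & tt <= t_dep, "ars", "transit"))
        at_col <- st == "colony"
        px[at_col] <- px[at_col] + stats::rnorm(sum(at_col), 0, 15)
        py[at_col] <- py[at_col] + stats::rnorm(sum(at_col), 0, 15)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          bird_id = bid,
          timestamp = day0 + (d - 1) * 86400 + tt,
          x = px, y = py, state = st,
          dest_x = ifelse(at_col, NA_real_, dest[1]),
          dest_y = ifelse(at_col, NA_real_, dest[2])
        )
      }
    }
    out <- do.call(rbind, rows[seq_len(ri)])
    rownames(out) <- NULL
    out
  })
}

# straight transit waypoints every fix interval of travel, with cross-track
# noise vanishing at both endpoints; excludes the start point (time t0),
# includes the arrival (time t1)
transit_waypoints <- function(from, to, fix_interval, t0, t1) {
  dur <- t1 - t0
  dist <- sqrt(sum((to - from)^2))
  frac <- seq_len(max(0L, floor(dur / fix_interval))) * fix_interval / dur
  frac <- frac[frac < 1 - 1e-9]
  x <- from[1] + frac * (to[1] - from[1])
  y <- from[2] + frac * (to[2] - from[2])
  amp <- 80 * sin(pi * frac) * stats::rnorm(length(frac), 0, 1)
  perp <- c(-(to[2] - from[2]), to[1] - from[1]) / max(dist, 1)
  list(t = c(t0 + frac * dur, t1),
       x = c(x + amp * perp[1], to[1]),
       y = c(y + amp * perp[2], to[2]))
}

# confined correlated random walk: slow steps, wide turning angles,
# reflected back toward the center when it leaves the patch radius
ars_path <- function(center, n, step, turn_sd, radius) {
  xy <- matrix(NA_real_, n, 2)
  pos <- center
  heading <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n)) {
    heading <- heading + stats::rnorm(1, 0, turn_sd)
    cand <- pos + step * c(cos(heading), sin(heading))
    r <- sqrt(sum((cand - center)^2))
    if (r > radius) {
      heading <- atan2(center[2] - pos[2], center[1] - pos[1]) +
        stats::rnorm(1, 0, 0.5)
      cand <- pos + step * c(cos(heading), sin(heading))
      r <- sqrt(sum((cand - center)^2))
      if (r > radius) cand <- center + (cand - center) * (radius / r)
    }
    pos <- cand
    xy[i, ] <- pos
  }
  xy
}

#' Generate bird metadata
#'
#' Sex, body mass, and tarsus length for `n_birds` individuals. Mass is
#' drawn uniformly within `mass_range`; tarsus follows the cubic allometry
#' `mass = a * tarsus^3` with lognormal noise of SD `noise_sd` on the log
#' scale. `noise_sd = 0` gives exact cubic allometry (a degenerate control
#' for body-condition standardization).
#'
#' @param n_birds number of birds (>= 1).
#' @param seed integer seed.
#' @param mass_range g, inclusive.
#' @param noise_sd lognormal SD of the allometric residual.
#' @param allom_a allometric constant (g / mm^3).
#' @return data.frame: `bird_id`, `sex` ("F"/"M"), `mass_g`, `tarsus_mm`.
#' @export
generate_bird_metadata <- function(n_birds, seed, mass_range = c(2600, 4330),
                                   noise_sd = 0.04, allom_a = 5e-3) {
  if (n_birds <= 0) stop("n_birds must be positive")
  with_seed(seed, {
    mass <- stats::runif(n_birds, mass_range[1], mass_range[2])
    tarsus <- (mass / allom_a)^(1 / 3) *
      exp(stats::rnorm(n_birds, 0, noise_sd))
    data.frame(
      bird_id = sprintf("b%02d", seq_len(n_birds)),
      sex = sample(rep_len(c("F", "M"), n_birds)),
      mass_g = mass,
      tarsus_mm = tarsus
    )
  })
}
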