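# Independent brute-force oracles used across the suite. These never call
# the implementation paths they are checking.

# FPT by walking the piecewise-linear path at 1 s resolution: positions are
# interpolated on a fine time lattice and the first crossing of the circle
# is located by direct scan.
walk_fpt_oracle <- function(x, y, t, radius, res = 1) {
  t <- as.numeric(t)
  # the walker visits every lattice time and every vertex it walks through
  tt <- sort(unique(c(seq(min(t), max(t), by = res), t)))
  px <- approx(t, x, xout = tt)$y
  py <- approx(t, y, xout = tt)$y
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sqrt((px - x[i])^2 + (py - y[i])^2)
    ti <- t[i]
    fwd <- which(d >= radius & tt >= ti)
    bwd <- which(d >= radius & tt <= ti)
    if (length(fwd) == 0 || length(bwd) == 0) next
    out[i] <- tt[fwd[1]] - tt[bwd[length(bwd)]]
  }
  out
}

# random zig-zag toy track with irregular step durations
random_toy_track <- function(n = 25, seed = 1) {
  set.seed(seed)
  ang <- cumsum(runif(n - 1, -2.5, 2.5))
  step <- runif(n - 1, 50, 600)
  x <- c(0, cumsum(step * cos(ang)))
  y <- c(0, cumsum(step * sin(ang)))
  dt <- runif(n - 1, 30, 400)
  t <- c(0, cumsum(dt))
  list(x = x, y = y, t = t)
}

# exhaustive-neighbor IDW: every finite cell, no k cutoff
idw_all_cells_oracle <- function(g, x, y, p = 2) {
  ctr <- grid_centers(g)
  cx <- rep(ctr$x, each = nrow(g$values))
  cy <- rep(ctr$y, times = ncol(g$values))
  v <- as.vector(g$values)
  ok <- is.finite(v)
  vapply(seq_along(x), function(i) {
    d <- sqrt((cx[ok] - x[i])^2 + (cy[ok] - y[i])^2)
    if (any(d < 1e-9)) return(v[ok][which(d < 1e-9)[1]])
    w <- d^(-p)
    sum(w * v[ok]) / sum(w)
  }, numeric(1))
}

# two-sample Kolmogorov-Smirnov distance and the large-sample critical
# value at level alpha (ties-safe: computed directly from the ECDFs)
ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}
ks_critical <- function(n, m, alpha = 0.01) {
  c_a <- sqrt(-0.5 * log(alpha / 2))
  c_a * sqrt((n + m) / (n * m))
}

# build a small raw-fix table around a colony: segments of away positions
# bracketed (or not) by colony fixes, at 15-min spacing
make_fix_table <- function(bird = "b1", day = "2014-06-01", colony = c(0, 0),
                           pattern, away_xy = c(5000, 0)) {
  # pattern: character vector of "C" (colony) / "A" (away)
  n <- length(pattern)
  ts <- as.POSIXct(paste(day, "08:00:00"), tz = "UTC") + 900 * seq_len(n)
  at <- pattern == "A"
  jitter <- seq_len(n) * 10
  data.frame(
    bird_id = bird, timestamp = ts,
    x = ifelse(at, away_xy[1] + jitter, colony[1]),
    y = ifelse(at, away_xy[2], colony[2])
  )
}

# a compact synthetic world shared by several tests (cached per session)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- env_scenario(days = seq(150, 190, by = 5))
      tr <- truth_params()
      st <- generate_env(sc, tr, 42)
      cache <<- list(scenario = sc, truth = tr, stacks = st)
    }
    cache
  }
})

# constant-environment stacks whose true suitability is exactly `values`
# on a left/right split of the domain (single date). All non-chla
# responses are pinned to their maxima so suitability = chla / plateau.
two_level_stacks <- function(truth, left_s = 0.2, right_s = 0.8, date = 150L) {
  nx <- 40; ny <- 20; cs <- 1000
  sst <- matrix(60, ny, nx)                      # far above the rise: ramp ~ 1
  sal <- matrix(truth$sal_opt, ny, nx)
  bathy <- matrix(truth$bathy_opt, ny, nx)
  chla <- matrix(truth$chla_plateau * left_s, ny, nx)
  chla[, (nx / 2 + 1):nx] <- truth$chla_plateau * right_s
  mk <- function(m, v) env_stack(list(env_grid(m, 0, 0, cs)), date, v)
  list(sst = mk(sst, "sst"), chla = mk(chla, "chla"),
       sal = mk(sal, "sal"), bathy = mk(bathy, "bathy"))
}
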