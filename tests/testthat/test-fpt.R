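ts0 <- as.POSIXct("2014-06-01 08:00:00", tz = "UTC")

# constant-speed straight track: n points every `dx` m at speed v m/s
straight_track <- function(n = 51, dx = 200, v = 2) {
  list(x = seq(0, by = dx, length.out = n), y = rep(0, n),
       t = ts0 + seq(0, by = dx / v, length.out = n))
}

test_that("straight constant-speed track gives interior FPT = 2r/v exactly", {
  tr <- straight_track(n = 51, dx = 200, v = 2)
  for (r in c(400, 1000, 2500)) {
    f <- first_passage_time(tr$x, tr$y, tr$t, r)
    interior <- which(tr$x > r & tr$x < max(tr$x) - r)
    expect_equal(f[interior], rep(2 * r / 2, length(interior)),
                 tolerance = 1e-9)
    # log-FPT variance collapses to zero over interior points
    expect_equal(var(log(f[interior])), 0, tolerance = 1e-12)
  }
})

test_that("points whose circle is never exited in one direction are undefined", {
  tr <- straight_track(n = 5, dx = 100, v = 2)  # 400 m track
  f <- first_passage_time(tr$x, tr$y, tr$t, 450)
  expect_true(all(is.na(f)))                    # radius exceeds whole track
  f2 <- first_passage_time(tr$x, tr$y, tr$t, 150)
  expect_true(is.na(f2[1]))                     # backward exit impossible
  expect_false(is.na(f2[3]))
  expect_error(first_passage_time(tr$x, tr$y, tr$t, -5), "positive")
})

test_that("segment-intersection FPT matches the 1 s walking oracle on toy tracks", {
  for (s in 1:12) {
    tk <- random_toy_track(n = 20, seed = s)
    r <- runif(1, 150, 900)
    got <- first_passage_time(tk$x, tk$y, tk$t, r)
    want <- walk_fpt_oracle(tk$x, tk$y, tk$t, r)
    expect_equal(is.na(got), is.na(want))
    ok <- !is.na(got)
    expect_true(all(abs(got[ok] - want[ok]) <= 2))
  }
})

test_that("FPT is nondecreasing in radius at every defined point", {
  tk <- random_toy_track(n = 30, seed = 77)
  radii <- seq(100, 1500, by = 100)
  m <- cpforage:::trip_fpt_matrix(tk$x, tk$y, tk$t, radii)
  for (i in seq_len(nrow(m))) {
    v <- m[i, !is.na(m[i, ])]
    if (length(v) > 1) expect_true(all(diff(v) >= -1e-9))
  }
})

test_that("the all-radii matrix agrees with the single-radius path", {
  tk <- random_toy_track(n = 25, seed = 5)
  radii <- c(200, 500, 1100)
  m <- cpforage:::trip_fpt_matrix(tk$x, tk$y, tk$t, radii)
  for (j in seq_along(radii))
    expect_equal(m[, j], first_passage_time(tk$x, tk$y, tk$t, radii[j]))
})

make_trips_df <- function(tracks) {
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    tk <- tracks[[i]]
    data.frame(bird_id = tk$bird %||% "b1", trip_id = paste0("t", i),
               seq = seq_along(tk$x), x = tk$x, y = tk$y,
               time = ts0 + tk$t, arc = NA_real_, date = 152L, year = 2014L)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the default radius grid evaluates 50 candidate scales", {
  tk <- random_toy_track(n = 60, seed = 2)
  trips <- make_trips_df(list(tk))
  prof <- scale_profile(trips)
  expect_equal(sort(unique(prof$radius)), seq(100, 5000, by = 100))
  expect_equal(nrow(prof), 50)
})

test_that("scale profile equals a direct recomputation from per-point FPT", {
  tk1 <- random_toy_track(n = 40, seed = 3)
  tk2 <- random_toy_track(n = 35, seed = 4)
  trips <- make_trips_df(list(tk1, tk2))
  radii <- c(300, 600, 1200)
  prof <- scale_profile(trips, radii)
  for (r in radii) {
    f <- c(first_passage_time(tk1$x, tk1$y, tk1$t, r),
           first_passage_time(tk2$x, tk2$y, tk2$t, r))
    f <- f[!is.na(f)]
    want <- if (length(f) >= 2) var(log(f)) else NA_real_
    expect_equal(prof$var_log_fpt[prof$radius == r], want)
  }
})

test_that("identical FPT values at a radius give zero variance", {
  tr <- straight_track(n = 61, dx = 100, v = 2)
  trips <- make_trips_df(list(list(x = tr$x, y = tr$y,
                                   t = as.numeric(tr$t) - as.numeric(ts0))))
  prof <- scale_profile(trips, c(500, 1000))
  expect_equal(prof$var_log_fpt, c(0, 0), tolerance = 1e-12)
})

test_that("scale selection takes the argmax of the across-bird mean profile", {
  mk_prof <- function(bird, peak) {
    r <- seq(100, 5000, by = 100)
    data.frame(bird_id = bird, radius = r,
               var_log_fpt = exp(-((r - peak) / 800)^2), n_defined = 100L)
  }
  p1 <- mk_prof("b1", 1400)
  class(p1) <- c("fpt_profile", "data.frame")
  expect_equal(select_scale(p1), 1400)
  # two identical birds: averaging leaves the optimum unchanged
  p2 <- rbind(mk_prof("b1", 1400), mk_prof("b2", 1400))
  class(p2) <- c("fpt_profile", "data.frame")
  expect_equal(select_scale(p2), 1400)
  # alternative rule: largest per-bird argmax
  p3 <- rbind(mk_prof("b1", 1000), mk_prof("b2", 2000))
  class(p3) <- c("fpt_profile", "data.frame")
  expect_equal(select_scale(p3, "per_bird_max"), 2000)
  p1$var_log_fpt <- NA_real_
  expect_error(select_scale(p1), "no radius")
})

test_that("90th-percentile extraction retains the expected points", {
  # 100 distinct FPT values on one bird: exactly 10 retained
  set.seed(8)
  tracks <- lapply(1:4, function(i) random_toy_track(n = 26, seed = 100 + i))
  trips <- make_trips_df(tracks)
  ars <- extract_ars(trips, scale = 400, percentile = 90)
  f <- unlist(lapply(tracks, function(tk)
    first_passage_time(tk$x, tk$y, tk$t, 400)))
  f <- f[!is.na(f)]
  thr <- quantile(f, 0.9, names = FALSE)
  expect_equal(nrow(ars), sum(f >= thr))
  expect_true(all(ars$fpt_s >= thr))
})

test_that("uniform-FPT trips are flagged degenerate and fully retained", {
  tr <- straight_track(n = 41, dx = 100, v = 2)
  trips <- make_trips_df(list(list(x = tr$x, y = tr$y,
                                   t = as.numeric(tr$t) - as.numeric(ts0))))
  ars <- extract_ars(trips, scale = 500, percentile = 90)
  f <- first_passage_time(tr$x, tr$y, tr$t, 500)
  expect_equal(nrow(ars), sum(!is.na(f)))       # all ties at the threshold
  expect_true("t1" %in% attr(ars, "degenerate_trips"))
})

test_that("retained ARS points fall inside the true foraging patch", {
  w <- tiny_world()
  fx <- simulate_tracks(w$scenario, w$truth, 2, days = seq(150, 190, 10),
                        seed = 13, stacks = w$stacks)
  trips <- rediscretize(segment_trips(dedupe_fixes(fx), w$scenario$colony_xy))
  prof <- scale_profile(trips, seq(200, 3000, by = 200))
  ars <- extract_ars(trips, select_scale(prof))
  # label each retained point by proximity to the trip's true patch center
  truth_dest <- unique(fx[!is.na(fx$dest_x),
                          c("bird_id", "dest_x", "dest_y")])
  frac_in <- mean(vapply(seq_len(nrow(ars)), function(i) {
    dd <- sqrt((truth_dest$dest_x - ars$x[i])^2 +
               (truth_dest$dest_y - ars$y[i])^2)
    any(dd <= 2 * w$truth$ars_radius)
  }, logical(1)))
  expect_gte(frac_in, 0.9)
})

test_that("the ARS scale is recovered within a factor of two across seeds", {
  sc <- env_scenario(days = seq(150, 190, by = 10))
  tr <- truth_params()            # ars_radius = 1000 m
  sel <- vapply(1:10, function(s) {
    st <- generate_env(sc, tr, 1000 + s)
    fx <- simulate_tracks(sc, tr, 2, days = seq(150, 190, 10),
                          seed = 2000 + s, stacks = st)
    trips <- rediscretize(segment_trips(dedupe_fixes(fx), sc$colony_xy))
    select_scale(scale_profile(trips))
  }, numeric(1))
  expect_gte(median(sel), 500)
  expect_lte(median(sel), 2000)
})
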