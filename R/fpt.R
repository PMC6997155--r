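#' First-passage time along a trip
#'
#' For each path point, the first-passage time (FPT) is the time the animal
#' takes to traverse a circle of the given radius centered on that point:
#' the interval between the backward and forward first crossings of the
#' circle. Crossing times are found by exact segment-circle intersection
#' with linear time interpolation inside the crossing step. Points whose
#' circle is never exited in one of the two directions (path ends inside)
#' get `NA`.
#'
#' @param x,y path coordinates (m), in order.
#' @param time POSIXct or numeric seconds, same length.
#' @param radius circle radius (m), > 0.
#' @return numeric vector of FPT seconds (NA where undefined).
#' @export
first_passage_time <- function(x, y, time, radius) {
  if (radius <= 0) stop("radius must be positive")
  n <- length(x)
  t <- as.numeric(time)
  out <- rep(NA_real_, n)
  if (n < 2L) return(out)
  for (i in seq_len(n)) {
    tf <- fpt_cross(x, y, t, i, radius, forward = TRUE)
    if (is.na(tf)) next
    tb <- fpt_cross(x, y, t, i, radius, forward = FALSE)
    if (is.na(tb)) next
    out[i] <- tf - tb
  }
  out
}

# time of the first crossing of the circle of `radius` centered at point i,
# scanning forward or backward; NA when the path never exits
fpt_cross <- function(x, y, t, i, radius, forward) {
  n <- length(x)
  idx <- if (forward) i:n else i:1
  dx <- x[idx] - x[i]; dy <- y[idx] - y[i]
  d2 <- dx * dx + dy * dy
  j <- which(d2 >= radius^2)[1L]
  if (is.na(j)) return(NA_real_)
  # crossing lies within the step from idx[j-1] to idx[j]
  a <- idx[j - 1L]; b <- idx[j]
  ax <- x[a] - x[i]; ay <- y[a] - y[i]
  bx <- x[b] - x[a]; by <- y[b] - y[a]
  A <- bx * bx + by * by
  B <- 2 * (ax * bx + ay * by)
  C <- ax * ax + ay * ay - radius^2
  disc <- B * B - 4 * A * C
  s <- if (A == 0 || disc < 0) 1 else (-B + sqrt(disc)) / (2 * A)
  s <- min(max(s, 0), 1)
  t[a] + s * (t[b] - t[a])
}

#' Variance-of-log-FPT scale profile per bird
#'
#' Computes FPT at every radius in `radii` for every point of every trip,
#' then pools all of a bird's defined FPT values per radius and takes the
#' sample variance of log(FPT). Radii with fewer than 2 defined values are
#' marked missing for that bird.
#'
#' @param trips rediscretized trip table ([rediscretize()] output).
#' @param radii candidate radii (m); the default grid 100..5000 by 100 has
#'   50 candidates.
#' @return object of class `fpt_profile`: data.frame with `bird_id`,
#'   `radius`, `var_log_fpt` (NA when missing), `n_defined`.
#' @export
scale_profile <- function(trips, radii = seq(100, 5000, by = 100)) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing")
  birds <- unique(trips$bird_id)
  rows <- list()
  for (bid in birds) {
    btr <- trips[trips$bird_id == bid, , drop = FALSE]
    # FPT for all radii per trip, reusing the per-trip geometry
    vals <- matrix(NA_real_, nrow(btr), length(radii))
    off <- 0L
    for (tid in unique(btr$trip_id)) {
      tr <- btr[btr$trip_id == tid, , drop = FALSE]
      tr <- tr[order(tr$seq), , drop = FALSE]
      m <- trip_fpt_matrix(tr$x, tr$y, as.numeric(tr$time), radii)
      vals[off + seq_len(nrow(tr)), ] <- m
      off <- off + nrow(tr)
    }
    v <- apply(vals, 2, function(col) {
      col <- col[is.finite(col) & col > 0]
      if (length(col) < 2L) NA_real_ else stats::var(log(col))
    })
    nn <- apply(vals, 2, function(col) sum(is.finite(col) & col > 0))
    rows[[length(rows) + 1L]] <- data.frame(
      bird_id = bid, radius = radii, var_log_fpt = v, n_defined = nn)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("fpt_profile", "data.frame")
  res
}

# FPT of every point of one trip at every radius in one pass. The first
# crossing index at each radius is found on the running maximum of the
# distance-from-center sequence (nondecreasing, so one findInterval call
# locates all radii); the exact crossing time then comes from the
# segment-circle quadratic, vectorized over radii.
trip_fpt_matrix <- function(x, y, t, radii) {
  n <- length(x)
  nr <- length(radii)
  out <- matrix(NA_real_, n, nr)
  cross_times <- function(i, idx) {
    # idx: path indices scanning away from i (first element is i itself)
    d <- sqrt((x[idx] - x[i])^2 + (y[idx] - y[i])^2)
    cm <- cummax(d)
    j <- findInterval(radii, cm, left.open = TRUE) + 1L  # first d >= radius
    ok <- j <= length(idx)
    tt <- rep(NA_real_, nr)
    if (!any(ok)) return(tt)
    a <- idx[j[ok] - 1L]; b <- idx[j[ok]]
    ax <- x[a] - x[i]; ay <- y[a] - y[i]
    bx <- x[b] - x[a]; by <- y[b] - y[a]
    A <- bx * bx + by * by
    B <- 2 * (ax * bx + ay * by)
    C <- ax * ax + ay * ay - radii[ok]^2
    disc <- pmax(B * B - 4 * A * C, 0)
    s <- ifelse(A == 0, 1, (-B + sqrt(disc)) / (2 * A))
    s <- pmin(pmax(s, 0), 1)
    tt[ok] <- t[a] + s * (t[b] - t[a])
    tt
  }
  for (i in seq_len(n)) {
    tf <- cross_times(i, i:n)
    if (all(is.na(tf))) next
    tb <- cross_times(i, i:1)
    out[i, ] <- tf - tb
  }
  out
}

#' Select the characteristic ARS scale
#'
#' Default rule ("mean_profile"): average var(log FPT) across birds at each
#' radius (ignoring birds missing at that radius) and return the radius
#' maximizing the average; ties break to the smallest radius. Alternative
#' rule ("per_bird_max"): take each bird's argmax radius and return the
#' largest.
#'
#' @param profile an `fpt_profile` from [scale_profile()].
#' @param method "mean_profile" (default) or "per_bird_max".
#' @return selected radius (m).
#' @export
select_scale <- function(profile, method = c("mean_profile", "per_bird_max")) {
  method <- match.arg(method)
  if (all(!is.finite(profile$var_log_fpt)))
    stop("no radius has a defined variance for any bird")
  if (method == "mean_profile") {
    agg <- stats::aggregate(var_log_fpt ~ radius, data = profile,
                            FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
    agg <- agg[is.finite(agg$var_log_fpt), , drop = FALSE]
    agg$radius[which.max(agg$var_log_fpt)]
  } else {
    per <- vapply(split(profile, profile$bird_id), function(p) {
      p <- p[is.finite(p$var_log_fpt), , drop = FALSE]
      if (nrow(p) == 0) return(NA_real_)
      p$radius[which.max(p$var_log_fpt)]
    }, numeric(1))
    max(per, na.rm = TRUE)
  }
}

#' Extract area-restricted search (foraging) points
#'
#' Computes FPT at the selected scale and retains points whose FPT is at or
#' above the reference distribution's percentile (linear-interpolation
#' quantile). The default reference pools each bird's defined FPT values;
#' a bird with fewer than 10 defined values falls back to the all-bird
#' pooled distribution (logged). Reference "trip" and "global" are exposed
#' as alternatives.
#'
#' @param trips rediscretized trip table.
#' @param scale selected radius (m).
#' @param percentile retention percentile (default 90).
#' @param reference "bird" (default), "trip", or "global".
#' @return data.frame of foraging points: `bird_id`, `trip_id`, `timestamp`,
#'   `date`, `year`, `x`, `y`, `fpt_s`, plus `run_id` numbering contiguous
#'   retained runs within each trip. Attribute `degenerate_trips` lists
#'   trips where every FPT value tied at the threshold.
#' @export
extract_ars <- function(trips, scale, percentile = 90,
                        reference = c("bird", "trip", "global")) {
  reference <- match.arg(reference)
  fpt <- rep(NA_real_, nrow(trips))
  for (tid in unique(trips$trip_id)) {
    sel <- which(trips$trip_id == tid)
    tr <- trips[sel, , drop = FALSE]
    o <- order(tr$seq)
    fpt[sel[o]] <- first_passage_time(tr$x[o], tr$y[o], tr$time[o], scale)
  }
  pr <- percentile / 100
  pooled <- fpt[is.finite(fpt)]
  if (length(pooled) == 0) stop("no defined FPT values at this scale")
  thr_global <- stats::quantile(pooled, pr, names = FALSE)
  grp <- switch(reference,
                bird = trips$bird_id, trip = trips$trip_id,
                global = rep("all", nrow(trips)))
  thr <- vapply(split(fpt, grp), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 10L) {
      message("extract_ars: reference set < 10 values, falling back to pooled distribution")
      thr_global
    } else stats::quantile(v, pr, names = FALSE)
  }, numeric(1))
  keep <- is.finite(fpt) & fpt >= thr[as.character(grp)]
  out <- data.frame(
    bird_id = trips$bird_id[keep], trip_id = trips$trip_id[keep],
    timestamp = trips$time[keep], date = trips$date[keep],
    year = trips$year[keep], x = trips$x[keep], y = trips$y[keep],
    fpt_s = fpt[keep]
  )
  # contiguous retained runs within each trip (for trip-level averaging)
  run <- integer(nrow(out))
  seqs <- trips$seq[keep]
  for (tid in unique(out$trip_id)) {
    sel <- which(out$trip_id == tid)
    s <- seqs[sel]
    run[sel] <- cumsum(c(1L, diff(s) > 1L))
  }
  out$run_id <- run
  degen <- vapply(split(fpt, trips$trip_id), function(v) {
    v <- v[is.finite(v)]
    length(v) > 0 && length(unique(v)) == 1L
  }, logical(1))
  attr(out, "degenerate_trips") <- names(degen)[degen]
  rownames(out) <- NULL
  out
}

#' Plot a scale profile (variance of log FPT against radius)
#' @param x an `fpt_profile`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fpt_profile <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x)[c("bird_id", "radius", "var_log_fpt")],
                         idvar = "radius", timevar = "bird_id",
                         direction = "wide")
  r <- wide$radius
  m <- as.matrix(wide[-1])
  graphics::matplot(r, m, type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.5),
                    xlab = "radius (m)", ylab = "var log(FPT)", ...)
  graphics::lines(r, rowMeans(m, na.rm = TRUE), lwd = 2, col = "firebrick")
  invisible(x)
}
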