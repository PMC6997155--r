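#' Remove duplicate GPS fixes
#'
#' Drops rows with an exactly repeated (bird_id, timestamp) pair, keeping
#' the first occurrence; row order is otherwise preserved.
#'
#' @param fixes data.frame with at least `bird_id` and `timestamp`.
#' @return the deduplicated data.frame.
#' @export
dedupe_fixes <- function(fixes) {
  fixes[!duplicated(fixes[c("bird_id", "timestamp")]), , drop = FALSE]
}

#' Segment fixes into complete same-day foraging trips
#'
#' A trip is a maximal run of consecutive fixes farther than `colony_radius`
#' from the colony, bracketed by colony fixes, with the whole excursion
#' (including its bracketing colony fixes) on one calendar date. Runs
#' touching the start or end of a bird's record, or crossing midnight, are
#' incomplete and discarded. Colony fixes themselves are excluded from trip
#' paths.
#'
#' @param fixes deduplicated fix table: `bird_id`, `timestamp` (POSIXct),
#'   `x`, `y` (m, projected).
#' @param colony_xy colony coordinates c(x, y).
#' @param colony_radius m; fixes within it count as "at the colony".
#' @param tz timezone defining the calendar date (default "UTC").
#' @return data.frame of trip path points: `bird_id`, `trip_id`, `seq`,
#'   `timestamp`, `x`, `y`, `date` (Julian day), `year`. Empty input gives
#'   an empty frame.
#' @export
segment_trips <- function(fixes, colony_xy, colony_radius = 500, tz = "UTC") {
  empty <- data.frame(bird_id = character(), trip_id = character(),
                      seq = integer(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric(),
                      date = integer(), year = integer())
  if (nrow(fixes) == 0) return(empty)
  out <- list()
  for (bid in unique(fixes$bird_id)) {
    fx <- fixes[fixes$bird_id == bid, , drop = FALSE]
    fx <- fx[order(fx$timestamp), , drop = FALSE]
    away <- sqrt((fx$x - colony_xy[1])^2 + (fx$y - colony_xy[2])^2) >
      colony_radius
    if (!any(away)) next
    r <- rle(away)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dates <- format(fx$timestamp, "%Y-%m-%d", tz = tz)
    k <- 0L
    for (i in which(r$values)) {
      s <- starts[i]; e <- ends[i]
      if (s == 1L || e == nrow(fx)) next        # no bracketing colony fix
      span <- dates[(s - 1L):(e + 1L)]
      if (length(unique(span)) != 1L) next      # crosses midnight
      k <- k + 1L
      path <- fx[s:e, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        bird_id = bid,
        trip_id = sprintf("%s_%s_%02d", bid, dates[s], k),
        seq = seq_len(nrow(path)),
        timestamp = path$timestamp, x = path$x, y = path$y,
        date = julian_day(path$timestamp[1]),
        year = as.integer(format(path$timestamp[1], "%Y", tz = tz))
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# rediscretize one path (x, y, t) to constant arc-length steps; returns NULL
# when the path is shorter than one step
redisc_path <- function(x, y, t, step) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seg > 0)        # drop zero-length segments (stationary)
  x <- x[keep]; y <- y[keep]; t <- t[keep]
  if (length(x) < 2L) return(NULL)
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  total <- arc[length(arc)]
  if (total < step) return(NULL)
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)   # retain final partial step
  list(
    x = stats::approx(arc, x, xout = s)$y,
    y = stats::approx(arc, y, xout = s)$y,
    t = stats::approx(arc, as.numeric(t), xout = s)$y,
    arc = s
  )
}

#' Rediscretize trips to constant step length
#'
#' Places points at arc-length positions 0, s, 2s, ... along each trip's
#' piecewise-linear path, interpolating position and time linearly within
#' segments, so every rediscretized point lies exactly on the original path.
#' The original final endpoint is appended so the path ends at the colony
#' approach. Trips whose path is shorter than one step are flagged
#' degenerate and dropped with a message.
#'
#' @param trips output of [segment_trips()].
#' @param step step length (m), default 200.
#' @return data.frame: `bird_id`, `trip_id`, `seq`, `x`, `y`, `time`
#'   (POSIXct, interpolated), `arc` (m along path), `date`, `year`.
#' @export
rediscretize <- function(trips, step = 200) {
  if (step <= 0) stop("step must be positive")
  out <- list()
  dropped <- 0L
  for (tid in unique(trips$trip_id)) {
    tr <- trips[trips$trip_id == tid, , drop = FALSE]
    tr <- tr[order(tr$seq), , drop = FALSE]
    rp <- redisc_path(tr$x, tr$y, tr$timestamp, step)
    if (is.null(rp)) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      bird_id = tr$bird_id[1], trip_id = tid, seq = seq_along(rp$x),
      x = rp$x, y = rp$y,
      time = as.POSIXct(rp$t, origin = "1970-01-01", tz = "UTC"),
      arc = rp$arc, date = tr$date[1], year = tr$year[1]
    )
  }
  if (dropped > 0L)
    message(sprintf("rediscretize: dropped %d degenerate trip(s) shorter than one step", dropped))
  if (length(out) == 0)
    return(data.frame(bird_id = character(), trip_id = character(),
                      seq = integer(), x = numeric(), y = numeric(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      arc = numeric(), date = integer(), year = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a Movebank-like fix CSV
#'
#' Accepts either projected `x`/`y` columns or
#' `location-long`/`location-lat`, which are projected on ingest with a
#' local equirectangular projection about the data centroid (adequate for
#' the sub-degree extents of a single-colony study).
#'
#' @param path CSV path with columns (`individual-local-identifier` or
#'   `bird_id`), (`timestamp`), and coordinates as above.
#' @return fix data.frame: `bird_id`, `timestamp` (POSIXct UTC), `x`, `y`.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  idcol <- intersect(c("bird_id", "individual-local-identifier", "id"), nm)[1]
  if (is.na(idcol)) stop("no bird id column found")
  ts <- as.POSIXct(df$timestamp, tz = "UTC")
  if (all(c("x", "y") %in% nm)) {
    x <- df$x; y <- df$y
  } else if (all(c("location-long", "location-lat") %in% nm)) {
    lon <- df[["location-long"]]; lat <- df[["location-lat"]]
    lat0 <- mean(lat, na.rm = TRUE)
    R <- 6371008.8
    x <- (lon - mean(lon, na.rm = TRUE)) * pi / 180 * R * cos(lat0 * pi / 180)
    y <- (lat - lat0) * pi / 180 * R
  } else stop("no coordinate columns found (x/y or location-long/lat)")
  data.frame(bird_id = as.character(df[[idcol]]), timestamp = ts, x = x, y = y)
}

#' Write trips to CSV
#' @param trips trip table ([segment_trips()] or [rediscretize()] output).
#' @param path output CSV path.
#' @export
write_trips <- function(trips, path) {
  df <- trips
  tcol <- intersect(c("time", "timestamp"), names(df))[1]
  df[[tcol]] <- format(df[[tcol]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
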