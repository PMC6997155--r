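#' Gridded environmental surface
#'
#' A minimal planar raster: a numeric matrix of cell values plus extent
#' metadata, in projected metric coordinates. Row `i`, column `j` holds the
#' cell whose center is at `x = xmin + (j - 0.5) * cellsize`,
#' `y = ymin + (i - 0.5) * cellsize` (rows run south to north).
#'
#' @param values numeric matrix of cell values (rows = y, cols = x).
#' @param xmin,ymin coordinates of the lower-left corner (m).
#' @param cellsize cell edge length (m), strictly positive.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(values, xmin, ymin, cellsize) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("grid values must be numeric")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("degenerate extent: grid must have at least 2 cells per axis")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf(
    "env_grid: %d x %d cells, cellsize %g m, extent x [%g, %g] y [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, x$xmin + ncol(x$values) * x$cellsize,
    x$ymin, x$ymin + nrow(x$values) * x$cellsize
  ))
  cat(sprintf("values: range [%g, %g]\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

grid_xmax <- function(g) g$xmin + ncol(g$values) * g$cellsize
grid_ymax <- function(g) g$ymin + nrow(g$values) * g$cellsize

#' Cell-center coordinates of a grid
#' @param g an `env_grid`.
#' @return list with vectors `x` (length ncol) and `y` (length nrow).
#' @export
grid_centers <- function(g) {
  list(
    x = g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$cellsize,
    y = g$ymin + (seq_len(nrow(g$values)) - 0.5) * g$cellsize
  )
}

#' Is a point inside the grid extent?
#' @param g an `env_grid`.
#' @param x,y point coordinates (vectorized).
#' @export
grid_contains <- function(g, x, y) {
  x >= g$xmin & x <= grid_xmax(g) & y >= g$ymin & y <= grid_ymax(g)
}

#' Nearest-cell value lookup
#'
#' Returns the value of the cell containing each point (NA outside extent).
#' @param g an `env_grid`.
#' @param x,y point coordinates (vectorized).
#' @export
grid_value_at <- function(g, x, y) {
  j <- pmin(pmax(ceiling((x - g$xmin) / g$cellsize), 1L), ncol(g$values))
  i <- pmin(pmax(ceiling((y - g$ymin) / g$cellsize), 1L), nrow(g$values))
  out <- g$values[cbind(i, j)]
  out[!grid_contains(g, x, y)] <- NA_real_
  out
}

#' Inverse-distance-weighted interpolation on one grid
#'
#' Value at a point is the inverse-distance weighted mean of the `k` nearest
#' cells with finite values, weights `d^(-p)`. A point lying exactly on a
#' cell center takes that cell's value. `k = Inf` uses every finite cell.
#'
#' @param g an `env_grid`.
#' @param x,y point coordinates (vectorized).
#' @param k number of nearest cells (default 4).
#' @param p distance-decay power (default 2).
#' @return numeric vector of interpolated values; NA where no finite
#'   neighbor exists.
#' @export
idw_interpolate <- function(g, x, y, k = 4, p = 2) {
  ctr <- grid_centers(g)
  cx <- rep(ctr$x, each = nrow(g$values))
  cy <- rep(ctr$y, times = ncol(g$values))
  v <- as.vector(g$values)
  ok <- is.finite(v)
  if (!any(ok)) return(rep(NA_real_, length(x)))
  cx <- cx[ok]; cy <- cy[ok]; v <- v[ok]
  kk <- if (is.finite(k)) min(k, length(v)) else length(v)
  vapply(seq_along(x), function(i) {
    d2 <- (cx - x[i])^2 + (cy - y[i])^2
    idx <- if (kk < length(v)) order(d2)[seq_len(kk)] else seq_along(v)
    d <- sqrt(d2[idx])
    hit <- d < 1e-9
    if (any(hit)) return(v[idx][which(hit)[1L]])
    w <- d^(-p)
    sum(w * v[idx]) / sum(w)
  }, numeric(1))
}

#' Date-indexed stack of gridded surfaces for one variable
#'
#' @param grids list of `env_grid` objects, one per date, identical geometry.
#' @param dates integer Julian days, same length as `grids`, strictly
#'   increasing.
#' @param var variable name (e.g. "sst").
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(grids, dates, var) {
  if (length(grids) != length(dates)) stop("one grid per date required")
  if (is.unsorted(dates, strictly = TRUE)) stop("dates must be strictly increasing")
  g1 <- grids[[1L]]
  for (g in grids) {
    if (!identical(dim(g$values), dim(g1$values)) ||
        g$xmin != g1$xmin || g$ymin != g1$ymin || g$cellsize != g1$cellsize)
      stop("all grids in a stack must share geometry")
  }
  structure(list(grids = grids, dates = as.integer(dates), var = var),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack '%s': %d dates (%d..%d), %d x %d cells\n",
              x$var, length(x$dates), min(x$dates), max(x$dates),
              nrow(x$grids[[1L]]$values), ncol(x$grids[[1L]]$values)))
  invisible(x)
}

#' Space-time IDW extraction from a stack
#'
#' Spatial IDW on the layer(s) nearest in time: a same-date layer is used
#' directly; otherwise the two bracketing dates' spatial values are linearly
#' interpolated in time. Dates outside the stack range take the nearest end
#' layer.
#'
#' @param stack an `env_stack`.
#' @param x,y,date point coordinates and integer Julian day (vectorized).
#' @inheritParams idw_interpolate
#' @export
stack_extract <- function(stack, x, y, date, k = 4, p = 2) {
  date <- as.integer(date)
  out <- numeric(length(x))
  # group points by date to amortize the per-layer work
  for (d in unique(date)) {
    sel <- which(date == d)
    ds <- stack$dates
    if (d <= ds[1L]) {
      out[sel] <- idw_interpolate(stack$grids[[1L]], x[sel], y[sel], k, p)
    } else if (d >= ds[length(ds)]) {
      out[sel] <- idw_interpolate(stack$grids[[length(ds)]], x[sel], y[sel], k, p)
    } else if (d %in% ds) {
      out[sel] <- idw_interpolate(stack$grids[[match(d, ds)]], x[sel], y[sel], k, p)
    } else {
      i1 <- max(which(ds < d)); i2 <- i1 + 1L
      v1 <- idw_interpolate(stack$grids[[i1]], x[sel], y[sel], k, p)
      v2 <- idw_interpolate(stack$grids[[i2]], x[sel], y[sel], k, p)
      w <- (d - ds[i1]) / (ds[i2] - ds[i1])
      out[sel] <- (1 - w) * v1 + w * v2
    }
  }
  out
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text interchange format readable by standard GIS tools. The first
#' data row is the northernmost.
#' @param g an `env_grid`.
#' @param path output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    "NODATA_value -9999"
  ), con)
  vals <- g$values
  vals[!is.finite(vals)] <- -9999
  for (i in rev(seq_len(nrow(vals))))
    writeLines(paste(formatC(vals[i, ], format = "g", digits = 8),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_ascii_grid()]
#' @param path file path.
#' @return an `env_grid`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1L]][2L])
  ncols <- as.integer(kv(1)); nrows <- as.integer(kv(2))
  xll <- kv(3); yll <- kv(4); cs <- kv(5); nodata <- kv(6)
  m <- matrix(scan(path, skip = 6, quiet = TRUE), nrow = nrows,
              ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  env_grid(m[rev(seq_len(nrows)), , drop = FALSE], xll, yll, cs)
}

#' Write an `env_stack` as one ASCII raster per date
#' @param stack an `env_stack`.
#' @param dir output directory (created if absent).
#' @return invisible vector of file paths, named `<var>_d<JJJ>.asc`.
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(stack$dates), function(i) {
    p <- file.path(dir, sprintf("%s_d%03d.asc", stack$var, stack$dates[i]))
    write_ascii_grid(stack$grids[[i]], p)
    p
  }, character(1))
  invisible(paths)
}
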