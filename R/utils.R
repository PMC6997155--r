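#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so all
#' generators are pure functions of (inputs, seed).
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a stage label
#'
#' Deterministic, label-dependent, and kept within 32-bit integer range so a
#' single run seed can drive every stochastic stage independently.
#' @param seed master integer seed.
#' @param label character stage label.
#' @keywords internal
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Julian day (day of year) of a timestamp
#' @param time POSIXct vector.
#' @keywords internal
julian_day <- function(time) as.integer(format(time, "%j", tz = "UTC"))
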