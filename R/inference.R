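#' Per-sex body condition index
#'
#' Standardized residuals, computed within each sex, from an ordinary
#' least-squares regression of log(body mass) on 3 * log(tarsus length).
#' With perfect cubic allometry the residuals are identically zero and the
#' standardization is undefined; indices are then set to 0 with a warning.
#'
#' @param metadata data.frame: `bird_id`, `sex`, `mass_g`, `tarsus_mm`.
#' @return `metadata` with a `condition` column (within-sex mean 0, SD 1).
#' @export
body_condition <- function(metadata) {
  if (any(metadata$mass_g <= 0 | metadata$tarsus_mm <= 0))
    stop("mass and tarsus must be positive")
  out <- metadata
  out$condition <- NA_real_
  for (s in unique(metadata$sex)) {
    sel <- metadata$sex == s
    if (sum(sel) < 3)
      stop(sprintf("need at least 3 birds of sex %s for the condition index", s))
    fit <- stats::lm(log(mass_g) ~ I(3 * log(tarsus_mm)),
                     data = metadata[sel, ])
    r <- stats::residuals(fit)
    if (stats::sd(r) < 1e-12) {
      warning(sprintf("sex %s: perfect allometry, condition indices set to 0", s))
      out$condition[sel] <- 0
    } else {
      out$condition[sel] <- (r - mean(r)) / stats::sd(r)
    }
  }
  out
}

#' Individual-trait mixed model of foraging habitat quality
#'
#' Gaussian random-intercept model of logit trip-mean quality on sex,
#' condition, and year, with bird identity as the random effect (REML via
#' nlme). When the between-bird variance collapses to zero the fit is
#' flagged singular and the fixed effects coincide with ordinary least
#' squares.
#'
#' @param trip_quality observed-group trip table ([trip_mean_quality()]).
#' @param metadata output of [body_condition()].
#' @return object of class `trait_model`: coefficient table (estimate, SE,
#'   t, p), random-effect SDs, `singular` flag, and the underlying fit.
#' @export
fit_trait_model <- function(trip_quality, metadata) {
  tq <- trip_quality[trip_quality$group == "observed", , drop = FALSE]
  df <- merge(tq, metadata[c("bird_id", "sex", "condition")], by = "bird_id")
  if (length(unique(df$bird_id)) < 2) stop("need at least 2 birds")
  df$resp <- logit(df$S)
  df$year_f <- factor(df$year)
  form <- if (nlevels(df$year_f) > 1) resp ~ sex + condition + year_f
          else resp ~ sex + condition
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | bird_id, data = df, method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate between-bird variance: collapse to OLS, flag singular
    ols <- stats::lm(form, data = df)
    ct <- summary(ols)$coefficients
    tab <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], row.names = NULL)
    return(structure(list(table = tab, sd_bird = 0, singular = TRUE,
                          fit = ols, n_trips = nrow(df)),
                     class = "trait_model"))
  }
  ct <- summary(fit)$tTable
  sd_bird <- sqrt(as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"]))
  sd_resid <- fit$sigma
  structure(list(
    table = data.frame(term = rownames(ct), estimate = ct[, "Value"],
                       se = ct[, "Std.Error"], t = ct[, "t-value"],
                       p = ct[, "p-value"], row.names = NULL),
    sd_bird = sd_bird, sd_resid = sd_resid,
    singular = sd_bird < 1e-6 * sd_resid,
    fit = fit, n_trips = nrow(df)), class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("Individual-trait mixed model (%d trips)%s\n", x$n_trips,
              if (x$singular) " [singular: between-bird variance ~ 0]" else ""))
  print(x$table, digits = 3)
  invisible(x)
}

#' Beta-likelihood additive model of trip quality over the season
#'
#' Fits trip-mean foraging habitat quality (open unit interval) with a beta
#' likelihood and logit link: parametric group (observed vs simulated) and
#' year terms, group-specific penalized cubic-regression-spline smooths of
#' Julian day, and bird identity as a ridge-penalized random intercept.
#' Smoothing parameters and the beta precision are selected by restricted
#' marginal likelihood. The simulated group is the reference level, so the
#' group coefficient is the observed-group offset in log-odds.
#'
#' @param trip_quality a [trip_mean_quality()] table (both groups).
#' @param k basis dimension per smooth (default 10).
#' @param random_bird include the bird random-intercept term.
#' @param partition_deviance also refit without the random-intercept block
#'   to report the fixed-effects share of deviance explained (set FALSE to
#'   skip the extra fit, e.g. in simulation loops).
#' @return object of class `beta_gam`: the mgcv fit (`gam`), group/year
#'   levels, day range, deviance explained and its fixed-effects share.
#' @export
fit_beta_gam <- function(trip_quality, k = 10, random_bird = TRUE,
                         partition_deviance = TRUE) {
  tq <- trip_quality
  if (any(tq$S <= 0 | tq$S >= 1))
    stop("responses must lie strictly inside (0, 1); see trip_mean_quality()")
  tq$group <- factor(tq$group, levels = c("simulated", "observed"))
  if (any(is.na(tq$group))) stop("group must be 'observed' or 'simulated'")
  tq$year_f <- factor(tq$year)
  tq$bird_f <- factor(tq$bird_id)
  tq$day <- as.numeric(tq$julian_day)
  terms <- c("group", if (nlevels(tq$year_f) > 1) "year_f",
             sprintf("s(day, by = group, bs = 'cr', k = %d)", k),
             if (random_bird && nlevels(tq$bird_f) > 1) "s(bird_f, bs = 're')")
  form <- stats::as.formula(paste("S ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, family = mgcv::betar(link = "logit"), data = tq,
                   method = "REML")
  dev_full <- summary(fit)$dev.expl
  # fixed-effects share: deviance explained by the refit without the
  # bird random-intercept block, relative to the full model
  dev_fixed <- if (partition_deviance && random_bird && nlevels(tq$bird_f) > 1) {
    terms_f <- setdiff(terms, "s(bird_f, bs = 're')")
    form_f <- stats::as.formula(paste("S ~", paste(terms_f, collapse = " + ")))
    refit <- mgcv::gam(form_f, family = mgcv::betar(link = "logit"),
                       data = tq, method = "REML")
    summary(refit)$dev.expl
  } else dev_full
  structure(list(gam = fit, data = tq, k = k,
                 group_levels = levels(tq$group),
                 years = levels(tq$year_f),
                 day_range = range(tq$day),
                 deviance_explained = dev_full,
                 fixed_effect_share = dev_fixed / dev_full,
                 phi = fit$family$getTheta(TRUE)),
            class = "beta_gam")
}

#' @export
print.beta_gam <- function(x, ...) {
  cat("Beta-likelihood additive model of trip-mean habitat quality\n")
  cat(sprintf("  %d trips, %.1f%% deviance explained (fixed-effects share %.1f%%), phi = %.1f\n",
              nrow(x$data), 100 * x$deviance_explained,
              100 * x$fixed_effect_share, x$phi))
  invisible(x)
}

#' @export
summary.beta_gam <- function(object, ...) {
  s <- summary(object$gam)
  pt <- as.data.frame(s$p.table)
  st <- as.data.frame(s$s.table)
  list(parametric = pt, smooths = st,
       deviance_explained = object$deviance_explained,
       fixed_effect_share = object$fixed_effect_share, phi = object$phi)
}

#' @export
coef.beta_gam <- function(object, ...) stats::coef(object$gam)

#' Pointwise difference between the two group smooths
#'
#' Builds the linear-predictor design rows for each grid day under the
#' observed and simulated group (all shared terms cancel in the
#' difference), differences them, and propagates the coefficient
#' covariance: D(d) = x_diff b, SE(d) = sqrt(x_diff V x_diff'), with an
#' approximate pointwise 95% interval D +/- 1.96 SE. Days where the
#' interval excludes zero are flagged significant. The difference includes
#' the parametric group offset, i.e. it compares the two fitted seasonal
#' curves.
#'
#' @param fit a [fit_beta_gam()] object.
#' @param grid Julian days to evaluate (default: every day in the fitted
#'   range).
#' @param level interval coverage (default 0.95).
#' @param allow_extrapolation permit grid days outside the fitted range.
#' @return object of class `smooth_difference`: data.frame `day`,
#'   `estimate`, `se`, `lo`, `hi`, `significant`.
#' @export
difference_smooth <- function(fit, grid = NULL, level = 0.95,
                              allow_extrapolation = FALSE) {
  if (is.null(grid))
    grid <- seq(fit$day_range[1], fit$day_range[2], by = 1)
  if (!allow_extrapolation &&
      (min(grid) < fit$day_range[1] || max(grid) > fit$day_range[2]))
    stop("grid outside the fitted day range (set allow_extrapolation = TRUE to override)")
  ref_year <- fit$years[1]
  ref_bird <- levels(fit$data$bird_f)[1]
  nd <- function(g) data.frame(day = grid,
                               group = factor(g, levels = fit$group_levels),
                               year_f = factor(ref_year, levels = fit$years),
                               bird_f = factor(ref_bird,
                                               levels = levels(fit$data$bird_f)))
  X1 <- stats::predict(fit$gam, nd("observed"), type = "lpmatrix")
  X0 <- stats::predict(fit$gam, nd("simulated"), type = "lpmatrix")
  Xd <- X1 - X0
  b <- stats::coef(fit$gam)
  V <- fit$gam$Vp
  est <- drop(Xd %*% b)
  se <- sqrt(pmax(rowSums((Xd %*% V) * Xd), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(day = grid, estimate = est, se = se,
                    lo = est - z * se, hi = est + z * se)
  out$significant <- out$lo > 0 | out$hi < 0
  class(out) <- c("smooth_difference", "data.frame")
  out
}

#' @export
plot.smooth_difference <- function(x, ...) {
  graphics::plot(x$day, x$estimate, type = "n", ylim = range(x$lo, x$hi),
                 xlab = "Julian day",
                 ylab = "difference in log-odds habitat quality", ...)
  graphics::polygon(c(x$day, rev(x$day)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$day, x$estimate, lwd = 2)
  graphics::abline(h = 0, lty = 2)
  sig <- x$day[x$significant]
  if (length(sig) > 0)
    graphics::points(sig, rep(min(x$lo), length(sig)), pch = 15, cex = 0.4,
                     col = "firebrick")
  invisible(x)
}

#' Pairwise Wald tests of year intercepts
#'
#' For each pair of year levels, tests the contrast of their parametric
#' coefficients with the Wald statistic X^2 = (c b)^2 / (c V c'), df = 1.
#'
#' @param fit a [fit_beta_gam()] object.
#' @param pairs optional 2-column matrix/data.frame of year-level pairs to
#'   test; all unordered pairs by default.
#' @return data.frame: `year_a`, `year_b`, `estimate`, `chisq`, `df`, `p`.
#' @export
wald_year_contrasts <- function(fit, pairs = NULL) {
  yrs <- fit$years
  if (length(yrs) < 2) stop("need at least 2 year levels")
  b <- stats::coef(fit$gam)
  V <- fit$gam$Vp
  cn <- names(b)
  coef_of <- function(y) {
    if (y == yrs[1]) return(NULL)              # reference level
    nm <- paste0("year_f", y)
    if (!nm %in% cn) stop(sprintf("coefficient for year %s not found", y))
    nm
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(yrs, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    ya <- as.character(pairs[r, 1]); yb <- as.character(pairs[r, 2])
    cvec <- stats::setNames(numeric(length(b)), cn)
    na <- coef_of(ya); nb_ <- coef_of(yb)
    if (!is.null(na)) cvec[na] <- cvec[na] - 1
    if (!is.null(nb_)) cvec[nb_] <- cvec[nb_] + 1
    est <- sum(cvec * b)
    v <- drop(cvec %*% V %*% cvec)
    if (v <= 0 && est != 0) {
      message(sprintf("singular contrast %s-%s skipped", ya, yb)); next
    }
    x2 <- if (v <= 0) 0 else est^2 / v
    rows[[length(rows) + 1L]] <- data.frame(
      year_a = ya, year_b = yb, estimate = est, chisq = x2, df = 1,
      p = stats::pchisq(x2, 1, lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
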