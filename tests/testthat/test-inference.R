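test_that("condition indices standardize residuals within each sex", {
  md <- generate_bird_metadata(30, seed = 1)
  ci <- body_condition(md)
  for (s in c("F", "M")) {
    v <- ci$condition[ci$sex == s]
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(sd(v), 1, tolerance = 1e-8)
  }
})

test_that("perfect allometry triggers the degenerate zero-index path", {
  md <- generate_bird_metadata(10, seed = 2, noise_sd = 0)
  w <- capture_warnings(ci <- body_condition(md))
  expect_match(w, "perfect allometry", all = TRUE)
  expect_length(w, 2)                           # one per sex
  expect_true(all(ci$condition == 0))
  expect_error(body_condition(md[1:3, ]), "at least 3")   # one sex too small
})

test_that("condition residuals match a normal-equations least-squares oracle", {
  md <- data.frame(
    bird_id = paste0("b", 1:5), sex = "F",
    mass_g = c(3000, 3400, 2900, 4100, 3600),
    tarsus_mm = c(84, 88, 86, 95, 90)
  )
  ci <- body_condition(md)
  X <- cbind(1, 3 * log(md$tarsus_mm))
  yv <- log(md$mass_g)
  r <- yv - X %*% solve(t(X) %*% X, t(X) %*% yv)
  expect_equal(ci$condition, as.numeric((r - mean(r)) / sd(r)),
               tolerance = 1e-10)
})

trait_sim <- function(seed, n_birds = 12, trips_per_bird = 8, bird_sd = 0.3,
                      sex_effect = 0, years = c(2014L, 2015L)) {
  set.seed(seed)
  md <- generate_bird_metadata(n_birds, seed = seed)
  md <- body_condition(md)
  re <- rnorm(n_birds, 0, bird_sd)
  rows <- do.call(rbind, lapply(seq_len(n_birds), function(i) {
    yr <- sample(years, trips_per_bird, TRUE)
    eta <- -0.5 + re[i] + sex_effect * (md$sex[i] == "M") +
      rnorm(trips_per_bird, 0, 0.4)
    data.frame(group = "observed", year = yr, julian_day = 150L,
               bird_id = md$bird_id[i],
               trip_id = paste0(md$bird_id[i], "_", seq_len(trips_per_bird)),
               S = plogis(eta))
  }))
  list(tq = rows, md = md)
}

test_that("zero between-bird variance collapses the trait model to OLS", {
  d <- trait_sim(3, bird_sd = 0)
  tm <- fit_trait_model(d$tq, d$md)
  df <- merge(d$tq, d$md[c("bird_id", "sex", "condition")], by = "bird_id")
  ols <- lm(qlogis(S) ~ sex + condition + factor(year), data = df)
  expect_equal(unname(tm$table$estimate), unname(coef(ols)), tolerance = 0.05)
})

test_that("a known sex effect is recovered within 2 standard errors", {
  hits <- 0
  for (s in 1:10) {
    d <- trait_sim(400 + s, n_birds = 16, trips_per_bird = 10,
                   sex_effect = 0.8)
    tm <- fit_trait_model(d$tq, d$md)
    row <- tm$table[tm$table$term == "sexM", ]
    if (abs(row$estimate - 0.8) <= 2 * row$se) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("trait-model fixed-effect tests hold their type-I error under the null", {
  n_rep <- 200
  rej <- matrix(NA, n_rep, 2, dimnames = list(NULL, c("sexM", "condition")))
  for (s in seq_len(n_rep)) {
    d <- trait_sim(1000 + s, n_birds = 12, trips_per_bird = 6,
                   sex_effect = 0)
    tm <- fit_trait_model(d$tq, d$md)
    for (term in colnames(rej)) {
      row <- tm$table[tm$table$term == term, ]
      rej[s, term] <- row$p < 0.05
    }
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  for (term in colnames(rej))
    expect_lt(abs(mean(rej[, term]) - 0.05), 3 * se + 1e-9)
})

test_that("a constant response is penalized to a flat smooth with the right intercept", {
  set.seed(5)
  tq <- sim_trip_quality(150, 5, f_obs = function(day) qlogis(0.4),
                         bird_sd = 0, phi = 60)
  fit <- fit_beta_gam(tq, partition_deviance = FALSE)
  s <- summary(fit)
  # second-derivative penalties leave the linear null space, so a fully
  # penalized cubic smooth keeps ~1 effective df; require near that floor
  expect_lt(max(s$smooths$edf), 2.5)
  ds <- difference_smooth(fit)
  expect_lt(diff(range(ds$estimate)), 0.3)    # flat difference curve
  mu_hat <- plogis(coef(fit)[["(Intercept)"]])
  expect_equal(mu_hat, 0.4, tolerance = 0.03)
})

test_that("the intercept-only beta fit matches a direct maximum-likelihood oracle", {
  set.seed(6)
  S <- rbeta(300, 0.55 * 25, 0.45 * 25)
  tq <- data.frame(group = rep(c("observed", "simulated"), each = 150),
                   year = 2014L, julian_day = 150L, bird_id = "sim",
                   trip_id = paste0("t", 1:300), S = S)
  fit <- mgcv::gam(S ~ 1, family = mgcv::betar(link = "logit"),
                   data = tq, method = "REML")
  # independent two-parameter beta likelihood optimization
  nll <- function(p) {
    mu <- plogis(p[1]); phi <- exp(p[2])
    -sum(dbeta(S, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  opt <- optim(c(0, 2), nll, method = "BFGS")
  expect_lt(abs(unname(coef(fit)[1]) - opt$par[1]), 1e-4)
  expect_lt(abs(log(fit$family$getTheta(TRUE)) - opt$par[2]), 5e-3)
})

test_that("group-specific smooths recover a generating offset curve", {
  offset_curve <- function(day) 0.5 * plogis((day - 150) / 4)
  tq <- sim_trip_quality(400, 7, f_obs = function(d) season_curve(d) + offset_curve(d),
                         f_sim = season_curve)
  fit <- fit_beta_gam(tq, partition_deviance = FALSE)
  ds <- difference_smooth(fit)
  rmse <- sqrt(mean((ds$estimate - offset_curve(ds$day))^2))
  expect_lt(rmse, 0.15)
})

test_that("swapping group labels exactly negates the difference smooth", {
  tq <- sim_trip_quality(150, 8, f_obs = function(d) season_curve(d) + 0.3,
                         bird_sd = 0)
  fit <- fit_beta_gam(tq, partition_deviance = FALSE)
  ds <- difference_smooth(fit)
  sw <- tq
  sw$group <- ifelse(tq$group == "observed", "simulated", "observed")
  fit2 <- fit_beta_gam(sw, partition_deviance = FALSE)
  ds2 <- difference_smooth(fit2)
  expect_equal(ds2$estimate, -ds$estimate, tolerance = 1e-6)
  expect_equal(ds2$lo, -ds$hi, tolerance = 1e-6)
})

test_that("a constant group offset is recovered by the mean difference", {
  tq <- sim_trip_quality(400, 9, f_obs = function(d) season_curve(d) + 0.5,
                         f_sim = season_curve)
  fit <- fit_beta_gam(tq, partition_deviance = FALSE)
  ds <- difference_smooth(fit)
  mean_d <- mean(ds$estimate)
  mean_se <- mean(ds$se)
  expect_lt(abs(mean_d - 0.5), 2 * mean_se)
})

test_that("extrapolation beyond the fitted day range is refused by default", {
  tq <- sim_trip_quality(60, 10, f_obs = season_curve, days = 140:180)
  fit <- fit_beta_gam(tq, partition_deviance = FALSE)
  expect_error(difference_smooth(fit, grid = 100:220), "outside the fitted")
  expect_silent(ds <- difference_smooth(fit, grid = 100:220,
                                        allow_extrapolation = TRUE))
  expect_equal(nrow(ds), 121)
})

test_that("deviance explained is invariant to trip order and bird relabeling", {
  tq <- sim_trip_quality(120, 11, f_obs = season_curve)
  f1 <- fit_beta_gam(tq, partition_deviance = FALSE)
  perm <- tq[sample(nrow(tq)), ]
  perm$bird_id <- chartr("b", "x", perm$bird_id)
  f2 <- fit_beta_gam(perm, partition_deviance = FALSE)
  expect_equal(f1$deviance_explained, f2$deviance_explained,
               tolerance = 1e-6)
})

test_that("stronger smoothing penalties reduce effective degrees of freedom", {
  tq <- sim_trip_quality(200, 12, f_obs = season_curve, bird_sd = 0)
  tq$group <- factor(tq$group, levels = c("simulated", "observed"))
  tq$day <- as.numeric(tq$julian_day)
  low <- mgcv::gam(S ~ group + s(day, by = group, bs = "cr", k = 10),
                   family = mgcv::betar(), data = tq, sp = c(1e-4, 1e-4))
  high <- mgcv::gam(S ~ group + s(day, by = group, bs = "cr", k = 10),
                    family = mgcv::betar(), data = tq, sp = c(1e4, 1e4))
  expect_gt(as.numeric(logLik(low)), as.numeric(logLik(high)))
  expect_gt(sum(low$edf), sum(high$edf))
})

test_that("Wald year contrasts match the scalar formula and handle self-contrasts", {
  tq <- sim_trip_quality(250, 13, f_obs = season_curve,
                         years = c(2014L, 2015L, 2016L),
                         year_effects = c(0, 0.3, -0.2))
  fit <- fit_beta_gam(tq, partition_deviance = FALSE)
  yc <- wald_year_contrasts(fit)
  expect_equal(nrow(yc), 3)
  # hand recomputation for the 2015 vs 2016 pair from coef and covariance
  b <- coef(fit$gam); V <- fit$gam$Vp
  est <- b[["year_f2016"]] - b[["year_f2015"]]
  i <- match(c("year_f2015", "year_f2016"), names(b))
  v <- V[i[1], i[1]] + V[i[2], i[2]] - 2 * V[i[1], i[2]]
  row <- yc[yc$year_a == "2015" & yc$year_b == "2016", ]
  expect_equal(row$estimate, est, tolerance = 1e-12)
  expect_equal(row$chisq, est^2 / v, tolerance = 1e-10)
  expect_equal(row$p, pchisq(est^2 / v, 1, lower.tail = FALSE))
  # self-contrast: zero statistic, p = 1
  self <- wald_year_contrasts(fit, pairs = cbind("2015", "2015"))
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)
  # strong generating year effects are detected
  expect_lt(yc$p[yc$year_a == "2014" & yc$year_b == "2015"], 0.001)
})

test_that("year-contrast p-values are uniform under identical year means", {
  n_rep <- 120
  ps <- vapply(seq_len(n_rep), function(s) {
    tq <- sim_trip_quality(120, 3000 + s, f_obs = season_curve,
                           years = c(2014L, 2015L), year_effects = c(0, 0),
                           bird_sd = 0)
    fit <- fit_beta_gam(tq, random_bird = FALSE, partition_deviance = FALSE)
    wald_year_contrasts(fit)$p[1]
  }, numeric(1))
  ks <- ks_distance(ps, runif(1e5, 0, 1))
  # KS distance against uniform at alpha = 0.01
  expect_lt(ks, ks_critical(n_rep, 1e5, 0.01))
})
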