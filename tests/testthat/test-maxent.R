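# small reusable presence/background draw with a known signal in one variable
signal_data <- function(n_pres = 150, n_bg = 400, seed = 1, strength = 3) {
  set.seed(seed)
  bg <- data.frame(a = runif(n_bg), b = runif(n_bg))
  pres <- data.frame(a = rbeta(n_pres, strength, 1), b = runif(n_pres))
  list(pres = pres, bg = bg)
}

test_that("zero-penalty linear fit matches presence feature means (moment matching)", {
  d <- signal_data(seed = 2)
  fe <- maxent_features(d$bg, classes = "linear")
  m <- maxent(d$pres, d$bg, lambda = 0, features = fe, tol = 1e-12)
  Xp <- cpforage:::expand_features(fe, d$pres)
  Xb <- cpforage:::expand_features(fe, d$bg)
  expect_lt(max(abs(colMeans(Xp) - drop(m$p_background %*% Xb))), 1e-6)
})

test_that("the raw distribution over background always normalizes to one", {
  d <- signal_data(seed = 3)
  for (lam in c(0.5, 2, 10)) {
    m <- maxent(d$pres, d$bg, lambda = lam)
    expect_equal(sum(m$p_background), 1, tolerance = 1e-9)
    expect_gte(m$entropy, 0)
  }
})

test_that("an overwhelming penalty forces all weights to zero (uniform model)", {
  d <- signal_data(seed = 4)
  m <- maxent(d$pres, d$bg, lambda = 1e6)
  expect_true(all(m$beta == 0))
  expect_equal(m$entropy, log(nrow(d$bg)))
  # uniform raw distribution: cloglog closed form 1 - exp(-1) everywhere
  s <- predict(m, d$bg)
  expect_equal(s, rep(1 - exp(-1), nrow(d$bg)), tolerance = 1e-9)
})

test_that("total weight mass is nonincreasing along the regularization path", {
  d <- signal_data(seed = 5)
  fe <- maxent_features(d$bg)
  norms <- vapply(c(0.25, 1, 2, 8, 32), function(lam)
    sum(abs(maxent(d$pres, d$bg, lambda = lam, features = fe)$beta)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("cloglog suitability is bounded and increasing in raw probability", {
  d <- signal_data(seed = 6)
  m <- maxent(d$pres, d$bg, lambda = 2)
  nd <- data.frame(a = seq(0, 1, 0.01), b = 0.5)
  raw <- predict(m, nd, type = "raw")
  clog <- predict(m, nd, type = "cloglog")
  expect_true(all(clog > 0 & clog < 1))
  o <- order(raw)
  expect_true(all(diff(clog[o]) >= -1e-12))
  expect_lt(predict(m, nd[1, ], type = "cloglog") -
            (1 - exp(-exp(m$entropy) * raw[1])), 1e-12)
})

test_that("AUC equals the brute-force pairwise comparison count", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc(c(0.3, 0.5), c(0.3, 0.5)), 0.5)   # all-ties symmetry
  expect_error(auc(numeric(0), 1), "non-empty")
  set.seed(9)
  p <- sample(round(runif(40), 2)); b <- sample(round(runif(60), 2))
  brute <- mean(outer(p, b, function(u, v) (u > v) + 0.5 * (u == v)))
  expect_equal(auc(p, b), brute)
})

test_that("no-signal fits shrink toward zero and do not inflate training AUC", {
  set.seed(10)
  bg <- data.frame(a = runif(500), b = runif(500))
  pres <- data.frame(a = runif(500), b = runif(500))  # same distribution
  m <- maxent(pres, bg, lambda = 2)
  expect_lt(sum(abs(m$beta)), 0.5)
  expect_lte(auc(predict(m, pres), predict(m, bg)), 0.6)
})

test_that("cross-validation separates separable data and averages projections", {
  pres <- data.frame(a = rep(1, 40) + rnorm(40, 0, 1e-3))
  bg <- data.frame(a = rnorm(200, 0, 0.1))
  cv <- maxent_cv(pres, bg, k = 5, lambda = 0.5, seed = 1)
  expect_equal(cv$auc, rep(1, 5), tolerance = 1e-9)
  # identical fold models: averaged projection equals any single model
  pr <- predict(cv, bg)
  single <- predict(cv$models[[1]], bg)
  agree <- vapply(cv$models, function(m) max(abs(predict(m, bg) - single)),
                  numeric(1))
  if (all(agree < 1e-9)) expect_equal(pr, single, tolerance = 1e-9)
  expect_error(maxent_cv(pres[1:3, , drop = FALSE], bg, k = 10), "folds")
})

test_that("label-shuffled cross-validation AUC is statistically indistinguishable from 0.5", {
  set.seed(12)
  all_pts <- data.frame(a = runif(600), b = runif(600))
  pres <- all_pts[1:200, ]              # labels carry no information
  bg <- all_pts[201:600, ]
  cv <- maxent_cv(pres, bg, k = 10, lambda = 2, seed = 2)
  se <- cv$auc_sd / sqrt(cv$k)
  expect_lt(abs(cv$auc_mean - 0.5), 3 * max(se, 0.02))
})

test_that("percent contribution credits gain to the moving variable and sums to 100", {
  d <- signal_data(seed = 13, strength = 5)
  m <- maxent(d$pres, d$bg, lambda = 1)
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_gt(pc["a"], 90)                # only `a` carries signal
  # duplicated symmetric variables split contribution roughly evenly
  set.seed(14)
  bg2 <- data.frame(a = runif(400))
  bg2$b <- bg2$a + rnorm(400, 0, 1e-6)
  pr2 <- data.frame(a = rbeta(200, 4, 1)); pr2$b <- pr2$a + rnorm(200, 0, 1e-6)
  fe2 <- maxent_features(bg2, classes = c("linear", "quadratic"))
  m2 <- maxent(pr2, bg2, lambda = 1, features = fe2)
  pc2 <- percent_contribution(m2)
  expect_equal(sum(pc2), 100, tolerance = 1e-6)
})

test_that("permutation importance isolates the informative variable", {
  d <- signal_data(seed = 15, strength = 5)
  m <- maxent(d$pres, d$bg, lambda = 1)
  pi <- permutation_importance(m, d$pres, d$bg, seed = 1)
  expect_gt(pi["a"], 90)
  expect_lt(pi["b"], 10)
  expect_equal(sum(pi), 100, tolerance = 1e-6)
})

test_that("dominant-variable ranking is recovered across seeded refits", {
  wins <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    bg <- data.frame(a = runif(300), b = runif(300))
    # `a` strongly informative, `b` weakly
    pres <- data.frame(a = rbeta(150, 4, 1), b = rbeta(150, 1.3, 1))
    m <- maxent(pres, bg, lambda = 1)
    pi <- permutation_importance(m, pres, bg, seed = s)
    if (pi["a"] > pi["b"]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("fitted suitability recovers the generating surface on held-out points", {
  w <- tiny_world()
  pres <- sample_prey_presences(w$stacks, w$truth, 1000, seed = 31)
  pres_a <- idw_annotate(pres, w$stacks)
  bg <- sample_background(list("2014" = w$stacks), 2014, 3000, 32)
  vars <- c("sst", "chla", "sal", "bathy")
  m <- maxent(pres_a[vars], bg[vars], lambda = 2)
  held <- sample_background(list("2014" = w$stacks), 2014, 1200, 33)
  truth_s <- true_suitability(held$sst, held$chla, held$sal, held$bathy,
                              w$truth)
  expect_gte(cor(predict(m, held[vars]), truth_s, method = "spearman"), 0.8)
})

test_that("non-finite covariates are rejected", {
  d <- signal_data(seed = 16)
  d$pres$a[1] <- NA
  expect_error(maxent(d$pres, d$bg), "non-finite")
})
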