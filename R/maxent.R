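#' Feature expansion for the maximum-entropy model
#'
#' Builds the standard presence-background feature classes from the raw
#' covariates: linear, quadratic, pairwise product, and two-sided hinge
#' features with knots at background quantiles. Raw covariates are first
#' scaled to \[0, 1\] over the background sample; each derived feature is
#' then rescaled so its background values span \[0, 1\]. The expansion is a
#' pure function of the background sample and the configuration.
#'
#' @param background data.frame/matrix of background covariates (columns =
#'   variables).
#' @param classes feature classes to include (subset of "linear",
#'   "quadratic", "product", "hinge").
#' @param hinge_knots interior knots per variable and direction.
#' @return object of class `maxent_features`.
#' @export
maxent_features <- function(background,
                            classes = c("linear", "quadratic", "product", "hinge"),
                            hinge_knots = 4) {
  bg <- as.matrix(background)
  if (!all(is.finite(bg))) stop("non-finite covariate values in background")
  vars <- colnames(bg)
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(bg)))
  lo <- apply(bg, 2, min); hi <- apply(bg, 2, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  knots <- lapply(seq_along(vars), function(j) {
    u <- (bg[, j] - lo[j]) / rng[j]
    qs <- stats::quantile(u, probs = seq_len(hinge_knots) / (hinge_knots + 1),
                          names = FALSE)
    unique(qs[qs > 0 & qs < 1])
  })
  names(knots) <- vars
  fe <- structure(list(vars = vars, lo = lo, hi = hi, rng = rng,
                       classes = classes, knots = knots,
                       feat_lo = NULL, feat_rng = NULL),
                  class = "maxent_features")
  raw <- expand_features(fe, bg, rescale = FALSE)
  flo <- apply(raw, 2, min); fhi <- apply(raw, 2, max)
  fe$feat_lo <- flo
  fe$feat_rng <- pmax(fhi - flo, .Machine$double.eps)
  fe
}

# build the feature matrix; parents attribute maps features to the raw
# variable(s) they derive from (products have two parents)
expand_features <- function(fe, data, rescale = TRUE) {
  x <- as.matrix(data)[, fe$vars, drop = FALSE]
  if (!all(is.finite(x))) stop("non-finite covariate values")
  u <- sweep(sweep(x, 2, fe$lo), 2, fe$rng, "/")
  cols <- list(); nms <- character(0); parents <- list()
  add <- function(v, nm, par) {
    cols[[length(cols) + 1L]] <<- v
    nms[length(nms) + 1L] <<- nm
    parents[[length(parents) + 1L]] <<- par
  }
  nv <- length(fe$vars)
  if ("linear" %in% fe$classes)
    for (j in seq_len(nv)) add(u[, j], fe$vars[j], fe$vars[j])
  if ("quadratic" %in% fe$classes)
    for (j in seq_len(nv))
      add(u[, j]^2, paste0(fe$vars[j], "^2"), fe$vars[j])
  if ("product" %in% fe$classes && nv >= 2)
    for (j in seq_len(nv - 1)) for (l in (j + 1):nv)
      add(u[, j] * u[, l], paste0(fe$vars[j], "*", fe$vars[l]),
          c(fe$vars[j], fe$vars[l]))
  if ("hinge" %in% fe$classes)
    for (j in seq_len(nv)) for (k in fe$knots[[j]]) {
      add(pmax(0, (u[, j] - k) / (1 - k)),
          sprintf("h(%s>%.3f)", fe$vars[j], k), fe$vars[j])
      add(pmax(0, (k - u[, j]) / k),
          sprintf("h(%s<%.3f)", fe$vars[j], k), fe$vars[j])
    }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  if (rescale)
    m <- sweep(sweep(m, 2, fe$feat_lo), 2, fe$feat_rng, "/")
  attr(m, "parents") <- parents
  m
}

#' Fit a maximum-entropy presence-background model
#'
#' Minimizes the L1-regularized maxent objective
#' \deqn{-\frac{1}{n_p}\sum_{i \in pres} \beta^T f_i + \log Z(\beta)
#'   + \sum_j \pi_j |\beta_j|,}
#' where \eqn{Z(\beta) = \sum_{b \in bg} \exp(\beta^T f_b)} normalizes the
#' raw distribution over the background, by cyclic coordinate descent with
#' damped Newton steps and soft thresholding (the objective is convex, so
#' the fit is deterministic). Per-feature penalties are
#' \eqn{\pi_j = \lambda s_j / \sqrt{n_p}} with \eqn{s_j} the background SD
#' of feature j and \eqn{\lambda} the regularization multiplier.
#'
#' Objective improvements are credited per update to the updated feature's
#' parent variable (product features split evenly), giving the percent
#' contribution trace.
#'
#' @param presence,background covariate data.frames (same columns).
#' @param lambda regularization multiplier (default 2).
#' @param max_iter cap on coordinate updates (default 1e6; convergence is
#'   normally reached far earlier).
#' @param tol convergence threshold on the objective change per full sweep.
#' @param features a [maxent_features()] expansion; built from `background`
#'   when NULL.
#' @return object of class `maxent`: weights `beta`, expansion, log
#'   normalizer `logZ`, entropy `H` of the fitted background distribution,
#'   penalties, gain attribution, convergence flag.
#' @export
maxent <- function(presence, background, lambda = 2, max_iter = 1e6,
                   tol = 1e-8, features = NULL) {
  if (nrow(as.data.frame(presence)) < 1) stop("at least one presence required")
  if (lambda < 0) stop("lambda must be >= 0")
  fe <- if (is.null(features)) maxent_features(background) else features
  Xp <- expand_features(fe, presence)
  Xb <- expand_features(fe, background)
  parents <- attr(Xb, "parents")
  np <- nrow(Xp); nb <- nrow(Xb); nf <- ncol(Xb)
  pen <- lambda * apply(Xb, 2, stats::sd) / sqrt(np)
  fbar <- colMeans(Xp)

  beta <- numeric(nf)
  eta_b <- numeric(nb)
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  obj <- function() -sum(fbar * beta) + logsumexp(eta_b) + sum(pen * abs(beta))
  gain <- stats::setNames(numeric(length(fe$vars)), fe$vars)

  cur <- obj()
  it <- 0L; converged <- FALSE
  repeat {
    prev <- cur
    for (j in seq_len(nf)) {
      it <- it + 1L
      p <- exp(eta_b - logsumexp(eta_b))
      m1 <- sum(p * Xb[, j])
      h <- sum(p * Xb[, j]^2) - m1^2
      g <- m1 - fbar[j]
      h <- max(h, 1e-10)
      z <- beta[j] - g / h
      bnew <- sign(z) * max(abs(z) - pen[j] / h, 0)
      step <- bnew - beta[j]
      if (step == 0) next
      step <- sign(step) * min(abs(step), 2)  # damp long steps
      # backtracking line search on the exact objective
      for (half in 1:12) {
        bnew <- beta[j] + step
        new_eta <- eta_b + step * Xb[, j]
        new_obj <- -sum(fbar * beta) - fbar[j] * step +
          logsumexp(new_eta) + sum(pen * abs(`[<-`(beta, j, bnew)))
        if (new_obj <= cur) break
        step <- step / 2
      }
      if (new_obj <= cur) {
        beta[j] <- bnew
        eta_b <- new_eta
        drop <- cur - new_obj
        par <- parents[[j]]
        gain[par] <- gain[par] + drop / length(par)
        cur <- new_obj
      }
      if (it >= max_iter) break
    }
    if (prev - cur < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }

  lZ <- logsumexp(eta_b)
  p <- exp(eta_b - lZ)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  structure(list(beta = beta, features = fe, logZ = lZ, entropy = H,
                 penalties = pen, lambda = lambda, gain = gain,
                 p_background = p, n_presence = np, n_background = nb,
                 iterations = it, converged = converged),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("Maximum-entropy presence-background model\n"))
  cat(sprintf("  %d presences, %d background points, %d features, lambda = %g\n",
              x$n_presence, x$n_background, length(x$beta), x$lambda))
  cat(sprintf("  entropy H = %.4f, %d nonzero weights, %s after %d updates\n",
              x$entropy, sum(x$beta != 0),
              if (x$converged) "converged" else "iteration cap hit",
              x$iterations))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) {
  stats::setNames(object$beta,
                  colnames(expand_features(object$features,
                                           matrix(object$features$lo, 1,
                                                  dimnames = list(NULL, object$features$vars)))))
}

#' Predict from a maximum-entropy model
#'
#' `type = "raw"` gives the normalized raw probability
#' \eqn{e^{\beta^T f(x)}/Z}; `"cloglog"` (default) gives the complementary
#' log-log suitability \eqn{1 - \exp(-e^H p_{raw}(x))}, bounded in (0, 1)
#' and strictly increasing in the raw probability; `"link"` gives
#' \eqn{\beta^T f(x)}.
#'
#' @param object a fitted `maxent` model.
#' @param newdata covariate data.frame.
#' @param type "cloglog", "raw", or "link".
#' @param ... unused.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("cloglog", "raw", "link"), ...) {
  type <- match.arg(type)
  X <- expand_features(object$features, newdata)
  eta <- drop(X %*% object$beta)
  switch(type,
         link = eta,
         raw = exp(eta - object$logZ),
         cloglog = 1 - exp(-exp(object$entropy) * exp(eta - object$logZ)))
}

#' Rank-based AUC (Mann-Whitney estimator)
#'
#' Probability that a random presence score exceeds a random background
#' score, with ties credited 0.5.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' k-fold cross-validated maximum-entropy model
#'
#' Partitions presences into `k` seeded folds, fits on k-1 folds against
#' the full background, scores the held-out presences, and reports per-fold
#' and mean +/- SD AUC. The final projection rule is the arithmetic mean of
#' the fold models' cloglog outputs.
#'
#' @inheritParams maxent
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return object of class `maxent_cv`: fold `models`, `auc` per fold,
#'   `auc_mean`, `auc_sd`, fold assignment.
#' @export
maxent_cv <- function(presence, background, k = 10, lambda = 2, seed = 1,
                      max_iter = 1e6, tol = 1e-8) {
  presence <- as.data.frame(presence)
  n <- nrow(presence)
  if (k > n) stop("more folds than presences")
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  fe <- maxent_features(background)
  models <- vector("list", k)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    fit <- maxent(presence[folds != f, , drop = FALSE], background,
                  lambda = lambda, max_iter = max_iter, tol = tol,
                  features = fe)
    held <- predict(fit, presence[folds == f, , drop = FALSE], type = "cloglog")
    bgsc <- predict(fit, background, type = "cloglog")
    models[[f]] <- fit
    aucs[f] <- auc(held, bgsc)
  }
  structure(list(models = models, auc = aucs, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), folds = folds, k = k,
                 lambda = lambda),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated maxent model: AUC %.3f +/- %.3f\n",
              x$k, x$auc_mean, x$auc_sd))
  invisible(x)
}

#' Averaged cloglog projection of a cross-validated model
#' @param object a `maxent_cv`.
#' @param newdata covariate data.frame.
#' @param ... unused.
#' @export
predict.maxent_cv <- function(object, newdata, ...) {
  rowMeans(vapply(object$models,
                  function(m) predict(m, newdata, type = "cloglog"),
                  numeric(nrow(as.data.frame(newdata)))))
}

#' Percent contribution of each variable
#'
#' Shares out the objective (gain) improvements accumulated during fitting
#' to the raw variables and normalizes to 100%.
#'
#' @param model a fitted `maxent` model.
#' @return named percentage vector summing to 100 (all zeros, with a
#'   warning, when no gain was achieved).
#' @export
percent_contribution <- function(model) {
  g <- model$gain
  tot <- sum(g)
  if (tot <= 0) {
    warning("zero total gain: contributions undefined, returning zeros")
    return(g * 0)
  }
  100 * g / tot
}

#' Permutation importance of each variable
#'
#' For each raw variable, permutes that variable's values across the
#' evaluation points (presences and background jointly), recomputes AUC,
#' and takes `max(0, AUC - AUC_permuted)`; the drops are normalized to
#' percentages.
#'
#' @param model fitted `maxent` model.
#' @param presence,background covariate data.frames for evaluation.
#' @param seed integer seed for the permutations.
#' @return named percentage vector summing to 100 (zeros when no variable
#'   matters).
#' @export
permutation_importance <- function(model, presence, background, seed = 1) {
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  base_auc <- auc(predict(model, presence), predict(model, background))
  vars <- model$features$vars
  np <- nrow(presence)
  all_pts <- rbind(presence[vars], background[vars])
  drops <- with_seed(seed, vapply(vars, function(v) {
    perm <- all_pts
    perm[[v]] <- sample(perm[[v]])
    sc <- predict(model, perm)
    max(0, base_auc - auc(sc[seq_len(np)], sc[-seq_len(np)]))
  }, numeric(1)))
  tot <- sum(drops)
  if (tot <= 0) return(drops * 0)
  100 * drops / tot
}
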