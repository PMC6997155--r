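#' Default pipeline configuration
#'
#' Analysis settings default to the study design encoded throughout the
#' package: 200 m rediscretization, 500 m colony radius, FPT radii 100-5000
#' m in 100 m steps with 90th-percentile ARS extraction, a regularization
#' multiplier of 2 with 10-fold cross-validation and 10,000 background
#' points for the prey model, 10,000 simulated null locations, and a
#' 10-basis cubic-regression-spline additive model.
#'
#' @param ... named overrides, merged recursively into the defaults.
#' @return nested configuration list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    input = "synthetic",
    years = c(2014, 2015),
    n_birds = 8,
    n_presence = 800,
    scenario = list(),    # env_scenario() overrides
    truth = list(),       # truth_params() overrides
    preference = list(min = -3, max = 3, mid_day = 155, scale = 8),
    trajectory = list(step = 200, colony_radius = 500),
    fpt = list(radii = seq(100, 5000, by = 100), percentile = 90,
               scale_rule = "mean_profile"),
    sdm = list(lambda = 2, k_folds = 10, n_background = 10000,
               max_iter = 1e6),
    null_model = list(n = 10000),
    gam = list(k = 10)
  )
  ov <- list(...)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_in(cfg, ov), class = "run_config")
}

#' Demo configuration: a small synthetic scenario
#'
#' A compact two-year scenario (3 birds per year, alternate tracking days,
#' reduced background and null samples) sized to run the full pipeline in
#' minutes on one CPU while preserving every stage of the analysis.
#' @param ... overrides passed on to [run_config()].
#' @export
demo_config <- function(...) {
  run_config(
    n_birds = 6,
    n_presence = 600,
    scenario = list(days = seq(120, 200, by = 2)),
    sdm = list(n_background = 4000),
    null_model = list(n = 4000),
    ...
  )
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# sigmoid season-long destination preference: negative (naive, currently
# poor sites) early, strongly suitability-seeking late
make_preference <- function(p) {
  function(day) p$min + (p$max - p$min) * stats::plogis((day - p$mid_day) / p$scale)
}

validate_config <- function(cfg) {
  req <- c("input", "years", "n_birds", "trajectory", "fpt", "sdm",
           "null_model", "gam")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0)
    stop(sprintf("config is missing required field(s): %s",
                 paste(miss, collapse = ", ")))
  if (cfg$input != "synthetic" && !dir.exists(cfg$input))
    stop(sprintf("config input path does not exist: %s", cfg$input))
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes synthetic-data generation (or ingest), trip segmentation and
#' rediscretization, FPT scale selection and ARS extraction, the
#' cross-validated prey distribution model, null-point simulation and
#' suitability projection, and the trend inference, writing per-stage CSV
#' outputs, a machine-readable `summary.json`, and a run log into `outdir`.
#' A stage failure halts the run with the stage name; earlier outputs are
#' retained.
#'
#' @param config a [run_config()] (default [demo_config()]).
#' @param outdir run directory (created).
#' @param seed master seed; each stochastic stage uses a derived child seed.
#' @param until last stage to execute, one of "simulate", "trips", "fpt",
#'   "sdm", "annotate", "infer" (default: all).
#' @return invisibly, a list with every stage's main objects and the
#'   summary list.
#' @export
run_pipeline <- function(config = demo_config(), outdir = tempfile("run_"),
                         seed = 1, until = "infer") {
  stages <- c("simulate", "trips", "fpt", "sdm", "annotate", "infer")
  until <- match.arg(until, stages)
  n_stage <- match(until, stages)
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  logline("run started %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  logline("R %s, package cpforage %s", getRversion(),
          as.character(utils::packageVersion("cpforage")))
  logline("seed %d, config md5 %s", seed, unname(tools::md5sum(cfg_path)))
  summ <- list(seed = seed)
  res <- list(config = config)
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    logline("stage %s: done", name)
    out
  }

  ## -- simulate ------------------------------------------------------------
  if (config$input != "synthetic")
    stop("only synthetic input is bundled; point data ingest uses read_fixes() directly")
  sim <- stage("simulate", {
    scenario <- do.call(env_scenario, config$scenario)
    truth <- do.call(truth_params, config$truth)
    pref <- make_preference(config$preference)
    years <- config$years
    stacks <- list(); fixes <- list(); presences <- list()
    for (y in years) {
      sy <- child_seed(seed, paste0("env", y))
      stacks[[as.character(y)]] <- generate_env(scenario, truth, sy)
      fixes[[as.character(y)]] <- simulate_tracks(
        scenario, truth, config$n_birds, preference = pref,
        seed = child_seed(seed, paste0("tracks", y)),
        stacks = stacks[[as.character(y)]], year = y)
      pr <- sample_prey_presences(stacks[[as.character(y)]], truth,
                                  ceiling(config$n_presence / length(years)),
                                  seed = child_seed(seed, paste0("prey", y)))
      pr$year <- y
      presences[[as.character(y)]] <- pr
    }
    fixes_all <- do.call(rbind, fixes)
    presences_all <- do.call(rbind, presences)
    utils::write.csv(presences_all, file.path(outdir, "prey_presences.csv"),
                     row.names = FALSE)
    md <- generate_bird_metadata(config$n_birds,
                                 child_seed(seed, "metadata"))
    utils::write.csv(md, file.path(outdir, "bird_metadata.csv"),
                     row.names = FALSE)
    list(scenario = scenario, truth = truth, stacks = stacks,
         fixes = fixes_all, presences = presences_all, metadata = md,
         preference = pref)
  })
  res$sim <- sim
  summ$n_fixes <- nrow(sim$fixes)
  if (n_stage < 2) return(finish_run(res, summ, outdir, logline))

  ## -- trips ---------------------------------------------------------------
  trips <- stage("trips", {
    fx <- dedupe_fixes(sim$fixes)
    tr <- segment_trips(fx, sim$scenario$colony_xy,
                        config$trajectory$colony_radius)
    rd <- rediscretize(tr, config$trajectory$step)
    write_trips(rd, file.path(outdir, "trips.csv"))
    rd
  })
  res$trips <- trips
  summ$n_trips <- length(unique(trips$trip_id))
  if (n_stage < 3) return(finish_run(res, summ, outdir, logline))

  ## -- fpt -----------------------------------------------------------------
  fptres <- stage("fpt", {
    prof <- scale_profile(trips, config$fpt$radii)
    utils::write.csv(as.data.frame(prof),
                     file.path(outdir, "fpt_profile.csv"), row.names = FALSE)
    scl <- select_scale(prof, config$fpt$scale_rule)
    ars <- extract_ars(trips, scl, config$fpt$percentile)
    utils::write.csv(ars, file.path(outdir, "foraging_points.csv"),
                     row.names = FALSE)
    list(profile = prof, scale = scl, ars = ars)
  })
  res$fpt <- fptres
  summ$selected_scale_m <- fptres$scale
  summ$n_ars_points <- nrow(fptres$ars)
  if (n_stage < 4) return(finish_run(res, summ, outdir, logline))

  ## -- sdm -----------------------------------------------------------------
  sdm <- stage("sdm", {
    years <- config$years
    # annotate prey presences per year with that year's stacks
    ann <- list()
    for (y in years) {
      p <- sim$presences[sim$presences$year == y, , drop = FALSE]
      ann[[as.character(y)]] <- idw_annotate(p, sim$stacks[[as.character(y)]])
    }
    pres_ann <- do.call(rbind, ann)
    # uniform background over water cells and season dates
    bg <- sample_background(sim$stacks, years,
                            config$sdm$n_background,
                            child_seed(seed, "background"))
    vars <- c("sst", "chla", "sal", "bathy")
    cv <- maxent_cv(pres_ann[vars], bg[vars], k = config$sdm$k_folds,
                    lambda = config$sdm$lambda, seed = child_seed(seed, "cv"),
                    max_iter = config$sdm$max_iter)
    full <- maxent(pres_ann[vars], bg[vars], lambda = config$sdm$lambda,
                   max_iter = config$sdm$max_iter)
    imp <- data.frame(
      variable = vars,
      percent_contribution = percent_contribution(full)[vars],
      permutation_importance =
        permutation_importance(full, pres_ann[vars], bg[vars],
                               child_seed(seed, "perm"))[vars])
    utils::write.csv(imp, file.path(outdir, "variable_importance.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(fold = seq_along(cv$auc), auc = cv$auc),
                     file.path(outdir, "cv_auc.csv"), row.names = FALSE)
    list(cv = cv, full = full, importance = imp, presences = pres_ann,
         background = bg)
  })
  res$sdm <- sdm
  summ$auc_mean <- sdm$cv$auc_mean
  summ$auc_sd <- sdm$cv$auc_sd
  summ$importance <- stats::setNames(
    as.list(sdm$importance$permutation_importance), sdm$importance$variable)
  if (n_stage < 5) return(finish_run(res, summ, outdir, logline))

  ## -- annotate ------------------------------------------------------------
  annot <- stage("annotate", {
    years <- config$years
    bathy <- sim$stacks[[1]]$bathy$grids[[1]]
    nulls <- simulate_null_points(fptres$ars, sim$scenario$colony_xy,
                                  n = config$null_model$n,
                                  seed = child_seed(seed, "null"),
                                  bathy = bathy)
    obs <- fptres$ars
    obs$source <- "observed"
    pts <- rbind(obs[c("source", "bird_id", "trip_id", "timestamp", "date",
                       "year", "x", "y")],
                 nulls[c("source", "bird_id", "trip_id", "timestamp", "date",
                         "year", "x", "y")])
    ann <- list()
    for (y in years) {
      p <- pts[pts$year == y, , drop = FALSE]
      ann[[as.character(y)]] <- idw_annotate(p, sim$stacks[[as.character(y)]])
    }
    pts_ann <- do.call(rbind, ann)
    pts_ann <- project_suitability(pts_ann, sdm$cv)
    tq <- trip_mean_quality(pts_ann)
    utils::write.csv(pts_ann, file.path(outdir, "annotated_points.csv"),
                     row.names = FALSE)
    utils::write.csv(tq, file.path(outdir, "trip_quality.csv"),
                     row.names = FALSE)
    list(points = pts_ann, trip_quality = tq, nulls = nulls)
  })
  res$annotate <- annot
  summ$n_trip_quality <- nrow(annot$trip_quality)
  if (n_stage < 6) return(finish_run(res, summ, outdir, logline))

  ## -- infer ---------------------------------------------------------------
  inf <- stage("infer", {
    md <- body_condition(sim$metadata)
    trait <- fit_trait_model(annot$trip_quality, md)
    bg_fit <- fit_beta_gam(annot$trip_quality, k = config$gam$k)
    ds <- difference_smooth(bg_fit)
    yc <- if (length(config$years) > 1) wald_year_contrasts(bg_fit) else NULL
    utils::write.csv(trait$table, file.path(outdir, "trait_model.csv"),
                     row.names = FALSE)
    s <- summary(bg_fit)
    utils::write.csv(cbind(term = rownames(s$parametric), s$parametric),
                     file.path(outdir, "gam_parametric.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(term = rownames(s$smooths), s$smooths),
                     file.path(outdir, "gam_smooths.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ds),
                     file.path(outdir, "difference_smooth.csv"),
                     row.names = FALSE)
    if (!is.null(yc))
      utils::write.csv(yc, file.path(outdir, "year_contrasts.csv"),
                       row.names = FALSE)
    grDevices::pdf(file.path(outdir, "difference_smooth.pdf"), 7, 5)
    plot(ds)
    grDevices::dev.off()
    list(condition = md, trait = trait, gam = bg_fit, diff = ds,
         year_contrasts = yc)
  })
  res$infer <- inf
  summ$deviance_explained <- inf$gam$deviance_explained
  summ$fixed_effect_share <- inf$gam$fixed_effect_share
  summ$significant_fraction <- mean(inf$diff$significant)
  summ$significant_positive_fraction <-
    mean(inf$diff$significant & inf$diff$estimate > 0)
  finish_run(res, summ, outdir, logline)
}

finish_run <- function(res, summ, outdir, logline) {
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("run finished %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"))
  res$summary <- summ
  res$outdir <- outdir
  invisible(res)
}

#' Sample annotated background points uniformly over water and season
#'
#' @param stacks_by_year named list (year -> stacks as from
#'   [generate_env()]).
#' @param years years to draw from (uniformly).
#' @param n number of background points.
#' @param seed integer seed.
#' @return data.frame: `year`, `date`, `x`, `y`, and the four annotated
#'   variables (nearest-cell IDW via [idw_annotate()]).
#' @export
sample_background <- function(stacks_by_year, years, n, seed) {
  with_seed(seed, {
    g1 <- stacks_by_year[[1]]$bathy$grids[[1]]
    water <- which(g1$values < 0)
    ctr <- grid_centers(g1)
    nxy <- dim(g1$values)
    yr <- years[sample.int(length(years), n, replace = TRUE)]
    cell <- water[sample.int(length(water), n, replace = TRUE)]
    i <- (cell - 1L) %% nxy[1] + 1L
    j <- (cell - 1L) %/% nxy[1] + 1L
    x <- ctr$x[j] + stats::runif(n, -g1$cellsize / 2, g1$cellsize / 2)
    y <- ctr$y[i] + stats::runif(n, -g1$cellsize / 2, g1$cellsize / 2)
    dts <- stacks_by_year[[1]]$sst$dates
    d <- dts[sample.int(length(dts), n, replace = TRUE)]
    out <- list()
    pts <- data.frame(year = yr, date = d, x = x, y = y)
    for (y2 in unique(yr)) {
      p <- pts[pts$year == y2, , drop = FALSE]
      out[[as.character(y2)]] <- idw_annotate(p, stacks_by_year[[as.character(y2)]])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
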