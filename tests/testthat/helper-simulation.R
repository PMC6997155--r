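# Simulated trip-quality tables with known generating curves on the logit
# scale: observed-group trips carry bird random intercepts, the simulated
# (null) group shares the pseudo-id "sim", responses are beta-distributed
# around the link-inverse mean with precision phi.
sim_trip_quality <- function(n_per_group, seed, f_obs, f_sim = f_obs,
                             phi = 30, n_birds = 15, bird_sd = 0.2,
                             years = 2014L, year_effects = 0,
                             days = 120:200) {
  set.seed(seed)
  n <- 2L * n_per_group
  day <- days[sample.int(length(days), n, TRUE)]
  grp <- rep(c("observed", "simulated"), each = n_per_group)
  bird <- ifelse(grp == "observed",
                 sprintf("b%02d", sample(n_birds, n, TRUE)), "sim")
  yr <- years[sample.int(length(years), n, TRUE)]
  ye <- stats::setNames(rep_len(year_effects, length(years)),
                        as.character(years))
  re <- stats::setNames(rnorm(n_birds, 0, bird_sd),
                        sprintf("b%02d", seq_len(n_birds)))
  eta <- ifelse(grp == "observed", f_obs(day), f_sim(day)) +
    ifelse(grp == "observed", re[bird], 0) + ye[as.character(yr)]
  mu <- plogis(eta)
  S <- rbeta(n, mu * phi, (1 - mu) * phi)
  S <- pmin(pmax(S, 1e-6), 1 - 1e-6)
  data.frame(group = grp, year = yr, julian_day = day, bird_id = bird,
             trip_id = paste0("t", seq_len(n)), S = S)
}

# a gently S-shaped seasonal curve on the link scale
season_curve <- function(day) -0.5 + 1.5 * plogis((day - 160) / 10)
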