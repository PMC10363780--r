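# End-to-end orchestration: simulate (or accept) collar data, segment
# rest phases, detect relocations, cluster resting sites, evaluate
# landscape covariates, and fit the three model families - with one
# config object and a summary that is recomputable from the stage tables.

#' Default pipeline configuration
#'
#' @param seed Optional integer seed applied at the start of
#'   [run_pipeline()].
#' @param simulate A [sim_config()] used when no study is supplied.
#' @param segmentation A [seg_params()].
#' @param relocation A [reloc_params()].
#' @param cluster_cutoff_m Resting-site dendrogram cut (default 50).
#' @param calendar A [hunting_calendar()].
#' @param n_avail_per_used Availability ratio for the RSF (default 1000).
#' @param cv A [cv_config()].
#' @param run_cv Whether to run the Boyce cross-validation (default TRUE).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = NULL, simulate = sim_config(),
                           segmentation = seg_params(),
                           relocation = reloc_params(),
                           cluster_cutoff_m = 50,
                           calendar = hunting_calendar(),
                           n_avail_per_used = 1000, cv = cv_config(),
                           run_cv = TRUE) {
  list(seed = seed, simulate = simulate, segmentation = segmentation,
       relocation = relocation, cluster_cutoff_m = cluster_cutoff_m,
       calendar = calendar, n_avail_per_used = n_avail_per_used, cv = cv,
       run_cv = run_cv)
}

#' Run the full resting-strategy pipeline
#'
#' Stages: (simulate) -> segment inactive phases -> detect relocations ->
#' daily resting locations -> cluster resting sites -> landscape
#' covariates -> seasonal RSF + selection ratios + Boyce CV -> seasonal
#' revisitation models -> relocation probability and distance models ->
#' summary statistics. Any stage failure propagates with its own error;
#' completed stage outputs are all returned.
#'
#' @param config [default_config()] output.
#' @param study Optional [sim_study()] result (or a compatible list with
#'   `act`, `gps`, `records`, `landscape`, `villages`); simulated from
#'   `config$simulate` when `NULL`.
#' @return Object of class `restsel_pipeline`: stage tables, fitted
#'   models, and a `summary` list.
#' @export
run_pipeline <- function(config = default_config(), study = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(study)) study <- sim_study(config$simulate)
  scape <- study$landscape
  villages <- study$villages
  roads_f <- suppressMessages(filter_roads(scape$roads))
  cov_fun <- function(px, py)
    landscape_covariates(px, py, villages, roads_f, scape$vegetation)
  ctr <- colMeans(study$gps[, c("x", "y")])
  proj <- if (!is.null(study$config$proj)) study$config$proj else lcc_projection()
  ll <- lcc_unproject(ctr[1], ctr[2], proj)
  lat <- ll[1, "lat"]; lon <- ll[1, "lon"]

  gap_days <- flag_gap_days(study$act, nominal_s = 300)
  phases <- extract_inactive_phases(study$act, lat, lon, config$segmentation,
                                    gap_days)
  events <- detect_relocations(phases, study$act, study$gps, config$relocation,
                               config$calendar)
  locations <- daily_resting_locations(phases, study$gps, events)
  locations <- cluster_resting_sites(locations, config$cluster_cutoff_m)
  sites <- summarise_sites(locations, config$calendar)
  sites <- cbind(sites, cov_fun(sites$x, sites$y))

  # home ranges from active-phase (outside inactive phase) fixes
  in_phase <- rep(FALSE, nrow(study$gps))
  for (i in seq_len(nrow(phases))) {
    sel <- study$gps$animal_id == phases$animal_id[i] &
      study$gps$timestamp >= phases$start[i] &
      study$gps$timestamp < phases$end[i]
    in_phase[sel] <- TRUE
  }
  active_fixes <- study$gps[!in_phase, , drop = FALSE]
  home_ranges <- lapply(split(active_fixes, active_fixes$animal_id),
                        function(g) home_range_kde(g$x, g$y))

  study_sites <- stats::setNames(as.character(study$records$study_site),
                                 study$records$animal_id)
  seasonal <- list()
  for (season in c("NHS", "HS")) {
    res <- tryCatch({
      rsf <- build_rsf_dataset(sites, home_ranges, season, cov_fun,
                               config$n_avail_per_used, study_sites)
      fit <- fit_rsf(rsf)
      cv <- if (isTRUE(config$run_cv)) boyce_cv(rsf, config$cv) else NULL
      rev_rows <- build_revisit_dataset(sites, study$records, season)
      rev_fit <- fit_revisitation(rev_rows)
      list(rsf_data = rsf, rsf_fit = fit, cv = cv,
           revisit_data = rev_rows, revisit_fit = rev_fit,
           revisit_r2 = marginal_r2(rev_fit))
    }, error = function(e) {
      warning(sprintf("seasonal models (%s) failed: %s", season, conditionMessage(e)))
      NULL
    })
    seasonal[season] <- list(res)  # keep a NULL slot if the season failed
  }

  reloc_rows <- build_relocation_dataset(phases, events, locations, cov_fun,
                                         study$records, config$calendar)
  reloc_fit <- fit_relocation(reloc_rows)
  reloc_prob <- relocation_probability_by_season(reloc_fit)
  dist_fit <- if (sum(reloc_rows$relocated) >= 10)
    fit_relocation_distance(reloc_rows) else NULL

  timing <- phase_timing_stats(phases, lat, lon)
  summary <- list(
    n_animals = length(unique(study$records$animal_id)),
    n_phases = nrow(phases), n_events = nrow(events),
    n_sites = nrow(sites),
    inactive_time_fraction = inactive_time_fraction(phases),
    timing = timing,
    revisited_fraction = revisited_fraction(sites),
    relocation = relocation_summary(events, phases, config$calendar),
    relocation_prob_model = reloc_prob,
    cv = lapply(seasonal, function(s) if (!is.null(s$cv)) s$cv[c("mean", "se")]))
  structure(list(config = config, study = study, phases = phases,
                 events = events, locations = locations, sites = sites,
                 home_ranges = home_ranges, seasonal = seasonal,
                 relocation_data = reloc_rows, relocation_fit = reloc_fit,
                 relocation_prob = reloc_prob,
                 relocation_distance_fit = dist_fit, summary = summary),
            class = "restsel_pipeline")
}

#' @export
print.restsel_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Resting-strategy pipeline: %d animals, %d phases, %d sites\n",
              s$n_animals, s$n_phases, s$n_sites))
  cat(sprintf("  time in inactive phase: %.1f%%\n",
              100 * s$inactive_time_fraction))
  cat(sprintf("  phase end within 30/90 min of sunset: %.0f%% / %.0f%%\n",
              100 * s$timing$frac_end_near_sunset[1],
              100 * s$timing$frac_end_near_sunset[2]))
  cat(sprintf("  phase start within 30/90 min of sunrise: %.0f%% / %.0f%%\n",
              100 * s$timing$frac_start_near_sunrise[1],
              100 * s$timing$frac_start_near_sunrise[2]))
  cat(sprintf("  sites revisited more than once: %.0f%%\n",
              100 * s$revisited_fraction))
  cat("  relocation probability by season (raw):\n")
  print(s$relocation[, c("season", "n_phases", "n_relocated", "p_relocation")],
        row.names = FALSE)
  invisible(x)
}
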